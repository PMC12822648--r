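#' Generative (ground-truth) parameters for the synthetic cohort
#'
#' Population-level parameters of the forward model. Each simulated voxel
#' carries a nonnegative responsiveness gain; shape-selective pattern
#' vectors are scaled by that gain, so that voxels ranking high on the
#' localizer statistic also tend to carry more shape information (the
#' coupling implicitly assumed by localizer-based voxel ranking).
#' Congruency acts multiplicatively on the shape-pattern amplitude, with
#' per-ROI gains so that a congruency effect can be confined to one region;
#' incongruent object reappearance additionally adds a spatially uniform
#' "surprise" amplitude. In Experiment 2 the occluded final period carries
#' the expected-shape pattern scaled by `occluded_signal_gain`, sharing
#' pattern geometry with the visible-object benchmark, on top of the
#' visible-background pattern.
#'
#' Noise is AR(1) Gaussian per voxel with marginal standard deviation
#' `noise_sigma`; white noise is the `ar1_rho = 0` special case.
#'
#' @param experiment 1 or 2.
#' @param ... overrides for any field: `noise_sigma`, `ar1_rho`,
#'   `roi_amp` (named per-ROI pattern amplitude), `conf_amp` (background
#'   confound amplitude relative to shape patterns), `gain_congruent`,
#'   `gain_incongruent` (scalars or named per-ROI vectors),
#'   `surprise_amplitude`, `occluded_signal_gain`, `loc_scale`,
#'   `loc_noise_sd` (localizer t-statistic construction),
#'   `subject_gain_sd` (between-subject SD of the gains),
#'   `responsiveness_shape` (gamma shape of the responsiveness gains).
#' @return object of class `truth_params`.
#' @export
truth_params <- function(experiment = 1, ...) {
  p <- list(experiment = as.integer(experiment),
            noise_sigma = 100,
            ar1_rho = 0.3,
            roi_amp = c(EVC = 1, LVC = 0.7),
            conf_amp = 0.5,
            gain_congruent = c(EVC = 1.09, LVC = 1.0),
            gain_incongruent = c(EVC = 0.92, LVC = 1.0),
            surprise_amplitude = 0.5,
            occluded_signal_gain = c(EVC = 0.095, LVC = 0.155),
            loc_scale = 5,
            loc_noise_sd = 1,
            subject_gain_sd = 0.05,
            responsiveness_shape = 6)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown))
    stop("unknown truth parameter(s): ", paste(unknown, collapse = ", "))
  p <- modifyList(p, dots)
  stopifnot(p$noise_sigma >= 0, p$ar1_rho >= 0, p$ar1_rho < 1,
            all(p$gain_congruent >= 0), all(p$gain_incongruent >= 0),
            p$conf_amp >= 0, p$occluded_signal_gain >= 0)
  class(p) <- "truth_params"
  p
}

roi_value <- function(x, roi) {
  # scalar or named per-ROI parameter, evaluated per voxel
  if (is.null(names(x))) rep(unname(x)[1], length(roi))
  else ifelse(roi %in% names(x), unname(x[roi]), unname(x)[1])
}

block_coords <- function(n, block_index) {
  side <- ceiling(n^(1 / 3))
  g <- expand.grid(x = seq_len(side), y = seq_len(side), z = seq_len(side))
  g <- g[seq_len(n), , drop = FALSE]
  g$x <- g$x + (block_index - 1L) * (side + 4L)
  as.matrix(g)
}

#' Draw one subject's ground truth
#'
#' Samples the voxel-level generative state of one simulated participant:
#' ROI/hemisphere labels with 3D grid coordinates, gamma-distributed
#' responsiveness gains, shape and background-confound pattern vectors
#' scaled by responsiveness, a synthetic localizer t-statistic
#' (responsiveness plus independent noise), and subject-level congruency /
#' surprise / occlusion gains jittered around the population values.
#'
#' @param params a [design_params()] object.
#' @param truth a [truth_params()] object.
#' @param seed integer seed.
#' @param voxels_per_roi named integer vector: voxels per ROI per
#'   hemisphere (e.g. `c(EVC = 1500, LVC = 1500)`).
#' @param n_other additional non-visual voxels (for whole-brain maps).
#' @return object of class `subject_truth`.
#' @export
make_subject <- function(params, truth, seed,
                         voxels_per_roi = c(EVC = 1500, LVC = 1500),
                         n_other = 0) {
  stopifnot(inherits(truth, "truth_params"), all(voxels_per_roi >= 1))
  rois <- names(voxels_per_roi)
  blocks <- list()
  bi <- 0L
  for (r in rois) for (h in c("L", "R")) {
    bi <- bi + 1L
    n <- voxels_per_roi[[r]]
    blocks[[bi]] <- data.frame(roi = r, hemisphere = h,
                               block_coords(n, bi))
  }
  if (n_other > 0) {
    bi <- bi + 1L
    blocks[[bi]] <- data.frame(roi = "other", hemisphere = NA_character_,
                               block_coords(n_other, bi))
  }
  meta <- do.call(rbind, blocks)
  rownames(meta) <- NULL
  nv <- nrow(meta)
  visual <- meta$roi != "other"

  with_seed(derive_seed(seed, 7), {
    g <- rgamma(nv, shape = truth$responsiveness_shape,
                rate = truth$responsiveness_shape)
    amp <- roi_value(truth$roi_amp, meta$roi) * as.numeric(visual)
    pattern_wide <- rnorm(nv) * g * amp
    repeat {
      pattern_narrow <- rnorm(nv) * g * amp
      cc <- suppressWarnings(cor(pattern_wide[visual],
                                 pattern_narrow[visual]))
      if (!any(visual) || is.na(cc) || abs(cc) < 0.9) break
    }
    pattern_bg30 <- rnorm(nv) * g * amp * truth$conf_amp
    pattern_bg90 <- rnorm(nv) * g * amp * truth$conf_amp
    meta$localizer_t <- ifelse(visual,
                               truth$loc_scale * g +
                                 rnorm(nv, 0, truth$loc_noise_sd),
                               rnorm(nv, 0, truth$loc_noise_sd))
    # first argument keeps names through pmax
    jitter_gain <- function(x) pmax(x + rnorm(length(x), 0,
                                              truth$subject_gain_sd), 0)
    gain_congruent <- jitter_gain(truth$gain_congruent)
    gain_incongruent <- jitter_gain(truth$gain_incongruent)
    surprise_amplitude <- jitter_gain(truth$surprise_amplitude)
    occluded_signal_gain <- jitter_gain(truth$occluded_signal_gain)
  })

  structure(list(voxel_meta = meta, responsiveness = g,
                 pattern_wide = pattern_wide,
                 pattern_narrow = pattern_narrow,
                 pattern_bg30 = pattern_bg30,
                 pattern_bg90 = pattern_bg90,
                 gain_congruent = gain_congruent,
                 gain_incongruent = gain_incongruent,
                 surprise_amplitude = surprise_amplitude,
                 occluded_signal_gain = occluded_signal_gain,
                 noise_sigma = truth$noise_sigma,
                 ar1_rho = truth$ar1_rho,
                 experiment = truth$experiment,
                 seed = seed),
            class = "subject_truth")
}

shape_pattern <- function(truth, shape) {
  switch(shape,
         wide = truth$pattern_wide,
         narrow = truth$pattern_narrow,
         stop("unknown shape label: ", shape))
}

bg_pattern <- function(truth, background) {
  switch(as.character(background),
         "30" = truth$pattern_bg30,
         "90" = truth$pattern_bg90,
         none = 0,
         "NA" = 0,
         0)
}

# True amplitude (voxel vector) of one simulation regressor, from the label
# metadata of its events.
true_amplitude <- function(truth, lab, run_type) {
  meta <- truth$voxel_meta
  nv <- nrow(meta)
  if (run_type == "localizer") {
    cat_amp <- switch(lab$condition, objects = 1, scrambled = 1,
                      faces = 0.3, scenes = 0.6, 0)
    return(truth$responsiveness * cat_amp *
             as.numeric(meta$roi != "other"))
  }
  if (run_type == "training") {
    base <- shape_pattern(truth, lab$shape)
    return(base + bg_pattern(truth, lab$background))
  }
  # main-task runs
  if (truth$experiment == 1) {
    gains <- if (identical(lab$congruency, "congruent"))
      truth$gain_congruent else truth$gain_incongruent
    gv <- roi_value(gains, meta$roi)
    amp <- gv * (shape_pattern(truth, lab$shape) +
                   bg_pattern(truth, lab$background))
    if (identical(lab$congruency, "incongruent"))
      amp <- amp + truth$surprise_amplitude
    return(amp)
  }
  # experiment 2 main task
  if (startsWith(lab$sim_label, "occl.")) {
    gv <- roi_value(truth$occluded_signal_gain, meta$roi)
    return(gv * shape_pattern(truth, lab$shape) +
             bg_pattern(truth, lab$background))
  }
  if (startsWith(lab$sim_label, "reapp.")) {
    return(shape_pattern(truth, lab$shape) +
             bg_pattern(truth, lab$background))
  }
  rep(0, nv)
}
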
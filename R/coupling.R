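#' Per-voxel condition-wise FIR activation time courses
#'
#' Averages the FIR beta estimates across runs, per condition and time bin,
#' yielding each voxel's post-onset activation curve under each condition.
#'
#' @param fir_runs list of FIR `beta_maps`, one per run, with identical
#'   label structure (error if runs are missing or inconsistent).
#' @param condition_col label column defining the conditions (default
#'   `congruency`; rows sharing a condition, e.g. the two shapes, are
#'   averaged together).
#' @return list with `conditions` (named list of bins x voxels matrices)
#'   and `bins` (0-based bin indices).
#' @export
voxel_timecourses <- function(fir_runs, condition_col = "congruency") {
  if (!length(fir_runs)) stop("missing run: no FIR estimates supplied")
  ref <- fir_runs[[1]]$labels
  for (b in fir_runs)
    if (!identical(dim(b$estimates), dim(fir_runs[[1]]$estimates)))
      stop("missing run: FIR estimates are inconsistent across runs")
  bins <- sort(unique(ref$bin))
  conds <- sort(unique(ref[[condition_col]]))
  nv <- ncol(fir_runs[[1]]$estimates)
  out <- lapply(conds, function(cond) {
    mat <- matrix(NA_real_, length(bins), nv)
    for (bi in seq_along(bins)) {
      rows <- which(ref[[condition_col]] == cond & ref$bin == bins[bi])
      per_run <- lapply(fir_runs, function(b)
        colMeans(b$estimates[rows, , drop = FALSE]))
      mat[bi, ] <- Reduce(`+`, per_run) / length(per_run)
    }
    mat
  })
  names(out) <- conds
  list(conditions = out, bins = bins)
}

#' Correlate voxel activation curves with a seed information curve
#'
#' Pearson correlation, across post-onset time bins, between the seed
#' region's time-resolved classifier-information curve and every voxel's
#' activation curve, per condition. Degenerate (zero-variance) voxels or
#' seeds contribute r = 0 and are flagged, keeping map geometry fixed
#' across subjects.
#'
#' @param seed_curves named list (per condition) of numeric seed curves.
#' @param voxel_curves output of [voxel_timecourses()].
#' @return object of class `coupling_maps`: list with `r` (named list of
#'   per-voxel correlation vectors) and `flagged` (logical list).
#' @export
coupling_maps <- function(seed_curves, voxel_curves) {
  conds <- names(seed_curves)
  stopifnot(all(conds %in% names(voxel_curves$conditions)))
  out <- list()
  flags <- list()
  for (cond in conds) {
    s <- as.numeric(seed_curves[[cond]])
    V <- voxel_curves$conditions[[cond]]
    if (length(s) < 3) stop("need at least 3 time bins for coupling")
    if (length(s) != nrow(V)) stop("bin counts differ between seed and voxels")
    sc <- s - mean(s)
    ss <- sqrt(sum(sc^2))
    Vc <- sweep(V, 2, colMeans(V))
    vs <- sqrt(colSums(Vc^2))
    bad <- unname(vs == 0 | ss == 0)
    denom <- ss * ifelse(bad, 1, unname(vs))
    r <- as.numeric(crossprod(sc, Vc)) / denom
    r[bad] <- 0
    out[[cond]] <- unname(r)
    flags[[cond]] <- bad
  }
  structure(list(r = out, flagged = flags), class = "coupling_maps")
}

#' Information-activation coupling for one subject
#'
#' For each seed-size setting, selects the top-N seed-region voxels across
#' both hemispheres by localizer ranking, computes the time-resolved
#' classifier-information curve via [time_resolved_decode()], correlates it
#' with every voxel's FIR activation curve per condition, and finally
#' averages the correlation maps across the settings.
#'
#' @param train stacked training betas with `shape` labels.
#' @param fir_runs list of per-run FIR `beta_maps` covering all voxels.
#' @param voxel_meta voxel metadata with `roi`, `hemisphere`, `localizer_t`.
#' @param seed_roi ROI supplying the seed voxels (default `"EVC"`).
#' @param voxel_count_settings seed sizes averaged over (default 500-1000
#'   in steps of 100).
#' @param n_bins FIR bins.
#' @param cost SVM regularization constant.
#' @return a `coupling_maps` object (averaged over settings), with the
#'   per-condition seed curves of the largest setting attached as
#'   attribute `seed_curves`.
#' @export
coupling_pipeline <- function(train, fir_runs, voxel_meta,
                              seed_roi = "EVC",
                              voxel_count_settings = seq(500, 1000, 100),
                              n_bins = 10, cost = 1) {
  idx <- which(voxel_meta$roi == seed_roi)
  if (!length(idx)) stop("no voxels in seed ROI ", seed_roi)
  ord <- idx[order(-voxel_meta$localizer_t[idx], idx)]
  if (max(voxel_count_settings) > length(ord))
    warning("seed setting ", max(voxel_count_settings),
            " exceeds available ", seed_roi, " voxels (", length(ord),
            "); truncating")
  vox_curves <- voxel_timecourses(fir_runs)
  fir <- stack_betas(fir_runs)
  acc <- NULL
  last_info <- NULL
  for (N in voxel_count_settings) {
    vox <- ord[seq_len(min(N, length(ord)))]
    info <- time_resolved_decode(train, fir, vox, n_bins = n_bins,
                                 cost = cost)
    seed_curves <- split(info$info, info$condition)
    seed_curves <- lapply(seed_curves, function(x) x) # keep bin order
    cm <- coupling_maps(seed_curves, vox_curves)
    acc <- if (is.null(acc)) cm$r
    else Map(`+`, acc, cm$r)
    last_info <- seed_curves
  }
  r <- lapply(acc, function(x) x / length(voxel_count_settings))
  structure(list(r = r,
                 flagged = lapply(r, function(x) rep(FALSE, length(x)))),
            class = "coupling_maps",
            seed_curves = last_info,
            settings = voxel_count_settings)
}

#' Group contrast of condition-wise coupling maps
#'
#' Per-voxel paired t (congruent minus incongruent) across subjects,
#' one-sided by default, thresholded and clustered exactly like the
#' univariate whole-brain contrast.
#'
#' @param maps_list list of per-subject `coupling_maps` with conditions
#'   `congruent` and `incongruent`.
#' @param coords voxel grid coordinates (voxels x 3).
#' @param alpha,cluster_min see [whole_brain_contrast()].
#' @param fisher_z if `TRUE`, correlations are variance-stabilized with
#'   `atanh` before the group test.
#' @return a `cluster_result` object.
#' @export
coupling_contrast <- function(maps_list, coords, alpha = 0.001,
                              cluster_min = 10, fisher_z = FALSE) {
  if (length(maps_list) < 3) stop("need at least 3 subjects")
  diffs <- t(vapply(maps_list, function(m) {
    a <- m$r$congruent
    b <- m$r$incongruent
    if (fisher_z) {
      a <- atanh(pmin(pmax(a, -0.999999), 0.999999))
      b <- atanh(pmin(pmax(b, -0.999999), 0.999999))
    }
    a - b
  }, numeric(length(maps_list[[1]]$r$congruent))))
  whole_brain_contrast(diffs, coords, alpha = alpha,
                       cluster_min = cluster_min, sided = "greater")
}
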
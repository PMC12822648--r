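#' Simulate one run of voxel time series
#'
#' Forward model: the event train of each simulation regressor is convolved
#' with the canonical HRF (impulses for brief reappearance events, boxcars
#' for mini-blocks and occluded periods) and scaled by the subject's true
#' per-voxel amplitude for that regressor; AR(1) Gaussian noise with
#' marginal SD `noise_sigma` and lag-1 autocorrelation `ar1_rho` is added
#' per voxel. The convolution path is shared with [build_design_matrix()],
#' so fitting the matching GLM to a noiseless run recovers the injected
#' amplitudes exactly (up to numerical precision).
#'
#' @param events one event table from [make_design()].
#' @param truth a [make_subject()] ground truth.
#' @param seed integer seed for the noise stream.
#' @return object of class `voxel_timeseries`: list with `data` (volumes x
#'   voxels), `tr_seconds`, `voxel_meta`, the simulation `design`, and
#'   `events`.
#' @export
simulate_run <- function(events, truth, seed) {
  stopifnot(inherits(truth, "subject_truth"))
  run_type <- attr(events, "run_type")
  dm <- build_design_matrix(events, basis = "canonical",
                            condition_by = "sim_label")
  task <- dm$labels$kind == "task"
  labs <- dm$labels[task, , drop = FALSE]
  nv <- nrow(truth$voxel_meta)
  B <- matrix(0, sum(task), nv)
  for (i in seq_len(nrow(labs)))
    B[i, ] <- true_amplitude(truth, labs[i, ], run_type)
  Y <- dm$X[, task, drop = FALSE] %*% B
  if (truth$noise_sigma > 0)
    Y <- Y + noise_ar1_cpp(nrow(Y), nv, truth$noise_sigma, truth$ar1_rho,
                           derive_seed(seed, 11))
  structure(list(data = Y, tr_seconds = dm$tr_seconds,
                 voxel_meta = truth$voxel_meta, design = dm,
                 events = events),
            class = "voxel_timeseries")
}

#' Simulate all runs of one subject
#'
#' @param design an [make_design()] object.
#' @param truth a [make_subject()] ground truth.
#' @param seed integer seed; each run receives a derived child seed.
#' @param types which run types to simulate.
#' @return list with one element per requested type, each a list of
#'   `voxel_timeseries`.
#' @export
simulate_subject_runs <- function(design, truth, seed,
                                  types = c("main", "training")) {
  out <- list()
  type_id <- c(main = 1L, training = 2L, localizer = 3L)
  for (tp in types) {
    out[[tp]] <- lapply(seq_along(design[[tp]]), function(r)
      simulate_run(design[[tp]][[r]], truth,
                   derive_seed(seed, type_id[[tp]], r)))
  }
  out
}

#' Simulate a cohort of independent subjects
#'
#' Each subject receives an independently randomized design (trial orders,
#' splits, catch placement), freshly drawn ground truth, and independent
#' noise, all reproducible from the single base seed through the
#' hierarchical seed split (cohort -> subject -> run).
#'
#' @param params [design_params()].
#' @param tparams [truth_params()].
#' @param n_subjects number of simulated participants (>= 2).
#' @param seed integer base seed.
#' @param voxels_per_roi,n_other passed to [make_subject()].
#' @param include_data if `FALSE`, only designs and ground truths are
#'   returned (run data can be regenerated deterministically).
#' @param types run types to simulate when `include_data` is `TRUE`.
#' @return object of class `mvpa_cohort`: list of subjects, each with
#'   `design`, `truth`, `seed`, and (optionally) `runs`.
#' @export
simulate_cohort <- function(params, tparams, n_subjects, seed,
                            voxels_per_roi = c(EVC = 1500, LVC = 1500),
                            n_other = 0, include_data = TRUE,
                            types = c("main", "training")) {
  stopifnot(n_subjects >= 2)
  subjects <- lapply(seq_len(n_subjects), function(s) {
    ss <- derive_seed(seed, 100, s)
    design <- make_design(params, derive_seed(ss, 1))
    truth <- make_subject(params, tparams, derive_seed(ss, 2),
                          voxels_per_roi, n_other)
    sub <- list(design = design, truth = truth, seed = ss)
    if (include_data)
      sub$runs <- simulate_subject_runs(design, truth, derive_seed(ss, 3),
                                        types)
    sub
  })
  structure(list(subjects = subjects, params = params, tparams = tparams,
                 seed = seed), class = "mvpa_cohort")
}

#' Simulate end-of-run reappearance-count reports
#'
#' Experiment 2 participants report, after each run, how many times the
#' object reappeared. The simulated report equals the true count plus
#' rounded Gaussian noise scaled by the subject's (in)attention, truncated
#' at zero; the run-wise correlation between true and reported counts
#' supports the interquartile-range exclusion rule.
#'
#' @param design an Experiment 2 [make_design()] object with catch trials.
#' @param attention nonnegative noise SD (0 = perfectly attentive).
#' @param seed integer seed.
#' @return data.frame with `run`, `true_count`, `reported_count`.
#' @export
simulate_reports <- function(design, attention, seed) {
  params <- design$params
  if (params$experiment != 2 || params$catch_fraction <= 0)
    stop("unsupported design: reappearance reports require an ",
         "Experiment 2 design with catch trials")
  true_count <- vapply(design$main, function(ev)
    sum(ev$catch & ev$duration > 0), integer(1))
  reported <- with_seed(seed, {
    pmax(0L, true_count + as.integer(round(rnorm(length(true_count),
                                                 0, attention))))
  })
  data.frame(run = seq_along(true_count), true_count = true_count,
             reported_count = reported)
}
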
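# Reduced designs used throughout the unit tests: same structure as the
# full experiments (balanced cells, splits, catch trials) at a fraction of
# the runtime.

tiny_params1 <- function(...) {
  design_params(1, n_runs_main = 2, trials_per_run = 16,
                miniblocks_per_training_run = 8,
                miniblocks_per_localizer_run = 8,
                run_length_volumes = c(main = 160, training = 150,
                                       localizer = 180), ...)
}

tiny_params2 <- function(...) {
  design_params(2, n_runs_main = 4, trials_per_run = 16,
                miniblocks_per_training_run = 16,
                miniblocks_per_localizer_run = 8,
                catch_range = c(1L, 4L),
                run_length_volumes = c(main = 160, training = 160,
                                       localizer = 180), ...)
}

tiny_truth <- function(experiment = 1, ...) {
  args <- list(...)
  if (!"noise_sigma" %in% names(args)) args$noise_sigma <- 30
  do.call(truth_params, c(list(experiment), args))
}

tiny_subject <- function(params, truth, seed = 1,
                         voxels_per_roi = c(EVC = 40, LVC = 40),
                         n_other = 0) {
  make_subject(params, truth, seed, voxels_per_roi, n_other)
}

# simulate, fit and stack the training and main-task betas of one subject
tiny_exp1_betas <- function(seed = 1, truth = tiny_truth(1), params = NULL) {
  if (is.null(params)) params <- tiny_params1()
  design <- make_design(params, derive_seed(seed, 1))
  tr <- tiny_subject(params, truth, derive_seed(seed, 2))
  train <- stack_betas(lapply(seq_along(design$training), function(r) {
    vts <- simulate_run(design$training[[r]], tr, derive_seed(seed, 3, r))
    fit_glm(vts, vts$design)
  }))
  main <- stack_betas(lapply(seq_along(design$main), function(r) {
    vts <- simulate_run(design$main[[r]], tr, derive_seed(seed, 4, r))
    fit_glm(vts, vts$design)
  }))
  list(design = design, truth = tr, train = train, main = main)
}

tiny_subrois <- function(truth, counts = c(10, 20, 40)) {
  make_subrois(truth$voxel_meta$localizer_t, truth$voxel_meta,
               counts = counts)
}

# minimal hand-built beta_maps object (for oracle tests)
fake_betas <- function(est, regressor, ...) {
  labels <- data.frame(regressor = regressor, kind = "task", ...)
  structure(list(estimates = est, labels = labels,
                 nuisance_estimates = NULL, flags = character(0)),
            class = "beta_maps")
}
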
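test_that("canonical HRF has unit peak near 5 s and an undershoot", {
  h <- canonical_hrf(0.01, 32)
  expect_equal(max(h), 1)
  expect_equal((which.max(h) - 1) * 0.01, 5, tolerance = 0.05)
  expect_lt(min(h[h != 0]), 0)
  # undershoot follows the peak
  expect_gt(which.min(h), which.max(h))
})

test_that("Experiment 1 main-task design has 16 task columns plus nuisance", {
  ev <- make_design(design_params(1), 2)$main[[1]]
  dm <- build_design_matrix(ev)
  expect_equal(dm$n_task, 16) # 4 conditions x (3 congruent splits + 1)
  expect_equal(nrow(dm$X), 404)
  expect_equal(sum(dm$labels$kind == "nuisance"), 1) # run intercept
  expect_false(any(duplicated(dm$labels$column)))
})

test_that("FIR basis yields one 0/1 stick column per bin per condition", {
  ev <- make_design(tiny_params1(), 3)$main[[1]]
  dm <- build_design_matrix(ev, basis = "fir", condition_by = "fir_label",
                            n_fir_bins = 10)
  task <- dm$labels$kind == "task"
  expect_equal(sum(task), 4 * 10) # shape x congruency conditions
  X <- dm$X[, task]
  expect_true(all(X %in% c(0, 1)))
  expect_equal(sort(unique(dm$labels$bin[task])), 0:9)
})

test_that("empty event tables produce a nuisance-only design", {
  ev <- make_design(tiny_params1(), 3)$main[[1]]
  dm <- build_design_matrix(ev[0, ], n_volumes = 50, tr_seconds = 1)
  expect_equal(dm$n_task, 0)
  expect_equal(ncol(dm$X), 1)
})

test_that("noiseless GLM recovers injected amplitudes through the HRF", {
  p <- tiny_params1()
  tr <- tiny_subject(p, tiny_truth(1, noise_sigma = 0), 4)
  for (run_type in c("main", "training")) {
    ev <- make_design(p, 9)[[run_type]][[1]]
    vts <- simulate_run(ev, tr, 1)
    b <- fit_glm(vts, vts$design)
    for (i in seq_len(nrow(b$labels))) {
      tru <- mvpainfo:::true_amplitude(tr, b$labels[i, ], run_type)
      expect_lt(max(abs(b$estimates[i, ] - tru)), 1e-8)
    }
  }
})

test_that("orthonormal designs reduce OLS to a projection", {
  set.seed(1)
  X <- qr.Q(qr(matrix(rnorm(30 * 4), 30)))
  Y <- matrix(rnorm(30 * 3), 30)
  dm <- structure(list(X = X, labels = data.frame(
    regressor = paste0("c", 1:4), kind = "task", bin = NA,
    column = paste0("c", 1:4), run = 1), run = 1), class = "design_matrix")
  b <- fit_glm(Y, dm)
  expect_equal(unname(b$estimates), unname(crossprod(X, Y)),
               tolerance = 1e-10)
})

test_that("rank-deficient fits equal the pseudoinverse oracle", {
  skip_if_not_installed("MASS")
  set.seed(7)
  for (i in 1:5) {
    X <- matrix(rnorm(20 * 5), 20)
    X[, 5] <- X[, 4] # exact collinearity
    Y <- matrix(rnorm(20 * 3), 20)
    dm <- structure(list(X = X, labels = data.frame(
      regressor = paste0("c", 1:5), kind = "task", bin = NA,
      column = paste0("c", 1:5), run = 1), run = 1),
      class = "design_matrix")
    b <- fit_glm(Y, dm)
    expect_equal(unname(b$estimates), unname(MASS::ginv(X) %*% Y),
                 tolerance = 1e-8)
  }
})

test_that("all-zero design columns are flagged with zero estimates", {
  X <- cbind(a = rnorm(20), zero = 0, intercept = 1)
  dm <- structure(list(X = X, labels = data.frame(
    regressor = c("a", "zero", "intercept"),
    kind = c("task", "task", "nuisance"), bin = NA,
    column = c("a", "zero", "intercept"), run = 1), run = 1),
    class = "design_matrix")
  b <- fit_glm(matrix(rnorm(20 * 2), 20), dm)
  expect_true("zero" %in% b$flags)
  expect_equal(unname(b$estimates["zero", ]), c(0, 0))
})

test_that("the estimator is linear and residuals are orthogonal to X", {
  p <- tiny_params1()
  ev <- make_design(p, 5)$main[[1]]
  dm <- build_design_matrix(ev)
  set.seed(2)
  n <- nrow(dm$X)
  y1 <- matrix(rnorm(n * 2), n)
  y2 <- matrix(rnorm(n * 2), n)
  b1 <- fit_glm(y1, dm)$estimates
  b2 <- fit_glm(y2, dm)$estimates
  b12 <- fit_glm(2 * y1 - 3 * y2, dm)$estimates
  expect_equal(b12, 2 * b1 - 3 * b2, tolerance = 1e-8)
  fit <- fit_glm(y1, dm)
  beta_all <- rbind(fit$estimates, fit$nuisance_estimates)
  resid <- y1 - dm$X %*% beta_all
  expect_lt(max(abs(crossprod(dm$X, resid))), 1e-8)
})

test_that("fit_fir equals fit_glm on the FIR design and recovers curves", {
  p <- tiny_params1()
  ev <- make_design(p, 5)$main[[1]]
  tr <- tiny_subject(p, tiny_truth(1, noise_sigma = 0), 4)
  vts <- simulate_run(ev, tr, 1)
  f1 <- fit_fir(vts, ev, n_bins = 10, condition_by = "fir_label")
  dm <- build_design_matrix(ev, basis = "fir", condition_by = "fir_label",
                            n_fir_bins = 10)
  f2 <- fit_glm(vts, dm)
  expect_equal(f1$estimates, f2$estimates)
  # constant series: all task estimates zero once the intercept absorbs it
  const <- matrix(5, nrow(dm$X), 3)
  fc <- fit_glm(const, dm)
  expect_lt(max(abs(fc$estimates)), 1e-8)
})

test_that("noiseless FIR deconvolution recovers a known bin response", {
  # two spaced events with a known 10-bin response on one voxel
  n_vol <- 80
  resp <- c(0, 1, 3, 5, 4, 2, 1, 0.5, 0.2, 0)
  onsets <- c(10, 40)
  y <- numeric(n_vol)
  for (o in onsets) y[o + 1 + 0:9] <- y[o + 1 + 0:9] + resp
  ev <- data.frame(onset = onsets, duration = 0, glm_label = "stim")
  fb <- fit_fir(matrix(y), ev, n_bins = 10,
                condition_by = "glm_label")
  expect_equal(unname(fb$estimates[, 1]), resp, tolerance = 1e-8)
})
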
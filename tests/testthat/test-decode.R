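test_that("feature standardization follows the population-SD formula", {
  expect_equal(zscore_features(cbind(c(1, 3))), cbind(c(-1, 1)),
               ignore_attr = TRUE)
  X <- cbind(a = c(2, 2, 2), b = c(1, 2, 3))
  Z <- zscore_features(X)
  expect_equal(unname(Z[, 1]), c(0, 0, 0))
  expect_true(attr(Z, "zero_variance")[1])
  set.seed(3)
  R <- matrix(rnorm(10 * 4), 10)
  ZR <- zscore_features(R)
  m <- colMeans(R)
  s <- sqrt(colMeans(sweep(R, 2, m)^2))
  expect_equal(ZR, sweep(sweep(R, 2, m), 2, s, "/"),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(zscore_features(matrix(1, 1, 3)), "2 samples")
})

test_that("the linear classifier separates and is label-antisymmetric", {
  X <- cbind(c(-1, -1.2, 1, 1.1), 0)
  y <- c(-1, -1, 1, 1)
  clf <- train_linear_classifier(X, y)
  expect_gt(clf$weights[1], 0)
  expect_true(all(sign(predict(clf, X)) == y))
  flipped <- train_linear_classifier(X, -y)
  expect_equal(flipped$weights, -clf$weights, tolerance = 1e-10)
  expect_equal(flipped$bias, -clf$bias, tolerance = 1e-10)
  expect_error(train_linear_classifier(X, c(1, 1, 1, 1)), "missing class")
})

test_that("decision signs match a brute-force margin search", {
  # coarse grid over weight directions on a small separable problem
  set.seed(42)
  X <- matrix(rnorm(20 * 3), 20)
  y <- rep(c(1, -1), 10)
  # guaranteed separable: classes in opposite orthants
  X[y == 1, ] <- abs(X[y == 1, ]) + 0.5
  X[y == -1, ] <- -abs(X[y == -1, ]) - 0.5
  grid <- as.matrix(expand.grid(w1 = seq(-1, 1, 0.25),
                                w2 = seq(-1, 1, 0.25),
                                w3 = seq(-1, 1, 0.25),
                                b = seq(-2, 2, 0.5)))
  margins <- apply(grid, 1, function(g) {
    d <- X %*% g[1:3] + g[4]
    nw <- sqrt(sum(g[1:3]^2))
    if (nw == 0) return(-Inf)
    min(y * d) / nw
  })
  best <- grid[which.max(margins), ]
  # a large cost approximates the hard-margin solution the grid searches
  clf <- train_linear_classifier(X, y, cost = 100, tol = 1e-6)
  d_grid <- sign(X %*% best[1:3] + best[4])
  expect_equal(unname(sign(predict(clf, X))), unname(drop(d_grid)))
  expect_true(all(sign(predict(clf, X)) == y))
})

test_that("decision values agree with the reference SVM implementation", {
  skip_if_not_installed("e1071")
  set.seed(11)
  X <- matrix(rnorm(40 * 30), 40)
  y <- rep(c(1, -1), 20)
  X[y == 1, 1:10] <- X[y == 1, 1:10] + 0.8
  clf <- train_linear_classifier(X, y, tol = 1e-6)
  m <- e1071::svm(X, factor(y, levels = c(1, -1)), kernel = "linear",
                  cost = 1, scale = FALSE)
  w <- drop(crossprod(m$coefs, m$SV))
  d_ref <- drop(X %*% w) - m$rho
  d_own <- predict(clf, X)
  expect_gt(cor(d_own, d_ref), 0.95)
  expect_true(mean(sign(d_own) == sign(d_ref)) >= 0.95)
})

test_that("classifier information behaves per its closed form and guards", {
  expect_equal(classifier_information(c(2, -2), c(1, -1)), 1.0)
  ci <- classifier_information(c(5, 5, 5), c(1, -1, 1))
  expect_equal(as.numeric(ci), 0)
  expect_true(attr(ci, "flagged"))
  expect_error(classifier_information(1:3, c(1, -1)), "length")
  # invariance to positive rescaling and offset of the raw distances
  set.seed(8)
  d <- rnorm(20)
  l <- sign(rnorm(20))
  expect_equal(classifier_information(d, l),
               classifier_information(3.7 * d + 2, l), tolerance = 1e-12)
})

test_that("label-independent distances give zero information on average", {
  set.seed(99)
  draws <- vapply(1:2000, function(i) {
    d <- rnorm(12)
    l <- sample(rep(c(1, -1), 6))
    classifier_information(d, l)
  }, numeric(1))
  expect_lt(abs(mean(draws)), 3 * sd(draws) / sqrt(length(draws)))
})

test_that("noiseless Experiment 1 betas hit the information ceiling", {
  t0 <- truth_params(1, noise_sigma = 0, gain_congruent = 1,
                     gain_incongruent = 1, surprise_amplitude = 0,
                     subject_gain_sd = 0)
  fx <- tiny_exp1_betas(3, truth = t0)
  sr <- tiny_subrois(fx$truth, counts = c(10, 40))
  curve <- cross_decode_exp1(fx$train, fx$main, sr)
  # perfect two-point separation in every cell, both conditions alike
  expect_equal(curve$info, rep(1, nrow(curve)), tolerance = 1e-8)
})

test_that("direction averaging is the arithmetic mean of the directions", {
  fx <- tiny_exp1_betas(5)
  sr <- tiny_subrois(fx$truth, counts = c(20))
  curve <- cross_decode_exp1(fx$train, fx$main, sr)
  key <- paste(curve$roi, curve$hemisphere, curve$n_voxels, curve$condition)
  for (k in unique(key)) {
    cc <- curve[key == k, ]
    expect_equal(cc$info[cc$direction == "average"],
                 mean(c(cc$info[cc$direction == "forward"],
                        cc$info[cc$direction == "reverse"])))
    expect_lte(cc$info[cc$direction == "average"], max(cc$info) + 1e-12)
    expect_gte(cc$info[cc$direction == "average"], min(cc$info) - 1e-12)
  }
})

test_that("missing decoding cells are reported by name", {
  fx <- tiny_exp1_betas(5)
  sr <- tiny_subrois(fx$truth, counts = c(10))
  keep <- !(fx$main$labels$congruency == "incongruent" &
              fx$main$labels$background == "30")
  broken <- list(mat = fx$main$mat[keep, ], labels = fx$main$labels[keep, ])
  expect_error(cross_decode_exp1(fx$train, broken, sr),
               "missing decoding cell: incongruent")
})

test_that("mean classifier information rises with generator SNR", {
  snr_levels <- list(c(EVC = 0, LVC = 0), c(EVC = 0.4, LVC = 0.4),
                     c(EVC = 1, LVC = 1))
  p <- tiny_params1()
  means <- vapply(seq_along(snr_levels), function(li) {
    tp <- tiny_truth(1, roi_amp = snr_levels[[li]])
    mean(vapply(1:8, function(s) {
      fx <- tiny_exp1_betas(100 * li + s, truth = tp, params = p)
      sr <- tiny_subrois(fx$truth, counts = c(20, 40))
      mean(summarize_curve(cross_decode_exp1(fx$train, fx$main, sr))$info)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_lt(abs(means[1]), 0.15) # chance at zero SNR
})

test_that("Experiment 2 occluded decoding recovers the injected signal", {
  p2 <- tiny_params2()
  run_one <- function(tp, seed) {
    design <- make_design(p2, derive_seed(seed, 1))
    tr <- tiny_subject(p2, tp, derive_seed(seed, 2))
    train <- stack_betas(lapply(seq_along(design$training), function(r) {
      vts <- simulate_run(design$training[[r]], tr, derive_seed(seed, 3, r))
      fit_glm(vts, vts$design)
    }))
    main <- stack_betas(lapply(seq_along(design$main), function(r) {
      ev <- design$main[[r]]
      vts <- simulate_run(ev, tr, derive_seed(seed, 4, r))
      fit_glm(vts, build_design_matrix(ev, condition_by = "glm_label"))
    }))
    sr <- tiny_subrois(tr, counts = c(20, 40))
    mean(summarize_curve(cross_decode_exp2(train, main, sr))$info)
  }
  tp_null <- tiny_truth(2, occluded_signal_gain = 0, subject_gain_sd = 0)
  tp_sig <- tiny_truth(2, occluded_signal_gain = 1)
  null_vals <- vapply(1:8, function(s) run_one(tp_null, s), numeric(1))
  sig_vals <- vapply(1:8, function(s) run_one(tp_sig, 50 + s), numeric(1))
  expect_lt(abs(mean(null_vals)),
            3 * sd(null_vals) / sqrt(length(null_vals)) + 0.02)
  expect_gt(mean(sig_vals), mean(null_vals) + 0.2)
})

test_that("time-resolved decoding localizes signal to the carrying bins", {
  # constructed FIR betas: wide/narrow patterns present only in bins 4-6
  set.seed(21)
  nv <- 60
  pw <- rnorm(nv)
  pn <- rnorm(nv)
  tr_labels <- data.frame(shape = rep(c("wide", "narrow"), 10),
                          run = rep(1:2, each = 10))
  train <- list(mat = t(vapply(seq_len(20), function(i)
    (if (tr_labels$shape[i] == "wide") pw else pn) + rnorm(nv, 0, 0.5),
    numeric(nv))), labels = tr_labels)
  grid <- expand.grid(bin = 0:9, run = 1:4,
                      shape = c("wide", "narrow"),
                      congruency = c("congruent", "incongruent"),
                      stringsAsFactors = FALSE)
  fir_mat <- t(vapply(seq_len(nrow(grid)), function(i) {
    base <- if (grid$bin[i] %in% 4:6)
      (if (grid$shape[i] == "wide") pw else pn) else 0
    base + rnorm(nv, 0, 0.3)
  }, numeric(nv)))
  fir <- list(mat = fir_mat, labels = grid)
  out <- time_resolved_decode(train, fir, seq_len(nv))
  expect_equal(nrow(out), 20) # 10 bins x 2 conditions
  for (cond in c("congruent", "incongruent")) {
    oc <- out[out$condition == cond, ]
    expect_gt(mean(oc$info[oc$bin %in% 4:6]),
              mean(oc$info[!oc$bin %in% 4:6]) + 0.2)
  }
  expect_error(time_resolved_decode(train, fir, seq_len(nv), n_bins = 5),
               "bin count")
})
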
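test_that("curve summaries are plain means over counts and hemispheres", {
  curve <- expand.grid(roi = "EVC", hemisphere = c("L", "R"),
                       n_voxels = c(100, 200),
                       condition = c("congruent", "incongruent"),
                       direction = "average", stringsAsFactors = FALSE)
  curve$info <- 0.3
  expect_equal(summarize_curve(curve)$info, c(0.3, 0.3))
  curve$info[curve$condition == "congruent"] <- c(0.2, 0.2, 0.4, 0.4)
  expect_equal(summarize_curve(curve)$info[1], 0.3)
  set.seed(4)
  curve$info <- rnorm(nrow(curve))
  sm <- summarize_curve(curve)
  for (cond in c("congruent", "incongruent"))
    expect_equal(sm$info[sm$condition == cond],
                 mean(curve$info[curve$condition == cond]))
  expect_error(summarize_curve(curve[-1, ]), "incomplete curve")
})

test_that("t tests match hand computation and guard zero variance", {
  x <- c(1.1, 0.8, 1.4, 0.9, 1.3) # printed five-value example
  r <- one_sample_t(x)
  m <- mean(x); s <- sd(x); n <- 5
  expect_equal(r$statistic, m / (s / sqrt(n)))
  expect_equal(r$p, 2 * pt(-abs(r$statistic), 4))
  expect_equal(r$cohens_d, m / s)
  expect_equal(c(r$ci_low, r$ci_high),
               m + c(-1, 1) * qt(0.975, 4) * s / sqrt(n))
  # symmetric values around zero
  z <- c(-2, -1, 0, 1, 2)
  rz <- one_sample_t(z)
  expect_equal(rz$statistic, 0)
  expect_equal(rz$p, 1)
  # identical pairs: zero-variance guard
  rp <- paired_t(x, x)
  expect_equal(rp$statistic, 0)
  expect_equal(rp$p, 1)
  expect_true(rp$flagged)
})

test_that("interaction F equals the squared difference-of-differences t", {
  set.seed(10)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    arr <- array(rnorm(n * 4), c(n, 2, 2))
    a <- interaction_anova_2x2(arr)
    dd <- (arr[, 1, 1] - arr[, 2, 1]) - (arr[, 1, 2] - arr[, 2, 2])
    tt <- one_sample_t(dd)
    expect_equal(a$F, tt$statistic^2, tolerance = 1e-10)
    expect_equal(a$partial_eta_sq, a$F / (a$F + (n - 1)), tolerance = 1e-12)
  }
  # identical congruency effect in both ROIs: F = 0
  arr <- array(rnorm(10 * 4), c(10, 2, 2))
  arr[, , 2] <- arr[, , 1] + 0.5
  a0 <- interaction_anova_2x2(arr)
  expect_equal(a0$F, 0)
})

test_that("interaction F agrees with aov's repeated-measures table", {
  set.seed(5)
  n <- 12
  df <- expand.grid(subject = factor(1:n),
                    congruency = c("c", "i"), roi = c("EVC", "LVC"))
  df$value <- rnorm(nrow(df)) + as.numeric(df$congruency == "c") *
    as.numeric(df$roi == "EVC")
  fit <- summary(stats::aov(value ~ congruency * roi +
                              Error(subject / (congruency * roi)),
                            data = df))
  f_aov <- fit[["Error: subject:congruency:roi"]][[1]]["congruency:roi",
                                                       "F value"]
  df2 <- df
  names(df2)[4] <- "value"
  a <- interaction_anova_2x2(df2)
  expect_equal(a$F, f_aov, tolerance = 1e-8)
})

test_that("TFCE converges to its closed forms as dh shrinks", {
  # isolated point of height t: integral of h^H dh -> t^(H+1)/(H+1)
  tt <- 3
  curve <- c(0, 0, tt, 0, 0)
  v <- tfce_1d(curve, E = 0.5, H = 2, dh = tt / 4000)[3]
  expect_equal(v, tt^3 / 3, tolerance = 0.001 * tt^3)
  # constant curve of height c over m points: m^E * c^(H+1)/(H+1)
  m <- 5; cc <- 2
  v2 <- tfce_1d(rep(cc, m), E = 0.5, H = 2, dh = cc / 4000)
  expect_equal(v2, rep(sqrt(m) * cc^3 / 3, m), tolerance = 0.001 * cc^3)
  # zero curve maps to zero
  expect_equal(tfce_1d(rep(0, 6)), rep(0, 6))
  # negative parts are mirrored with sign restored
  neg <- tfce_1d(c(0, -tt, 0), dh = tt / 2000)
  expect_equal(neg[2], -tt^3 / 3, tolerance = 0.01 * tt^3)
})

test_that("TFCE is monotone under curve scaling", {
  set.seed(2)
  curves <- matrix(rnorm(8 * 12, mean = 0.3), 8)
  t1 <- tfce_1d(colMeans(curves) / (apply(curves, 2, sd) / sqrt(8)))
  for (k in c(1.5, 3)) {
    tk <- tfce_1d(k * colMeans(curves) / (apply(curves, 2, sd) / sqrt(8)))
    expect_true(all(abs(tk) >= abs(t1) - 1e-10))
  }
})

test_that("sign-flip TFCE test behaves at the null and under negation", {
  zero <- matrix(0, 6, 10)
  r0 <- tfce_signflip_test(zero, 200, seed = 1)
  expect_true(all(r0$p_fwe == 1))
  set.seed(12)
  curves <- matrix(rnorm(10 * 8, 0.5, 0.5), 10)
  r1 <- tfce_signflip_test(curves, 500, seed = 3)
  r2 <- tfce_signflip_test(-curves, 500, seed = 3)
  expect_equal(r2$t, -r1$t)
  expect_equal(r2$p_fwe, r1$p_fwe) # two-sided conclusions unchanged
  expect_warning(tfce_signflip_test(curves, 50, seed = 1), "100 permutations")
})

test_that("sign-flip p-values are uniform under a true null", {
  # replicate null cohorts; KS test on the min-p over a 1-point curve
  # (single point makes pointwise and max nulls coincide)
  set.seed(33)
  ps <- vapply(1:200, function(i) {
    curves <- matrix(rnorm(12), 12, 1)
    tfce_signflip_test(curves, 400, seed = i)$p_fwe[1]
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the attention exclusion rule applies Q1 - 2 IQR exactly", {
  x <- c(rep(0.9, 33), 0.1)
  keep <- exclude_inattentive(x)
  expect_identical(which(!keep), 34L) # IQR = 0: only the outlier drops
  expect_true(all(exclude_inattentive(rep(0.8, 10))))
  # direct quartile oracle on a spread sample
  set.seed(6)
  y <- c(runif(20, 0.6, 1), 0.2, 0.05)
  thr <- quantile(y, 0.25, type = 7) - 2 * IQR(y, type = 7)
  expect_identical(exclude_inattentive(y), y >= thr)
  # monotone: lowering one subject never un-excludes another
  y2 <- y
  y2[21] <- 0.01
  excl1 <- which(!exclude_inattentive(y))
  excl2 <- which(!exclude_inattentive(y2))
  expect_true(all(setdiff(excl1, 21) %in% union(excl2, 21)))
  expect_error(exclude_inattentive(c(0.5, 0.5, 0.5)), "4 subjects")
})

test_that("univariate ROI means collapse voxels then sub-ROI sizes", {
  meta <- data.frame(roi = "EVC", hemisphere = rep("L", 3))
  sr <- make_subrois(c(3, 2, 1), meta, counts = c(1, 3), rois = "EVC",
                     hemispheres = "L")
  betas <- list(mat = rbind(c(1, 2, 3), c(5, 6, 7)),
                labels = data.frame(congruency = c("congruent",
                                                   "incongruent")))
  u <- univariate_roi(betas, sr)
  # congruent: sub-ROI means are 1 (top voxel) and 2 (all three) -> 1.5
  expect_equal(u$value[u$condition == "congruent"], 1.5)
  expect_equal(u$value[u$condition == "incongruent"], 5.5)
  # constant betas: every condition mean equals the constant
  betas2 <- list(mat = matrix(4, 2, 3), labels = betas$labels)
  expect_equal(univariate_roi(betas2, sr)$value, c(4, 4))
})

test_that("whole-brain contrast recovers extent-thresholded clusters", {
  set.seed(9)
  coords <- as.matrix(expand.grid(x = 1:10, y = 1:10, z = 1:4))
  nv <- nrow(coords)
  n <- 16
  block12 <- which(coords[, 1] <= 4 & coords[, 2] <= 3 & coords[, 3] == 1)
  expect_length(block12, 12)
  block5 <- which(coords[, 1] == 10 & coords[, 2] %in% 6:10 &
                    coords[, 3] == 4)
  expect_length(block5, 5)
  maps <- matrix(rnorm(n * nv, 0, 0.1), n)
  maps[, block12] <- maps[, block12] + 2
  maps[, block5] <- maps[, block5] + 2
  res <- whole_brain_contrast(maps, coords)
  expect_equal(nrow(res$clusters), 1) # the 5-voxel block is removed
  expect_equal(res$clusters$n_voxels, 12)
  pk <- res$clusters[1, c("peak_x", "peak_y", "peak_z")]
  expect_true(any(coords[block12, 1] == pk$peak_x &
                    coords[block12, 2] == pk$peak_y &
                    coords[block12, 3] == pk$peak_z))
  expect_error(whole_brain_contrast(maps[1:2, ], coords), "3 subjects")
})

test_that("null maps cross the voxel threshold at about the nominal rate", {
  set.seed(14)
  coords <- as.matrix(expand.grid(x = 1:12, y = 1:12, z = 1:6))
  alpha <- 0.01
  frac <- mean(vapply(1:30, function(i) {
    maps <- matrix(rnorm(10 * nrow(coords)), 10)
    mean(whole_brain_contrast(maps, coords, alpha = alpha)$mask)
  }, numeric(1)))
  expect_lt(abs(frac - alpha), 0.35 * alpha)
})
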
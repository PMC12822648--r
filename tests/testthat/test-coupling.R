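make_fir_run <- function(est, bins, congruency, shape) {
  fake_betas(est, paste0(shape, ".", congruency, ".bin", bins),
             bin = bins, congruency = congruency, shape = shape)
}

test_that("voxel time courses average across runs", {
  bins <- rep(0:2, 2)
  congr <- rep(c("congruent", "incongruent"), each = 3)
  shape <- "wide"
  e1 <- matrix(seq_len(12), 6, 2)
  e2 <- matrix(seq_len(12) + 2, 6, 2)
  vc <- voxel_timecourses(list(make_fir_run(e1, bins, congr, shape),
                               make_fir_run(e2, bins, congr, shape)))
  expect_equal(vc$conditions$congruent, (e1[1:3, ] + e2[1:3, ]) / 2)
  # identical runs reproduce any single run
  vc2 <- voxel_timecourses(list(make_fir_run(e1, bins, congr, shape),
                                make_fir_run(e1, bins, congr, shape)))
  expect_equal(vc2$conditions$congruent, e1[1:3, ])
  # opposite runs cancel
  vc3 <- voxel_timecourses(list(make_fir_run(e1, bins, congr, shape),
                                make_fir_run(-e1, bins, congr, shape)))
  expect_true(all(vc3$conditions$congruent == 0))
  expect_error(voxel_timecourses(list()), "missing run")
})

test_that("coupling maps are signed correlations with degenerate guards", {
  s <- c(0, 1, 3, 2, 1, 0, 0, 1, 2, 1)
  V <- cbind(s, -s, rep(1, 10), rnorm(10))
  vc <- list(conditions = list(congruent = V), bins = 0:9)
  cm <- coupling_maps(list(congruent = s), vc)
  expect_equal(cm$r$congruent[1], 1)
  expect_equal(cm$r$congruent[2], -1)
  expect_equal(cm$r$congruent[3], 0) # zero-variance voxel, flagged
  expect_true(cm$flagged$congruent[3])
  expect_equal(cm$r$congruent[4], cor(s, V[, 4]))
  expect_error(coupling_maps(list(congruent = s[1:2]),
                             list(conditions = list(congruent = V[1:2, ]),
                                  bins = 0:1)), "3 time bins")
})

test_that("coupling maps are invariant to affine rescaling", {
  set.seed(20)
  s <- rnorm(10)
  V <- matrix(rnorm(10 * 5), 10)
  vc <- list(conditions = list(congruent = V), bins = 0:9)
  r1 <- coupling_maps(list(congruent = s), vc)$r$congruent
  vc2 <- list(conditions = list(congruent = 2.5 * V + 7), bins = 0:9)
  r2 <- coupling_maps(list(congruent = -0.5 + 4 * s), vc2)$r$congruent
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("independent noise voxels decorrelate from the seed on average", {
  set.seed(31)
  s <- rnorm(10)
  V <- matrix(rnorm(10 * 10000), 10)
  vc <- list(conditions = list(congruent = V), bins = 0:9)
  r <- coupling_maps(list(congruent = s), vc)$r$congruent
  expect_lt(abs(mean(r)), 3 * sd(r) / sqrt(length(r)))
})

test_that("the coupling pipeline averages over the six seed settings", {
  p <- tiny_params1()
  tr <- tiny_subject(p, tiny_truth(1), 8, n_other = 10)
  design <- make_design(p, 2)
  seed_run <- function(r) {
    vts <- simulate_run(design$training[[r]], tr, 600 + r)
    fit_glm(vts, vts$design)
  }
  train <- stack_betas(lapply(1:2, seed_run))
  fir_runs <- lapply(1:2, function(r) {
    ev <- design$main[[r]]
    vts <- simulate_run(ev, tr, 700 + r)
    fit_fir(vts, ev, condition_by = "fir_label")
  })
  settings <- c(10, 15, 20, 25, 30, 35)
  cm <- coupling_pipeline(train, fir_runs, tr$voxel_meta,
                          voxel_count_settings = settings)
  expect_equal(attr(cm, "settings"), settings)
  expect_length(cm$r$congruent, nrow(tr$voxel_meta))
  expect_true(all(abs(unlist(cm$r)) <= 1 + 1e-12))
  # a single setting equals the average of one repetition
  cm1 <- coupling_pipeline(train, fir_runs, tr$voxel_meta,
                           voxel_count_settings = 20)
  cm1b <- coupling_pipeline(train, fir_runs, tr$voxel_meta,
                            voxel_count_settings = rep(20, 3))
  expect_equal(cm1$r, cm1b$r, tolerance = 1e-12)
})

test_that("coupling contrast recovers constructed condition-specific voxels", {
  set.seed(17)
  coords <- as.matrix(expand.grid(x = 1:10, y = 1:10, z = 1:3))
  nv <- nrow(coords)
  block <- which(coords[, 1] <= 5 & coords[, 2] <= 3 & coords[, 3] == 2)
  expect_length(block, 15)
  make_subj <- function(coupled) {
    seed_c <- rnorm(10)
    seed_i <- rnorm(10)
    V_c <- matrix(rnorm(10 * nv, 0, 1), 10)
    V_i <- matrix(rnorm(10 * nv, 0, 1), 10)
    if (coupled) V_c[, block] <- seed_c + 0.15 * V_c[, block]
    vc <- list(conditions = list(congruent = V_c, incongruent = V_i),
               bins = 0:9)
    coupling_maps(list(congruent = seed_c, incongruent = seed_i), vc)
  }
  maps <- lapply(1:14, function(s) make_subj(TRUE))
  res <- coupling_contrast(maps, coords, alpha = 0.001, cluster_min = 10)
  expect_gte(nrow(res$clusters), 1)
  hit <- any(res$mask[block])
  expect_true(hit)
  # label swap flips every t
  swapped <- lapply(maps, function(m)
    structure(list(r = list(congruent = m$r$incongruent,
                            incongruent = m$r$congruent),
                   flagged = m$flagged), class = "coupling_maps"))
  r2 <- coupling_contrast(swapped, coords)
  r1 <- coupling_contrast(maps, coords)
  expect_equal(r2$t_map, -r1$t_map, tolerance = 1e-12)
  # identical condition maps: nothing survives
  same <- lapply(1:6, function(s) {
    m <- make_subj(FALSE)
    m$r$incongruent <- m$r$congruent
    m
  })
  expect_equal(nrow(coupling_contrast(same, coords)$clusters), 0)
})
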
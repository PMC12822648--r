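#' Collapse a classifier-information curve to per-condition scalars
#'
#' Arithmetic mean of one subject's classifier information over voxel-
#' inclusion counts and hemispheres, per ROI and condition -- the summary
#' entering the group t tests. Errors if any (roi, hemisphere, n_voxels,
#' condition) cell is absent.
#'
#' @param curve a `cinfo_curve` data.frame (one subject).
#' @param direction which decoding direction to summarize.
#' @return data.frame with `roi`, `condition`, `info`.
#' @export
summarize_curve <- function(curve, direction = "average") {
  d <- curve[curve$direction == direction, , drop = FALSE]
  if (!nrow(d)) stop("no rows for direction '", direction, "'")
  # completeness is checked within each ROI (voxel-count grids may be
  # truncated differently per region)
  have <- paste(d$roi, d$hemisphere, d$n_voxels, d$condition)
  for (r in unique(d$roi)) {
    dr <- d[d$roi == r, , drop = FALSE]
    full <- expand.grid(hemisphere = unique(dr$hemisphere),
                        n_voxels = unique(dr$n_voxels),
                        condition = unique(dr$condition),
                        stringsAsFactors = FALSE)
    want <- paste(r, full$hemisphere, full$n_voxels, full$condition)
    if (!all(want %in% have))
      stop("incomplete curve: missing cell(s) ",
           paste(utils::head(want[!want %in% have], 3), collapse = "; "))
  }
  out <- stats::aggregate(info ~ roi + condition, data = d, FUN = mean)
  out[order(out$roi, out$condition), , drop = FALSE]
}

test_result <- function(statistic, dof, p, d, ci, sided, n, flagged = FALSE) {
  structure(list(statistic = statistic, dof = dof, p = p, cohens_d = d,
                 ci_low = ci[1], ci_high = ci[2], sided = sided, n = n,
                 flagged = flagged),
            class = "mvpa_test")
}

#' @export
print.mvpa_test <- function(x, ...) {
  cat(sprintf("t(%g) = %.3f, p = %.4g (%s-sided), d = %.3f, CI [%.3f, %.3f]\n",
              x$dof, x$statistic, x$p, x$sided, x$cohens_d, x$ci_low,
              x$ci_high))
  invisible(x)
}

#' One-sample and paired t tests with effect size
#'
#' Textbook one-sample t against `mu` with Cohen's d (mean over SD) and the
#' 95% confidence interval of the mean. Zero variance is guarded: the
#' statistic becomes `+/-Inf` (or 0 when the mean equals `mu`) and the
#' result is flagged. `paired_t(a, b)` is the one-sample test on `a - b`.
#'
#' @param values numeric vector (n >= 2).
#' @param mu null value.
#' @param sided `"two"` or `"greater"`.
#' @return object of class `mvpa_test` with fields `statistic`, `dof`, `p`,
#'   `cohens_d`, `ci_low`, `ci_high`, `sided`, `n`, `flagged`.
#' @export
one_sample_t <- function(values, mu = 0, sided = c("two", "greater")) {
  sided <- match.arg(sided)
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  m <- mean(values)
  s <- sd(values)
  if (s == 0) {
    t <- if (m == mu) 0 else sign(m - mu) * Inf
    p <- if (m == mu) 1 else 0
    return(test_result(t, n - 1, p, if (m == mu) 0 else sign(m - mu) * Inf,
                       c(m, m), sided, n, flagged = TRUE))
  }
  se <- s / sqrt(n)
  t <- (m - mu) / se
  p <- if (sided == "two") 2 * pt(-abs(t), n - 1) else pt(t, n - 1,
                                                          lower.tail = FALSE)
  tc <- stats::qt(0.975, n - 1)
  test_result(t, n - 1, p, (m - mu) / s, c(m - tc * se, m + tc * se),
              sided, n)
}

#' @rdname one_sample_t
#' @param a,b paired numeric vectors of equal length.
#' @export
paired_t <- function(a, b, sided = c("two", "greater")) {
  if (length(a) != length(b)) stop("paired vectors differ in length")
  one_sample_t(a - b, 0, sided)
}

#' Within-subject 2x2 interaction (congruency by ROI)
#'
#' Repeated-measures interaction F with (1, n-1) degrees of freedom. For a
#' 2x2 within-subject design this equals the squared paired t on each
#' subject's difference-of-differences, which is how it is computed;
#' partial eta squared follows as F / (F + dof_error).
#'
#' @param values numeric array `n x 2 x 2` (subject, factor A, factor B) or
#'   a data.frame with columns `subject`, `congruency`, `roi`, `value`.
#' @return list with `F`, `dof`, `p`, `partial_eta_sq`, `n`.
#' @export
interaction_anova_2x2 <- function(values) {
  if (is.data.frame(values)) {
    a <- sort(unique(values$congruency))
    b <- sort(unique(values$roi))
    s <- sort(unique(values$subject))
    if (length(a) != 2 || length(b) != 2) stop("design is not 2x2")
    arr <- array(NA_real_, c(length(s), 2, 2))
    for (i in seq_len(nrow(values)))
      arr[match(values$subject[i], s), match(values$congruency[i], a),
          match(values$roi[i], b)] <- values$value[i]
    if (anyNA(arr)) stop("missing cell in 2x2 within-subject table")
    values <- arr
  }
  stopifnot(length(dim(values)) == 3, dim(values)[2] == 2,
            dim(values)[3] == 2)
  n <- dim(values)[1]
  dd <- (values[, 1, 1] - values[, 2, 1]) - (values[, 1, 2] - values[, 2, 2])
  tt <- one_sample_t(dd)
  Fv <- tt$statistic^2
  p <- if (is.infinite(Fv)) 0 else pf(Fv, 1, n - 1, lower.tail = FALSE)
  list(F = Fv, dof = c(1, n - 1), p = p,
       partial_eta_sq = if (is.infinite(Fv)) 1 else Fv / (Fv + (n - 1)),
       n = n)
}

#' Threshold-free cluster enhancement of a 1D statistic curve
#'
#' For every point s of the curve, integrates extent^E * height^H over
#' thresholds from `dh` up to the statistic at s (in steps of `dh`), where
#' the extent is the length of the contiguous run of points at or above the
#' threshold containing s. Negative statistics are enhanced on the mirrored
#' curve with the sign restored.
#'
#' @param statistic numeric curve (e.g. per-sub-ROI t values).
#' @param E,H extent and height exponents (defaults 0.5 and 2).
#' @param dh threshold step; defaults to `max(abs(statistic)) / 100`.
#' @return numeric vector of enhanced values, same length as the input.
#' @export
tfce_1d <- function(statistic, E = 0.5, H = 2, dh = NULL) {
  m <- max(abs(statistic))
  if (m == 0) return(numeric(length(statistic)))
  if (is.null(dh)) dh <- m / 100
  stopifnot(dh > 0)
  tfce_curve_cpp(as.numeric(statistic), E, H, dh)
}

#' Sign-flip permutation test on TFCE-enhanced group curves
#'
#' The observed one-sample t curve across subjects is TFCE-enhanced; the
#' null distribution is built by flipping the sign of each subject's entire
#' curve with probability 1/2 and recomputing the enhanced curve. With the
#' default `null_mode = "max"`, each permutation contributes its maximum
#' enhanced value over points, so the per-point p values are family-wise
#' corrected; `"pointwise"` compares each point against its own null.
#' Permutation p values use the add-one convention
#' `(1 + #\{null >= observed\}) / (1 + n_permutations)`.
#'
#' @param curves numeric matrix, subjects x points.
#' @param n_permutations number of random sign flips (default 10000).
#' @param E,H,dh TFCE parameters; `dh` defaults to a 100-step grid on the
#'   observed t curve.
#' @param seed integer seed for the flips.
#' @param sided `"two"` (magnitude of the enhanced values) or `"greater"`.
#' @param null_mode `"max"` (FWE via the max statistic) or `"pointwise"`.
#' @return object of class `tfce_result`: list with `t`, `observed_tfce`,
#'   `p_fwe`, `z`, `n_permutations`, `seed`, and the parameters.
#' @export
tfce_signflip_test <- function(curves, n_permutations = 10000, E = 0.5,
                               H = 2, dh = NULL, seed = 1,
                               sided = c("two", "greater"),
                               null_mode = c("max", "pointwise")) {
  sided <- match.arg(sided)
  null_mode <- match.arg(null_mode)
  stopifnot(is.matrix(curves), nrow(curves) >= 2)
  if (n_permutations < 100)
    warning("fewer than 100 permutations; tail estimates are unstable")
  n <- nrow(curves)
  m <- colMeans(curves)
  s <- apply(curves, 2, sd)
  t_obs <- ifelse(s > 0, m / (s / sqrt(n)), 0)
  if (max(abs(t_obs)) == 0) {
    np <- length(t_obs)
    return(structure(list(t = t_obs, observed_tfce = numeric(np),
                          p_fwe = rep(1, np), z = rep(-Inf, np),
                          n_permutations = n_permutations, seed = seed,
                          E = E, H = H, dh = NA_real_, sided = sided,
                          null_mode = null_mode), class = "tfce_result"))
  }
  if (is.null(dh)) dh <- max(abs(t_obs)) / 100
  obs <- tfce_curve_cpp(t_obs, E, H, dh)
  signs <- signflip_matrix_cpp(as.integer(n_permutations), n,
                               derive_seed(seed, 4242))
  null <- tfce_signflip_null_cpp(curves, signs, E, H, dh)
  if (sided == "two") {
    null <- abs(null)
    ref <- abs(obs)
  } else {
    ref <- obs
  }
  if (null_mode == "max") {
    null_stat <- apply(null, 1, max)
    p <- vapply(ref, function(o) (1 + sum(null_stat >= o)) /
                  (1 + n_permutations), numeric(1))
  } else {
    p <- vapply(seq_along(ref), function(k)
      (1 + sum(null[, k] >= ref[k])) / (1 + n_permutations), numeric(1))
  }
  structure(list(t = t_obs, observed_tfce = obs, p_fwe = p,
                 z = qnorm(1 - p), n_permutations = n_permutations,
                 seed = seed, E = E, H = H, dh = dh, sided = sided,
                 null_mode = null_mode),
            class = "tfce_result")
}

#' @export
print.tfce_result <- function(x, ...) {
  cat("TFCE sign-flip test (", x$n_permutations, " permutations, ",
      x$null_mode, " null): ", sum(x$p_fwe < 0.05), "/", length(x$p_fwe),
      " points at p_fwe < 0.05\n", sep = "")
  invisible(x)
}

#' Attention-based participant exclusion rule
#'
#' A subject is excluded when their true-versus-reported correlation falls
#' strictly below the first quartile minus two interquartile ranges.
#' Quartiles use linear interpolation (R's default type 7), which matters
#' for IQR-based rules and is therefore fixed here.
#'
#' @param correlations per-subject mean run-wise correlations (n >= 4).
#' @return logical keep-mask (TRUE = retain).
#' @export
exclude_inattentive <- function(correlations) {
  if (length(correlations) < 4) stop("need at least 4 subjects")
  q1 <- quantile(correlations, 0.25, type = 7, names = FALSE)
  iqr <- IQR(correlations, type = 7)
  correlations >= q1 - 2 * iqr
}

#' Mean univariate activation per condition within sub-ROIs
#'
#' Averages beta weights across voxels within each sub-ROI, then across
#' sub-ROI sizes, per condition and ROI-by-hemisphere mask -- the
#' within-ROI univariate summary accompanying the decoding analysis.
#'
#' @param betas stacked betas (see [stack_betas()]); rows are averaged
#'   across runs within condition.
#' @param subrois a [make_subrois()] object.
#' @param condition_col label column defining the conditions.
#' @return data.frame with `roi`, `hemisphere`, `condition`, `value`.
#' @export
univariate_roi <- function(betas, subrois, condition_col = "congruency") {
  conds <- sort(unique(betas$labels[[condition_col]]))
  rows <- list()
  k <- 0
  for (entry in subrois$entries) {
    for (cond in conds) {
      r <- betas$labels[[condition_col]] == cond
      mv <- colMeans(betas$mat[r, , drop = FALSE])
      v <- mean(vapply(entry$counts, function(N)
        mean(mv[subroi_members(entry, N)]), numeric(1)))
      k <- k + 1
      rows[[k]] <- data.frame(roi = entry$roi,
                              hemisphere = entry$hemisphere,
                              condition = cond, value = v,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# connected components of 3D voxel coordinates under 6-connectivity
cluster_components <- function(coords) {
  k <- nrow(coords)
  if (k == 0) return(integer(0))
  M <- max(coords) + 2
  key <- coords[, 1] + M * coords[, 2] + M * M * coords[, 3]
  offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))
  nb <- matrix(NA_integer_, k, 6)
  for (j in 1:6) {
    nk <- (coords[, 1] + offsets[j, 1]) + M * (coords[, 2] + offsets[j, 2]) +
      M * M * (coords[, 3] + offsets[j, 3])
    nb[, j] <- match(nk, key)
  }
  lab <- integer(k)
  cur <- 0L
  for (i in seq_len(k)) {
    if (lab[i]) next
    cur <- cur + 1L
    stack <- i
    lab[i] <- cur
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      nbr <- nb[v, ]
      nbr <- nbr[!is.na(nbr)]
      nbr <- nbr[lab[nbr] == 0]
      lab[nbr] <- cur
      stack <- c(stack, nbr)
    }
  }
  lab
}

#' Second-level whole-brain cluster contrast
#'
#' One-sample t across subjects per voxel, thresholded at an uncorrected
#' alpha; surviving voxels are grouped into face-adjacent (6-connected) 3D
#' clusters, and clusters smaller than `cluster_min` voxels are removed.
#' Positive and negative suprathreshold voxels are clustered separately
#' under the two-sided test.
#'
#' @param maps numeric matrix, subjects x voxels (e.g. per-subject
#'   condition-difference maps); at least 3 subjects.
#' @param coords integer matrix of voxel grid coordinates (voxels x 3).
#' @param alpha voxel-wise threshold (default 0.001, uncorrected).
#' @param cluster_min minimum cluster extent in voxels (default 10).
#' @param sided `"two"` or `"greater"`.
#' @return object of class `cluster_result`: list with `t_map`, `p`,
#'   `mask`, and `clusters` (data.frame: `cluster`, `sign`, `n_voxels`,
#'   `peak_x`, `peak_y`, `peak_z`, `peak_t`).
#' @export
whole_brain_contrast <- function(maps, coords, alpha = 0.001,
                                 cluster_min = 10,
                                 sided = c("two", "greater")) {
  sided <- match.arg(sided)
  if (nrow(maps) < 3) stop("need at least 3 subjects")
  stopifnot(ncol(maps) == nrow(coords))
  n <- nrow(maps)
  m <- colMeans(maps)
  s <- sqrt(pmax(0, (colSums(maps^2) - n * m^2) / (n - 1)))
  t <- ifelse(s > 0, m / (s / sqrt(n)), 0)
  p <- if (sided == "two") 2 * pt(-abs(t), n - 1)
  else pt(t, n - 1, lower.tail = FALSE)
  mask <- p < alpha
  cl_rows <- list()
  ci <- 0
  signs <- if (sided == "two") c(1, -1) else 1
  for (sg in signs) {
    idx <- which(mask & sign(t) == sg)
    if (!length(idx)) next
    lab <- cluster_components(coords[idx, , drop = FALSE])
    for (l in unique(lab)) {
      vox <- idx[lab == l]
      if (length(vox) < cluster_min) next
      pk <- vox[which.max(abs(t[vox]))]
      ci <- ci + 1
      cl_rows[[ci]] <- data.frame(cluster = ci, sign = sg,
                                  n_voxels = length(vox),
                                  peak_x = coords[pk, 1],
                                  peak_y = coords[pk, 2],
                                  peak_z = coords[pk, 3],
                                  peak_t = t[pk])
    }
  }
  clusters <- if (ci) do.call(rbind, cl_rows)
  else data.frame(cluster = integer(0), sign = integer(0),
                  n_voxels = integer(0), peak_x = integer(0),
                  peak_y = integer(0), peak_z = integer(0),
                  peak_t = numeric(0))
  if (nrow(clusters) > 1) {
    o <- order(-clusters$n_voxels)
    clusters <- clusters[o, , drop = FALSE]
    clusters$cluster <- seq_len(nrow(clusters))
    rownames(clusters) <- NULL
  }
  structure(list(t_map = t, p = p, mask = mask, clusters = clusters,
                 alpha = alpha, cluster_min = cluster_min, sided = sided),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("Whole-brain contrast (alpha = ", x$alpha, ", extent >= ",
      x$cluster_min, "): ", nrow(x$clusters), " cluster(s)\n", sep = "")
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}
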
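#' Standardize a sample-by-voxel feature matrix
#'
#' Centers each voxel (column) to mean 0 and scales it to population
#' standard deviation 1. Zero-variance voxels are mapped to all-zero
#' columns and flagged rather than dropped, so feature geometry is
#' preserved across datasets.
#'
#' @param X numeric matrix, samples in rows (at least 2).
#' @return standardized matrix with logical attribute `zero_variance`.
#' @export
zscore_features <- function(X) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) < 2) stop("cannot standardize fewer than 2 samples")
  m <- colMeans(X)
  Xc <- sweep(X, 2, m)
  s <- sqrt(colMeans(Xc^2))
  zero <- s == 0
  s[zero] <- 1
  Z <- sweep(Xc, 2, s, "/")
  Z[, zero] <- 0
  attr(Z, "zero_variance") <- zero
  Z
}

#' Train a linear maximum-margin classifier
#'
#' Hinge-loss linear support-vector classifier with an L2 penalty on
#' weights and (regularized) intercept, solved in the dual by deterministic
#' cyclic coordinate descent. The decision function is oriented so that the
#' +1 class lies on the positive side; consequently flipping all labels
#' exactly negates the weights.
#'
#' @param X standardized sample-by-feature matrix.
#' @param y labels coded +1 / -1 (both classes must be present).
#' @param cost regularization constant C (default 1).
#' @param tol dual convergence tolerance.
#' @param max_pass maximum coordinate-descent sweeps.
#' @param alpha0 optional dual variables from a related fit (e.g. the next
#'   smaller nested voxel set) used as a warm start.
#' @return object of class `linear_classifier` with `weights`, `bias`,
#'   `cost`, `converged`, and the dual variables `alpha`.
#' @export
train_linear_classifier <- function(X, y, cost = 1, tol = 1e-3,
                                    max_pass = 1000, alpha0 = NULL) {
  if (!is.matrix(X)) X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop("labels must be coded +1 / -1")
  if (!any(y == 1)) stop("missing class: +1")
  if (!any(y == -1)) stop("missing class: -1")
  fit <- svm_linear_cpp(X, y, cost, tol, as.integer(max_pass), alpha0)
  w <- fit$weights
  b <- fit$bias
  if (sum((drop(X %*% w) + b) * y) < 0) {
    w <- -w
    b <- -b
  }
  structure(list(weights = w, bias = b, cost = cost,
                 converged = fit$converged, passes = fit$passes,
                 alpha = fit$alpha),
            class = "linear_classifier")
}

#' @export
print.linear_classifier <- function(x, ...) {
  cat("Linear SVM:", length(x$weights), "features, cost", x$cost,
      if (x$converged) "(converged)" else "(max passes reached)", "\n")
  invisible(x)
}

#' Signed distances from the decision boundary
#'
#' @param object a `linear_classifier`.
#' @param newdata sample-by-feature matrix.
#' @param type `"decision"` for raw decision values `w.x + b`, `"class"`
#'   for their signs.
#' @param ... unused.
#' @export
predict.linear_classifier <- function(object, newdata,
                                      type = c("decision", "class"), ...) {
  type <- match.arg(type)
  d <- drop(as.matrix(newdata) %*% object$weights) + object$bias
  if (type == "class") sign(d) else d
}

#' Classifier information: mean label-matched standardized distance
#'
#' The decoding statistic: distances from the decision boundary are
#' z-scored across test samples (population SD) and averaged after
#' multiplication with the true labels,
#' \deqn{\mathrm{CI} = \frac{1}{n} \sum_i d_i l_i,}
#' where \eqn{d_i} are the standardized distances and \eqn{l_i \in \{-1,1\}}.
#' Positive values indicate above-chance decoding; the chance level is 0 by
#' construction, and the statistic is invariant to any positive rescaling
#' of the raw distances. Zero-variance distances yield 0 with a flag.
#'
#' @param distances raw signed distances for the test samples (>= 2).
#' @param labels true labels, +1 / -1.
#' @return numeric scalar, with attribute `flagged = TRUE` when the
#'   zero-variance guard fired.
#' @export
classifier_information <- function(distances, labels) {
  if (length(distances) != length(labels))
    stop("distances and labels differ in length")
  if (length(distances) < 2) stop("need at least 2 test samples")
  if (!all(labels %in% c(-1, 1))) stop("labels must be coded +1 / -1")
  m <- mean(distances)
  s <- sqrt(mean((distances - m)^2))
  if (s == 0) return(structure(0, flagged = TRUE))
  mean(((distances - m) / s) * labels)
}

# score one test cell: pooled across runs (default) or within run
score_cell <- function(d, y, runs, pooling, measure) {
  if (measure == "accuracy") return(mean(sign(d) == y))
  if (pooling == "pooled") return(as.numeric(classifier_information(d, y)))
  mean(vapply(unique(runs), function(r) {
    i <- runs == r
    as.numeric(classifier_information(d[i], y[i]))
  }, numeric(1)))
}

orientation_label <- function(condition) {
  ifelse(substr(condition, 1, 1) == "A", 1, -1)
}

#' Background-matched cross-decoding of proximal shape (Experiment 1)
#'
#' For each sub-ROI size, separate linear classifiers discriminate the two
#' object orientations against each matched scene background (A30 vs B30;
#' A90 vs B90), trained on the benchmark mini-block betas. Test samples
#' from the main task are pooled across runs within each congruency (and,
#' for congruent trials, split) by background cell before the distances are
#' z-scored; classifier information is averaged over backgrounds, over the
#' three congruent splits, and -- in the `"average"` direction -- over both
#' train/test directions (the reverse direction trains one classifier per
#' congruency-by-background-by-split cell on the main-task betas and tests
#' it on the matching-background training betas). Incongruent test labels
#' are the orientation actually shown.
#'
#' @param train stacked training-run betas (see [stack_betas()]); labels
#'   must carry `condition`, `background`, `run`.
#' @param test stacked main-task betas; labels must carry `condition`,
#'   `congruency`, `split_id`, `background`, `run`.
#' @param subrois a [make_subrois()] object.
#' @param cost SVM regularization constant.
#' @param pooling `"pooled"` (default) z-scores distances across all runs
#'   of a cell; `"within_run"` z-scores per run then averages.
#' @param measure `"information"` (classifier information, chance 0) or
#'   `"accuracy"` (classification accuracy, chance 0.5).
#' @return object of class `cinfo_curve`: data.frame with columns `roi`,
#'   `hemisphere`, `n_voxels`, `condition`, `direction`
#'   (forward / reverse / average), `info`.
#' @export
cross_decode_exp1 <- function(train, test, subrois, cost = 1,
                              pooling = c("pooled", "within_run"),
                              measure = c("information", "accuracy")) {
  pooling <- match.arg(pooling)
  measure <- match.arg(measure)
  tl <- train$labels
  ml <- test$labels
  bgs <- c("30", "90")
  cong_splits <- sort(unique(ml$split_id[ml$congruency == "congruent"]))
  if (!length(cong_splits)) stop("missing decoding cell: no congruent splits")
  cells <- rbind(
    expand.grid(congruency = "congruent", split = cong_splits, bg = bgs,
                stringsAsFactors = FALSE),
    expand.grid(congruency = "incongruent", split = NA_integer_, bg = bgs,
                stringsAsFactors = FALSE))
  ytr_all <- orientation_label(tl$condition)
  yte_all <- orientation_label(ml$condition)
  tr_rows_bg <- lapply(stats::setNames(bgs, bgs),
                       function(bg) which(tl$background == bg))
  te_rows_cell <- lapply(seq_len(nrow(cells)), function(i) {
    cc <- cells[i, ]
    w <- which(ml$congruency == cc$congruency & ml$background == cc$bg &
                 (if (is.na(cc$split)) TRUE else
                    !is.na(ml$split_id) & ml$split_id == cc$split))
    if (!length(w))
      stop("missing decoding cell: ", cc$congruency,
           if (!is.na(cc$split)) paste0(" split ", cc$split),
           " background ", cc$bg)
    w
  })

  cell_bg <- cells$bg
  rows <- list()
  k <- 0
  for (entry in subrois$entries) {
    ord <- entry$order
    Ztr <- zscore_features(train$mat[, ord, drop = FALSE])
    Zte <- zscore_features(test$mat[, ord, drop = FALSE])
    warm_bg <- list()
    warm_cell <- vector("list", nrow(cells))
    for (N in entry$counts) {
      cols <- seq_len(min(N, length(ord)))
      clf_bg <- lapply(names(tr_rows_bg), function(bg) {
        r <- tr_rows_bg[[bg]]
        clf <- train_linear_classifier(Ztr[r, cols, drop = FALSE],
                                       ytr_all[r], cost = cost,
                                       alpha0 = warm_bg[[bg]])
        warm_bg[[bg]] <<- clf$alpha
        clf
      })
      names(clf_bg) <- names(tr_rows_bg)
      fwd <- rev_ <- numeric(nrow(cells))
      for (i in seq_len(nrow(cells))) {
        cbg <- cell_bg[i]
        tei <- te_rows_cell[[i]]
        Xte <- Zte[tei, cols, drop = FALSE]
        yte <- yte_all[tei]
        fwd[i] <- score_cell(predict(clf_bg[[cbg]], Xte), yte,
                             ml$run[tei], pooling, measure)
        rclf <- train_linear_classifier(Xte, yte, cost = cost,
                                        alpha0 = warm_cell[[i]])
        warm_cell[[i]] <- rclf$alpha
        tri <- tr_rows_bg[[cbg]]
        rev_[i] <- score_cell(predict(rclf, Ztr[tri, cols, drop = FALSE]),
                              ytr_all[tri], tl$run[tri], pooling, measure)
      }
      for (cond in c("congruent", "incongruent")) {
        sel <- cells$congruency == cond
        f <- mean(fwd[sel])
        rv <- mean(rev_[sel])
        k <- k + 1
        rows[[k]] <- data.frame(
          roi = entry$roi, hemisphere = entry$hemisphere, n_voxels = N,
          condition = cond,
          direction = c("forward", "reverse", "average"),
          info = c(f, rv, (f + rv) / 2), stringsAsFactors = FALSE)
      }
    }
  }
  structure(do.call(rbind, rows), class = c("cinfo_curve", "data.frame"))
}

#' Wide-versus-narrow cross-decoding of the occluded period (Experiment 2)
#'
#' A single linear classifier per sub-ROI size discriminates wide versus
#' narrow proximal shape on the background-free training-run betas and is
#' tested on the occluded final-period betas of the main task (catch trials
#' must already be excluded, i.e. absent from the wide/narrow test rows);
#' the reverse direction trains on the occluded betas and tests on the
#' training betas, and the `"average"` direction averages the two.
#'
#' @param train stacked training betas; labels carry `shape`, `run`.
#' @param test stacked occluded-period betas; rows whose `glm_label` is not
#'   `wide`/`narrow` (catch, reappearance) are ignored.
#' @inheritParams cross_decode_exp1
#' @return `cinfo_curve` data.frame with `condition = "occluded"`.
#' @export
cross_decode_exp2 <- function(train, test, subrois, cost = 1,
                              pooling = c("pooled", "within_run"),
                              measure = c("information", "accuracy")) {
  pooling <- match.arg(pooling)
  measure <- match.arg(measure)
  tl <- train$labels
  keep <- test$labels$glm_label %in% c("wide", "narrow")
  if (!any(keep)) stop("missing decoding cell: no occluded wide/narrow rows")
  ml <- test$labels[keep, , drop = FALSE]
  ytr <- ifelse(tl$shape == "wide", 1, -1)
  yte <- ifelse(ml$glm_label == "wide", 1, -1)
  if (!any(ytr == 1) || !any(ytr == -1))
    stop("missing class in training betas")
  rows <- list()
  k <- 0
  for (entry in subrois$entries) {
    ord <- entry$order
    Ztr <- zscore_features(train$mat[, ord, drop = FALSE])
    Zte <- zscore_features(test$mat[keep, ord, drop = FALSE])
    warm_f <- warm_r <- NULL
    for (N in entry$counts) {
      cols <- seq_len(min(N, length(ord)))
      clf <- train_linear_classifier(Ztr[, cols, drop = FALSE], ytr,
                                     cost = cost, alpha0 = warm_f)
      warm_f <- clf$alpha
      f <- score_cell(predict(clf, Zte[, cols, drop = FALSE]), yte,
                      ml$run, pooling, measure)
      rclf <- train_linear_classifier(Zte[, cols, drop = FALSE], yte,
                                      cost = cost, alpha0 = warm_r)
      warm_r <- rclf$alpha
      rv <- score_cell(predict(rclf, Ztr[, cols, drop = FALSE]), ytr,
                       tl$run, pooling, measure)
      k <- k + 1
      rows[[k]] <- data.frame(
        roi = entry$roi, hemisphere = entry$hemisphere, n_voxels = N,
        condition = "occluded",
        direction = c("forward", "reverse", "average"),
        info = c(f, rv, (f + rv) / 2), stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows), class = c("cinfo_curve", "data.frame"))
}

#' Time-resolved decoding of FIR patterns
#'
#' Trains one wide-versus-narrow classifier on the training-run mini-block
#' betas of the given seed voxels and scores the FIR pattern of every
#' post-onset time bin, separately per condition, yielding a short
#' classifier-information time course per condition.
#'
#' @param train stacked training betas with a `shape` label column.
#' @param fir stacked FIR betas ([fit_fir()] across runs) with `bin`,
#'   `congruency`, `shape`, `run` label columns.
#' @param voxels integer voxel indices of the seed set.
#' @param n_bins expected number of FIR bins.
#' @param cost SVM regularization constant.
#' @return data.frame with `condition`, `bin` (0-based), `info`.
#' @export
time_resolved_decode <- function(train, fir, voxels, n_bins = 10, cost = 1) {
  bins <- sort(unique(fir$labels$bin))
  if (!identical(as.integer(bins), seq_len(n_bins) - 1L))
    stop("FIR bin count (", length(bins), ") does not match configured ",
         n_bins)
  ytr <- ifelse(train$labels$shape == "wide", 1, -1)
  Ztr <- zscore_features(train$mat[, voxels, drop = FALSE])
  Zf <- zscore_features(fir$mat[, voxels, drop = FALSE])
  clf <- train_linear_classifier(Ztr, ytr, cost = cost)
  conds <- sort(unique(fir$labels$congruency))
  out <- expand.grid(condition = conds, bin = bins,
                     stringsAsFactors = FALSE)
  out$info <- NA_real_
  yf <- ifelse(fir$labels$shape == "wide", 1, -1)
  for (i in seq_len(nrow(out))) {
    r <- which(fir$labels$congruency == out$condition[i] &
                 fir$labels$bin == out$bin[i])
    d <- predict(clf, Zf[r, , drop = FALSE])
    out$info[i] <- as.numeric(classifier_information(d, yf[r]))
  }
  out
}
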
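#' Build a first-level design matrix
#'
#' Constructs one task regressor per condition label by convolving the
#' event train with the canonical HRF on an oversampled time grid
#' (zero-duration events enter as unit impulses, positive durations as
#' boxcars), or, for the FIR basis, one 0/1 stick column per post-onset
#' time bin per condition (bin 0 aligned to the onset volume). Nuisance
#' columns are appended unconvolved, and a run intercept is always
#' included as the final nuisance regressor.
#'
#' @param events an event table (see [make_design()]); any data.frame with
#'   `onset`, `duration` and the column named by `condition_by` works.
#' @param basis `"canonical"` or `"fir"`.
#' @param n_volumes,tr_seconds run geometry; defaults read from `events`
#'   attributes.
#' @param condition_by column name(s) defining the condition labels; when
#'   several are given the interaction defines the regressors.
#' @param nuisance optional numeric matrix of nuisance columns
#'   (`n_volumes` rows), e.g. motion parameters.
#' @param n_fir_bins,fir_bin_seconds FIR geometry (defaults: 10 bins of 1 s).
#' @param oversample temporal oversampling factor for HRF convolution.
#' @param hrf optional HRF kernel sampled at `tr_seconds / oversample`;
#'   defaults to [canonical_hrf()].
#' @return object of class `design_matrix`: list with `X` (volumes x
#'   regressors), `labels` (one row per column: `column`, `regressor`,
#'   `kind`, `bin`, plus event metadata for task columns), `basis`,
#'   `tr_seconds`, `run`.
#' @export
build_design_matrix <- function(events, basis = c("canonical", "fir"),
                                n_volumes = attr(events, "n_volumes"),
                                tr_seconds = attr(events, "tr_seconds"),
                                condition_by = "glm_label",
                                nuisance = NULL,
                                n_fir_bins = 10, fir_bin_seconds = 1,
                                oversample = 4, hrf = NULL) {
  basis <- match.arg(basis)
  stopifnot(!is.null(n_volumes), !is.null(tr_seconds))
  if (nrow(events) > 0) {
    if (any(events$duration < 0)) stop("negative event duration")
    lab <- if (length(condition_by) == 1) as.character(events[[condition_by]])
    else apply(events[condition_by], 1, paste, collapse = ".")
    regs <- sort(unique(lab))
  } else {
    lab <- character(0)
    regs <- character(0)
  }

  meta_cols <- intersect(c("condition", "shape", "background", "congruency",
                           "split_id", "miniblock", "catch", "sim_label",
                           "glm_label"), names(events))

  onset <- events$onset
  duration <- events$duration
  kidx <- match(lab, regs)

  if (basis == "canonical") {
    dt <- tr_seconds / oversample
    if (is.null(hrf)) hrf <- canonical_hrf(dt, 32)
    nf <- n_volumes * oversample
    sample_idx <- seq(1, by = oversample, length.out = n_volumes)
    U <- matrix(0, nf, length(regs))
    for (i in seq_along(onset)) {
      i0 <- floor(onset[i] / dt) + 1
      if (i0 > nf) stop("event onset beyond run end")
      k <- kidx[i]
      if (duration[i] == 0) {
        U[i0, k] <- U[i0, k] + 1 / dt
      } else {
        i1 <- min(nf, i0 + ceiling(duration[i] / dt) - 1)
        U[i0:i1, k] <- U[i0:i1, k] + 1
      }
    }
    for (k in seq_along(regs)) {
      dk <- duration[kidx == k]
      if (any(dk == 0) && any(dk > 0))
        warning("regressor '", regs[k], "' mixes zero-duration events ",
                "with boxcars; zero-duration events treated as impulses")
    }
    if (length(regs)) {
      # all regressors convolved in one batched FFT
      L <- stats::nextn(nf + length(hrf) - 1, c(2, 3, 5))
      H <- stats::fft(c(hrf, numeric(L - length(hrf))))
      Upad <- rbind(U, matrix(0, L - nf, ncol(U)))
      conv <- Re(stats::mvfft(stats::mvfft(Upad) * H, inverse = TRUE)) / L
      X_task <- conv[sample_idx, , drop = FALSE] * dt
    } else {
      X_task <- matrix(0, n_volumes, 0)
    }
    col_names <- regs
    labels <- data.frame(regressor = regs, kind = rep("task", length(regs)),
                         bin = rep(NA_integer_, length(regs)),
                         events[match(regs, lab), meta_cols, drop = FALSE],
                         row.names = NULL, stringsAsFactors = FALSE)
  } else {
    bins <- seq_len(n_fir_bins) - 1L
    X_task <- matrix(0, n_volumes, length(regs) * n_fir_bins)
    col_names <- character(length(regs) * n_fir_bins)
    for (k in seq_along(regs)) {
      ev_on <- onset[kidx == k]
      for (b in bins) {
        j <- (k - 1L) * n_fir_bins + b + 1L
        v <- floor((ev_on + b * fir_bin_seconds) / tr_seconds) + 1
        v <- v[v >= 1 & v <= n_volumes]
        X_task[v, j] <- 1
        col_names[j] <- paste0(regs[k], ".bin", b)
      }
    }
    labels <- data.frame(regressor = rep(regs, each = n_fir_bins),
                         kind = "task", bin = rep(bins, length(regs)),
                         events[rep(match(regs, lab), each = n_fir_bins),
                                meta_cols, drop = FALSE],
                         row.names = NULL, stringsAsFactors = FALSE)
  }
  if (!nrow(labels))
    labels <- data.frame(regressor = character(0), kind = character(0),
                         bin = integer(0))

  nuis <- cbind(nuisance, intercept = rep(1, n_volumes))
  nuis_labels <- data.frame(regressor = colnames(nuis) %||%
                              paste0("nuisance", seq_len(ncol(nuis))),
                            kind = "nuisance", bin = NA_integer_)
  X <- cbind(X_task, nuis)
  colnames(X) <- c(col_names, nuis_labels$regressor)

  all_labels <- merge_label_frames(labels, nuis_labels)
  all_labels$column <- colnames(X)
  all_labels$run <- attr(events, "run") %||% NA_integer_

  structure(list(X = X, labels = all_labels, basis = basis,
                 n_fir_bins = if (basis == "fir") n_fir_bins else NA_integer_,
                 tr_seconds = tr_seconds,
                 n_task = ncol(X_task),
                 run = attr(events, "run") %||% NA_integer_),
            class = "design_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

merge_label_frames <- function(a, b) {
  for (nm in setdiff(names(a), names(b))) b[[nm]] <- NA
  for (nm in setdiff(names(b), names(a))) a[[nm]] <- NA
  rbind(a, b[names(a)])
}

#' Fit a voxel-wise general linear model
#'
#' Ordinary least squares by the Moore-Penrose pseudoinverse (via SVD), so
#' rank-deficient designs return the minimum-norm solution. All regressors
#' (task and nuisance) are fitted jointly; only the task rows are returned
#' as the beta maps, with nuisance estimates kept separately.
#'
#' @param ts a voxel time-series object (see [simulate_run()]) or a plain
#'   time x voxel matrix.
#' @param design a [build_design_matrix()] object.
#' @return object of class `beta_maps`: list with `estimates` (task
#'   regressors x voxels), `labels` (task label rows), `nuisance_estimates`,
#'   and `flags` naming any all-zero design columns (their estimates are 0).
#' @export
fit_glm <- function(ts, design) {
  Y <- if (is.list(ts)) ts$data else ts
  X <- design$X
  if (nrow(Y) != nrow(X))
    stop("time series rows (", nrow(Y), ") do not match design rows (",
         nrow(X), ")")
  zero_cols <- colnames(X)[colSums(X != 0) == 0]
  beta <- pinv_solve(X, Y)
  task <- design$labels$kind == "task"
  est <- beta[task, , drop = FALSE]
  rownames(est) <- design$labels$column[task]
  structure(list(estimates = est,
                 labels = design$labels[task, , drop = FALSE],
                 nuisance_estimates = beta[!task, , drop = FALSE],
                 flags = zero_cols,
                 run = design$run),
            class = "beta_maps")
}

# minimum-norm least squares: Cholesky normal equations when the design is
# well-conditioned, SVD pseudoinverse otherwise (identical solutions for
# full-rank designs, minimum-norm for rank-deficient ones)
pinv_solve <- function(X, Y) {
  XtX <- crossprod(X)
  ch <- tryCatch(chol(XtX), error = function(e) NULL)
  if (!is.null(ch)) {
    dg <- diag(ch)
    if (min(dg) > 1e-7 * max(dg))
      return(chol2inv(ch) %*% crossprod(X, Y))
  }
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * max(sv$d, 0)
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  sv$v %*% (dinv * crossprod(sv$u, Y))
}

#' Deconvolve per-condition response time courses with an FIR basis
#'
#' Convenience wrapper: builds the finite-impulse-response design for
#' `events` (default 10 bins of 1 s, bin 0 at the onset volume) and fits it
#' with [fit_glm()], yielding one amplitude estimate per condition per
#' post-onset time bin per voxel.
#'
#' @inheritParams build_design_matrix
#' @param ts voxel time series of the same run.
#' @return a `beta_maps` object whose labels carry the `bin` column.
#' @export
fit_fir <- function(ts, events, n_bins = 10, fir_bin_seconds = 1,
                    condition_by = "glm_label", nuisance = NULL) {
  Y <- if (is.list(ts)) ts$data else ts
  n_volumes <- attr(events, "n_volumes") %||% nrow(Y)
  tr <- attr(events, "tr_seconds") %||%
    (if (is.list(ts)) ts$tr_seconds else NULL) %||% 1
  dm <- build_design_matrix(events, basis = "fir",
                            n_volumes = n_volumes, tr_seconds = tr,
                            condition_by = condition_by,
                            nuisance = nuisance, n_fir_bins = n_bins,
                            fir_bin_seconds = fir_bin_seconds)
  fit_glm(ts, dm)
}

#' Stack beta maps from several runs into one sample matrix
#'
#' @param beta_list list of `beta_maps` (one per run).
#' @return list with `mat` (samples x voxels; one row per task regressor
#'   per run) and `labels` (matching rows, including `run`).
#' @export
stack_betas <- function(beta_list) {
  stopifnot(length(beta_list) >= 1)
  mat <- do.call(rbind, lapply(beta_list, function(b) b$estimates))
  labels <- do.call(rbind, lapply(beta_list, function(b) b$labels))
  rownames(mat) <- NULL
  rownames(labels) <- NULL
  list(mat = mat, labels = labels)
}
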
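#' Write tidy results and a run manifest
#'
#' Serializes a results bundle to CSV files plus a JSON manifest carrying
#' the full configuration, seed, package version, and a configuration
#' hash, so that two runs with identical configurations produce
#' byte-identical outputs.
#'
#' @param results an `mvpa_results` object.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_results <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  curves <- do.call(rbind, lapply(seq_along(results$curves), function(s) {
    cv <- results$curves[[s]]
    cv$subject <- s
    cv
  }))
  wr(curves, "curves.csv")
  wr(results$summaries, "summary.csv")

  tests_df <- do.call(rbind, lapply(names(results$tests), function(nm) {
    t <- results$tests[[nm]]
    data.frame(test = nm, statistic = t$statistic, dof = t$dof, p = t$p,
               cohens_d = t$cohens_d, ci_low = t$ci_low,
               ci_high = t$ci_high, sided = t$sided, n = t$n)
  }))
  wr(tests_df, "group_tests.csv")

  for (r in names(results$tfce)) {
    tf <- results$tfce[[r]]
    wr(data.frame(point = seq_along(tf$t), t = tf$t,
                  tfce = tf$observed_tfce, p_fwe = tf$p_fwe, z = tf$z),
       paste0("tfce_", r, ".csv"))
  }
  if (!is.null(results$univariate)) {
    wr(results$univariate$table, "univariate.csv")
  }
  if (!is.null(results$wholebrain)) {
    wr(results$wholebrain$clusters, "wholebrain_clusters.csv")
  }
  if (!is.null(results$coupling)) {
    wr(results$coupling$clusters, "coupling_clusters.csv")
  }
  if (!is.null(results$anova)) {
    wr(data.frame(F = results$anova$F, dof1 = results$anova$dof[1],
                  dof2 = results$anova$dof[2], p = results$anova$p,
                  partial_eta_sq = results$anova$partial_eta_sq),
       "interaction_anova.csv")
  }

  cfg <- results$config
  cfg$out_dir <- NULL # location metadata; results are path-independent
  manifest <- list(
    package = "mvpainfo",
    version = as.character(utils::packageVersion("mvpainfo")),
    experiment = results$experiment,
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    config = unclass(cfg),
    files = basename(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(c(files, file.path(out_dir, "manifest.json")))
}

#' Export event tables as BIDS-style TSV files
#'
#' One `events_<type>_run-XX.tsv` per run with columns `onset`,
#' `duration`, `trial_type`, `congruency`, `split_id`.
#'
#' @param design an [make_design()] object.
#' @param dir output directory.
#' @return invisibly, the files written.
#' @export
write_events_tsv <- function(design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (tp in c("main", "training", "localizer")) {
    for (r in seq_along(design[[tp]])) {
      ev <- design[[tp]][[r]]
      df <- data.frame(onset = ev$onset, duration = ev$duration,
                       trial_type = ev$condition,
                       congruency = ev$congruency,
                       split_id = ev$split_id)
      path <- file.path(dir, sprintf("events_%s_run-%02d.tsv", tp, r))
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "n/a")
      files <- c(files, path)
    }
  }
  invisible(files)
}

#' Export voxel metadata as TSV
#'
#' @param voxel_meta the metadata data.frame of a [make_subject()] truth.
#' @param path output file.
#' @export
write_voxel_meta_tsv <- function(voxel_meta, path) {
  utils::write.table(voxel_meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
  invisible(path)
}

#' Write one simulated run as a 4D NIfTI file
#'
#' Voxels are placed at their grid coordinates; requires the RNifti
#' package.
#'
#' @param vts a [simulate_run()] object.
#' @param path output `.nii` / `.nii.gz` path.
#' @export
write_run_nifti <- function(vts, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("the RNifti package is required for NIfTI export")
  meta <- vts$voxel_meta
  dims <- c(max(meta$x), max(meta$y), max(meta$z), nrow(vts$data))
  arr <- array(0, dims)
  for (v in seq_len(nrow(meta)))
    arr[meta$x[v], meta$y[v], meta$z[v], ] <- vts$data[, v]
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(1, 1, 1, vts$tr_seconds)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Plot a classifier-information curve
#'
#' Classifier information against the number of included voxels, one line
#' per condition, averaged over hemispheres.
#'
#' @param x a `cinfo_curve` data.frame.
#' @param direction decoding direction to plot.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cinfo_curve <- function(x, direction = "average", ...) {
  d <- x[x$direction == direction, , drop = FALSE]
  agg <- stats::aggregate(info ~ n_voxels + condition + roi, data = d,
                          FUN = mean)
  rois <- unique(agg$roi)
  op <- graphics::par(mfrow = c(1, length(rois)))
  on.exit(graphics::par(op))
  for (r in rois) {
    a <- agg[agg$roi == r, ]
    wide <- stats::reshape(a, idvar = "n_voxels", timevar = "condition",
                           direction = "wide")
    ns <- wide$n_voxels
    graphics::matplot(ns, wide[, -(1:2), drop = FALSE], type = "l",
                      lty = 1, xlab = "voxels included",
                      ylab = "classifier information", main = r, ...)
    graphics::abline(h = 0, col = "grey60", lty = 2)
    graphics::legend("topright", legend = sub("^info\\.", "",
                                              names(wide)[-(1:2)]),
                     col = seq_len(ncol(wide) - 2), lty = 1, bty = "n")
  }
  invisible(x)
}
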
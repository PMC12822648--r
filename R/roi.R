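#' Voxel-wise localizer t statistic
#'
#' One-sample t, across localizer runs, of the per-run stimuli-versus-
#' baseline contrast (by default the mean of the `objects` and `scrambled`
#' condition betas). With an intercept-only baseline this is the
#' responsiveness statistic used to rank voxels for sub-ROI selection.
#'
#' @param localizer_betas list of `beta_maps`, one per localizer run
#'   (at least two runs).
#' @param stimulus_conditions condition labels entering the contrast.
#' @return numeric vector of per-voxel t values with attribute
#'   `zero_variance` flagging voxels whose contrast had no variance across
#'   runs (their t is `+/-Inf`, or 0 when the mean is also 0).
#' @export
localizer_tmap <- function(localizer_betas,
                           stimulus_conditions = c("objects", "scrambled")) {
  if (length(localizer_betas) < 2)
    stop("at least two localizer runs are required")
  con <- vapply(localizer_betas, function(b) {
    rows <- b$labels$regressor %in% stimulus_conditions
    if (!any(rows)) stop("stimulus conditions not found in localizer betas")
    colMeans(b$estimates[rows, , drop = FALSE])
  }, numeric(ncol(localizer_betas[[1]]$estimates)))
  m <- rowMeans(con)
  s <- apply(con, 1, sd)
  n <- ncol(con)
  zero <- s == 0
  t <- ifelse(zero, ifelse(m == 0, 0, sign(m) * Inf), m / (s / sqrt(n)))
  attr(t, "zero_variance") <- zero
  t
}

#' Construct nested sub-ROIs by localizer ranking
#'
#' Within each ROI-by-hemisphere mask, voxels are sorted by descending
#' localizer statistic (ties broken by ascending voxel index) and the top-N
#' sets for every requested N are returned. Sets are nested by
#' construction; the default grid of 100 to 6000 in steps of 100 yields 60
#' sub-ROIs per ROI and hemisphere. Counts beyond the mask size are
#' truncated with a warning.
#'
#' @param tmap per-voxel statistic (e.g. [localizer_tmap()] or the
#'   synthetic `localizer_t` column of the voxel metadata).
#' @param voxel_meta data.frame with `roi` and `hemisphere` columns.
#' @param counts increasing positive voxel-inclusion counts.
#' @param rois,hemispheres which masks to build.
#' @return object of class `subroi_set`: list of entries, each with `roi`,
#'   `hemisphere`, `counts` (after truncation), `n_available`, and `order`
#'   (ranked voxel indices up to the largest count); the members at N are
#'   `order[1:N]`.
#' @export
make_subrois <- function(tmap, voxel_meta, counts = seq(100, 6000, by = 100),
                         rois = c("EVC", "LVC"),
                         hemispheres = c("L", "R")) {
  stopifnot(all(counts > 0), !is.unsorted(counts, strictly = TRUE))
  entries <- list()
  for (r in rois) for (h in hemispheres) {
    idx <- which(voxel_meta$roi == r & voxel_meta$hemisphere == h)
    if (!length(idx)) stop("empty mask for ", r, " ", h)
    ord <- idx[order(-tmap[idx], idx)]
    avail <- length(idx)
    cts <- counts
    if (max(counts) > avail) {
      warning("requested sub-ROI size ", max(counts), " exceeds the ", r,
              " ", h, " mask (", avail, " voxels); truncating")
      cts <- unique(pmin(counts, avail))
    }
    entries[[paste(r, h, sep = ".")]] <-
      list(roi = r, hemisphere = h, counts = cts, n_available = avail,
           order = ord[seq_len(min(max(cts), avail))])
  }
  structure(list(entries = entries, counts = counts), class = "subroi_set")
}

#' Voxel members of one sub-ROI
#'
#' @param entry one element of a [make_subrois()] `entries` list.
#' @param n inclusion count.
#' @return integer voxel indices (the top `min(n, available)` by rank).
#' @export
subroi_members <- function(entry, n) {
  entry$order[seq_len(min(n, length(entry$order)))]
}
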
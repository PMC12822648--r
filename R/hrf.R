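#' Canonical double-gamma haemodynamic response function
#'
#' Samples the conventional canonical HRF -- a gamma density peaking around
#' 5 s minus a scaled gamma undershoot peaking around 15 s -- at the
#' acquisition interval `tr_seconds`, and rescales the sampled kernel to
#' unit peak. The default shape parameters are the widely used ones:
#' response delay 6 s, undershoot delay 16 s, unit dispersions, and an
#' undershoot one sixth the size of the peak.
#'
#' @param tr_seconds sampling interval in seconds (> 0).
#' @param duration_seconds kernel length in seconds.
#' @param peak_delay,undershoot_delay gamma delays (shape/rate ratio), seconds.
#' @param peak_disp,undershoot_disp gamma dispersions (1/rate), seconds.
#' @param undershoot_ratio relative amplitude of the undershoot.
#' @return numeric vector of kernel samples at `0, tr, 2 tr, ...`, with
#'   `max(kernel) == 1`.
#' @examples
#' h <- canonical_hrf(1)
#' which.max(h) - 1L # peak latency in seconds
#' @export
canonical_hrf <- function(tr_seconds, duration_seconds = 32,
                          peak_delay = 6, undershoot_delay = 16,
                          peak_disp = 1, undershoot_disp = 1,
                          undershoot_ratio = 1 / 6) {
  stopifnot(tr_seconds > 0, duration_seconds > tr_seconds)
  t <- seq(0, duration_seconds, by = tr_seconds)
  h <- dgamma(t, shape = peak_delay / peak_disp, rate = 1 / peak_disp) -
    undershoot_ratio *
      dgamma(t, shape = undershoot_delay / undershoot_disp,
             rate = 1 / undershoot_disp)
  h / max(h)
}
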
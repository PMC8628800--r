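#' Remove short wake-flanked REM bouts from a hypnogram
#'
#' Rule-based smoothing for a characteristic scoring error: brief REM
#' predictions inside continuous wake (resting wake EEG can resemble REM).
#' Every maximal run of REM of length at most `max_bout` whose immediate left
#' and right neighbours are both WAKE is relabeled WAKE in a single
#' left-to-right pass. Runs touching either end of the sequence have a
#' missing flank and are left untouched, as are REM runs bordering NREM (the
#' physiological NREM-to-REM entry).
#'
#' The rule hook is deliberately simple so other customized smoothing rules
#' can be composed around it. Note the caveat: on predictions of poor
#' quality, or labels where true wake-flanked short REM exists, smoothing can
#' remove genuine REM.
#'
#' @param h A [hypnogram()] (or stage-label vector).
#' @param max_bout Maximum REM run length (in epochs) that is removed
#'   (default 1, the most conservative reading of "short").
#' @return A hypnogram of the same length and epoch length.
#' @examples
#' stage_sequence(smooth_rem_in_wake(hypnogram(c("WAKE", "REM", "WAKE"))))
#' @export
smooth_rem_in_wake <- function(h, max_bout = 1) {
  stopifnot(max_bout >= 1)
  s <- stage_sequence(h)
  n <- length(s)
  if (n > 0) {
    r <- rle(s)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (r$values[k] == "REM" && r$lengths[k] <= max_bout &&
          k > 1L && k < length(r$values) &&
          r$values[k - 1L] == "WAKE" && r$values[k + 1L] == "WAKE") {
        s[starts[k]:ends[k]] <- "WAKE"
      }
    }
  }
  hypnogram(s, epoch_length_s = epoch_length(h))
}
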
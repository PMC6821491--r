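#' Waveform shape metrics of a mean action potential
#'
#' The depolarization peak is the global voltage maximum and the
#' after-hyperpolarization trough the global minimum occurring after it
#' (ties broken to the earliest sample).  Half duration is half the time
#' from peak to trough; the amplitude ratio is `(n - p) / (n + p)` where
#' `n` is the maximal depolarization and `p` the magnitude of the
#' hyperpolarization.
#'
#' @param waveform Data frame with columns `time_ms` and `voltage`
#'   (ascending time).
#' @return List with `half_duration_ms`, `amplitude_ratio`, `peak_ms`,
#'   `trough_ms`, `n` and `p`.
#' @examples
#' wf <- waveform_template(n_amp = 2, p_amp = 1)
#' waveform_metrics(wf)$amplitude_ratio   # close to 1/3
#' @export
waveform_metrics <- function(waveform) {
  t <- waveform$time_ms
  v <- waveform$voltage
  if (is.unsorted(t)) stop("waveform samples must be in ascending time order")
  i_peak <- which.max(v)
  after <- seq_along(v) > i_peak
  if (!any(after)) {
    stop("waveform has no samples after the depolarization peak")
  }
  v_after <- v[after]
  i_trough <- which(after)[which.min(v_after)]
  n <- v[i_peak]
  p <- -v[i_trough]
  if (p <= 0) {
    stop("waveform has no after-hyperpolarization trough below zero")
  }
  list(half_duration_ms = (t[i_trough] - t[i_peak]) / 2,
       amplitude_ratio = (n - p) / (n + p),
       peak_ms = t[i_peak],
       trough_ms = t[i_trough],
       n = n,
       p = p)
}
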
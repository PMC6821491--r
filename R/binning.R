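#' Trial-aligned spike binning
#'
#' Computes firing rate (spikes/s) in fixed-width bins around every cue:
#' from `window_pre_s` before cue onset to `window_post_s` after cue offset.
#' With the defaults (20 s pre, 10 s cue, 20 s post, 250 ms bins) each trial
#' contributes 200 bins.  Bins are half-open `[t, t + width)` with cue onset
#' at local time 0, so the bin starting at onset is column
#' `window_pre_s / bin_width_s + 1`.
#'
#' Trials whose alignment window falls outside the recorded session are
#' excluded and reported via a message and the `excluded_trials` field.
#'
#' @param recording A `pag_neuron` (or list with `spike_times_s`,
#'   `neuron_id`).
#' @param schedule A `pag_schedule`.
#' @param bin_width_s Bin width in seconds (default 0.25).
#' @param window_pre_s,window_post_s Seconds before onset / after offset
#'   (defaults 20 and 20).
#' @param session_length_s Recorded duration used for bounds checking.
#' @return A `pag_aligned` list: `neuron_id`, `rates` (trials x bins matrix,
#'   spikes/s), `cue_type`, `trial`, bin geometry fields, and
#'   `excluded_trials`.
#' @export
bin_spikes <- function(recording, schedule,
                       bin_width_s = 0.25,
                       window_pre_s = 20,
                       window_post_s = 20,
                       session_length_s = attr(schedule, "session_length_s")) {
  dur <- unique(schedule$cue_duration_s)
  if (length(dur) != 1L) stop("mixed cue durations are not supported")
  total <- window_pre_s + dur + window_post_s
  n_bins <- total / bin_width_s
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    stop("window length must be divisible by bin_width_s")
  }
  n_bins <- as.integer(round(n_bins))
  onset <- schedule$cue_onset_s
  ok <- onset - window_pre_s >= 0 &
    onset + dur + window_post_s <= (session_length_s %||% Inf)
  if (any(!ok)) {
    message(sprintf("bin_spikes: excluding %d trial(s) whose window exceeds the session", sum(!ok)))
  }
  kept <- which(ok)
  spikes <- recording$spike_times_s
  edges0 <- seq(-window_pre_s, dur + window_post_s, by = bin_width_s)
  rates <- matrix(0, nrow = length(kept), ncol = n_bins)
  # spikes are sorted, so each trial's window is a contiguous slice
  lo <- findInterval(onset[kept] - window_pre_s, spikes, left.open = TRUE)
  hi <- findInterval(onset[kept] + dur + window_post_s, spikes,
                     left.open = TRUE)
  for (i in seq_along(kept)) {
    if (hi[i] > lo[i]) {
      rel <- spikes[(lo[i] + 1L):hi[i]] - onset[kept[i]]
      rates[i, ] <- tabulate(findInterval(rel, edges0), nbins = n_bins) /
        bin_width_s
    }
  }
  structure(list(neuron_id = recording$neuron_id,
                 rates = rates,
                 cue_type = schedule$cue_type[kept],
                 trial = schedule$trial[kept],
                 bin_width_s = bin_width_s,
                 window_pre_s = window_pre_s,
                 window_post_s = window_post_s,
                 cue_duration_s = dur,
                 excluded_trials = schedule$trial[!ok]),
            class = "pag_aligned")
}

# Column indices of the bins covering [from_s, to_s) in cue-local time.
bin_columns <- function(aligned, from_s, to_s) {
  start <- (from_s + aligned$window_pre_s) / aligned$bin_width_s
  stop <- (to_s + aligned$window_pre_s) / aligned$bin_width_s
  if (abs(start - round(start)) > 1e-9 || abs(stop - round(stop)) > 1e-9) {
    stop("window is not aligned to the bin grid")
  }
  seq.int(round(start) + 1L, round(stop))
}

#' Baseline-differential Z-score normalization
#'
#' For every trial the mean firing rate over the `baseline_s` seconds before
#' cue onset is subtracted from each of that trial's bins (differential
#' firing); the differentials of all bins of all trials are then jointly
#' Z-transformed so the unit's normalized firing has grand mean 0 and
#' standard deviation 1.  Pooling all bins (rather than only pre-cue bins)
#' keeps units with little baseline activity normalizable.
#'
#' @param aligned A `pag_aligned` from [bin_spikes()].
#' @param baseline_s Pre-cue baseline for the per-trial differential
#'   (default 2 s).
#' @param sd_type `"population"` (divisor N, default) or `"sample"`
#'   (divisor N-1) for the pooled standard deviation.
#' @return A `pag_normfiring` list like the input with `z` (trials x bins
#'   matrix), `baseline_mean` (per trial), and the pooled `center`/`scale`.
#'   A unit with zero pooled variance cannot be normalized: an error of
#'   class `pag_unnormalizable_error` is signalled so callers can drop the
#'   unit.
#' @export
normalize_firing <- function(aligned, baseline_s = 2,
                             sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (nrow(aligned$rates) < 2L) stop("need at least 2 trials to normalize")
  base_cols <- bin_columns(aligned, -baseline_s, 0)
  base_mean <- rowMeans(aligned$rates[, base_cols, drop = FALSE])
  diffs <- aligned$rates - base_mean
  mu <- mean(diffs)
  n <- length(diffs)
  sigma <- sqrt(sum((diffs - mu)^2) / if (sd_type == "population") n else n - 1)
  if (sigma == 0) {
    stop(errorCondition(
      sprintf("unit %s has zero pooled variance and cannot be Z-normalized",
              aligned$neuron_id),
      class = c("pag_unnormalizable_error", "error", "condition")))
  }
  out <- aligned
  out$z <- (diffs - mu) / sigma
  out$baseline_mean <- base_mean
  out$center <- mu
  out$scale <- sigma
  out$sd_type <- sd_type
  class(out) <- c("pag_normfiring", "pag_aligned")
  out
}

#' Mean normalized firing in an early or late cue window
#'
#' Averages Z-scored firing over the bins of the requested cue window across
#' all trials of one cue type.  `"early"` is the first half of the cue
#' (0-5 s for a 10-s cue) and `"late"` the second half.
#'
#' @param norm A `pag_normfiring`.
#' @param cue_type Cue type to average over.
#' @param window `"early"` or `"late"`.
#' @return Scalar mean Z.
#' @export
window_mean <- function(norm, cue_type, window = c("early", "late")) {
  window <- match.arg(window)
  rows <- norm$cue_type == cue_type
  if (!any(rows)) stop(sprintf("no trials of cue type '%s'", cue_type))
  half <- norm$cue_duration_s / 2
  cols <- if (window == "early") bin_columns(norm, 0, half) else
    bin_columns(norm, half, norm$cue_duration_s)
  mean(norm$z[rows, cols, drop = FALSE])
}
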
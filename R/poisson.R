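# Piecewise-constant Poisson process sampling shared by the poke and spike
# generators.  Segments are half-open [start, end) with a non-negative rate.

# Segmentation of [0, session_length) induced by the cue periods.
# `cue_rates` is a matrix with one row per trial and columns `early`, `late`
# (rates in events/s during the two cue halves; equal for an unsplit cue).
session_segments <- function(schedule, baseline_rate, cue_rates,
                             session_length_s) {
  onset <- schedule$cue_onset_s
  dur <- schedule$cue_duration_s
  mid <- onset + dur / 2
  offset <- onset + dur
  if (any(offset > session_length_s)) {
    stop("schedule extends beyond session_length_s")
  }
  bounds <- sort(unique(c(0, onset, mid, offset, session_length_s)))
  start <- bounds[-length(bounds)]
  end <- bounds[-1]
  # locate each segment relative to the trial it (possibly) falls inside
  j <- findInterval(start, onset)
  rate <- rep(baseline_rate, length(start))
  inside <- j >= 1L & start < offset[pmax(j, 1L)]
  early <- inside & start < mid[pmax(j, 1L)]
  rate[early] <- cue_rates[j[early], "early"]
  rate[inside & !early] <- cue_rates[j[inside & !early], "late"]
  data.frame(start = start, end = end, rate = rate)
}

sample_piecewise_poisson <- function(segments) {
  len <- segments$end - segments$start
  if (any(len < 0) || any(segments$rate < 0)) {
    stop("segments must have non-negative length and rate")
  }
  counts <- stats::rpois(nrow(segments), segments$rate * len)
  idx <- rep.int(seq_len(nrow(segments)), counts)
  sort(segments$start[idx] + stats::runif(length(idx)) * len[idx])
}
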
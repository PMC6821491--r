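#' Conditioned-suppression ratio
#'
#' Fear is measured by suppression of rewarded nose poking:
#' `(baseline rate - cue rate) / (baseline rate + cue rate)`.
#' A ratio of 1.00 indicates complete suppression (high fear), 0.00 none,
#' and negative values indicate facilitation.  When both rates are zero the
#' ratio is undefined and `NaN` is returned.
#'
#' @param baseline_rate Poke rate during the pre-cue baseline window
#'   (pokes/s), >= 0.
#' @param cue_rate Poke rate during the cue (pokes/s), >= 0.  Both arguments
#'   are vectorized.
#' @return Numeric ratio in \[-1, 1\], or `NaN` where undefined.
#' @examples
#' suppression_ratio(10, 0)   # 1: complete suppression
#' suppression_ratio(4, 12)   # -0.5: facilitation
#' @export
suppression_ratio <- function(baseline_rate, cue_rate) {
  if (any(baseline_rate < 0, na.rm = TRUE) || any(cue_rate < 0, na.rm = TRUE)) {
    stop("poke rates must be >= 0")
  }
  denom <- baseline_rate + cue_rate
  ifelse(denom > 0, (baseline_rate - cue_rate) / denom, NaN)
}

#' Per-trial suppression ratios for a session
#'
#' For every trial the baseline poke rate is counted over a window
#' immediately preceding cue onset and the cue rate over the full cue.
#' Trials whose baseline window would overlap the previous trial's cue or
#' shock raise a configuration error.
#'
#' @param session A `pag_session` (or any list with `schedule` and
#'   `poke_times_s`).
#' @param baseline_window_s Pre-cue baseline duration in seconds
#'   (default 20).
#' @return Data frame with columns `trial`, `cue_type`, `baseline_rate`,
#'   `cue_rate`, `ratio` (NaN where both rates are zero).
#' @export
session_suppression <- function(session, baseline_window_s = 20) {
  sch <- session$schedule
  pokes <- session$poke_times_s
  stopifnot_scalar_num(baseline_window_s, "baseline_window_s")
  if (baseline_window_s <= 0) stop("baseline_window_s must be > 0")
  onset <- sch$cue_onset_s
  prev_end <- c(-Inf, (sch$cue_onset_s + sch$cue_duration_s +
                         ifelse(sch$shock, sch$shock_latency_s, 0))[-nrow(sch)])
  if (any(onset - baseline_window_s < prev_end)) {
    stop("baseline window overlaps the previous trial's cue/shock period")
  }
  count_in <- function(lo, hi) {  # pokes in half-open [lo, hi)
    findInterval(hi, pokes, left.open = TRUE) -
      findInterval(lo, pokes, left.open = TRUE)
  }
  base_rate <- count_in(onset - baseline_window_s, onset) / baseline_window_s
  cue_rate <- count_in(onset, onset + sch$cue_duration_s) / sch$cue_duration_s
  data.frame(trial = sch$trial,
             cue_type = sch$cue_type,
             baseline_rate = base_rate,
             cue_rate = cue_rate,
             ratio = suppression_ratio(base_rate, cue_rate))
}

#' Mean differential suppression between two cue types
#'
#' The discrimination contrast for a cue pair: mean ratio of the first cue
#' type minus mean ratio of the second, after collapsing uncertainty shock
#' and omission trials (subjects cannot tell them apart during the cue) and
#' excluding undefined (0/0) ratios.
#'
#' @param records Data frame from [session_suppression()] (or several
#'   sessions' records stacked).
#' @param pair Character vector of two cue types, e.g.
#'   `c("danger", "uncertainty")`.
#' @return Single numeric difference of means.
#' @export
differential_suppression <- function(records, pair) {
  if (length(pair) != 2L) stop("pair must name two cue types")
  means <- vapply(pair, function(ct) {
    r <- records$ratio[records$cue_type == ct]
    r <- r[is.finite(r)]
    if (!length(r)) {
      stop(sprintf("cue type '%s' has no defined suppression ratios", ct))
    }
    mean(r)
  }, numeric(1))
  unname(means[1] - means[2])
}
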
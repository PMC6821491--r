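#' Generate nose-poke times for a session
#'
#' Nose poking on a variable-interval food schedule is emulated as a Poisson
#' process at `base_rate_hz` outside cues; during a cue of type `t` the rate
#' drops to `base_rate_hz * (1 - suppression_by_cue[t])`, so a suppression
#' fraction of 1 silences poking completely and 0 leaves it untouched.
#'
#' The default suppression fractions (danger 0.92, uncertainty 0.71, safety
#' 0.10) are chosen so that the expected conditioned-suppression ratios
#' f/(2-f) land near the discriminative profile typical of well-trained
#' animals: about 0.85 to danger, 0.55 to uncertainty and 0.05 to safety.
#'
#' @param schedule A `pag_schedule` from [generate_schedule()].
#' @param base_rate_hz Baseline poke rate in pokes/s (default 0.6).
#' @param suppression_by_cue Named fractions in \[0, 1\] per cue type.
#' @param seed Integer seed.
#' @param session_length_s Session duration; defaults to the schedule's.
#' @return Sorted numeric vector of poke timestamps in seconds.
#' @examples
#' sched <- generate_schedule(seed = 1)
#' pokes <- generate_pokes(sched, seed = 2)
#' @export
generate_pokes <- function(schedule,
                           base_rate_hz = 0.6,
                           suppression_by_cue = c(danger = 0.92,
                                                  uncertainty = 0.71,
                                                  safety = 0.10),
                           seed,
                           session_length_s = attr(schedule, "session_length_s")) {
  stopifnot_scalar_num(base_rate_hz, "base_rate_hz")
  if (base_rate_hz <= 0) stop("base_rate_hz must be > 0")
  types <- unique(schedule$cue_type)
  if (!all(types %in% names(suppression_by_cue))) {
    stop("suppression_by_cue must name every cue type in the schedule")
  }
  s <- suppression_by_cue[schedule$cue_type]
  if (any(s < 0 | s > 1)) stop("suppression fractions must lie in [0, 1]")
  rate <- base_rate_hz * (1 - s)
  cue_rates <- cbind(early = rate, late = rate)
  seg <- session_segments(schedule, base_rate_hz, cue_rates, session_length_s)
  with_seed(seed, sample_piecewise_poisson(seg))
}
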
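#' Default trial design of a fear-discrimination session
#'
#' A single recording session presents 32 ten-second auditory cues: 6 danger
#' trials (shock probability 1.00), 16 uncertainty trials of which 6 end in
#' shock (probability 6/16 = 0.375), and 10 safety trials (probability 0.00).
#' Foot shock follows cue offset by 2 s on shocked trials.
#'
#' @return Named integer vector with elements `danger`, `uncertainty_shock`,
#'   `uncertainty_omission`, `safety`.
#' @export
default_design <- function() {
  c(danger = 6L, uncertainty_shock = 6L, uncertainty_omission = 10L,
    safety = 10L)
}

#' Generate a randomized cue schedule for one session
#'
#' Trial types are permuted uniformly at random under `seed` and separated by
#' inter-trial intervals drawn from a shifted (truncated) exponential
#' distribution with the requested mean, so ITIs are memoryless above a floor
#' that keeps peri-cue analysis windows of neighbouring trials disjoint.
#' The ITI is the gap between the previous trial's cue offset (or session
#' start) and the next cue onset.
#'
#' @param design Named integer vector of trial counts per type; names must be
#'   `danger`, `uncertainty_shock`, `uncertainty_omission`, `safety`.
#' @param mean_iti_s Mean inter-trial interval in seconds (default 210 s,
#'   i.e. 3.5 min).
#' @param cue_duration_s Cue length in seconds (default 10).
#' @param shock_latency_s Delay from cue offset to shock on shocked trials
#'   (default 2 s).
#' @param min_iti_s Floor of the ITI distribution (default 50 s); must leave
#'   room for the 20 s pre-cue alignment window after the previous trial's
#'   20 s post-cue window.
#' @param seed Integer seed; required, the schedule is deterministic given it.
#' @return A `pag_schedule` data frame with one row per trial and columns
#'   `trial`, `cue_type` (`danger`/`uncertainty`/`safety`), `shock`,
#'   `cue_onset_s`, `cue_duration_s`, `shock_latency_s`.  The attribute
#'   `session_length_s` holds the session duration.
#' @examples
#' sched <- generate_schedule(seed = 1)
#' nrow(sched)                       # 32 trials
#' mean(sched$shock[sched$cue_type == "uncertainty"])  # 0.375
#' @export
generate_schedule <- function(design = default_design(),
                              mean_iti_s = 210,
                              cue_duration_s = 10,
                              shock_latency_s = 2,
                              min_iti_s = 50,
                              seed) {
  types <- c("danger", "uncertainty_shock", "uncertainty_omission", "safety")
  if (!all(names(design) %in% types) || is.null(names(design))) {
    stop("design must be named with: ", paste(types, collapse = ", "))
  }
  design <- design[intersect(types, names(design))]
  if (any(design != round(design)) || any(design < 0)) {
    stop("trial counts must be non-negative integers")
  }
  stopifnot_scalar_num(cue_duration_s, "cue_duration_s", min = 0)
  if (cue_duration_s <= 0) stop("cue_duration_s must be > 0")
  stopifnot_scalar_num(mean_iti_s, "mean_iti_s")
  if (mean_iti_s <= cue_duration_s + shock_latency_s) {
    stop("mean_iti_s must exceed cue_duration_s + shock_latency_s")
  }
  if (min_iti_s >= mean_iti_s) stop("min_iti_s must be below mean_iti_s")
  n <- sum(design)
  if (n == 0L) stop("design contains no trials")

  subtype <- rep(names(design), times = design)
  with_seed(seed, {
    subtype <- sample(subtype)              # uniform random trial order
    iti <- min_iti_s + stats::rexp(n, rate = 1 / (mean_iti_s - min_iti_s))
    cue_off <- cumsum(iti + cue_duration_s)
    onset <- cue_off - cue_duration_s
    sched <- data.frame(
      trial = seq_len(n),
      cue_type = sub("_(shock|omission)$", "", subtype),
      shock = subtype %in% c("danger", "uncertainty_shock"),
      cue_onset_s = onset,
      cue_duration_s = cue_duration_s,
      shock_latency_s = shock_latency_s
    )
    attr(sched, "session_length_s") <-
      cue_off[n] + shock_latency_s + min_iti_s
    attr(sched, "seed") <- check_seed(seed)
    class(sched) <- c("pag_schedule", "data.frame")
    sched
  })
}

#' Shock probability assigned to each cue type
#'
#' @param q Probability assigned to the uncertainty cue (default 0.375, the
#'   scheduled shock fraction 6/16).
#' @return Named numeric vector over `danger`, `uncertainty`, `safety`.
#' @export
cue_probabilities <- function(q = 0.375) {
  if (q < 0 || q > 1) stop("q must lie in [0, 1]")
  c(danger = 1, uncertainty = q, safety = 0)
}
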
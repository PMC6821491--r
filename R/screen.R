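#' Per-trial raw firing rates in the screening windows
#'
#' For every trial, raw firing rate (spikes/s) over the 10-s baseline just
#' before cue onset, the first 5 s of the cue (early) and the last 5 s
#' (late).  These are the paired observations used to screen for cue
#' inhibition.
#'
#' @param recording A `pag_neuron`.
#' @param schedule A `pag_schedule`.
#' @param baseline_s Baseline window length (default 10 s).
#' @return Data frame `trial`, `cue_type`, `baseline`, `early`, `late`
#'   (rates in spikes/s).
#' @export
screening_rates <- function(recording, schedule, baseline_s = 10) {
  spikes <- recording$spike_times_s
  onset <- schedule$cue_onset_s
  half <- schedule$cue_duration_s / 2
  count <- function(lo, hi) {  # spikes in half-open [lo, hi)
    findInterval(hi, spikes, left.open = TRUE) -
      findInterval(lo, spikes, left.open = TRUE)
  }
  data.frame(trial = schedule$trial,
             cue_type = schedule$cue_type,
             baseline = count(onset - baseline_s, onset) / baseline_s,
             early = count(onset, onset + half) / half,
             late = count(onset + half, onset + 2 * half) / half)
}

#' Screen one unit for cue-inhibited firing
#'
#' A unit is screened with paired two-tailed t-tests comparing its 10-s
#' baseline rate with early (first 5 s) and late (last 5 s) cue firing, for
#' the danger and uncertainty cues (uncertainty shock and omission trials
#' pooled).  The unit counts as cue-inhibited if any of the four
#' comparisons shows a significant decrease at `alpha` (default 0.0125, the
#' Bonferroni-style threshold used with this screen).  Units significant
#' only to safety can be flagged for exclusion.
#'
#' Comparisons with zero-variance paired differences have no defined t
#' statistic; they are reported as `NA` and treated as non-significant.
#'
#' @param rates Data frame from [screening_rates()].
#' @param alpha Significance threshold per comparison (default 0.0125).
#' @param screen_safety Also test the safety cue so that safety-only
#'   responders can be excluded downstream (default TRUE).
#' @return A `pag_screen` list: `tests` (data frame `cue`, `window`, `t`,
#'   `p`, `direction`, `mean_baseline`, `mean_cue`), `inhibited` (logical),
#'   `safety_only` (logical: significant to safety but to neither screened
#'   cue).
#' @export
screen_inhibited <- function(rates, alpha = 0.0125, screen_safety = TRUE) {
  stopifnot_scalar_num(alpha, "alpha")
  cues <- c("danger", "uncertainty", if (screen_safety) "safety")
  grid <- expand.grid(cue = cues, window = c("early", "late"),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    rows <- rates$cue_type == grid$cue[i]
    if (sum(rows) < 2L) stop("need at least 2 trials per screened cue")
    base <- rates$baseline[rows]
    cue <- rates[[grid$window[i]]][rows]
    tt <- tryCatch(stats::t.test(cue, base, paired = TRUE),
                   error = function(e) NULL)
    data.frame(cue = grid$cue[i], window = grid$window[i],
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p = if (is.null(tt)) NA_real_ else tt$p.value,
               direction = if (mean(cue) < mean(base)) "decrease" else "increase",
               mean_baseline = mean(base), mean_cue = mean(cue))
  })
  tests <- do.call(rbind, res)
  sig_dec <- !is.na(tests$p) & tests$p < alpha & tests$direction == "decrease"
  sig_any <- !is.na(tests$p) & tests$p < alpha
  main <- tests$cue %in% c("danger", "uncertainty")
  structure(list(tests = tests,
                 inhibited = any(sig_dec[main]),
                 safety_only = screen_safety &&
                   any(sig_any[!main]) && !any(sig_any[main]),
                 alpha = alpha),
            class = "pag_screen")
}
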
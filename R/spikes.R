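#' Construct a neuron response archetype
#'
#' An archetype describes how a synthetic unit's firing rate is modulated by
#' each cue: the baseline rate is multiplied by `early` during the first half
#' of the cue and by `late` during the second half.  Four canonical shapes
#' are provided:
#'
#' * `flip` — strongly inhibited early to danger but excited late, with
#'   sustained partial inhibition to uncertainty and little safety response;
#' * `sustain` — graded inhibition held through the whole cue
#'   (danger < uncertainty < safety, safety untouched);
#' * `onset_excited` — transient excitation to every cue onset;
#' * `flat` — no cue modulation (a null unit).
#'
#' @param label One of `"flip"`, `"sustain"`, `"onset_excited"`, `"flat"`.
#' @param baseline_rate_hz Baseline firing rate in spikes/s (default 10).
#' @param cue_gain Optional named list `cue_type -> c(early, late)` rate
#'   multipliers overriding the label's canonical shape.
#' @return A `pag_archetype` list with fields `label`, `baseline_rate_hz`,
#'   `cue_gain`.
#' @examples
#' neuron_archetype("flip")$cue_gain$danger
#' @export
neuron_archetype <- function(label = c("flip", "sustain", "onset_excited", "flat"),
                             baseline_rate_hz = 10,
                             cue_gain = NULL) {
  label <- match.arg(label)
  stopifnot_scalar_num(baseline_rate_hz, "baseline_rate_hz", min = 0)
  if (is.null(cue_gain)) {
    cue_gain <- switch(label,
      flip = list(danger = c(0.2, 2.0), uncertainty = c(0.4, 0.7),
                  safety = c(0.95, 1.0)),
      sustain = list(danger = c(0.3, 0.3), uncertainty = c(0.65, 0.65),
                     safety = c(1.0, 1.0)),
      onset_excited = list(danger = c(1.8, 1.0), uncertainty = c(1.8, 1.0),
                           safety = c(1.8, 1.0)),
      flat = list(danger = c(1, 1), uncertainty = c(1, 1), safety = c(1, 1))
    )
  }
  gains <- unlist(cue_gain)
  if (any(gains < 0)) stop("rate multipliers must be >= 0")
  if (label == "flip" &&
      !(cue_gain$danger[1] < 1 && cue_gain$danger[2] > 1)) {
    stop("a flip archetype needs danger early multiplier < 1 and late > 1")
  }
  if (label == "sustain" && any(cue_gain$danger >= 1)) {
    stop("a sustain archetype needs danger multipliers < 1")
  }
  structure(list(label = label, baseline_rate_hz = baseline_rate_hz,
                 cue_gain = lapply(cue_gain, function(g) {
                   names(g) <- c("early", "late"); g
                 })),
            class = "pag_archetype")
}

#' Biphasic mean-waveform template
#'
#' A difference-of-Gaussians action-potential shape: a depolarization peak of
#' amplitude `n_amp` at `peak_ms` followed by an after-hyperpolarization
#' trough of depth `p_amp` at `trough_ms`.  Because the construction is
#' analytic, the half-duration `(trough_ms - peak_ms) / 2` and amplitude
#' ratio `(n - p) / (n + p)` of the sampled template are known exactly
#' (up to the sampling grid).
#'
#' @param n_amp,p_amp Depolarization and hyperpolarization amplitudes
#'   (arbitrary voltage units), both > 0.
#' @param peak_ms,trough_ms Peak and trough times; `trough_ms > peak_ms`.
#' @param peak_sd_ms,trough_sd_ms Widths of the two Gaussian lobes.
#' @param dt_ms Sampling step (default 0.025 ms, i.e. 40 kHz).
#' @param span_ms Total template duration.
#' @return Data frame with columns `time_ms`, `voltage`.
#' @export
waveform_template <- function(n_amp = 100, p_amp = 40,
                              peak_ms = 0.2, trough_ms = 0.6,
                              peak_sd_ms = 0.07, trough_sd_ms = 0.16,
                              dt_ms = 0.025, span_ms = 1.4) {
  if (n_amp <= 0 || p_amp <= 0) stop("amplitudes must be > 0")
  if (trough_ms <= peak_ms) stop("trough_ms must follow peak_ms")
  t <- seq(0, span_ms, by = dt_ms)
  v <- n_amp * exp(-(t - peak_ms)^2 / (2 * peak_sd_ms^2)) -
       p_amp * exp(-(t - trough_ms)^2 / (2 * trough_sd_ms^2))
  data.frame(time_ms = t, voltage = v)
}

#' Generate an inhomogeneous Poisson spike train for one synthetic unit
#'
#' Spikes are drawn from a Poisson process whose rate is the archetype's
#' baseline outside cues, `baseline * early` during the first half of each
#' cue and `baseline * late` during the second half.  A mean waveform is
#' synthesized from [waveform_template()] with mild unit-to-unit jitter in
#' amplitudes and trough time so that waveform metrics vary across a
#' population the way sorted units do.
#'
#' @param archetype A `pag_archetype`.
#' @param schedule A `pag_schedule`.
#' @param seed Integer seed for this unit.
#' @param neuron_id Identifier string (default derived from the seed).
#' @param session_length_s Session duration; defaults to the schedule's.
#' @return A `pag_neuron` list: `neuron_id`, `spike_times_s` (sorted),
#'   `waveform` (data frame `time_ms`, `voltage`), `archetype` label, and the
#'   generating parameters.
#' @examples
#' sched <- generate_schedule(seed = 1)
#' nrn <- generate_spikes(neuron_archetype("flip"), sched, seed = 7)
#' @export
generate_spikes <- function(archetype, schedule, seed,
                            neuron_id = sprintf("unit_%d", check_seed(seed)),
                            session_length_s = attr(schedule, "session_length_s")) {
  if (!inherits(archetype, "pag_archetype")) {
    stop("archetype must come from neuron_archetype()")
  }
  if (nrow(schedule) == 0L) stop("schedule has no trials")
  gain <- archetype$cue_gain
  base <- archetype$baseline_rate_hz
  cue_rates <- base * t(vapply(schedule$cue_type,
                               function(ct) gain[[ct]], numeric(2)))
  colnames(cue_rates) <- c("early", "late")
  seg <- session_segments(schedule, base, cue_rates, session_length_s)
  with_seed(seed, {
    spikes <- sample_piecewise_poisson(seg)
    wf <- waveform_template(
      n_amp = 100 * stats::runif(1, 0.85, 1.15),
      p_amp = 40 * stats::runif(1, 0.85, 1.15),
      trough_ms = 0.6 + stats::runif(1, -0.05, 0.05)
    )
    structure(list(neuron_id = neuron_id,
                   spike_times_s = spikes,
                   waveform = wf,
                   archetype = archetype$label,
                   baseline_rate_hz = base,
                   seed = check_seed(seed)),
              class = "pag_neuron")
  })
}

#' @export
print.pag_neuron <- function(x, ...) {
  cat(sprintf("<pag_neuron %s> %s archetype, %d spikes, baseline %.1f Hz\n",
              x$neuron_id, x$archetype, length(x$spike_times_s),
              x$baseline_rate_hz))
  invisible(x)
}
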
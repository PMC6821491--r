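# Small builders shared across test files.

# A schedule with few trials and short ITIs so fixtures stay fast.
tiny_schedule <- function(seed = 1,
                          design = c(danger = 2, uncertainty_shock = 1,
                                     uncertainty_omission = 2, safety = 2),
                          mean_iti_s = 80, min_iti_s = 45) {
  generate_schedule(design, mean_iti_s = mean_iti_s, min_iti_s = min_iti_s,
                    seed = seed)
}

# A hand-laid schedule with exactly known onsets (one trial per cue type).
fixed_schedule <- function(cue_types = c("danger", "uncertainty", "safety"),
                           spacing_s = 100, cue_duration_s = 10) {
  n <- length(cue_types)
  sched <- data.frame(trial = seq_len(n),
                      cue_type = cue_types,
                      shock = cue_types == "danger",
                      cue_onset_s = spacing_s * seq_len(n),
                      cue_duration_s = cue_duration_s,
                      shock_latency_s = 2)
  attr(sched, "session_length_s") <- spacing_s * (n + 1)
  class(sched) <- c("pag_schedule", "data.frame")
  sched
}

# Wrap explicit spike times as a recording.
as_recording <- function(spike_times, neuron_id = "unit") {
  structure(list(neuron_id = neuron_id,
                 spike_times_s = sort(spike_times),
                 waveform = waveform_template(),
                 archetype = NA_character_,
                 baseline_rate_hz = NA_real_,
                 seed = NA_integer_),
            class = "pag_neuron")
}

# Normalized-firing object built directly from a given Z matrix, bypassing
# spikes, for tests that need exact Z values.
as_normfiring <- function(z, cue_type, bin_width_s = 0.25,
                          window_pre_s = 20, window_post_s = 20,
                          cue_duration_s = 10) {
  structure(list(neuron_id = "unit", rates = z, z = z,
                 cue_type = cue_type, trial = seq_len(nrow(z)),
                 bin_width_s = bin_width_s, window_pre_s = window_pre_s,
                 window_post_s = window_post_s,
                 cue_duration_s = cue_duration_s,
                 excluded_trials = integer()),
            class = c("pag_normfiring", "pag_aligned"))
}

# Session-like object from explicit pokes and schedule.
as_session <- function(schedule, poke_times) {
  structure(list(schedule = schedule, poke_times_s = sort(poke_times),
                 session_length_s = attr(schedule, "session_length_s"),
                 neurons = list(), truth = NULL, seed = NA_integer_),
            class = "pag_session")
}
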
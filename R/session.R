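#' Simulate a full recording session with planted ground truth
#'
#' Draws a randomized cue schedule, a suppressed nose-poke train, and one
#' spike train per requested archetype.  All randomness descends from the
#' single `seed`: the schedule, the poke train and each neuron receive
#' documented sub-seeds derived from it, so sessions are bit-reproducible.
#'
#' @param roster Named integer vector of neuron counts per archetype label,
#'   e.g. `c(flip = 40, sustain = 40)`.
#' @param seed Master integer seed.
#' @param design,mean_iti_s Passed to [generate_schedule()].
#' @param baseline_rate_hz Baseline firing rate shared by all units.
#' @param poke_rate_hz,suppression_by_cue Passed to [generate_pokes()].
#' @return A `pag_session` list: `schedule`, `poke_times_s`,
#'   `session_length_s`, `neurons` (list of `pag_neuron`), `truth` (data
#'   frame `neuron_id`, `archetype`), `seed`.
#' @examples
#' sess <- simulate_session(c(flip = 2, flat = 1), seed = 42)
#' sess$truth
#' @export
simulate_session <- function(roster = c(flip = 1, sustain = 1, flat = 1),
                             seed,
                             design = default_design(),
                             mean_iti_s = 210,
                             baseline_rate_hz = 10,
                             poke_rate_hz = 0.6,
                             suppression_by_cue = c(danger = 0.92,
                                                    uncertainty = 0.71,
                                                    safety = 0.10)) {
  if (is.null(names(roster)) || any(roster < 0)) {
    stop("roster must be a named vector of non-negative counts")
  }
  n_neurons <- sum(roster)
  sub <- derive_subseeds(seed, 2L + n_neurons)
  schedule <- generate_schedule(design, mean_iti_s = mean_iti_s, seed = sub[1])
  pokes <- generate_pokes(schedule, base_rate_hz = poke_rate_hz,
                          suppression_by_cue = suppression_by_cue,
                          seed = sub[2])
  labels <- rep(names(roster), times = roster)
  neurons <- vector("list", n_neurons)
  for (i in seq_len(n_neurons)) {
    neurons[[i]] <- generate_spikes(
      neuron_archetype(labels[i], baseline_rate_hz = baseline_rate_hz),
      schedule, seed = sub[2L + i],
      neuron_id = sprintf("n%03d_%s", i, labels[i])
    )
  }
  structure(list(schedule = schedule,
                 poke_times_s = pokes,
                 session_length_s = attr(schedule, "session_length_s"),
                 neurons = neurons,
                 truth = data.frame(
                   neuron_id = vapply(neurons, `[[`, "", "neuron_id"),
                   archetype = labels),
                 seed = check_seed(seed)),
            class = "pag_session")
}

#' @export
print.pag_session <- function(x, ...) {
  cat(sprintf("<pag_session> %d trials, %d pokes, %d neurons, seed %d\n",
              nrow(x$schedule), length(x$poke_times_s),
              length(x$neurons), x$seed))
  invisible(x)
}

#' Write a simulated session as plain comma-separated tables
#'
#' Produces `events.csv` (`event_type` in cue_on/cue_off/shock/poke,
#' `time_s`, `trial_index`, `cue_type`), `spikes.csv` (`neuron_id`,
#' `time_s`) and `waveforms.csv` (`neuron_id`, `time_ms`, `voltage`).
#'
#' @param session A `pag_session`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_session_tables <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sch <- session$schedule
  events <- rbind(
    data.frame(event_type = "cue_on", time_s = sch$cue_onset_s,
               trial_index = sch$trial, cue_type = sch$cue_type),
    data.frame(event_type = "cue_off",
               time_s = sch$cue_onset_s + sch$cue_duration_s,
               trial_index = sch$trial, cue_type = sch$cue_type),
    data.frame(event_type = "shock",
               time_s = (sch$cue_onset_s + sch$cue_duration_s +
                           sch$shock_latency_s)[sch$shock],
               trial_index = sch$trial[sch$shock],
               cue_type = sch$cue_type[sch$shock]),
    data.frame(event_type = "poke", time_s = session$poke_times_s,
               trial_index = NA_integer_, cue_type = NA_character_)
  )
  events <- events[order(events$time_s), ]
  spikes <- do.call(rbind, lapply(session$neurons, function(n) {
    data.frame(neuron_id = n$neuron_id, time_s = n$spike_times_s)
  }))
  waves <- do.call(rbind, lapply(session$neurons, function(n) {
    cbind(neuron_id = n$neuron_id, n$waveform)
  }))
  paths <- file.path(dir, c("events.csv", "spikes.csv", "waveforms.csv"))
  utils::write.csv(events, paths[1], row.names = FALSE)
  utils::write.csv(spikes, paths[2], row.names = FALSE)
  utils::write.csv(waves, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Read a session back from its events/spikes/waveforms tables
#'
#' Accepts the dialect written by [write_session_tables()] (or user data in
#' the same shape) and reconstructs the schedule, poke train and neurons.
#'
#' @param dir Directory holding `events.csv`, `spikes.csv`, `waveforms.csv`.
#' @return A `pag_session` (without planted `truth` or `seed`).
#' @export
read_session_tables <- function(dir) {
  events <- utils::read.csv(file.path(dir, "events.csv"))
  spikes <- utils::read.csv(file.path(dir, "spikes.csv"))
  waves_path <- file.path(dir, "waveforms.csv")
  waves <- if (file.exists(waves_path)) utils::read.csv(waves_path) else NULL
  on_ev <- events[events$event_type == "cue_on", ]
  off_ev <- events[events$event_type == "cue_off", ]
  shock_ev <- events[events$event_type == "shock", ]
  on_ev <- on_ev[order(on_ev$trial_index), ]
  off_ev <- off_ev[order(off_ev$trial_index), ]
  dur <- off_ev$time_s - on_ev$time_s
  latency <- if (nrow(shock_ev)) {
    shock_ev$time_s[1] - off_ev$time_s[match(shock_ev$trial_index[1],
                                             off_ev$trial_index)]
  } else 2
  sched <- data.frame(trial = on_ev$trial_index,
                      cue_type = on_ev$cue_type,
                      shock = on_ev$trial_index %in% shock_ev$trial_index,
                      cue_onset_s = on_ev$time_s,
                      cue_duration_s = dur,
                      shock_latency_s = latency)
  last <- max(events$time_s,
              if (nrow(spikes)) max(spikes$time_s) else 0)
  attr(sched, "session_length_s") <- last
  class(sched) <- c("pag_schedule", "data.frame")
  ids <- unique(spikes$neuron_id)
  neurons <- lapply(ids, function(id) {
    wf <- if (!is.null(waves)) {
      w <- waves[waves$neuron_id == id, c("time_ms", "voltage")]
      rownames(w) <- NULL
      w
    } else NULL
    structure(list(neuron_id = id,
                   spike_times_s = sort(spikes$time_s[spikes$neuron_id == id]),
                   waveform = wf,
                   archetype = NA_character_,
                   baseline_rate_hz = NA_real_,
                   seed = NA_integer_),
              class = "pag_neuron")
  })
  structure(list(schedule = sched,
                 poke_times_s = sort(events$time_s[events$event_type == "poke"]),
                 session_length_s = last,
                 neurons = neurons,
                 truth = NULL,
                 seed = NA_integer_),
            class = "pag_session")
}
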
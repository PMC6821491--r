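test_that("schedules honour the session design exactly, every seed", {
  for (seed in 1:20) {
    sched <- generate_schedule(seed = seed)
    expect_equal(nrow(sched), 32L)
    expect_equal(sum(sched$cue_type == "danger"), 6L)
    expect_equal(sum(sched$cue_type == "uncertainty"), 16L)
    expect_equal(sum(sched$cue_type == "safety"), 10L)
    expect_equal(mean(sched$shock[sched$cue_type == "uncertainty"]), 0.375)
    expect_true(all(sched$shock[sched$cue_type == "danger"]))
    expect_false(any(sched$shock[sched$cue_type == "safety"]))
    expect_true(all(diff(sched$cue_onset_s) > 0))
  }
})

test_that("a single-safety design yields one unshocked trial", {
  sched <- generate_schedule(c(danger = 0, uncertainty_shock = 0,
                               uncertainty_omission = 0, safety = 1),
                             seed = 4)
  expect_equal(nrow(sched), 1L)
  expect_false(sched$shock)
})

test_that("schedule generation is seed-deterministic and validates input", {
  expect_identical(generate_schedule(seed = 7), generate_schedule(seed = 7))
  expect_false(identical(generate_schedule(seed = 7)$cue_onset_s,
                         generate_schedule(seed = 8)$cue_onset_s))
  expect_error(generate_schedule(c(danger = 1.5, uncertainty_shock = 0,
                                   uncertainty_omission = 0, safety = 0),
                                 seed = 1),
               "non-negative integers")
  expect_error(generate_schedule(), "seed")
  expect_error(generate_schedule(seed = 1, mean_iti_s = 5),
               "must exceed")
})

test_that("sampled ITIs have the configured mean", {
  sched <- generate_schedule(
    c(danger = 250, uncertainty_shock = 0, uncertainty_omission = 0,
      safety = 250), mean_iti_s = 210, seed = 2)
  gaps <- diff(sched$cue_onset_s) - sched$cue_duration_s[1]
  # mean 210, sd 160 per gap: check the empirical mean within 4 SE
  expect_lt(abs(mean(gaps) - 210), 4 * 160 / sqrt(length(gaps)))
  expect_true(all(gaps >= 50))
})

test_that("pokes follow a homogeneous Poisson process when unsuppressed", {
  sched <- tiny_schedule(seed = 1)
  len <- attr(sched, "session_length_s")
  pokes <- generate_pokes(sched, base_rate_hz = 0.5,
                          suppression_by_cue = c(danger = 0, uncertainty = 0,
                                                 safety = 0), seed = 9)
  expect_lt(abs(length(pokes) - 0.5 * len), 4 * sqrt(0.5 * len))
  expect_true(!is.unsorted(pokes) && all(pokes >= 0 & pokes <= len))
})

test_that("full danger suppression silences poking inside every danger cue", {
  sched <- tiny_schedule(seed = 3)
  pokes <- generate_pokes(sched, base_rate_hz = 2,
                          suppression_by_cue = c(danger = 1, uncertainty = 0,
                                                 safety = 0), seed = 10)
  dg <- sched[sched$cue_type == "danger", ]
  for (i in seq_len(nrow(dg))) {
    expect_equal(sum(pokes >= dg$cue_onset_s[i] &
                       pokes < dg$cue_onset_s[i] + dg$cue_duration_s[i]), 0L)
  }
  expect_error(generate_pokes(sched, base_rate_hz = -1, seed = 1), ">")
})

test_that("partial suppression reproduces the closed-form in-cue poke mean", {
  # danger suppression 0.9 at base 0.5 Hz over a 10-s cue: mean count 0.5
  sched <- fixed_schedule("danger")
  counts <- vapply(1:400, function(s) {
    p <- generate_pokes(sched, base_rate_hz = 0.5,
                        suppression_by_cue = c(danger = 0.9), seed = s)
    sum(p >= sched$cue_onset_s & p < sched$cue_onset_s + 10)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 0.5), 4 * sqrt(0.5 / 400))
})

test_that("flat archetypes spike at baseline rate; zero baseline is silent", {
  sched <- tiny_schedule(seed = 5)
  nrn <- generate_spikes(neuron_archetype("flat", baseline_rate_hz = 10),
                         sched, seed = 21)
  len <- attr(sched, "session_length_s")
  for (w in list(c(0, 100), c(len - 100, len))) {
    n_w <- sum(nrn$spike_times_s >= w[1] & nrn$spike_times_s < w[2])
    expect_lt(abs(n_w / 100 - 10), 4 * sqrt(10 / 100))
  }
  silent <- generate_spikes(neuron_archetype("flat", baseline_rate_hz = 0),
                            sched, seed = 22)
  expect_length(silent$spike_times_s, 0)
})

test_that("flip archetypes express the planted early:late danger rate ratio", {
  sched <- fixed_schedule("danger")
  arch <- neuron_archetype("flip", baseline_rate_hz = 20,
                           cue_gain = list(danger = c(0.2, 2.0),
                                           uncertainty = c(0.4, 0.7),
                                           safety = c(1, 1)))
  early <- late <- numeric(300)
  for (s in 1:300) {
    sp <- generate_spikes(arch, sched, seed = s)$spike_times_s
    on <- sched$cue_onset_s
    early[s] <- sum(sp >= on & sp < on + 5)
    late[s] <- sum(sp >= on + 5 & sp < on + 10)
  }
  # planted rates: 4 Hz early, 40 Hz late over 5 s windows
  expect_lt(abs(mean(early) - 20), 3 * sqrt(20 / 300))
  expect_lt(abs(mean(late) - 200), 3 * sqrt(200 / 300))
  expect_lt(abs(mean(early) / mean(late) - 0.1), 0.01)
})

test_that("spike generation is bit-reproducible under a seed", {
  sched <- tiny_schedule(seed = 2)
  a <- generate_spikes(neuron_archetype("sustain"), sched, seed = 33)
  b <- generate_spikes(neuron_archetype("sustain"), sched, seed = 33)
  expect_identical(a, b)
  expect_error(generate_spikes(neuron_archetype("flat"), sched[0, ], seed = 1),
               "no trials")
})

test_that("archetype constructors enforce their shape constraints", {
  expect_error(neuron_archetype("flip",
                                cue_gain = list(danger = c(1.2, 2),
                                                uncertainty = c(1, 1),
                                                safety = c(1, 1))),
               "flip")
  expect_error(neuron_archetype("sustain",
                                cue_gain = list(danger = c(1, 1),
                                                uncertainty = c(1, 1),
                                                safety = c(1, 1))),
               "sustain")
  expect_error(neuron_archetype("flat",
                                cue_gain = list(danger = c(-1, 1),
                                                uncertainty = c(1, 1),
                                                safety = c(1, 1))),
               ">= 0")
})

test_that("waveform template peak/trough ground truth is analytic", {
  wf <- waveform_template(n_amp = 100, p_amp = 40, peak_ms = 0.2,
                          trough_ms = 0.6)
  expect_equal(wf$time_ms[which.max(wf$voltage)], 0.2, tolerance = 0.03)
  i_peak <- which.max(wf$voltage)
  after <- wf$voltage[seq_along(wf$voltage) > i_peak]
  expect_equal(wf$time_ms[i_peak + which.min(after)], 0.6, tolerance = 0.03)
  expect_error(waveform_template(trough_ms = 0.1), "follow")
})

test_that("sessions with ordered planted suppression yield ordered ratios", {
  diffs <- t(vapply(1:30, function(s) {
    sess <- simulate_session(
      roster = c(flat = 0), seed = s,
      design = c(danger = 4, uncertainty_shock = 2,
                 uncertainty_omission = 4, safety = 4),
      mean_iti_s = 90,
      suppression_by_cue = c(danger = 0.95, uncertainty = 0.5, safety = 0))
    sup <- session_suppression(sess)
    m <- tapply(sup$ratio, sup$cue_type, mean, na.rm = TRUE)
    c(m[["danger"]], m[["uncertainty"]], m[["safety"]])
  }, numeric(3)))
  means <- colMeans(diffs, na.rm = TRUE)
  expect_gt(means[1], means[2])
  expect_gt(means[2], means[3])
})

test_that("simulated sessions round-trip through the csv table dialect", {
  sess <- simulate_session(c(flip = 1, flat = 1), seed = 17,
                           design = c(danger = 2, uncertainty_shock = 1,
                                      uncertainty_omission = 1, safety = 2),
                           mean_iti_s = 90)
  dir <- withr::local_tempdir()
  write_session_tables(sess, dir)
  back <- read_session_tables(dir)
  expect_equal(back$schedule$cue_onset_s, sess$schedule$cue_onset_s,
               tolerance = 1e-9)
  expect_equal(back$schedule$cue_type, sess$schedule$cue_type)
  expect_equal(back$schedule$shock, sess$schedule$shock)
  expect_equal(back$poke_times_s, sess$poke_times_s, tolerance = 1e-9)
  expect_equal(back$neurons[[1]]$spike_times_s,
               sess$neurons[[1]]$spike_times_s, tolerance = 1e-9)
})
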
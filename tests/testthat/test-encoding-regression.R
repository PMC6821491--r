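# Interval matrix for a synthetic unit whose firing is planted as
# beta0 * standardized probability regressor (uncertainty assigned q_true)
# plus Gaussian noise, in every cue interval.
planted_intervals <- function(cue_type, q_true, beta0, noise_sd,
                              n_intervals = 14) {
  x <- unname(cue_probabilities(q_true)[cue_type])
  xs <- as.vector(scale(x))
  y <- matrix(rnorm(length(x) * n_intervals, sd = noise_sd),
              ncol = n_intervals) + beta0 * xs
  attr(y, "cue_type") <- cue_type
  y
}

session_cue_types <- function(seed = 1) {
  generate_schedule(seed = seed)$cue_type
}

test_that("interval firing averages each group of four 250-ms bins", {
  z <- matrix(0, nrow = 3, ncol = 200)
  z[, 81:84] <- 1                        # first cue second
  z[2, 73:76] <- c(2, 4, 6, 8)           # first pre-cue second, trial 2
  nm <- as_normfiring(z, c("danger", "uncertainty", "safety"))
  iv <- interval_firing(nm)
  expect_equal(ncol(iv), 14L)
  expect_equal(attr(iv, "interval_start_s"), -2:11)
  expect_equal(iv[, 3], rep(1, 3))       # cue onset interval
  expect_equal(iv[2, 1], 5)              # mean of 2,4,6,8
  expect_equal(sum(iv[3, -3]), 0)
  # all-zero input stays all-zero
  expect_equal(interval_firing(as_normfiring(matrix(0, 2, 200),
                                             c("danger", "safety"))),
               matrix(0, 2, 14), ignore_attr = TRUE)
})

test_that("interval means agree with the mean of the in-window 250-ms bins", {
  set.seed(11)
  z <- matrix(rnorm(5 * 200), nrow = 5)
  nm <- as_normfiring(z, rep(c("danger", "safety"), length.out = 5))
  iv <- interval_firing(nm)
  for (tr in 1:5) {
    expect_equal(mean(iv[tr, ]), mean(z[tr, 73:128]), tolerance = 1e-12)
  }
})

test_that("regressor construction assigns probabilities and fear output", {
  rec <- data.frame(trial = 1:4,
                    cue_type = c("danger", "uncertainty", "uncertainty",
                                 "safety"),
                    baseline_rate = 1, cue_rate = 0,
                    ratio = c(0.9, 0.5, NaN, 0.05))
  reg <- trial_regressors(rec)
  expect_equal(reg$probability, c(1, 0.375, 0.375, 0))
  expect_equal(reg$fear_output[1:2], c(0.9, 0.5))
  expect_true(is.nan(reg$fear_output[3]))
  expect_error(trial_regressors(rec, q = 1.5), "\\[0, 1\\]")
  # q endpoints: the probability regressor degenerates to cue indicators
  ct <- c("danger", "uncertainty", "safety", "uncertainty")
  expect_equal(unname(cue_probabilities(1)[ct]),
               as.numeric(ct %in% c("danger", "uncertainty")))
  expect_equal(unname(cue_probabilities(0)[ct]),
               as.numeric(ct == "danger"))
})

test_that("firing equal to the standardized regressor gives beta 1", {
  ct <- session_cue_types(3)
  x <- as.vector(scale(unname(cue_probabilities(0.375)[ct])))
  iv <- matrix(rep(x, 14), ncol = 14)
  attr(iv, "cue_type") <- ct
  reg <- data.frame(trial = seq_along(ct), cue_type = ct, probability = x)
  b <- fit_betas(iv, reg)
  expect_equal(b$beta, rep(1, 14), tolerance = 1e-10)
})

test_that("betas are near zero for firing independent of the regressors", {
  ct <- session_cue_types(5)
  reg <- data.frame(trial = seq_along(ct), cue_type = ct,
                    probability = unname(cue_probabilities(0.375)[ct]))
  set.seed(21)
  betas <- replicate(600, {
    iv <- matrix(rnorm(32), ncol = 1)
    fit_betas(iv, reg)$beta
  })
  # null standardized betas have SD ~ 1/sqrt(n-1)
  se <- 1 / sqrt(31) / sqrt(600)
  expect_lt(abs(mean(betas)), 3 * se)
})

test_that("planted negative coupling is recovered at the attenuated value", {
  # closed form: cor = beta0 / sqrt(beta0^2 + sd^2) for y = beta0*x + noise
  ct <- session_cue_types(8)
  x <- as.vector(scale(unname(cue_probabilities(0.375)[ct])))
  reg <- data.frame(trial = seq_along(ct), cue_type = ct, probability = x)
  beta0 <- -0.8; sd_n <- 0.2
  set.seed(31)
  est <- replicate(400, {
    iv <- matrix(beta0 * x + rnorm(32, sd = sd_n), ncol = 1)
    fit_betas(iv, reg)$beta
  })
  expect_equal(mean(est), beta0 / sqrt(beta0^2 + sd_n^2), tolerance = 0.05)
})

test_that("undefined fear-output trials are dropped pairwise", {
  ct <- session_cue_types(2)
  fo <- runif(32)
  fo[c(3, 17)] <- NaN
  keep <- is.finite(fo)
  iv <- matrix(rnorm(32 * 14), ncol = 14)
  reg <- data.frame(trial = 1:32, cue_type = ct, fear_output = fo)
  b <- fit_betas(iv, reg)
  direct <- vapply(1:14, function(j) cor(iv[keep, j], fo[keep]), numeric(1))
  expect_equal(b$beta, direct, tolerance = 1e-12)
  # zero regressor variance is flagged, not silently fit
  regc <- data.frame(trial = 1:32, cue_type = ct, probability = 1)
  expect_warning(bc <- fit_betas(iv, regc), "zero variance")
  expect_true(all(is.na(bc$beta)))
})

test_that("separate and joint modes agree for orthogonalized regressors", {
  ct <- session_cue_types(13)
  x1 <- as.vector(scale(unname(cue_probabilities(0.375)[ct])))
  set.seed(41)
  x2 <- rnorm(32)
  x2 <- as.vector(scale(residuals(lm(x2 ~ x1))))   # orthogonal to x1
  iv <- matrix(rnorm(32 * 14), ncol = 14)
  reg <- data.frame(trial = 1:32, cue_type = ct, a = x1, b = x2)
  sep <- fit_betas(iv, reg, mode = "separate_simple")
  joint <- fit_betas(iv, reg, mode = "joint")
  ord <- order(sep$regressor, sep$interval)
  expect_equal(sep$beta[ord], joint$beta[order(joint$regressor,
                                               joint$interval)],
               tolerance = 1e-10)
})

test_that("tuning curves have nine points and recover a planted assignment", {
  ct <- session_cue_types(17)
  set.seed(51)
  neurons <- lapply(1:40, function(i) {
    list(intervals = planted_intervals(ct, q_true = 0.5, beta0 = 0.6,
                                       noise_sd = 0.3), cue_type = ct)
  })
  tc <- tuning_curve(neurons, epoch = "early")
  expect_equal(nrow(tc), 9L)
  expect_equal(tc$q, seq(0, 1, by = 0.125))
  expect_equal(sum(tc$is_extremum), 1L)
  ext <- attr(tc, "extremum")
  expect_equal(ext$q, 0.5)
  expect_equal(ext$kind, "peak")
  # sign-flipping all firing flips peak to trough at the same assignment
  flipped <- lapply(neurons, function(nn) {
    nn$intervals <- -nn$intervals; nn
  })
  tf <- tuning_curve(flipped, epoch = "early")
  expect_equal(attr(tf, "extremum")$q, 0.5)
  expect_equal(attr(tf, "extremum")$kind, "trough")
  expect_equal(tf$mean_beta, -tc$mean_beta, tolerance = 1e-12)
  expect_error(tuning_curve(list(), epoch = "early"), "empty")
})

test_that("population beta statistics reduce to closed forms", {
  ints <- interval_epochs()
  grid <- expand.grid(neuron_id = sprintf("u%d", 1:8),
                      regressor = c("fear_output", "probability"),
                      interval = 1:14, stringsAsFactors = FALSE)
  # all betas equal 0.4: CI degenerates to [c, c], sign test p = 2 * 0.5^8
  betas <- grid
  betas$beta <- 0.4
  st <- suppressWarnings(beta_population_stats(betas, seed = 3,
                                               n_resamples = 200))
  expect_true(all(abs(st$ci$mean - 0.4) < 1e-12))
  expect_true(all(abs(st$ci$lower - 0.4) < 1e-12 &
                    abs(st$ci$upper - 0.4) < 1e-12))
  expect_equal(unique(st$sign$p), 2 * 0.5^8)
  # symmetric +/- betas in equal numbers: sign test p = 1
  betas$beta <- rep(c(0.3, -0.3), length.out = nrow(betas) / 14)
  st2 <- suppressWarnings(beta_population_stats(betas, seed = 3,
                                                n_resamples = 200))
  expect_true(all(st2$sign$p == 1))
  # identical betas across regressors: R squared 1
  set.seed(61)
  b <- rnorm(8)
  betas$beta <- b[match(betas$neuron_id, sprintf("u%d", 1:8))]
  st3 <- beta_population_stats(betas, seed = 3, n_resamples = 200)
  expect_equal(st3$correlation$r_squared, c(1, 1), tolerance = 1e-12)
})
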
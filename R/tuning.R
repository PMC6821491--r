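#' Threat-probability tuning curve
#'
#' Repeats the single-unit probability regression nine times, sweeping the
#' probability assigned to the uncertainty cue over
#' `0.000, 0.125, ..., 1.000` while danger stays 1.00 and safety 0.00.
#' For each assignment, per-interval betas over the cue are averaged within
#' the requested epoch (early = first 5 cue intervals, late = last 5) for
#' each unit, then across units.  The tuning extremum is the assignment
#' with the largest absolute mean beta — a peak if the mean beta there is
#' positive, a trough if negative.  At `q = 1` the regressor is the binary
#' danger-or-uncertainty indicator; at `q = 0` it is the danger indicator.
#'
#' @param neurons List of units, each a list with `intervals` (trials x
#'   intervals matrix from [interval_firing()]) and `cue_type` (per-trial
#'   types; taken from the matrix attribute when absent).
#' @param epoch `"early"` or `"late"`.
#' @param q_grid Uncertainty probability assignments (default the nine
#'   values 0 to 1 in steps of 0.125).
#' @param pre_s,cue_s,interval_s Interval geometry (defaults 2, 10, 1).
#' @return A `pag_tuning` data frame `q`, `mean_beta`, `is_extremum`, with
#'   attributes `epoch` and `extremum` (list `q`, `beta`,
#'   `kind` = `"peak"`/`"trough"`).
#' @export
tuning_curve <- function(neurons, epoch = c("early", "late"),
                         q_grid = seq(0, 1, by = 0.125),
                         pre_s = 2, cue_s = 10, interval_s = 1) {
  epoch <- match.arg(epoch)
  if (!length(neurons)) stop("neuron set is empty")
  if (any(q_grid < 0 | q_grid > 1)) stop("q_grid values must lie in [0, 1]")
  idx <- interval_epochs(pre_s, cue_s, interval_s)[[epoch]]
  per_q <- vapply(q_grid, function(q) {
    prob <- cue_probabilities(q)
    unit_means <- vapply(neurons, function(nn) {
      Y <- nn$intervals
      ct <- nn$cue_type %||% attr(Y, "cue_type")
      betas <- beta_against(Y[, idx, drop = FALSE], unname(prob[ct]))
      mean(betas)
    }, numeric(1))
    mean(unit_means)
  }, numeric(1))
  i_ext <- which.max(abs(per_q))
  out <- data.frame(q = q_grid, mean_beta = per_q,
                    is_extremum = seq_along(q_grid) == i_ext)
  attr(out, "epoch") <- epoch
  attr(out, "extremum") <- list(q = q_grid[i_ext], beta = per_q[i_ext],
                                kind = if (per_q[i_ext] > 0) "peak" else "trough")
  class(out) <- c("pag_tuning", "data.frame")
  out
}

#' Population-level statistics of encoding betas
#'
#' For a population of units' per-interval betas: a studentized bootstrap
#' CI of the mean beta at every interval and regressor, an exact sign test
#' on each unit's epoch-mean beta per regressor and epoch, and the squared
#' Pearson correlation between the two regressors' epoch-mean betas across
#' units.
#'
#' @param betas Long data frame with columns `neuron_id`, `regressor`,
#'   `interval`, `beta` (stack of [fit_betas()] results).
#' @param seed Integer seed for the bootstrap.
#' @param n_resamples Bootstrap resamples (default 1000).
#' @param pre_s,cue_s,interval_s Interval geometry (defaults 2, 10, 1).
#' @return List with `ci` (data frame `regressor`, `interval`, `mean`,
#'   `lower`, `upper`, `excludes_zero`), `sign` (data frame `regressor`,
#'   `epoch`, `p`, `n`, `positive`), and `correlation` (data frame `epoch`,
#'   `r_squared`, `p`, `n`; NULL unless exactly two regressors).
#' @export
beta_population_stats <- function(betas, seed, n_resamples = 1000,
                                  pre_s = 2, cue_s = 10, interval_s = 1) {
  need <- c("neuron_id", "regressor", "interval", "beta")
  if (!all(need %in% names(betas))) {
    stop("betas must have columns ", paste(need, collapse = ", "))
  }
  if (length(unique(betas$neuron_id)) < 2L) stop("need at least 2 units")
  epochs <- interval_epochs(pre_s, cue_s, interval_s)[c("early", "late")]
  regs <- unique(betas$regressor)
  sub <- derive_subseeds(seed, length(regs) * length(unique(betas$interval)))
  k <- 0L
  ci <- do.call(rbind, lapply(regs, function(rc) {
    do.call(rbind, lapply(sort(unique(betas$interval)), function(iv) {
      k <<- k + 1L
      b <- betas$beta[betas$regressor == rc & betas$interval == iv]
      b <- b[is.finite(b)]
      bc <- bootstrap_ci(b, n_resamples = n_resamples, seed = sub[k])
      data.frame(regressor = rc, interval = iv, mean = bc$mean,
                 lower = bc$lower, upper = bc$upper,
                 excludes_zero = bc$lower > 0 | bc$upper < 0)
    }))
  }))
  epoch_means <- function(rc, idx) {
    sel <- betas[betas$regressor == rc & betas$interval %in% idx, ]
    tapply(sel$beta, sel$neuron_id, mean, na.rm = TRUE)
  }
  sign_df <- do.call(rbind, lapply(regs, function(rc) {
    do.call(rbind, lapply(names(epochs), function(ep) {
      st <- sign_test(epoch_means(rc, epochs[[ep]]))
      data.frame(regressor = rc, epoch = ep, p = st$p, n = st$n,
                 positive = st$positive)
    }))
  }))
  correlation <- NULL
  if (length(regs) == 2L) {
    correlation <- do.call(rbind, lapply(names(epochs), function(ep) {
      a <- epoch_means(regs[1], epochs[[ep]])
      b <- epoch_means(regs[2], epochs[[ep]])
      ids <- intersect(names(a), names(b))
      pc <- tryCatch(pearson_r2(a[ids], b[ids]),
                     error = function(e) list(r_squared = NA_real_,
                                              p = NA_real_,
                                              n = length(ids)))
      data.frame(epoch = ep, r_squared = pc$r_squared, p = pc$p, n = pc$n)
    }))
  }
  list(ci = ci, sign = sign_df, correlation = correlation)
}
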
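#' Collapse normalized firing into 1-s intervals around the cue
#'
#' Averages the 250-ms Z-scored bins into consecutive 1-s intervals
#' spanning 2 s pre-cue, the cue, and 2 s post-cue — 14 intervals for a
#' 10-s cue.  These interval means are the dependent variable of the
#' trial-by-trial encoding regression.
#'
#' @param norm A `pag_normfiring` from [normalize_firing()].
#' @param pre_s,post_s Seconds before onset / after offset to keep
#'   (defaults 2 and 2).
#' @param interval_s Interval length (default 1 s); must be a multiple of
#'   the bin width.
#' @return Trials x intervals numeric matrix with the per-trial cue types
#'   in attribute `cue_type` and interval start times (cue-local seconds)
#'   in attribute `interval_start_s`.
#' @export
interval_firing <- function(norm, pre_s = 2, post_s = 2, interval_s = 1) {
  per <- interval_s / norm$bin_width_s
  if (abs(per - round(per)) > 1e-9) {
    stop("interval_s must be a multiple of the bin width")
  }
  cols <- bin_columns(norm, -pre_s, norm$cue_duration_s + post_s)
  n_int <- length(cols) / per
  if (abs(n_int - round(n_int)) > 1e-9) stop("window/interval geometry mismatch")
  n_int <- as.integer(round(n_int))
  z <- norm$z[, cols, drop = FALSE]
  grp <- rep(seq_len(n_int), each = per)
  out <- t(apply(z, 1, function(row) tapply(row, grp, mean)))
  dimnames(out) <- NULL
  attr(out, "cue_type") <- norm$cue_type
  attr(out, "interval_start_s") <- -pre_s + (seq_len(n_int) - 1) * interval_s
  out
}

#' Interval indices of the early and late cue epochs
#'
#' With the default geometry (2 s pre-cue, 10 s cue, 1-s intervals), cue
#' intervals are 3-12; `early` is the first five (0-5 s of the cue) and
#' `late` the last five (5-10 s).
#'
#' @param pre_s Pre-cue seconds included in the interval matrix.
#' @param cue_s Cue duration.
#' @param interval_s Interval length.
#' @return List with integer vectors `cue`, `early`, `late`.
#' @export
interval_epochs <- function(pre_s = 2, cue_s = 10, interval_s = 1) {
  first <- pre_s / interval_s + 1
  cue <- seq.int(first, first + cue_s / interval_s - 1)
  half <- length(cue) / 2
  list(cue = cue, early = cue[seq_len(half)], late = cue[-seq_len(half)])
}

#' Trial-by-trial regressors: fear output and threat probability
#'
#' The fear-output regressor is each trial's suppression ratio over the
#' full 10-s cue; the threat-probability regressor is the shock probability
#' assigned to that trial's cue (danger 1.00, uncertainty `q`, safety
#' 0.00).  Trials with an undefined (0/0) suppression ratio get `NaN` fear
#' output and are dropped pairwise when that regressor is fit.
#'
#' @param records Data frame from [session_suppression()].
#' @param q Probability assigned to the uncertainty cue (default 0.375).
#' @return Data frame `trial`, `cue_type`, `fear_output`, `probability`.
#' @export
trial_regressors <- function(records, q = 0.375) {
  prob <- cue_probabilities(q)
  data.frame(trial = records$trial,
             cue_type = records$cue_type,
             fear_output = records$ratio,
             probability = unname(prob[records$cue_type]))
}

# Standardized regression coefficients of each column of Y on x: with both
# sides z-scored across trials this is the Pearson correlation.  Rows with
# non-finite x are dropped; zero-variance columns give NA.
beta_against <- function(Y, x, standardized = TRUE) {
  ok <- is.finite(x)
  x <- x[ok]
  Y <- Y[ok, , drop = FALSE]
  if (length(x) < 3L) stop("need at least 3 trials with defined regressor values")
  if (stats::sd(x) == 0) {
    warning("regressor has zero variance; betas undefined")
    return(rep(NA_real_, ncol(Y)))
  }
  if (standardized) {
    suppressWarnings(as.vector(stats::cor(x, Y)))
  } else {
    as.vector(stats::cov(x, Y)) / stats::var(x)
  }
}

#' Fit per-interval encoding betas for one unit
#'
#' Ordinary least squares of the unit's 1-s interval firing on each
#' regressor across trials.  In `separate_simple` mode (default) each
#' regressor is fit on its own; in `joint` mode all regressors enter one
#' multiple regression per interval.  Betas are standardized by default
#' (firing is already Z-scored; the regressor is z-scored across trials) so
#' fear output and threat probability are on a common scale.
#'
#' @param intervals Trials x intervals matrix from [interval_firing()].
#' @param regressors Data frame from [trial_regressors()] (columns other
#'   than `trial` / `cue_type` are treated as regressors).
#' @param mode `"separate_simple"` or `"joint"`.
#' @param standardized Report standardized coefficients (default TRUE).
#' @return Long data frame `regressor`, `interval`, `beta`.
#' @export
fit_betas <- function(intervals, regressors,
                      mode = c("separate_simple", "joint"),
                      standardized = TRUE) {
  mode <- match.arg(mode)
  reg_cols <- setdiff(names(regressors), c("trial", "cue_type"))
  if (nrow(regressors) != nrow(intervals)) {
    stop("regressors and intervals must describe the same trials")
  }
  n_int <- ncol(intervals)
  if (mode == "separate_simple") {
    out <- lapply(reg_cols, function(rc) {
      data.frame(regressor = rc, interval = seq_len(n_int),
                 beta = beta_against(intervals, regressors[[rc]],
                                     standardized = standardized))
    })
    do.call(rbind, out)
  } else {
    X <- as.matrix(regressors[, reg_cols, drop = FALSE])
    ok <- apply(is.finite(X), 1, all)
    X <- X[ok, , drop = FALSE]
    Y <- intervals[ok, , drop = FALSE]
    if (nrow(X) < ncol(X) + 2L) stop("too few complete trials for joint fit")
    if (any(apply(X, 2, stats::sd) == 0)) {
      warning("a regressor has zero variance; betas undefined")
      return(data.frame(regressor = rep(reg_cols, each = n_int),
                        interval = rep(seq_len(n_int), length(reg_cols)),
                        beta = NA_real_))
    }
    Xs <- if (standardized) scale(X) else X
    Ys <- if (standardized) {
      sds <- apply(Y, 2, stats::sd)
      sds[sds == 0] <- 1       # all-constant interval: beta 0, not NaN
      sweep(sweep(Y, 2, colMeans(Y)), 2, sds, "/")
    } else Y
    coefs <- stats::lm.fit(cbind(1, Xs), Ys)$coefficients[-1, , drop = FALSE]
    out <- lapply(seq_along(reg_cols), function(i) {
      data.frame(regressor = reg_cols[i], interval = seq_len(n_int),
                 beta = unname(coefs[i, ]))
    })
    do.call(rbind, out)
  }
}
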
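#' Studentized bootstrap confidence interval for a mean
#'
#' Resamples the data `n_resamples` times with replacement and forms the
#' bootstrap-t (studentized) interval: each resample's mean is studentized
#' by its own standard-error estimate, and the quantiles of the resulting t
#' distribution are inverted around the observed mean.  By default the
#' resample standard error is the plug-in estimate `sd(x*) / sqrt(n)`,
#' which is exact for a mean; a nested-bootstrap estimate (`se_method =
#' "nested"`) is available for checking robustness.
#'
#' @param values Numeric vector, at least 2 finite values.
#' @param n_resamples Number of bootstrap resamples (default 1000).
#' @param seed Integer seed; required, the interval is deterministic given it.
#' @param conf Confidence level (default 0.95).
#' @param se_method `"plugin"` (default) or `"nested"`.
#' @param inner_resamples Inner resamples for `se_method = "nested"`
#'   (default 50).
#' @return A `pag_bootci` list: `mean`, `lower`, `upper`, `n_resamples`,
#'   `method = "studentized"`, `seed`, `conf`.
#' @examples
#' bootstrap_ci(rnorm(50), seed = 1)
#' @export
bootstrap_ci <- function(values, n_resamples = 1000, seed, conf = 0.95,
                         se_method = c("plugin", "nested"),
                         inner_resamples = 50) {
  se_method <- match.arg(se_method)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) stop("need at least 2 finite values")
  theta <- mean(values)
  if (stats::sd(values) == 0) {
    warning("constant input: degenerate confidence interval")
    return(structure(list(mean = theta, lower = theta, upper = theta,
                          n_resamples = n_resamples, method = "studentized",
                          se_method = se_method, seed = check_seed(seed),
                          conf = conf),
                     class = "pag_bootci"))
  }
  se_hat <- stats::sd(values) / sqrt(n)
  alpha <- (1 - conf) / 2
  with_seed(seed, {
    idx <- matrix(sample.int(n, n_resamples * n, replace = TRUE),
                  nrow = n_resamples)
    xs <- matrix(values[idx], nrow = n_resamples)
    means <- rowMeans(xs)
    if (se_method == "plugin") {
      vars <- (rowMeans(xs^2) - means^2) * n / (n - 1)
      ses <- sqrt(pmax(vars, 0) / n)
    } else {
      ses <- vapply(seq_len(n_resamples), function(b) {
        ii <- matrix(sample.int(n, inner_resamples * n, replace = TRUE),
                     nrow = inner_resamples)
        stats::sd(rowMeans(matrix(xs[b, ][ii], nrow = inner_resamples)))
      }, numeric(1))
    }
    tstar <- (means - theta) / ses
    tstar <- tstar[is.finite(tstar)]
    q <- stats::quantile(tstar, c(1 - alpha, alpha), names = FALSE, type = 7)
    structure(list(mean = theta,
                   lower = theta - q[1] * se_hat,
                   upper = theta - q[2] * se_hat,
                   n_resamples = n_resamples, method = "studentized",
                   se_method = se_method, seed = check_seed(seed),
                   conf = conf),
              class = "pag_bootci")
  })
}

#' @export
print.pag_bootci <- function(x, ...) {
  cat(sprintf("mean %.4f, %d%% studentized bootstrap CI [%.4f, %.4f] (%d resamples)\n",
              x$mean, round(100 * x$conf), x$lower, x$upper, x$n_resamples))
  invisible(x)
}

#' Exact two-tailed sign test
#'
#' Tests whether values (or paired differences) are biased away from zero:
#' zeros are excluded, and the count of positive signs among the remaining
#' `n` values is referred to an exact Binomial(n, 1/2) distribution,
#' two-tailed.
#'
#' @param values Numeric vector of values or paired differences.
#' @return List with `p` (exact two-tailed p, `NaN` if every value is
#'   zero), `n` (nonzero count), `positive` (positive count),
#'   `zeros_excluded`.
#' @examples
#' sign_test(c(1, 2, 3, 4, 5))$p   # 2 * 0.5^5
#' @export
sign_test <- function(values) {
  values <- values[!is.na(values)]
  nz <- values[values != 0]
  if (!length(nz)) {
    warning("all values are zero: sign test undefined")
    return(list(p = NaN, n = 0L, positive = 0L,
                zeros_excluded = length(values)))
  }
  k <- sum(nz > 0)
  n <- length(nz)
  list(p = stats::binom.test(k, n, p = 0.5)$p.value,
       n = n, positive = k, zeros_excluded = length(values) - n)
}

#' Two-factor within-subject (repeated measures) ANOVA
#'
#' Full-factorial repeated measures ANOVA for a balanced design in which
#' every subject contributes one observation per cell of factor A x factor
#' B.  Each effect is tested against its own subject-by-effect interaction
#' error term; degrees of freedom are uncorrected (no sphericity
#' adjustment), and partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param y Numeric 3-dimensional array, subjects x levels of A x levels
#'   of B, no missing cells.
#' @param names_ab Length-2 character vector naming the factors (default
#'   `c("A", "B")`).
#' @return Data frame with one row per effect (`A`, `B`, `A:B`):
#'   `df_num`, `df_den`, `SS`, `SS_error`, `F`, `p`, `partial_eta_sq`.
#' @examples
#' y <- array(rnorm(10 * 3 * 4), dim = c(10, 3, 4))
#' rm_anova2(y, names_ab = c("cue", "bin"))
#' @export
rm_anova2 <- function(y, names_ab = c("A", "B")) {
  if (!is.array(y) || length(dim(y)) != 3L) {
    stop("y must be a 3-d array: subjects x A x B")
  }
  if (anyNA(y)) stop("design must be balanced with no missing cells")
  d <- dim(y)
  nS <- d[1]; nA <- d[2]; nB <- d[3]
  if (nS < 2L || nA < 2L || nB < 2L) {
    stop("need at least 2 subjects and 2 levels per factor")
  }
  m <- mean(y)
  m_s <- apply(y, 1, mean)
  m_a <- apply(y, 2, mean)
  m_b <- apply(y, 3, mean)
  m_sa <- apply(y, c(1, 2), mean)
  m_sb <- apply(y, c(1, 3), mean)
  m_ab <- apply(y, c(2, 3), mean)

  ss_a <- nS * nB * sum((m_a - m)^2)
  ss_b <- nS * nA * sum((m_b - m)^2)
  ss_ab <- nS * sum((m_ab - outer(m_a, m_b, "+") + m)^2)
  ss_sa <- nB * sum((m_sa - outer(m_s, m_a, "+") + m)^2)
  ss_sb <- nA * sum((m_sb - outer(m_s, m_b, "+") + m)^2)
  # residual (subject x A x B interaction) sum of squares
  res <- y
  for (a in seq_len(nA)) for (b in seq_len(nB)) {
    res[, a, b] <- y[, a, b] - m_sa[, a] - m_sb[, b] - m_ab[a, b] +
      m_s + m_a[a] + m_b[b] - m
  }
  ss_sab <- sum(res^2)

  df <- data.frame(
    effect = c(names_ab[1], names_ab[2],
               paste(names_ab, collapse = ":")),
    df_num = c(nA - 1, nB - 1, (nA - 1) * (nB - 1)),
    df_den = c((nS - 1) * (nA - 1), (nS - 1) * (nB - 1),
               (nS - 1) * (nA - 1) * (nB - 1)),
    SS = c(ss_a, ss_b, ss_ab),
    SS_error = c(ss_sa, ss_sb, ss_sab)
  )
  df$F <- (df$SS / df$df_num) / (df$SS_error / df$df_den)
  df$p <- stats::pf(df$F, df$df_num, df$df_den, lower.tail = FALSE)
  df$partial_eta_sq <- df$SS / (df$SS + df$SS_error)
  df
}

#' Pearson correlation reported as R-squared
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with `r`, `r_squared`, `p` (two-tailed, from the t
#'   transform) and `n`.
#' @export
pearson_r2 <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p = ct$p.value, n = length(x))
}
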
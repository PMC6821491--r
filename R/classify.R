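#' Split cue-inhibited units into Flip and Sustain populations
#'
#' k-means clustering (k = 2, Euclidean distance, best of `n_restarts`
#' seeded random initializations by within-cluster sum of squares) applied
#' to each unit's mean normalized firing during early and late danger cue
#' presentation.  The cluster whose centroid has the higher late-danger
#' coordinate is labelled `flip` (inhibited early, excited late); the other
#' is `sustain` (inhibition maintained throughout the cue).
#'
#' @param features Data frame or matrix with columns `early` and `late`
#'   (mean danger Z per unit) and optionally `neuron_id`.
#' @param seed Integer seed for the k-means restarts.
#' @param n_restarts Number of random initializations (default 100).
#' @return A `pag_labels` data frame `neuron_id`, `early`, `late`,
#'   `cluster`, with the 2 x 2 centroid matrix in attribute `centroids`.
#' @export
classify_flip_sustain <- function(features, seed, n_restarts = 100) {
  features <- as.data.frame(features)
  if (!all(c("early", "late") %in% names(features))) {
    stop("features must have columns 'early' and 'late'")
  }
  ids <- features$neuron_id %||% rownames(features) %||%
    as.character(seq_len(nrow(features)))
  x <- as.matrix(features[, c("early", "late")])
  if (nrow(x) < 2L) stop("need at least 2 units to cluster")
  if (!all(is.finite(x))) stop("features must be finite")
  if (all(apply(x, 2, function(col) diff(range(col)) == 0))) {
    stop("all feature points are identical; clusters are degenerate")
  }
  km <- with_seed(seed, stats::kmeans(x, centers = 2, nstart = n_restarts))
  flip_cluster <- which.max(km$centers[, "late"])
  cluster <- ifelse(km$cluster == flip_cluster, "flip", "sustain")
  centroids <- km$centers[c(flip_cluster, 3L - flip_cluster), , drop = FALSE]
  rownames(centroids) <- c("flip", "sustain")
  out <- data.frame(neuron_id = ids, early = x[, "early"], late = x[, "late"],
                    cluster = cluster, row.names = NULL)
  attr(out, "centroids") <- centroids
  attr(out, "tot_withinss") <- km$tot.withinss
  class(out) <- c("pag_labels", "data.frame")
  out
}

#' Compare waveform properties between two populations
#'
#' Independent-samples two-tailed t-tests (pooled variance, df = n1+n2-2)
#' per waveform metric between the two clusters, the standard check that
#' functionally defined populations are not simply different spike shapes.
#'
#' @param metrics Data frame with a `cluster` column (two levels) and one
#'   numeric column per metric.
#' @param metric_cols Character vector of metric column names; defaults to
#'   every numeric column other than `cluster`.
#' @return Data frame `metric`, `t`, `df`, `p`, and per-group means.
#' @export
compare_waveforms <- function(metrics, metric_cols = NULL) {
  if (!"cluster" %in% names(metrics)) stop("metrics needs a 'cluster' column")
  groups <- unique(metrics$cluster)
  if (length(groups) != 2L) stop("exactly two clusters are required")
  if (any(table(metrics$cluster) < 2L)) {
    stop("each cluster needs at least 2 units")
  }
  if (is.null(metric_cols)) {
    metric_cols <- setdiff(names(metrics)[vapply(metrics, is.numeric, TRUE)],
                           "cluster")
  }
  res <- lapply(metric_cols, function(m) {
    a <- metrics[[m]][metrics$cluster == groups[1]]
    b <- metrics[[m]][metrics$cluster == groups[2]]
    tt <- stats::t.test(a, b, var.equal = TRUE)
    out <- data.frame(metric = m, t = unname(tt$statistic),
                      df = unname(tt$parameter), p = tt$p.value)
    out[[paste0("mean_", groups[1])]] <- mean(a)
    out[[paste0("mean_", groups[2])]] <- mean(b)
    out
  })
  do.call(rbind, res)
}
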
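#' Build a validated pipeline configuration
#'
#' Collects every tunable of the analysis with its default: session design,
#' synthetic roster, bin geometry, screening alpha, k-means restarts,
#' bootstrap resamples, regression mode and uncertainty probability.
#' Values are validated here, before any stage runs.
#'
#' @param seed Master seed for the whole run.
#' @param roster Named counts of synthetic archetypes.
#' @param design Trial counts per type.
#' @param mean_iti_s,baseline_rate_hz,poke_rate_hz,suppression_by_cue
#'   Generator parameters (see [simulate_session()]).
#' @param bin_width_s,window_pre_s,window_post_s Alignment geometry.
#' @param norm_baseline_s Differential-firing baseline (2 s).
#' @param behav_baseline_s Behavioral baseline window (20 s).
#' @param screen_baseline_s Screening baseline window (10 s).
#' @param alpha Screening significance threshold (0.0125).
#' @param kmeans_restarts,n_resamples,regression_mode,q,q_grid Downstream
#'   settings.
#' @param outdir Output directory, or NULL to keep results in memory.
#' @return A `pag_config` list.
#' @export
run_config <- function(seed,
                       roster = c(flip = 20, sustain = 20, flat = 10),
                       design = default_design(),
                       mean_iti_s = 210,
                       baseline_rate_hz = 10,
                       poke_rate_hz = 0.6,
                       suppression_by_cue = c(danger = 0.92,
                                              uncertainty = 0.71,
                                              safety = 0.10),
                       bin_width_s = 0.25,
                       window_pre_s = 20,
                       window_post_s = 20,
                       norm_baseline_s = 2,
                       behav_baseline_s = 20,
                       screen_baseline_s = 10,
                       alpha = 0.0125,
                       kmeans_restarts = 100,
                       n_resamples = 1000,
                       regression_mode = c("separate_simple", "joint"),
                       q = 0.375,
                       q_grid = seq(0, 1, by = 0.125),
                       outdir = NULL) {
  regression_mode <- match.arg(regression_mode)
  cfg <- list(seed = check_seed(seed), roster = roster, design = design,
              mean_iti_s = mean_iti_s, baseline_rate_hz = baseline_rate_hz,
              poke_rate_hz = poke_rate_hz,
              suppression_by_cue = suppression_by_cue,
              bin_width_s = bin_width_s, window_pre_s = window_pre_s,
              window_post_s = window_post_s,
              norm_baseline_s = norm_baseline_s,
              behav_baseline_s = behav_baseline_s,
              screen_baseline_s = screen_baseline_s, alpha = alpha,
              kmeans_restarts = kmeans_restarts, n_resamples = n_resamples,
              regression_mode = regression_mode, q = q, q_grid = q_grid,
              outdir = outdir)
  for (nm in c("mean_iti_s", "baseline_rate_hz", "poke_rate_hz",
               "bin_width_s", "alpha")) {
    stopifnot_scalar_num(cfg[[nm]], nm, min = 0)
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must lie in (0, 1)")
  if (cfg$q < 0 || cfg$q > 1) stop("q must lie in [0, 1]")
  class(cfg) <- "pag_config"
  cfg
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key: value`; nested names use dots
#' (`roster.flip: 40`, `suppression_by_cue.danger: 0.92`); `#` starts a
#' comment.  Unknown keys are an error.  Values are passed to
#' [run_config()] on top of its defaults.
#'
#' @param path File path.
#' @param ... Overrides applied after the file (e.g. from CLI flags).
#' @return A `pag_config`.
#' @export
read_run_config <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  args <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("cannot parse config line: ", ln)
    key <- m[2]; val <- m[3]
    num <- suppressWarnings(as.numeric(val))
    val <- if (!is.na(num)) num else val
    if (grepl(".", key, fixed = TRUE)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      vec <- args[[parts[1]]] %||% numeric()
      vec[parts[2]] <- val
      args[[parts[1]]] <- vec
    } else {
      args[[key]] <- val
    }
  }
  overrides <- list(...)
  args[names(overrides)] <- overrides
  known <- names(formals(run_config))
  bad <- setdiff(names(args), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(run_config, args)
}

#' Run the full analysis pipeline on a synthetic session
#'
#' Generates a session from the configured roster, computes suppression
#' ratios, screens every unit for cue inhibition, classifies the inhibited
#' units into Flip and Sustain, fits encoding betas and population
#' statistics per cluster, sweeps the threat-probability tuning curves, and
#' compares waveform metrics between clusters.  When `outdir` is set,
#' every stage's tidy table and a JSON run summary are written; the run is
#' a pure function of the configuration, so identical configurations
#' reproduce identical summaries.
#'
#' @param config A `pag_config` from [run_config()].
#' @return A `pag_report` list: `config`, `session`, `suppression`,
#'   `screen`, `labels`, `metrics`, `waveform_tests`, `betas`,
#'   `population_stats`, `tuning`, `recovery`, `summary`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pag_config")) stop("config must come from run_config()")
  sub <- derive_subseeds(config$seed, 4L)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  session <- stage("generate", simulate_session(
    roster = config$roster, seed = sub[1], design = config$design,
    mean_iti_s = config$mean_iti_s,
    baseline_rate_hz = config$baseline_rate_hz,
    poke_rate_hz = config$poke_rate_hz,
    suppression_by_cue = config$suppression_by_cue))

  suppression <- stage("behavior",
    session_suppression(session, baseline_window_s = config$behav_baseline_s))

  screen_rows <- list(); norm_list <- list(); metrics_rows <- list()
  feats <- list()
  unnormalizable <- character()
  stage("normalize/screen", for (nrn in session$neurons) {
    sr <- screening_rates(nrn, session$schedule,
                          baseline_s = config$screen_baseline_s)
    sc <- screen_inhibited(sr, alpha = config$alpha)
    screen_rows[[nrn$neuron_id]] <- cbind(neuron_id = nrn$neuron_id,
                                          sc$tests,
                                          inhibited = sc$inhibited,
                                          safety_only = sc$safety_only)
    aligned <- bin_spikes(nrn, session$schedule,
                          bin_width_s = config$bin_width_s,
                          window_pre_s = config$window_pre_s,
                          window_post_s = config$window_post_s)
    norm <- tryCatch(
      normalize_firing(aligned, baseline_s = config$norm_baseline_s),
      pag_unnormalizable_error = function(e) NULL)
    if (is.null(norm)) {
      unnormalizable <- c(unnormalizable, nrn$neuron_id)
      next
    }
    norm_list[[nrn$neuron_id]] <- norm
    wm <- waveform_metrics(nrn$waveform)
    metrics_rows[[nrn$neuron_id]] <- data.frame(
      neuron_id = nrn$neuron_id,
      baseline_rate = mean(sr$baseline),
      half_duration_ms = wm$half_duration_ms,
      amplitude_ratio = wm$amplitude_ratio)
    if (sc$inhibited && !sc$safety_only) {
      feats[[nrn$neuron_id]] <- data.frame(
        neuron_id = nrn$neuron_id,
        early = window_mean(norm, "danger", "early"),
        late = window_mean(norm, "danger", "late"))
    }
  })
  screen <- do.call(rbind, c(screen_rows, list(make.row.names = FALSE)))
  metrics <- do.call(rbind, c(metrics_rows, list(make.row.names = FALSE)))

  labels <- NULL
  if (length(feats) >= 2L) {
    labels <- stage("classify", classify_flip_sustain(
      do.call(rbind, feats), seed = sub[2],
      n_restarts = config$kmeans_restarts))
  }

  waveform_tests <- NULL
  betas <- NULL; population_stats <- NULL; tuning <- NULL
  if (!is.null(labels)) {
    mt <- merge(metrics, labels[, c("neuron_id", "cluster")], by = "neuron_id")
    if (all(table(mt$cluster) >= 2L) && length(unique(mt$cluster)) == 2L) {
      waveform_tests <- stage("waveforms", compare_waveforms(mt))
    }
    regressors <- trial_regressors(suppression, q = config$q)
    beta_rows <- list(); unit_tables <- list()
    stage("encode", for (id in labels$neuron_id) {
      iv <- interval_firing(norm_list[[id]])
      unit_tables[[id]] <- list(intervals = iv,
                                cue_type = attr(iv, "cue_type"))
      b <- fit_betas(iv, regressors, mode = config$regression_mode)
      beta_rows[[id]] <- cbind(neuron_id = id, b,
                               cluster = labels$cluster[labels$neuron_id == id])
    })
    betas <- do.call(rbind, c(beta_rows, list(make.row.names = FALSE)))
    population_stats <- list(); tuning <- list()
    cl_seeds <- c(flip = sub[3], sustain = sub[4])
    for (cl in intersect(c("flip", "sustain"), unique(labels$cluster))) {
      ids <- labels$neuron_id[labels$cluster == cl]
      if (length(ids) >= 2L) {
        population_stats[[cl]] <- stage("population_stats",
          beta_population_stats(betas[betas$neuron_id %in% ids, ],
                                seed = cl_seeds[[cl]],
                                n_resamples = config$n_resamples))
        tuning[[cl]] <- stage("tune", lapply(
          c(early = "early", late = "late"),
          function(ep) tuning_curve(unit_tables[ids], epoch = ep,
                                    q_grid = config$q_grid)))
      }
    }
  }

  recovery <- NULL
  if (!is.null(session$truth) && !is.null(labels)) {
    tr <- merge(session$truth, labels[, c("neuron_id", "cluster")],
                by = "neuron_id", all.x = TRUE)
    planted <- tr$archetype %in% c("flip", "sustain")
    recovery <- list(
      n_planted = sum(planted),
      n_recovered = sum(planted & !is.na(tr$cluster) &
                          tr$cluster == tr$archetype),
      false_inclusions = sum(!planted & !is.na(tr$cluster)))
    recovery$fraction_recovered <- recovery$n_recovered /
      max(recovery$n_planted, 1L)
  }

  summary <- build_summary(config, session, suppression, screen, labels,
                           waveform_tests, population_stats, tuning,
                           recovery, unnormalizable)

  report <- structure(list(config = config, session = session,
                           suppression = suppression, screen = screen,
                           labels = labels, metrics = metrics,
                           waveform_tests = waveform_tests, betas = betas,
                           population_stats = population_stats,
                           tuning = tuning, recovery = recovery,
                           norm = norm_list, summary = summary),
                      class = "pag_report")
  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

build_summary <- function(config, session, suppression, screen, labels,
                          waveform_tests, population_stats, tuning,
                          recovery, unnormalizable) {
  mean_ratio <- tapply(suppression$ratio[is.finite(suppression$ratio)],
                       suppression$cue_type[is.finite(suppression$ratio)],
                       mean)
  per_unit <- unique(screen[, c("neuron_id", "inhibited", "safety_only")])
  counts <- list(
    trials = nrow(session$schedule),
    neurons = length(session$neurons),
    inhibited = sum(per_unit$inhibited),
    safety_only = sum(per_unit$safety_only),
    unnormalizable = length(unnormalizable),
    classified = if (is.null(labels)) 0L else nrow(labels),
    flip = if (is.null(labels)) 0L else sum(labels$cluster == "flip"),
    sustain = if (is.null(labels)) 0L else sum(labels$cluster == "sustain"))
  tuning_summary <- NULL
  if (!is.null(tuning) && length(tuning)) {
    tuning_summary <- lapply(tuning, function(cl) {
      lapply(cl, function(tc) attr(tc, "extremum"))
    })
  }
  sign_summary <- NULL
  if (!is.null(population_stats) && length(population_stats)) {
    sign_summary <- lapply(population_stats, `[[`, "sign")
  }
  cfg <- unclass(config)
  cfg$outdir <- NULL
  list(config = cfg,
       counts = counts,
       mean_suppression = as.list(mean_ratio),
       differential_suppression = list(
         danger_vs_uncertainty =
           differential_suppression(suppression, c("danger", "uncertainty")),
         uncertainty_vs_safety =
           differential_suppression(suppression, c("uncertainty", "safety"))),
       sign_tests = sign_summary,
       tuning_extrema = tuning_summary,
       recovery = recovery)
}

write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_session_tables(report$session, outdir)
  wr <- function(x, name) {
    if (!is.null(x)) {
      utils::write.csv(x, file.path(outdir, name), row.names = FALSE)
    }
  }
  wr(report$suppression, "suppression.csv")
  wr(report$screen, "screen.csv")
  wr(report$labels, "labels.csv")
  wr(report$metrics, "metrics.csv")
  wr(report$waveform_tests, "waveform_tests.csv")
  wr(report$betas, "betas.csv")
  if (!is.null(report$tuning)) {
    tidy <- do.call(rbind, lapply(names(report$tuning), function(cl) {
      do.call(rbind, lapply(names(report$tuning[[cl]]), function(ep) {
        cbind(set = cl, epoch = ep, report$tuning[[cl]][[ep]])
      }))
    }))
    wr(tidy, "tuning.csv")
  }
  wr(export_heatmap_matrix(report), "heatmap.csv")
  jsonlite::write_json(report$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Per-unit interval firing matrix for heat plots
#'
#' A tidy table of each classified unit's mean normalized firing in 1-s
#' intervals per cue type — the matrix behind the population heat plot.
#'
#' @param report A `pag_report` from [run_pipeline()].
#' @return Data frame `neuron_id`, `cluster`, `cue_type`, `interval`,
#'   `mean_z` (empty with headers when no unit was classified).
#' @export
export_heatmap_matrix <- function(report) {
  empty <- data.frame(neuron_id = character(), cluster = character(),
                      cue_type = character(), interval = integer(),
                      mean_z = numeric())
  if (is.null(report$labels)) return(empty)
  rows <- lapply(seq_len(nrow(report$labels)), function(i) {
    id <- report$labels$neuron_id[i]
    iv <- interval_firing(report$norm[[id]])
    ct <- attr(iv, "cue_type")
    do.call(rbind, lapply(unique(ct), function(cue) {
      data.frame(neuron_id = id, cluster = report$labels$cluster[i],
                 cue_type = cue, interval = seq_len(ncol(iv)),
                 mean_z = colMeans(iv[ct == cue, , drop = FALSE]))
    }))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
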
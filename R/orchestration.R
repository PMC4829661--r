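# Orchestration: ensembles, sweeps, figure-style outputs ---------------------

#' Ensemble run configuration
#'
#' @param layout A `genome_layout`, or `NULL` to generate one from
#'   `genome_params` per run.
#' @param genome_params A [synthetic_genome_params()] used when `layout`
#'   is `NULL`.
#' @param params A [replication_params()]; its seed is replaced by each
#'   ensemble seed.
#' @param variant Model variant passed to [run_simulation()].
#' @param seeds Integer vector of distinct seeds (one run each).
#' @param record_interval Time-series recording interval (s).
#' @param snapshot_times Fork-snapshot times (s) per run.
#' @param out_dir Optional directory; when set, per-seed outputs are
#'   written there as CSV.
#' @return A `run_config` object.
#' @export
run_config <- function(layout = NULL,
                       genome_params = synthetic_genome_params(),
                       params = replication_params(),
                       variant = "combined",
                       seeds = 1:10,
                       record_interval = 300,
                       snapshot_times = numeric(0),
                       out_dir = NULL) {
  seeds <- as.integer(seeds)
  if (anyDuplicated(seeds)) stop("seeds must be distinct")
  if (length(seeds) < 1) stop("at least one seed is required")
  structure(
    list(layout = layout, genome_params = genome_params, params = params,
         variant = variant, seeds = seeds,
         record_interval = record_interval,
         snapshot_times = snapshot_times, out_dir = out_dir),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Recognized top-level keys: `replication` (fields of
#' [replication_params()]), `genome` (fields of
#' [synthetic_genome_params()]), `variant`, `seeds`, `record_interval`,
#' `snapshot_times`, `out_dir`.
#'
#' @param file YAML path.
#' @return A `run_config`.
#' @export
read_run_config <- function(file) {
  y <- yaml::read_yaml(file)
  rp <- do.call(replication_params, y$replication %||% list())
  gp <- do.call(synthetic_genome_params, y$genome %||% list())
  run_config(
    layout = NULL, genome_params = gp, params = rp,
    variant = y$variant %||% "combined",
    seeds = y$seeds %||% 1:10,
    record_interval = y$record_interval %||% 300,
    snapshot_times = y$snapshot_times %||% numeric(0),
    out_dir = y$out_dir
  )
}

#' Run a multi-seed ensemble
#'
#' Runs one simulation per seed (layout fixed, or regenerated with the
#' run seed when the config has none), collects per-seed summary
#' statistics, and keeps the individual results.  Failed seeds are
#' reported and skipped; the others are retained.
#'
#' @param config A [run_config()].
#' @return An `ensemble_summary`: `per_seed` data frame (seed, completion
#'   time, firings, spontaneous fraction), `results` list, `summary`
#'   (means and standard deviations), `failed` seeds.
#' @export
run_ensemble <- function(config) {
  stopifnot(inherits(config, "run_config"))
  results <- list()
  failed <- integer(0)
  rows <- list()
  for (s in config$seeds) {
    layout <- config$layout
    if (is.null(layout)) {
      gp <- config$genome_params
      gp$seed <- s
      layout <- generate_synthetic_genome(gp)
    }
    p <- config$params
    p$seed <- s
    res <- tryCatch(
      run_simulation(layout, p, variant = config$variant,
                     record_interval = config$record_interval,
                     snapshot_times = config$snapshot_times),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      warning(sprintf("seed %d failed: %s", s, conditionMessage(res)))
      failed <- c(failed, s)
      next
    }
    results[[as.character(s)]] <- res
    rows[[as.character(s)]] <- data.frame(
      seed = s,
      completion_time = res$completion_time,
      total_firings = nrow(res$firings),
      spontaneous_fraction = spontaneous_fraction(res)
    )
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      write.csv(res$firings,
                file.path(config$out_dir, sprintf("firings_seed%d.csv", s)),
                row.names = FALSE)
      write.csv(res$time_series,
                file.path(config$out_dir,
                          sprintf("time_series_seed%d.csv", s)),
                row.names = FALSE)
    }
  }
  per_seed <- do.call(rbind, rows)
  if (is.null(per_seed) || nrow(per_seed) == 0) {
    stop("all ensemble seeds failed")
  }
  structure(
    list(
      per_seed = per_seed,
      results = results,
      failed = failed,
      summary = data.frame(
        statistic = c("completion_time", "total_firings",
                      "spontaneous_fraction"),
        mean = c(mean(per_seed$completion_time),
                 mean(per_seed$total_firings),
                 mean(per_seed$spontaneous_fraction)),
        sd = c(sd(per_seed$completion_time),
               sd(per_seed$total_firings),
               sd(per_seed$spontaneous_fraction))
      )
    ),
    class = "ensemble_summary"
  )
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("<ensemble_summary> %d runs (%d failed)\n",
              nrow(x$per_seed), length(x$failed)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Fraction-replicated time series of a result
#'
#' Per-class and total replicated fraction of the genome over time,
#' normalized by the class genomic content (analogous to published
#' fraction-replicated curves).
#'
#' @param result A `simulation_result`.
#' @param class_lengths Named lengths (bp) per class; computed from the
#'   per-class totals at completion when omitted.
#' @return Data frame: `time`, `eu`, `fac`, `con`, `total`.
#' @export
replicated_fraction_series <- function(result, class_lengths = NULL) {
  ts <- result$time_series
  if (is.null(class_lengths)) class_lengths <- result$replicated_by_class
  data.frame(
    time = ts$time,
    eu = ts$replicated_eu / class_lengths[["EU"]],
    fac = ts$replicated_fac / class_lengths[["FAC"]],
    con = ts$replicated_con / class_lengths[["CON"]],
    total = (ts$replicated_eu + ts$replicated_fac + ts$replicated_con) /
      sum(class_lengths)
  )
}

#' Write figure-style CSV outputs from an ensemble
#'
#' Produces desk-scale analogues of the package's headline plots:
#' \describe{
#'   \item{`f2c`}{fraction of replicated chromatin over time, per class}
#'   \item{`f2d`}{active fork counts per class over time}
#'   \item{`f3f`}{number and mean size of 1D clusters over time}
#'   \item{`timing`}{averaged replication-timing profile}
#'   \item{`fig4`}{in-silico microscopy projections (requires a
#'     conformation)}
#' }
#'
#' @param ensemble An [run_ensemble()] result.
#' @param which Subset of figures to produce.
#' @param out_dir Output directory.
#' @param positions Sampling positions for the timing profile.
#' @param conformation Optional `conformation` for `fig4`.
#' @param windows Named list of time windows (s) for `fig4`.
#' @return Invisible character vector of files written.
#' @export
reproduce_figures <- function(ensemble,
                              which = c("f2c", "f2d", "f3f", "timing"),
                              out_dir = ".",
                              positions = NULL,
                              conformation = NULL,
                              windows = NULL) {
  stopifnot(inherits(ensemble, "ensemble_summary"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- ensemble$results
  if (length(results) == 0) stop("ensemble holds no results")
  files <- character(0)
  emit <- function(df, name) {
    f <- file.path(out_dir, name)
    write.csv(df, f, row.names = FALSE)
    files <<- c(files, f)
  }
  if ("f2c" %in% which) {
    fr <- lapply(results, replicated_fraction_series)
    # align on the longest grid; shorter runs are complete (fraction 1)
    tmax <- which.max(vapply(fr, nrow, integer(1)))
    grid <- fr[[tmax]]$time
    avg <- Reduce(`+`, lapply(fr, function(d) {
      i <- findInterval(grid, d$time)
      as.matrix(d[pmin(pmax(i, 1), nrow(d)), c("eu", "fac", "con", "total")])
    })) / length(fr)
    emit(data.frame(time = grid, avg), "f2c_replicated_fraction.csv")
  }
  if ("f2d" %in% which) {
    ts <- results[[1]]$time_series
    emit(ts[, c("time", "forks_eu", "forks_fac", "forks_con",
                "free_factors")],
         "f2d_fork_counts.csv")
  }
  if ("f3f" %in% which) {
    has_snaps <- vapply(results, function(r) length(r$snapshots) > 0,
                        logical(1))
    if (!any(has_snaps)) {
      stop("f3f requires results run with snapshot_times")
    }
    cs <- cluster_series(results[[which(has_snaps)[1]]])
    emit(cs, "f3f_cluster_series.csv")
  }
  if ("timing" %in% which) {
    if (is.null(positions)) {
      total <- results[[1]]$total_length
      positions <- seq(0, total - 1, length.out = min(2000, total))
    }
    emit(timing_profile(unname(results), positions), "timing_profile.csv")
  }
  if ("fig4" %in% which) {
    if (is.null(conformation)) stop("fig4 requires a conformation")
    res1 <- results[[1]]
    if (length(res1$snapshots) == 0) {
      stop("fig4 requires results run with snapshot_times")
    }
    if (is.null(windows)) {
      tend <- res1$completion_time
      windows <- list(early = c(0.05, 0.05) * tend + c(0, 900),
                      mid = c(0.5, 0.5) * tend + c(0, 900),
                      late = c(0.9, 0.9) * tend + c(0, 900))
    }
    for (nm in names(windows)) {
      cloud <- accumulate_forks(res1, conformation, windows[[nm]])
      emit(as.data.frame(cloud), sprintf("fig4_%s_points.csv", nm))
    }
  }
  invisible(files)
}
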
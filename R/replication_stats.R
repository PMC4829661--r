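# Derived replication statistics ---------------------------------------------

#' Distances between adjacent fired origins
#'
#' Per chromosome, fired-origin positions are sorted and successive
#' differences emitted; distances never span chromosome barriers.
#' Comparable to inter-origin distances from DNA combing experiments.
#'
#' @param result A `simulation_result`.
#' @return Numeric vector of distances in bp (possibly empty).
#' @export
inter_origin_distances <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  f <- result$firings
  if (nrow(f) < 2) return(numeric(0))
  unlist(lapply(split(f$position, f$chrom_index), function(p) {
    if (length(p) < 2) return(numeric(0))
    diff(sort(p))
  }), use.names = FALSE)
}

#' Identify 1D replication clusters among active forks
#'
#' Two adjacent forks belong to the same cluster when their distance is
#' strictly less than `threshold` and no chromosome barrier lies between
#' them.  A cluster's size is the genomic span between its outermost
#' forks; a singleton cluster has span 0 but is counted.
#'
#' @param positions Sorted (or unsorted) fork positions in bp.
#' @param barriers Barrier positions (chromosome boundaries).
#' @param threshold Clustering distance in bp (default 1 Mbp).
#' @return Data frame with one row per cluster: `n_forks`, `start`, `end`,
#'   `span`.
#' @export
identify_clusters <- function(positions, barriers = numeric(0),
                              threshold = 1e6) {
  if (length(positions) == 0) {
    return(data.frame(n_forks = integer(0), start = numeric(0),
                      end = numeric(0), span = numeric(0)))
  }
  p <- sort(positions)
  if (length(p) == 1) {
    return(data.frame(n_forks = 1L, start = p, end = p, span = 0))
  }
  gaps <- diff(p)
  # barrier between two forks: they sit in different barrier intervals
  bi <- findInterval(p, barriers)
  brk <- gaps >= threshold | bi[-1] != bi[-length(bi)]
  id <- cumsum(c(1L, as.integer(brk)))
  agg <- lapply(split(p, id), function(x) {
    c(n = length(x), start = x[1], end = x[length(x)])
  })
  m <- do.call(rbind, agg)
  data.frame(n_forks = as.integer(m[, 1]), start = m[, 2], end = m[, 3],
             span = m[, 3] - m[, 2], row.names = NULL)
}

#' Cluster statistics over recorded fork snapshots
#'
#' @param result A `simulation_result` run with `snapshot_times`.
#' @param threshold Clustering distance in bp.
#' @return Data frame per snapshot: `time`, `n_clusters`, `mean_span`,
#'   `total_forks`.
#' @export
cluster_series <- function(result, threshold = 1e6) {
  stopifnot(inherits(result, "simulation_result"))
  if (length(result$snapshots) == 0) {
    stop("result carries no fork snapshots; rerun with snapshot_times")
  }
  rows <- lapply(result$snapshots, function(s) {
    cl <- identify_clusters(s$position, result$barriers, threshold)
    data.frame(
      time = attr(s, "time"),
      n_clusters = nrow(cl),
      mean_span = if (nrow(cl) > 0) mean(cl$span) else NA_real_,
      total_forks = nrow(s)
    )
  })
  do.call(rbind, rows)
}

#' Cluster front ("wave") speed
#'
#' With all limiting factors active, the DNA replicated per cluster per
#' unit time is \eqn{\nu L_{max} / N_c}; while a cluster advances on two
#' fronts each front moves at \eqn{v_w = \nu L_{max} / (2 N_c)}.
#'
#' @param nu Fork speed (bp/s).
#' @param l_max Limiting factor maximum.
#' @param n_clusters Number of 1D clusters \eqn{N_c}.
#' @return Front speed in bp/s.
#' @export
cluster_front_speed <- function(nu = 28, l_max = 12000, n_clusters) {
  if (any(n_clusters < 1)) stop("n_clusters must be >= 1")
  nu * l_max / (2 * n_clusters)
}

#' Replication timing profile at sampling positions
#'
#' For each position, the time at which its containing replicon covered
#' it: the origin firing time plus the fork travel time over the distance
#' from origin to position (under the global speed schedule).  Profiles
#' from several runs are averaged position-wise.
#'
#' @param results A `simulation_result` or list of them.
#' @param positions Global genomic positions (bp).
#' @return Data frame `position`, `time` (s; `NA` where unreplicated).
#' @export
timing_profile <- function(results, positions) {
  if (inherits(results, "simulation_result")) results <- list(results)
  stopifnot(length(results) >= 1)
  times <- vapply(results, function(res) {
    p <- res$params
    r <- res$replicons
    f <- res$firings
    done <- !is.na(r$left_end) & !is.na(r$right_end)
    r <- r[done, ]
    f <- f[done, ]
    o <- order(r$left_end)
    r <- r[o, ]
    f <- f[o, ]
    i <- findInterval(positions, r$left_end)
    t_out <- rep(NA_real_, length(positions))
    ok <- i >= 1
    ok[ok] <- positions[ok] <= r$right_end[i[ok]] + 1e-9
    if (any(ok)) {
      oi <- i[ok]
      d <- abs(positions[ok] - r$origin[oi])
      s0 <- fork_distance(f$time[oi], p$max_fork_speed,
                          p$speed_ramp_duration)
      t_out[ok] <- fork_travel_time(s0 + d, p$max_fork_speed,
                                    p$speed_ramp_duration)
    }
    t_out
  }, numeric(length(positions)))
  times <- matrix(times, nrow = length(positions))
  data.frame(position = positions, time = rowMeans(times))
}

#' Pearson correlation between two timing profiles
#'
#' Profiles are matched on common positions.  Replication time and
#' experimental timing signals are often anticorrelated by sign
#' convention (early DNA has high timing signal); compare `abs(r)` when
#' the convention differs.
#'
#' @param profile_a,profile_b Data frames with `position` and `time` (or
#'   `value`) columns.
#' @return Pearson correlation coefficient; `NA` (with a warning) when a
#'   profile has zero variance.
#' @export
profile_correlation <- function(profile_a, profile_b) {
  va <- profile_a[[if ("time" %in% names(profile_a)) "time" else "value"]]
  vb <- profile_b[[if ("time" %in% names(profile_b)) "time" else "value"]]
  m <- merge(data.frame(position = profile_a$position, a = va),
             data.frame(position = profile_b$position, b = vb),
             by = "position")
  m <- m[stats::complete.cases(m), ]
  if (nrow(m) < 3) stop("fewer than 3 common positions")
  if (sd(m$a) == 0 || sd(m$b) == 0) {
    warning("zero variance in a profile; correlation undefined")
    return(NA_real_)
  }
  cor(m$a, m$b)
}

#' Bootstrap test of the mean inter-origin distance
#'
#' Repeatedly draws subsets of `subset_size` distances (without
#' replacement within a subset), and compares subset means with the
#' reference mean (188 kbp from DNA combing).  The P value is the smaller
#' of the fractions of subset means below/above the reference; ties are
#' split evenly between the two fractions.  When one fraction is zero the
#' P value is reported as bounded above by `1/repetitions`.
#'
#' @param distances Numeric vector of inter-origin distances (bp).
#' @param reference_mean Experimental reference mean (bp).
#' @param subset_size Subset size.
#' @param repetitions Number of bootstrap repetitions.
#' @param seed Integer seed.
#' @return A `bootstrap_test` list: `p_value`, `upper_bound` (logical),
#'   `fraction_below`, `fraction_above`, `mean_of_means`.
#' @export
bootstrap_mean_test <- function(distances, reference_mean = 188000,
                                subset_size = 50L, repetitions = 10000L,
                                seed = 1L) {
  if (length(distances) < subset_size) {
    stop("sample smaller than the subset size")
  }
  with_seed(seed, {
    means <- vapply(seq_len(repetitions), function(i) {
      mean(distances[sample.int(length(distances), subset_size)])
    }, numeric(1))
    below <- sum(means < reference_mean)
    above <- sum(means > reference_mean)
    ties <- repetitions - below - above
    fb <- (below + ties / 2) / repetitions
    fa <- (above + ties / 2) / repetitions
    p <- min(fb, fa)
    structure(
      list(p_value = max(p, 0), upper_bound = p == 0,
           reported_p = if (p == 0) 1 / repetitions else p,
           fraction_below = fb, fraction_above = fa,
           mean_of_means = mean(means)),
      class = "bootstrap_test"
    )
  })
}

#' @export
print.bootstrap_test <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_test> P %s%.4g (below %.3f, above %.3f)\n",
    if (x$upper_bound) "< " else "= ", x$reported_p,
    x$fraction_below, x$fraction_above
  ))
  invisible(x)
}

#' Bin distances into a histogram with fixed breaks
#'
#' @param distances Numeric vector (bp).
#' @param breaks Bin breaks (bp); values outside are dropped.
#' @return Integer vector of counts, one per bin.
#' @export
bin_distances <- function(distances, breaks = seq(0, 8e5, by = 2e4)) {
  d <- distances[distances >= breaks[1] & distances < breaks[length(breaks)]]
  as.integer(table(cut(d, breaks, right = FALSE)))
}

#' Distance between an observed and a simulated histogram
#'
#' Chi-square: simulated counts are scaled to the observed total and used
#' as expected values, \eqn{\chi^2 = \sum (o_i - e_i)^2 / e_i}.
#' Kullback-Leibler: both are normalized to frequencies,
#' \eqn{KL = \sum p_i \ln(p_i / q_i)}.  A pseudo-count of 0.5 is added to
#' empty simulated bins before scaling so both measures stay finite.
#'
#' @param observed,simulated Count vectors on a common binning.
#' @param measure `"chi2"` or `"kl"`.
#' @return Nonnegative scalar.
#' @export
distribution_distance <- function(observed, simulated,
                                  measure = c("chi2", "kl")) {
  measure <- match.arg(measure)
  if (length(observed) != length(simulated)) {
    stop("histograms must share a common binning")
  }
  sim <- as.numeric(simulated)
  sim[sim == 0] <- 0.5
  obs <- as.numeric(observed)
  if (measure == "chi2") {
    e <- sim / sum(sim) * sum(obs)
    sum((obs - e)^2 / e)
  } else {
    p <- obs / sum(obs)
    q <- sim / sum(sim)
    keep <- p > 0
    sum(p[keep] * log(p[keep] / q[keep]))
  }
}

#' Sweep the inhibition distance against an observed distance histogram
#'
#' Runs one simulation batch per inhibition-distance value, bins the
#' simulated inter-origin distances like the observed histogram, and
#' reports both distance measures and the total number of fired origins.
#'
#' @param layout A `genome_layout`.
#' @param params A [replication_params()]; its `inhibition_distance` is
#'   overridden by each sweep value.
#' @param di_values Inhibition distances to test (bp).
#' @param observed Observed histogram counts on `breaks`.
#' @param breaks Histogram breaks (bp).
#' @param n_seeds Simulations averaged per value.
#' @return Data frame: `di`, `chi2`, `kl`, `total_firings`.
#' @export
sweep_inhibition_distance <- function(layout, params = replication_params(),
                                      di_values = seq(0, 120000, by = 5000),
                                      observed, breaks = seq(0, 8e5, 2e4),
                                      n_seeds = 1L) {
  stopifnot(length(observed) == length(breaks) - 1L)
  rows <- lapply(di_values, function(di) {
    p <- params
    p$inhibition_distance <- di
    counts <- 0
    firings <- 0
    for (s in seq_len(n_seeds)) {
      p$seed <- params$seed + (s - 1L)
      res <- run_simulation(layout, p)
      counts <- counts + bin_distances(inter_origin_distances(res), breaks)
      firings <- firings + nrow(res$firings)
    }
    data.frame(
      di = di,
      chi2 = distribution_distance(observed, counts, "chi2"),
      kl = distribution_distance(observed, counts, "kl"),
      total_firings = firings / n_seeds
    )
  })
  do.call(rbind, rows)
}

#' Write a timing profile as bedGraph
#'
#' @param profile Data frame from [timing_profile()].
#' @param file Output path.
#' @param chrom Chromosome label for the bedGraph rows.
#' @param span Interval span per position (bp).
#' @export
write_timing_bedgraph <- function(profile, file, chrom = "genome",
                                  span = 1000) {
  df <- data.frame(
    chrom = chrom,
    start = format(profile$position, scientific = FALSE, trim = TRUE),
    end = format(profile$position + span, scientific = FALSE, trim = TRUE),
    value = profile$time
  )
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}

#' Read a timing profile from bedGraph or 2-column CSV
#'
#' @param file Input path; tab-separated bedGraph (chrom, start, end,
#'   value) or comma-separated (position, value).
#' @return Data frame `position`, `value`.
#' @export
read_timing_profile <- function(file) {
  first <- readLines(file, n = 1)
  if (grepl("\t", first)) {
    df <- read.table(file, sep = "\t", header = FALSE)
    data.frame(position = df[[2]], value = df[[4]])
  } else {
    df <- utils::read.csv(file, header = FALSE)
    data.frame(position = df[[1]], value = df[[2]])
  }
}
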
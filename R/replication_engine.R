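# Replication engine ---------------------------------------------------------
#
# Event-driven stochastic simulation of S-phase: potential origins are
# placed uniformly at random, fire spontaneously with chromatin-class
# probabilities or are induced by nearby active forks (domino effect),
# subject to an inhibition distance and a diffusible limiting factor that
# caps the number of simultaneously active forks.  The inner loop is
# compiled code; the functions below expose the model's elementary
# quantities for direct use and testing.

#' Replication model parameters
#'
#' Defaults are the HeLa parameter set used throughout: 500,000 potential
#' origins, at most 12,000 simultaneously active forks (the limiting
#' factor, rising as \eqn{L(t) = L_{max}(1 - e^{-t/\tau})} with
#' \eqn{\tau = 15} min), fork speed ramping linearly from 0 to 28 bp/s over
#' the first 2.8 h, induced firing with Gaussian width \eqn{\sigma = 240}
#' kbp cut off below probability 0.1, inhibition within 55 kbp of an active
#' fork, and spontaneous firing probabilities 0.8 / 0.05 / 0 for EU / FAC /
#' CON chromatin.
#'
#' @param n_potential_origins Number of potential origins \eqn{N_0}.
#' @param limiting_factor_max Maximum simultaneous forks \eqn{L_{max}}.
#' @param factor_timescale Limiting-factor growth timescale \eqn{\tau} (s).
#' @param max_fork_speed Plateau fork speed \eqn{\nu} (bp/s).
#' @param speed_ramp_duration Duration of the linear speed ramp (s).
#' @param induced_sigma Gaussian s.d. of induced firing \eqn{\sigma} (bp).
#' @param induced_cutoff Gaussian values below this are set to zero.
#' @param inhibition_distance No firing closer than this to a fork (bp).
#' @param p_spontaneous Length-3 numeric (EU, FAC, CON): relative
#'   spontaneous firing probabilities.
#' @param seed Integer seed controlling all randomness of a run.
#' @return A `replication_params` object.
#' @export
replication_params <- function(n_potential_origins = 500000L,
                               limiting_factor_max = 12000L,
                               factor_timescale = 900,
                               max_fork_speed = 28,
                               speed_ramp_duration = 10080,
                               induced_sigma = 240000,
                               induced_cutoff = 0.1,
                               inhibition_distance = 55000,
                               p_spontaneous = c(EU = 0.8, FAC = 0.05,
                                                 CON = 0.0),
                               seed = 1L) {
  p <- as.numeric(p_spontaneous)
  stopifnot(length(p) == 3L, all(p >= 0), all(p <= 1))
  if (!(p[3] <= p[2] && p[2] <= p[1])) {
    stop("spontaneous probabilities must satisfy p_con <= p_fac <= p_eu")
  }
  stopifnot(
    n_potential_origins >= 1, limiting_factor_max >= 1,
    factor_timescale > 0, max_fork_speed > 0, speed_ramp_duration >= 0,
    induced_sigma > 0, induced_cutoff > 0, induced_cutoff < 1,
    inhibition_distance >= 0
  )
  structure(
    list(
      n_potential_origins = as.integer(n_potential_origins),
      limiting_factor_max = as.integer(limiting_factor_max),
      factor_timescale = factor_timescale,
      max_fork_speed = max_fork_speed,
      speed_ramp_duration = speed_ramp_duration,
      induced_sigma = induced_sigma,
      induced_cutoff = induced_cutoff,
      inhibition_distance = inhibition_distance,
      p_spontaneous = setNames(p, CHROMATIN_CLASSES),
      seed = as.integer(seed)
    ),
    class = "replication_params"
  )
}

#' @export
print.replication_params <- function(x, ...) {
  cat(sprintf(
    paste0("<replication_params> N0=%d Lmax=%d tau=%gs nu=%g bp/s ",
           "ramp=%gs sigma=%g bp di=%g bp p=(%g,%g,%g) seed=%d\n"),
    x$n_potential_origins, x$limiting_factor_max, x$factor_timescale,
    x$max_fork_speed, x$speed_ramp_duration, x$induced_sigma,
    x$inhibition_distance, x$p_spontaneous[1], x$p_spontaneous[2],
    x$p_spontaneous[3], x$seed
  ))
  invisible(x)
}

#' Place potential origins uniformly on the genome
#'
#' @param layout A `genome_layout`.
#' @param n_origins Number of origins to place.
#' @param seed Integer seed (deterministic placement per seed).
#' @return Sorted numeric vector of global positions in base pairs.
#' @export
place_origins <- function(layout, n_origins, seed = 1L) {
  stopifnot(inherits(layout, "genome_layout"), n_origins >= 1)
  with_seed(seed, sort(runif(n_origins, 0, layout$total_length)))
}

#' Available limiting-factor count at time t
#'
#' \eqn{\lfloor L_{max}(1 - e^{-t/\tau}) \rfloor}: the number of fork
#' "licences" available `t` seconds after S-phase entry.
#'
#' @param t Time(s) in seconds, `t >= 0`.
#' @param l_max Maximum factor count.
#' @param tau Growth timescale in seconds.
#' @return Integer vector of available factor counts.
#' @export
limiting_factor <- function(t, l_max = 12000, tau = 900) {
  if (any(t < 0)) stop("t must be >= 0")
  as.integer(floor(l_max * (1 - exp(-t / tau))))
}

#' Fork speed at time t
#'
#' Linear ramp from 0 at S-phase entry to the plateau speed `nu` at
#' `ramp` seconds, constant afterwards: \eqn{v(t) = \nu\,\min(t/ramp, 1)}.
#'
#' @param t Time(s) in seconds.
#' @param nu Plateau speed (bp/s).
#' @param ramp Ramp duration (s); `0` means constant speed.
#' @return Speed(s) in bp/s.
#' @export
fork_speed <- function(t, nu = 28, ramp = 10080) {
  if (ramp <= 0) return(rep(nu, length(t)))
  nu * pmin(t / ramp, 1)
}

#' Cumulative fork travel distance
#'
#' \eqn{s(t) = \int_0^t v(u)\,du} under the linear speed ramp.
#'
#' @inheritParams fork_speed
#' @return Distance(s) in bp.
#' @export
fork_distance <- function(t, nu = 28, ramp = 10080) {
  if (ramp <= 0) return(nu * t)
  ifelse(t <= ramp, 0.5 * nu * t^2 / ramp, nu * (t - 0.5 * ramp))
}

#' Inverse of the cumulative fork travel distance
#'
#' The time at which a fork created at t = 0 has travelled `d` base pairs.
#'
#' @param d Distance(s) in bp, `d >= 0`.
#' @inheritParams fork_speed
#' @return Time(s) in seconds.
#' @export
fork_travel_time <- function(d, nu = 28, ramp = 10080) {
  if (any(d < 0)) stop("d must be >= 0")
  if (ramp <= 0) return(d / nu)
  d_ramp <- 0.5 * nu * ramp
  ifelse(d <= d_ramp, sqrt(2 * d * ramp / nu), d / nu + 0.5 * ramp)
}

#' Time of collision between two approaching forks
#'
#' Two forks approaching each other close their gap at twice the common
#' fork speed; the collision time solves
#' \eqn{gap = 2\,(s(t_c) - s(t_{ref}))}.
#'
#' @param gap Distance between the forks at `t_ref` (bp).
#' @param t_ref Reference time (s).
#' @inheritParams fork_speed
#' @return Absolute collision time in seconds.
#' @export
collision_time <- function(gap, t_ref = 0, nu = 28, ramp = 10080) {
  if (any(gap < 0)) stop("gap must be >= 0")
  fork_travel_time(fork_distance(t_ref, nu, ramp) + gap / 2, nu, ramp)
}

#' Induced (domino-like) firing probability at a distance from a fork
#'
#' Gaussian of the distance with s.d. `sigma`, cut to zero below `cutoff`
#' and inside the inhibition distance:
#' \eqn{g = e^{-d^2 / 2\sigma^2}}; returns 0 if `d < di` or `g < cutoff`.
#'
#' @param distance Distance(s) from an active fork (bp), `>= 0`.
#' @param sigma Gaussian s.d. (bp).
#' @param cutoff Probability floor below which induction is zero.
#' @param di Inhibition distance (bp).
#' @return Relative probabilities in `[0, 1]`.
#' @export
induced_probability <- function(distance, sigma = 240000, cutoff = 0.1,
                                di = 55000) {
  if (any(distance < 0)) stop("distance must be >= 0")
  g <- exp(-distance^2 / (2 * sigma^2))
  g[distance < di | g < cutoff] <- 0
  g
}

#' Relative firing probability of an origin given nearby forks
#'
#' The maximum of the spontaneous class probability and the induced
#' probabilities from all active forks on the same chromosome; zero if any
#' such fork is closer than the inhibition distance.  Induced contributions
#' never cross chromosome barriers, which is why only same-chromosome fork
#' positions are considered.
#'
#' @param position Origin position (bp).
#' @param zone_class Chromatin class of the origin's zone
#'   (`"EU"`, `"FAC"`, `"CON"`).
#' @param fork_positions Positions of active forks on the same chromosome.
#' @param params A [replication_params()].
#' @return A single relative probability in `[0, 1]`.
#' @export
firing_probability <- function(position, zone_class, fork_positions,
                               params = replication_params()) {
  zone_class <- match.arg(zone_class, CHROMATIN_CLASSES)
  d <- abs(fork_positions - position)
  if (any(d < params$inhibition_distance)) return(0)
  p_sp <- params$p_spontaneous[[zone_class]]
  p_ind <- if (length(d) > 0) {
    max(induced_probability(d, params$induced_sigma, params$induced_cutoff,
                            params$inhibition_distance))
  } else 0
  max(p_sp, p_ind)
}

#' Limiting-factor release schedule
#'
#' Times at which the available factor count \eqn{\lfloor L(t) \rfloor}
#' increments: \eqn{t_k = -\tau \ln(1 - k/L_{max})} for
#' \eqn{k = 1, \ldots, L_{max}-1}.  The final increment, unreachable under
#' the exact formula, is granted where \eqn{L(t) = L_{max} - 1/2}, i.e. at
#' \eqn{t = \tau \ln(2 L_{max})}.
#'
#' @inheritParams limiting_factor
#' @return Data frame with columns `k` and `time` (seconds).
#' @export
schedule_factor_releases <- function(l_max = 12000, tau = 900) {
  k <- seq_len(l_max)
  time <- c(-tau * log(1 - k[-l_max] / l_max), tau * log(2 * l_max))
  data.frame(k = k, time = time)
}

# Build the flat zone/barrier arrays the compiled engine consumes.
layout_arrays <- function(layout) {
  z <- layout$zones
  list(
    gstart = z$gstart,
    gend = z$gend,
    class0 = as.integer(z$class) - 1L,
    chrom0 = as.integer(z$chrom_index) - 1L,
    barriers = layout$barriers
  )
}

#' Run the replication simulation
#'
#' Event-driven simulation until every base pair of the genome is
#' replicated.  Deterministic for a given parameter seed.
#'
#' @param layout A `genome_layout`.
#' @param params A [replication_params()].
#' @param variant Model variant: `"combined"` (default), `"spontaneous_only"`
#'   (induced firing disabled), or `"induced_only"` (spontaneous firing
#'   disabled and one origin fired in every euchromatic zone at t = 0).
#' @param record_interval Time-series recording interval (s).
#' @param snapshot_times Times (s) at which to record all active fork
#'   positions (needed for cluster series and in-silico microscopy).
#' @param forced_firings Optional data frame with columns `position` and
#'   `time`: deterministic firing schedule used for validation scenarios.
#'   Forced firings bypass the limiting factor.
#' @param origins Optional pre-placed origin positions (sorted); by default
#'   [place_origins()] is called with the parameter seed.
#' @param max_time Hard time cap (s); `Inf` runs to completion.
#' @return A `simulation_result` with elements `firings` (position, time,
#'   mode, class, chromosome), `replicons` (origin with left/right end),
#'   `time_series` (per-class replicated bp and fork counts, free factors),
#'   `snapshots`, `completion_time`, `params`, `variant` and layout summary.
#' @export
run_simulation <- function(layout, params = replication_params(),
                           variant = c("combined", "spontaneous_only",
                                       "induced_only"),
                           record_interval = 300,
                           snapshot_times = numeric(0),
                           forced_firings = NULL,
                           origins = NULL,
                           max_time = Inf) {
  stopifnot(inherits(layout, "genome_layout"),
            inherits(params, "replication_params"))
  variant <- match.arg(variant)
  arr <- layout_arrays(layout)
  if (is.null(origins)) {
    origins <- place_origins(layout, params$n_potential_origins, params$seed)
  }
  induced_on <- variant != "spontaneous_only"
  spontaneous_on <- variant != "induced_only"

  fpos <- numeric(0)
  ftime <- numeric(0)
  if (variant == "induced_only") {
    # one initial firing per euchromatic zone at t = 0: a random potential
    # origin inside the zone, or the zone midpoint if it holds none
    eu <- layout$zones[layout$zones$class == "EU", ]
    fpos <- with_seed(params$seed + 1L, vapply(seq_len(nrow(eu)), function(i) {
      lo <- findInterval(eu$gstart[i], origins) + 1L
      hi <- findInterval(eu$gend[i] - 1e-9, origins)
      if (hi >= lo) origins[[sample(lo:hi, 1L)]]
      else (eu$gstart[i] + eu$gend[i]) / 2
    }, numeric(1)))
    ftime <- rep(0, length(fpos))
  }
  if (!is.null(forced_firings)) {
    stopifnot(all(c("position", "time") %in% names(forced_firings)))
    fpos <- c(fpos, forced_firings$position)
    ftime <- c(ftime, forced_firings$time)
  }

  raw <- .simulate_replication_cpp(
    arr$gstart, arr$gend, arr$class0, arr$chrom0, arr$barriers,
    origins,
    params$limiting_factor_max, params$factor_timescale,
    params$max_fork_speed, params$speed_ramp_duration,
    params$induced_sigma, params$induced_cutoff,
    params$inhibition_distance,
    params$p_spontaneous,
    induced_on, spontaneous_on,
    fpos, ftime,
    record_interval, snapshot_times,
    params$seed, max_time
  )

  firings <- raw$firings
  firings$mode <- factor(c("spontaneous", "induced", "initial")[firings$mode + 1L],
                         levels = c("spontaneous", "induced", "initial"))
  firings$class <- factor(CHROMATIN_CLASSES[firings$class_index + 1L],
                          levels = CHROMATIN_CLASSES)
  firings$class_index <- NULL

  replicons <- data.frame(
    origin = firings$position,
    left_end = firings$left_end,
    right_end = firings$right_end,
    chrom_index = firings$chrom_index
  )
  firings$left_end <- NULL
  firings$right_end <- NULL

  snapshots <- raw$snapshots
  st <- sort(snapshot_times)
  for (i in seq_along(snapshots)) {
    snapshots[[i]]$class <- factor(
      CHROMATIN_CLASSES[snapshots[[i]]$class_index + 1L],
      levels = CHROMATIN_CLASSES)
    snapshots[[i]]$class_index <- NULL
    attr(snapshots[[i]], "time") <- st[i]
  }

  structure(
    list(
      firings = firings,
      replicons = replicons,
      time_series = raw$time_series,
      snapshots = snapshots,
      snapshot_times = st[seq_along(snapshots)],
      completion_time = raw$completion_time,
      complete = raw$complete,
      replicated_by_class = setNames(raw$replicated_by_class,
                                     CHROMATIN_CLASSES),
      total_length = layout$total_length,
      barriers = layout$barriers,
      params = params,
      variant = variant,
      n_events = raw$n_events
    ),
    class = "simulation_result"
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    paste0("<simulation_result> variant=%s: %d firings, ",
           "completion %.2f h, %.3f Gbp replicated\n"),
    x$variant, nrow(x$firings), x$completion_time / 3600,
    sum(x$replicated_by_class) / 1e9
  ))
  invisible(x)
}

#' Run a named model variant
#'
#' Convenience wrapper around [run_simulation()]: `"spontaneous_only"`
#' disables induced firing, `"induced_only"` disables spontaneous firing
#' and fires one origin per euchromatic zone at t = 0, `"combined"` is the
#' full model.
#'
#' @inheritParams run_simulation
#' @return A `simulation_result`.
#' @export
run_model_variant <- function(layout, params = replication_params(),
                              variant = c("combined", "spontaneous_only",
                                          "induced_only"),
                              ...) {
  variant <- match.arg(variant)
  run_simulation(layout, params, variant = variant, ...)
}

#' Fraction of all firings that were spontaneous
#'
#' A firing is classified spontaneous when the spontaneous term attains the
#' maximum of the two probabilities at draw time (ties count as
#' spontaneous); initial firings of the induced-only variant are excluded.
#'
#' @param result A `simulation_result`.
#' @return Fraction in `[0, 1]`.
#' @export
spontaneous_fraction <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  m <- result$firings$mode
  n <- sum(m != "initial")
  if (n == 0) return(NA_real_)
  sum(m == "spontaneous") / n
}
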
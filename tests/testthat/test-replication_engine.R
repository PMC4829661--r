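test_that("limiting factor follows the saturating-exponential closed form", {
  expect_equal(limiting_factor(0), 0L)
  expect_equal(limiting_factor(1e9), 12000L)
  expect_equal(limiting_factor(900, 12000, 900),
               as.integer(floor(12000 * (1 - exp(-1)))))
  expect_equal(limiting_factor(900, 12000, 900), 7585L)
  expect_error(limiting_factor(-1), ">= 0")
  t <- seq(0, 7200, by = 10)
  expect_true(all(diff(limiting_factor(t)) >= 0))
})

test_that("factor release times invert the floor increments of L(t)", {
  sched <- schedule_factor_releases(12000, 900)
  expect_equal(nrow(sched), 12000L)
  expect_equal(sched$time[1], -900 * log(1 - 1 / 12000))
  expect_equal(sched$time[6000], 900 * log(2))
  expect_equal(sched$time[12000], 900 * log(2 * 12000))
  expect_true(all(diff(sched$time) > 0))
  # just after release k (k < L_max) the available count is exactly k
  k <- c(1L, 17L, 6000L, 11999L)
  expect_equal(limiting_factor(sched$time[k] + 1e-6), k)
  expect_equal(limiting_factor(sched$time[k] - 1e-6), k - 1L)
})

test_that("fork speed ramps linearly and its distance integral inverts", {
  expect_equal(fork_speed(0), 0)
  expect_equal(fork_speed(10080), 28)
  expect_equal(fork_speed(99999), 28)
  expect_equal(fork_speed(5040), 14)  # halfway up the ramp
  expect_equal(fork_distance(10080), 28 * 10080 / 2)
  # inversion round-trip across the ramp boundary
  d <- c(0, 1e3, 1e5, 1.411e5, 5e5, 2e7)
  expect_equal(fork_distance(fork_travel_time(d)), d)
  expect_error(fork_travel_time(-5), ">= 0")
  # constant-speed degenerate case
  expect_equal(fork_speed(3, nu = 28, ramp = 0), 28)
  expect_equal(fork_travel_time(280, nu = 28, ramp = 0), 10)
})

test_that("collision times match closed form and a numeric oracle", {
  # constant speed: gap closes at 2 * nu
  expect_equal(collision_time(1000, nu = 28, ramp = 0), 1000 / 56)
  expect_equal(collision_time(0, nu = 28, ramp = 0), 0)
  # during the ramp, invert s(t) = nu t^2 / (2 ramp) numerically
  gap <- 1000
  oracle <- uniroot(
    function(t) 2 * fork_distance(t, 28, 10080) - gap,
    c(0, 10080)
  )$root
  expect_equal(collision_time(gap, t_ref = 0), oracle, tolerance = 1e-6)
  # starting mid-ramp
  t_ref <- 5000
  oracle2 <- uniroot(
    function(t) 2 * (fork_distance(t, 28, 10080) -
                       fork_distance(t_ref, 28, 10080)) - gap,
    c(t_ref, 20000)
  )$root
  expect_equal(collision_time(gap, t_ref = t_ref), oracle2,
               tolerance = 1e-6)
})

test_that("induced firing probability is a cut Gaussian with inhibition", {
  expect_equal(induced_probability(30000), 0)       # inside d_i
  expect_equal(induced_probability(55000),
               exp(-55000^2 / (2 * 240000^2)))      # boundary allowed
  expect_equal(induced_probability(240000), exp(-0.5), tolerance = 1e-12)
  expect_equal(induced_probability(600000), 0)      # below cutoff 0.1
  expect_gt(exp(-600000^2 / (2 * 240000^2)), 0)     # nonzero before cut
  expect_error(induced_probability(-1), ">= 0")
})

test_that("origin firing probability combines spontaneous and induced", {
  p <- replication_params()
  expect_equal(firing_probability(1e6, "EU", numeric(0), p), 0.8)
  expect_equal(firing_probability(1e6, "CON", numeric(0), p), 0)
  expect_equal(firing_probability(1e6, "FAC", 1e6 + 240000, p),
               exp(-0.5))
  # any fork inside d_i zeroes the probability outright
  expect_equal(firing_probability(1e6, "EU", c(1e6 + 30000, 2e6), p), 0)
  # induced contribution from the best of several forks
  expect_equal(
    firing_probability(1e6, "CON", c(1e6 + 240000, 1e6 + 400000), p),
    exp(-0.5)
  )
})

test_that("origin placement is uniform, sorted and seed-deterministic", {
  lay <- toy_layout()
  o1 <- place_origins(lay, 500, seed = 9)
  o2 <- place_origins(lay, 500, seed = 9)
  o3 <- place_origins(lay, 500, seed = 10)
  expect_identical(o1, o2)
  expect_false(isTRUE(all.equal(o1, o3)))
  expect_true(!is.unsorted(o1))
  expect_true(all(o1 >= 0 & o1 < lay$total_length))
  expect_length(place_origins(lay, 1, seed = 1), 1L)
  # mean spacing ~ total / N
  expect_equal(mean(diff(o1)), lay$total_length / 500, tolerance = 0.1)
})

test_that("simulation replicates every base pair exactly once", {
  lay <- toy_layout()
  res <- run_simulation(lay, toy_params(seed = 2))
  expect_true(res$complete)
  expect_equal(sum(res$replicated_by_class), lay$total_length,
               tolerance = 1e-9)
  r <- res$replicons[order(res$replicons$left_end), ]
  expect_equal(sum(r$right_end - r$left_end), lay$total_length,
               tolerance = 1e-6)
  # adjacent replicons share endpoints exactly (no gaps, no overlaps)
  for (ci in unique(r$chrom_index)) {
    d <- r[r$chrom_index == ci, ]
    expect_equal(d$left_end[1], lay$barriers[ci])
    expect_equal(d$right_end[nrow(d)], lay$barriers[ci + 1])
    if (nrow(d) > 1) {
      expect_equal(d$left_end[-1], d$right_end[-nrow(d)])
    }
  }
})

test_that("simulation is reproducible for a seed and differs across seeds", {
  lay <- toy_layout()
  a <- run_simulation(lay, toy_params(seed = 5))
  b <- run_simulation(lay, toy_params(seed = 5))
  c <- run_simulation(lay, toy_params(seed = 6))
  expect_identical(a$firings, b$firings)
  expect_identical(a$completion_time, b$completion_time)
  expect_false(isTRUE(all.equal(a$firings$position, c$firings$position)))
})

test_that("factor accounting holds at every recorded instant", {
  lay <- toy_layout()
  p <- toy_params(seed = 3)
  res <- run_simulation(lay, p, record_interval = 120)
  ts <- res$time_series
  forks <- ts$forks_eu + ts$forks_fac + ts$forks_con
  cap <- limiting_factor(ts$time, p$limiting_factor_max,
                         p$factor_timescale)
  # records are taken before processing events that fall exactly on the
  # grid, so the discretized capacity may lag floor(L(t)) by one
  expect_true(all(abs(forks + ts$free_factors - cap) <= 1))
  expect_true(all(forks <= p$limiting_factor_max))
  expect_true(all(ts$free_factors >= 0))
})

test_that("no origin fires within the inhibition distance of an active fork", {
  lay <- toy_layout()
  p <- toy_params(seed = 4)
  res <- run_simulation(lay, p)
  f <- res$firings
  r <- res$replicons
  nu <- p$max_fork_speed
  ramp <- p$speed_ramp_duration
  # reconstruct active fork positions at each firing time from replicons:
  # a fork born at (origin, t0) is active until it reaches its end
  s_at <- fork_distance(f$time, nu, ramp)
  left_end_t <- fork_travel_time(
    fork_distance(f$time, nu, ramp) + (f$position - r$left_end), nu, ramp)
  right_end_t <- fork_travel_time(
    fork_distance(f$time, nu, ramp) + (r$right_end - f$position), nu, ramp)
  viol <- 0
  for (i in seq_len(nrow(f))) {
    t <- f$time[i]
    x <- f$position[i]
    s_t <- fork_distance(t, nu, ramp)
    act <- which(f$time < t & f$chrom_index == f$chrom_index[i])
    if (length(act) == 0) next
    travelled <- s_t - s_at[act]
    lpos <- f$position[act] - travelled
    rpos <- f$position[act] + travelled
    d <- c(abs(x - lpos[t < left_end_t[act] - 1e-9]),
           abs(x - rpos[t < right_end_t[act] - 1e-9]))
    if (length(d) > 0 && min(d) < p$inhibition_distance - 1e-6) {
      viol <- viol + 1
    }
  }
  expect_equal(viol, 0)
})

test_that("event-driven results match a brute-force time-stepped oracle", {
  # deterministic scenarios: scheduled firings only, no stochastic firing
  lay <- manual_layout(list(
    data.frame(start = c(0, 4e4), end = c(4e4, 1e5),
               class = c("EU", "CON")),
    data.frame(start = 0, end = 6e4, class = "EU")
  ))
  zero_p <- replication_params(
    n_potential_origins = 1L, p_spontaneous = c(0, 0, 0),
    max_fork_speed = 28, speed_ramp_duration = 0, seed = 1
  )
  scenarios <- list(
    # single origin per chromosome
    data.frame(position = c(2e4, 1.3e5), time = c(0, 10)),
    # three origins on one chromosome, staggered: inner pairs collide,
    # outer forks reach barriers; one late firing lands on replicated
    # DNA and must be skipped by both simulators
    data.frame(position = c(1e4, 4.8e4, 8.9e4, 5.2e4, 1.4e5),
               time = c(0, 100, 200, 1200, 50)),
    # stale-collision scenario: a pair whose partner annihilates first
    data.frame(position = c(2e4, 3.6e4, 7.9e4, 1.3e5),
               time = c(0, 100, 140, 0))
  )
  dt <- 0.1
  for (sc in scenarios) {
    eng <- run_simulation(lay, zero_p, variant = "spontaneous_only",
                          forced_firings = sc)
    ora <- oracle_simulate(lay, sc, nu = 28, ramp = 0, dt = dt)
    expect_true(eng$complete)
    expect_true(ora$complete)
    expect_equal(eng$completion_time, ora$completion_time,
                 tolerance = 3 * dt / ora$completion_time)
    # same set of effective firings
    expect_equal(nrow(eng$firings), nrow(ora$replicons))
    eo <- order(eng$replicons$origin)
    oo <- order(ora$replicons$origin)
    expect_equal(eng$replicons$origin[eo], ora$replicons$origin[oo])
    expect_lt(max(abs(eng$replicons$left_end[eo] -
                        ora$replicons$left[oo])), 2 * dt * 28)
    expect_lt(max(abs(eng$replicons$right_end[eo] -
                        ora$replicons$right[oo])), 2 * dt * 28)
  }
})

test_that("oracle equivalence also holds during the speed ramp", {
  lay <- manual_layout(list(
    data.frame(start = 0, end = 1e5, class = "EU")
  ))
  ramp_p <- replication_params(
    n_potential_origins = 1L, p_spontaneous = c(0, 0, 0),
    max_fork_speed = 28, speed_ramp_duration = 10080, seed = 1
  )
  sc <- data.frame(position = c(2.5e4, 7.5e4), time = c(0, 600))
  dt <- 0.1
  eng <- run_simulation(lay, ramp_p, variant = "spontaneous_only",
                        forced_firings = sc)
  ora <- oracle_simulate(lay, sc, nu = 28, ramp = 10080, dt = dt)
  expect_equal(eng$completion_time, ora$completion_time,
               tolerance = 3 * dt / ora$completion_time)
  # collision position: the gap closes under time-varying speed
  eo <- order(eng$replicons$origin)
  expect_lt(abs(eng$replicons$right_end[eo][1] - ora$replicons$right[1]),
            2 * dt * 28)
})

test_that("model variants alter firing modes as specified", {
  lay <- toy_layout()
  sp <- run_simulation(lay, toy_params(seed = 7),
                       variant = "spontaneous_only")
  expect_true(all(sp$firings$mode == "spontaneous"))
  expect_true(sp$complete)

  ind <- run_simulation(lay, toy_params(seed = 7),
                        variant = "induced_only")
  n_eu <- sum(lay$zones$class == "EU")
  init <- ind$firings[ind$firings$mode == "initial", ]
  expect_equal(nrow(init), n_eu)
  expect_true(all(init$time == 0))
  expect_true(all(init$class == "EU"))
  expect_true(all(ind$firings$mode %in% c("initial", "induced")))
  expect_true(ind$complete)
})

test_that("completion time decreases with more factors and faster forks", {
  lay <- toy_layout()
  mean_completion <- function(l_max, nu) {
    mean(vapply(1:2, function(s) {
      p <- replication_params(
        n_potential_origins = 2000L, limiting_factor_max = l_max,
        max_fork_speed = nu, seed = s)
      run_simulation(lay, p)$completion_time
    }, numeric(1)))
  }
  by_lmax <- vapply(c(12, 60, 240), mean_completion, numeric(1), nu = 28)
  expect_true(all(diff(by_lmax) < 0))
  by_nu <- vapply(c(14, 28, 56), function(nu) {
    mean_completion(60, nu)
  }, numeric(1))
  expect_true(all(diff(by_nu) < 0))
})

test_that("a genome that cannot be replicated raises a progress error", {
  # all-CON chromosome, no induced seeds, no spontaneous firing possible
  lay <- manual_layout(list(
    data.frame(start = 0, end = 1e6, class = "CON")
  ))
  p <- replication_params(n_potential_origins = 100L, seed = 1,
                          p_spontaneous = c(0, 0, 0))
  expect_error(run_simulation(lay, p), "cannot progress")
})
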
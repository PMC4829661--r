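fake_result <- function(firings, params = replication_params(),
                        replicons = NULL, barriers = NULL) {
  structure(
    list(firings = firings, params = params, replicons = replicons,
         barriers = barriers),
    class = "simulation_result"
  )
}

test_that("inter-origin distances are per-chromosome adjacent differences", {
  f <- data.frame(position = c(1e5, 9e5, 4e5), chrom_index = c(1, 1, 1))
  d <- inter_origin_distances(fake_result(f))
  expect_equal(sort(d), c(3e5, 5e5))
  # one firing per chromosome yields no distances
  f2 <- data.frame(position = c(1e5, 9e5), chrom_index = c(1, 2))
  expect_length(inter_origin_distances(fake_result(f2)), 0L)
  # distances from a real run are positive and never span barriers
  res <- run_simulation(toy_layout(), toy_params(seed = 2))
  d3 <- inter_origin_distances(res)
  expect_true(all(d3 > 0))
  expect_lt(max(d3), max(diff(toy_layout()$barriers)))
})

test_that("cluster identification groups forks below the gap threshold", {
  cl <- identify_clusters(c(0.1e6, 0.5e6, 2.0e6), threshold = 1e6)
  expect_equal(cl$n_forks, c(2L, 1L))
  expect_equal(cl$span, c(0.4e6, 0))
  # strict inequality: a gap of exactly 1 Mbp separates clusters
  cl2 <- identify_clusters(c(0, 1e6), threshold = 1e6)
  expect_equal(nrow(cl2), 2L)
  cl3 <- identify_clusters(c(0, 1e6 - 1), threshold = 1e6)
  expect_equal(nrow(cl3), 1L)
  # a barrier splits otherwise-close forks
  cl4 <- identify_clusters(c(0.9e6, 1.1e6), barriers = c(0, 1e6, 2e6),
                           threshold = 1e6)
  expect_equal(nrow(cl4), 2L)
  expect_equal(nrow(identify_clusters(numeric(0))), 0L)
})

test_that("cluster identification matches an O(n^2) union-find oracle", {
  barriers <- c(0, 3e7, 5e7, 1e8)
  set.seed(42)
  for (trial in 1:100) {
    n <- sample(1:300, 1)
    pos <- runif(n, 0, 1e8)
    thr <- runif(1, 1e5, 5e6)
    fast <- identify_clusters(pos, barriers, thr)
    slow <- cluster_oracle(pos, barriers, thr)
    expect_equal(nrow(fast), nrow(slow))
    expect_equal(sort(fast$n_forks), sort(slow$n_forks))
    expect_equal(sort(fast$span), sort(slow$span), tolerance = 1e-9)
    expect_equal(sum(fast$n_forks), n)
  }
})

test_that("cluster series counts every active fork exactly once", {
  res <- run_simulation(toy_layout(), toy_params(seed = 8),
                        snapshot_times = seq(0, 4e4, by = 4e3))
  cs <- cluster_series(res)
  expect_equal(nrow(cs), length(res$snapshots))
  for (i in seq_along(res$snapshots)) {
    expect_equal(cs$total_forks[i], nrow(res$snapshots[[i]]))
    cl <- identify_clusters(res$snapshots[[i]]$position, res$barriers)
    expect_equal(cs$n_clusters[i], nrow(cl))
    expect_equal(sum(cl$n_forks), cs$total_forks[i])
  }
  expect_error(cluster_series(run_simulation(toy_layout(),
                                             toy_params(seed = 8))),
               "snapshot")
})

test_that("cluster front speed follows nu * L_max / (2 N_c)", {
  expect_equal(cluster_front_speed(28, 12000, 1680), 100)
  expect_equal(cluster_front_speed(28, 12000, 6000), 28)
  expect_equal(cluster_front_speed(28, 12000, 1), 28 * 12000 / 2)
  expect_error(cluster_front_speed(28, 12000, 0), ">= 1")
})

test_that("timing profile interpolates fork arrival within replicons", {
  p <- replication_params(max_fork_speed = 28, speed_ramp_duration = 0)
  f <- data.frame(position = c(1e3, 1e4), time = c(10, 50),
                  mode = "spontaneous", class = "EU",
                  chrom_index = c(1, 1))
  reps <- data.frame(origin = c(1e3, 1e4), left_end = c(0, 5.5e3),
                     right_end = c(5.5e3, 2e4), chrom_index = c(1, 1))
  res <- fake_result(f, p, replicons = reps)
  prof <- timing_profile(res, c(1e3, 1e4, 1.5e3, 8e3))
  expect_equal(prof$time[1], 10)           # at the origin: firing time
  expect_equal(prof$time[2], 50)
  expect_equal(prof$time[3], 10 + 500 / 28) # right-moving fork arrival
  expect_equal(prof$time[4], 50 + 2000 / 28) # left-moving fork arrival
  # averaging across runs is the arithmetic mean per position
  f2 <- f
  f2$time <- f2$time + 100
  res2 <- fake_result(f2, p, replicons = reps)
  both <- timing_profile(list(res, res2), c(1e3, 8e3))
  expect_equal(both$time, prof$time[c(1, 4)] + 50)
  # positions outside any replicon are flagged missing
  gap <- timing_profile(res, 2.5e4)
  expect_true(is.na(gap$time))
})

test_that("timing profile equals firing times exactly at origins", {
  res <- run_simulation(toy_layout(), toy_params(seed = 2))
  k <- seq(1, nrow(res$firings), by = 7)
  prof <- timing_profile(res, res$firings$position[k])
  expect_equal(prof$time, res$firings$time[k], tolerance = 1e-9)
})

test_that("profile correlation is Pearson's r on matched positions", {
  a <- data.frame(position = 1:3, time = c(2, 4, 6))
  expect_equal(profile_correlation(a, a), 1)
  b <- a
  b$time <- -a$time
  expect_equal(profile_correlation(a, b), -1)
  expect_equal(profile_correlation(
    data.frame(position = 1:3, time = c(1, 2, 3)),
    data.frame(position = 1:3, value = c(2, 4, 6))), 1)
  flat <- data.frame(position = 1:3, time = c(1, 1, 1))
  expect_warning(r <- profile_correlation(a, flat), "variance")
  expect_true(is.na(r))
  expect_error(profile_correlation(a, data.frame(position = 9:11,
                                                 time = 1:3)),
               "common")
})

test_that("bootstrap mean test splits fractions around the reference", {
  set.seed(1)
  sym <- rnorm(5000, mean = 188000, sd = 30000)
  bt <- bootstrap_mean_test(sym, repetitions = 2000, seed = 3)
  expect_gt(bt$p_value, 0.3)
  expect_lt(abs(bt$fraction_below + bt$fraction_above - 1), 1e-12)

  low <- rnorm(5000, mean = 120000, sd = 10000)
  bt2 <- bootstrap_mean_test(low, repetitions = 2000, seed = 3)
  expect_true(bt2$upper_bound)
  expect_equal(bt2$reported_p, 1 / 2000)
  expect_equal(bt2$fraction_below, 1)

  expect_error(bootstrap_mean_test(1:10, subset_size = 50), "smaller")
})

test_that("bootstrap P values are not anti-conservative near the null", {
  # i.i.d. samples centred on the reference: P < 0.05 should be rare
  set.seed(7)
  hits <- sum(vapply(1:200, function(i) {
    x <- rlnorm(300, log(188000), 0.4)
    x <- x * 188000 / mean(x)  # centre the sample mean on the reference
    bootstrap_mean_test(x, repetitions = 500, seed = i)$p_value < 0.05
  }, logical(1)))
  expect_lte(hits, 20)
})

test_that("histogram distances behave like chi-square and KL", {
  expect_equal(distribution_distance(c(5, 5), c(5, 5), "chi2"), 0)
  expect_equal(distribution_distance(c(5, 5), c(10, 10), "kl"), 0)
  expect_equal(distribution_distance(c(10, 0), c(5, 5), "chi2"), 10)
  # empty simulated bin gets a 0.5 pseudo-count, keeping KL finite
  kl <- distribution_distance(c(10, 0), c(0, 10), "kl")
  expect_true(is.finite(kl) && kl > 0)
  p <- c(1, 0) / 1
  q <- c(0.5, 10) / 10.5
  expect_equal(kl, sum(p[1] * log(p[1] / q[1])))
  expect_error(distribution_distance(1:3, 1:4), "binning")
  expect_equal(bin_distances(c(5e4, 7e4, 3e5, 9e5),
                             breaks = seq(0, 8e5, 2e4))[c(3, 4, 16)],
               c(1L, 1L, 1L))
})

test_that("total firings decrease as the inhibition distance grows", {
  lay <- toy_layout()
  obs <- bin_distances(rlnorm(500, log(2e5), 0.5),
                       breaks = seq(0, 8e5, 2e4))
  sw <- sweep_inhibition_distance(
    lay, toy_params(seed = 1), di_values = c(0, 55000, 120000),
    observed = obs, n_seeds = 2
  )
  expect_equal(nrow(sw), 3L)
  expect_true(all(diff(sw$total_firings) < 0))
  expect_true(all(sw$chi2 >= 0) && all(sw$kl > -1e-9))
})

test_that("timing profiles survive a bedGraph round trip", {
  prof <- data.frame(position = c(0, 1e4, 2e4), time = c(5, 10, 15))
  f <- withr::local_tempfile(fileext = ".bedGraph")
  write_timing_bedgraph(prof, f, span = 1e4)
  back <- read_timing_profile(f)
  expect_equal(back$position, prof$position)
  expect_equal(back$value, prof$time)
})
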
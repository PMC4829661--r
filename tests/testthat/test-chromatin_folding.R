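test_that("bead chains have ceil(length / bead_size) beads with majority classes", {
  lay <- manual_layout(list(
    data.frame(start = 0, end = 1e6, class = "EU"),
    data.frame(start = c(0, 6e4), end = c(6e4, 2.5e5),
               class = c("EU", "FAC"))
  ))
  ch <- build_chains(lay, bead_size = 1e5)
  expect_equal(sum(ch$chrom_index == 1), 10L)
  expect_equal(sum(ch$chrom_index == 2), 3L)
  # bead 1 of chromosome 2 straddles EU (60%) / FAC (40%): majority EU
  b <- ch[ch$chrom_index == 2, ]
  expect_equal(as.character(b$class), c("EU", "FAC", "FAC"))
  # full HeLa-scale bead count: one bead per 100 kbp
  lay2 <- generate_synthetic_genome(synthetic_genome_params(seed = 1))
  ch2 <- build_chains(lay2, bead_size = 1e5)
  expect_equal(nrow(ch2),
               sum(ceiling(lay2$chromosomes$length / 1e5)))
  expect_lt(abs(nrow(ch2) - 103634) / 103634, 0.02)
})

test_that("random loops are non-adjacent, intra-chromosome, near target size", {
  lay <- toy_layout()
  ch <- build_chains(lay, bead_size = 1e5)
  lp <- sample_loops(ch, total_loops = 400L, mean_loop_size = 2e6,
                     seed = 4)
  expect_equal(nrow(lp), 400L)
  expect_true(all(lp[, 2] - lp[, 1] >= 2))
  expect_true(all(ch$chrom_index[lp[, 1]] == ch$chrom_index[lp[, 2]]))
  # mean genomic loop size within 10% of 2 Mbp across seeds
  mean_size <- mean(vapply(1:10, function(s) {
    l <- sample_loops(ch, 400L, 2e6, seed = s)
    mean((l[, 2] - l[, 1]) * 1e5)
  }, numeric(1)))
  expect_lt(abs(mean_size - 2e6) / 2e6, 0.1)
  # a 3-bead chain admits only the (1, 3) pair
  lay3 <- manual_layout(list(
    data.frame(start = 0, end = 3e5, class = "EU")))
  ch3 <- build_chains(lay3, bead_size = 1e5)
  l3 <- sample_loops(ch3, 20L, 2e6, seed = 1)
  expect_true(all(l3[, 1] == 1L & l3[, 2] == 3L))
  # loops are infeasible on chains below three beads
  lay1 <- manual_layout(list(
    data.frame(start = 0, end = 2e5, class = "EU")))
  expect_error(sample_loops(build_chains(lay1, 1e5), 5L, 2e6, 1),
               "infeasible")
})

test_that("energy terms follow the harmonic and gravity-like forms", {
  conf <- dimer(kappa = 3e-6)
  # two bonded beads 0.5 um apart: U = kappa/2 * d_nm^2
  u <- folding_energy(conf)
  expect_equal(u$chain, 0.5 * 3e-6 * 500^2)
  expect_equal(u$loop, 0)
  expect_equal(u$repulsion, 0)
  expect_equal(u$periphery, 0)
  expect_equal(u$total, u$chain)
  # coincident beads: chain term vanishes; a loop between them adds 0
  conf2 <- conf
  conf2$positions[2, ] <- conf2$positions[1, ]
  expect_equal(folding_energy(conf2)$chain, 0)
  conf2$loops <- cbind(1L, 2L)
  expect_equal(folding_energy(conf2)$total, 0)
})

test_that("chromosome repulsion is finite for coincident centres", {
  lay <- manual_layout(list(
    data.frame(start = 0, end = 3e6, class = "EU"),
    data.frame(start = 0, end = 3e6, class = "EU")
  ))
  ch <- build_chains(lay, bead_size = 1e6)
  fp <- folding_params(bead_size = 1e6, total_loops = 0L,
                       kappa_periphery = c(0, 0), seed = 1)
  conf <- init_conformation(ch, fp, loops = matrix(integer(0), 0, 2))
  conf$positions <- matrix(0, 6, 3)  # everything at the origin
  u <- folding_energy(conf)
  expect_true(is.finite(u$repulsion))
  expect_gt(u$repulsion, 0)
})

test_that("single-bead Metropolis steps respect the acceptance rule", {
  conf <- dimer(kappa = 3e-6, step_sigma = 0.2, seed = 2)
  set.seed(11)
  # with zero springs every in-bounds move is downhill-or-flat: accepted
  flat <- dimer(kappa = 0, step_sigma = 0.2, seed = 2)
  moved <- metropolis_step(flat, bead = 2)
  expect_true(attr(moved, "accepted"))
  expect_equal(attr(moved, "delta_energy"), 0)
  # repeated stepping keeps beads inside the allowed region
  cramped <- dimer(kappa = 0, step_sigma = 2, seed = 3)
  cramped$params$semi_axes <- c(2, 2, 2)
  for (i in 1:50) cramped <- metropolis_step(cramped)
  m2 <- rowSums(sweep(cramped$positions, 2,
                      cramped$params$semi_axes, "/")^2)
  expect_true(all(m2 <= 1 + 1e-12))
})

test_that("the dimer samples the Boltzmann bond-length distribution", {
  conf <- dimer(kappa = 3e-6, step_sigma = 0.6, seed = 5)
  rel <- relax(conf, n_sweeps = 120000L, tune = FALSE, track_bond = 10L)
  r <- rel$bond_trace
  r <- r[-(1:1000)]  # burn-in
  # |r| follows a Maxwell distribution with per-component variance
  # kT / kappa_eff, kappa_eff = kappa * 1e6 per um^2
  a2 <- 1 / (3e-6 * 1e6)
  expect_equal(mean(r^2), 3 * a2, tolerance = 0.05)
  ks <- stats::ks.test(r, function(q) stats::pchisq(q^2 / a2, df = 3))
  expect_gt(ks$p.value, 0.01)
  expect_gt(rel$acceptance_rate, 0.1)
  expect_lt(rel$acceptance_rate, 0.9)
})

test_that("relaxation dissipates energy and keeps exact bookkeeping", {
  lay <- toy_layout(seed = 5, n_chromosomes = 3,
                    target_total_length = 3e7)
  ch <- build_chains(lay, bead_size = 1e6)
  fp <- folding_params(bead_size = 1e6, total_loops = 30L, seed = 9)
  # the random blob start is far from equilibrium (taut CON bonds)
  conf <- init_conformation(ch, fp)
  rel <- relax(conf, n_sweeps = 300L, seed = 2)
  tr <- rel$energy_trace
  expect_gt(mean(head(tr, 30)), mean(tail(tr, 30)))
  # incremental energy equals a full recomputation
  expect_equal(rel$running_energy, rel$energy_terms$total,
               tolerance = 1e-8)
  # hard constraints hold for every bead
  m2 <- rowSums(sweep(rel$positions, 2, fp$semi_axes, "/")^2)
  expect_true(all(m2 <= 1 + 1e-9))
  for (k in 1:2) {
    dn <- sqrt(rowSums(sweep(rel$positions, 2,
                             fp$nucleolus_centers[k, ], "-")^2))
    expect_true(all(dn >= fp$nucleolus_radius - 1e-9))
  }
})

test_that("relaxed chromatin shows class-ordered compaction", {
  lay <- toy_layout(seed = 6, n_chromosomes = 4,
                    target_total_length = 8e7)
  ch <- build_chains(lay, bead_size = 5e5)
  fp <- folding_params(bead_size = 5e5, total_loops = 80L, seed = 3)
  rel <- relax(init_conformation(ch, fp), n_sweeps = 2500L,
               record_every = 250L)
  b <- rel$beads
  same <- which(b$chrom_index[-1] == b$chrom_index[-nrow(b)])
  # bond uses the softer class of its two beads; pool squared bond
  # extensions over the last recorded conformations
  cls <- pmin(as.integer(b$class[same]), as.integer(b$class[same + 1]))
  d2 <- unlist(lapply(rel$recorded[5:10], function(pos) {
    rowSums((pos[same + 1, ] - pos[same, ])^2)
  }))
  msd <- tapply(d2, rep(cls, 6), mean)
  expect_true(msd[["3"]] < msd[["2"]])   # CON tighter than FAC
  expect_true(msd[["2"]] < msd[["1"]])   # FAC tighter than EU
})

test_that("facultative heterochromatin accumulates at the periphery", {
  deltas <- vapply(1:3, function(s) {
    lay <- toy_layout(seed = s + 20, n_chromosomes = 4,
                      target_total_length = 4e7)
    ch <- build_chains(lay, bead_size = 1e6)
    fp <- folding_params(bead_size = 1e6, total_loops = 40L, seed = s)
    rel <- relax(init_conformation(ch, fp), n_sweeps = 600L)
    d <- boundary_distance(rel$positions, fp)
    mean(d[rel$beads$class == "EU"]) - mean(d[rel$beads$class == "FAC"])
  }, numeric(1))
  # FAC beads sit closer to envelope/nucleolar surfaces than EU beads
  expect_gt(mean(deltas), 0)
})

test_that("genomic positions map to interpolated bead coordinates", {
  lay <- manual_layout(list(
    data.frame(start = 0, end = 1e6, class = "EU")
  ))
  ch <- build_chains(lay, bead_size = 1e5)
  fp <- folding_params(bead_size = 1e5, total_loops = 0L,
                       kappa_periphery = c(0, 0), seed = 1)
  conf <- init_conformation(ch, fp, loops = matrix(integer(0), 0, 2))
  conf$positions <- cbind(seq_len(10), 0, 0)  # bead i at x = i
  # interval midpoint of bead 4 ([3e5, 4e5) -> midpoint 3.5e5)
  expect_equal(map_position_to_3d(conf, 3.5e5)[1, ],
               c(x = 4, y = 0, z = 0))
  # boundary between beads 4 and 5 interpolates halfway
  expect_equal(map_position_to_3d(conf, 4e5)[1, ],
               c(x = 4.5, y = 0, z = 0))
  # chromosome ends clamp to the terminal beads
  expect_equal(unname(map_position_to_3d(conf, 1e4)[1, 1]), 1)
  expect_equal(unname(map_position_to_3d(conf, 9.9e5)[1, 1]), 10)
  expect_error(map_position_to_3d(conf, 2e6), "range")
})
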
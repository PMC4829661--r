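# Shared fixtures: all inputs are generated in code at test time.

# Small synthetic genome used by most engine tests: 4 chromosomes,
# ~40 Mbp, zones around 1.5 Mbp.  Memoized per (seed) for speed.
.toy_cache <- new.env(parent = emptyenv())

toy_layout <- function(seed = 3, n_chromosomes = 4,
                       target_total_length = 4e7) {
  key <- paste(seed, n_chromosomes, target_total_length, sep = "_")
  if (is.null(.toy_cache[[key]])) {
    .toy_cache[[key]] <- generate_synthetic_genome(synthetic_genome_params(
      n_chromosomes = n_chromosomes,
      target_total_length = target_total_length,
      zone_meanlog = log(1.5e6), zone_sdlog = 0.5,
      fraction_tolerance = 0.10, seed = seed
    ))
  }
  .toy_cache[[key]]
}

toy_params <- function(seed = 1, ...) {
  replication_params(n_potential_origins = 2000L,
                     limiting_factor_max = 60L, seed = seed, ...)
}

# Hand-built layout: one chromosome per element of `zone_list`, each a
# data.frame(start, end, class) tiling the chromosome.
manual_layout <- function(zone_list) {
  templates <- lapply(seq_along(zone_list), function(i) {
    chromosome_template(sprintf("m%d", i), zone_list[[i]])
  })
  names(templates) <- vapply(templates, `[[`, character(1), "name")
  copies <- setNames(rep(1L, length(templates)), names(templates))
  apply_karyotype(templates, karyotype_spec(copies))
}

# Brute-force fixed-timestep replication oracle.  Fires the scheduled
# origins (skipping ones already replicated), advances all forks by the
# integrated speed per step, annihilates overlapping replicon fronts at
# their midpoint, and absorbs forks at chromosome barriers.  Independent
# of the event-driven engine; O(n^2) per step.
oracle_simulate <- function(layout, firings, nu = 28, ramp = 0,
                            dt = 0.05, t_max = 1e7) {
  firings <- firings[order(firings$time), , drop = FALSE]
  barriers <- layout$barriers
  reps <- data.frame(origin = numeric(0), left = numeric(0),
                     right = numeric(0), chrom = integer(0),
                     left_alive = logical(0), right_alive = logical(0),
                     fired = numeric(0))
  covered <- function(x, chrom) {
    any(reps$chrom == chrom & reps$left - 1e-9 <= x &
          x <= reps$right + 1e-9)
  }
  t <- 0
  fi <- 1
  collisions <- numeric(0)
  repeat {
    # firings due in [t, t+dt)
    while (fi <= nrow(firings) && firings$time[fi] < t + dt) {
      x <- firings$position[fi]
      chrom <- findInterval(x, barriers)
      if (!covered(x, chrom)) {
        reps <- rbind(reps, data.frame(
          origin = x, left = x, right = x, chrom = chrom,
          left_alive = TRUE, right_alive = TRUE, fired = firings$time[fi]
        ))
      }
      fi <- fi + 1
    }
    ds <- fork_distance(t + dt, nu, ramp) - fork_distance(t, nu, ramp)
    reps$left[reps$left_alive] <- reps$left[reps$left_alive] - ds
    reps$right[reps$right_alive] <- reps$right[reps$right_alive] + ds
    # barrier absorption
    for (i in seq_len(nrow(reps))) {
      blo <- barriers[reps$chrom[i]]
      bhi <- barriers[reps$chrom[i] + 1]
      if (reps$left_alive[i] && reps$left[i] <= blo) {
        reps$left[i] <- blo
        reps$left_alive[i] <- FALSE
      }
      if (reps$right_alive[i] && reps$right[i] >= bhi) {
        reps$right[i] <- bhi
        reps$right_alive[i] <- FALSE
      }
    }
    # collisions: any live right front overlapping a live left front
    repeat {
      hit <- FALSE
      o <- order(reps$origin)
      for (k in seq_len(length(o) - 1)) {
        i <- o[k]
        for (m in seq(k + 1, length(o))) {
          j <- o[m]
          if (reps$chrom[i] != reps$chrom[j]) next
          if (reps$right_alive[i] && reps$left_alive[j] &&
              reps$right[i] >= reps$left[j]) {
            meet <- (reps$right[i] + reps$left[j]) / 2
            reps$right[i] <- meet
            reps$left[j] <- meet
            reps$right_alive[i] <- FALSE
            reps$left_alive[j] <- FALSE
            collisions <- c(collisions, t + dt)
            hit <- TRUE
          }
        }
      }
      if (!hit) break
    }
    t <- t + dt
    done <- nrow(reps) > 0 && fi > nrow(firings) &&
      !any(reps$left_alive | reps$right_alive)
    if (done || t > t_max) break
  }
  total <- sum(reps$right - reps$left)
  list(replicons = reps, completion_time = t, collisions = collisions,
       replicated = total, complete = abs(total - layout$total_length) < 1)
}

# O(n^2) union-find clustering oracle: two forks are connected when they
# are closer than the threshold with no barrier between them; clusters
# are the connected components.
cluster_oracle <- function(positions, barriers, threshold) {
  n <- length(positions)
  if (n == 0) {
    return(data.frame(n_forks = integer(0), span = numeric(0)))
  }
  bi <- findInterval(positions, barriers)
  parent <- seq_len(n)
  findr <- function(i) {
    r <- i
    while (parent[r] != r) r <- parent[r]
    r
  }
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (abs(positions[i] - positions[j]) < threshold && bi[i] == bi[j]) {
        ri <- findr(i)
        rj <- findr(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), findr, integer(1))
  comps <- split(positions, roots)
  data.frame(
    n_forks = vapply(comps, length, integer(1)),
    span = vapply(comps, function(x) max(x) - min(x), numeric(1)),
    row.names = NULL
  )
}

# A tiny two-bead system with no confinement, loops, repulsion or
# periphery terms: a pure harmonic dimer whose equilibrium statistics are
# known in closed form.
dimer <- function(kappa = 3e-6, step_sigma = 0.5, seed = 1) {
  lay <- manual_layout(list(
    data.frame(start = 0, end = 2e6, class = "CON")
  ))
  ch <- build_chains(lay, bead_size = 1e6)
  fp <- folding_params(
    bead_size = 1e6, kappa_class = c(kappa, kappa, kappa),
    total_loops = 0L, kappa_repulsion = 0,
    kappa_periphery = c(0, 0), semi_axes = c(500, 500, 500),
    nucleolus_radius = 0, step_sigma = step_sigma, seed = seed
  )
  conf <- init_conformation(ch, fp,
                            loops = matrix(integer(0), 0, 2))
  conf$positions <- rbind(c(0, 0, 0), c(0.5, 0, 0))
  conf
}

# distance to the nearest of nuclear envelope / nucleolar surfaces,
# mirroring the folding model's geometry (for localization tests)
boundary_distance <- function(pos, params) {
  semi <- params$semi_axes
  vapply(seq_len(nrow(pos)), function(i) {
    x <- pos[i, ]
    m <- sqrt(sum((x / semi)^2))
    d <- if (m < 1e-12) min(semi) else sqrt(sum(x^2)) / m * (1 - m)
    for (k in seq_len(nrow(params$nucleolus_centers))) {
      dn <- sqrt(sum((x - params$nucleolus_centers[k, ])^2)) -
        params$nucleolus_radius
      d <- min(d, dn)
    }
    max(d, 0)
  }, numeric(1))
}
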
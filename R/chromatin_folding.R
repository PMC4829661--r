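# Random-loop chromatin folding ----------------------------------------------
#
# Chromosomes are bead-spring Gaussian chains (no volume exclusion), one
# bead per `bead_size` bp, with random intra-chromosome loop springs.
# Beads move inside an oblate ellipsoidal nucleus containing two
# impenetrable spherical nucleoli, and relax by Metropolis Monte Carlo at
# 290 K.  Heterochromatin compaction is encoded by class-specific spring
# constants (EU softest, CON stiffest); facultative heterochromatin is
# attracted to the nuclear/nucleolar periphery by a softened gravity-like
# potential, constitutive heterochromatin is pushed inwards by the same
# form with reversed sign and lower strength.

#' Chromatin folding parameters
#'
#' Spring constants are in units of kT per nm^2 (chain and loops), the
#' chromosome repulsion constant in kT per nm, and periphery strengths in
#' kT per micrometre; positions are in micrometres and energies in kT at
#' the reference temperature of 290 K.
#'
#' @param bead_size Genomic length per bead (bp).
#' @param kappa_class Length-3 (EU, FAC, CON) chain spring constants.
#' @param kappa_loop Loop spring constant.
#' @param total_loops Number of random loop connections genome-wide.
#' @param mean_loop_size Mean genomic loop span (bp).
#' @param kappa_repulsion Chromosome-centre repulsion strength.
#' @param kappa_periphery Length-2 (FAC attraction, CON repulsion)
#'   periphery strengths.
#' @param r_soft Softening radius of the periphery potential (um).
#' @param semi_axes Nuclear ellipsoid semi-axes (um), x/y horizontal and
#'   z vertical.
#' @param nucleolus_radius Radius of each nucleolus (um).
#' @param nucleolus_centers Two-row matrix of nucleolus centres (um);
#'   default symmetric on the long axis at +/- rx/2.
#' @param temperature Reservoir temperature (K); energies are expressed in
#'   kT at 290 K, so acceptance uses beta = 290/temperature.
#' @param step_sigma Initial Metropolis step size (um), auto-tuned.
#' @param seed Integer seed.
#' @return A `folding_params` object.
#' @export
folding_params <- function(bead_size = 1e5,
                           kappa_class = c(EU = 1e-8, FAC = 5e-7,
                                           CON = 3e-6),
                           kappa_loop = 5e-7,
                           total_loops = 5000L,
                           mean_loop_size = 2e6,
                           kappa_repulsion = 1e-4,
                           kappa_periphery = c(FAC = 30.0, CON = 15.0),
                           r_soft = 1.0,
                           semi_axes = c(7.5, 5, 3.5),
                           nucleolus_radius = 1.35,
                           nucleolus_centers = NULL,
                           temperature = 290,
                           step_sigma = 0.3,
                           seed = 1L) {
  stopifnot(bead_size > 0, length(kappa_class) == 3L,
            all(kappa_class >= 0), kappa_loop >= 0, total_loops >= 0,
            mean_loop_size > 0, kappa_repulsion >= 0,
            length(kappa_periphery) == 2L, all(kappa_periphery >= 0),
            r_soft > 0, length(semi_axes) == 3L, all(semi_axes > 0),
            nucleolus_radius >= 0, temperature > 0)
  if (is.null(nucleolus_centers)) {
    nucleolus_centers <- rbind(c(-semi_axes[1] / 2, 0, 0),
                               c(semi_axes[1] / 2, 0, 0))
  }
  nucleolus_centers <- as.matrix(nucleolus_centers)
  m2 <- rowSums(sweep(nucleolus_centers, 2, semi_axes, "/")^2)
  if (any(m2 > 1)) stop("nucleolus centers must lie inside the ellipsoid")
  structure(
    list(
      bead_size = bead_size,
      kappa_class = setNames(as.numeric(kappa_class), CHROMATIN_CLASSES),
      kappa_loop = kappa_loop,
      total_loops = as.integer(total_loops),
      mean_loop_size = mean_loop_size,
      kappa_repulsion = kappa_repulsion,
      kappa_periphery = setNames(as.numeric(kappa_periphery),
                                 c("FAC", "CON")),
      r_soft = r_soft,
      semi_axes = semi_axes,
      nucleolus_radius = nucleolus_radius,
      nucleolus_centers = nucleolus_centers,
      temperature = temperature,
      step_sigma = step_sigma,
      seed = as.integer(seed)
    ),
    class = "folding_params"
  )
}

#' Build bead chains from a genome layout
#'
#' One bead per `bead_size` bp (the last bead of a chromosome may be
#' shorter); each bead's chromatin class is the class with the largest
#' genomic overlap with the bead's interval (ties broken towards the more
#' open class, EU before FAC before CON).
#'
#' @param layout A `genome_layout`.
#' @param bead_size Genomic length per bead (bp).
#' @return A `bead_chains` object: data frame with one row per bead
#'   (`chrom_index`, `bead`, `class`, `gstart`, `gend`) plus attributes.
#' @export
build_chains <- function(layout, bead_size = 1e5) {
  stopifnot(inherits(layout, "genome_layout"), bead_size > 0)
  rows <- lapply(seq_len(nrow(layout$chromosomes)), function(ci) {
    len <- layout$chromosomes$length[ci]
    g0 <- layout$chromosomes$gstart[ci]
    nb <- ceiling(len / bead_size)
    start <- (seq_len(nb) - 1) * bead_size
    end <- pmin(start + bead_size, len)
    z <- layout$zones[layout$zones$chrom_index == ci, ]
    # per-bead class overlap via interval intersection against all zones
    cls <- vapply(seq_len(nb), function(b) {
      ov <- pmax(0, pmin(z$end, end[b]) - pmax(z$start, start[b]))
      byc <- vapply(CHROMATIN_CLASSES,
                    function(k) sum(ov[z$class == k]), numeric(1))
      CHROMATIN_CLASSES[which.max(byc)]
    }, character(1))
    data.frame(
      chrom_index = ci, bead = seq_len(nb), class = cls,
      gstart = g0 + start, gend = g0 + end
    )
  })
  beads <- do.call(rbind, rows)
  beads$class <- chromatin_class_factor(beads$class)
  structure(beads, class = c("bead_chains", "data.frame"),
            bead_size = bead_size,
            n_chromosomes = nrow(layout$chromosomes))
}

#' Sample random loop connections
#'
#' Loops are allocated to chromosomes proportionally to their bead counts;
#' each loop links two non-adjacent beads of one chromosome, with a span
#' (in beads) of 2 plus a geometric variate whose mean matches
#' `mean_loop_size`.  Chains shorter than three beads cannot hold a loop.
#'
#' @param chains A [build_chains()] result.
#' @param total_loops Number of loops to draw.
#' @param mean_loop_size Target mean genomic loop span (bp).
#' @param seed Integer seed.
#' @return Integer matrix with columns `from`, `to` (row indices into
#'   `chains`, 1-based).
#' @export
sample_loops <- function(chains, total_loops = 5000L, mean_loop_size = 2e6,
                         seed = 1L) {
  stopifnot(inherits(chains, "bead_chains"))
  bead_size <- attr(chains, "bead_size")
  nb <- table(factor(chains$chrom_index,
                     levels = seq_len(attr(chains, "n_chromosomes"))))
  nb <- as.integer(nb)
  eligible <- which(nb >= 3L)
  if (length(eligible) == 0L) {
    stop("no chromosome has >= 3 beads; loops are infeasible")
  }
  offsets <- cumsum(c(0L, nb))
  mean_span <- max(mean_loop_size / bead_size, 2)
  with_seed(seed, {
    chrom_draw <- sample(eligible, total_loops, replace = TRUE,
                         prob = nb[eligible])
    from <- integer(total_loops)
    to <- integer(total_loops)
    for (i in seq_len(total_loops)) {
      n <- nb[chrom_draw[i]]
      span <- 2L + stats::rgeom(1, 1 / (mean_span - 1))
      span <- min(span, n - 1L)
      a <- sample.int(n - span, 1L)
      from[i] <- offsets[chrom_draw[i]] + a
      to[i] <- offsets[chrom_draw[i]] + a + span
    }
    cbind(from = from, to = to)
  })
}

#' Initialize a chromatin conformation
#'
#' Each chromosome is seeded as a Gaussian blob around a random centre
#' inside the nucleus; beads falling outside the allowed region are
#' resampled towards the blob centre.  The result is a valid (if
#' unequilibrated) conformation for [relax()].
#'
#' @param chains A [build_chains()] result.
#' @param params A [folding_params()].
#' @param loops Optional loop matrix from [sample_loops()]; drawn with the
#'   parameter seed when omitted.
#' @param blob_sd Initial blob s.d. (um).
#' @return A `conformation` object: `positions` (n x 3 matrix, um),
#'   `beads`, `loops`, `params`.
#' @export
init_conformation <- function(chains, params = folding_params(),
                              loops = NULL, blob_sd = 0.8) {
  stopifnot(inherits(chains, "bead_chains"),
            inherits(params, "folding_params"))
  if (is.null(loops)) {
    loops <- sample_loops(chains, params$total_loops,
                          params$mean_loop_size, params$seed)
  }
  semi <- params$semi_axes
  nuc <- params$nucleolus_centers
  inside <- function(p) {
    m2 <- sum((p / semi)^2)
    if (m2 > 1) return(FALSE)
    for (k in seq_len(nrow(nuc))) {
      if (sum((p - nuc[k, ])^2) < params$nucleolus_radius^2) return(FALSE)
    }
    TRUE
  }
  positions <- with_seed(params$seed + 7L, {
    out <- matrix(0, nrow(chains), 3)
    for (ci in unique(chains$chrom_index)) {
      idx <- which(chains$chrom_index == ci)
      repeat {
        ctr <- runif(3, -0.6, 0.6) * semi
        if (inside(ctr)) break
      }
      for (i in idx) {
        p <- ctr + rnorm(3, 0, blob_sd)
        tries <- 0
        while (!inside(p)) {
          p <- ctr + rnorm(3, 0, blob_sd / 2)
          tries <- tries + 1
          if (tries > 200) { p <- ctr; break }
        }
        out[i, ] <- p
      }
    }
    out
  })
  structure(
    list(positions = positions, beads = chains, loops = loops,
         params = params),
    class = "conformation"
  )
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf(
    "<conformation> %d beads, %d chromosomes, %d loops\n",
    nrow(x$positions), attr(x$beads, "n_chromosomes"), nrow(x$loops)
  ))
  invisible(x)
}

folding_args <- function(conf) {
  p <- conf$params
  list(
    pos = conf$positions,
    chrom0 = as.integer(conf$beads$chrom_index) - 1L,
    class0 = as.integer(conf$beads$class) - 1L,
    kappa_class = p$kappa_class,
    loops0 = cbind(conf$loops[, 1] - 1L, conf$loops[, 2] - 1L),
    kappa_loop = p$kappa_loop,
    kappa_rep = p$kappa_repulsion,
    kappa_fac = p$kappa_periphery[["FAC"]],
    kappa_con = p$kappa_periphery[["CON"]],
    r_soft = p$r_soft,
    semi = p$semi_axes,
    nucleoli = p$nucleolus_centers,
    nucleolus_radius = p$nucleolus_radius
  )
}

#' Total potential energy of a conformation
#'
#' Sum of the four terms (chain springs, loop springs, chromosome-centre
#' repulsion, periphery attraction/repulsion), in units of kT at 290 K.
#'
#' @param conformation A `conformation`.
#' @return Named list: `chain`, `loop`, `repulsion`, `periphery`, `total`.
#' @export
folding_energy <- function(conformation) {
  stopifnot(inherits(conformation, "conformation"))
  a <- folding_args(conformation)
  .folding_energy_cpp(a$pos, a$chrom0, a$class0, a$kappa_class,
                      a$loops0, a$kappa_loop, a$kappa_rep, a$kappa_fac,
                      a$kappa_con, a$r_soft, a$semi, a$nucleoli,
                      a$nucleolus_radius)
}

#' One Metropolis step on a single bead
#'
#' Proposes an isotropic Gaussian displacement of one bead; moves leaving
#' the nucleus or entering a nucleolus are rejected outright, others are
#' accepted with probability \eqn{\min(1, e^{-\Delta U / kT})}.  Intended
#' for inspection and testing; use [relax()] for production sweeps.
#'
#' @param conformation A `conformation`.
#' @param bead Bead row index; random when `NULL`.
#' @param step_sigma Proposal s.d. (um); defaults to the parameter value.
#' @return The updated conformation with attributes `accepted` and
#'   `delta_energy`.
#' @export
metropolis_step <- function(conformation, bead = NULL, step_sigma = NULL) {
  stopifnot(inherits(conformation, "conformation"))
  p <- conformation$params
  n <- nrow(conformation$positions)
  if (is.null(bead)) bead <- sample.int(n, 1L)
  if (is.null(step_sigma)) step_sigma <- p$step_sigma
  beta <- 290 / p$temperature
  old <- conformation$positions[bead, ]
  prop <- old + rnorm(3, 0, step_sigma)
  semi <- p$semi_axes
  ok <- sum((prop / semi)^2) <= 1 &&
    all(sqrt(rowSums(sweep(p$nucleolus_centers, 2, prop, function(a, b)
      (b - a))^2)) >= p$nucleolus_radius)
  accepted <- FALSE
  du <- NA_real_
  if (ok) {
    u0 <- folding_energy(conformation)$total
    trial <- conformation
    trial$positions[bead, ] <- prop
    du <- folding_energy(trial)$total - u0
    if (du <= 0 || runif(1) < exp(-beta * du)) {
      conformation <- trial
      accepted <- TRUE
    }
  }
  attr(conformation, "accepted") <- accepted
  attr(conformation, "delta_energy") <- du
  conformation
}

#' Relax a conformation by Metropolis Monte Carlo
#'
#' Runs `n_sweeps` sweeps (one proposed single-bead move per bead per
#' sweep) at the reservoir temperature, auto-tuning the step size towards
#' a 30-50% acceptance rate during the first fifth of the sweeps.
#' Convergence is flagged when the linear energy slope over the last 20%
#' of sweeps is statistically indistinguishable from zero.
#'
#' @param conformation A `conformation`.
#' @param n_sweeps Number of sweeps.
#' @param tune Auto-tune the step size during burn-in.
#' @param record_every Record the full conformation every this many sweeps
#'   (0 = never).
#' @param track_bond Record the bead-0/bead-1 distance every this many
#'   sweeps (0 = never); used for sampling diagnostics.
#' @param seed Integer seed; defaults to the parameter seed.
#' @return The relaxed `conformation`, with elements `energy_trace`,
#'   `acceptance_rate`, `energy_terms`, `converged`, `step_sigma`, and
#'   optionally `recorded` / `bond_trace`.
#' @export
relax <- function(conformation, n_sweeps = 200L, tune = TRUE,
                  record_every = 0L, track_bond = 0L, seed = NULL) {
  stopifnot(inherits(conformation, "conformation"), n_sweeps >= 1)
  p <- conformation$params
  a <- folding_args(conformation)
  res <- .relax_cpp(a$pos, a$chrom0, a$class0, a$kappa_class,
                    a$loops0, a$kappa_loop, a$kappa_rep, a$kappa_fac,
                    a$kappa_con, a$r_soft, a$semi, a$nucleoli,
                    a$nucleolus_radius,
                    as.integer(n_sweeps), p$step_sigma, tune,
                    290 / p$temperature,
                    as.integer(seed %||% p$seed),
                    as.integer(record_every), as.integer(track_bond))
  out <- conformation
  out$positions <- res$positions
  out$energy_trace <- res$energy_trace
  out$acceptance_rate <- res$acceptance_rate
  out$energy_terms <- res$energy_terms
  out$running_energy <- res$running_energy
  out$step_sigma <- res$step_sigma
  out$bond_trace <- res$bond_trace
  out$recorded <- res$recorded
  # convergence: zero slope of the energy over the final 20% of sweeps
  tailn <- max(10L, floor(n_sweeps / 5))
  if (length(res$energy_trace) >= tailn) {
    y <- tail(res$energy_trace, tailn)
    fit <- stats::lm(y ~ seq_along(y))
    pv <- summary(fit)$coefficients[2, 4]
    out$converged <- is.na(pv) || pv > 0.05
  } else {
    out$converged <- NA
  }
  out
}

#' Map a genomic position to 3D nuclear coordinates
#'
#' Linear interpolation between the centres of the flanking beads of the
#' containing chromosome; positions beyond the terminal bead centres are
#' clamped to the terminal bead.
#'
#' @param conformation A `conformation`.
#' @param position Global genomic position(s) in bp.
#' @return Matrix with one row per position (x, y, z in um).
#' @export
map_position_to_3d <- function(conformation, position) {
  stopifnot(inherits(conformation, "conformation"))
  beads <- conformation$beads
  pos3 <- conformation$positions
  lo <- min(beads$gstart)
  hi <- max(beads$gend)
  if (any(position < lo | position >= hi)) {
    stop("position out of range of the bead chains")
  }
  i <- findInterval(position, beads$gstart)
  out <- matrix(NA_real_, length(position), 3)
  for (k in seq_along(position)) {
    b <- i[k]
    mid <- (beads$gstart[b] + beads$gend[b]) / 2
    ci <- beads$chrom_index[b]
    if (position[k] >= mid) {
      nxt <- b + 1L
      if (nxt > nrow(beads) || beads$chrom_index[nxt] != ci) {
        out[k, ] <- pos3[b, ]
      } else {
        mid2 <- (beads$gstart[nxt] + beads$gend[nxt]) / 2
        w <- (position[k] - mid) / (mid2 - mid)
        out[k, ] <- (1 - w) * pos3[b, ] + w * pos3[nxt, ]
      }
    } else {
      prv <- b - 1L
      if (prv < 1L || beads$chrom_index[prv] != ci) {
        out[k, ] <- pos3[b, ]
      } else {
        mid2 <- (beads$gstart[prv] + beads$gend[prv]) / 2
        w <- (position[k] - mid2) / (mid - mid2)
        out[k, ] <- (1 - w) * pos3[prv, ] + w * pos3[b, ]
      }
    }
  }
  colnames(out) <- c("x", "y", "z")
  out
}

#' Write a conformation as CSV
#'
#' Columns: chromosome index, bead index, chromatin class, x, y, z (um).
#'
#' @param conformation A `conformation`.
#' @param file Output path.
#' @export
write_conformation_csv <- function(conformation, file) {
  df <- data.frame(
    chrom_index = conformation$beads$chrom_index,
    bead = conformation$beads$bead,
    class = as.character(conformation$beads$class),
    x = conformation$positions[, 1],
    y = conformation$positions[, 2],
    z = conformation$positions[, 3]
  )
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
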
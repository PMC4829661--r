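# Genome model: chromatin-zone layouts ---------------------------------------
#
# A genome layout is the 1D substrate of the replication engine: an ordered
# set of chromosomes laid out on a single concatenated coordinate axis, each
# chromosome tiled exactly (no gaps, no overlaps) by chromatin zones of three
# classes -- euchromatin (EU), facultative (FAC) and constitutive (CON)
# heterochromatin.  Chromosome boundaries are "barriers": replication forks
# stop there and induced firing cannot reach across them.
#
# Coordinates are 0-based, half-open, and continuous (fractional base pairs
# are legal internally because fork speed is non-integer).

GIEMSA_CLASS_MAP <- c(
  gneg    = "EU",
  gpos25  = "FAC",
  gpos50  = "FAC",
  gpos75  = "CON",
  gpos100 = "CON",
  acen    = "CON",
  gvar    = "CON",
  stalk   = "CON"
)

#' Construct a chromosome template
#'
#' A chromosome template is a named chromosome tiled by chromatin zones.
#' Zones must tile the chromosome exactly: the first zone starts at 0, every
#' zone starts where its predecessor ends, and the last zone ends at the
#' chromosome length.
#'
#' @param name Chromosome name (e.g. `"chr1"`).
#' @param zones A data frame with columns `start`, `end` (base pairs,
#'   0-based half-open) and `class` (one of `"EU"`, `"FAC"`, `"CON"`).
#' @return An object of class `chromosome_template` with fields `name`,
#'   `length` and `zones`.
#' @export
chromosome_template <- function(name, zones) {
  stopifnot(is.character(name), length(name) == 1L)
  zones <- as.data.frame(zones)
  stopifnot(all(c("start", "end", "class") %in% names(zones)))
  zones <- zones[order(zones$start), c("start", "end", "class")]
  zones$class <- chromatin_class_factor(zones$class)
  if (nrow(zones) == 0L) stop("chromosome '", name, "' has no zones")
  if (any(zones$end <= zones$start)) {
    stop("chromosome '", name, "' has empty or inverted zone(s)")
  }
  if (zones$start[1] != 0) {
    stop("chromosome '", name, "' zones do not start at 0")
  }
  if (nrow(zones) > 1L &&
      any(abs(zones$start[-1] - zones$end[-nrow(zones)]) > 1e-9)) {
    stop("chromosome '", name, "' has gapped or overlapping zones")
  }
  structure(
    list(name = name, length = zones$end[nrow(zones)], zones = zones),
    class = "chromosome_template"
  )
}

#' @export
print.chromosome_template <- function(x, ...) {
  cat(sprintf(
    "<chromosome_template> %s: %.0f bp, %d zones (%s)\n",
    x$name, x$length, nrow(x$zones),
    paste(sprintf("%s=%d", CHROMATIN_CLASSES,
                  tabulate(x$zones$class, 3L)), collapse = " ")
  ))
  invisible(x)
}

#' Parse a UCSC cytoBand file into chromosome templates
#'
#' Reads Giemsa banding data in the UCSC cytoBand format (five tab-separated
#' columns: chrom, start, end, band name, stain) and classifies every band
#' into a chromatin class: unstained bands (`gneg`) become euchromatin,
#' lightly stained bands (`gpos25`, `gpos50`) become facultative
#' heterochromatin, and all other stains (`gpos75`, `gpos100`, `acen`,
#' `gvar`, `stalk`) become constitutive heterochromatin.
#'
#' Adjacent same-class bands are kept as separate zones (band-level zone
#' counts are preserved).
#'
#' @param file Path to a cytoBand file, a connection, or a character vector
#'   of lines (when `text = TRUE`).
#' @param text If `TRUE`, `file` is interpreted as the file content itself.
#' @return A named list of [chromosome_template()] objects, in order of
#'   first appearance in the file.
#' @export
parse_cytoband <- function(file, text = FALSE) {
  df <- if (text) {
    read.table(text = file, sep = "\t", header = FALSE,
               col.names = c("chrom", "start", "end", "band", "stain"),
               colClasses = c("character", "numeric", "numeric",
                              "character", "character"))
  } else {
    read.table(file, sep = "\t", header = FALSE,
               col.names = c("chrom", "start", "end", "band", "stain"),
               colClasses = c("character", "numeric", "numeric",
                              "character", "character"))
  }
  if (nrow(df) == 0L) stop("empty cytoBand input")
  unknown <- !(df$stain %in% names(GIEMSA_CLASS_MAP))
  if (any(unknown)) {
    i <- which(unknown)[1]
    stop(sprintf(
      "unknown Giemsa stain '%s' at row %d (%s:%.0f-%.0f)",
      df$stain[i], i, df$chrom[i], df$start[i], df$end[i]
    ))
  }
  df$class <- unname(GIEMSA_CLASS_MAP[df$stain])
  chroms <- unique(df$chrom)
  templates <- lapply(chroms, function(ch) {
    sub <- df[df$chrom == ch, ]
    sub <- sub[order(sub$start), ]
    if (sub$start[1] != 0) {
      stop("chromosome '", ch, "': first band does not start at 0")
    }
    if (nrow(sub) > 1L && any(sub$start[-1] != sub$end[-nrow(sub)])) {
      stop("chromosome '", ch, "': gapped or overlapping bands")
    }
    chromosome_template(ch, sub[, c("start", "end", "class")])
  })
  names(templates) <- chroms
  templates
}

#' Serialize chromosome templates to cytoBand-format text
#'
#' Inverse of [parse_cytoband()] up to stain identity: each class is written
#' with a representative stain (`EU` as `gneg`, `FAC` as `gpos25`, `CON` as
#' `gpos100`), so `parse_cytoband(format_cytoband(x), text = TRUE)` yields
#' templates with identical zones and classes.
#'
#' @param templates A list of [chromosome_template()] objects.
#' @return A character vector of tab-separated lines.
#' @export
format_cytoband <- function(templates) {
  stain_rep <- c(EU = "gneg", FAC = "gpos25", CON = "gpos100")
  unlist(lapply(templates, function(tmpl) {
    z <- tmpl$zones
    sprintf("%s\t%.0f\t%.0f\tz%d\t%s",
            tmpl$name, z$start, z$end, seq_len(nrow(z)),
            stain_rep[as.character(z$class)])
  }), use.names = FALSE)
}

#' Specify a karyotype (per-chromosome copy numbers)
#'
#' @param copies Named integer vector: copy number per chromosome name.
#' @param inactive_x_copies Number of X-chromosome copies to treat as the
#'   inactive X, which is modelled as 100% facultative heterochromatin.
#' @param x_name Name of the X chromosome in `copies`.
#' @return An object of class `karyotype_spec`.
#' @export
karyotype_spec <- function(copies, inactive_x_copies = 0L, x_name = "chrX") {
  copies <- setNames(as.integer(copies), names(copies))
  if (is.null(names(copies)) || any(!nzchar(names(copies)))) {
    stop("'copies' must be a named vector")
  }
  if (any(copies < 1L)) stop("copy numbers must be >= 1")
  inactive_x_copies <- as.integer(inactive_x_copies)
  if (inactive_x_copies > 0L) {
    if (!x_name %in% names(copies)) {
      stop("inactive_x_copies > 0 but '", x_name, "' not in karyotype")
    }
    if (inactive_x_copies > copies[[x_name]]) {
      stop("inactive_x_copies exceeds the number of X copies")
    }
  }
  structure(
    list(copies = copies, inactive_x_copies = inactive_x_copies,
         x_name = x_name),
    class = "karyotype_spec"
  )
}

#' Read a karyotype from a two-column CSV
#'
#' @param file CSV with columns `name` and `copies` (header required).
#' @inheritParams karyotype_spec
#' @return A [karyotype_spec()].
#' @export
read_karyotype <- function(file, inactive_x_copies = 0L, x_name = "chrX") {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "copies") %in% names(df)))
  karyotype_spec(setNames(df$copies, df$name),
                 inactive_x_copies = inactive_x_copies, x_name = x_name)
}

new_genome_layout <- function(chromosomes, zones) {
  # chromosomes: data.frame(index, name, copy, length, gstart, gend)
  # zones: data.frame(chrom_index, start, end, class, gstart, gend)
  total <- sum(chromosomes$length)
  barriers <- c(0, cumsum(chromosomes$length))
  structure(
    list(
      chromosomes = chromosomes,
      zones = zones,
      barriers = barriers,
      total_length = total
    ),
    class = "genome_layout"
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  fr <- layout_class_fractions(x)
  cat(sprintf(
    paste0("<genome_layout> %d chromosomes, %.3f Gbp, %d zones\n",
           "  class fractions: EU %.1f%%  FAC %.1f%%  CON %.1f%%\n"),
    nrow(x$chromosomes), x$total_length / 1e9, nrow(x$zones),
    100 * fr[["EU"]], 100 * fr[["FAC"]], 100 * fr[["CON"]]
  ))
  invisible(x)
}

#' Instantiate a genome layout from templates and a karyotype
#'
#' Replicates each chromosome template according to its copy number,
#' concatenates all copies on a single global coordinate axis, and places
#' barriers at every chromosome boundary (including both genome ends).  The
#' designated inactive-X copies are reclassified as a single facultative
#' heterochromatin zone spanning the whole chromosome.
#'
#' @param templates Named list of [chromosome_template()] objects.
#' @param karyotype A [karyotype_spec()].
#' @return A `genome_layout` object with fields `chromosomes`, `zones`
#'   (with both chromosome-local and global coordinates), `barriers` and
#'   `total_length`.
#' @export
apply_karyotype <- function(templates, karyotype) {
  stopifnot(inherits(karyotype, "karyotype_spec"))
  missing <- setdiff(names(karyotype$copies), names(templates))
  if (length(missing) > 0) {
    stop("karyotype names missing from templates: ",
         paste(missing, collapse = ", "))
  }
  chrom_rows <- list()
  zone_rows <- list()
  idx <- 0L
  for (nm in names(karyotype$copies)) {
    tmpl <- templates[[nm]]
    n_cop <- karyotype$copies[[nm]]
    for (cop in seq_len(n_cop)) {
      idx <- idx + 1L
      z <- tmpl$zones
      inactive <- nm == karyotype$x_name &&
        cop > n_cop - karyotype$inactive_x_copies
      if (inactive) {
        z <- data.frame(start = 0, end = tmpl$length,
                        class = chromatin_class_factor("FAC"))
      }
      chrom_rows[[idx]] <- data.frame(
        index = idx, name = nm, copy = cop, length = tmpl$length,
        stringsAsFactors = FALSE
      )
      zone_rows[[idx]] <- data.frame(
        chrom_index = idx, start = z$start, end = z$end, class = z$class
      )
    }
  }
  chromosomes <- do.call(rbind, chrom_rows)
  offsets <- c(0, cumsum(chromosomes$length))
  chromosomes$gstart <- offsets[seq_len(nrow(chromosomes))]
  chromosomes$gend <- offsets[-1]
  zones <- do.call(rbind, zone_rows)
  zones$gstart <- zones$start + chromosomes$gstart[zones$chrom_index]
  zones$gend <- zones$end + chromosomes$gstart[zones$chrom_index]
  new_genome_layout(chromosomes, zones)
}

#' Parameters for the synthetic genome generator
#'
#' Defaults emulate the aneuploid HeLa genome used throughout the package:
#' 76 chromosomes totalling about 10.36 Gbp, with 42/22/36% of the DNA in
#' euchromatin / facultative / constitutive heterochromatin and zone sizes
#' drawn from a lognormal placing most mass between 1 and 6 Mbp.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param target_total_length Target genome size in base pairs.
#' @param class_fractions Length-3 numeric (EU, FAC, CON) summing to 1.
#' @param zone_meanlog,zone_sdlog Lognormal parameters for zone sizes (bp).
#' @param min_zone_size Zones shorter than this are absorbed into their
#'   predecessor when closing a chromosome.
#' @param chrom_sdlog Lognormal shape for relative chromosome lengths.
#' @param fraction_tolerance Maximum allowed deviation of realized class
#'   fractions from the targets; tracking accuracy is limited by the
#'   zone-to-genome size ratio, so small toy genomes need a looser value.
#' @param seed Integer seed; the generator is deterministic per seed.
#' @return A `synthetic_genome_params` object.
#' @export
synthetic_genome_params <- function(n_chromosomes = 76L,
                                    target_total_length = 10.36e9,
                                    class_fractions = c(EU = 0.42,
                                                        FAC = 0.22,
                                                        CON = 0.36),
                                    zone_meanlog = log(2.7e6),
                                    zone_sdlog = 0.55,
                                    min_zone_size = 2e5,
                                    chrom_sdlog = 0.45,
                                    fraction_tolerance = 0.02,
                                    seed = 1L) {
  class_fractions <- as.numeric(class_fractions)
  if (length(class_fractions) != 3L || any(class_fractions < 0) ||
      abs(sum(class_fractions) - 1) > 1e-8) {
    stop("class_fractions must be 3 nonnegative values summing to 1")
  }
  target_total_length <- as.numeric(target_total_length)
  if (target_total_length <= 0) stop("target_total_length must be > 0")
  if (n_chromosomes < 1L) stop("n_chromosomes must be >= 1")
  if (target_total_length / n_chromosomes < min_zone_size) {
    stop("target length too small for the requested chromosome count")
  }
  structure(
    list(
      n_chromosomes = as.integer(n_chromosomes),
      target_total_length = target_total_length,
      class_fractions = setNames(class_fractions, CHROMATIN_CLASSES),
      zone_meanlog = zone_meanlog,
      zone_sdlog = zone_sdlog,
      min_zone_size = min_zone_size,
      chrom_sdlog = chrom_sdlog,
      fraction_tolerance = fraction_tolerance,
      seed = as.integer(seed)
    ),
    class = "synthetic_genome_params"
  )
}

#' Generate a synthetic chromatin-zone genome
#'
#' Builds a genome layout without external data.  Chromosome lengths are
#' lognormal, rescaled to the target total.  Each chromosome is tiled left
#' to right with zones whose sizes are lognormal and whose classes are
#' chosen greedily by class deficit (the class furthest below its target
#' genomic fraction, with a random tie-break among near-equal deficits),
#' under a banding-order
#' constraint: no two adjacent zones share a class, and a euchromatin zone
#' is always flanked by heterochromatin.  Every chromosome is guaranteed at
#' least one euchromatin zone, so that the induced-only model variant (one
#' initial origin per EU zone) can replicate every chromosome.
#'
#' @param params A [synthetic_genome_params()] object.
#' @return A `genome_layout`.
#' @export
generate_synthetic_genome <- function(params = synthetic_genome_params()) {
  stopifnot(inherits(params, "synthetic_genome_params"))
  fr <- params$class_fractions
  with_seed(params$seed, {
    n <- params$n_chromosomes
    lens <- rlnorm(n, meanlog = 0, sdlog = params$chrom_sdlog)
    lens <- lens / sum(lens) * params$target_total_length
    lens <- pmax(lens, 2 * params$min_zone_size)
    # integer-bp chromosome lengths and zone boundaries (fork positions
    # stay continuous; the static layout does not need fractions)
    lens <- round(lens / sum(lens) * params$target_total_length)

    # running genomic totals per class, used for deficit weighting
    placed <- c(EU = 0, FAC = 0, CON = 0)
    positive <- fr > 0
    chrom_rows <- vector("list", n)
    zone_rows <- vector("list", n)
    for (ci in seq_len(n)) {
      L <- lens[ci]
      pos <- 0
      zs <- list()
      prev_class <- NA_character_
      has_eu <- FALSE
      repeat {
        size <- round(rlnorm(1, params$zone_meanlog, params$zone_sdlog))
        closing <- pos + size >= L - params$min_zone_size
        if (closing) size <- L - pos
        # deficit per class: how far below target it would remain after
        # this zone; the greedy argmax keeps realized fractions tracking
        # the targets to within about one zone size
        total_placed <- sum(placed)
        deficit <- fr * (total_placed + size) - placed
        deficit[!positive] <- -Inf
        if (!is.na(prev_class)) deficit[prev_class] <- -Inf
        # EU must be flanked by heterochromatin: after EU only FAC/CON
        if (closing && !has_eu && positive[["EU"]] &&
            !identical(prev_class, "EU")) {
          cls <- "EU"
        } else if (all(!is.finite(deficit))) {
          cls <- names(which.max(fr))
        } else {
          # random tie-break among classes within half a zone of the top
          near <- which(deficit >= max(deficit) - size / 2)
          cls <- CHROMATIN_CLASSES[near[sample.int(length(near), 1)]]
        }
        zs[[length(zs) + 1L]] <- c(pos, pos + size)
        names(zs)[length(zs)] <- cls
        placed[cls] <- placed[cls] + size
        if (cls == "EU") has_eu <- TRUE
        prev_class <- cls
        pos <- pos + size
        if (closing) break
      }
      zmat <- do.call(rbind, zs)
      zone_rows[[ci]] <- data.frame(
        chrom_index = ci, start = zmat[, 1], end = zmat[, 2],
        class = chromatin_class_factor(names(zs))
      )
      chrom_rows[[ci]] <- data.frame(
        index = ci, name = sprintf("syn%02d", ci), copy = 1L, length = L,
        stringsAsFactors = FALSE
      )
    }
    chromosomes <- do.call(rbind, chrom_rows)
    offsets <- c(0, cumsum(chromosomes$length))
    chromosomes$gstart <- offsets[seq_len(n)]
    chromosomes$gend <- offsets[-1]
    zones <- do.call(rbind, zone_rows)
    zones$gstart <- zones$start + chromosomes$gstart[zones$chrom_index]
    zones$gend <- zones$end + chromosomes$gstart[zones$chrom_index]
    layout <- new_genome_layout(chromosomes, zones)
    realized <- layout_class_fractions(layout)
    dev <- max(abs(realized - fr))
    if (dev > params$fraction_tolerance) {
      stop(sprintf(
        "realized class fractions deviate by %.1f points from targets; %s",
        100 * dev, "adjust zone-size or fraction parameters"
      ))
    }
    layout
  })
}

#' Genomic fraction of each chromatin class in a layout
#'
#' @param layout A `genome_layout`.
#' @return Named numeric vector (EU, FAC, CON) summing to 1.
#' @export
layout_class_fractions <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  len <- tapply(layout$zones$end - layout$zones$start, layout$zones$class,
                sum, default = 0)
  out <- setNames(as.numeric(len[CHROMATIN_CLASSES]), CHROMATIN_CLASSES)
  out[is.na(out)] <- 0
  out / layout$total_length
}

#' Zone counts per chromatin class
#'
#' @param layout A `genome_layout`.
#' @return Named integer vector (EU, FAC, CON).
#' @export
zone_counts <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  setNames(tabulate(layout$zones$class, 3L), CHROMATIN_CLASSES)
}

#' Look up the chromatin zone containing a genomic position
#'
#' @param layout A `genome_layout`.
#' @param position Global position(s) in base pairs, `0 <= position <
#'   total_length`.  Half-open convention: a position equal to a zone end
#'   belongs to the next zone.
#' @return A data frame with one row per position: `chrom_index`, `gstart`,
#'   `gend`, `class`.
#' @export
zone_at <- function(layout, position) {
  stopifnot(inherits(layout, "genome_layout"))
  if (any(position < 0 | position >= layout$total_length)) {
    stop("position out of range [0, total_length)")
  }
  i <- findInterval(position, layout$zones$gstart)
  layout$zones[i, c("chrom_index", "gstart", "gend", "class")]
}

#' Index of the chromosome containing a genomic position
#' @inheritParams zone_at
#' @return Integer vector of chromosome indices.
#' @export
chromosome_at <- function(layout, position) {
  zone_at(layout, position)$chrom_index
}

#' Write a genome layout as BED
#'
#' One row per zone: chromosome instance name (`name.copy`), local start,
#' local end, chromatin class.
#'
#' @param layout A `genome_layout`.
#' @param file Output path.
#' @export
write_layout_bed <- function(layout, file) {
  ch <- layout$chromosomes
  z <- layout$zones
  bed <- data.frame(
    chrom = sprintf("%s.%d", ch$name[z$chrom_index], ch$copy[z$chrom_index]),
    start = format(z$start, scientific = FALSE, trim = TRUE, digits = 15),
    end = format(z$end, scientific = FALSE, trim = TRUE, digits = 15),
    class = as.character(z$class)
  )
  write.table(bed, file, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read a genome layout from BED written by [write_layout_bed()]
#'
#' @param file BED path (chrom, start, end, class).
#' @return A `genome_layout`; chromosome order follows first appearance.
#' @export
read_layout_bed <- function(file) {
  df <- read.table(file, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "class"),
                   colClasses = c("character", "numeric", "numeric",
                                  "character"))
  chroms <- unique(df$chrom)
  chrom_rows <- list()
  zone_rows <- list()
  for (ci in seq_along(chroms)) {
    sub <- df[df$chrom == chroms[ci], ]
    sub <- sub[order(sub$start), ]
    if (sub$start[1] != 0 ||
        (nrow(sub) > 1 && any(abs(sub$start[-1] - sub$end[-nrow(sub)]) > 1e-9))) {
      stop("chromosome '", chroms[ci], "': zones do not tile")
    }
    parts <- strsplit(chroms[ci], ".", fixed = TRUE)[[1]]
    copy <- suppressWarnings(as.integer(parts[length(parts)]))
    name <- if (!is.na(copy) && length(parts) > 1) {
      paste(parts[-length(parts)], collapse = ".")
    } else {
      copy <- 1L
      chroms[ci]
    }
    chrom_rows[[ci]] <- data.frame(
      index = ci, name = name, copy = copy, length = sub$end[nrow(sub)],
      stringsAsFactors = FALSE
    )
    zone_rows[[ci]] <- data.frame(
      chrom_index = ci, start = sub$start, end = sub$end,
      class = chromatin_class_factor(sub$class)
    )
  }
  chromosomes <- do.call(rbind, chrom_rows)
  offsets <- c(0, cumsum(chromosomes$length))
  chromosomes$gstart <- offsets[seq_along(chroms)]
  chromosomes$gend <- offsets[-1]
  zones <- do.call(rbind, zone_rows)
  zones$gstart <- zones$start + chromosomes$gstart[zones$chrom_index]
  zones$gend <- zones$end + chromosomes$gstart[zones$chrom_index]
  new_genome_layout(chromosomes, zones)
}
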
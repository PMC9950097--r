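#' Construct a marker map
#'
#' A marker map records, for every array probe, its genomic location
#' (1-based, hg19-style coordinates), the population frequency of the B
#' allele (PFB), the local GC fraction, and whether the probe maps uniquely
#' to a copy-stable region of the genome.
#'
#' @param marker_id character vector of unique probe names.
#' @param chromosome character vector ("1".."22", "X", "Y").
#' @param position_bp integer vector, 1-based positions, strictly
#'   increasing within each chromosome.
#' @param pfb population B-allele frequency in \[0, 1\].
#' @param gc_frac local GC fraction in \[0, 1\].
#' @param is_stable logical; TRUE for uniquely-mapping probes outside
#'   commonly copy-variable regions.
#' @return A `data.frame` of class `marker_map`, ordered by chromosome and
#'   position.
#' @export
marker_map <- function(marker_id, chromosome, position_bp, pfb, gc_frac,
                       is_stable = TRUE) {
  chromosome <- sub("^chr", "", as.character(chromosome))
  map <- data.frame(
    marker_id = as.character(marker_id),
    chromosome = chromosome,
    position_bp = as.integer(position_bp),
    pfb = as.numeric(pfb),
    gc_frac = as.numeric(gc_frac),
    is_stable = rep_len(as.logical(is_stable), length(marker_id)),
    stringsAsFactors = FALSE
  )
  map <- map[order(chrom_order(map$chromosome), map$position_bp), , drop = FALSE]
  rownames(map) <- NULL
  class(map) <- c("marker_map", "data.frame")
  validate_marker_map(map)
  map
}

validate_marker_map <- function(map) {
  if (anyDuplicated(map$marker_id))
    stopf("duplicate marker_id: %s",
          map$marker_id[duplicated(map$marker_id)][1])
  if (any(map$pfb < 0 | map$pfb > 1, na.rm = TRUE))
    stopf("pfb outside [0, 1]")
  if (any(map$gc_frac < 0 | map$gc_frac > 1, na.rm = TRUE))
    stopf("gc_frac outside [0, 1]")
  for (chr in unique(map$chromosome)) {
    pos <- map$position_bp[map$chromosome == chr]
    if (any(diff(pos) <= 0))
      stopf("positions not strictly increasing on chromosome %s", chr)
  }
  invisible(map)
}

#' A scaled example genome for simulation
#'
#' Returns chromosome lengths and centromere intervals for a compact
#' synthetic genome used throughout the test-bed simulations. Lengths are
#' deliberately smaller than real human chromosomes so that dense marker
#' maps stay cheap; the coordinate conventions (1-based, centromeric
#' probe-free gap) match hg19 usage.
#'
#' @param n_chrom number of autosomes to include (named "1", "2", ...).
#' @param chrom_length_bp length of each autosome in bp.
#' @param centromere_frac centre of the centromeric gap as a fraction of
#'   chromosome length.
#' @param centromere_width_bp width of the probe-free centromeric gap.
#' @param include_sex also include "X" and "Y" chromosomes.
#' @return list with `chrom_lengths` (named numeric) and `centromeres`
#'   (data.frame: chromosome, start_bp, end_bp).
#' @export
example_genome <- function(n_chrom = 2, chrom_length_bp = 5e7,
                           centromere_frac = 0.45,
                           centromere_width_bp = 2e6,
                           include_sex = FALSE) {
  chroms <- as.character(seq_len(n_chrom))
  lens <- rep(chrom_length_bp, n_chrom)
  if (include_sex) {
    chroms <- c(chroms, "X", "Y")
    lens <- c(lens, chrom_length_bp, round(chrom_length_bp / 3))
  }
  names(lens) <- chroms
  centro_mid <- round(lens * centromere_frac)
  centromeres <- data.frame(
    chromosome = chroms,
    start_bp = as.integer(centro_mid - centromere_width_bp / 2),
    end_bp = as.integer(centro_mid + centromere_width_bp / 2),
    stringsAsFactors = FALSE
  )
  list(chrom_lengths = lens, centromeres = centromeres)
}

#' Generate a random marker map
#'
#' Markers are scattered uniformly along each chromosome (avoiding the
#' centromeric gap, which real arrays cannot probe), sorted, and annotated
#' with a population B-allele frequency drawn from a truncated
#' Beta(0.5, 0.5) and a smooth low-frequency GC field in \[0.3, 0.7\].
#'
#' @param n_markers total number of markers (>= 1), apportioned to
#'   chromosomes proportionally to length.
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param centromeres data.frame (chromosome, start_bp, end_bp) of
#'   probe-free centromeric gaps; may be NULL.
#' @param seed integer seed; the map is deterministic given the seed.
#' @param prop_unstable fraction of markers flagged as not copy-stable.
#' @return a [marker_map].
#' @export
generate_marker_map <- function(n_markers, chrom_lengths, centromeres = NULL,
                                seed = 1L, prop_unstable = 0.02) {
  if (length(n_markers) != 1L || n_markers < 1)
    stopf("n_markers must be a positive integer")
  if (length(chrom_lengths) == 0)
    stopf("chrom_lengths must be nonempty")
  if (any(chrom_lengths <= 0))
    stopf("zero-length chromosome: %s",
          names(chrom_lengths)[chrom_lengths <= 0][1])
  chroms <- names(chrom_lengths) %||% as.character(seq_along(chrom_lengths))
  chroms <- sub("^chr", "", chroms)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  n_per <- round(n_markers * chrom_lengths / sum(chrom_lengths))
  n_per[n_per < 1] <- 1L
  # fix rounding so the total is exact
  while (sum(n_per) != n_markers) {
    i <- if (sum(n_per) > n_markers) which.max(n_per) else which.min(n_per)
    n_per[i] <- n_per[i] + sign(n_markers - sum(n_per))
  }

  pieces <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    chr <- chroms[i]
    len <- chrom_lengths[i]
    cen <- NULL
    if (!is.null(centromeres)) {
      hit <- sub("^chr", "", centromeres$chromosome) == chr
      if (any(hit)) cen <- centromeres[hit, , drop = FALSE][1, ]
    }
    pos <- integer(0)
    while (length(pos) < n_per[i]) {
      cand <- as.integer(ceiling(stats::runif(2L * n_per[i], 0, len)))
      if (!is.null(cen))
        cand <- cand[cand < cen$start_bp | cand > cen$end_bp]
      pos <- unique(c(pos, cand))
    }
    pos <- sort(pos[seq_len(n_per[i])])
    gc <- smooth_gc_field(pos, len)
    pieces[[i]] <- data.frame(
      chromosome = chr, position_bp = pos, gc_frac = gc,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, pieces)
  pfb <- stats::rbeta(nrow(out), 0.5, 0.5)
  pfb <- clamp(pfb, 0.01, 0.99)
  marker_map(
    marker_id = sprintf("snp%06d", seq_len(nrow(out))),
    chromosome = out$chromosome,
    position_bp = out$position_bp,
    pfb = pfb,
    gc_frac = out$gc_frac,
    is_stable = stats::runif(nrow(out)) > prop_unstable
  )
}

# smooth random GC field in [0.3, 0.7]: a few random low-frequency
# sinusoids rescaled; emulates the megabase-scale GC waves of real genomes
smooth_gc_field <- function(pos, chrom_len, n_waves = 4L) {
  x <- pos / chrom_len
  f <- stats::runif(n_waves, 1, 8)
  ph <- stats::runif(n_waves, 0, 2 * pi)
  amp <- stats::runif(n_waves, 0.3, 1)
  s <- rowSums(sapply(seq_len(n_waves),
                      function(k) amp[k] * sin(2 * pi * f[k] * x + ph[k])))
  if (length(pos) == 1L) s <- sum(amp * sin(2 * pi * f * x + ph))
  rng <- max(abs(s), 1e-9)
  0.5 + 0.2 * s / rng
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# arm label ("15q" style) per marker given centromere table
marker_arms <- function(map, centromeres) {
  arm <- rep(NA_character_, nrow(map))
  for (i in seq_len(nrow(centromeres))) {
    chr <- sub("^chr", "", centromeres$chromosome[i])
    on_chr <- map$chromosome == chr
    arm[on_chr & map$position_bp < centromeres$start_bp[i]] <-
      paste0(chr, "p")
    arm[on_chr & map$position_bp > centromeres$end_bp[i]] <-
      paste0(chr, "q")
  }
  # chromosomes without a centromere entry: whole chromosome as one "arm"
  arm[is.na(arm)] <- paste0(map$chromosome[is.na(arm)], "q")
  arm
}
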
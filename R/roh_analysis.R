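#' Marker preparation for ROH calling
#'
#' Excludes markers with minor-allele frequency below `maf_min` (estimated
#' from the cohort genotypes) and LD-prunes the remainder so that no two
#' retained markers have pairwise r-squared above `r2_threshold`.
#'
#' @param cohort a `cnv_cohort`.
#' @param maf_min minimum minor-allele frequency, default 0.01
#'   (exclusive: frequencies below 1 percent are removed).
#' @param r2_threshold pruning threshold, default 0.3.
#' @return logical vector over the map's markers: TRUE = use for ROH.
#' @export
roh_marker_prep <- function(cohort, maf_min = 0.01, r2_threshold = 0.3) {
  g <- cohort_genotypes(cohort)
  d <- genotype_dosage(g)
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf >= maf_min
  keep_idx <- which(keep)
  pruned <- ld_prune(d[, keep_idx, drop = FALSE],
                     r2_threshold = r2_threshold,
                     chromosome = cohort$map$chromosome[keep_idx])
  out <- rep(FALSE, ncol(g))
  out[keep_idx[pruned]] <- TRUE
  out
}

roh_criteria <- function(min_kb = 1000, min_snps = 100,
                         density_kb_per_snp = 50, het_per_mb = 1,
                         max_gap_kb = 1000) {
  list(min_kb = min_kb, min_snps = min_snps,
       density_kb_per_snp = density_kb_per_snp, het_per_mb = het_per_mb,
       max_gap_kb = max_gap_kb)
}

#' Call runs of homozygosity for one sample
#'
#' Emits maximal runs of consecutive homozygous genotypes satisfying all
#' five criteria: (1) span at least `min_kb` kilobases; (2) at least
#' `min_snps` markers; (3) density of at least one marker per
#' `density_kb_per_snp` kb; (4) at most `het_per_mb` heterozygous
#' genotypes per megabase of span (with a floor of one); (5) no
#' inter-marker gap larger than `max_gap_kb` kb (runs are split at such
#' gaps, e.g. across centromeres). Runs are grown greedily marker by
#' marker; a heterozygote is admitted only while the running het budget is
#' respected; missing genotypes neither break a run nor count as
#' heterozygous (set `missing_breaks = TRUE` for the stricter behaviour).
#' Input markers are expected to be MAF-filtered and LD-pruned (see
#' [roh_marker_prep()]).
#'
#' @param genotypes character vector (`AA`/`AB`/`BB`/`NC`) aligned to
#'   `map`.
#' @param map the [marker_map] (restricted to the prepared markers).
#' @param sample_id sample name for the output rows.
#' @param criteria list from `roh_criteria()`.
#' @param pruned set FALSE to acknowledge unpruned input (a warning is
#'   issued; results are not comparable across datasets).
#' @param missing_breaks treat missing genotypes as run breaks.
#' @return data.frame of segments: `sample_id`, `chromosome`, `start_bp`,
#'   `end_bp`, `n_snps`, `n_het`, `length_kb`.
#' @export
call_roh <- function(genotypes, map, sample_id = "sample",
                     criteria = roh_criteria(), pruned = TRUE,
                     missing_breaks = FALSE) {
  if (!pruned)
    warnf("input markers not LD-pruned; ROH results are not comparable")
  segs <- list()
  max_gap <- criteria$max_gap_kb * 1000
  for (chr in unique(map$chromosome)) {
    idx <- which(map$chromosome == chr)
    pos <- map$position_bp[idx]
    g <- genotypes[idx]
    # blocks split at gaps > max_gap
    brk <- which(diff(pos) > max_gap)
    block_id <- cumsum(c(1, seq_along(pos)[-1] %in% (brk + 1)))
    for (b in unique(block_id)) {
      sel <- which(block_id == b)
      segs <- c(segs, roh_scan_block(pos[sel], g[sel], chr, sample_id,
                                     criteria, missing_breaks))
    }
  }
  if (!length(segs))
    return(data.frame(sample_id = character(0), chromosome = character(0),
                      start_bp = integer(0), end_bp = integer(0),
                      n_snps = integer(0), n_het = integer(0),
                      length_kb = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

# greedy left-to-right scan within one gap-free block
roh_scan_block <- function(pos, g, chr, sample_id, criteria,
                           missing_breaks) {
  is_hom <- g %in% c("AA", "BB")
  is_het <- g == "AB"
  is_mis <- g == "NC"
  n <- length(pos)
  segs <- list()
  i <- 1
  while (i <= n) {
    if (!is_hom[i]) { i <- i + 1; next }
    start <- i
    het_idx <- integer(0)
    last_hom <- i
    j <- i + 1
    while (j <= n) {
      if (is_het[j]) {
        span <- pos[j] - pos[start] + 1
        budget <- max(1, floor(span / 1e6) * criteria$het_per_mb)
        if (length(het_idx) + 1 > budget) break
        het_idx <- c(het_idx, j)
      } else if (is_mis[j]) {
        if (missing_breaks) break
      } else last_hom <- j
      j <- j + 1
    }
    # close at the last homozygous marker; trailing hets are trimmed
    end <- last_hom
    n_het <- sum(het_idx <= end)
    seg <- finalize_roh(pos, start, end, n_het, chr, sample_id, criteria)
    if (!is.null(seg)) segs[[length(segs) + 1]] <- seg
    restart <- if (length(het_idx)) het_idx[1] + 1 else j
    i <- max(restart, end + 1, i + 1)
  }
  segs
}

finalize_roh <- function(pos, start, end, n_het, chr, sample_id,
                         criteria) {
  if (end <= start) return(NULL)
  span <- pos[end] - pos[start] + 1
  n_snps <- end - start + 1
  if (span < criteria$min_kb * 1000) return(NULL)
  if (n_snps < criteria$min_snps) return(NULL)
  if (span / n_snps > criteria$density_kb_per_snp * 1000) return(NULL)
  if (n_het > max(1, floor(span / 1e6) * criteria$het_per_mb)) return(NULL)
  data.frame(sample_id = sample_id, chromosome = chr,
             start_bp = pos[start], end_bp = pos[end],
             n_snps = n_snps, n_het = n_het,
             length_kb = span / 1000, stringsAsFactors = FALSE)
}

#' Independent post-hoc validation of ROH segments
#'
#' Re-checks every emitted segment directly against the genotype data and
#' the five criteria (span, marker count, density, het budget, gap),
#' without reusing the caller's bookkeeping.
#'
#' @param segments data.frame from [call_roh()].
#' @param genotypes,map the data the segments were called from.
#' @param criteria list from `roh_criteria()`.
#' @return logical vector, one entry per segment (TRUE = all criteria
#'   hold).
#' @export
validate_roh_segments <- function(segments, genotypes, map,
                                  criteria = roh_criteria()) {
  vapply(seq_len(nrow(segments)), function(i) {
    sg <- segments[i, ]
    idx <- which(map$chromosome == sg$chromosome &
                   map$position_bp >= sg$start_bp &
                   map$position_bp <= sg$end_bp)
    if (!length(idx)) return(FALSE)
    span <- sg$end_bp - sg$start_bp + 1
    g <- genotypes[idx]
    pos <- map$position_bp[idx]
    span >= criteria$min_kb * 1000 &&
      length(idx) >= criteria$min_snps &&
      span / length(idx) <= criteria$density_kb_per_snp * 1000 &&
      sum(g == "AB") <= max(1, floor(span / 1e6) * criteria$het_per_mb) &&
      (length(pos) < 2 || max(diff(pos)) <= criteria$max_gap_kb * 1000)
  }, logical(1))
}

#' Call ROH for every sample in a cohort
#'
#' @param cohort a `cnv_cohort`.
#' @param keep logical marker mask from [roh_marker_prep()]; NULL uses all
#'   markers (with the unpruned warning).
#' @param ... passed to [call_roh()].
#' @return combined per-sample segment table.
#' @export
call_roh_cohort <- function(cohort, keep = NULL, ...) {
  if (is.null(keep)) {
    map <- cohort$map
    res <- lapply(cohort$samples, function(s)
      call_roh(s$genotype, map, s$sample_id, pruned = FALSE, ...))
  } else {
    map <- cohort$map[keep, , drop = FALSE]
    res <- lapply(cohort$samples, function(s)
      call_roh(s$genotype[keep], map, s$sample_id, ...))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Case-control ROH burden summary with permutation p-values
#'
#' Per group: segment count, rate per sample, proportion of samples with
#' at least one segment, mean per-sample total span, and mean segment
#' size. Each case-versus-control contrast gets a one-sided empirical
#' p-value from phenotype-label permutation (shared engine with the CNV
#' burden tests).
#'
#' @param segments per-sample segment table.
#' @param phenotypes phenotype table (`sample_id`, `status`).
#' @param n_perms permutation replicates, default 10000.
#' @param seed integer seed.
#' @return list: `summary` (per-group data.frame), `p_values` (named,
#'   one-sided case > control).
#' @export
roh_burden_summary <- function(segments, phenotypes, n_perms = 10000,
                               seed = 1L) {
  burden_engine(segments, phenotypes, size_col = "length_kb",
                n_perms = n_perms, seed = seed)
}

#' Case-control ROH region scan
#'
#' Computes per-marker case and control carrier counts from the segment
#' pileup, then reports (a) seed regions - maximal marker runs carried by
#' at least `core_cases` cases - extended outward marker by marker while
#' at least `flank_min_cases` cases still overlap and no additional
#' control carrier appears (the control count never exceeds its maximum
#' over the seed); and (b) maximal runs carried by at least
#' `alt_min_cases` cases and zero controls. Regions of rule (b) that
#' overlap a rule-(a) region are not repeated.
#'
#' @param segments per-sample ROH segment table.
#' @param phenotypes phenotype table.
#' @param map the [marker_map] the segments were called on.
#' @param core_cases seed threshold, default 10.
#' @param flank_min_cases extension threshold, default 7.
#' @param alt_min_cases rule-(b) threshold, default 7.
#' @return data.frame: `chromosome`, `start_bp`, `end_bp`, `min_aff`,
#'   `max_aff`, `num_unaff`, `rule`.
#' @export
roh_region_scan <- function(segments, phenotypes, map, core_cases = 10,
                            flank_min_cases = 7, alt_min_cases = 7) {
  status <- phenotypes$status[match(segments$sample_id,
                                    phenotypes$sample_id)]
  empty <- data.frame(chromosome = character(0), start_bp = integer(0),
                      end_bp = integer(0), min_aff = integer(0),
                      max_aff = integer(0), num_unaff = integer(0),
                      rule = character(0), stringsAsFactors = FALSE)
  if (!nrow(segments)) return(empty)
  out <- list()
  for (chr in unique(segments$chromosome)) {
    idx <- which(map$chromosome == chr)
    if (!length(idx)) next
    pos <- map$position_bp[idx]
    counts <- function(who) {
      sel <- segments$chromosome == chr & status == who
      cv <- integer(length(pos))
      for (r in which(sel)) {
        lo <- findInterval(segments$start_bp[r] - 1L, pos) + 1L
        hi <- findInterval(segments$end_bp[r], pos)
        if (lo <= hi) cv[lo:hi] <- cv[lo:hi] + 1L
      }
      cv
    }
    aff <- counts("case")
    unaff <- counts("control")

    emit <- function(lo, hi, rule) {
      data.frame(chromosome = chr, start_bp = pos[lo], end_bp = pos[hi],
                 min_aff = min(aff[lo:hi]), max_aff = max(aff[lo:hi]),
                 num_unaff = max(unaff[lo:hi]), rule = rule,
                 stringsAsFactors = FALSE)
    }

    runs_a <- run_bounds(aff >= core_cases)
    regions_a <- list()
    for (r in seq_len(nrow(runs_a))) {
      lo <- runs_a$lo[r]; hi <- runs_a$hi[r]
      ctrl_base <- max(unaff[lo:hi])
      while (lo > 1 && aff[lo - 1] >= flank_min_cases &&
             unaff[lo - 1] <= ctrl_base) lo <- lo - 1
      while (hi < length(pos) && aff[hi + 1] >= flank_min_cases &&
             unaff[hi + 1] <= ctrl_base) hi <- hi + 1
      regions_a[[r]] <- c(lo, hi)
      out[[length(out) + 1]] <- emit(lo, hi, "core10_extend7")
    }
    runs_b <- run_bounds(aff >= alt_min_cases & unaff == 0)
    for (r in seq_len(nrow(runs_b))) {
      lo <- runs_b$lo[r]; hi <- runs_b$hi[r]
      overlaps_a <- any(vapply(regions_a, function(ab)
        lo <= ab[2] && hi >= ab[1], logical(1)))
      if (!overlaps_a)
        out[[length(out) + 1]] <- emit(lo, hi, "cases7_controls0")
    }
  }
  if (!length(out)) return(empty)
  out <- do.call(rbind, out)
  out <- out[order(chrom_order(out$chromosome), out$start_bp), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# maximal TRUE runs of a logical vector as lo/hi index bounds
run_bounds <- function(flag) {
  r <- rle(flag)
  hi <- cumsum(r$lengths)
  lo <- hi - r$lengths + 1
  data.frame(lo = lo[r$values], hi = hi[r$values])
}
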
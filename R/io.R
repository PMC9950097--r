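#' Write a cohort's signal matrix in PennCNV-style format
#'
#' Tab-delimited text with columns `Name`, `Chr`, `Position`, then for each
#' sample `<id>.Log R Ratio`, `<id>.B Allele Freq`, `<id>.GType`. Missing
#' genotypes are written as `NC`.
#'
#' @param cohort a `cnv_cohort`, or a list of `intensity_sample` (then
#'   `map` must be given).
#' @param path output file.
#' @param map marker map (ignored when `cohort` is a `cnv_cohort`).
#' @return `path`, invisibly.
#' @export
write_signal_matrix <- function(cohort, path, map = NULL) {
  if (inherits(cohort, "cnv_cohort")) {
    samples <- cohort$samples
    map <- cohort$map
  } else samples <- cohort
  if (is.null(map)) stopf("a marker map is required")
  out <- data.frame(Name = map$marker_id, Chr = map$chromosome,
                    Position = map$position_bp, stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (s in samples) {
    out[[paste0(s$sample_id, ".Log R Ratio")]] <- s$lrr
    out[[paste0(s$sample_id, ".B Allele Freq")]] <- s$baf
    out[[paste0(s$sample_id, ".GType")]] <- s$genotype
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a PennCNV-style signal matrix
#'
#' @param path signal file written by [write_signal_matrix()] (or any
#'   tab-delimited file with the same column conventions).
#' @param map optional [marker_map]; when given, rows are re-aligned to map
#'   order and every file marker must be present in the map.
#' @return list with `map` (from the file's coordinate columns, or the
#'   supplied map) and `samples` (named list of `intensity_sample`).
#' @export
read_signal_matrix <- function(path, map = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  dat <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("Name", "Chr", "Position")
  if (!all(need %in% names(dat)))
    stopf("signal file must have Name/Chr/Position columns")
  # reject ragged lines: read.delim fills, so detect NA holes in coordinates
  if (anyNA(dat$Position)) {
    bad <- which(is.na(dat$Position))[1]
    stopf("truncated or non-numeric line %d in %s", bad + 1L, path)
  }
  if (!is.null(map)) {
    missing_in_map <- setdiff(dat$Name, map$marker_id)
    if (length(missing_in_map))
      stopf("marker %s present in file but absent from map",
            missing_in_map[1])
    ord <- match(map$marker_id, dat$Name)
    ord <- ord[!is.na(ord)]
    dat <- dat[ord, , drop = FALSE]
    used_map <- map[map$marker_id %in% dat$Name, , drop = FALSE]
  } else {
    used_map <- marker_map(dat$Name, dat$Chr, dat$Position,
                           pfb = rep(0.5, nrow(dat)),
                           gc_frac = rep(0.5, nrow(dat)))
    ord <- match(used_map$marker_id, dat$Name)
    dat <- dat[ord, , drop = FALSE]
  }
  lrr_cols <- grep("\\.Log R Ratio$", names(dat), value = TRUE)
  ids <- sub("\\.Log R Ratio$", "", lrr_cols)
  samples <- vector("list", length(ids))
  names(samples) <- ids
  for (id in ids) {
    lrr <- dat[[paste0(id, ".Log R Ratio")]]
    if (!is.numeric(lrr)) {
      bad <- which(is.na(suppressWarnings(as.numeric(lrr))))[1]
      stopf("non-numeric LRR for sample %s at line %d", id, bad + 1L)
    }
    samples[[id]] <- intensity_sample(
      id, lrr, dat[[paste0(id, ".B Allele Freq")]],
      dat[[paste0(id, ".GType")]]
    )
  }
  list(map = used_map, samples = samples)
}

#' Write a population B-allele-frequency (PFB) file
#' @param map a [marker_map].
#' @param path output file.
#' @export
write_pfb <- function(map, path) {
  utils::write.table(
    data.frame(Name = map$marker_id, Chr = map$chromosome,
               Position = map$position_bp, PFB = round(map$pfb, 4)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read CNV calls
#'
#' The native format is a PennCNV/PLINK-style tab-delimited table with
#' 1-based inclusive coordinates: `sample_id`, `chromosome`, `start_bp`,
#' `end_bp`, `copy_number`, `n_probes`, `confidence`. The BED export
#' converts to 0-based half-open intervals (start decremented by one).
#'
#' @param calls data.frame of CNV calls.
#' @param path output file.
#' @param bed_path optional path for a BED export.
#' @return `path`, invisibly.
#' @export
write_cnv_calls <- function(calls, path, bed_path = NULL) {
  cols <- c("sample_id", "chromosome", "start_bp", "end_bp",
            "copy_number", "n_probes", "confidence")
  if (nrow(calls) == 0)
    calls <- data.frame(sample_id = character(0), chromosome = character(0),
                        start_bp = integer(0), end_bp = integer(0),
                        copy_number = integer(0), n_probes = integer(0),
                        confidence = numeric(0))
  utils::write.table(calls[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = paste0("chr", calls$chromosome),
                      start = calls$start_bp - 1L, end = calls$end_bp,
                      name = sprintf("%s_CN%d", calls$sample_id,
                                     calls$copy_number))
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_cnv_calls
#' @export
read_cnv_calls <- function(path) {
  dat <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(chromosome = "character"))
  dat
}

#' Write / read runs-of-homozygosity segments
#'
#' Mirrors the `.hom`-style per-segment table: `sample_id`, `chromosome`,
#' `start_bp`, `end_bp`, `n_snps`, `n_het`, `length_kb` (1-based inclusive
#' coordinates).
#'
#' @param segments data.frame of ROH segments.
#' @param path output file.
#' @param bed_path optional BED export (0-based half-open).
#' @export
write_roh <- function(segments, path, bed_path = NULL) {
  cols <- c("sample_id", "chromosome", "start_bp", "end_bp",
            "n_snps", "n_het", "length_kb")
  if (nrow(segments) == 0)
    segments <- data.frame(sample_id = character(0),
                           chromosome = character(0),
                           start_bp = integer(0), end_bp = integer(0),
                           n_snps = integer(0), n_het = integer(0),
                           length_kb = numeric(0))
  utils::write.table(segments[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = paste0("chr", segments$chromosome),
                      start = segments$start_bp - 1L,
                      end = segments$end_bp,
                      name = segments$sample_id)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_roh
#' @export
read_roh <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(chromosome = "character"))
}

#' Write / read a phenotype table
#'
#' Columns: `sample_id`, `status` (case/control), `sex`
#' (male/female/unknown), `cohort_label`.
#'
#' @param phenotypes data.frame.
#' @param path file path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (anyDuplicated(ph$sample_id))
    stopf("duplicate sample_id in phenotype table")
  if (!all(ph$status %in% c("case", "control")))
    stopf("status must be case/control")
  ph
}

#' Write a truth-event table
#' @param truth data.frame from [truth_event()].
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Packaged table of CNV loci previously associated with schizophrenia
#'
#' Recurrent (mostly NAHR-mediated) loci with hg19 intervals, the
#' copy-number direction of the reported association (`loss`, `gain` or
#' `both`) and whether the reported effect is risk or protective.
#'
#' @return data.frame with columns `name`, `chromosome`, `start_bp`,
#'   `end_bp`, `cnv_type`, `direction`.
#' @export
known_loci <- function() {
  path <- system.file("extdata", "known_schizophrenia_loci.tsv",
                      package = "cnvscreen")
  if (!nzchar(path)) stopf("packaged locus table not found")
  read_known_loci(path)
}

#' @rdname known_loci
#' @param path a locus table file (tab-delimited with the same columns).
#' @export
read_known_loci <- function(path) {
  dat <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(chromosome = "character"))
  need <- c("name", "chromosome", "start_bp", "end_bp", "cnv_type",
            "direction")
  if (!all(need %in% names(dat)))
    stopf("locus table missing columns: %s",
          paste(setdiff(need, names(dat)), collapse = ", "))
  for (i in seq_len(nrow(dat))) {
    if (is.na(dat$start_bp[i]) || is.na(dat$end_bp[i]) ||
        dat$start_bp[i] > dat$end_bp[i])
      stopf("malformed interval in locus table row %d (%s)", i, dat$name[i])
    if (!dat$cnv_type[i] %in% c("loss", "gain", "both"))
      stopf("bad cnv_type in locus table row %d (%s)", i, dat$name[i])
  }
  dat
}
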
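#' Noise model for the synthetic-cohort generator
#'
#' @param lrr_sd per-marker Gaussian SD of the Log R Ratio (log2 scale).
#' @param baf_sd Gaussian SD around each B-allele-frequency cluster mean.
#' @param outlier_rate probability that a marker's BAF is replaced by a
#'   Uniform(0,1) draw and its genotype by a no-call; models genotyping
#'   failures. Must be < 0.1.
#' @param gc_wave_amplitude coefficient of the additive GC wave:
#'   `lrr += gc_wave_amplitude * (gc_frac - mean(gc_frac))`.
#' @param batch_shift_sd SD of the per-batch constant LRR offset (samples
#'   are split into two batches).
#' @return list of class `noise_model`.
#' @export
noise_model <- function(lrr_sd = 0.2, baf_sd = 0.03, outlier_rate = 0.005,
                        gc_wave_amplitude = 0.1, batch_shift_sd = 0.1) {
  if (lrr_sd <= 0 || baf_sd <= 0) stopf("noise SDs must be positive")
  if (outlier_rate < 0 || outlier_rate >= 0.1)
    stopf("outlier_rate must be in [0, 0.1)")
  structure(list(lrr_sd = lrr_sd, baf_sd = baf_sd,
                 outlier_rate = outlier_rate,
                 gc_wave_amplitude = gc_wave_amplitude,
                 batch_shift_sd = batch_shift_sd),
            class = "noise_model")
}

#' Ground-truth event table for planted alterations
#'
#' @param sample_id sample carrying the event.
#' @param kind "cnv" (germline copy-number change), "mosaic" (arm-scale
#'   event present in a fraction of cells) or "roh" (autozygous segment).
#' @param chromosome,start_bp,end_bp 1-based inclusive interval.
#' @param copy_number for `cnv`: integer copy number 0--4 (not 2); for
#'   `mosaic`: signed change (-1 loss, +1 gain, 0 copy-neutral LOH).
#' @param cell_fraction fraction of cells carrying a mosaic event, in (0,1].
#' @return data.frame with one row per event.
#' @export
truth_event <- function(sample_id, kind, chromosome, start_bp, end_bp,
                        copy_number = NA_integer_,
                        cell_fraction = NA_real_) {
  if (!length(sample_id))
    return(data.frame(sample_id = character(0), kind = character(0),
                      chromosome = character(0), start_bp = integer(0),
                      end_bp = integer(0), copy_number = integer(0),
                      cell_fraction = numeric(0), stringsAsFactors = FALSE))
  kind <- match.arg(kind, c("cnv", "mosaic", "roh"), several.ok = TRUE)
  ev <- data.frame(sample_id = sample_id, kind = kind,
                   chromosome = sub("^chr", "", as.character(chromosome)),
                   start_bp = as.integer(start_bp),
                   end_bp = as.integer(end_bp),
                   copy_number = as.integer(copy_number),
                   cell_fraction = as.numeric(cell_fraction),
                   stringsAsFactors = FALSE)
  if (any(ev$start_bp > ev$end_bp)) stopf("start_bp > end_bp in truth event")
  bad <- ev$kind == "mosaic" &
    (is.na(ev$cell_fraction) | ev$cell_fraction <= 0 | ev$cell_fraction > 1)
  if (any(bad)) stopf("mosaic events need cell_fraction in (0, 1]")
  ev
}

# LRR state means shared between the generator defaults and the HMM;
# conventional Illumina/PennCNV-scale values
lrr_state_means <- function() {
  c(CN0 = -3.0, CN1 = -0.66, CN2 = 0.0, `CN2-LOH` = 0.0,
    CN3 = 0.40, CN4 = 0.68)
}

# BAF band deviation d implied by a mosaic event:
#   loss:    d = f/2 / (2 - f);  gain: d = f/2 / (2 + f);  CN-LOH: d = f/2
mosaic_band_deviation <- function(cell_fraction, change) {
  f <- cell_fraction
  if (change < 0) 0.5 * f / (2 - f)
  else if (change > 0) 0.5 * f / (2 + f)
  else f / 2
}

mosaic_lrr_shift <- function(cell_fraction, change) {
  f <- cell_fraction
  if (change < 0) log2((2 - f) / 2)
  else if (change > 0) log2((2 + f) / 2)
  else 0
}

#' Simulate a case-control SNP-array cohort with planted events
#'
#' Generates per-sample Log R Ratio, B-allele frequency and genotype
#' vectors aligned to a marker map. Genotypes follow Hardy-Weinberg
#' proportions at each marker's population B-allele frequency. Planted
#' deletions and duplications move the LRR to the configured copy-number
#' state mean and reshape the BAF clusters (e.g. the heterozygous band is
#' absent under CN1 and splits to 1/3, 2/3 under CN3); mosaic events split
#' the heterozygous band to 0.5 +/- d with d given by the cell fraction;
#' autozygous (roh) events force homozygous genotypes. A GC wave and
#' per-batch intensity offsets are added according to the noise model.
#'
#' @param map a [marker_map].
#' @param n_cases,n_controls cohort sizes; samples are named
#'   `case_<i>` / `control_<i>`.
#' @param events a truth table from [truth_event()] (or an empty
#'   data.frame) whose `sample_id`s name simulated samples.
#' @param noise a [noise_model()].
#' @param seed integer seed; the cohort is deterministic given the seed.
#' @param sex optional character vector (`male`/`female`) per sample,
#'   recycled; defaults to alternating. Only used when the map carries X/Y
#'   markers.
#' @return list of class `cnv_cohort` with elements `map`, `samples`
#'   (named list of `intensity_sample`), `phenotypes`, `truth`, `noise`.
#' @export
simulate_cohort <- function(map, n_cases, n_controls, events = NULL,
                            noise = noise_model(), seed = 1L, sex = NULL) {
  validate_marker_map(map)
  ids <- c(sprintf("case_%03d", seq_len(n_cases)),
           sprintf("control_%03d", seq_len(n_controls)))
  status <- rep(c("case", "control"), c(n_cases, n_controls))
  if (is.null(sex)) sex <- rep_len(c("male", "female"), length(ids))
  else sex <- rep_len(sex, length(ids))

  if (is.null(events))
    events <- truth_event(character(0), character(0), character(0),
                          integer(0), integer(0))
  if (nrow(events)) {
    if (!all(events$sample_id %in% ids))
      stopf("truth event names unknown sample: %s",
            setdiff(events$sample_id, ids)[1])
    for (i in seq_len(nrow(events))) {
      on_chr <- map$chromosome == events$chromosome[i]
      if (!any(on_chr)) stopf("event on chromosome %s not covered by map",
                              events$chromosome[i])
      rng <- range(map$position_bp[on_chr])
      if (events$start_bp[i] < rng[1] || events$end_bp[i] > rng[2])
        stopf("event %s:%d-%d outside map coordinates",
              events$chromosome[i], events$start_bp[i], events$end_bp[i])
    }
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  n_mark <- nrow(map)
  gc_centered <- map$gc_frac - mean(map$gc_frac)
  batch <- rep_len(1:2, length(ids))
  batch_offsets <- stats::rnorm(2, 0, noise$batch_shift_sd)
  means <- lrr_state_means()

  samples <- vector("list", length(ids))
  names(samples) <- ids
  for (s in seq_along(ids)) {
    gt <- simulate_genotypes(map$pfb)
    baf <- baf_from_genotype(gt, noise$baf_sd)
    lrr <- stats::rnorm(n_mark, 0, noise$lrr_sd) +
      noise$gc_wave_amplitude * gc_centered + batch_offsets[batch[s]]

    if (any(c("X", "Y") %in% map$chromosome))
      sex_adjust <- apply_sex_signal(map, gt, baf, lrr, sex[s],
                                     means, noise)
    else sex_adjust <- list(gt = gt, baf = baf, lrr = lrr)
    gt <- sex_adjust$gt; baf <- sex_adjust$baf; lrr <- sex_adjust$lrr

    ev_s <- events[events$sample_id == ids[s], , drop = FALSE]
    for (i in seq_len(nrow(ev_s))) {
      idx <- which(map$chromosome == ev_s$chromosome[i] &
                     map$position_bp >= ev_s$start_bp[i] &
                     map$position_bp <= ev_s$end_bp[i])
      if (!length(idx)) next
      planted <- plant_event(ev_s[i, ], idx, map$pfb[idx], gt[idx],
                             baf[idx], means, noise)
      gt[idx] <- planted$gt; baf[idx] <- planted$baf
      lrr[idx] <- planted$lrr_shift +
        if (is.na(planted$lrr_level[1])) lrr[idx] else
          planted$lrr_level + stats::rnorm(length(idx), 0, noise$lrr_sd) +
        noise$gc_wave_amplitude * gc_centered[idx] + batch_offsets[batch[s]]
    }

    out <- stats::runif(n_mark) < noise$outlier_rate
    if (any(out)) {
      baf[out] <- stats::runif(sum(out))
      gt[out] <- "NC"
    }
    samples[[s]] <- intensity_sample(ids[s], lrr, baf, gt)
  }

  phenotypes <- data.frame(
    sample_id = ids, status = status, sex = sex,
    cohort_label = paste0("synthetic_", status),
    stringsAsFactors = FALSE
  )
  structure(list(map = map, samples = samples, phenotypes = phenotypes,
                 truth = events, noise = noise, seed = as.integer(seed)),
            class = "cnv_cohort")
}

# Hardy-Weinberg genotype draw at pfb p: AA (1-p)^2, AB 2p(1-p), BB p^2
simulate_genotypes <- function(pfb) {
  u <- stats::runif(length(pfb))
  p_aa <- (1 - pfb)^2
  p_ab <- 2 * pfb * (1 - pfb)
  ifelse(u < p_aa, "AA", ifelse(u < p_aa + p_ab, "AB", "BB"))
}

baf_from_genotype <- function(gt, baf_sd) {
  mu <- c(AA = 0, AB = 0.5, BB = 1)[gt]
  clamp(mu + stats::rnorm(length(gt), 0, baf_sd), 0, 1)
}

# modify a slice of one sample's signal for one planted event; returns
# lrr_level = per-marker LRR mean (NA = keep background noise process) and
# lrr_shift = additive offset applied on top of the existing values
plant_event <- function(ev, idx, pfb, gt, baf, means, noise) {
  n <- length(idx)
  lrr_level <- NA_real_
  lrr_shift <- 0
  if (ev$kind == "cnv") {
    cn <- ev$copy_number
    if (cn == 0) {
      gt <- rep("NC", n)
      baf <- stats::runif(n)
      lrr_level <- means["CN0"]
    } else if (cn == 1) {
      b <- stats::runif(n) < pfb
      gt <- ifelse(b, "BB", "AA")
      baf <- clamp(as.numeric(b) + stats::rnorm(n, 0, noise$baf_sd), 0, 1)
      lrr_level <- means["CN1"]
    } else if (cn %in% c(3, 4)) {
      k <- stats::rbinom(n, cn, pfb)
      gt <- ifelse(k == 0, "AA", ifelse(k == cn, "BB", "AB"))
      baf <- clamp(k / cn + stats::rnorm(n, 0, noise$baf_sd), 0, 1)
      lrr_level <- means[if (cn == 3) "CN3" else "CN4"]
    } else stopf("cnv copy_number must be 0, 1, 3 or 4")
  } else if (ev$kind == "roh") {
    b <- stats::runif(n) < pfb
    gt <- ifelse(b, "BB", "AA")
    baf <- clamp(as.numeric(b) + stats::rnorm(n, 0, noise$baf_sd), 0, 1)
  } else if (ev$kind == "mosaic") {
    d <- mosaic_band_deviation(ev$cell_fraction, ev$copy_number)
    lrr_shift <- mosaic_lrr_shift(ev$cell_fraction, ev$copy_number)
    het <- gt == "AB"
    sign <- ifelse(stats::runif(sum(het)) < 0.5, -1, 1)
    baf[het] <- clamp(0.5 + sign * d +
                        stats::rnorm(sum(het), 0, noise$baf_sd), 0, 1)
  }
  list(gt = gt, baf = baf, lrr_level = lrr_level, lrr_shift = lrr_shift)
}

# sex-chromosome signal: males carry one X (no het band, CN1-level LRR)
# and one Y; females two X and no Y (Y probes read as background loss)
apply_sex_signal <- function(map, gt, baf, lrr, sex, means, noise) {
  on_x <- map$chromosome == "X"
  on_y <- map$chromosome == "Y"
  n_x <- sum(on_x); n_y <- sum(on_y)
  if (sex == "male") {
    if (n_x) {
      b <- stats::runif(n_x) < map$pfb[on_x]
      gt[on_x] <- ifelse(b, "BB", "AA")
      baf[on_x] <- clamp(as.numeric(b) + stats::rnorm(n_x, 0, noise$baf_sd),
                         0, 1)
      lrr[on_x] <- lrr[on_x] + means["CN1"]
    }
    # Y present: LRR stays at baseline
  } else {
    if (n_y) {
      gt[on_y] <- "NC"
      baf[on_y] <- stats::runif(n_y)
      lrr[on_y] <- lrr[on_y] + means["CN0"]
    }
  }
  list(gt = gt, baf = baf, lrr = lrr)
}

#' Scatter random non-overlapping CNV truth events across a cohort
#'
#' Draws, for each sample, one or more germline CNV events (copy numbers
#' 0, 1, 3, 4) of random size, placed uniformly within chromosome arms
#' (never across a centromere), with a buffer between events of the same
#' sample. Events whose probe support falls below the calling minima
#' (3 probes for homozygous deletions, 15 otherwise) are discarded, so
#' every returned truth event is in principle callable.
#'
#' @param map a [marker_map].
#' @param sample_ids samples to plant events in.
#' @param seed integer seed.
#' @param centromeres optional centromere table bounding the arms.
#' @param copy_numbers,cn_prob candidate copy numbers and their weights.
#' @param lengths_bp candidate event lengths.
#' @param events_per_sample integer vector sampled per sample.
#' @param buffer_bp minimum distance between events of one sample.
#' @return truth-event data.frame (see [truth_event()]).
#' @export
plant_random_cnvs <- function(map, sample_ids, seed = 1L,
                              centromeres = NULL,
                              copy_numbers = c(0L, 1L, 3L, 4L),
                              cn_prob = c(0.15, 0.35, 0.35, 0.15),
                              lengths_bp = c(4e5, 5e5, 7e5, 1e6),
                              events_per_sample = 1:2,
                              buffer_bp = 3e5) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  # arm intervals with a margin inside the covered marker range
  arms <- list()
  for (chr in unique(map$chromosome)) {
    pos <- map$position_bp[map$chromosome == chr]
    lo <- min(pos) + 5e5
    hi <- max(pos) - 5e5
    cen <- NULL
    if (!is.null(centromeres)) {
      hit <- sub("^chr", "", centromeres$chromosome) == chr
      if (any(hit)) cen <- centromeres[hit, , drop = FALSE][1, ]
    }
    if (is.null(cen)) {
      arms[[length(arms) + 1]] <- list(chr = chr, lo = lo, hi = hi)
    } else {
      arms[[length(arms) + 1]] <- list(chr = chr, lo = lo,
                                       hi = cen$start_bp - 5e5)
      arms[[length(arms) + 1]] <- list(chr = chr,
                                       lo = cen$end_bp + 5e5, hi = hi)
    }
  }
  rows <- list()
  for (id in sample_ids) {
    k <- sample(rep(events_per_sample, 2), 1)
    placed <- list()
    for (j in seq_len(k)) {
      for (try in 1:20) {
        cn <- sample(rep(copy_numbers, 2), 1, prob = rep(cn_prob, 2))
        len <- sample(rep(lengths_bp, 2), 1)
        arm <- arms[[sample.int(length(arms), 1)]]
        if (arm$hi - arm$lo < len + 1) next
        start <- round(stats::runif(1, arm$lo, arm$hi - len))
        end <- start + len
        clash <- any(vapply(placed, function(p)
          p$chr == arm$chr && start <= p$end + buffer_bp &&
            end >= p$start - buffer_bp, logical(1)))
        if (clash) next
        n_probes <- sum(map$chromosome == arm$chr &
                          map$position_bp >= start &
                          map$position_bp <= end)
        if (n_probes < ifelse(cn == 0, 3, 15)) next
        placed[[length(placed) + 1]] <- list(chr = arm$chr, start = start,
                                             end = end)
        rows[[length(rows) + 1]] <- truth_event(id, "cnv", arm$chr,
                                                start, end,
                                                copy_number = cn)
        break
      }
    }
  }
  if (!length(rows)) return(truth_event(character(0), character(0),
                                        character(0), integer(0),
                                        integer(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-sample intensity record
#'
#' @param sample_id sample name.
#' @param lrr,baf,genotype vectors aligned to the marker map; genotypes in
#'   `AA`, `AB`, `BB`, `NC` (no-call).
#' @return list of class `intensity_sample`.
#' @export
intensity_sample <- function(sample_id, lrr, baf, genotype) {
  n <- length(lrr)
  if (length(baf) != n || length(genotype) != n)
    stopf("lrr, baf and genotype must have equal length")
  if (!all(genotype %in% c("AA", "AB", "BB", "NC")))
    stopf("genotypes must be AA/AB/BB/NC")
  structure(list(sample_id = as.character(sample_id),
                 lrr = as.numeric(lrr), baf = as.numeric(baf),
                 genotype = as.character(genotype),
                 call_rate = mean(genotype != "NC")),
            class = "intensity_sample")
}

#' @export
print.intensity_sample <- function(x, ...) {
  cat(sprintf("<intensity_sample> %s: %d markers, call rate %.3f\n",
              x$sample_id, length(x$lrr), x$call_rate))
  invisible(x)
}

#' @export
print.cnv_cohort <- function(x, ...) {
  cat(sprintf(
    "<cnv_cohort> %d samples (%d cases / %d controls), %d markers, %d truth events\n",
    length(x$samples), sum(x$phenotypes$status == "case"),
    sum(x$phenotypes$status == "control"), nrow(x$map), nrow(x$truth)))
  invisible(x)
}

# sample x marker matrix of one signal component
cohort_matrix <- function(cohort, what = c("lrr", "baf")) {
  what <- match.arg(what)
  do.call(rbind, lapply(cohort$samples, `[[`, what))
}

# sample x marker genotype matrix (character)
cohort_genotypes <- function(cohort) {
  do.call(rbind, lapply(cohort$samples, `[[`, "genotype"))
}
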
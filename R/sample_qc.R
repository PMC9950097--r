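#' Compute Log R Ratio and B-allele frequency from raw allele intensities
#'
#' Implements the standard cluster-interpolation construction: for each
#' marker the summed intensity `R = X + Y` and the polar angle
#' `theta = (2/pi) * atan2(Y, X)` are compared with the canonical genotype
#' cluster medians. The expected `R` is linearly interpolated between the
#' two clusters flanking the observed theta, and `LRR = log2(R / R_exp)`.
#' BAF is piecewise linear in theta: 0 at or below the AA cluster, 0.5 at
#' the AB cluster, 1 at or above the BB cluster.
#'
#' @param x_intensity,y_intensity numeric vectors of A- and B-allele
#'   intensities, one value per marker.
#' @param cluster_medians data.frame with per-marker columns `theta_aa`,
#'   `r_aa`, `theta_ab`, `r_ab`, `theta_bb`, `r_bb`. Markers with any
#'   missing cluster are flagged unusable (LRR/BAF set to `NA`).
#' @return list with numeric vectors `lrr`, `baf` and logical `usable`.
#' @export
compute_lrr_baf <- function(x_intensity, y_intensity, cluster_medians) {
  n <- length(x_intensity)
  cm <- cluster_medians
  need <- c("theta_aa", "r_aa", "theta_ab", "r_ab", "theta_bb", "r_bb")
  if (!all(need %in% names(cm)))
    stopf("cluster_medians missing columns: %s",
          paste(setdiff(need, names(cm)), collapse = ", "))
  usable <- stats::complete.cases(cm[, need])
  theta <- (2 / pi) * atan2(y_intensity, x_intensity)
  r <- x_intensity + y_intensity

  baf <- rep(NA_real_, n)
  r_exp <- rep(NA_real_, n)
  lo <- usable & theta <= cm$theta_aa
  hi <- usable & theta >= cm$theta_bb
  mid_lo <- usable & theta > cm$theta_aa & theta < cm$theta_ab
  mid_hi <- usable & theta >= cm$theta_ab & theta < cm$theta_bb

  baf[lo] <- 0
  r_exp[lo] <- cm$r_aa[lo]
  baf[hi] <- 1
  r_exp[hi] <- cm$r_bb[hi]
  frac <- (theta[mid_lo] - cm$theta_aa[mid_lo]) /
    (cm$theta_ab[mid_lo] - cm$theta_aa[mid_lo])
  baf[mid_lo] <- 0.5 * frac
  r_exp[mid_lo] <- cm$r_aa[mid_lo] + frac * (cm$r_ab[mid_lo] - cm$r_aa[mid_lo])
  frac <- (theta[mid_hi] - cm$theta_ab[mid_hi]) /
    (cm$theta_bb[mid_hi] - cm$theta_ab[mid_hi])
  baf[mid_hi] <- 0.5 + 0.5 * frac
  r_exp[mid_hi] <- cm$r_ab[mid_hi] + frac * (cm$r_bb[mid_hi] - cm$r_ab[mid_hi])

  lrr <- rep(NA_real_, n)
  ok <- usable & r_exp > 0 & r > 0
  lrr[ok] <- log2(r[ok] / r_exp[ok])
  list(lrr = lrr, baf = baf, usable = usable)
}

#' Per-sample intensity QC metrics
#'
#' `lrr_mean` and `lrr_sd` are computed only over LRR values in
#' \[-2, +2\] (so real large copy-number changes do not inflate the
#' noise estimate); `het_baf_sd` only over BAF values in \[0.15, 0.85\]
#' (putative heterozygotes).
#'
#' @param sample an `intensity_sample`.
#' @return one-row data.frame: `sample_id`, `lrr_mean`, `lrr_sd`,
#'   `het_baf_sd`, `call_rate`.
#' @export
sample_qc_metrics <- function(sample) {
  lrr_in <- sample$lrr[!is.na(sample$lrr) & sample$lrr >= -2 &
                         sample$lrr <= 2]
  het <- sample$baf[!is.na(sample$baf) & sample$baf >= 0.15 &
                      sample$baf <= 0.85]
  data.frame(sample_id = sample$sample_id,
             lrr_mean = mean(lrr_in),
             lrr_sd = stats::sd(lrr_in),
             het_baf_sd = if (length(het) >= 2) stats::sd(het) else NA_real_,
             call_rate = sample$call_rate,
             stringsAsFactors = FALSE)
}

#' Cohort-level sample pass/fail screen
#'
#' Excludes samples whose restricted-window LRR SD or heterozygous-BAF SD
#' exceeds the cohort mean by more than `sd_mult` cohort standard
#' deviations of that metric, and samples with genotype call rate at or
#' below `call_rate_min`. Reasons are recorded per failing sample.
#'
#' @param metrics data.frame of per-sample metrics, one row per sample
#'   (from [sample_qc_metrics()]); a `cnv_cohort` is also accepted.
#' @param call_rate_min minimum call rate (exclusive), default 0.95.
#' @param sd_mult outlier multiplier, default 3.
#' @param reference optional list with fixed `lrr_sd_mean`, `lrr_sd_sd`,
#'   `baf_sd_mean`, `baf_sd_sd` reference statistics; when given, cohort
#'   statistics are not recomputed (useful for idempotent re-screening).
#' @return `metrics` with added `pass` (logical) and `reasons` (character)
#'   columns.
#' @export
sample_pass_filter <- function(metrics, call_rate_min = 0.95, sd_mult = 3,
                               reference = NULL) {
  if (inherits(metrics, "cnv_cohort"))
    metrics <- do.call(rbind, lapply(metrics$samples, sample_qc_metrics))
  if (nrow(metrics) < 2 && is.null(reference))
    stopf("cohort statistics undefined for a single-sample cohort")
  if (is.null(reference))
    reference <- list(
      lrr_sd_mean = mean(metrics$lrr_sd, na.rm = TRUE),
      lrr_sd_sd = stats::sd(metrics$lrr_sd, na.rm = TRUE),
      baf_sd_mean = mean(metrics$het_baf_sd, na.rm = TRUE),
      baf_sd_sd = stats::sd(metrics$het_baf_sd, na.rm = TRUE)
    )
  lrr_cut <- reference$lrr_sd_mean + sd_mult * reference$lrr_sd_sd
  baf_cut <- reference$baf_sd_mean + sd_mult * reference$baf_sd_sd
  reasons <- character(nrow(metrics))
  fail_lrr <- !is.na(metrics$lrr_sd) & metrics$lrr_sd > lrr_cut
  fail_baf <- !is.na(metrics$het_baf_sd) & metrics$het_baf_sd > baf_cut
  fail_cr <- metrics$call_rate <= call_rate_min
  add <- function(reasons, hit, tag)
    ifelse(hit, ifelse(nzchar(reasons), paste(reasons, tag, sep = ";"), tag),
           reasons)
  reasons <- add(reasons, fail_lrr, "lrr_sd")
  reasons <- add(reasons, fail_baf, "het_baf_sd")
  reasons <- add(reasons, fail_cr, "call_rate")
  metrics$pass <- !nzchar(reasons)
  metrics$reasons <- reasons
  attr(metrics, "reference") <- reference
  metrics
}

#' Hardy-Weinberg exact test p-value
#'
#' Exact (no mid-p) two-sided test: the p-value is the total probability,
#' under the conditional distribution of heterozygote counts given allele
#' counts, of all tables no more probable than the observed one. Computed
#' with the standard numerically-stable recurrence over heterozygote
#' counts. Monomorphic markers return 1 by convention.
#'
#' @param n_aa,n_ab,n_bb genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  rare <- min(n_a, n_b)
  if (rare == 0) return(1)
  # possible het counts share the parity of the rare allele count
  het_vals <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(het_vals))
  # start at the modal het count and apply the two-term recurrence
  mid <- round(rare * (2 * n - rare) / (2 * n))
  if (mid %% 2 != rare %% 2) mid <- mid + 1
  mid <- min(mid, rare)
  i_mid <- which(het_vals == mid)
  probs[i_mid] <- 1
  if (i_mid < length(het_vals)) {
    for (i in seq(i_mid, length(het_vals) - 1)) {
      h <- het_vals[i]
      hom_r <- (rare - h) / 2
      hom_c <- (2 * n - rare - h) / 2
      probs[i + 1] <- probs[i] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
    }
  }
  if (i_mid > 1) {
    for (i in seq(i_mid, 2)) {
      h <- het_vals[i]
      hom_r <- (rare - h) / 2
      hom_c <- (2 * n - rare - h) / 2
      probs[i - 1] <- probs[i] * h * (h - 1) /
        (4 * (hom_r + 1) * (hom_c + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[het_vals == n_ab]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}

#' Marker-level QC filter
#'
#' Applies, per marker: genotype call rate > `call_rate_min`;
#' Hardy-Weinberg exact p > `hwe_min`; and when sex labels are supplied,
#' sex-differential missingness (Fisher exact on a missing-by-sex table)
#' and sex-differential allele frequency (allele-count chi-square, Fisher
#' fallback at expected counts < 5), both requiring p > `sex_min`.
#'
#' @param genotypes character matrix, samples in rows, markers in columns
#'   (`AA`/`AB`/`BB`/`NC`).
#' @param sex optional character vector per sample (`male`/`female`).
#' @param call_rate_min default 0.95 (exclusive).
#' @param hwe_min default 1e-5 (exclusive).
#' @param sex_min default 1e-4 (exclusive).
#' @return data.frame per marker with the test values, `pass`, `reasons`.
#' @export
marker_pass_filter <- function(genotypes, sex = NULL,
                               call_rate_min = 0.95, hwe_min = 1e-5,
                               sex_min = 1e-4) {
  m <- ncol(genotypes)
  call_rate <- colMeans(genotypes != "NC")
  hwe_p <- vapply(seq_len(m), function(j) {
    g <- genotypes[, j]
    hwe_exact_p(sum(g == "AA"), sum(g == "AB"), sum(g == "BB"))
  }, numeric(1))
  sex_miss_p <- rep(NA_real_, m)
  sex_freq_p <- rep(NA_real_, m)
  if (!is.null(sex)) {
    is_m <- sex == "male"
    for (j in seq_len(m)) {
      g <- genotypes[, j]
      miss <- g == "NC"
      tab <- rbind(c(sum(miss & is_m), sum(!miss & is_m)),
                   c(sum(miss & !is_m), sum(!miss & !is_m)))
      sex_miss_p[j] <-
        if (sum(tab[, 1]) == 0) 1 else stats::fisher.test(tab)$p.value
      b_m <- 2 * sum(g == "BB" & is_m) + sum(g == "AB" & is_m)
      a_m <- 2 * sum(g == "AA" & is_m) + sum(g == "AB" & is_m)
      b_f <- 2 * sum(g == "BB" & !is_m) + sum(g == "AB" & !is_m)
      a_f <- 2 * sum(g == "AA" & !is_m) + sum(g == "AB" & !is_m)
      tab <- rbind(c(a_m, b_m), c(a_f, b_f))
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        sex_freq_p[j] <- 1
      } else {
        expct <- outer(rowSums(tab), colSums(tab)) / sum(tab)
        sex_freq_p[j] <- if (any(expct < 5))
          stats::fisher.test(tab)$p.value
        else suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      }
    }
  }
  reasons <- character(m)
  add <- function(reasons, hit, tag)
    ifelse(hit, ifelse(nzchar(reasons), paste(reasons, tag, sep = ";"), tag),
           reasons)
  reasons <- add(reasons, call_rate <= call_rate_min, "call_rate")
  reasons <- add(reasons, hwe_p <= hwe_min, "hwe")
  if (!is.null(sex)) {
    reasons <- add(reasons, sex_miss_p <= sex_min, "sex_missingness")
    reasons <- add(reasons, sex_freq_p <= sex_min, "sex_frequency")
  }
  data.frame(marker = colnames(genotypes) %||% seq_len(m),
             call_rate = call_rate, hwe_p = hwe_p,
             sex_miss_p = sex_miss_p, sex_freq_p = sex_freq_p,
             pass = !nzchar(reasons), reasons = reasons,
             stringsAsFactors = FALSE)
}

genotype_dosage <- function(genotypes) {
  d <- matrix(NA_real_, nrow(genotypes), ncol(genotypes))
  d[genotypes == "AA"] <- 0
  d[genotypes == "AB"] <- 1
  d[genotypes == "BB"] <- 2
  dimnames(d) <- dimnames(genotypes)
  d
}

#' LD pruning by pairwise genotypic r-squared
#'
#' Sliding windows of `window_snps` markers advanced by `step`; within each
#' window, for every retained pair whose squared genotype correlation
#' exceeds `r2_threshold`, the member with the lower minor-allele frequency
#' is removed (ties: the later marker). Pruning is applied within
#' chromosomes when a chromosome vector is given. The two conventional
#' presets are `r2_threshold = 0.2` (ancestry/relatedness marker prep) and
#' `0.3` (ROH prep).
#'
#' @param genotypes character matrix (samples x markers) or numeric dosage
#'   matrix (0/1/2).
#' @param window_snps,step window size and advance, defaults 50 and 5.
#' @param r2_threshold exclusive r-squared threshold in (0, 1).
#' @param chromosome optional chromosome label per marker.
#' @return logical vector: TRUE for retained markers.
#' @export
ld_prune <- function(genotypes, window_snps = 50, step = 5,
                     r2_threshold = 0.2, chromosome = NULL) {
  if (r2_threshold <= 0 || r2_threshold >= 1)
    stopf("r2_threshold must be in (0, 1)")
  d <- if (is.character(genotypes)) genotype_dosage(genotypes) else genotypes
  m <- ncol(d)
  keep <- rep(TRUE, m)
  maf <- apply(d, 2, function(x) {
    p <- mean(x, na.rm = TRUE) / 2
    min(p, 1 - p)
  })
  groups <- if (is.null(chromosome)) list(seq_len(m))
  else split(seq_len(m), chromosome)
  for (idx in groups) {
    if (length(idx) < 2) next
    starts <- seq(1, max(1, length(idx) - 1), by = step)
    for (s in starts) {
      win <- idx[s:min(s + window_snps - 1, length(idx))]
      win <- win[keep[win]]
      if (length(win) < 2) next
      cc <- suppressWarnings(stats::cor(d[, win, drop = FALSE],
                                        use = "pairwise.complete.obs"))
      cc[is.na(cc)] <- 0
      for (a in seq_len(length(win) - 1)) {
        if (!keep[win[a]]) next
        for (b in seq(a + 1, length(win))) {
          if (!keep[win[b]]) next
          if (cc[a, b]^2 > r2_threshold) {
            drop <- if (maf[win[a]] < maf[win[b]]) win[a] else win[b]
            keep[drop] <- FALSE
            if (drop == win[a]) break
          }
        }
      }
    }
  }
  keep
}

#' Method-of-moments relatedness (PI_HAT)
#'
#' Estimates the IBD-state probabilities P(IBD=0,1,2) for a sample pair
#' from observed identity-by-state counts and their expectations given
#' allele frequencies, then `pi_hat = P(IBD=2) + P(IBD=1)/2`. Negative
#' moment estimates are truncated to zero and the probabilities
#' renormalized, as in the conventional `--genome` implementation.
#'
#' @param g1,g2 genotype vectors (character `AA`/`AB`/`BB`/`NC` or dosage
#'   0/1/2 with NA).
#' @param allele_freqs B-allele frequency per marker.
#' @return list: `pi_hat`, `z0`, `z1`, `z2`, `ibs0`, `ibs1`, `ibs2`,
#'   `n_markers`.
#' @export
estimate_pi_hat <- function(g1, g2, allele_freqs) {
  to_dose <- function(g) {
    if (is.character(g)) c(AA = 0, AB = 1, BB = 2, NC = NA)[g] else g
  }
  d1 <- to_dose(g1); d2 <- to_dose(g2)
  ok <- !is.na(d1) & !is.na(d2) & allele_freqs > 0 & allele_freqs < 1
  if (!any(ok)) stopf("no overlapping non-missing markers")
  if (sum(ok) < 1000)
    warnf("only %d overlapping markers; PI_HAT estimate may be unstable",
          sum(ok))
  d1 <- d1[ok]; d2 <- d2[ok]; p <- allele_freqs[ok]; q <- 1 - p
  ibs <- 2 - abs(d1 - d2)
  ibs[(d1 == 0 & d2 == 2) | (d1 == 2 & d2 == 0)] <- 0
  n <- length(ibs)
  n0 <- sum(ibs == 0); n1 <- sum(ibs == 1); n2 <- sum(ibs == 2)

  e0_z0 <- sum(2 * p^2 * q^2)
  e1_z0 <- sum(4 * p^3 * q + 4 * p * q^3)
  e2_z0 <- sum(p^4 + q^4 + 4 * p^2 * q^2)
  e1_z1 <- sum(2 * p^2 * q + 2 * p * q^2)
  e2_z1 <- sum(p^3 + q^3 + p^2 * q + p * q^2)

  z0 <- n0 / e0_z0
  z1 <- (n1 - z0 * e1_z0) / e1_z1
  z2 <- (n2 - z0 * e2_z0 - z1 * e2_z1) / n
  z <- pmax(c(z0, z1, z2), 0)
  z <- z / sum(z)
  pi_hat <- clamp(z[3] + 0.5 * z[2], 0, 1)
  list(pi_hat = pi_hat, z0 = z[1], z1 = z[2], z2 = z[3],
       ibs0 = n0, ibs1 = n1, ibs2 = n2, n_markers = n)
}

#' Ancestry principal components
#'
#' Centers each marker at twice its sample allele frequency, scales by the
#' binomial SD `sqrt(2p(1-p))`, and decomposes the resulting matrix.
#' Missing genotypes are mean-imputed; monomorphic markers are dropped.
#'
#' @param genotypes character or dosage matrix, samples x markers
#'   (QC-passed, LD-pruned).
#' @param k number of components to return (reduced with a warning when
#'   larger than the available rank).
#' @return list: `scores` (samples x k), `var_explained` (length k).
#' @export
ancestry_pca <- function(genotypes, k = 10) {
  d <- if (is.character(genotypes)) genotype_dosage(genotypes) else genotypes
  p <- colMeans(d, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1 & !is.na(p)
  d <- d[, poly, drop = FALSE]; p <- p[poly]
  for (j in seq_len(ncol(d))) {
    miss <- is.na(d[, j])
    if (any(miss)) d[miss, j] <- 2 * p[j]
  }
  z <- sweep(d, 2, 2 * p)
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  max_k <- min(nrow(z) - 1, ncol(z))
  if (k > max_k) {
    warnf("reducing requested components from %d to %d", k, max_k)
    k <- max_k
  }
  sv <- svd(z, nu = k, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  rownames(scores) <- rownames(genotypes)
  list(scores = scores,
       var_explained = sv$d[seq_len(k)]^2 / sum(sv$d^2))
}

#' Sex-chromosome validation and aneuploidy screen
#'
#' Reports median LRR on X and Y and the X heterozygosity rate per sample,
#' and flags: sex-label discordance (female-like X signal with a male
#' label, or the reverse), depressed Y median LRR below `y_loss_threshold`
#' in males (partial/mosaic Y loss), and a split X heterozygous BAF band
#' (mosaic X aneuploidy).
#'
#' @param samples list of `intensity_sample`.
#' @param map the [marker_map] (must carry X and/or Y markers).
#' @param sex labelled sex per sample (`male`/`female`), recycled.
#' @param y_loss_threshold default -0.5.
#' @param x_split_sd BAF SD above which the X het band is called split,
#'   default 0.13.
#' @return data.frame per sample with medians, rates and `flags`.
#' @export
sex_aneuploidy_screen <- function(samples, map, sex,
                                  y_loss_threshold = -0.5,
                                  x_split_sd = 0.13) {
  on_x <- map$chromosome == "X"
  on_y <- map$chromosome == "Y"
  if (!any(on_x) && !any(on_y)) {
    warnf("no X/Y markers in map; sex screen skipped")
    return(NULL)
  }
  sex <- rep_len(sex, length(samples))
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    x_lrr <- stats::median(s$lrr[on_x], na.rm = TRUE)
    y_lrr <- if (any(on_y)) stats::median(s$lrr[on_y], na.rm = TRUE)
    else NA_real_
    gx <- s$genotype[on_x]
    x_het <- if (sum(gx != "NC")) mean(gx[gx != "NC"] == "AB") else NA_real_
    bafx <- s$baf[on_x]
    bafx <- bafx[!is.na(bafx) & bafx > 0.15 & bafx < 0.85]
    x_baf_sd <- if (length(bafx) >= 10) stats::sd(bafx) else NA_real_
    flags <- character(0)
    if (any(on_x) && !is.na(x_het)) {
      if (sex[i] == "male" && x_het > 0.1)
        flags <- c(flags, "sex_discordant")
      if (sex[i] == "female" && x_het < 0.02)
        flags <- c(flags, "sex_discordant")
    }
    if (sex[i] == "male" && !is.na(y_lrr) && y_lrr < y_loss_threshold)
      flags <- c(flags, "partial_y_loss")
    if (!is.na(x_baf_sd) && x_baf_sd > x_split_sd && x_het > 0.02)
      flags <- c(flags, "mosaic_x")
    data.frame(sample_id = s$sample_id, sex = sex[i],
               x_median_lrr = x_lrr, y_median_lrr = y_lrr,
               x_het_rate = x_het, x_het_baf_sd = x_baf_sd,
               flags = paste(flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
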
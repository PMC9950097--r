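#' Per-arm heterozygous-BAF dispersion statistics
#'
#' For every chromosomal arm, computes the standard deviation and
#' interquartile range of the B-allele frequencies of putative
#' heterozygotes (BAF strictly between 0.15 and 0.85). Arm-scale mosaic
#' events split the het band to 0.5 +/- d and inflate both statistics;
#' arms that are one long run of homozygosity have too few het markers and
#' are reported as absent.
#'
#' @param sample an `intensity_sample`.
#' @param map the [marker_map].
#' @param centromeres centromere table defining p/q arms.
#' @param min_het minimum heterozygous markers for an arm to be scored,
#'   default 50.
#' @return data.frame: `sample_id`, `chrom_arm`, `n_het_markers`,
#'   `baf_sd`, `baf_iqr` (NA below `min_het`).
#' @export
arm_baf_stats <- function(sample, map, centromeres, min_het = 50) {
  arms <- marker_arms(map, centromeres)
  het <- !is.na(sample$baf) & sample$baf > 0.15 & sample$baf < 0.85
  rows <- lapply(unique(arms), function(a) {
    b <- sample$baf[het & arms == a]
    data.frame(sample_id = sample$sample_id, chrom_arm = a,
               n_het_markers = length(b),
               baf_sd = if (length(b) >= min_het) stats::sd(b) else NA_real_,
               baf_iqr = if (length(b) >= min_het)
                 stats::IQR(b) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag mosaic-outlier arms across a cohort
#'
#' Robust bivariate outlier rule on the cloud of all scored arms: an arm
#' is flagged when its het-BAF SD or IQR exceeds the cohort median by more
#' than `k` median absolute deviations of that statistic. Arms with fewer
#' than the minimum het markers (near-total ROH arms) are excluded from
#' flagging; they form their own low-het cloud and are not mosaic.
#'
#' @param stats data.frame of per-arm statistics, rows pooled over samples
#'   (from [arm_baf_stats()]).
#' @param k MAD multiplier, default 5.
#' @param min_arms minimum scored arms needed to form a reference cloud,
#'   default 20.
#' @return `stats` with an added logical `outlier` column.
#' @export
flag_mosaic_outliers <- function(stats, k = 5, min_arms = 20) {
  scored <- !is.na(stats$baf_sd)
  if (sum(scored) < min_arms)
    stopf("need at least %d scored arms to form a reference cloud",
          min_arms)
  med_sd <- stats::median(stats$baf_sd[scored])
  mad_sd <- stats::mad(stats$baf_sd[scored])
  med_iqr <- stats::median(stats$baf_iqr[scored])
  mad_iqr <- stats::mad(stats$baf_iqr[scored])
  stats$outlier <- scored &
    (stats$baf_sd > med_sd + k * pmax(mad_sd, 1e-4) |
       stats$baf_iqr > med_iqr + k * pmax(mad_iqr, 1e-4))
  stats
}

#' Two-state BAF HMM for mosaic breakpoints
#'
#' Scans the heterozygous-band markers of one chromosome with a two-state
#' hidden Markov model on `y = |BAF - 0.5|`: the copy-neutral state emits
#' a half-Gaussian around 0 with SD `sigma`; the mosaic state emits a
#' Gaussian centred at a band deviation `d`, profiled over a grid (best
#' grid point by total Viterbi likelihood, then refined as the mean `y`
#' over the decoded mosaic run). Transitions use the same distance-decay
#' family as the CNV HMM. Runs of the mosaic state shorter than
#' `min_markers` are discarded; breakpoints are the outermost het markers
#' of the run. Direction is taken from the sign of the mean LRR over the
#' event, with a dead zone below `lrr_dead_zone` reported as `unknown`.
#'
#' @param sample an `intensity_sample`.
#' @param map the [marker_map].
#' @param chromosome chromosome to scan.
#' @param sigma het-band BAF noise SD; estimated from the sample's
#'   genome-wide het band (robustly) when NULL.
#' @param d_grid candidate band deviations, default `seq(0.02, 0.30, 0.01)`.
#' @param min_markers minimum het markers in a mosaic run, default 25.
#' @param prior_mosaic prior weight of the mosaic state, default 0.01.
#' @param distance_scale_bp,rho_max distance-decay transition family as in
#'   the CNV HMM, with stickier defaults (D = 1 Mb, rho_max = 0.2) because
#'   the targets are arm-scale events.
#' @param lrr_dead_zone |mean LRR| below this gives direction "unknown",
#'   default 0.02.
#' @param refine_max_gap_bp boundary refinement never crosses an inter-het
#'   gap larger than this (keeps runs from jumping the centromere),
#'   default 1 Mb.
#' @return data.frame of mosaic events: `sample_id`, `chromosome`,
#'   `start_bp`, `end_bp`, `n_het_markers`, `band_deviation`, `direction`,
#'   `cell_fraction_estimate` (rows may be empty).
#' @export
mosaic_baf_hmm <- function(sample, map, chromosome, sigma = NULL,
                           d_grid = seq(0.02, 0.30, by = 0.01),
                           min_markers = 25, prior_mosaic = 0.01,
                           distance_scale_bp = 1e6, rho_max = 0.2,
                           lrr_dead_zone = 0.02,
                           refine_max_gap_bp = 1e6) {
  chromosome <- sub("^chr", "", as.character(chromosome))
  het <- which(map$chromosome == chromosome & !is.na(sample$baf) &
                 sample$baf > 0.15 & sample$baf < 0.85 &
                 sample$genotype != "NC")
  empty <- data.frame(sample_id = character(0), chromosome = character(0),
                      start_bp = integer(0), end_bp = integer(0),
                      n_het_markers = integer(0),
                      band_deviation = numeric(0), direction = character(0),
                      cell_fraction_estimate = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(het) < min_markers) return(empty)
  y <- abs(sample$baf[het] - 0.5)
  if (is.null(sigma)) {
    # estimate het-band noise away from the scanned chromosome so a large
    # event cannot inflate its own null SD; fall back to a low quantile of
    # the folded values (25th pct of a half-Gaussian = 0.319 sigma)
    off <- !is.na(sample$baf) & sample$baf > 0.15 & sample$baf < 0.85 &
      sample$genotype != "NC" & map$chromosome != chromosome
    if (sum(off) >= 200) {
      sigma <- stats::mad(sample$baf[off], center = 0.5)
    } else {
      sigma <- stats::quantile(y, 0.25, names = FALSE) / 0.3186
    }
    sigma <- max(min(sigma, 0.1), 0.005)
  }
  pos <- map$position_bp[het]
  priors <- c(1 - prior_mosaic, prior_mosaic)
  # folded-Gaussian emissions: y = |BAF - 0.5| folds the two split bands
  ll_n <- log(2) + stats::dnorm(y, 0, sigma, log = TRUE)

  best <- NULL
  for (d in d_grid) {
    ll_m <- log(stats::dnorm(y, d, sigma) + stats::dnorm(y, -d, sigma))
    path <- viterbi_decode(cbind(ll_n, ll_m), log(priors), diff(pos),
                           priors, rho_max, distance_scale_bp)
    lp <- attr(path, "log_prob")
    if (is.null(best) || lp > best$lp)
      best <- list(d = d, path = path, lp = lp)
  }
  state <- as.integer(best$path)
  # bridge short neutral interruptions inside one mosaic stretch
  r0 <- rle(state)
  if (length(r0$values) > 2) {
    e0 <- cumsum(r0$lengths)
    s0 <- e0 - r0$lengths + 1
    for (k in seq_along(r0$values)) {
      if (r0$values[k] == 1L && r0$lengths[k] < min_markers &&
          k > 1 && k < length(r0$values))
        state[s0[k]:e0[k]] <- 2L
    }
  }
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  rows <- list()
  for (k in seq_along(r$values)) {
    if (r$values[k] != 2L || r$lengths[k] < min_markers) next
    run <- starts[k]:ends[k]
    d_hat <- mean(y[run])
    # refine boundaries: sticky transitions bias Viterbi towards late
    # entry/early exit, so re-anchor the run at the maximum-sum interval
    # of the per-marker log-likelihood ratio through the run's core,
    # iterating with the re-estimated band deviation until stable
    s_new <- starts[k]; e_new <- ends[k]
    # refinement may not cross large het-free gaps (e.g. the centromere)
    gaps <- diff(pos)
    lo_lim <- s_new
    while (lo_lim > 1 && gaps[lo_lim - 1] <= refine_max_gap_bp)
      lo_lim <- lo_lim - 1
    hi_lim <- e_new
    while (hi_lim < length(pos) && gaps[hi_lim] <= refine_max_gap_bp)
      hi_lim <- hi_lim + 1
    for (it in 1:3) {
      llr <- log(stats::dnorm(y, d_hat, sigma) +
                   stats::dnorm(y, -d_hat, sigma)) -
        (log(2) + stats::dnorm(y, 0, sigma, log = TRUE))
      mid <- (s_new + e_new) %/% 2
      left <- rev(cumsum(rev(llr[lo_lim:mid])))
      s_prev <- s_new; e_prev <- e_new
      s_new <- lo_lim + which.max(left) - 1
      right <- cumsum(llr[mid:hi_lim])
      e_new <- mid + which.max(right) - 1
      d_hat <- mean(y[s_new:e_new])
      if (s_new == s_prev && e_new == e_prev) break
    }
    run <- s_new:e_new
    lo <- run[1]; hi <- run[length(run)]
    in_ev <- map$chromosome == chromosome &
      map$position_bp >= pos[lo] & map$position_bp <= pos[hi]
    mean_lrr <- mean(sample$lrr[in_ev], na.rm = TRUE)
    direction <- if (is.na(mean_lrr) || abs(mean_lrr) < lrr_dead_zone)
      "unknown" else if (mean_lrr > 0) "gain" else "loss"
    frac <- estimate_mosaic_fraction(d_hat, direction)
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = sample$sample_id, chromosome = chromosome,
      start_bp = pos[lo], end_bp = pos[hi],
      n_het_markers = length(run), band_deviation = d_hat,
      direction = direction,
      cell_fraction_estimate = frac$cell_fraction,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cell fraction from a BAF band deviation
#'
#' Standard BAF-mixture algebra: a mosaic loss in a cell fraction `f`
#' moves the het band to `0.5 +/- d` with `d = f/2 / (2 - f)`, a gain
#' with `d = f/2 / (2 + f)`, and copy-neutral LOH with `d = f/2`.
#' Inverting: loss `f = 4d / (1 + 2d)`; gain `f = 4d / (1 - 2d)` (capped
#' at 1); copy-neutral `f = 2d`. With unknown direction all three are
#' reported and the loss/gain bracket returned as the point estimate
#' midpoint.
#'
#' @param d band deviation in (0, 0.35); values >= 0.5 are rejected.
#' @param direction `"loss"`, `"gain"`, `"neutral"` or `"unknown"`.
#' @return list: `cell_fraction` (point estimate), `by_direction`
#'   (named vector of the candidate fractions).
#' @export
estimate_mosaic_fraction <- function(d, direction = c("unknown", "loss",
                                                      "gain", "neutral")) {
  direction <- match.arg(direction)
  if (d < 0 || d >= 0.5) stopf("band deviation d must be in [0, 0.5)")
  f_loss <- min(1, 4 * d / (1 + 2 * d))
  f_gain <- min(1, 4 * d / (1 - 2 * d))
  f_neut <- min(1, 2 * d)
  by_dir <- c(loss = f_loss, gain = f_gain, neutral = f_neut)
  f <- switch(direction, loss = f_loss, gain = f_gain, neutral = f_neut,
              unknown = (f_loss + f_gain) / 2)
  list(cell_fraction = f, by_direction = by_dir)
}

#' Cohort-wide mosaic screen
#'
#' Computes per-arm BAF dispersion statistics for every sample, flags
#' outlier arms against the cohort cloud, and runs the two-state BAF HMM
#' on each flagged arm's chromosome to localize the event.
#'
#' @param cohort a `cnv_cohort`.
#' @param centromeres centromere table.
#' @param k MAD multiplier for [flag_mosaic_outliers()].
#' @param sigma het-band noise SD passed to the BAF HMM; by default the
#'   median het-BAF SD over the cohort's non-outlier arms.
#' @param ... passed to [mosaic_baf_hmm()].
#' @return list: `arm_stats` (all arms, with `outlier`), `events`
#'   (localized mosaic events).
#' @export
mosaic_screen <- function(cohort, centromeres, k = 5, sigma = NULL, ...) {
  stats <- do.call(rbind, lapply(cohort$samples, arm_baf_stats,
                                 map = cohort$map,
                                 centromeres = centromeres))
  stats <- flag_mosaic_outliers(stats, k = k)
  if (is.null(sigma)) {
    neutral <- !is.na(stats$baf_sd) & !stats$outlier
    if (any(neutral)) sigma <- stats::median(stats$baf_sd[neutral])
  }
  flagged <- stats[stats$outlier, , drop = FALSE]
  events <- list()
  for (i in seq_len(nrow(flagged))) {
    chr <- sub("[pq]$", "", flagged$chrom_arm[i])
    ev <- mosaic_baf_hmm(cohort$samples[[flagged$sample_id[i]]],
                         cohort$map, chr, sigma = sigma, ...)
    if (nrow(ev)) events[[length(events) + 1]] <- ev
  }
  events <- if (length(events)) unique(do.call(rbind, events))
  else data.frame()
  list(arm_stats = stats, events = events)
}
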
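#' HMM parameters for CNV calling
#'
#' The six canonical hidden states are CN0 (homozygous deletion), CN1
#' (hemizygous deletion), CN2 (diploid reference), CN2-LOH (copy-neutral
#' loss of heterozygosity), CN3 and CN4 (duplications). Each state carries
#' a Gaussian LRR emission (mean/SD) and a BAF cluster mixture whose
#' cluster means follow the state's allele count and whose weights follow
#' Hardy-Weinberg proportions at the marker's population B-allele
#' frequency. Transitions decay with inter-marker distance:
#' `rho(d) = rho_max * (1 - exp(-d / distance_scale_bp))`, with the
#' off-diagonal entry i->j equal to `prior_j * rho(d)`.
#'
#' @param lrr_mean,lrr_sd named per-state vectors.
#' @param baf_sd Gaussian SD around each BAF cluster mean.
#' @param outlier_weight weight of the Uniform(0,1) BAF outlier component.
#' @param state_priors named per-state prior weights (normalized).
#' @param distance_scale_bp transition decay length D, default 100 kb.
#' @param rho_max asymptotic switch probability scale, default 0.5.
#' @return list of class `hmm_params`.
#' @export
hmm_params <- function(lrr_mean = lrr_state_means(),
                       lrr_sd = c(CN0 = 1.0, CN1 = 0.25, CN2 = 0.2,
                                  `CN2-LOH` = 0.2, CN3 = 0.25, CN4 = 0.3),
                       baf_sd = 0.03, outlier_weight = 0.01,
                       state_priors = c(CN0 = 1e-4, CN1 = 1e-3, CN2 = 0.995,
                                        `CN2-LOH` = 1e-3, CN3 = 1e-3,
                                        CN4 = 1e-4),
                       distance_scale_bp = 1e5, rho_max = 0.5) {
  states <- c("CN0", "CN1", "CN2", "CN2-LOH", "CN3", "CN4")
  stopifnot(all(states %in% names(lrr_mean)),
            all(states %in% names(lrr_sd)),
            all(states %in% names(state_priors)))
  if (any(lrr_sd <= 0)) stopf("lrr_sd must be positive")
  structure(list(states = states,
                 copy_number = c(CN0 = 0L, CN1 = 1L, CN2 = 2L,
                                 `CN2-LOH` = 2L, CN3 = 3L, CN4 = 4L),
                 lrr_mean = lrr_mean[states], lrr_sd = lrr_sd[states],
                 baf_sd = baf_sd, outlier_weight = outlier_weight,
                 state_priors = state_priors[states] / sum(state_priors[states]),
                 distance_scale_bp = distance_scale_bp,
                 rho_max = rho_max),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("<hmm_params> 6-state LRR/BAF model\n")
  print(data.frame(state = x$states, lrr_mean = x$lrr_mean,
                   lrr_sd = x$lrr_sd, prior = x$state_priors,
                   row.names = NULL))
  cat(sprintf("distance scale D = %g bp, rho_max = %g, baf_sd = %g\n",
              x$distance_scale_bp, x$rho_max, x$baf_sd))
  invisible(x)
}

# BAF cluster means and HWE weights per state for one pfb value p
state_baf_clusters <- function(state, p) {
  switch(state,
         CN0 = NULL,  # no genotype signal: uniform BAF
         CN1 = list(mean = c(0, 1), w = c(1 - p, p)),
         CN2 = list(mean = c(0, 0.5, 1),
                    w = c((1 - p)^2, 2 * p * (1 - p), p^2)),
         `CN2-LOH` = list(mean = c(0, 1), w = c(1 - p, p)),
         CN3 = list(mean = c(0, 1 / 3, 2 / 3, 1),
                    w = stats::dbinom(0:3, 3, p)),
         CN4 = list(mean = (0:4) / 4, w = stats::dbinom(0:4, 4, p)))
}

# censored-Gaussian BAF density of one cluster, vectorized over markers:
# interior values use the Gaussian density, values clamped at exactly 0 or
# 1 use the censored tail mass
cluster_baf_density <- function(baf, mu, sd) {
  dens <- stats::dnorm(baf, mu, sd)
  at0 <- !is.na(baf) & baf == 0
  at1 <- !is.na(baf) & baf == 1
  dens[at0] <- stats::pnorm(0, mu, sd)
  dens[at1] <- stats::pnorm(1, mu, sd, lower.tail = FALSE)
  dens
}

#' Joint LRR+BAF emission log-likelihood of one state
#'
#' Sum of the Gaussian LRR log-density at the state's mean/SD and the log
#' of the state's BAF mixture: Hardy-Weinberg-weighted clusters adapted to
#' the state's allele count (CN1 and CN2-LOH have clusters at 0 and 1 only;
#' CN3 adds bands at 1/3 and 2/3; CN0 is uniform), each a censored
#' Gaussian, plus a Uniform(0,1) outlier component.
#'
#' @param state one of `CN0`, `CN1`, `CN2`, `CN2-LOH`, `CN3`, `CN4`.
#' @param lrr,baf,pfb aligned numeric vectors.
#' @param params an [hmm_params()].
#' @return per-marker log-likelihood vector.
#' @export
emission_loglik <- function(state, lrr, baf, pfb, params = hmm_params()) {
  state <- match.arg(state, params$states)
  ll_lrr <- stats::dnorm(lrr, params$lrr_mean[state],
                         params$lrr_sd[state], log = TRUE)
  w_out <- params$outlier_weight
  if (state == "CN0") {
    mix <- rep(1, length(baf))  # uniform on [0,1]
  } else {
    cluster_means <- state_baf_clusters(state, pfb[1])$mean
    mix <- rep(0, length(baf))
    for (k in seq_along(cluster_means)) {
      wk <- weight_for_cluster(state, pfb, k)
      mix <- mix + wk * cluster_baf_density(baf, cluster_means[k],
                                            params$baf_sd)
    }
  }
  ll_baf <- log((1 - w_out) * mix + w_out * 1)
  ll_lrr + ll_baf
}

# vectorized HWE weight of cluster k for a state across pfb values
weight_for_cluster <- function(state, p, k) {
  switch(state,
         CN1 = cbind(1 - p, p)[, k],
         `CN2-LOH` = cbind(1 - p, p)[, k],
         CN2 = cbind((1 - p)^2, 2 * p * (1 - p), p^2)[, k],
         CN3 = stats::dbinom(k - 1, 3, p),
         CN4 = stats::dbinom(k - 1, 4, p))
}

# n x 6 emission log-likelihood matrix
emission_matrix <- function(lrr, baf, pfb, params) {
  vapply(params$states,
         function(s) emission_loglik(s, lrr, baf, pfb, params),
         numeric(length(lrr)))
}

#' Distance-dependent transition matrix
#'
#' Off-diagonal i->j entry is `prior_j * rho(d)` with
#' `rho(d) = rho_max * (1 - exp(-d / D))`; the diagonal takes the
#' remainder so each row sums to one. At `d = 0` the matrix is the
#' identity; as `d` grows the off-diagonal entries approach the state
#' priors scaled by `rho_max`.
#'
#' @param distance_bp inter-marker distance in bp (>= 0).
#' @param params an [hmm_params()].
#' @return 6 x 6 row-stochastic matrix.
#' @export
transition_matrix <- function(distance_bp, params = hmm_params()) {
  if (distance_bp < 0) stopf("distance_bp must be >= 0")
  s <- length(params$states)
  rho <- params$rho_max * (1 - exp(-distance_bp / params$distance_scale_bp))
  tm <- matrix(rep(params$state_priors * rho, each = s), s, s)
  diag(tm) <- 0
  diag(tm) <- 1 - rowSums(tm)
  dimnames(tm) <- list(params$states, params$states)
  tm
}

#' Viterbi decoding under the distance-decay transition family
#'
#' Generic most-probable-path decoder shared by the CNV and mosaic HMMs.
#' Transitions between consecutive markers follow
#' `off-diagonal i->j = prior_j * rho_max * (1 - exp(-d / D))` with the
#' diagonal taking the remainder.
#'
#' @param log_emit n x S matrix of per-marker, per-state emission
#'   log-likelihoods.
#' @param log_init length-S initial state log-probabilities.
#' @param distances length n-1 inter-marker distances in bp.
#' @param priors state prior weights.
#' @param rho_max,distance_scale_bp transition decay parameters.
#' @return integer state-index path of length n with attribute
#'   `log_prob`, the log-probability of the best path.
#' @export
viterbi_decode <- function(log_emit, log_init, distances, priors, rho_max,
                           distance_scale_bp) {
  n <- nrow(log_emit)
  s <- ncol(log_emit)
  psi <- matrix(0L, n, s)
  delta <- log_init + log_emit[1, ]
  if (n > 1) {
    rho <- rho_max * (1 - exp(-distances / distance_scale_bp))
    for (t in 2:n) {
      off <- matrix(rep(priors * rho[t - 1], each = s), s, s)
      diag(off) <- 0
      dg <- 1 - rowSums(off)
      logT <- log(off)
      diag(logT) <- log(dg)
      cand <- delta + logT            # [i, j] = delta_i + logT[i, j]
      best <- max.col(t(cand), ties.method = "first")
      psi[t, ] <- best
      delta <- cand[cbind(best, seq_len(s))] + log_emit[t, ]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  if (n > 1) for (t in seq(n, 2)) path[t - 1] <- psi[t, path[t]]
  attr(path, "log_prob") <- max(delta)
  path
}

#' Viterbi segmentation of one sample
#'
#' Decodes the most probable copy-number state path per autosome and emits
#' maximal runs of non-diploid states as raw segments. Segment boundaries
#' are the outermost probe positions of the run.
#'
#' @param sample an `intensity_sample` (LRR already corrected).
#' @param map the [marker_map].
#' @param params an [hmm_params()].
#' @param chromosomes chromosomes to decode; defaults to the autosomes
#'   present in the map.
#' @return data.frame of raw segments: `sample_id`, `chromosome`,
#'   `start_bp`, `end_bp`, `state`, `copy_number`, `n_probes`,
#'   `start_idx`, `end_idx` (global marker indices).
#' @export
viterbi_segments <- function(sample, map, params = hmm_params(),
                             chromosomes = NULL) {
  if (is.null(chromosomes))
    chromosomes <- unique(map$chromosome[is_autosome(map$chromosome)])
  segs <- list()
  for (chr in chromosomes) {
    idx <- which(map$chromosome == chr)
    ok <- idx[!is.na(sample$lrr[idx]) & !is.na(sample$baf[idx])]
    if (length(ok) < 2) {
      warnf("chromosome %s has < 2 usable markers; skipped", chr)
      next
    }
    le <- emission_matrix(sample$lrr[ok], sample$baf[ok], map$pfb[ok],
                          params)
    path <- viterbi_decode(le, log(params$state_priors),
                           diff(map$position_bp[ok]),
                           params$state_priors, params$rho_max,
                           params$distance_scale_bp)
    r <- rle(as.integer(path))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in seq_along(r$values)) {
      st <- params$states[r$values[k]]
      if (st == "CN2") next
      i0 <- ok[starts[k]]; i1 <- ok[ends[k]]
      segs[[length(segs) + 1]] <- data.frame(
        sample_id = sample$sample_id, chromosome = chr,
        start_bp = map$position_bp[i0], end_bp = map$position_bp[i1],
        state = st, copy_number = unname(params$copy_number[st]),
        n_probes = r$lengths[k], start_idx = i0, end_idx = i1,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(segs)) return(empty_calls())
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

# re-anchor segment boundaries at the maximum-sum interval of the
# per-probe emission log-likelihood ratio (state vs CN2) through the
# segment core; the sticky transition penalty otherwise trims edge probes
refine_segment_boundaries <- function(segs, sample, map, params,
                                      window = 20L) {
  if (!nrow(segs)) return(segs)
  segs <- segs[order(segs$chromosome, segs$start_bp), , drop = FALSE]
  for (i in seq_len(nrow(segs))) {
    chr <- segs$chromosome[i]
    on_chr <- which(map$chromosome == chr & !is.na(sample$lrr) &
                      !is.na(sample$baf))
    s_pos <- match(segs$start_idx[i], on_chr)
    e_pos <- match(segs$end_idx[i], on_chr)
    if (is.na(s_pos) || is.na(e_pos)) next
    lo_lim <- max(1, s_pos - window)
    hi_lim <- min(length(on_chr), e_pos + window)
    # never cross a neighbouring segment on the same chromosome
    if (i > 1 && segs$chromosome[i - 1] == chr) {
      prev_end <- match(segs$end_idx[i - 1], on_chr)
      if (!is.na(prev_end)) lo_lim <- max(lo_lim, prev_end + 1)
    }
    if (i < nrow(segs) && segs$chromosome[i + 1] == chr) {
      nxt_start <- match(segs$start_idx[i + 1], on_chr)
      if (!is.na(nxt_start)) hi_lim <- min(hi_lim, nxt_start - 1)
    }
    idx <- on_chr[lo_lim:hi_lim]
    llr <- emission_loglik(segs$state[i], sample$lrr[idx], sample$baf[idx],
                           map$pfb[idx], params) -
      emission_loglik("CN2", sample$lrr[idx], sample$baf[idx],
                      map$pfb[idx], params)
    mid <- ((s_pos + e_pos) %/% 2) - lo_lim + 1
    left <- rev(cumsum(rev(llr[1:mid])))
    s_new <- which.max(left)
    right <- cumsum(llr[mid:length(llr)])
    e_new <- mid + which.max(right) - 1
    segs$start_idx[i] <- idx[s_new]
    segs$end_idx[i] <- idx[e_new]
    segs$start_bp[i] <- map$position_bp[idx[s_new]]
    segs$end_bp[i] <- map$position_bp[idx[e_new]]
    segs$n_probes[i] <- sum(map$chromosome == chr &
                              map$position_bp >= segs$start_bp[i] &
                              map$position_bp <= segs$end_bp[i])
  }
  segs
}

empty_calls <- function() {
  data.frame(sample_id = character(0), chromosome = character(0),
             start_bp = integer(0), end_bp = integer(0),
             state = character(0), copy_number = integer(0),
             n_probes = integer(0), start_idx = integer(0),
             end_idx = integer(0), confidence = numeric(0),
             stringsAsFactors = FALSE)
}

#' Bayes-factor confidence of a segment
#'
#' log10 likelihood ratio, over the segment's probes, of the called
#' state's emissions versus the diploid (CN2) emissions. Emission-only:
#' transition terms do not enter.
#'
#' @param segment one row of a segment data.frame (needs `state`,
#'   `start_idx`, `end_idx`).
#' @param sample the `intensity_sample` the segment came from.
#' @param map the [marker_map].
#' @param params an [hmm_params()].
#' @return numeric log10 Bayes factor.
#' @export
bayes_factor <- function(segment, sample, map, params = hmm_params()) {
  idx <- seq(segment$start_idx, segment$end_idx)
  idx <- idx[map$chromosome[idx] == segment$chromosome &
               !is.na(sample$lrr[idx]) & !is.na(sample$baf[idx])]
  ll_state <- emission_loglik(segment$state, sample$lrr[idx],
                              sample$baf[idx], map$pfb[idx], params)
  ll_ref <- emission_loglik("CN2", sample$lrr[idx], sample$baf[idx],
                            map$pfb[idx], params)
  sum(ll_state - ll_ref) / log(10)
}

add_confidence <- function(calls, sample, map, params) {
  if (!nrow(calls)) {
    calls$confidence <- numeric(0)
    return(calls)
  }
  calls$confidence <- vapply(seq_len(nrow(calls)), function(i)
    bayes_factor(calls[i, ], sample, map, params), numeric(1))
  calls
}

#' Probe-count and confidence filtering of CNV calls
#'
#' Keeps homozygous deletions (CN0) with at least `min_probes_homdel`
#' probes, other CNV states with at least `min_probes_other` probes, and
#' only calls with Bayes-factor confidence of at least `min_confidence`.
#' Copy-neutral LOH segments are excluded from the CNV list (they belong
#' to the ROH context).
#'
#' @param calls segment data.frame with `confidence`.
#' @param min_probes_homdel default 3.
#' @param min_probes_other default 15.
#' @param min_confidence default 10.
#' @return filtered data.frame.
#' @export
filter_calls <- function(calls, min_probes_homdel = 3,
                         min_probes_other = 15, min_confidence = 10) {
  if (!nrow(calls)) return(calls)
  keep <- calls$state != "CN2-LOH" &
    calls$confidence >= min_confidence &
    ifelse(calls$copy_number == 0,
           calls$n_probes >= min_probes_homdel,
           calls$n_probes >= min_probes_other)
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge adjacent same-copy-number calls
#'
#' Two neighbouring calls of one sample on one chromosome are merged when
#' they have the same copy number and the gap between them (probe boundary
#' to probe boundary) is strictly less than 20 percent of the smaller
#' call's length. Probe counts are recounted from the map over the merged
#' span and confidence is recomputed; merging iterates to a fixed point.
#'
#' @param calls calls for one sample (any chromosomes), non-overlapping.
#' @param sample,map,params needed to recount probes and recompute
#'   confidence.
#' @param max_gap_frac default 0.2 (strict `<`).
#' @return merged calls.
#' @export
merge_adjacent <- function(calls, sample, map, params = hmm_params(),
                           max_gap_frac = 0.2) {
  if (nrow(calls) < 2) return(calls)
  out <- list()
  for (chr in unique(calls$chromosome)) {
    cc <- calls[calls$chromosome == chr, , drop = FALSE]
    cc <- cc[order(cc$start_bp), , drop = FALSE]
    if (any(cc$start_bp[-1] <= cc$end_bp[-nrow(cc)]))
      stopf("overlapping calls on chromosome %s (upstream bug)", chr)
    repeat {
      merged_any <- FALSE
      i <- 1
      while (i < nrow(cc)) {
        gap <- cc$start_bp[i + 1] - cc$end_bp[i] - 1
        len_i <- cc$end_bp[i] - cc$start_bp[i] + 1
        len_j <- cc$end_bp[i + 1] - cc$start_bp[i + 1] + 1
        if (cc$copy_number[i + 1] == cc$copy_number[i] &&
            cc$state[i + 1] == cc$state[i] &&
            gap < max_gap_frac * min(len_i, len_j)) {
          cc$end_bp[i] <- cc$end_bp[i + 1]
          cc$end_idx[i] <- cc$end_idx[i + 1]
          cc$n_probes[i] <- sum(map$chromosome == chr &
                                  map$position_bp >= cc$start_bp[i] &
                                  map$position_bp <= cc$end_bp[i])
          cc <- cc[-(i + 1), , drop = FALSE]
          cc$confidence[i] <- bayes_factor(cc[i, ], sample, map, params)
          merged_any <- TRUE
        } else i <- i + 1
      }
      if (!merged_any) break
    }
    out[[chr]] <- cc
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Split calls spanning a centromere
#'
#' A call overlapping a centromeric interval is split into two calls, the
#' first ending at the last probe before the centromere and the second
#' beginning at the first probe after it. Probe counts and confidences are
#' recomputed; a resulting side that fails the probe-count or confidence
#' minima is dropped, as is a call entirely inside the probe-free gap.
#'
#' @param calls calls for one sample.
#' @param centromeres data.frame (chromosome, start_bp, end_bp).
#' @param sample,map,params for recomputation.
#' @param min_probes_homdel,min_probes_other,min_confidence as in
#'   [filter_calls()].
#' @return calls with no centromere-spanning entries.
#' @export
split_at_centromere <- function(calls, centromeres, sample, map,
                                params = hmm_params(),
                                min_probes_homdel = 3,
                                min_probes_other = 15,
                                min_confidence = 10) {
  if (!nrow(calls)) return(calls)
  rows <- list()
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, , drop = FALSE]
    cen <- centromeres[sub("^chr", "", centromeres$chromosome) ==
                         cl$chromosome, , drop = FALSE]
    if (!nrow(cen) || cl$end_bp < cen$start_bp[1] ||
        cl$start_bp > cen$end_bp[1]) {
      rows[[length(rows) + 1]] <- cl
      next
    }
    cen <- cen[1, ]
    on_chr <- map$chromosome == cl$chromosome
    left_idx <- which(on_chr & map$position_bp >= cl$start_bp &
                        map$position_bp < cen$start_bp)
    right_idx <- which(on_chr & map$position_bp > cen$end_bp &
                         map$position_bp <= cl$end_bp)
    if (!length(left_idx) && !length(right_idx)) {
      warnf("call %s:%d-%d lies entirely inside the centromeric gap; dropped",
            cl$chromosome, cl$start_bp, cl$end_bp)
      next
    }
    for (side in list(left_idx, right_idx)) {
      if (!length(side)) next
      piece <- cl
      piece$start_bp <- map$position_bp[min(side)]
      piece$end_bp <- map$position_bp[max(side)]
      piece$start_idx <- min(side)
      piece$end_idx <- max(side)
      piece$n_probes <- length(side)
      piece$confidence <- bayes_factor(piece, sample, map, params)
      min_p <- if (piece$copy_number == 0) min_probes_homdel
      else min_probes_other
      if (piece$n_probes >= min_p && piece$confidence >= min_confidence)
        rows[[length(rows) + 1]] <- piece
    }
  }
  if (!length(rows)) return(empty_calls())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full CNV-calling pipeline for one sample
#'
#' Viterbi segmentation, Bayes-factor confidence, probe-count and
#' confidence filtering, adjacent-call merging, and centromere splitting,
#' in that order.
#'
#' @param sample an `intensity_sample` with corrected LRR.
#' @param map the [marker_map].
#' @param params an [hmm_params()].
#' @param centromeres optional centromere table; when NULL no splitting is
#'   performed.
#' @param ... filtering thresholds passed to [filter_calls()].
#' @return data.frame of CNV calls.
#' @export
call_cnvs <- function(sample, map, params = hmm_params(),
                      centromeres = NULL, ...) {
  raw <- viterbi_segments(sample, map, params)
  raw <- refine_segment_boundaries(raw, sample, map, params)
  raw <- add_confidence(raw, sample, map, params)
  calls <- filter_calls(raw, ...)
  if (nrow(calls) > 1) calls <- merge_adjacent(calls, sample, map, params)
  if (!is.null(centromeres))
    calls <- split_at_centromere(calls, centromeres, sample, map, params)
  calls
}

#' Call CNVs for every sample in a cohort
#'
#' @param cohort a `cnv_cohort` (run [correct_intensities()] first).
#' @param params,centromeres,... passed to [call_cnvs()].
#' @return combined data.frame of calls across samples.
#' @export
call_cnvs_cohort <- function(cohort, params = hmm_params(),
                             centromeres = NULL, ...) {
  res <- lapply(cohort$samples, call_cnvs, map = cohort$map,
                params = params, centromeres = centromeres, ...)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (is.null(out)) empty_calls() else out
}
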
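# shared fixtures, built in code

clamp_test <- function(x, lo = 0.02, hi = 0.98) pmin(pmax(x, lo), hi)

# band deviation implied by a mosaic change, from the mixture algebra
mosaic_band_deviation_test <- function(f, change) {
  if (change < 0) 0.5 * f / (2 - f)
  else if (change > 0) 0.5 * f / (2 + f)
  else f / 2
}

# Hardy-Weinberg genotype draw used when a test builds signals by hand
simulate_genotypes_test <- function(pfb) {
  u <- runif(length(pfb))
  p_aa <- (1 - pfb)^2
  p_ab <- 2 * pfb * (1 - pfb)
  ifelse(u < p_aa, "AA", ifelse(u < p_aa + p_ab, "AB", "BB"))
}

# evenly spaced deterministic map: spacing_bp between markers, constant pfb
uniform_map <- function(n, chrom = "1", spacing_bp = 10000, pfb = 0.5,
                        gc = 0.5, start_bp = spacing_bp) {
  marker_map(sprintf("m%s_%04d", chrom, seq_len(n)),
             rep(chrom, n),
             seq(start_bp, by = spacing_bp, length.out = n),
             pfb = rep_len(pfb, n), gc_frac = rep_len(gc, n))
}

# quiet noise model: no GC wave or batch structure unless a test plants one
quiet_noise <- function(lrr_sd = 0.2, baf_sd = 0.03, outlier_rate = 0) {
  noise_model(lrr_sd = lrr_sd, baf_sd = baf_sd,
              outlier_rate = max(outlier_rate, 1e-9),
              gc_wave_amplitude = 0, batch_shift_sd = 1e-9)
}

# hand-built intensity sample on a uniform map
flat_sample <- function(id, n, lrr = 0, baf = NULL, genotype = NULL) {
  if (is.null(genotype)) genotype <- rep("AB", n)
  if (is.null(baf))
    baf <- c(AA = 0, AB = 0.5, BB = 1, NC = 0.5)[genotype]
  intensity_sample(id, rep_len(lrr, n), baf, genotype)
}

# brute-force HWE exact p by full enumeration with log-multinomials
hwe_enum_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  na <- 2 * n_aa + n_ab
  if (na == 0 || na == 2 * n) return(1)
  hets <- seq(min(na, 2 * n - na) %% 2, min(na, 2 * n - na), by = 2)
  logp <- vapply(hets, function(h) {
    aa <- (na - h) / 2
    bb <- n - aa - h
    lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
      h * log(2) -
      (lgamma(2 * n + 1) - lgamma(na + 1) - lgamma(2 * n - na + 1))
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[hets == n_ab]
  sum(p[p <= obs * (1 + 1e-9)])
}

# exhaustive Viterbi oracle: enumerate every state path (small n only)
viterbi_brute_force <- function(log_emit, log_init, distances, params) {
  n <- nrow(log_emit)
  s <- ncol(log_emit)
  stopifnot(s^n <= 4e6)
  logT <- lapply(distances, function(d) log(transition_matrix(d, params)))
  paths <- as.matrix(expand.grid(rep(list(seq_len(s)), n)))
  score <- log_init[paths[, 1]] + log_emit[cbind(1, paths[, 1])]
  if (n > 1) for (t in 2:n) {
    score <- score + logT[[t - 1]][cbind(paths[, t - 1], paths[, t])] +
      log_emit[cbind(t, paths[, t])]
  }
  best <- which.max(score)
  list(path = as.integer(paths[best, ]), log_prob = max(score))
}

# independent backward-recursion max-path oracle (handles larger n)
viterbi_backward_oracle <- function(log_emit, log_init, distances, params) {
  n <- nrow(log_emit)
  s <- ncol(log_emit)
  logT <- lapply(distances, function(d) log(transition_matrix(d, params)))
  # best score of the path suffix starting at t in state j
  suffix <- matrix(0, n, s)
  suffix[n, ] <- log_emit[n, ]
  if (n > 1) for (t in seq(n - 1, 1)) {
    for (j in seq_len(s))
      suffix[t, j] <- log_emit[t, j] +
        max(logT[[t]][j, ] + suffix[t + 1, ])
  }
  max(log_init + suffix[1, ])
}

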
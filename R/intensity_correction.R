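#' Select copy-stable probes for intensity PCA
#'
#' Retains markers flagged as uniquely-mapping/copy-stable whose
#' cross-sample LRR variance lies below the given quantile; probes inside
#' common copy-variable regions have inflated variance and are removed by
#' the empirical criterion even when flagged stable.
#'
#' @param map a [marker_map] with `is_stable` flags.
#' @param lrr_matrix samples x markers LRR matrix aligned to `map`.
#' @param var_quantile variance quantile below which stable probes are
#'   kept, default 0.9.
#' @param min_probes minimum acceptable stable set, default 100.
#' @return integer vector of retained marker indices.
#' @export
select_stable_probes <- function(map, lrr_matrix, var_quantile = 0.9,
                                 min_probes = 100) {
  if (!any(map$is_stable)) stopf("empty stable probe set")
  v <- apply(lrr_matrix, 2, stats::var)
  cand <- which(map$is_stable)
  cut <- stats::quantile(v[cand], var_quantile, names = FALSE)
  keep <- cand[v[cand] <= cut]
  if (length(keep) < min_probes)
    stopf("only %d stable probes retained (< %d); PCA would be unstable",
          length(keep), min_probes)
  keep
}

#' Regress intensity principal components out of LRR
#'
#' Fits a PCA on the samples x stable-probes LRR matrix; the leading
#' components capture DNA quantity/quality and batch effects. Each probe's
#' LRR (stable or not) is then regressed across samples on the top
#' `n_pcs` sample scores and replaced by its residual plus the probe mean.
#' Rare events such as individual deletions are not absorbed because they
#' contribute negligible cross-sample variance.
#'
#' @param lrr_matrix samples x markers LRR matrix.
#' @param stable_idx marker indices from [select_stable_probes()]; defaults
#'   to all markers.
#' @param n_pcs number of components to remove, default 10; 0 returns the
#'   input unchanged.
#' @param max_private_mass components whose three largest squared sample
#'   loadings sum beyond this are carried by a handful of samples -
#'   typically large rare CNVs, not batch or quality effects - and are
#'   not regressed out (regressing them out would both erase the
#'   carriers' events and leak them into other samples). Genuine
#'   cohort-level artifacts spread their loading mass across many
#'   samples and fall well below the default 0.35.
#' @return list: `lrr` (corrected matrix, same shape), `scores`
#'   (samples x kept components), `var_explained`, `dropped_private`
#'   (number of single-sample components discarded).
#' @export
pca_correct_lrr <- function(lrr_matrix, stable_idx = NULL, n_pcs = 10,
                            max_private_mass = 0.35) {
  n <- nrow(lrr_matrix)
  if (n_pcs == 0)
    return(list(lrr = lrr_matrix, scores = NULL, var_explained = NULL,
                dropped_private = 0L))
  if (n_pcs >= n)
    stopf("n_pcs (%d) must be smaller than the number of samples (%d)",
          n_pcs, n)
  if (is.null(stable_idx)) stable_idx <- seq_len(ncol(lrr_matrix))
  xs <- scale(lrr_matrix[, stable_idx, drop = FALSE], center = TRUE,
              scale = FALSE)
  sv <- svd(xs, nu = n_pcs, nv = 0)
  # a component carried by three or fewer samples is private structure
  # (usually a large rare CNV); regressing it out would erase the
  # carriers' events and leak them into every other sample
  top3 <- apply(sv$u^2, 2, function(z)
    sum(sort(z, decreasing = TRUE)[seq_len(min(3, length(z)))]))
  keep <- which(top3 < max_private_mass)
  if (!length(keep))
    return(list(lrr = lrr_matrix, scores = NULL, var_explained = NULL,
                dropped_private = n_pcs))
  scores <- sv$u[, keep, drop = FALSE] %*%
    diag(sv$d[keep], length(keep), length(keep))
  scores <- scale(scores, center = TRUE, scale = FALSE)
  # per-probe least squares on the sample scores, all probes at once
  beta <- solve(crossprod(scores), crossprod(scores, lrr_matrix))
  fitted <- scores %*% beta
  corrected <- lrr_matrix - fitted
  list(lrr = corrected, scores = scores,
       var_explained = sv$d[keep]^2 / sum(sv$d^2),
       dropped_private = n_pcs - length(keep))
}

#' GC-wave adjustment of LRR
#'
#' Per-sample (default) regression of LRR on local GC fraction; the fitted
#' wave is subtracted. Only copy-neutral-behaving markers (|LRR| <
#' `neutral_abs_lrr`) enter the fit so that real CNVs do not pull the
#' wave estimate. A spline fit (`method = "spline"`) is available for
#' non-linear waves.
#'
#' @param lrr numeric vector (one sample) or samples x markers matrix.
#' @param gc_frac GC fraction per marker.
#' @param method `"linear"` (default) or `"spline"`.
#' @param neutral_abs_lrr markers with |LRR| below this enter the fit,
#'   default 0.5.
#' @param pooled when `lrr` is a matrix, fit one shared wave instead of a
#'   per-sample wave.
#' @return adjusted LRR, same shape as the input.
#' @export
gc_adjust <- function(lrr, gc_frac, method = c("linear", "spline"),
                      neutral_abs_lrr = 0.5, pooled = FALSE) {
  method <- match.arg(method)
  if (stats::var(gc_frac) == 0) {
    warnf("constant gc_frac; GC adjustment is a no-op")
    return(lrr)
  }
  adjust_one <- function(y, coefs = NULL) {
    use <- !is.na(y) & abs(y) < neutral_abs_lrr
    if (sum(use) < 10) return(y)
    if (method == "linear") {
      fit <- stats::lm.fit(cbind(1, gc_frac[use]), y[use])
      y - cbind(1, gc_frac) %*% fit$coefficients
    } else {
      fit <- stats::smooth.spline(gc_frac[use], y[use], df = 5)
      y - stats::predict(fit, gc_frac)$y
    }
  }
  if (is.matrix(lrr)) {
    if (pooled) {
      wave <- colMeans(lrr)
      use <- abs(wave) < neutral_abs_lrr
      fit <- stats::lm.fit(cbind(1, gc_frac[use]), wave[use])
      pred <- as.numeric(cbind(1, gc_frac) %*% fit$coefficients)
      sweep(lrr, 2, pred)
    } else t(apply(lrr, 1, function(y) as.numeric(adjust_one(y))))
  } else as.numeric(adjust_one(lrr))
}

#' Full intensity-correction pipeline for a cohort
#'
#' PC correction on stable probes followed by per-sample GC-wave
#' adjustment, in that order. Returns a cohort whose samples carry
#' corrected LRR.
#'
#' @param cohort a `cnv_cohort`.
#' @param n_pcs components to remove, default 10 (capped below the sample
#'   count).
#' @param var_quantile stable-probe variance quantile, default 0.9.
#' @param ... passed to [gc_adjust()].
#' @return the cohort with corrected per-sample `lrr`.
#' @export
correct_intensities <- function(cohort, n_pcs = 10, var_quantile = 0.9,
                                ...) {
  lrr <- cohort_matrix(cohort, "lrr")
  n_pcs <- min(n_pcs, nrow(lrr) - 2)
  stable <- select_stable_probes(cohort$map, lrr,
                                 var_quantile = var_quantile)
  corrected <- pca_correct_lrr(lrr, stable, n_pcs = n_pcs)$lrr
  corrected <- gc_adjust(corrected, cohort$map$gc_frac, ...)
  for (i in seq_along(cohort$samples))
    cohort$samples[[i]]$lrr <- corrected[i, ]
  cohort
}
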
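#' Breakpoint-tolerant precision/recall of CNV calls against truth
#'
#' A call matches a truth event when sample, chromosome and copy number
#' agree and both breakpoints fall within `tol_probes` probes of the
#' truth breakpoints (greedy one-to-one matching).
#'
#' @param calls CNV call table.
#' @param truth truth-event table (kind `cnv`).
#' @param map the [marker_map].
#' @param tol_probes breakpoint tolerance in probes, default 3.
#' @return list: `precision`, `recall`, `matched_truth`, `matched_call`.
#' @export
cnv_recovery_stats <- function(calls, truth, map, tol_probes = 3) {
  probe_idx <- function(chr, s, e)
    which(map$chromosome == chr & map$position_bp >= s &
            map$position_bp <= e)
  matched_truth <- rep(FALSE, nrow(truth))
  matched_call <- rep(FALSE, nrow(calls))
  for (i in seq_len(nrow(truth))) {
    ti <- probe_idx(truth$chromosome[i], truth$start_bp[i],
                    truth$end_bp[i])
    if (!length(ti)) next
    for (j in seq_len(nrow(calls))) {
      if (matched_call[j]) next
      if (calls$sample_id[j] != truth$sample_id[i] ||
          calls$chromosome[j] != truth$chromosome[i] ||
          calls$copy_number[j] != truth$copy_number[i]) next
      ci <- probe_idx(calls$chromosome[j], calls$start_bp[j],
                      calls$end_bp[j])
      if (length(ci) && abs(min(ci) - min(ti)) <= tol_probes &&
          abs(max(ci) - max(ti)) <= tol_probes) {
        matched_truth[i] <- TRUE
        matched_call[j] <- TRUE
        break
      }
    }
  }
  list(precision = mean(matched_call), recall = mean(matched_truth),
       matched_truth = matched_truth, matched_call = matched_call)
}

#' Length of a 1-based inclusive genomic interval
#'
#' `bp = end - start + 1`; `kb` is rounded to the nearest integer and `mb`
#' to one decimal, matching how event sizes are conventionally printed.
#'
#' @param start_bp,end_bp interval bounds (vectors allowed), 1-based
#'   inclusive.
#' @return data.frame with columns `bp`, `kb`, `mb`.
#' @export
interval_length <- function(start_bp, end_bp) {
  if (any(start_bp > end_bp)) stopf("start_bp > end_bp")
  bp <- as.numeric(end_bp) - as.numeric(start_bp) + 1
  data.frame(bp = bp, kb = round(bp / 1000), mb = round(bp / 1e6, 1))
}

# empirical p with the (r + 1) / (n + 1) estimator; never exactly zero
emp_p <- function(perm_stats, observed, sided = "one") {
  if (sided == "two") {
    r <- sum(abs(perm_stats) >= abs(observed) - 1e-12)
  } else r <- sum(perm_stats >= observed - 1e-12)
  (1 + r) / (1 + length(perm_stats))
}

# shared label-permutation burden engine over per-sample event tables
burden_engine <- function(events, phenotypes, size_col = "length_kb",
                          n_perms = 10000, seed = 1L) {
  if (!all(c("case", "control") %in% phenotypes$status))
    stopf("both cases and controls are required")
  ids <- phenotypes$sample_id
  is_case <- phenotypes$status == "case"
  if (nrow(events)) {
    sizes <- events[[size_col]]
    tot <- tapply(sizes, factor(events$sample_id, levels = ids), sum)
    cnt <- tapply(sizes, factor(events$sample_id, levels = ids), length)
  } else tot <- cnt <- NULL
  total <- as.numeric(tot %||% rep(0, length(ids)))
  count <- as.numeric(cnt %||% rep(0, length(ids)))
  total[is.na(total)] <- 0
  count[is.na(count)] <- 0

  group_stats <- function(case_mask) {
    grp <- function(mask) {
      n <- sum(mask)
      k <- sum(count[mask])
      c(rate = k / n, prop = mean(count[mask] > 0),
        total = mean(total[mask]),
        mean_size = if (k > 0) sum(total[mask]) / k else 0)
    }
    grp(case_mask) - grp(!case_mask)
  }
  obs <- group_stats(is_case)

  summary <- do.call(rbind, lapply(c(case = TRUE, control = FALSE),
                                   function(case) {
    mask <- is_case == case
    k <- sum(count[mask])
    data.frame(group = if (case) "case" else "control",
               n_samples = sum(mask), n_events = k,
               rate = k / sum(mask),
               prop_with_event = mean(count[mask] > 0),
               mean_total_per_sample = mean(total[mask]),
               mean_event_size = if (k > 0) sum(total[mask]) / k else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  perms <- matrix(NA_real_, n_perms, 4)
  n_case <- sum(is_case)
  for (b in seq_len(n_perms)) {
    mask <- rep(FALSE, length(ids))
    mask[sample.int(length(ids), n_case)] <- TRUE
    perms[b, ] <- group_stats(mask)
  }
  p_values <- vapply(1:4, function(j) emp_p(perms[, j], obs[j]),
                     numeric(1))
  names(p_values) <- c("rate", "prop_with_event", "mean_total_per_sample",
                       "mean_event_size")
  list(summary = summary, observed = obs, p_values = p_values,
       n_perms = n_perms, seed = as.integer(seed))
}

#' Case-control CNV burden summary
#'
#' Computes, per group and over calls strictly larger than `min_kb`
#' kilobases: sample count, event count, rate of events per sample,
#' proportion of samples with at least one event, mean per-sample total
#' span, and mean event size.
#'
#' @param calls CNV call table (`sample_id`, `start_bp`, `end_bp`, ...).
#' @param phenotypes phenotype table.
#' @param min_kb strict lower size bound in kb, default 100 (a call of
#'   exactly `min_kb` is excluded).
#' @return per-group data.frame (sizes in kb).
#' @export
cnv_burden_summary <- function(calls, phenotypes, min_kb = 100) {
  calls <- size_filter(calls, min_kb)
  burden_engine(calls, phenotypes, n_perms = 0, seed = 1L)$summary
}

size_filter <- function(calls, min_kb) {
  if (!nrow(calls)) {
    calls$length_kb <- numeric(0)
    return(calls)
  }
  calls$length_kb <- (calls$end_bp - calls$start_bp + 1) / 1000
  calls[calls$length_kb > min_kb, , drop = FALSE]
}

#' CNV burden permutation test
#'
#' One-sided (case > control) empirical p-values for the rate, proportion,
#' mean total span and mean event size contrasts, over calls strictly
#' larger than `min_kb`, by phenotype-label permutation.
#'
#' @inheritParams cnv_burden_summary
#' @param n_perms permutation replicates.
#' @param seed integer seed.
#' @return list as from the shared burden engine: `summary`, `observed`,
#'   `p_values`, `n_perms`, `seed`.
#' @export
cnv_burden_test <- function(calls, phenotypes, min_kb = 100,
                            n_perms = 10000, seed = 1L) {
  burden_engine(size_filter(calls, min_kb), phenotypes,
                n_perms = n_perms, seed = seed)
}

#' Label-permutation test of a per-sample statistic
#'
#' The observed statistic is the difference of group means (case minus
#' control). Labels are permuted preserving group sizes; the pointwise
#' empirical p-value uses the `(r + 1) / (n + 1)` estimator so it is never
#' exactly zero. Deterministic given the seed.
#'
#' @param x numeric per-sample statistic, aligned to `phenotypes`.
#' @param phenotypes phenotype table (`sample_id`, `status`).
#' @param n_perms number of permutations (>= 100).
#' @param seed integer seed.
#' @param sided `"one"` (case > control) or `"two"`.
#' @param statistic_name label for printing.
#' @return list of class `perm_result`: `statistic_name`, `observed`,
#'   `n_perms`, `emp1`, `emp2`, `seed`.
#' @export
permute_label_test <- function(x, phenotypes, n_perms = 10000, seed = 1L,
                               sided = c("one", "two"),
                               statistic_name = "mean_difference") {
  sided <- match.arg(sided)
  if (n_perms < 100) stopf("n_perms must be at least 100")
  is_case <- phenotypes$status == "case"
  n_case <- sum(is_case)
  if (n_case == 0 || n_case == length(is_case))
    stopf("both groups must be non-empty")
  obs <- mean(x[is_case]) - mean(x[!is_case])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  n <- length(x)
  sum_all <- sum(x)
  perm <- vapply(seq_len(n_perms), function(b) {
    pick <- sample.int(n, n_case)
    s <- sum(x[pick])
    s / n_case - (sum_all - s) / (n - n_case)
  }, numeric(1))
  emp1 <- emp_p(perm, obs, sided)
  structure(list(statistic_name = statistic_name, observed = obs,
                 n_perms = n_perms, emp1 = emp1, emp2 = emp1,
                 seed = as.integer(seed)),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("<perm_result> %s: observed %.4g, EMP1 %.4g (n_perms %d)\n",
              x$statistic_name, x$observed, x$emp1, x$n_perms))
  invisible(x)
}

#' Segmental case-control CNV scan with max-statistic correction
#'
#' At every marker the statistic is the case carrier count minus the
#' control carrier count scaled by the case/control ratio (one-sided,
#' case-enriched). Phenotype labels are permuted `n_perms` times; `emp1`
#' is the pointwise empirical p-value and `emp2` the family-wise one: the
#' proportion of permutations whose genome-wide maximum statistic reaches
#' the marker's observed value. `emp2 >= emp1` everywhere by
#' construction.
#'
#' @param calls CNV call table.
#' @param phenotypes phenotype table.
#' @param map the [marker_map].
#' @param n_perms default 10000.
#' @param seed integer seed.
#' @param chunk permutations per block (memory control).
#' @return data.frame per marker with carriers, `stat`, `emp1`, `emp2`;
#'   empty when there are no calls.
#' @export
segmental_scan <- function(calls, phenotypes, map, n_perms = 10000,
                           seed = 1L, chunk = 1000) {
  empty <- data.frame(marker_id = character(0), chromosome = character(0),
                      position_bp = integer(0), n_case = integer(0),
                      n_control = integer(0), stat = numeric(0),
                      emp1 = numeric(0), emp2 = numeric(0),
                      stringsAsFactors = FALSE)
  if (!nrow(calls)) return(empty)
  ids <- phenotypes$sample_id
  is_case <- phenotypes$status == "case"
  n_case <- sum(is_case)
  ratio <- n_case / sum(!is_case)

  carrier <- matrix(0, length(ids), nrow(map),
                    dimnames = list(ids, map$marker_id))
  for (r in seq_len(nrow(calls))) {
    s <- match(calls$sample_id[r], ids)
    if (is.na(s)) next
    hit <- map$chromosome == calls$chromosome[r] &
      map$position_bp >= calls$start_bp[r] &
      map$position_bp <= calls$end_bp[r]
    carrier[s, hit] <- 1
  }
  covered <- which(colSums(carrier) > 0)
  obs_case <- as.numeric(crossprod(carrier, as.numeric(is_case)))
  obs_ctrl <- colSums(carrier) - obs_case
  obs <- obs_case - ratio * obs_ctrl

  emp1_r <- rep(0, length(covered))
  emp2_r <- rep(0, length(covered))
  if (length(covered)) {
    cm <- carrier[, covered, drop = FALSE]
    tot <- colSums(cm)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
    done <- 0
    while (done < n_perms) {
      b <- min(chunk, n_perms - done)
      lab <- vapply(seq_len(b), function(i) {
        v <- numeric(length(ids))
        v[sample.int(length(ids), n_case)] <- 1
        v
      }, numeric(length(ids)))
      pc <- crossprod(cm, lab)               # loci x b case counts
      ps <- pc - ratio * (tot - pc)          # permuted statistics
      mx <- apply(ps, 2, max)
      emp1_r <- emp1_r + rowSums(ps >= obs[covered] - 1e-12)
      emp2_r <- emp2_r + vapply(seq_along(covered), function(l)
        sum(mx >= obs[covered][l] - 1e-12), numeric(1))
      done <- done + b
    }
  }
  emp1 <- rep(1, nrow(map))
  emp2 <- rep(1, nrow(map))
  emp1[covered] <- (1 + emp1_r) / (1 + n_perms)
  emp2[covered] <- (1 + emp2_r) / (1 + n_perms)
  data.frame(marker_id = map$marker_id, chromosome = map$chromosome,
             position_bp = map$position_bp, n_case = obs_case,
             n_control = obs_ctrl, stat = obs, emp1 = emp1, emp2 = emp2,
             stringsAsFactors = FALSE)
}

#' Annotate CNV calls against known disease loci
#'
#' Each call is annotated with every known locus it overlaps whose
#' reported copy-number direction matches the call (deletions match
#' `loss`/`both` loci, duplications `gain`/`both`). An optional reciprocal
#' overlap threshold requires the overlap to cover at least that fraction
#' of both the call and the locus. When a gene BED table is supplied
#' (`chromosome`, `start_bp`, `end_bp`, `gene`; 1-based inclusive), the
#' number of genes each call spans is reported.
#'
#' @param calls CNV call table.
#' @param known locus table, default the packaged [known_loci()].
#' @param reciprocal_overlap fraction in \[0, 1\]; 0 (default) means any
#'   overlap.
#' @param gene_table optional gene interval table.
#' @return `calls` with added `known_locus`, `locus_direction` and
#'   (optionally) `n_genes` columns.
#' @export
annotate_known_loci <- function(calls, known = known_loci(),
                                reciprocal_overlap = 0,
                                gene_table = NULL) {
  if (!nrow(calls)) {
    calls$known_locus <- character(0)
    calls$locus_direction <- character(0)
    return(calls)
  }
  ann <- character(nrow(calls))
  dir <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    cn <- calls$copy_number[i]
    type <- if (cn < 2) "loss" else "gain"
    hits <- which(known$chromosome == calls$chromosome[i] &
                    known$start_bp <= calls$end_bp[i] &
                    known$end_bp >= calls$start_bp[i] &
                    (known$cnv_type == "both" | known$cnv_type == type))
    if (length(hits) && reciprocal_overlap > 0) {
      keep <- vapply(hits, function(h) {
        ov <- min(calls$end_bp[i], known$end_bp[h]) -
          max(calls$start_bp[i], known$start_bp[h]) + 1
        len_c <- calls$end_bp[i] - calls$start_bp[i] + 1
        len_l <- known$end_bp[h] - known$start_bp[h] + 1
        ov / len_c >= reciprocal_overlap && ov / len_l >= reciprocal_overlap
      }, logical(1))
      hits <- hits[keep]
    }
    ann[i] <- paste(known$name[hits], collapse = ";")
    dir[i] <- paste(unique(known$direction[hits]), collapse = ";")
  }
  calls$known_locus <- ann
  calls$locus_direction <- dir
  if (!is.null(gene_table)) {
    calls$n_genes <- vapply(seq_len(nrow(calls)), function(i)
      sum(gene_table$chromosome == calls$chromosome[i] &
            gene_table$start_bp <= calls$end_bp[i] &
            gene_table$end_bp >= calls$start_bp[i]), numeric(1))
  }
  calls
}
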
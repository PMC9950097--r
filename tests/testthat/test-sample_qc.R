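test_that("compute_lrr_baf reproduces cluster identities", {
  cl <- data.frame(theta_aa = 0.1, r_aa = 1.6, theta_ab = 0.5, r_ab = 2.0,
                   theta_bb = 0.9, r_bb = 1.7)
  # observation exactly at the AB cluster
  th <- 0.5; r <- 2.0
  x <- r * cos(pi / 2 * th) / (cos(pi / 2 * th) + sin(pi / 2 * th))
  y <- r - x
  res <- compute_lrr_baf(x, y, cl)
  expect_equal(res$baf, 0.5, tolerance = 1e-9)
  expect_equal(res$lrr, 0, tolerance = 1e-9)

  # observation at the AA cluster: BAF 0
  th <- 0.1; r <- 1.6
  x <- r * cos(pi / 2 * th) / (cos(pi / 2 * th) + sin(pi / 2 * th))
  y <- r - x
  res <- compute_lrr_baf(x, y, cl)
  expect_equal(res$baf, 0)
  expect_equal(res$lrr, 0, tolerance = 1e-9)

  # R doubled relative to the interpolated expectation: LRR = log2(2) = 1
  th <- 0.3; r_exp <- 1.6 + (0.3 - 0.1) / (0.5 - 0.1) * (2.0 - 1.6)
  r <- 2 * r_exp
  x <- r * cos(pi / 2 * th) / (cos(pi / 2 * th) + sin(pi / 2 * th))
  y <- r - x
  res <- compute_lrr_baf(x, y, cl)
  expect_equal(res$lrr, 1, tolerance = 1e-9)

  # missing cluster flags the marker unusable
  cl_na <- cl; cl_na$theta_ab <- NA
  res <- compute_lrr_baf(1, 1, cl_na)
  expect_false(res$usable)
  expect_true(is.na(res$lrr))
})

test_that("HWE exact p matches full-enumeration oracle on many tables", {
  set.seed(42)
  tables <- rbind(
    c(50, 50, 50), c(0, 0, 100), c(100, 0, 0), c(10, 80, 10),
    c(40, 20, 40), c(1, 1, 1), c(0, 10, 90), c(66, 67, 67),
    t(replicate(40, {
      n <- sample(3:200, 1)
      as.numeric(stats::rmultinom(1, n, prob = runif(3)))
    }))
  )
  for (i in seq_len(nrow(tables))) {
    got <- hwe_exact_p(tables[i, 1], tables[i, 2], tables[i, 3])
    want <- hwe_enum_oracle(tables[i, 1], tables[i, 2], tables[i, 3])
    expect_equal(got, want, tolerance = 1e-8,
                 label = sprintf("HWE p for (%d,%d,%d)", tables[i, 1],
                                 tables[i, 2], tables[i, 3]))
  }
  expect_equal(hwe_exact_p(30, 0, 0), 1)  # monomorphic convention
})

test_that("sample screen excludes intensity outliers and low call rates", {
  set.seed(7)
  metrics <- data.frame(
    sample_id = sprintf("s%02d", 1:50),
    lrr_mean = rnorm(50, 0, 0.01),
    lrr_sd = rnorm(50, 0.2, 0.01),
    het_baf_sd = rnorm(50, 0.03, 0.002),
    call_rate = rep(0.99, 50)
  )
  out <- sample_pass_filter(metrics)
  expect_true(all(out$pass))

  noisy <- metrics
  noisy$lrr_sd[7] <- 1.0  # 5x the cohort level
  noisy$call_rate[9] <- 0.94
  out <- sample_pass_filter(noisy)
  expect_false(out$pass[7])
  expect_match(out$reasons[7], "lrr_sd")
  expect_false(out$pass[9])
  expect_match(out$reasons[9], "call_rate")
  expect_equal(sum(!out$pass), 2)

  same <- metrics
  same$lrr_sd <- 0.2
  same$het_baf_sd <- 0.03
  expect_true(all(sample_pass_filter(same)$pass))
  expect_error(sample_pass_filter(metrics[1, ]), "single-sample")
})

test_that("sample metrics use the restricted windows", {
  lrr <- c(rep(0.1, 50), rep(-3, 10))  # deleted region must not count
  baf <- c(rep(0.5, 30), rep(0.01, 30))
  s <- intensity_sample("x", lrr, baf, rep("AA", 60))
  m <- sample_qc_metrics(s)
  expect_equal(m$lrr_mean, 0.1)
  expect_equal(m$lrr_sd, 0)
  expect_equal(m$het_baf_sd, 0)  # only the 0.5 band is in [0.15, 0.85]
})

test_that("marker filter applies call-rate, HWE and sex tests", {
  set.seed(5)
  n <- 120
  sex <- rep(c("male", "female"), each = n / 2)
  g_ok <- replicate(1, sample(c("AA", "AB", "BB"), n, TRUE,
                              prob = c(0.25, 0.5, 0.25)))
  g_miss <- g_ok; g_miss[sample(n, 13)] <- "NC"       # ~11% missing
  g_hwe <- sample(c("AA", "BB"), n, TRUE)             # no hets at p=0.5
  g_sexmiss <- g_ok; g_sexmiss[1:20] <- "NC"          # males only missing
  geno <- cbind(ok = g_ok, miss = g_miss, hwe = g_hwe,
                sexmiss = g_sexmiss)
  res <- marker_pass_filter(geno, sex = sex)
  expect_true(res$pass[1])
  expect_false(res$pass[2])
  expect_match(res$reasons[2], "call_rate")
  expect_false(res$pass[3])
  expect_match(res$reasons[3], "hwe")
  expect_false(res$pass[4])
  expect_match(res$reasons[4], "sex_missingness")

  # identical (low) missingness in both sexes: sex-missingness p = 1
  g_even <- g_ok
  g_even[c(1:2, (n / 2 + 1):(n / 2 + 2))] <- "NC"
  res2 <- marker_pass_filter(cbind(even = g_even), sex = sex)
  expect_equal(res2$sex_miss_p, 1, tolerance = 1e-9)
  expect_true(res2$pass)
})

test_that("LD pruning removes duplicates and keeps independent markers", {
  set.seed(11)
  n <- 200
  base <- matrix(rbinom(n * 30, 2, 0.4), n, 30)
  dup <- cbind(base, base[, 3])  # duplicated column has r2 = 1
  keep <- ld_prune(dup, r2_threshold = 0.5)
  expect_false(keep[3] && keep[31])

  keep_ind <- ld_prune(base, r2_threshold = 0.2)
  expect_gt(mean(keep_ind), 0.8)

  # a stricter threshold removes a superset of markers
  corr <- base
  corr[, 11] <- ifelse(rbinom(n, 1, 0.9) == 1, base[, 10], 2 - base[, 10])
  k02 <- ld_prune(corr, r2_threshold = 0.2)
  k03 <- ld_prune(corr, r2_threshold = 0.3)
  expect_true(all(which(!k03) %in% which(!k02)))
  expect_error(ld_prune(base, r2_threshold = 1.2), "r2_threshold")
})

test_that("PI_HAT recovers self, parent-offspring and unrelated pairs", {
  set.seed(13)
  m <- 5000
  p <- runif(m, 0.1, 0.9)
  draw <- function() rbinom(m, 1, p) + rbinom(m, 1, p)
  g1 <- draw()
  self <- estimate_pi_hat(g1, g1, p)
  expect_gt(self$pi_hat, 0.95)
  expect_equal(self$ibs0, 0)

  unrel <- estimate_pi_hat(g1, draw(), p)
  expect_lt(abs(unrel$pi_hat), 0.05)

  # parent-offspring: the child inherits one haplotype from the parent
  parent_h <- cbind(rbinom(m, 1, p), rbinom(m, 1, p))
  parent <- rowSums(parent_h)
  child <- parent_h[cbind(seq_len(m), sample(1:2, m, TRUE))] +
    rbinom(m, 1, p)
  po <- estimate_pi_hat(parent, child, p)
  expect_lt(abs(po$pi_hat - 0.5), 0.05)
  expect_equal(po$ibs0 + po$ibs1 + po$ibs2, m)
  expect_error(estimate_pi_hat(c(NA, NA), c(1, 1), c(0.5, 0.5)),
               "overlapping")
})

test_that("ancestry PCA separates divergent populations", {
  set.seed(17)
  m <- 400
  p1 <- runif(m, 0.05, 0.95)
  fst_shift <- rnorm(m, 0, 0.18)
  p2 <- clamp_test(p1 + fst_shift)
  g <- rbind(
    t(replicate(30, rbinom(m, 2, p1))),
    t(replicate(30, rbinom(m, 2, p2)))
  )
  pca <- ancestry_pca(g, k = 4)
  pop <- rep(1:2, each = 30)
  pc1 <- pca$scores[, 1]
  # complete separation on PC1
  expect_true(max(pc1[pop == 1]) < min(pc1[pop == 2]) ||
                min(pc1[pop == 1]) > max(pc1[pop == 2]))
  expect_true(all(diff(pca$var_explained) <= 1e-12))

  ident <- matrix(rep(rbinom(50, 2, 0.5), each = 10), 10, 50)
  expect_warning(pca0 <- ancestry_pca(ident, k = 20), "reducing")
  expect_lt(max(abs(pca0$scores)), 1e-8)
})

test_that("sex screen flags discordance and partial Y loss", {
  g <- example_genome(n_chrom = 1, chrom_length_bp = 2e7,
                      include_sex = TRUE)
  map <- generate_marker_map(1200, g$chrom_lengths, g$centromeres,
                             seed = 19)
  coh <- simulate_cohort(map, 2, 2, noise = quiet_noise(), seed = 20,
                         sex = c("male", "female", "male", "female"))
  scr <- sex_aneuploidy_screen(coh$samples, map, coh$phenotypes$sex)
  expect_equal(scr$flags, rep("", 4))
  expect_lt(scr$x_het_rate[1], 0.02)
  expect_gt(scr$x_het_rate[2], 0.1)

  # mosaic Y loss: depress Y LRR by 0.5 in a male
  s <- coh$samples[[1]]
  on_y <- map$chromosome == "Y"
  s$lrr[on_y] <- s$lrr[on_y] - 0.6
  scr2 <- sex_aneuploidy_screen(list(s), map, "male")
  expect_match(scr2$flags, "partial_y_loss")

  # XX sample labelled male is discordant
  scr3 <- sex_aneuploidy_screen(coh$samples[2], map, "male")
  expect_match(scr3$flags, "sex_discordant")
})
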
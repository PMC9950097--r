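params <- hmm_params()

test_that("emission likelihoods favour the generating state", {
  # diploid het marker: CN1 has no 0.5 band
  ll_cn2 <- emission_loglik("CN2", 0, 0.5, 0.5, params)
  ll_cn1 <- emission_loglik("CN1", 0, 0.5, 0.5, params)
  expect_gt(ll_cn2, ll_cn1)

  # AAB band at 1/3 with LRR at the CN3 mean
  lrr3 <- params$lrr_mean["CN3"]
  expect_gt(emission_loglik("CN3", lrr3, 1 / 3, 0.5, params),
            emission_loglik("CN2", lrr3, 1 / 3, 0.5, params))

  # outlier BAF: mixture is bounded below by the outlier component
  ll <- emission_loglik("CN2", 0, 0.27, 0.5, params)
  lrr_part <- dnorm(0, params$lrr_mean["CN2"], params$lrr_sd["CN2"],
                    log = TRUE)
  expect_gte(ll - lrr_part, log(params$outlier_weight))

  # direct-density check for a CN3 emission
  p <- 0.3; b <- 0.66; l <- 0.35
  w <- dbinom(0:3, 3, p)
  mix <- sum(w * dnorm(b, c(0, 1 / 3, 2 / 3, 1), params$baf_sd))
  want <- dnorm(l, params$lrr_mean["CN3"], params$lrr_sd["CN3"],
                log = TRUE) +
    log((1 - params$outlier_weight) * mix + params$outlier_weight)
  expect_equal(unname(emission_loglik("CN3", l, b, p, params)), unname(want),
               tolerance = 1e-12)
})

test_that("transition matrix is distance-aware and row-stochastic", {
  expect_equal(unname(transition_matrix(0, params)), diag(6))
  for (d in c(1, 1e3, 1e6))
    expect_equal(unname(rowSums(transition_matrix(d, params))), rep(1, 6))
  # off-diagonals approach rho_max * prior at large distance
  tm <- transition_matrix(1e12, params)
  off <- tm[1, -1]
  expect_equal(unname(off),
               unname(params$rho_max * params$state_priors[-1]),
               tolerance = 1e-9)
  expect_error(transition_matrix(-5, params), ">= 0")
})

test_that("Viterbi equals the exhaustive-path maximum on small instances", {
  set.seed(23)
  for (rep in 1:12) {
    n <- sample(3:7, 1)
    log_emit <- matrix(rnorm(n * 6, 0, 2), n, 6)
    distances <- sample(c(1e3, 5e4, 2e5), n - 1, TRUE)
    got <- viterbi_decode(log_emit, log(params$state_priors), distances,
                          params$state_priors, params$rho_max,
                          params$distance_scale_bp)
    want <- viterbi_brute_force(log_emit, log(params$state_priors),
                                distances, params)
    expect_equal(as.integer(got), want$path)
    expect_equal(attr(got, "log_prob"), want$log_prob, tolerance = 1e-9)
  }
  # larger instances against the independent backward-recursion oracle
  for (rep in 1:5) {
    n <- 12
    log_emit <- matrix(rnorm(n * 6, 0, 2), n, 6)
    distances <- sample(c(1e3, 5e4, 2e5), n - 1, TRUE)
    got <- viterbi_decode(log_emit, log(params$state_priors), distances,
                          params$state_priors, params$rho_max,
                          params$distance_scale_bp)
    want <- viterbi_backward_oracle(log_emit, log(params$state_priors),
                                    distances, params)
    expect_equal(attr(got, "log_prob"), want, tolerance = 1e-9)
  }
})

test_that("pure diploid signal yields no segments", {
  map <- uniform_map(300, pfb = 0.4)
  set.seed(31)
  gt <- simulate_genotypes_test(map$pfb)
  s <- intensity_sample("s", rnorm(300, 0, 0.15),
                        clamp_test(c(AA = 0, AB = 0.5, BB = 1)[gt] +
                                     rnorm(300, 0, 0.02), 0, 1), gt)
  expect_equal(nrow(viterbi_segments(s, map, params)), 0L)
})

test_that("a planted high-SNR deletion is recovered within 2 probes", {
  map <- uniform_map(400, pfb = 0.5)
  set.seed(37)
  gt <- simulate_genotypes_test(map$pfb)
  lrr <- rnorm(400, 0, 0.066)  # 10x SNR for the CN1 mean of -0.66
  baf <- clamp_test(c(AA = 0, AB = 0.5, BB = 1)[gt] + rnorm(400, 0, 0.02),
                    0, 1)
  del <- 151:250
  lrr[del] <- rnorm(100, params$lrr_mean["CN1"], 0.066)
  b <- runif(100) < map$pfb[del]
  gt[del] <- ifelse(b, "BB", "AA")
  baf[del] <- clamp_test(as.numeric(b) + rnorm(100, 0, 0.02), 0, 1)
  s <- intensity_sample("s", lrr, baf, gt)
  segs <- viterbi_segments(s, map, params)
  segs <- segs[segs$state == "CN1", ]
  expect_equal(nrow(segs), 1L)
  expect_lte(abs(segs$start_idx - 151), 2)
  expect_lte(abs(segs$end_idx - 250), 2)
})

test_that("bayes factor is an emission log10 ratio and adds over probes", {
  map <- uniform_map(3, pfb = 0.5)
  s <- intensity_sample("s", c(-0.7, -0.6, -0.66), c(0.01, 0.99, 0.02),
                        c("AA", "BB", "AA"))
  seg <- data.frame(sample_id = "s", chromosome = "1",
                    start_bp = map$position_bp[1],
                    end_bp = map$position_bp[3], state = "CN1",
                    copy_number = 1L, n_probes = 3L, start_idx = 1L,
                    end_idx = 3L)
  got <- bayes_factor(seg, s, map, params)
  want <- sum(emission_loglik("CN1", s$lrr, s$baf, map$pfb, params) -
                emission_loglik("CN2", s$lrr, s$baf, map$pfb, params)) /
    log(10)
  expect_equal(got, want, tolerance = 1e-12)
  expect_gt(got, 0)

  # probes sitting exactly at CN2 means: confidence <= 0
  s2 <- intensity_sample("s", c(0, 0, 0), c(0.5, 0.5, 0.5),
                         c("AB", "AB", "AB"))
  expect_lte(bayes_factor(seg, s2, map, params), 0)

  # confidence grows with segment length at fixed per-probe SNR
  map10 <- uniform_map(10, pfb = 0.5)
  s10 <- intensity_sample("s", rep(-0.66, 10), rep(0.01, 10),
                          rep("AA", 10))
  bf_len <- sapply(c(3, 6, 10), function(k) {
    sg <- seg
    sg$end_bp <- map10$position_bp[k]; sg$end_idx <- k
    bayes_factor(sg, s10, map10, params)
  })
  expect_true(all(diff(bf_len) > 0))
})

test_that("probe-count and confidence boundaries are enforced exactly", {
  mk <- function(state, cn, n_probes, conf)
    data.frame(sample_id = "s", chromosome = "1", start_bp = 1L,
               end_bp = 2L, state = state, copy_number = cn,
               n_probes = n_probes, start_idx = 1L, end_idx = 2L,
               confidence = conf)
  calls <- rbind(mk("CN0", 0L, 3L, 12),    # kept: boundary hom-del
                 mk("CN0", 0L, 2L, 12),    # dropped: probes
                 mk("CN1", 1L, 14L, 30),   # dropped: probes
                 mk("CN1", 1L, 15L, 10),   # kept: boundary confidence
                 mk("CN3", 3L, 20L, 9.9),  # dropped: confidence
                 mk("CN2-LOH", 2L, 200L, 90))  # routed out of CNV list
  out <- filter_calls(calls)
  expect_equal(nrow(out), 2L)
  expect_setequal(out$state, c("CN0", "CN1"))
  expect_equal(out$n_probes, c(3L, 15L))
})

test_that("merging follows the strict 20 percent gap rule", {
  # markers every 10 kb; two CN1 calls of 100 kb and 90 kb
  map <- uniform_map(120, spacing_bp = 10000, pfb = 0.5)
  s <- intensity_sample("s", rep(-0.66, 120), rep(0.01, 120),
                        rep("AA", 120))
  mk <- function(i0, i1, state = "CN1", cn = 1L)
    data.frame(sample_id = "s", chromosome = "1",
               start_bp = map$position_bp[i0],
               end_bp = map$position_bp[i1], state = state,
               copy_number = cn, n_probes = i1 - i0 + 1L,
               start_idx = i0, end_idx = i1, confidence = 50)
  # A spans 10k-110k (100 kb), B 120k-210k (90 kb): the 10 kb gap is
  # below the 18 kb (20% of the smaller call) bound, so they merge
  a <- mk(1, 11); b <- mk(12, 21)
  merged <- merge_adjacent(rbind(a, b), s, map, params)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$start_bp, map$position_bp[1])
  expect_equal(merged$end_bp, map$position_bp[21])
  expect_equal(merged$n_probes, 21L)

  # a 20 kb gap fails the strict < 18 kb rule and keeps them apart
  b2 <- mk(13, 22)
  expect_equal(nrow(merge_adjacent(rbind(a, b2), s, map, params)), 2L)

  # different copy numbers never merge
  b3 <- mk(12, 21, state = "CN3", cn = 3L)
  expect_equal(nrow(merge_adjacent(rbind(a, b3), s, map, params)), 2L)

  # overlapping input is an upstream bug
  expect_error(merge_adjacent(rbind(a, mk(5, 30)), s, map, params),
               "overlapping")
})

test_that("centromere splitting re-anchors calls at flanking probes", {
  # 50 probes, centromere between probes 20 and 31 (gap in positions)
  pos <- c(seq(1e5, by = 1e4, length.out = 20),
           seq(5e6, by = 1e4, length.out = 30))
  map <- marker_map(sprintf("m%02d", 1:50), rep("1", 50), pos,
                    rep(0.5, 50), rep(0.5, 50))
  cen <- data.frame(chromosome = "1", start_bp = 3e5 + 1e4,
                    end_bp = 4.99e6)
  s <- intensity_sample("s", rep(-0.66, 50), rep(0.01, 50), rep("AA", 50))
  spanning <- data.frame(sample_id = "s", chromosome = "1",
                         start_bp = pos[1], end_bp = pos[50],
                         state = "CN1", copy_number = 1L, n_probes = 50L,
                         start_idx = 1L, end_idx = 50L, confidence = 100)
  out <- split_at_centromere(spanning, cen, s, map, params)
  expect_equal(nrow(out), 2L)
  expect_equal(out$start_bp, c(pos[1], pos[21]))
  expect_equal(out$end_bp, c(pos[20], pos[50]))
  expect_equal(out$n_probes, c(20L, 30L))

  # call strictly on the p-arm side is unchanged
  parm <- spanning
  parm$end_bp <- pos[18]; parm$end_idx <- 18L; parm$n_probes <- 18L
  expect_equal(split_at_centromere(parm, cen, s, map, params)$end_bp,
               pos[18])

  # a side left with too few probes is dropped by the 15-probe rule
  short_q <- spanning
  short_q$end_bp <- pos[22]; short_q$end_idx <- 22L
  out2 <- split_at_centromere(short_q, cen, s, map, params)
  expect_equal(nrow(out2), 1L)
  expect_equal(out2$end_bp, pos[20])
})

test_that("filter, merge and split reach a fixed point", {
  g <- example_genome(n_chrom = 2, chrom_length_bp = 2e7)
  map <- generate_marker_map(2500, g$chrom_lengths, g$centromeres,
                             seed = 41)
  ev <- rbind(
    truth_event("case_001", "cnv", "1", 2e6, 3.5e6, copy_number = 1),
    truth_event("case_001", "cnv", "2", 5e6, 6e6, copy_number = 3)
  )
  coh <- simulate_cohort(map, 1, 0, events = ev, noise = quiet_noise(),
                         seed = 42)
  s <- coh$samples[[1]]
  calls <- call_cnvs(s, map, params, centromeres = g$centromeres)
  expect_gte(nrow(calls), 2L)
  again <- split_at_centromere(
    merge_adjacent(filter_calls(calls), s, map, params),
    g$centromeres, s, map, params)
  expect_equal(again[order(again$chromosome, again$start_bp),
                     c("chromosome", "start_bp", "end_bp", "copy_number")],
               calls[order(calls$chromosome, calls$start_bp),
                     c("chromosome", "start_bp", "end_bp", "copy_number")])
  # no call spans a centromere
  for (i in seq_len(nrow(calls))) {
    cen <- g$centromeres[g$centromeres$chromosome == calls$chromosome[i], ]
    expect_false(calls$start_bp[i] < cen$start_bp &&
                   calls$end_bp[i] > cen$end_bp)
  }
})
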
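test_that("ROH criteria boundaries are enforced", {
  # 200 homozygous markers over 2 Mb: a clean segment with zero hets
  map <- uniform_map(200, spacing_bp = 10050)
  g <- rep(c("AA", "BB"), 100)
  segs <- call_roh(g, map, "s")
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$n_snps, 200L)
  expect_equal(segs$n_het, 0L)
  expect_gte(segs$length_kb, 1000)

  # 99 markers: fails the 100-SNP minimum
  map99 <- uniform_map(99, spacing_bp = 12000)
  expect_equal(nrow(call_roh(rep("AA", 99), map99, "s")), 0L)

  # 150 markers over 9 Mb: density 1 per 60 kb fails the 50 kb rule
  map_sparse <- uniform_map(150, spacing_bp = 60000)
  expect_equal(nrow(call_roh(rep("AA", 150), map_sparse, "s")), 0L)

  # a gap > 1 Mb splits the run
  pos <- c(seq(1e4, by = 10050, length.out = 150),
           seq(1e4 + 150 * 10050 + 1.2e6, by = 10050, length.out = 150))
  map_gap <- marker_map(sprintf("g%03d", 1:300), rep("1", 300), pos,
                        rep(0.5, 300), rep(0.5, 300))
  segs_gap <- call_roh(rep("AA", 300), map_gap, "s")
  expect_equal(nrow(segs_gap), 2L)
  expect_true(all(segs_gap$n_snps == 150L))
})

test_that("het budget admits one het per megabase with a floor of one", {
  map <- uniform_map(300, spacing_bp = 10050)  # ~3 Mb span
  g <- rep("AA", 300)
  g[150] <- "AB"
  segs <- call_roh(g, map, "s")
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$n_het, 1L)
  expect_equal(segs$n_snps, 300L)

  # four hets in ~3 Mb exceed the budget: run is clipped
  g4 <- rep("AA", 300)
  g4[c(80, 120, 160, 200)] <- "AB"
  segs4 <- call_roh(g4, map, "s")
  if (nrow(segs4))
    expect_true(all(validate_roh_segments(segs4, g4, map)))

  # missing genotypes neither break the run nor count as het
  gm <- rep("AA", 300)
  gm[sample(300, 20)] <- "NC"
  segs_m <- call_roh(gm, map, "s")
  expect_equal(nrow(segs_m), 1L)
  expect_equal(segs_m$n_het, 0L)

  expect_warning(call_roh(g, map, "s", pruned = FALSE), "pruned")
})

test_that("every emitted segment passes the independent validator", {
  g <- example_genome(n_chrom = 2, chrom_length_bp = 3e7)
  map <- generate_marker_map(3000, g$chrom_lengths, g$centromeres,
                             seed = 13)
  ev <- rbind(
    truth_event("case_001", "roh", "1", 2e6, 8e6),
    truth_event("case_001", "roh", "2", 16e6, 22e6),
    truth_event("control_001", "roh", "1", 18e6, 26e6)
  )
  coh <- simulate_cohort(map, 10, 10, events = ev, noise = quiet_noise(),
                         seed = 14)
  keep <- roh_marker_prep(coh, maf_min = 0.05)
  expect_gt(sum(keep), 1000)  # pruning keeps most independent markers
  segs <- call_roh_cohort(coh, keep)
  expect_gte(nrow(segs), 3L)
  pruned_map <- coh$map[keep, , drop = FALSE]
  for (id in unique(segs$sample_id)) {
    ok <- validate_roh_segments(segs[segs$sample_id == id, ],
                                coh$samples[[id]]$genotype[keep],
                                pruned_map)
    expect_true(all(ok), label = sprintf("segments of %s", id))
  }
  # planted autozygous intervals are recovered
  case_segs <- segs[segs$sample_id == "case_001" &
                      segs$chromosome == "1", ]
  expect_true(any(case_segs$start_bp < 3e6 & case_segs$end_bp > 7e6))
})

test_that("burden summary contrasts behave under null and planted effects", {
  set.seed(15)
  ph <- data.frame(sample_id = sprintf("s%03d", 1:200),
                   status = rep(c("case", "control"), each = 100))
  mk_segs <- function(scale_case) {
    rows <- lapply(seq_len(200), function(i) {
      k <- rpois(1, 3)
      if (k == 0) return(NULL)
      len <- rlnorm(k, log(2000), 0.3) *
        if (i <= 100) scale_case else 1
      data.frame(sample_id = ph$sample_id[i], chromosome = "1",
                 start_bp = 1L, end_bp = 2L, n_snps = 150L, n_het = 0L,
                 length_kb = len)
    })
    do.call(rbind, rows)
  }
  null_res <- roh_burden_summary(mk_segs(1), ph, n_perms = 2000, seed = 1)
  expect_true(all(null_res$p_values > 0.05))
  expect_true(all(null_res$p_values < 0.95))

  eff_res <- roh_burden_summary(mk_segs(2), ph, n_perms = 2000, seed = 2)
  expect_lt(eff_res$p_values["mean_event_size"], 0.01)

  empty <- roh_burden_summary(mk_segs(1)[0, ], ph, n_perms = 200, seed = 3)
  expect_true(all(empty$summary$n_events == 0))
  expect_true(all(empty$p_values == 1))
})

test_that("region scan reproduces constructed carrier fixtures", {
  map <- uniform_map(100, spacing_bp = 100000)  # 10 Mb, 100 markers
  ph <- data.frame(sample_id = c(sprintf("ca%02d", 1:12),
                                 sprintf("co%02d", 1:5)),
                   status = rep(c("case", "control"), c(12, 5)))
  seg <- function(id, i0, i1)
    data.frame(sample_id = id, chromosome = "1",
               start_bp = map$position_bp[i0],
               end_bp = map$position_bp[i1], n_snps = i1 - i0 + 1L,
               n_het = 0L,
               length_kb = (map$position_bp[i1] - map$position_bp[i0] + 1) / 1000)

  # 10 cases across the core 40-60; 7 of them extend over 30-70
  segs <- rbind(
    do.call(rbind, lapply(1:7, function(i) seg(sprintf("ca%02d", i), 30, 70))),
    do.call(rbind, lapply(8:10, function(i) seg(sprintf("ca%02d", i), 40, 60)))
  )
  reg <- roh_region_scan(segs, ph, map)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$min_aff, 7L)
  expect_equal(reg$max_aff, 10L)
  expect_equal(reg$num_unaff, 0L)
  expect_equal(reg$start_bp, map$position_bp[30])
  expect_equal(reg$end_bp, map$position_bp[70])

  # only 9 cases in the core: no rule-(a) region, but rule (b) fires
  segs9 <- segs[segs$sample_id != "ca10", ]
  reg9 <- roh_region_scan(segs9, ph, map)
  expect_equal(nrow(reg9), 1L)
  expect_equal(reg9$rule, "cases7_controls0")
  expect_equal(reg9$max_aff, 9L)

  # a control segment stops the extension at its boundary
  segs_ctrl <- rbind(segs, seg("co01", 25, 35))
  reg_c <- roh_region_scan(segs_ctrl, ph, map)
  expect_equal(nrow(reg_c), 1L)
  expect_equal(reg_c$start_bp, map$position_bp[36])
  expect_equal(reg_c$end_bp, map$position_bp[70])
  expect_equal(reg_c$num_unaff, 0L)
})

test_that("region scan is symmetric under coordinate reversal", {
  map <- uniform_map(60, spacing_bp = 100000)
  ph <- data.frame(sample_id = sprintf("ca%02d", 1:12),
                   status = rep("case", 12))
  ph$status[11:12] <- "control"
  seg <- function(id, i0, i1)
    data.frame(sample_id = id, chromosome = "1",
               start_bp = map$position_bp[i0],
               end_bp = map$position_bp[i1], n_snps = i1 - i0 + 1L,
               n_het = 0L, length_kb = 1)
  segs <- do.call(rbind, lapply(1:10, function(i)
    seg(sprintf("ca%02d", i), 10 + i, 40 + i)))
  fwd <- roh_region_scan(segs, ph, map)

  # mirror: position -> max + min - position
  lim <- max(map$position_bp) + min(map$position_bp)
  map_rev <- marker_map(map$marker_id, map$chromosome,
                        sort(lim - map$position_bp), map$pfb, map$gc_frac)
  segs_rev <- segs
  segs_rev$start_bp <- lim - segs$end_bp
  segs_rev$end_bp <- lim - segs$start_bp
  rev <- roh_region_scan(segs_rev, ph, map_rev)
  expect_equal(nrow(rev), nrow(fwd))
  expect_equal(sort(lim - rev$end_bp), sort(fwd$start_bp))
  expect_equal(rev$max_aff, fwd$max_aff)
})
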
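test_that("allele frequencies are simple ratios with guarded domain", {
  expect_equal(allele_frequency(16, 32), 0.5)
  expect_equal(allele_frequency(32, 32), 1.0)
  expect_equal(allele_frequency(0, 10), 0.0)
  expect_error(allele_frequency(1, 0), "depth 0")
  expect_error(allele_frequency(5, 3), "alt_count")
})

test_that("a single 10-SNP window averages its member AFs", {
  tr <- data.frame(chrom = "chrA", pos = (1:10) * 100,
                   af_mut = seq(0.1, 1.0, by = 0.1), af_wt = 0.5)
  w <- sliding_window_mean(tr, 10)
  expect_equal(nrow(w), 1L)
  expect_equal(w$af_mut_mean, 0.55)
  expect_equal(w$af_wt_mean, 0.5)
  expect_equal(w$start_bp, 100)
  expect_equal(w$end_bp, 1000)
  # nine SNPs cannot fill a 10-SNP window
  expect_equal(nrow(sliding_window_mean(tr[1:9, ], 10)), 0L)
  expect_error(sliding_window_mean(tr, 0), "window_snps")
})

test_that("window means match the brute-force oracle on random multi-chromosome tracks", {
  set.seed(7)
  for (rep in 1:5) {
    tr <- data.frame(
      chrom = sample(c("c1", "c2", "c3"), 120, replace = TRUE),
      pos = sample.int(1e6, 120),
      af_mut = runif(120), af_wt = runif(120)
    )
    for (w in c(3, 10)) {
      got <- sliding_window_mean(tr, w)
      want <- oracle_window_means(tr, w)
      got <- got[order(got$chrom, got$start_idx), ]
      want <- want[order(want$chrom, want$start_idx), ]
      expect_equal(got$af_mut_mean, want$af_mut_mean)
      expect_equal(got$af_wt_mean, want$af_wt_mean)
      expect_equal(got$mid_bp, want$mid_bp)
    }
  }
})

test_that("region calling applies the dual thresholds and merges windows", {
  # unlinked genome: nothing passes
  flat <- data.frame(chrom = "c1", start_idx = 1:20, end_idx = 10:29,
                     start_bp = (1:20) * 100, end_bp = (10:29) * 100,
                     mid_bp = (5:24) * 100,
                     af_mut_mean = 0.5, af_wt_mean = 0.5, n_snps = 10)
  expect_equal(nrow(call_candidate_regions(flat)), 0L)

  # 20 SNPs all AF_mut = 1, AF_wt = 0.33: every window passes, one region
  tr <- data.frame(chrom = "c1", pos = (1:20) * 1000,
                   af_mut = 1.0, af_wt = 0.33)
  w <- sliding_window_mean(tr, 10)
  reg <- call_candidate_regions(w)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start_bp, 1000)
  expect_equal(reg$end_bp, 20000)
  expect_equal(reg$n_windows, 11L)
  expect_error(call_candidate_regions(w, t_high = 0.4, t_low = 0.95), "t_low")
})

test_that("called regions never overlap and merging ignores window order", {
  set.seed(11)
  for (rep in 1:10) {
    tr <- data.frame(chrom = sample(c("c1", "c2"), 80, TRUE),
                     pos = sample.int(1e6, 80),
                     af_mut = sample(c(0.3, 0.99), 80, TRUE),
                     af_wt = sample(c(0.2, 0.6), 80, TRUE))
    w <- sliding_window_mean(tr, 5)
    reg <- call_candidate_regions(w)
    if (nrow(reg) > 1) {
      for (cn in unique(reg$chrom)) {
        r <- reg[reg$chrom == cn, ]
        if (nrow(r) > 1) expect_true(all(r$start_bp[-1] > r$end_bp[-nrow(r)]))
      }
    }
    shuf <- w[sample.int(nrow(w)), ]
    expect_equal(call_candidate_regions(shuf), reg)
  }
})

test_that("the study-design simulation recovers the causal region", {
  sim <- simulate_bulk_experiment(bsa_preset(), seed = 101)
  sc <- bsa_scan(sim$table, causal = sim$truth)
  expect_gte(nrow(sc$regions), 1L)
  expect_true(any(sc$regions$contains_causal))
  w <- window_at(sc, sim$truth$chrom, sim$truth$pos)
  expect_gt(w$af_mut_mean, 0.95)
  expect_lt(w$af_wt_mean, 0.4)
})

test_that("an introgression block adds a high-AF region that ranks below the causal one", {
  # condition on a replicate where the causal region is detected (detection
  # probability is measured separately); this example exercises region
  # multiplicity and ranking in the two-high-AF-regions scenario
  sim <- NULL
  for (s in c(55, 101, 202, 303, 404)) {
    cand <- feasible_sim(s)
    sc0 <- bsa_scan(cand$table, causal = cand$truth)
    if (any(sc0$regions$contains_causal)) { sim <- cand; break }
  }
  expect_false(is.null(sim))
  # fixed divergent block on the causal chromosome, far from the causal site
  tab <- inject_introgression_block(
    sim$table, list(chrom = "chr12", start = 40e6, end = 50e6),
    af_both_bulks = 1.0, genome = tomato_genome(), seed = 56
  )
  track <- af_track(filter_depth(tab))
  w <- sliding_window_mean(track, 10)
  high <- call_candidate_regions(w, rule = "high_only",
                                 causal = sim$truth)
  expect_gte(nrow(high), 2L)
  expect_equal(sum(high$contains_causal), 1L)
  ranked <- rank_regions(high)
  expect_true(ranked$contains_causal[1])
  # the block alone fails the dual rule
  dual <- call_candidate_regions(w, causal = sim$truth)
  block_rows <- dual$chrom == "chr12" & dual$start_bp >= 40e6
  expect_false(any(block_rows))
  # a 0.5-AF block adds no candidate region: calls match the untouched table
  tab2 <- inject_introgression_block(
    sim$table, list(chrom = "chr12", start = 40e6, end = 50e6),
    af_both_bulks = 0.5, genome = tomato_genome(), seed = 57
  )
  w2 <- sliding_window_mean(af_track(filter_depth(tab2)), 10)
  w0 <- sliding_window_mean(af_track(filter_depth(sim$table)), 10)
  expect_equal(call_candidate_regions(w2, rule = "high_only"),
               call_candidate_regions(w0, rule = "high_only"))
})

test_that("rank_regions orders by causal plausibility with documented tie-breaks", {
  regions <- data.frame(
    chrom = c("c1", "c2", "c3"),
    start_bp = c(100, 100, 100), end_bp = c(200, 200, 200),
    n_windows = c(5L, 8L, 5L),
    min_af_mut = c(0.97, 1.00, 0.97),
    max_af_wt = c(0.30, 0.99, 0.20)
  )
  ranked <- rank_regions(regions)
  # the both-bulks-high block (c2) drops last despite the highest min AF_mut
  expect_equal(ranked$chrom, c("c3", "c1", "c2"))
  expect_equal(ranked$rank, 1:3)
  single <- rank_regions(regions[1, ])
  expect_equal(single$chrom, "c1")
  empty <- rank_regions(regions[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("bsa_scan objects print, summarise and plot", {
  sim <- simulate_bulk_experiment(tiny_config(), seed = 77)
  sc <- bsa_scan(sim$table, causal = sim$truth)
  expect_s3_class(sc, "bsa_scan")
  expect_output(print(sc), "allele-frequency scan")
  expect_output(print(summary(sc)), "mean mutant-bulk AF")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(sc))
})
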
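test_that("simulate_ems_variants honours count, ordering, uniqueness and determinism", {
  g <- tomato_genome()
  v0 <- simulate_ems_variants(g, 0, causal_shn2(), seed = 1)
  expect_equal(nrow(v0), 1L)
  expect_true(v0$is_causal)
  expect_equal(v0$pos, 2751259)

  v <- simulate_ems_variants(g, 500, causal_shn2(), seed = 3)
  expect_equal(nrow(v), 501L)
  expect_equal(sum(v$is_causal), 1L)
  for (cn in unique(v$chrom)) {
    p <- v$pos[v$chrom == cn]
    expect_true(all(diff(p) > 0))
  }
  v2 <- simulate_ems_variants(g, 500, causal_shn2(), seed = 3)
  expect_identical(v, v2)

  expect_error(
    simulate_ems_variants(g, 0, list(chrom = "chr12", pos = 1e9,
                                     ref = "G", alt = "T")),
    "outside"
  )
})

test_that("background substitutions follow the EMS transition spectrum", {
  g <- one_chrom_genome()
  v <- simulate_ems_variants(g, 2000, one_chrom_causal(), seed = 5,
                             transition_prob = 1)
  bg <- v[!v$is_causal, ]
  expect_true(all(paste0(bg$ref, bg$alt) %in% c("GA", "CT")))
  expect_true(all(v$ref != v$alt))
})

test_that("BC1F2 meiosis gives single parental segments without recombination", {
  g <- genome_model("chr1", 1e6, 0)
  v <- simulate_ems_variants(g, 0, list(chrom = "chr1", pos = 5e5,
                                        ref = "G", alt = "T"), seed = 1)
  pop <- make_bc1f2(v, 20, g, seed = 2)
  for (ind in pop$individuals) {
    expect_length(ind[["chr1"]]$h1$ends, 1L)
    expect_length(ind[["chr1"]]$h2$ends, 1L)
    expect_equal(ind[["chr1"]]$h1$ends, 1e6)
  }
})

test_that("BC1F2 segregates ~25% mutant phenotype and 1:2:1 causal genotypes", {
  g <- one_chrom_genome()
  v <- simulate_ems_variants(g, 0, one_chrom_causal(), seed = 1)
  pop <- make_bc1f2(v, 10000, g, seed = 11)
  frac <- mean(pop$phenotype == "mutant_phenotype")
  expect_lt(abs(frac - 0.25), 0.015)
  counts <- table(factor(pop$causal_genotype, 0:2))
  ht <- suppressWarnings(stats::chisq.test(counts, p = c(1, 2, 1) / 4))
  expect_gt(ht$p.value, 0.01)
  # phenotype consistent with causal genotype under full penetrance
  expect_identical(pop$phenotype == "mutant_phenotype",
                   pop$causal_genotype == 2L)
})

test_that("causal genotype frequencies are calibrated across seeds", {
  g <- one_chrom_genome()
  v <- simulate_ems_variants(g, 0, one_chrom_causal(), seed = 1)
  pass <- vapply(1:20, function(s) {
    pop <- make_bc1f2(v, 10000, g, seed = 100 + s)
    counts <- table(factor(pop$causal_genotype, 0:2))
    ht <- suppressWarnings(stats::chisq.test(counts, p = c(1, 2, 1) / 4))
    ht$p.value > 0.01
  }, TRUE)
  expect_gte(sum(pass), 19L)
})

test_that("select_bulks samples disjoint within-phenotype bulks and errors clearly", {
  g <- one_chrom_genome()
  v <- simulate_ems_variants(g, 0, one_chrom_causal(), seed = 1)
  pop <- make_bc1f2(v, 216, g, seed = 4)
  bulks <- select_bulks(pop, 38, seed = 5)
  expect_length(bulks$mutant_bulk, 38L)
  expect_length(bulks$wt_like_bulk, 38L)

  b0 <- select_bulks(pop, 0, seed = 6)
  expect_length(b0$mutant_bulk, 0L)
  expect_length(b0$wt_like_bulk, 0L)

  pop$phenotype[] <- "wt_like"
  expect_error(select_bulks(pop, 10, seed = 7), "mutant_phenotype")
})

test_that("pooled reads are exact for a fixed bulk and error-free sequencing", {
  g <- one_chrom_genome()
  v <- simulate_ems_variants(g, 0, one_chrom_causal(), seed = 1)
  pop <- make_bc1f2(v, 216, g, seed = 4)
  bulks <- select_bulks(pop, 38, seed = 5)
  counts <- simulate_pooled_reads(bulks$mutant_bulk, v, mean_depth = 40,
                                  error_rate = 0, seed = 6)
  # mutant bulk is homozygous causal by construction
  expect_equal(counts$alt_count, counts$depth)
  expect_error(simulate_pooled_reads(list(), v, 32, 0.002), "empty")
})

test_that("variants unlinked to the causal locus sit near AF 0.5 in both bulks", {
  # expectation property: a finite bulk drifts per seed, so average the
  # bulk-mean unlinked AF over replicate experiments
  g <- genome_model(c("chr12", "chr05"), c(68.1e6, 65.9e6), c(1, 1))
  set.seed(1)
  v <- rbind(
    data.frame(chrom = "chr05", pos = sort(sample.int(65e6, 400)),
               ref = "G", alt = "A", is_causal = FALSE),
    data.frame(chrom = "chr12", pos = 2751259, ref = "G", alt = "T",
               is_causal = TRUE)
  )
  attr(v, "genome") <- g
  means <- matrix(NA_real_, 6, 2)
  for (s in 1:6) {
    pop <- make_bc1f2(v, 160, g, seed = 2 + s)
    bulks <- select_bulks(pop, 25, seed = 3 + s)
    means[s, ] <- vapply(bulks, function(bulk) {
      counts <- simulate_pooled_reads(bulk, v, 32, 0, seed = 4 + s)
      unlinked <- counts$chrom == "chr05"
      mean(counts$alt_count[unlinked] / counts$depth[unlinked])
    }, 0)
  }
  expect_lt(abs(mean(means[, 1]) - 0.5), 0.05)  # mutant bulk
  expect_lt(abs(mean(means[, 2]) - 0.5), 0.05)  # WT-like bulk
})

test_that("pooled-read sampler matches the binomial sampling oracle in distribution", {
  # zero-recombination chromosome: every site shares the bulk's causal-locus
  # carrier fraction, giving a known true allele fraction
  g <- genome_model("chr1", 1e6, 0)
  set.seed(10)
  v <- data.frame(chrom = "chr1", pos = sort(sample.int(1e6, 10000)),
                  ref = "G", alt = "A", is_causal = FALSE)
  v$is_causal[5000] <- TRUE
  v$ref[5000] <- "G"; v$alt[5000] <- "T"
  pop <- make_bc1f2(v, 40, g, seed = 20)
  bulk <- pop$individuals[1:20]
  geno_total <- sum(pop$causal_genotype[1:20])
  p_true <- geno_total / 40
  err <- 0.002
  p_eff <- p_true * (1 - err) + (1 - p_true) * err

  counts <- simulate_pooled_reads(bulk, v, mean_depth = 32,
                                  error_rate = err, seed = 21)
  set.seed(22)
  oracle <- stats::rbinom(10000, stats::rpois(10000, 32), p_eff)
  ks <- suppressWarnings(stats::ks.test(counts$alt_count, oracle))
  expect_gt(ks$p.value, 0.01)
})

test_that("penetrance below one removes phenotype expression from some homozygotes", {
  g <- one_chrom_genome()
  v <- simulate_ems_variants(g, 0, one_chrom_causal(), seed = 1)
  pop <- make_bc1f2(v, 4000, g, seed = 8, penetrance = 0.5)
  n_hom <- sum(pop$causal_genotype == 2L)
  n_expr <- sum(pop$phenotype == "mutant_phenotype")
  expect_lt(n_expr, n_hom)
  expect_gt(n_expr, 0.3 * n_hom)
  expect_true(all(pop$causal_genotype[pop$phenotype == "mutant_phenotype"] == 2L))
})

test_that("introgression blocks overwrite both bulks and validate their interval", {
  tab <- data.frame(chrom = "chr12", pos = c(1e6, 2e6, 3e6),
                    ref = "G", alt = "A",
                    depth_wt = 50L, alt_wt = 5L,
                    depth_mut = 50L, alt_mut = 5L)
  out <- inject_introgression_block(tab, list(chrom = "chr12", start = 1.5e6,
                                              end = 2.5e6), 1.0, seed = 1)
  expect_equal(out$alt_wt[2], 50L)
  expect_equal(out$alt_mut[2], 50L)
  expect_equal(out$alt_wt[c(1, 3)], c(5L, 5L))
  # empty interval is a no-op
  expect_identical(
    inject_introgression_block(tab, list(chrom = "chr12", start = 5e6,
                                         end = 4e6), 1.0),
    tab
  )
  expect_error(
    inject_introgression_block(tab, list(chrom = "chr99", start = 1,
                                         end = 2), 1.0,
                               genome = tomato_genome()),
    "chr99"
  )
})

test_that("YAML configuration overrides preset fields", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "n_population: 50",
    "n_per_bulk: 10",
    "error_rate: 0.01",
    "causal:",
    "  chrom: chr01",
    "  pos: 1000000",
    "  ref: G",
    "  alt: T"
  ), path)
  cfg <- read_sim_config(path)
  expect_equal(cfg$n_population, 50)
  expect_equal(cfg$n_per_bulk, 10)
  expect_equal(cfg$error_rate, 0.01)
  expect_equal(cfg$causal$chrom, "chr01")
  expect_equal(cfg$mean_depth, 32)     # preset retained
  writeLines("bogus_field: 1", path)
  expect_error(read_sim_config(path), "unknown config")
})

test_that("exported experiments round-trip through their VCF", {
  cfg <- tiny_config()
  sim <- simulate_bulk_experiment(cfg, seed = 3)
  prefix <- file.path(tempdir(), "simexp")
  paths <- export_experiment(sim, prefix)
  tab <- read_bulk_vcf(paths[1])
  expect_equal(nrow(tab), nrow(sim$table))
  expect_equal(tab$alt_mut, sim$table$alt_mut)
  truth <- read.delim(paths[3])
  expect_equal(truth$pos, sim$truth$pos)
})
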
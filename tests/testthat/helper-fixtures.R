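# Shared fixtures and independent oracles used across the suite.

# single-chromosome genome carrying the causal locus (fast population sims)
one_chrom_genome <- function() {
  genome_model("chr12", 68.1e6, 1.0)
}

one_chrom_causal <- function() {
  list(chrom = "chr12", pos = 2751259, ref = "G", alt = "T")
}

# scaled-down full pipeline configuration for quick end-to-end checks
tiny_config <- function() {
  cfg <- bsa_preset()
  cfg$n_background <- 300L
  cfg$n_population <- 80L
  cfg$n_per_bulk <- 15L
  cfg
}

# brute-force sliding-window means: literal loop over every window
oracle_window_means <- function(track, window_snps, step = 1) {
  out <- list()
  for (cn in unique(track$chrom)) {
    tr <- track[track$chrom == cn, , drop = FALSE]
    tr <- tr[order(tr$pos), , drop = FALSE]
    n <- nrow(tr)
    if (n < window_snps) next
    for (s in seq(1, n - window_snps + 1, by = step)) {
      idx <- s:(s + window_snps - 1)
      out[[length(out) + 1]] <- data.frame(
        chrom = cn, start_idx = s,
        af_mut_mean = mean(tr$af_mut[idx]),
        af_wt_mean = mean(tr$af_wt[idx]),
        mid_bp = mean(tr$pos[idx])
      )
    }
  }
  do.call(rbind, out)
}

# brute-force DEG predicate scan
oracle_filter_degs <- function(records, lfc_cut = 1, q_cut = 0.05,
                               fpkm_cut = 5) {
  keep <- logical(nrow(records))
  has_fpkm <- all(c("fpkm_wt", "fpkm_mut") %in% names(records))
  for (i in seq_len(nrow(records))) {
    ok <- abs(records$log2fc[i]) >= lfc_cut && records$q[i] < q_cut
    if (ok && has_fpkm) {
      ok <- records$fpkm_wt[i] > fpkm_cut || records$fpkm_mut[i] > fpkm_cut
    }
    keep[i] <- isTRUE(ok)
  }
  records[keep, , drop = FALSE]
}

# whole-protein rebuild-and-diff consequence oracle for CDS positions;
# independent of the per-codon classifier (splices, mutates the genome,
# translates with Biostrings and diffs the proteins)
oracle_cds_consequence <- function(genome_seq, cds_df, strand, pos, alt) {
  splice <- function(seqchars) {
    segs <- lapply(seq_len(nrow(cds_df)), function(k) {
      paste(seqchars[cds_df$start[k]:cds_df$end[k]], collapse = "")
    })
    s <- paste(unlist(segs), collapse = "")
    if (strand == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    s
  }
  xlate <- function(s) {
    # plain code-table translation: initiator-codon special-casing off so
    # that first-codon changes are judged like any other codon
    as.character(Biostrings::translate(Biostrings::DNAString(s),
                                       no.init.codon = TRUE))
  }
  chars <- strsplit(as.character(genome_seq), "")[[1]]
  ref_prot <- xlate(splice(chars))
  chars[pos] <- alt
  mut_prot <- xlate(splice(chars))
  ra <- strsplit(ref_prot, "")[[1]]
  ma <- strsplit(mut_prot, "")[[1]]
  diff <- which(ra != ma)
  if (!length(diff)) return("synonymous")
  i <- diff[1]
  if (ma[i] == "*") return("nonsense")
  if (ra[i] == "*") return("stop_loss")
  "missense"
}

# full-preset simulation conditioned on experiment feasibility: with 216
# plants a rare seed yields fewer than 38 mutant-phenotype individuals (the
# real study was itself conditioned on having 38 glossy plants); such
# populations are re-drawn from a derived seed
feasible_sim <- function(seed) {
  for (k in 0:9) {
    sim <- tryCatch(
      simulate_bulk_experiment(bsa_preset(), seed = seed + 1000000L * k),
      error = function(e) NULL
    )
    if (!is.null(sim)) return(sim)
  }
  stop("no feasible population after 10 attempts")
}

# small hand-written VCF used for parser edge cases
write_fixture_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "wt_like_bulk", "mutant_bulk", sep = "\t"),
    paste("chr1", "100", ".", "G", "T", ".", "PASS", ".", "GT:AD:DP",
          "./.:30,2:32", "./.:10,22:32", sep = "\t"),
    paste("chr1", "200", ".", "GA", "G", ".", "PASS", ".", "GT:AD:DP",
          "./.:20,5:25", "./.:18,6:24", sep = "\t"),
    paste("chr1", "300", ".", "A", "T,C", ".", "PASS", ".", "GT:AD:DP",
          "./.:5,3,2:10", "./.:6,2,4:12", sep = "\t")
  )
  writeLines(lines, path)
  path
}
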
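#' Simulate an EMS-induced variant set with one causal mutation
#'
#' Draws `n_background` background EMS variants uniformly along the genome
#' (chromosomes chosen proportionally to physical length) and adds the causal
#' variant. Background substitutions follow the canonical EMS spectrum:
#' with probability `transition_prob` a G>A or C>T transition, otherwise a
#' random transversion. Position collisions are resolved by resampling,
#' never by dropping variants.
#'
#' @param genome a [genome_model()].
#' @param n_background number of non-causal variants (`>= 0`).
#' @param causal list with elements `chrom`, `pos` (1-based), `ref`, `alt`
#'   describing the causal single-nucleotide variant.
#' @param seed integer seed; the call is deterministic for a fixed seed.
#' @param transition_prob probability that a background variant is a
#'   canonical EMS G:C->A:T transition.
#'
#' @return A `data.frame` with columns `chrom`, `pos`, `ref`, `alt`,
#'   `is_causal`, sorted by chromosome (genome order) and position, with
#'   unique positions per chromosome and exactly one causal row.
#' @export
#' @examples
#' g <- tomato_genome()
#' v <- simulate_ems_variants(g, 100, causal_shn2(), seed = 1)
#' sum(v$is_causal)
simulate_ems_variants <- function(genome, n_background, causal, seed = NULL,
                                  transition_prob = 0.98) {
  stopifnot(inherits(genome, "genome_model"))
  if (n_background < 0) stop("'n_background' must be >= 0")
  causal <- as.list(causal)
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(causal))) {
    stop("'causal' must provide chrom, pos, ref and alt")
  }
  causal$pos <- as.numeric(causal$pos)
  len <- chrom_length(genome, causal$chrom)
  if (causal$pos < 1 || causal$pos > len) {
    stop("causal position ", causal$pos, " outside chromosome ", causal$chrom)
  }
  if (causal$ref == causal$alt) stop("causal ref and alt must differ")
  if (!is.null(seed)) set.seed(seed)

  n_background <- as.integer(n_background)
  if (n_background > 0) {
    chroms <- sample(genome$chrom, n_background, replace = TRUE,
                     prob = genome$length_bp)
    pos <- numeric(n_background)
    for (cn in unique(chroms)) {
      idx <- which(chroms == cn)
      len_c <- chrom_length(genome, cn)
      taken <- if (identical(cn, causal$chrom)) causal$pos else numeric(0)
      p <- floor(runif(length(idx), 1, len_c + 1))
      # resample collisions (with the causal site or among themselves)
      repeat {
        bad <- duplicated(p) | p %in% taken
        if (!any(bad)) break
        p[bad] <- floor(runif(sum(bad), 1, len_c + 1))
      }
      pos[idx] <- p
    }
    is_ts <- runif(n_background) < transition_prob
    ref <- character(n_background)
    alt <- character(n_background)
    gc_ref <- sample(c("G", "C"), n_background, replace = TRUE)
    ref[is_ts] <- gc_ref[is_ts]
    alt[is_ts] <- ifelse(gc_ref[is_ts] == "G", "A", "T")
    if (any(!is_ts)) {
      tv_ref <- sample(c("A", "C", "G", "T"), sum(!is_ts), replace = TRUE)
      tv_partners <- list(A = c("C", "T"), G = c("C", "T"),
                          C = c("A", "G"), T = c("A", "G"))
      tv_alt <- vapply(tv_ref, function(b) sample(tv_partners[[b]], 1), "")
      ref[!is_ts] <- tv_ref
      alt[!is_ts] <- tv_alt
    }
    bg <- data.frame(chrom = chroms, pos = pos, ref = ref, alt = alt,
                     is_causal = FALSE, stringsAsFactors = FALSE)
  } else {
    bg <- data.frame(chrom = character(0), pos = numeric(0),
                     ref = character(0), alt = character(0),
                     is_causal = logical(0), stringsAsFactors = FALSE)
  }
  out <- rbind(bg, data.frame(chrom = causal$chrom, pos = causal$pos,
                              ref = causal$ref, alt = causal$alt,
                              is_causal = TRUE, stringsAsFactors = FALSE))
  ord <- order(match(out$chrom, genome$chrom), out$pos)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "genome") <- genome
  out
}

#' The shn2-style causal variant
#'
#' Convenience constructor for the default causal variant used by the
#' simulation preset: a G>T transversion on chromosome 12 at position
#' 2,751,259, the kind of single exonic change that underlies a recessive
#' glossy-fruit cuticle mutant.
#'
#' @return list with `chrom`, `pos`, `ref`, `alt`.
#' @export
causal_shn2 <- function() {
  list(chrom = "chr12", pos = 2751259, ref = "G", alt = "T")
}

# One meiotic product of a heterozygote: alternating parental-origin
# segments. Crossover count ~ Poisson(genetic length in Morgans), positions
# uniform on the physical map (Haldane, no interference). Origin 1 = mutant
# parent, 0 = wild-type parent. Represented as parallel vectors of segment
# right edges (`ends`, last = chromosome length) and origins.
sim_gamete <- function(len_bp, len_morgan) {
  n_co <- rpois(1L, len_morgan)
  start <- sample(0:1, 1L)
  if (n_co == 0L) {
    list(ends = len_bp, origin = start)
  } else {
    cuts <- sort(runif(n_co, 1, len_bp))
    list(ends = c(cuts, len_bp),
         origin = rep_len(c(start, 1L - start), n_co + 1L))
  }
}

# Parental origin of a haplotype at the given positions (vectorised).
hap_origin_at <- function(hap, pos) {
  idx <- pmin(findInterval(pos, hap$ends) + 1L, length(hap$ends))
  hap$origin[idx]
}

#' Simulate a BC1F2 population segregating a recessive causal mutation
#'
#' The BC1F1 parent is heterozygous at every EMS variant (mutant line
#' backcrossed to the non-mutagenized parent). Each BC1F2 individual is
#' produced by two independent simulated meioses of the BC1F1 heterozygote:
#' the crossover count per chromosome is Poisson with mean equal to the
#' genetic length in Morgans and crossover positions are uniform on the
#' physical map. Phenotype is assigned recessively from the causal-locus
#' genotype: an individual shows the mutant phenotype iff it is homozygous
#' for the causal allele (and, when `penetrance < 1`, with that probability).
#'
#' @param variants variant set from [simulate_ems_variants()] (only the
#'   causal variant determines phenotype).
#' @param n number of individuals (`>= 1`).
#' @param genome a [genome_model()].
#' @param seed integer seed.
#' @param penetrance probability that a homozygous-causal individual
#'   expresses the mutant phenotype (default 1, full penetrance).
#'
#' @return An object of class `"bc1f2_population"`: a list with
#'   `individuals` (each a list of per-chromosome haplotype pairs),
#'   `phenotype` (`"mutant_phenotype"` or `"wt_like"`), `causal_genotype`
#'   (0/1/2 copies of the causal allele), `genome` and `causal`.
#' @export
#' @examples
#' g <- genome_model("chr1", 1e6, 0.5)
#' v <- simulate_ems_variants(g, 0, list(chrom = "chr1", pos = 5e5,
#'                                       ref = "G", alt = "T"), seed = 1)
#' pop <- make_bc1f2(v, 50, g, seed = 2)
#' table(pop$phenotype)
make_bc1f2 <- function(variants, n, genome, seed = NULL, penetrance = 1) {
  stopifnot(inherits(genome, "genome_model"))
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("'n' must be >= 1")
  if (penetrance < 0 || penetrance > 1) stop("'penetrance' must be in [0, 1]")
  causal <- variants[variants$is_causal, , drop = FALSE]
  if (nrow(causal) != 1L) stop("variant set must contain exactly one causal variant")
  if (!is.null(seed)) set.seed(seed)

  n_chr <- nrow(genome)
  causal_ci <- match(causal$chrom, genome$chrom)
  individuals <- vector("list", n)
  causal_geno <- integer(n)
  for (i in seq_len(n)) {
    haps <- vector("list", n_chr)
    for (ci in seq_len(n_chr)) {
      haps[[ci]] <- list(
        h1 = sim_gamete(genome$length_bp[ci], genome$length_morgan[ci]),
        h2 = sim_gamete(genome$length_bp[ci], genome$length_morgan[ci])
      )
    }
    names(haps) <- genome$chrom
    individuals[[i]] <- haps
    hp <- haps[[causal_ci]]
    causal_geno[i] <- hap_origin_at(hp$h1, causal$pos) +
      hap_origin_at(hp$h2, causal$pos)
  }
  expressed <- causal_geno == 2L
  if (penetrance < 1) {
    expressed <- expressed & (runif(n) < penetrance)
  }
  structure(
    list(
      individuals = individuals,
      phenotype = ifelse(expressed, "mutant_phenotype", "wt_like"),
      causal_genotype = causal_geno,
      genome = genome,
      causal = list(chrom = causal$chrom, pos = causal$pos,
                    ref = causal$ref, alt = causal$alt)
    ),
    class = "bc1f2_population"
  )
}

#' @export
print.bc1f2_population <- function(x, ...) {
  cat("BC1F2 population:", length(x$individuals), "individuals\n")
  cat("  causal locus:", x$causal$chrom, x$causal$pos,
      paste0(x$causal$ref, ">", x$causal$alt), "\n")
  tab <- table(factor(x$phenotype, c("mutant_phenotype", "wt_like")))
  cat("  phenotypes: ", tab[["mutant_phenotype"]], " mutant_phenotype / ",
      tab[["wt_like"]], " wt_like\n", sep = "")
  invisible(x)
}

# Count of mutant-origin haplotypes (0/1/2) per individual at arbitrary loci.
# `positions` is a numeric vector on a single chromosome.
population_genotypes <- function(individuals, chrom, positions) {
  m <- vapply(individuals, function(ind) {
    hp <- ind[[chrom]]
    hap_origin_at(hp$h1, positions) + hap_origin_at(hp$h2, positions)
  }, integer(length(positions)))
  # individuals in columns; return individuals x loci
  if (length(positions) == 1L) m <- matrix(m, nrow = 1L)
  t(m)
}

#' Select phenotype-contrasted bulks from a population
#'
#' Randomly samples, without replacement, `n_per_bulk` individuals of each
#' phenotype class to form the two bulks submitted to pooled sequencing.
#'
#' @param pop a [make_bc1f2()] population.
#' @param n_per_bulk bulk size (the study design used 38 per bulk).
#' @param seed integer seed.
#'
#' @return list with elements `mutant_bulk` and `wt_like_bulk`, each a list
#'   of individuals (disjoint by construction), carrying the population's
#'   genome and causal locus as attributes.
#' @export
select_bulks <- function(pop, n_per_bulk, seed = NULL) {
  stopifnot(inherits(pop, "bc1f2_population"))
  n_per_bulk <- as.integer(n_per_bulk)
  if (n_per_bulk < 0) stop("'n_per_bulk' must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (cls in c("mutant_phenotype", "wt_like")) {
    idx <- which(pop$phenotype == cls)
    if (length(idx) < n_per_bulk) {
      stop("not enough '", cls, "' individuals: have ", length(idx),
           ", need ", n_per_bulk)
    }
    pick <- if (n_per_bulk > 0) sample(idx, n_per_bulk) else integer(0)
    bulk <- pop$individuals[pick]
    attr(bulk, "genome") <- pop$genome
    attr(bulk, "causal") <- pop$causal
    out[[if (cls == "mutant_phenotype") "mutant_bulk" else "wt_like_bulk"]] <- bulk
  }
  out
}

#' Simulate pooled sequencing of a bulk at a set of variants
#'
#' Per variant, the read depth is Poisson with mean `mean_depth`; each read
#' is drawn from a uniformly chosen chromosome copy among the bulk's `2n`
#' haplotypes, reports the mutant (alt) allele iff that copy is of mutant
#' parental origin at the site, and is then flipped with probability
#' `error_rate` (sequencing/mapping error).
#'
#' @param bulk a list of individuals, e.g. one element of [select_bulks()].
#' @param variants variant set from [simulate_ems_variants()].
#' @param mean_depth mean per-site depth (`> 0`); the study sequenced at
#'   ~32X.
#' @param error_rate per-read allele flip probability, in `[0, 0.5)`.
#' @param seed integer seed.
#'
#' @return `data.frame` with `chrom`, `pos`, `depth`, `alt_count`
#'   (`0 <= alt_count <= depth`), one row per variant in input order.
#' @export
simulate_pooled_reads <- function(bulk, variants, mean_depth = 32,
                                  error_rate = 0.002, seed = NULL) {
  if (length(bulk) == 0L) stop("bulk is empty")
  if (mean_depth <= 0) stop("'mean_depth' must be > 0")
  if (error_rate < 0 || error_rate >= 0.5) stop("'error_rate' must be in [0, 0.5)")
  if (!is.null(seed)) set.seed(seed)

  nv <- nrow(variants)
  depth <- integer(nv)
  alt_count <- integer(nv)
  for (cn in unique(variants$chrom)) {
    rows <- which(variants$chrom == cn)
    pos <- variants$pos[rows]
    # haplotype carrier status: loci x 2n logical matrix
    carriers <- matrix(FALSE, length(pos), 2L * length(bulk))
    for (i in seq_along(bulk)) {
      hp <- bulk[[i]][[cn]]
      carriers[, 2L * i - 1L] <- hap_origin_at(hp$h1, pos) == 1L
      carriers[, 2L * i] <- hap_origin_at(hp$h2, pos) == 1L
    }
    n_hap <- ncol(carriers)
    for (k in seq_along(rows)) {
      d <- rpois(1L, mean_depth)
      depth[rows[k]] <- d
      if (d == 0L) next
      copy <- sample.int(n_hap, d, replace = TRUE)
      is_alt <- carriers[k, copy]
      if (error_rate > 0) {
        flip <- runif(d) < error_rate
        is_alt <- xor(is_alt, flip)
      }
      alt_count[rows[k]] <- sum(is_alt)
    }
  }
  data.frame(chrom = variants$chrom, pos = variants$pos,
             depth = depth, alt_count = alt_count,
             stringsAsFactors = FALSE)
}

#' Combine per-bulk pooled counts into a two-bulk variant table
#'
#' @param variants variant set (provides `ref`/`alt`).
#' @param wt_counts,mut_counts outputs of [simulate_pooled_reads()] for the
#'   WT-like and mutant-phenotype bulks, row-aligned with `variants`.
#'
#' @return a variant table `data.frame` with columns `chrom`, `pos`, `ref`,
#'   `alt`, `depth_wt`, `alt_wt`, `depth_mut`, `alt_mut` (bulk order fixed:
#'   WT-like first, mutant second), sorted by chromosome and position.
#' @export
bulk_counts_table <- function(variants, wt_counts, mut_counts) {
  stopifnot(nrow(variants) == nrow(wt_counts),
            nrow(variants) == nrow(mut_counts),
            all(variants$pos == wt_counts$pos),
            all(variants$pos == mut_counts$pos))
  out <- data.frame(
    chrom = variants$chrom, pos = variants$pos,
    ref = variants$ref, alt = variants$alt,
    depth_wt = wt_counts$depth, alt_wt = wt_counts$alt_count,
    depth_mut = mut_counts$depth, alt_mut = mut_counts$alt_count,
    stringsAsFactors = FALSE
  )
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Overwrite a genomic interval with a fixed divergent block
#'
#' Models an introgression fragment from a wild relative that is fixed in
#' the mapping population: every variant inside the interval has its alt
#' counts redrawn as Binomial(depth, `af_both_bulks`) in BOTH bulks, so the
#' block mimics a high-allele-frequency region that is not linked to the
#' phenotype.
#'
#' @param table two-bulk variant table (see [bulk_counts_table()]).
#' @param interval list or vector with `chrom`, `start`, `end` (1-based,
#'   closed).
#' @param af_both_bulks target alt-allele fraction inside the block.
#' @param genome optional [genome_model()]; when supplied the interval is
#'   validated against it.
#' @param seed integer seed.
#'
#' @return the modified table. An interval containing no variants is a
#'   no-op.
#' @export
inject_introgression_block <- function(table, interval, af_both_bulks,
                                       genome = NULL, seed = NULL) {
  interval <- as.list(interval)
  stopifnot(all(c("chrom", "start", "end") %in% names(interval)))
  start <- as.numeric(interval$start); end <- as.numeric(interval$end)
  if (af_both_bulks < 0 || af_both_bulks > 1) stop("'af_both_bulks' must be in [0, 1]")
  if (!is.null(genome)) {
    len <- chrom_length(genome, interval$chrom)  # errors on unknown chromosome
    if (start < 1 || end > len) {
      stop("interval [", start, ", ", end, "] outside chromosome ",
           interval$chrom)
    }
  }
  if (start > end) return(table)
  hit <- table$chrom == interval$chrom & table$pos >= start & table$pos <= end
  if (!any(hit)) return(table)
  if (!is.null(seed)) set.seed(seed)
  table$alt_wt[hit] <- rbinom(sum(hit), table$depth_wt[hit], af_both_bulks)
  table$alt_mut[hit] <- rbinom(sum(hit), table$depth_mut[hit], af_both_bulks)
  table
}

#' Default simulation preset mirroring the mapping study design
#'
#' 12 tomato-like chromosomes, ~1300 background EMS variants genome-wide,
#' a BC1F2 population of 216 plants, bulks of 38, pooled sequencing at mean
#' depth 32 with a 0.002 per-read error rate, full penetrance.
#'
#' @return named list of simulation parameters consumed by
#'   [simulate_bulk_experiment()].
#' @export
bsa_preset <- function() {
  list(
    genome = tomato_genome(),
    causal = causal_shn2(),
    n_background = 1300L,
    transition_prob = 0.98,
    n_population = 216L,
    n_per_bulk = 38L,
    mean_depth = 32,
    error_rate = 0.002,
    penetrance = 1
  )
}

#' Read a simulation configuration from YAML
#'
#' The YAML file may supply any subset of the [bsa_preset()] fields
#' (`n_background`, `n_population`, `n_per_bulk`, `mean_depth`,
#' `error_rate`, `penetrance`, `transition_prob`, a `causal` block with
#' `chrom`/`pos`/`ref`/`alt`, and a `genome` block as a list of
#' `{name, length_bp, length_morgan}` entries); unspecified fields keep
#' their preset values.
#'
#' @param path path to a YAML file.
#' @return a configuration list as returned by [bsa_preset()].
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  preset <- bsa_preset()
  if (!is.null(cfg$genome)) {
    preset$genome <- genome_model(
      chrom = vapply(cfg$genome, `[[`, "", "name"),
      length_bp = vapply(cfg$genome, `[[`, 0, "length_bp"),
      length_morgan = vapply(cfg$genome, `[[`, 0, "length_morgan")
    )
    cfg$genome <- NULL
  }
  if (!is.null(cfg$causal)) {
    preset$causal <- cfg$causal
    cfg$causal <- NULL
  }
  known <- intersect(names(cfg), names(preset))
  unknown <- setdiff(names(cfg), names(preset))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  preset[known] <- cfg[known]
  preset
}

#' Run a full bulked-segregant simulation
#'
#' Chains [simulate_ems_variants()], [make_bc1f2()], [select_bulks()] and
#' [simulate_pooled_reads()] under one seed, returning every intermediate
#' product plus the combined two-bulk variant table.
#'
#' @param config parameter list, see [bsa_preset()] / [read_sim_config()].
#' @param seed integer seed; sub-seeds for each stage are derived from it.
#'
#' @return list with `variants`, `population`, `bulks`, `table` (two-bulk
#'   variant table) and `truth` (the causal variant).
#' @export
#' @examples
#' cfg <- bsa_preset()
#' cfg$n_background <- 120          # desk-scale example
#' cfg$n_population <- 60
#' cfg$n_per_bulk <- 10
#' sim <- simulate_bulk_experiment(cfg, seed = 1)
#' head(sim$table)
simulate_bulk_experiment <- function(config = bsa_preset(), seed = 1) {
  seed <- as.integer(seed)
  variants <- simulate_ems_variants(config$genome, config$n_background,
                                    config$causal, seed = seed,
                                    transition_prob = config$transition_prob)
  pop <- make_bc1f2(variants, config$n_population, config$genome,
                    seed = seed + 1L, penetrance = config$penetrance)
  bulks <- select_bulks(pop, config$n_per_bulk, seed = seed + 2L)
  wt_counts <- simulate_pooled_reads(bulks$wt_like_bulk, variants,
                                     config$mean_depth, config$error_rate,
                                     seed = seed + 3L)
  mut_counts <- simulate_pooled_reads(bulks$mutant_bulk, variants,
                                      config$mean_depth, config$error_rate,
                                      seed = seed + 4L)
  list(
    variants = variants,
    population = pop,
    bulks = bulks,
    table = bulk_counts_table(variants, wt_counts, mut_counts),
    truth = config$causal
  )
}

#' Export a simulated experiment to plain-text files
#'
#' Writes a two-sample VCF of bulk allele depths (`<prefix>.vcf`), a TSV of
#' per-individual causal genotypes and phenotypes (`<prefix>_genotypes.tsv`)
#' and a one-line truth file naming the causal variant
#' (`<prefix>_truth.tsv`).
#'
#' @param sim output of [simulate_bulk_experiment()].
#' @param out_prefix path prefix for the three files.
#' @return invisibly, the three paths.
#' @export
export_experiment <- function(sim, out_prefix) {
  vcf <- paste0(out_prefix, ".vcf")
  write_bulk_vcf(sim$table, vcf)
  gt <- data.frame(
    individual = seq_along(sim$population$individuals),
    phenotype = sim$population$phenotype,
    causal_genotype = sim$population$causal_genotype
  )
  gt_path <- paste0(out_prefix, "_genotypes.tsv")
  write.table(gt, gt_path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- data.frame(chrom = sim$truth$chrom, pos = sim$truth$pos,
                      ref = sim$truth$ref, alt = sim$truth$alt)
  truth_path <- paste0(out_prefix, "_truth.tsv")
  write.table(truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(vcf, gt_path, truth_path))
}
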
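#' Genotype a population at a marker scaffold
#'
#' Scores every individual of a simulated BC1F2 population at a set of
#' marker positions on one chromosome, emulating the KASP-style marker data
#' used for recombinant fine-mapping.
#'
#' @param pop a [make_bc1f2()] population.
#' @param chrom chromosome name.
#' @param positions marker positions (bp), any order.
#' @return an object of class `"marker_genotypes"`: list with `genotypes`
#'   (individuals x markers character matrix of `"hom_mut"`, `"het"`,
#'   `"hom_wt"`), `positions` (sorted), `phenotype` and `chrom`.
#' @export
marker_genotypes <- function(pop, chrom, positions) {
  stopifnot(inherits(pop, "bc1f2_population"))
  positions <- sort(as.numeric(positions))
  counts <- population_genotypes(pop$individuals, chrom, positions)
  geno <- matrix(c("hom_wt", "het", "hom_mut")[counts + 1L],
                 nrow = nrow(counts),
                 dimnames = list(NULL, paste0("M", seq_along(positions))))
  structure(
    list(genotypes = geno, positions = positions,
         phenotype = pop$phenotype, chrom = chrom),
    class = "marker_genotypes"
  )
}

#' Read / write a marker-genotype matrix as TSV
#'
#' The TSV holds one row per individual: a `phenotype` column followed by
#' one column per marker; the header row carries the marker positions as
#' `M<pos>` column names.
#'
#' @param data a `marker_genotypes` object (for writing).
#' @param path file path.
#' @param chrom chromosome label recorded on reading (default `"chr"`).
#' @return `read_marker_tsv()` returns a `marker_genotypes` object;
#'   `write_marker_tsv()` returns `path` invisibly.
#' @export
write_marker_tsv <- function(data, path) {
  stopifnot(inherits(data, "marker_genotypes"))
  df <- data.frame(phenotype = data$phenotype, data$genotypes,
                   check.names = FALSE)
  names(df)[-1L] <- paste0("M", format(data$positions, scientific = FALSE,
                                       trim = TRUE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_tsv
#' @export
read_marker_tsv <- function(path, chrom = "chr") {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot("phenotype" %in% names(df))
  mk <- setdiff(names(df), "phenotype")
  positions <- as.numeric(sub("^M", "", mk))
  geno <- as.matrix(df[, mk, drop = FALSE])
  ord <- order(positions)
  structure(
    list(genotypes = geno[, ord, drop = FALSE],
         positions = positions[ord],
         phenotype = df$phenotype, chrom = chrom),
    class = "marker_genotypes"
  )
}

#' Count recombinants per marker among phenotype-selected individuals
#'
#' A phenotypically mutant individual is inferred homozygous-mutant at the
#' causal locus (recessive trait), so any marker where its genotype is not
#' `hom_mut` reveals at least one crossover between marker and causal site.
#' Heterozygous calls count as recombinant; `missing` calls are excluded
#' from both numerator and denominator.
#'
#' @param data a `marker_genotypes` object.
#' @param selected_phenotype phenotype class to score (default
#'   `"mutant_phenotype"`; scoring the WT-like class is exposed for
#'   completeness but is uninformative under the same logic).
#' @return `data.frame` with `marker`, `pos`, `n_recombinant`, `n_scored`.
#' @export
count_recombinants <- function(data, selected_phenotype = "mutant_phenotype") {
  stopifnot(inherits(data, "marker_genotypes"))
  sel <- data$phenotype == selected_phenotype
  if (!any(sel)) {
    stop("no individuals with phenotype '", selected_phenotype, "'")
  }
  g <- data$genotypes[sel, , drop = FALSE]
  scored <- g != "missing" & !is.na(g)
  rec <- g != "hom_mut" & scored
  data.frame(
    marker = colnames(data$genotypes),
    pos = data$positions,
    n_recombinant = colSums(rec),
    n_scored = colSums(scored),
    row.names = NULL
  )
}

#' Infer the candidate interval from per-marker recombinant counts
#'
#' The causal site must lie where selected individuals show no
#' recombination: the interval is the maximal contiguous run of
#' zero-recombinant markers (longest run; ties broken by fewer flanking
#' recombinants, then leftmost). Bounds are the positions of the nearest
#' flanking markers with `> 0` recombinants, reported open (the causal site
#' lies strictly inside); a chromosome end replaces a missing flank
#' (`NA` bound).
#'
#' @param counts output of [count_recombinants()], or a numeric vector of
#'   per-marker recombinant counts.
#' @param positions marker positions (ignored when `counts` is a
#'   data.frame).
#' @return list of class `"finemap_result"`: `left_marker`/`right_marker`
#'   (indices into the sorted markers, `NA` at chromosome ends),
#'   `left_bp`/`right_bp` (open bounds), `zero_markers` (indices of the
#'   chosen zero run), `unresolved` (TRUE when every marker is
#'   recombinant-free), `empty` (TRUE when no marker is recombinant-free).
#' @export
#' @examples
#' infer_interval(c(3, 1, 0, 0, 2), positions = c(10, 20, 30, 40, 50))
infer_interval <- function(counts, positions = NULL) {
  if (is.data.frame(counts)) {
    positions <- counts$pos
    counts <- counts$n_recombinant
  }
  if (length(counts) < 2L) stop("need at least 2 markers")
  if (length(positions) != length(counts)) {
    stop("'positions' must match 'counts' in length")
  }
  ord <- order(positions)
  counts <- counts[ord]
  positions <- positions[ord]
  zero <- counts == 0
  res <- list(left_marker = NA_integer_, right_marker = NA_integer_,
              left_bp = NA_real_, right_bp = NA_real_,
              zero_markers = integer(0), unresolved = FALSE, empty = FALSE,
              positions = positions, counts = counts)
  class(res) <- "finemap_result"
  if (!any(zero)) {
    res$empty <- TRUE
    attr(res, "diagnostic") <- "every marker shows recombinants; no interval"
    return(res)
  }
  r <- rle(zero)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  zi <- which(r$values)
  flank_cost <- vapply(zi, function(k) {
    lc <- if (run_start[k] > 1L) counts[run_start[k] - 1L] else 0
    rc <- if (run_end[k] < length(counts)) counts[run_end[k] + 1L] else 0
    lc + rc
  }, 0)
  best <- zi[order(-r$lengths[zi], flank_cost, run_start[zi])][1L]
  run <- seq.int(run_start[best], run_end[best])
  res$zero_markers <- run
  if (run[1L] > 1L) {
    res$left_marker <- run[1L] - 1L
    res$left_bp <- positions[run[1L] - 1L]
  }
  if (run[length(run)] < length(counts)) {
    res$right_marker <- run[length(run)] + 1L
    res$right_bp <- positions[run[length(run)] + 1L]
  }
  res$unresolved <- length(run) == length(counts)
  res
}

#' @export
print.finemap_result <- function(x, ...) {
  if (x$empty) {
    cat("finemap: no zero-recombinant marker;",
        attr(x, "diagnostic"), "\n")
    return(invisible(x))
  }
  lb <- if (is.na(x$left_bp)) "chromosome start" else format(x$left_bp, big.mark = ",")
  rb <- if (is.na(x$right_bp)) "chromosome end" else format(x$right_bp, big.mark = ",")
  cat("finemap interval: (", lb, ", ", rb, ") — ",
      length(x$zero_markers), " zero-recombinant marker(s)",
      if (x$unresolved) " [unresolved: all markers recombinant-free]",
      "\n", sep = "")
  invisible(x)
}

#' Chi-square goodness-of-fit test for Mendelian segregation
#'
#' Pearson chi-square (df = 1) of observed mutant / wild-type phenotype
#' counts against an expected ratio, by default the 1:3 recessive
#' single-gene expectation for an F2-type segregating population.
#'
#' @param n_mutant,n_wt observed phenotype counts (`>= 0`, total `> 0`).
#' @param expected_ratio length-2 ratio of expected (mutant, wild-type)
#'   proportions; default `c(1, 3)`.
#' @return list with `statistic`, `df` (= 1) and `p.value`.
#' @export
#' @examples
#' chi_square_segregation(54, 162)  # exact 1:3 -> statistic 0
chi_square_segregation <- function(n_mutant, n_wt, expected_ratio = c(1, 3)) {
  if (n_mutant < 0 || n_wt < 0) stop("counts must be >= 0")
  if (n_mutant + n_wt == 0) stop("total count must be > 0")
  if (length(expected_ratio) != 2L || any(expected_ratio <= 0)) {
    stop("'expected_ratio' must be two positive numbers")
  }
  ht <- suppressWarnings(
    chisq.test(c(n_mutant, n_wt), p = expected_ratio / sum(expected_ratio))
  )
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value)
}
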
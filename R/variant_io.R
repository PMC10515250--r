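#' Read a two-bulk variant table from VCF
#'
#' Parses a VCF with exactly two samples carrying per-allele `AD` counts
#' (the WT-like bulk first, the mutant-phenotype bulk second — sample names
#' containing `wt`/`mut` override column order). Multi-allelic records are
#' split into one row per alternate allele; records whose ref or alt allele
#' is not a single nucleotide (indels, symbolic alleles) are skipped and the
#' number of skipped records is attached as attribute `"skipped"`.
#'
#' Per-bulk depth is taken as the sum of the `AD` entries of the record, so
#' a sample with `AD=10,22` contributes depth 32 and alt count 22.
#'
#' @param path path to a VCF (plain or gzipped).
#' @return a variant table `data.frame` (`chrom`, `pos`, `ref`, `alt`,
#'   `depth_wt`, `alt_wt`, `depth_mut`, `alt_mut`), sorted by
#'   chromosome/position, with attribute `skipped`.
#' @export
read_bulk_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- v@gt
  samples <- colnames(gt)[-1L]
  if (length(samples) == 0L) stop("VCF has zero samples")
  if (length(samples) != 2L) {
    stop("expected exactly two bulk samples, found ", length(samples))
  }
  wt_i <- grep("wt", samples, ignore.case = TRUE)
  mut_i <- grep("mut", samples, ignore.case = TRUE)
  if (length(wt_i) == 1L && length(mut_i) == 1L && wt_i != mut_i) {
    ord <- c(wt_i, mut_i)
  } else {
    ord <- 1:2
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad) || all(is.na(ad))) {
    stop("VCF lacks a per-allele depth (AD) FORMAT field")
  }

  rows <- vector("list", nrow(fix))
  skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    ref <- fix$REF[i]
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    if (any(is.na(ad[i, ]))) {
      stop("record ", fix$CHROM[i], ":", fix$POS[i], " lacks AD values")
    }
    ad_i <- lapply(ad[i, ord], function(s)
      suppressWarnings(as.integer(strsplit(s, ",", fixed = TRUE)[[1]])))
    depth_i <- vapply(ad_i, function(x) sum(x, na.rm = TRUE), 0L)
    keep_alt <- nchar(ref) == 1L & nchar(alts) == 1L &
      alts %in% c("A", "C", "G", "T") & ref %in% c("A", "C", "G", "T")
    if (!any(keep_alt)) {
      skipped <- skipped + 1L
      next
    }
    sub <- lapply(which(keep_alt), function(k) {
      data.frame(
        chrom = fix$CHROM[i], pos = as.numeric(fix$POS[i]),
        ref = ref, alt = alts[k],
        depth_wt = depth_i[[1]], alt_wt = ad_i[[1]][k + 1L],
        depth_mut = depth_i[[2]], alt_mut = ad_i[[2]][k + 1L],
        stringsAsFactors = FALSE
      )
    })
    rows[[i]] <- do.call(rbind, sub)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), pos = numeric(0),
                      ref = character(0), alt = character(0),
                      depth_wt = integer(0), alt_wt = integer(0),
                      depth_mut = integer(0), alt_mut = integer(0))
  }
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  if (skipped > 0L) {
    message(skipped, " non-SNV record(s) skipped")
  }
  attr(out, "skipped") <- skipped
  out
}

#' Write a two-bulk variant table as VCF 4.2
#'
#' Emits one biallelic SNV record per row with per-sample `GT:AD:DP`
#' (genotype left unassigned, `./.`), samples `wt_like_bulk` and
#' `mutant_bulk` in that order, plus `##contig` lines and optional
#' provenance metadata.
#'
#' @param table a variant table (see [read_bulk_vcf()] for columns).
#' @param path output path.
#' @param meta optional named list written as `##<name>=<value>` header
#'   lines (e.g. tool parameters and seed).
#' @return invisibly, `path`.
#' @export
write_bulk_vcf <- function(table, path, meta = NULL) {
  req <- c("chrom", "pos", "ref", "alt", "depth_wt", "alt_wt",
           "depth_mut", "alt_mut")
  if (!all(req %in% names(table))) {
    stop("table must have columns: ", paste(req, collapse = ", "))
  }
  if (any(table$alt_wt > table$depth_wt) || any(table$alt_mut > table$depth_mut)) {
    stop("alt_count exceeds depth")
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=bsamap",
    if (!is.null(meta)) sprintf("##%s=%s", names(meta),
                                vapply(meta, as.character, "")),
    sprintf("##contig=<ID=%s>", unique(table$chrom)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "wt_like_bulk", "mutant_bulk", sep = "\t")
  )
  fmt_sample <- function(depth, alt) {
    sprintf("./.:%d,%d:%d", depth - alt, alt, depth)
  }
  body <- paste(table$chrom, format(table$pos, scientific = FALSE, trim = TRUE),
                ".", table$ref, table$alt, ".", "PASS", ".", "GT:AD:DP",
                fmt_sample(table$depth_wt, table$alt_wt),
                fmt_sample(table$depth_mut, table$alt_mut),
                sep = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Filter variants by sequencing depth
#'
#' Keeps variants whose read depth lies within `[min_depth, max_depth]`
#' (inclusive). With `scope = "per_bulk"` (default) both bulks must satisfy
#' the bound; `scope = "summed"` applies it to the summed depth of the two
#' bulks.
#'
#' @param table a variant table.
#' @param min_depth,max_depth inclusive depth bounds (defaults 10 and 100).
#' @param scope `"per_bulk"` or `"summed"`.
#' @return the filtered table.
#' @export
#' @examples
#' tab <- data.frame(chrom = "chr1", pos = 1:3, ref = "G", alt = "T",
#'                   depth_wt = c(9L, 10L, 50L), alt_wt = 0L,
#'                   depth_mut = c(50L, 100L, 101L), alt_mut = 0L)
#' filter_depth(tab)$pos   # only pos 2 survives
filter_depth <- function(table, min_depth = 10, max_depth = 100,
                         scope = c("per_bulk", "summed")) {
  if (min_depth > max_depth) stop("'min_depth' must be <= 'max_depth'")
  scope <- match.arg(scope)
  keep <- if (scope == "per_bulk") {
    table$depth_wt >= min_depth & table$depth_wt <= max_depth &
      table$depth_mut >= min_depth & table$depth_mut <= max_depth
  } else {
    total <- table$depth_wt + table$depth_mut
    total >= min_depth & total <= max_depth
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter variants by substitution class
#'
#' `mode = "all"` (default) keeps every SNV; `mode = "transitions_only"`
#' keeps purine-purine / pyrimidine-pyrimidine changes (A<->G, C<->T), the
#' canonical EMS spectrum. The default is `"all"` because a causal mutation
#' may be a transversion, as in the glossy-fruit mutant's G>T change.
#'
#' @param table a variant table.
#' @param mode `"all"` or `"transitions_only"`.
#' @return the filtered table.
#' @export
filter_substitution_class <- function(table, mode = c("all", "transitions_only")) {
  mode <- match.arg(mode)
  if (mode == "all") return(table)
  purine <- c("A", "G")
  is_transition <- (table$ref %in% purine) == (table$alt %in% purine) &
    table$ref != table$alt
  out <- table[is_transition, , drop = FALSE]
  rownames(out) <- NULL
  out
}
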
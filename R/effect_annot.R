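#' Translate a DNA codon
#'
#' Standard genetic code; stop codons translate to `"*"`.
#'
#' @param codon a string of exactly 3 uppercase DNA bases (A/C/G/T).
#' @return one-letter amino-acid code.
#' @export
#' @examples
#' translate_codon("AAG")  # "K"
#' translate_codon("TAA")  # "*"
translate_codon <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L) {
    stop("'codon' must be a single 3-base string")
  }
  if (grepl("[^ACGT]", codon)) {
    stop("ambiguous or invalid base in codon '", codon, "'")
  }
  unname(Biostrings::GENETIC_CODE[codon])
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

revcomp_chr <- function(x) {
  paste(rev(DNA_COMPLEMENT[strsplit(x, "")[[1]]]), collapse = "")
}

#' Load gene models (GFF3) and genome sequence (FASTA) for annotation
#'
#' Reads transcript structures (`mRNA` + `exon` + `CDS` features) and the
#' genome they live on. The spliced CDS of each transcript is extracted in
#' coding orientation; transcripts whose CDS length is not a multiple of 3
#' are flagged `partial` and excluded from codon-level classification.
#'
#' @param gff_path GFF3 file of gene models (multiple transcripts per gene
#'   allowed).
#' @param fasta_path FASTA genome.
#' @return an object of class `"gene_models"`: list with `seq`
#'   (a [Biostrings::DNAStringSet]) and `transcripts` (one record per
#'   transcript: id, gene, chrom, strand, exon and CDS tables, spliced CDS
#'   sequence).
#' @export
read_gene_models <- function(gff_path, fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gff <- rtracklayer::import(gff_path, format = "gff3")
  type <- as.character(gff$type)
  tx_rows <- which(type %in% c("mRNA", "transcript"))
  transcripts <- list()
  for (i in tx_rows) {
    tx_id <- gff$ID[i]
    parent <- gff$Parent[[i]]
    gene_id <- if (length(parent)) parent[1] else NA_character_
    kids <- which(vapply(gff$Parent, function(p) tx_id %in% p, TRUE))
    feat <- function(what) {
      j <- kids[type[kids] == what]
      if (!length(j)) return(data.frame(start = numeric(0), end = numeric(0)))
      df <- data.frame(start = GenomicRanges::start(gff[j]),
                       end = GenomicRanges::end(gff[j]))
      df[order(df$start), , drop = FALSE]
    }
    exons <- feat("exon")
    cds <- feat("CDS")
    chrom <- as.character(GenomicRanges::seqnames(gff[i]))
    strand <- as.character(GenomicRanges::strand(gff[i]))
    cds_seq <- NA_character_
    partial <- TRUE
    if (nrow(cds)) {
      segs <- vapply(seq_len(nrow(cds)), function(k) {
        as.character(Biostrings::subseq(seqs[[chrom]], cds$start[k], cds$end[k]))
      }, "")
      cds_seq <- paste(segs, collapse = "")
      if (strand == "-") cds_seq <- revcomp_chr(cds_seq)
      partial <- nchar(cds_seq) %% 3L != 0L
    }
    transcripts[[tx_id]] <- list(
      tx_id = tx_id, gene_id = gene_id, chrom = chrom, strand = strand,
      exons = exons, cds = cds, cds_seq = cds_seq, partial = partial
    )
  }
  structure(list(seq = seqs, transcripts = transcripts),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", length(x$seq), "sequence(s),",
      length(x$transcripts), "transcript(s)\n")
  invisible(x)
}

# genomic position -> 1-based position in the spliced CDS (coding
# orientation); NA when the position is not in the CDS.
cds_position <- function(tx, pos) {
  cds <- tx$cds
  if (!nrow(cds)) return(NA_integer_)
  lens <- cds$end - cds$start + 1L
  seg <- which(pos >= cds$start & pos <= cds$end)
  if (!length(seg)) return(NA_integer_)
  if (tx$strand == "+") {
    before <- if (seg > 1L) sum(lens[seq_len(seg - 1L)]) else 0L
    before + (pos - cds$start[seg] + 1L)
  } else {
    n <- nrow(cds)
    after <- if (seg < n) sum(lens[seq.int(seg + 1L, n)]) else 0L
    after + (cds$end[seg] - pos + 1L)
  }
}

classify_one_transcript <- function(tx, pos, alt, splice_window = 2L) {
  exons <- tx$exons
  span <- c(min(exons$start), max(exons$end))
  if (pos < span[1] || pos > span[2]) return(NULL)
  in_exon <- any(pos >= exons$start & pos <= exons$end)
  out <- list(transcript = tx$tx_id, gene = tx$gene_id,
              class = NA_character_, codon_change = NA_character_,
              protein_change = NA_character_)
  if (!in_exon) {
    # intronic: distance to nearest exon edge decides splice_site
    d <- min(abs(c(pos - exons$end[exons$end < pos],
                   exons$start[exons$start > pos] - pos)))
    out$class <- if (d <= splice_window) "splice_site" else "intronic"
    return(out)
  }
  cpos <- cds_position(tx, pos)
  if (is.na(cpos) || tx$partial) {
    out$class <- "utr"
    return(out)
  }
  codon_i <- (cpos - 1L) %/% 3L + 1L
  within <- (cpos - 1L) %% 3L + 1L
  codon_ref <- substr(tx$cds_seq, 3L * (codon_i - 1L) + 1L, 3L * codon_i)
  alt_coding <- if (tx$strand == "-") DNA_COMPLEMENT[[alt]] else alt
  codon_alt <- codon_ref
  substr(codon_alt, within, within) <- alt_coding
  aa_ref <- translate_codon(codon_ref)
  aa_alt <- translate_codon(codon_alt)
  out$class <- if (aa_ref == aa_alt) "synonymous"
  else if (aa_alt == "*") "nonsense"
  else if (aa_ref == "*") "stop_loss"
  else "missense"
  out$codon_change <- paste0(codon_ref, ">", codon_alt)
  out$protein_change <- paste0(aa_ref, codon_i, aa_alt)
  out
}

#' Classify a single-nucleotide variant against gene models
#'
#' Maps the variant through the exon structure of every overlapping
#' transcript (strand-aware), identifies the affected codon from the CDS
#' frame and reports one consequence per transcript. Consequence classes:
#' `intergenic`, `intronic`, `splice_site` (intronic, within
#' `splice_window` bp of an exon boundary), `utr`, `synonymous`,
#' `missense`, `nonsense`, `stop_loss`. The `deleterious` flag marks
#' protein-damaging classes (`missense`, `nonsense`, `stop_loss`,
#' `splice_site`).
#'
#' @param models a [read_gene_models()] object.
#' @param variant list with `chrom`, `pos`, `ref`, `alt`; `ref` must match
#'   the genome at `pos`.
#' @param splice_window intronic distance (bp) from an exon boundary called
#'   as splice site (default 2).
#' @return `data.frame` with one row per overlapping transcript (a single
#'   `intergenic` row when none overlaps): `chrom`, `pos`, `ref`, `alt`,
#'   `transcript`, `gene`, `class`, `codon_change`, `protein_change`,
#'   `deleterious`.
#' @export
classify_snv <- function(models, variant, splice_window = 2L) {
  stopifnot(inherits(models, "gene_models"))
  v <- as.list(variant)
  pos <- as.numeric(v$pos)
  if (!v$chrom %in% names(models$seq)) {
    stop("unknown chromosome '", v$chrom, "'")
  }
  genome_base <- as.character(Biostrings::subseq(models$seq[[v$chrom]], pos, pos))
  if (genome_base != v$ref) {
    stop("reference mismatch at ", v$chrom, ":", pos,
         " (genome has ", genome_base, ", variant says ", v$ref, ")")
  }
  hits <- list()
  for (tx in models$transcripts) {
    if (tx$chrom != v$chrom) next
    res <- classify_one_transcript(tx, pos, v$alt, splice_window)
    if (!is.null(res)) hits[[length(hits) + 1L]] <- res
  }
  if (!length(hits)) {
    hits <- list(list(transcript = NA_character_, gene = NA_character_,
                      class = "intergenic", codon_change = NA_character_,
                      protein_change = NA_character_))
  }
  out <- do.call(rbind, lapply(hits, function(h) {
    data.frame(chrom = v$chrom, pos = pos, ref = v$ref, alt = v$alt,
               transcript = h$transcript, gene = h$gene, class = h$class,
               codon_change = h$codon_change,
               protein_change = h$protein_change,
               stringsAsFactors = FALSE)
  }))
  out$deleterious <- out$class %in% c("missense", "nonsense", "stop_loss",
                                      "splice_site")
  out
}

EFFECT_SEVERITY <- c(nonsense = 5, splice_site = 5, stop_loss = 5,
                     missense = 4, synonymous = 3, utr = 3,
                     intronic = 2, intergenic = 1)

#' Prioritize candidate variants by predicted protein impact
#'
#' Collapses per-transcript effects to the most severe consequence per
#' variant and orders variants: nonsense/splice-site/stop-loss, then
#' missense, then synonymous/UTR, then intronic, then intergenic; within a
#' class by candidate-region rank (when supplied) and genomic position.
#' This reproduces the exonic/deleterious triage that singles out the one
#' protein-altering change among the high-scoring candidates of a mapped
#' region.
#'
#' @param effects row-bound output of [classify_snv()] over the candidate
#'   variants.
#' @param region_rank optional numeric vector, one value per row of
#'   `effects`, giving the rank of the candidate region each variant falls
#'   in (see [rank_regions()]).
#' @return one row per variant, most severe effect first, with a
#'   `deleterious` flag.
#' @export
prioritize <- function(effects, region_rank = NULL) {
  if (nrow(effects) == 0L) return(effects)
  if (is.null(region_rank)) region_rank <- rep(1, nrow(effects))
  key <- paste(effects$chrom, effects$pos, effects$ref, effects$alt)
  sev <- EFFECT_SEVERITY[effects$class]
  best <- tapply(seq_len(nrow(effects)), key, function(idx) {
    idx[which.max(sev[idx])]
  })
  out <- effects[as.integer(best), , drop = FALSE]
  rr <- region_rank[as.integer(best)]
  ord <- order(-EFFECT_SEVERITY[out$class], rr, out$chrom, out$pos)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_codons <- function(n) {
  non_stop <- setdiff(names(Biostrings::GENETIC_CODE),
                      c("TAA", "TAG", "TGA"))
  paste(sample(non_stop, n, replace = TRUE), collapse = "")
}

#' Write the synthetic two-isoform demo gene fixture
#'
#' Generates a small synthetic genome (FASTA) and gene models (GFF3)
#' emulating the structure of the tomato *SlSHN2* locus: a plus-strand gene
#' with two splice isoforms sharing exon 2, whose codon 114 is `AAG` with
#' its third base at the last position of exon 2, plus a minus-strand
#' control gene. A G>T substitution at that exon-2 terminal base therefore
#' yields the missense change `K114N` in both isoforms. All coordinates are
#' toy-scale; the sequence is random apart from the designed codons and is
#' a synthetic stand-in, not the real locus.
#'
#' @param dir directory in which `demo_gene.fa` and `demo_gene.gff3` are
#'   written.
#' @param seed seed for the random sequence background.
#' @return list with `fasta`, `gff3` (paths), `k114_variant` (the G>T
#'   variant at the exon-2 boundary) and `cds_map` (layout bookkeeping used
#'   by tests).
#' @export
write_demo_gene <- function(dir = tempdir(), seed = 42) {
  set.seed(seed)
  chrom <- "chr12_toy"
  L <- 3000L
  genome <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

  put <- function(genome, start, s) {
    stopifnot(start + nchar(s) - 1L <= length(genome))
    genome[start:(start + nchar(s) - 1L)] <- strsplit(s, "")[[1]]
    genome
  }

  # plus-strand gene: CDS 360 bp (120 codons), codon 114 = AAG ending at
  # the last base of exon 2
  cds1 <- paste0("ATG", random_codons(112), "AAG", random_codons(5), "TAA")
  stopifnot(nchar(cds1) == 360L, substr(cds1, 340, 342) == "AAG")
  genome <- put(genome, 201L, substr(cds1, 1, 200))    # exon1 CDS (201-400)
  genome <- put(genome, 501L, substr(cds1, 201, 342))  # exon2 CDS (501-642)
  genome <- put(genome, 743L, substr(cds1, 343, 360))  # exon3 CDS, t1 (743-760)
  tail2 <- paste0(random_codons(5), "TAA")             # t2-specific last CDS exon
  genome <- put(genome, 901L, tail2)                   # exon4 CDS, t2 (901-918)
  # splice dinucleotides (cosmetic)
  genome <- put(genome, 401L, "GT"); genome <- put(genome, 499L, "AG")
  genome <- put(genome, 643L, "GT"); genome <- put(genome, 741L, "AG")
  genome <- put(genome, 899L, "AG")

  # minus-strand control gene: CDS 90 bp (30 codons)
  cds2 <- paste0("ATG", random_codons(28), "TAA")
  genome <- put(genome, 2001L, revcomp_chr(substr(cds2, 1, 60)))   # 2001-2060
  genome <- put(genome, 1831L, revcomp_chr(substr(cds2, 61, 90)))  # 1831-1860
  genome <- put(genome, 1999L, "AC"); genome <- put(genome, 1861L, "CT")

  fasta <- file.path(dir, "demo_gene.fa")
  writeLines(c(paste0(">", chrom), paste(genome, collapse = "")), fasta)

  g <- function(type, start, end, strand, attrs, phase = ".") {
    paste(chrom, "bsamap", type, start, end, ".", strand, phase, attrs,
          sep = "\t")
  }
  gff <- c(
    "##gff-version 3",
    g("gene", 101, 958, "+", "ID=gene1"),
    g("mRNA", 101, 800, "+", "ID=t1;Parent=gene1"),
    g("exon", 101, 400, "+", "Parent=t1"),
    g("exon", 501, 642, "+", "Parent=t1"),
    g("exon", 743, 800, "+", "Parent=t1"),
    g("CDS", 201, 400, "+", "Parent=t1", 0),
    g("CDS", 501, 642, "+", "Parent=t1", 1),
    g("CDS", 743, 760, "+", "Parent=t1", 0),
    g("mRNA", 101, 958, "+", "ID=t2;Parent=gene1"),
    g("exon", 101, 400, "+", "Parent=t2"),
    g("exon", 501, 642, "+", "Parent=t2"),
    g("exon", 901, 958, "+", "Parent=t2"),
    g("CDS", 201, 400, "+", "Parent=t2", 0),
    g("CDS", 501, 642, "+", "Parent=t2", 1),
    g("CDS", 901, 918, "+", "Parent=t2", 0),
    g("gene", 1801, 2100, "-", "ID=gene2"),
    g("mRNA", 1801, 2100, "-", "ID=t3;Parent=gene2"),
    g("exon", 2001, 2100, "-", "Parent=t3"),
    g("exon", 1801, 1860, "-", "Parent=t3"),
    g("CDS", 2001, 2060, "-", "Parent=t3", 0),
    g("CDS", 1831, 1860, "-", "Parent=t3", 0)
  )
  gff3 <- file.path(dir, "demo_gene.gff3")
  writeLines(gff, gff3)

  list(
    fasta = fasta,
    gff3 = gff3,
    k114_variant = list(chrom = chrom, pos = 642, ref = "G", alt = "T"),
    cds_map = list(chrom = chrom, plus_tx = c("t1", "t2"), minus_tx = "t3",
                   cds1 = cds1, cds2 = cds2,
                   t1_cds = data.frame(start = c(201, 501, 743),
                                       end = c(400, 642, 760)),
                   t3_cds = data.frame(start = c(1831, 2001),
                                       end = c(1860, 2060)))
  )
}
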
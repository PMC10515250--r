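#' Define a genome model for forward-genetics simulation
#'
#' A genome model lists the chromosomes over which EMS variants, meiotic
#' crossovers and pooled reads are simulated. Each chromosome has a physical
#' length in base pairs and a genetic length in Morgans; crossover positions
#' are placed assuming a linear cM/bp relationship along each chromosome.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length_bp numeric vector of physical lengths (bp), all `> 0`.
#' @param length_morgan numeric vector of genetic lengths (Morgans), all
#'   `>= 0`. A genetic length of 0 disables recombination on that chromosome.
#'
#' @return A `data.frame` of class `"genome_model"` with columns `chrom`,
#'   `length_bp` and `length_morgan`.
#' @seealso [tomato_genome()] for the default 12-chromosome preset.
#' @export
#' @examples
#' genome_model("chr1", 1e6, 0.5)
genome_model <- function(chrom, length_bp, length_morgan) {
  chrom <- as.character(chrom)
  if (anyDuplicated(chrom)) {
    stop("chromosome names must be unique")
  }
  if (length(length_bp) != length(chrom) || length(length_morgan) != length(chrom)) {
    stop("'chrom', 'length_bp' and 'length_morgan' must have equal length")
  }
  if (any(!is.finite(length_bp)) || any(length_bp <= 0)) {
    stop("physical chromosome lengths must be positive")
  }
  if (any(!is.finite(length_morgan)) || any(length_morgan < 0)) {
    stop("genetic chromosome lengths must be non-negative")
  }
  gm <- data.frame(
    chrom = chrom,
    length_bp = as.numeric(length_bp),
    length_morgan = as.numeric(length_morgan),
    stringsAsFactors = FALSE
  )
  class(gm) <- c("genome_model", "data.frame")
  gm
}

#' Twelve-chromosome tomato-like genome preset
#'
#' Chromosome physical sizes approximate the tomato reference assembly used
#' for EMS mutant mapping (rounded to 0.1 Mb); each chromosome is assigned a
#' genetic length of 1 Morgan, giving a ~1200 cM genome close to the tomato
#' consensus linkage map.
#'
#' @return A [genome_model()] with chromosomes `chr01` ... `chr12`.
#' @export
#' @examples
#' tomato_genome()
tomato_genome <- function() {
  sizes_mb <- c(98.5, 55.3, 70.4, 66.9, 65.9, 49.8,
                68.1, 65.9, 72.4, 65.5, 56.3, 68.1)
  genome_model(
    chrom = sprintf("chr%02d", 1:12),
    length_bp = sizes_mb * 1e6,
    length_morgan = rep(1.0, 12)
  )
}

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chrom)
  if (any(is.na(i))) {
    stop("unknown chromosome(s): ", paste(chrom[is.na(i)], collapse = ", "))
  }
  genome$length_bp[i]
}
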
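#' Per-variant allele frequency
#'
#' The fraction of pooled reads carrying the alternate (mutant) allele.
#'
#' @param alt_count alt-supporting read count(s).
#' @param depth total read depth(s), all `>= 1` (zero-depth sites must be
#'   removed upstream, e.g. by [filter_depth()]).
#' @return numeric allele frequencies in `[0, 1]`.
#' @export
#' @examples
#' allele_frequency(16, 32)
allele_frequency <- function(alt_count, depth) {
  if (any(depth < 1)) stop("allele frequency undefined at depth 0")
  if (any(alt_count < 0) || any(alt_count > depth)) {
    stop("'alt_count' must satisfy 0 <= alt_count <= depth")
  }
  alt_count / depth
}

#' Per-variant allele-frequency track for the two bulks
#'
#' Computes `af_wt` and `af_mut` per variant plus the `delta_af`
#' (mutant minus WT-like) column, which is emitted for plotting only and
#' plays no part in region calling.
#'
#' @param table a two-bulk variant table (see [read_bulk_vcf()]).
#' @return the table with columns `af_wt`, `af_mut`, `delta_af` appended.
#' @export
af_track <- function(table) {
  table$af_wt <- allele_frequency(table$alt_wt, table$depth_wt)
  table$af_mut <- allele_frequency(table$alt_mut, table$depth_mut)
  table$delta_af <- table$af_mut - table$af_wt
  table
}

#' Sliding-window means of bulk allele frequencies
#'
#' Slides a window of `window_snps` consecutive SNPs (step `step`, in SNPs)
#' along each chromosome and averages the two bulk allele frequencies over
#' the member SNPs. Windows never span chromosomes; a chromosome with fewer
#' SNPs than the window emits no windows.
#'
#' @param track output of [af_track()] (or any data.frame with `chrom`,
#'   `pos`, `af_wt`, `af_mut`), assumed sorted by chromosome and position.
#' @param window_snps window size in SNPs (`>= 1`; the study used 10).
#' @param step window step in SNPs (`>= 1`).
#' @return `data.frame` with one row per window: `chrom`, `start_idx` /
#'   `end_idx` (per-chromosome SNP indices), `start_bp` / `end_bp`
#'   (positions of the outermost member SNPs), `mid_bp` (mean position of
#'   member SNPs), `af_mut_mean`, `af_wt_mean`, `n_snps`.
#' @export
#' @examples
#' tr <- data.frame(chrom = "chr1", pos = 1:10 * 100,
#'                  af_mut = seq(0.1, 1, 0.1), af_wt = 0.5)
#' sliding_window_mean(tr, 10)$af_mut_mean  # 0.55
sliding_window_mean <- function(track, window_snps = 10, step = 1) {
  window_snps <- as.integer(window_snps)
  step <- as.integer(step)
  if (is.na(window_snps) || window_snps < 1) stop("'window_snps' must be >= 1")
  if (is.na(step) || step < 1) stop("'step' must be >= 1")
  pieces <- lapply(unique(track$chrom), function(cn) {
    tr <- track[track$chrom == cn, , drop = FALSE]
    tr <- tr[order(tr$pos), , drop = FALSE]
    n <- nrow(tr)
    if (n < window_snps) return(NULL)
    starts <- seq.int(1L, n - window_snps + 1L, by = step)
    ends <- starts + window_snps - 1L
    cmut <- c(0, cumsum(tr$af_mut))
    cwt <- c(0, cumsum(tr$af_wt))
    cpos <- c(0, cumsum(tr$pos))
    data.frame(
      chrom = cn,
      start_idx = starts, end_idx = ends,
      start_bp = tr$pos[starts], end_bp = tr$pos[ends],
      mid_bp = (cpos[ends + 1L] - cpos[starts]) / window_snps,
      af_mut_mean = (cmut[ends + 1L] - cmut[starts]) / window_snps,
      af_wt_mean = (cwt[ends + 1L] - cwt[starts]) / window_snps,
      n_snps = window_snps,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start_idx = integer(0),
                      end_idx = integer(0), start_bp = numeric(0),
                      end_bp = numeric(0), mid_bp = numeric(0),
                      af_mut_mean = numeric(0), af_wt_mean = numeric(0),
                      n_snps = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Call candidate causal regions from windowed allele frequencies
#'
#' Under the default `"dual"` rule a window passes iff its mean mutant-bulk
#' AF exceeds `t_high` AND its mean WT-like-bulk AF is below `t_low`
#' (strict inequalities). `rule = "high_only"` drops the WT-like condition,
#' which reproduces the raw high-AF region detection that also picks up
#' fixed introgression blocks. Overlapping or adjacent passing windows are
#' merged; region bounds are the bp positions of the outermost member SNPs
#' (1-based, closed).
#'
#' @param windows output of [sliding_window_mean()].
#' @param t_high mutant-bulk threshold in (0, 1) (default 0.95).
#' @param t_low WT-like-bulk threshold in (0, 1), `t_low < t_high`
#'   (default 0.4).
#' @param rule `"dual"` (default) or `"high_only"`.
#' @param causal optional list with `chrom`/`pos`; when given, each region
#'   gains a `contains_causal` flag.
#' @return `data.frame` of non-overlapping regions: `chrom`, `start_bp`,
#'   `end_bp`, `n_windows`, `min_af_mut`, `max_af_wt` (and
#'   `contains_causal`), in genomic order.
#' @export
call_candidate_regions <- function(windows, t_high = 0.95, t_low = 0.4,
                                   rule = c("dual", "high_only"),
                                   causal = NULL) {
  rule <- match.arg(rule)
  if (t_high <= 0 || t_high >= 1 || t_low <= 0 || t_low >= 1) {
    stop("thresholds must lie in (0, 1)")
  }
  if (t_low >= t_high) stop("'t_low' must be < 't_high'")
  pass <- windows$af_mut_mean > t_high
  if (rule == "dual") pass <- pass & (windows$af_wt_mean < t_low)
  regions <- list()
  for (cn in unique(windows$chrom)) {
    idx <- which(windows$chrom == cn & pass)
    if (!length(idx)) next
    w <- windows[idx, , drop = FALSE]
    w <- w[order(w$start_idx), , drop = FALSE]
    grp <- cumsum(c(1L, w$start_idx[-1L] > head(cummax(w$end_idx), -1L) + 1L))
    for (g in split(seq_len(nrow(w)), grp)) {
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = cn,
        start_bp = min(w$start_bp[g]),
        end_bp = max(w$end_bp[g]),
        n_windows = length(g),
        min_af_mut = min(w$af_mut_mean[g]),
        max_af_wt = max(w$af_wt_mean[g]),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, regions)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), n_windows = integer(0),
                      min_af_mut = numeric(0), max_af_wt = numeric(0))
  }
  out <- out[order(out$chrom, out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(causal)) {
    out$contains_causal <- out$chrom == causal$chrom &
      out$start_bp <= causal$pos & out$end_bp >= causal$pos
  }
  out
}

#' Rank candidate regions by causal plausibility
#'
#' Regions whose maximum WT-like window AF stays below `t_low` (the
#' signature of a recessive causal locus: absent from most WT-like
#' chromosomes) rank ahead of regions that are high in both bulks (the
#' signature of a fixed introgression block). Within each group regions are
#' ordered by descending minimum mutant-bulk AF, then ascending maximum
#' WT-like AF, then descending window support, ties broken by genomic
#' order.
#'
#' @param regions output of [call_candidate_regions()].
#' @param t_low WT-like-bulk threshold used for the primary grouping.
#' @return the reordered regions with a `rank` column prepended.
#' @export
rank_regions <- function(regions, t_low = 0.4) {
  if (nrow(regions) == 0L) {
    regions$rank <- integer(0)
    return(regions)
  }
  ord <- order(
    !(regions$max_af_wt < t_low),      # causal-compatible regions first
    -regions$min_af_mut,
    regions$max_af_wt,
    -regions$n_windows,
    regions$chrom,
    regions$start_bp
  )
  out <- regions[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Locate the window covering a genomic position
#'
#' Among the windows whose member-SNP span contains `pos`, returns the one
#' whose midpoint is closest to `pos` (the "causal window" used when
#' reporting smoothed allele frequencies at a known site).
#'
#' @param windows output of [sliding_window_mean()] (or a `bsa_scan`
#'   object).
#' @param chrom,pos the position of interest.
#' @return a one-row window `data.frame`, or `NULL` when no window covers
#'   the position.
#' @export
window_at <- function(windows, chrom, pos) {
  if (inherits(windows, "bsa_scan")) windows <- windows$windows
  hit <- windows$chrom == chrom & windows$start_bp <= pos & windows$end_bp >= pos
  if (!any(hit)) return(NULL)
  w <- windows[hit, , drop = FALSE]
  w[which.min(abs(w$mid_bp - pos)), , drop = FALSE]
}

#' Bulked segregant allele-frequency scan
#'
#' The package's central analysis: filters a two-bulk variant table by
#' depth (and optionally substitution class), computes per-variant bulk
#' allele frequencies, smooths them over a sliding window of SNPs, calls
#' candidate causal regions with the dual-bulk thresholds and ranks them.
#'
#' @param table a two-bulk variant table (from [read_bulk_vcf()] or
#'   [simulate_bulk_experiment()]).
#' @param window_snps,step sliding-window size and step in SNPs.
#' @param t_high,t_low region-calling thresholds, see
#'   [call_candidate_regions()].
#' @param min_depth,max_depth depth filter bounds, see [filter_depth()].
#' @param subst substitution-class filter mode, see
#'   [filter_substitution_class()].
#' @param causal optional known causal locus (list with `chrom`, `pos`),
#'   used to flag the containing region in simulations.
#'
#' @return An object of class `"bsa_scan"`: a list with the filtered
#'   `track` (per-variant AFs), `windows`, ranked `regions`, the `params`
#'   used, and filtering bookkeeping (`n_input`, `n_filtered`). Has
#'   `print()`, `summary()` and `plot()` methods.
#' @export
#' @examples
#' cfg <- bsa_preset()
#' cfg$n_background <- 400; cfg$n_population <- 60; cfg$n_per_bulk <- 12
#' sim <- simulate_bulk_experiment(cfg, seed = 7)
#' sc <- bsa_scan(sim$table, causal = sim$truth)
#' sc
bsa_scan <- function(table, window_snps = 10, step = 1,
                     t_high = 0.95, t_low = 0.4,
                     min_depth = 10, max_depth = 100,
                     subst = c("all", "transitions_only"),
                     causal = NULL) {
  subst <- match.arg(subst)
  n_input <- nrow(table)
  tab <- filter_depth(table, min_depth, max_depth)
  tab <- filter_substitution_class(tab, subst)
  track <- af_track(tab)
  windows <- sliding_window_mean(track, window_snps, step)
  regions <- call_candidate_regions(windows, t_high, t_low, causal = causal)
  regions <- rank_regions(regions, t_low)
  structure(
    list(
      track = track,
      windows = windows,
      regions = regions,
      causal = causal,
      params = list(window_snps = window_snps, step = step,
                    t_high = t_high, t_low = t_low,
                    min_depth = min_depth, max_depth = max_depth,
                    subst = subst),
      n_input = n_input,
      n_filtered = nrow(tab)
    ),
    class = "bsa_scan"
  )
}

#' @export
print.bsa_scan <- function(x, ...) {
  p <- x$params
  cat("Bulked segregant allele-frequency scan\n")
  cat(sprintf("  %d variants (%d after depth %d-%d%s filter), window %d SNPs (step %d)\n",
              x$n_input, x$n_filtered, p$min_depth, p$max_depth,
              if (p$subst == "transitions_only") ", transitions-only" else "",
              p$window_snps, p$step))
  cat(sprintf("  calling rule: window AF_mut > %.2f and AF_wt < %.2f\n",
              p$t_high, p$t_low))
  nr <- nrow(x$regions)
  if (nr == 0L) {
    cat("  no candidate regions called\n")
  } else {
    cat("  candidate regions:", nr, "\n")
    print(head(x$regions, 5L), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.bsa_scan <- function(object, ...) {
  structure(list(scan = object), class = "summary.bsa_scan")
}

#' @export
print.summary.bsa_scan <- function(x, ...) {
  sc <- x$scan
  print(sc)
  if (!is.null(sc$causal)) {
    w <- window_at(sc$windows, sc$causal$chrom, sc$causal$pos)
    if (is.null(w)) {
      cat("  causal site not covered by any window\n")
    } else {
      cat(sprintf("  causal window (%s:%s-%s): AF_mut = %.3f, AF_wt = %.3f\n",
                  w$chrom, format(w$start_bp, big.mark = ","),
                  format(w$end_bp, big.mark = ","),
                  w$af_mut_mean, w$af_wt_mean))
    }
  }
  per_chr <- tapply(sc$track$af_mut, sc$track$chrom, mean)
  cat("  mean mutant-bulk AF by chromosome:\n")
  print(round(per_chr, 3))
  invisible(x)
}

#' Plot a bulked segregant scan along the genome
#'
#' Draws the sliding-window mean allele frequencies of the mutant bulk
#' (green) and the WT-like bulk (orange) against a concatenated genome
#' coordinate, with the two calling thresholds as dashed lines and called
#' regions shaded.
#'
#' @param x a `bsa_scan` object.
#' @param ... further arguments passed to [graphics::plot.window()]
#'   (unused).
#' @return invisibly, `x`.
#' @export
plot.bsa_scan <- function(x, ...) {
  w <- x$windows
  if (nrow(w) == 0L) {
    stop("no windows to plot (fewer SNPs than the window size?)")
  }
  chroms <- unique(w$chrom)
  span <- vapply(chroms, function(cn) max(w$end_bp[w$chrom == cn]), 0)
  offset <- setNames(c(0, cumsum(as.numeric(span)))[seq_along(chroms)], chroms)
  gx <- offset[w$chrom] + w$mid_bp
  op <- par(mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot.new()
  plot.window(xlim = range(gx), ylim = c(0, 1))
  if (nrow(x$regions)) {
    for (i in seq_len(nrow(x$regions))) {
      r <- x$regions[i, ]
      graphics::rect(offset[r$chrom] + r$start_bp, 0,
                     offset[r$chrom] + r$end_bp, 1,
                     col = adjustcolor("grey", 0.4), border = NA)
    }
  }
  for (cn in chroms) {
    sel <- w$chrom == cn
    lines(gx[sel], w$af_mut_mean[sel], col = "forestgreen")
    lines(gx[sel], w$af_wt_mean[sel], col = "darkorange")
  }
  abline(h = c(x$params$t_high, x$params$t_low), lty = 2, col = "grey40")
  abline(v = offset[-1L], col = "grey85")
  axis(2)
  axis(1, at = offset + span / 2, labels = chroms, las = 2, cex.axis = 0.7,
       tick = FALSE)
  title(ylab = "window mean allele frequency",
        main = "Bulked segregant allele-frequency scan")
  legend("left", legend = c("mutant bulk", "WT-like bulk"),
         col = c("forestgreen", "darkorange"), lty = 1, bty = "n", cex = 0.8)
  box()
  invisible(x)
}
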
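#' Read a differential-expression table
#'
#' Reads a TSV of per-gene expression summaries (gene id, putative
#' function, manual category label, log2 fold change mutant/WT, q-value,
#' optional per-genotype FPKM columns), such as the packaged transcriptions
#' of the fruit-exocarp DEG tables shipped in `inst/extdata`.
#'
#' @param path TSV path; see [bsamap_example()] for the packaged tables.
#' @return `data.frame` with at least `gene`, `category`, `log2fc`, `q`.
#' @export
read_deg_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene", "category", "log2fc", "q")
  if (!all(req %in% names(df))) {
    stop("DEG table must have columns: ", paste(req, collapse = ", "))
  }
  if (any(df$q < 0 | df$q > 1, na.rm = TRUE)) stop("q-values must lie in [0, 1]")
  df
}

#' Path to a packaged example data file
#'
#' @param file file name under the package's `extdata` (default: list the
#'   available files).
#' @return a path, or a character vector of file names.
#' @export
#' @examples
#' bsamap_example()
bsamap_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "bsamap")))
  }
  p <- system.file("extdata", file, package = "bsamap")
  if (p == "") stop("no packaged file '", file, "'")
  p
}

#' Threshold filter for differentially expressed genes
#'
#' Keeps records with `|log2fc| >= lfc_cut`, `q < q_cut` and — when FPKM
#' columns (`fpkm_wt`, `fpkm_mut`) are present — expression above
#' `fpkm_cut` in at least one genotype (strictly greater). Split into
#' up-regulated (`log2fc > 0`) and down-regulated lists.
#'
#' @param records a DEG `data.frame` (see [read_deg_table()]).
#' @param lfc_cut absolute log2 fold-change threshold (default 1, i.e.
#'   two-fold).
#' @param q_cut q-value threshold (default 0.05; the looser 0.07 used for
#'   volcano-plot display is available by argument).
#' @param fpkm_cut FPKM threshold (default 5), applied only when FPKM
#'   columns exist.
#' @return list with elements `up` and `down` (data.frames).
#' @export
filter_degs <- function(records, lfc_cut = 1.0, q_cut = 0.05, fpkm_cut = 5.0) {
  keep <- abs(records$log2fc) >= lfc_cut & records$q < q_cut
  if (all(c("fpkm_wt", "fpkm_mut") %in% names(records))) {
    keep <- keep & (records$fpkm_wt > fpkm_cut | records$fpkm_mut > fpkm_cut)
  }
  keep[is.na(keep)] <- FALSE
  kept <- records[keep, , drop = FALSE]
  list(up = kept[kept$log2fc > 0, , drop = FALSE],
       down = kept[kept$log2fc <= 0, , drop = FALSE])
}

#' Count DEG records per functional category
#'
#' @param records a DEG `data.frame` with a `category` column; every record
#'   must be labelled.
#' @return named integer vector of exact multiset counts.
#' @export
count_by_category <- function(records) {
  if (nrow(records) == 0L) return(integer(0))
  bad <- is.na(records$category) | records$category == ""
  if (any(bad)) {
    stop("records without category label: ",
         paste(records$gene[bad], collapse = ", "))
  }
  tab <- table(records$category)
  setNames(as.integer(tab), names(tab))
}

#' Fold change between two positive measurements
#'
#' Reports the ratio of the larger to the smaller value (rounded to one
#' decimal, the convention of biochemical load comparisons) and the
#' direction of change from reference to alternative.
#'
#' @param value_ref reference (e.g. wild-type) value, `> 0`.
#' @param value_alt alternative (e.g. mutant) value, `> 0`.
#' @return list with `fold` and `direction` (`"increase"`, `"reduction"`
#'   or `"none"`).
#' @export
#' @examples
#' fold_change(1674, 302)  # 5.5-fold reduction
fold_change <- function(value_ref, value_alt) {
  if (value_ref <= 0 || value_alt <= 0) stop("values must be > 0")
  fold <- round(max(value_ref, value_alt) / min(value_ref, value_alt), 1)
  direction <- if (value_alt > value_ref) "increase"
  else if (value_alt < value_ref) "reduction"
  else "none"
  list(fold = fold, direction = direction)
}

group_summary <- function(g) {
  if (is.list(g) || (is.numeric(g) && !is.null(names(g)) &&
                     all(c("mean", "sd", "n") %in% names(g)))) {
    g <- as.list(g)
    if (!all(c("mean", "sd", "n") %in% names(g))) {
      stop("summary input needs 'mean', 'sd' and 'n'")
    }
    list(mean = g$mean, sd = g$sd, n = g$n)
  } else {
    list(mean = mean(g), sd = stats::sd(g), n = length(g))
  }
}

#' Pooled-variance Student's t test (raw values or summaries)
#'
#' Classic two-sample Student's t with pooled variance, accepting either
#' raw numeric vectors or `mean`/`sd`/`n` summaries per group (the form in
#' which biochemical results are printed, mean +/- SD with n = 3).
#' Two-sided p-value. When both groups have zero variance and equal means
#' the test is degenerate and `t = 0`, `p = 1` by convention.
#'
#' @param a,b numeric vectors of raw values, or lists / named vectors with
#'   `mean`, `sd`, `n` (n >= 2, sd >= 0).
#' @return list with `t`, `df` and `p.value`.
#' @export
#' @examples
#' two_sample_t(c(mean = 10, sd = 1, n = 3), c(mean = 12, sd = 1, n = 3))
two_sample_t <- function(a, b) {
  ga <- group_summary(a)
  gb <- group_summary(b)
  if (ga$n < 2 || gb$n < 2) stop("each group needs n >= 2")
  if (ga$sd < 0 || gb$sd < 0) stop("SD must be >= 0")
  df <- ga$n + gb$n - 2
  sp2 <- ((ga$n - 1) * ga$sd^2 + (gb$n - 1) * gb$sd^2) / df
  if (sp2 == 0) {
    if (ga$mean == gb$mean) {
      return(list(t = 0, df = df, p.value = 1))
    }
    return(list(t = sign(ga$mean - gb$mean) * Inf, df = df, p.value = 0))
  }
  t_stat <- (ga$mean - gb$mean) / sqrt(sp2 * (1 / ga$n + 1 / gb$n))
  list(t = t_stat, df = df, p.value = 2 * pt(-abs(t_stat), df))
}

#' Construct a cell-wall sugar profile
#'
#' Container for the monosaccharide composition of cutin-embedded
#' polysaccharides (mol% of total sugars) plus the esterification
#' measurements: methanol released from pectin methyl esters (mol),
#' galacturonic (uronic) acid (mol), acetic acid (mass) and total
#' polysaccharide (mass).
#'
#' @param rha,ara,xyl,man,gal,gala,glc molar proportions (mol%, `>= 0`) of
#'   rhamnose, arabinose, xylose, mannose, galactose, galacturonic acid and
#'   glucose.
#' @param methanol_mol,uronic_mol,acetic_mass,poly_mass esterification
#'   inputs (see [esterification_degrees()]); optional.
#' @return named list of class `"sugar_profile"`.
#' @export
sugar_profile <- function(rha = 0, ara = 0, xyl = 0, man = 0, gal = 0,
                          gala = 0, glc = 0,
                          methanol_mol = NA, uronic_mol = NA,
                          acetic_mass = NA, poly_mass = NA) {
  molpct <- c(rha = rha, ara = ara, xyl = xyl, man = man, gal = gal,
              gala = gala, glc = glc)
  if (any(molpct < 0, na.rm = TRUE)) stop("mol%% entries must be >= 0")
  structure(list(rha = rha, ara = ara, xyl = xyl, man = man, gal = gal,
                 gala = gala, glc = glc,
                 methanol_mol = methanol_mol, uronic_mol = uronic_mol,
                 acetic_mass = acetic_mass, poly_mass = poly_mass),
            class = "sugar_profile")
}

#' Diagnostic cell-wall composition ratios
#'
#' Computes the three molar ratios used to interpret cutin-embedded
#' polysaccharide composition: `rgi_branching` = (Ara + Gal)/Rha, a proxy
#' for rhamnogalacturonan-I side-chain abundance; `pectin_linearity` =
#' GalA/(Rha + Ara + Gal); and `xyl_man` = Xyl/Man, the mannan-to-
#' xyloglucan balance of the hemicellulose fraction. A zero denominator
#' (e.g. rhamnose below the detection limit) yields `NA` with a
#' `not_computable` flag rather than an error.
#'
#' @param profile a [sugar_profile()] (or a named list with the sugar
#'   fields).
#' @return list with the three ratios and `not_computable`, a character
#'   vector naming the ratios whose denominator was zero.
#' @export
#' @examples
#' cell_wall_ratios(sugar_profile(rha = 2, ara = 2, gal = 4,
#'                                xyl = 4, man = 2, gala = 10))
cell_wall_ratios <- function(profile) {
  p <- as.list(profile)
  vals <- unlist(p[c("rha", "ara", "xyl", "man", "gal", "gala")])
  if (any(vals < 0, na.rm = TRUE)) stop("sugar amounts must be >= 0")
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  out <- list(
    rgi_branching = safe_div(p$ara + p$gal, p$rha),
    pectin_linearity = safe_div(p$gala, p$rha + p$ara + p$gal),
    xyl_man = safe_div(p$xyl, p$man)
  )
  out$not_computable <- names(out)[vapply(out[1:3], is.na, TRUE)]
  out
}

#' Degrees of pectin methyl-esterification and acetylation
#'
#' The degree of methyl esterification (DM) is the molar amount of methanol
#' per 100 mol of uronic (galacturonic) acid; the degree of acetylation
#' (DA) is the mass of acetic acid per mass of polysaccharides, reported as
#' the raw mass ratio.
#'
#' @param profile a [sugar_profile()] carrying `methanol_mol`,
#'   `uronic_mol`, `acetic_mass`, `poly_mass`; alternatively pass those
#'   four values directly.
#' @param methanol_mol,uronic_mol,acetic_mass,poly_mass direct inputs,
#'   used when `profile` is missing.
#' @return list with `DM` and `DA`.
#' @export
#' @examples
#' esterification_degrees(methanol_mol = 20, uronic_mol = 100,
#'                        acetic_mass = 1, poly_mass = 50)
esterification_degrees <- function(profile = NULL, methanol_mol = NULL,
                                   uronic_mol = NULL, acetic_mass = NULL,
                                   poly_mass = NULL) {
  if (!is.null(profile)) {
    p <- as.list(profile)
    methanol_mol <- p$methanol_mol
    uronic_mol <- p$uronic_mol
    acetic_mass <- p$acetic_mass
    poly_mass <- p$poly_mass
  }
  if (is.null(uronic_mol) || is.na(uronic_mol) || uronic_mol <= 0) {
    stop("DM needs uronic acid > 0")
  }
  if (is.null(poly_mass) || is.na(poly_mass) || poly_mass <= 0) {
    stop("DA needs polysaccharide mass > 0")
  }
  list(DM = methanol_mol / uronic_mol * 100,
       DA = acetic_mass / poly_mass)
}

#' Partition cell-wall sugars into cellulose, hemicellulose and pectin
#'
#' Follows the two-step hydrolysis accounting: cellulose is the glucose
#' released only by the second (pre-hydrolysis) step; hemicellulose is the
#' total neutral sugar minus that cellulosic glucose; pectin is the uronic
#' (galacturonic) acid.
#'
#' @param cellulosic_glc glucose from the second hydrolysis (`>= 0`).
#' @param neutral_total total neutral sugars including cellulosic glucose
#'   (`>= 0`).
#' @param uronic_acid galacturonic acid amount (`>= 0`).
#' @return list with `cellulose`, `hemicellulose`, `pectin` and an
#'   `inconsistent_input` flag set when the subtraction goes negative (the
#'   raw negative value is kept so the inconsistency stays visible).
#' @export
#' @examples
#' polysaccharide_partition(10, 25, 8)
polysaccharide_partition <- function(cellulosic_glc, neutral_total,
                                     uronic_acid) {
  if (cellulosic_glc < 0 || neutral_total < 0 || uronic_acid < 0) {
    stop("inputs must be >= 0")
  }
  hemi <- neutral_total - cellulosic_glc
  list(cellulose = cellulosic_glc,
       hemicellulose = hemi,
       pectin = uronic_acid,
       inconsistent_input = hemi < 0)
}
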
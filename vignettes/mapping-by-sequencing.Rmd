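---
title: "Mapping-by-sequencing with bsamap: models, parameters and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping-by-sequencing with bsamap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsamap)
```

## The experimental design being modelled

`bsamap` implements the analysis of a classic recessive-mutant
mapping-by-sequencing experiment. A homozygous EMS mutant is crossed to its
non-mutagenized parent; the BC1F1 hybrid — heterozygous at every EMS-induced
variant — is selfed to give a BC1F2 population in which a monogenic
recessive mutation segregates 1:2:1 by genotype and 3:1 by phenotype.
Plants expressing the mutant phenotype (all homozygous at the causal locus)
and phenotypically wild-type plants are pooled into two bulks and each pool
is sequenced. At the causal locus and sites linked to it, the mutant bulk
shows a mutant-allele frequency near 1 and the wild-type-like bulk near 1/3;
everywhere else both bulks hover around 1/2. Scanning smoothed allele
frequencies along the genome therefore exposes the causal region, which is
then narrowed by genotyping recombinants at flanking markers and interpreted
by variant-effect annotation.

## The simulator

`simulate_bulk_experiment()` chains four generative steps, each exposed on
its own with an explicit `seed` (no hidden RNG state):

* **EMS variants** (`simulate_ems_variants()`). Background variants are
  placed uniformly, chromosomes chosen proportionally to physical length;
  position collisions are resampled, never dropped. Substitutions follow
  the canonical EMS spectrum — G:C→A:T transitions with probability
  `transition_prob` (default 0.98) — while the causal variant is specified
  explicitly and may be (as in the motivating study) a G→T transversion.
* **Meiosis** (`make_bc1f2()`). Crossovers per chromosome per gamete are
  Poisson with mean equal to the chromosome's genetic length in Morgans
  (Haldane model, no interference); crossover positions are uniform on the
  physical map, i.e. a linear cM/bp relation. Each BC1F2 individual is two
  independent gametes of the BC1F1 heterozygote. These are the simplest
  assumptions consistent with marker-scale mapping claims; real genomes
  have recombination coldspots (notably pericentromeric) that this model
  ignores.
* **Phenotype** is assigned recessively from the causal genotype. Full
  penetrance is the default; a `penetrance < 1` option exists because
  expressivity of cuticle phenotypes is environmentally variable, but it is
  off by default so that phenotype-selected bulks are genetically clean.
* **Pooled reads** (`simulate_pooled_reads()`). Per site, depth is
  Poisson(`mean_depth`); each read picks one of the bulk's 2n chromosome
  copies uniformly, reports the allele that copy carries, and is flipped
  with probability `error_rate`. The sampler is deliberately read-level;
  the test suite checks it against a closed-form binomial oracle by a
  Kolmogorov–Smirnov comparison.

### Default preset

`bsa_preset()` mirrors the motivating study: 12 chromosomes with
tomato-like physical sizes, 216 BC1F2 plants, bulks of 38, mean depth 32X,
error rate 0.002, and a causal G→T at chr12:2,751,259. Two values are not
given by any study and were fixed once as field-realistic choices:
~1,300 background EMS variants genome-wide (EMS populations in miniature
tomato cultivars segregate on the order of a few thousand induced SNVs; a
mapping line carries a subset) and a genetic length of 1 Morgan per
chromosome (≈1,200 cM genome, close to the tomato consensus map under the
linear cM/bp simplification).

## The scan

`bsa_scan()` is the package's estimator-like core and returns a classed
object with `print()`, `summary()` and `plot()` methods. Its stages, all
available as standalone functions:

* **Depth filter** — keep sites with 10 ≤ depth ≤ 100, *inclusive* and
  applied *per bulk* (both bulks must pass). The inclusive per-bulk reading
  is the conservative interpretation of a "depth between 10 and 100" rule;
  a summed-bulk variant is available via `scope = "summed"`.
* **Substitution filter** — default `all`, because a causal EMS hit can be
  a transversion; `transitions_only` implements the strict EMS spectrum.
* **Windowing** — means (not medians; the choice is a convention fixed
  here) of each bulk's AF over 10 consecutive SNPs, step 1 SNP. Windows
  never span chromosomes; a chromosome with fewer SNPs than the window
  yields no windows rather than one shrunken window, keeping window
  statistics identically distributed.
* **Region calling** — a window passes iff mean AF_mut > 0.95 **and**
  mean AF_wt < 0.4, strict inequalities. Overlapping/adjacent passing
  windows merge; region bounds are the outermost member-SNP positions,
  1-based closed. `rule = "high_only"` drops the wild-type condition and
  reproduces the raw high-AF detection that also picks up fixed
  introgression blocks (regions divergent from the reference in *both*
  bulks), which is how such a block shows up as a second high-AF region on
  the causal chromosome.
* **Ranking** — regions whose maximum wild-type-bulk window AF stays below
  0.4 rank ahead of both-bulks-high regions; within a group, by descending
  minimum AF_mut, ascending maximum AF_wt, descending window support, then
  genomic order. This makes the causal region outrank an introgression
  block even when the block's AF is exactly 1.
* A `delta_af` column (AF_mut − AF_wt) is emitted for plotting only; the
  caller never uses it, and no ΔSNP-index/G-statistic methods from the
  wider BSA-seq literature are implemented.

## Effect annotation

`classify_snv()` is a miniature consequence classifier: coordinates are
mapped through exon structures (strand-aware, multiple isoforms per gene),
the affected codon is cut from the spliced CDS and both alleles are
translated with the standard genetic code. Classes are `intergenic`,
`intronic`, `splice_site` (intronic, within 2 bp of an exon boundary — the
conventional splice donor/acceptor window), `utr`, `synonymous`,
`missense`, `nonsense`, `stop_loss`; `missense`, `nonsense`, `stop_loss`
and `splice_site` carry the deleterious flag used by `prioritize()`. When
a variant hits several isoforms, every effect is reported and the variant
is ranked by its most severe one. Protein changes use single-letter
ref-position-alt notation (e.g. `K114N`). Transcripts whose CDS length is
not a multiple of 3 are flagged partial and classified only to the UTR
level. First-codon substitutions are judged by the plain code table (a
start-loss class is not distinguished). Indels and MNVs are out of scope.

The packaged demo locus (`write_demo_gene()`) is a *synthetic* two-isoform
gene built programmatically: both isoforms share exon 2, codon 114 is AAG
with its third base at the exon-2/intron-2 boundary, so a G→T there yields
K114N missense in both isoforms while the first intronic base beyond it is
a splice site. The test suite validates the classifier against an
independent oracle that rebuilds and diffs the whole mutant protein at
every CDS position on both strands.

## Fine mapping and segregation

Among phenotypically mutant plants (inferred homozygous at the causal
locus), any marker genotype other than `hom_mut` reveals a crossover:
heterozygous calls count as recombinant, `missing` calls are excluded from
numerator and denominator. The candidate interval is the maximal contiguous
run of zero-recombinant markers — longest run, ties broken by fewer
flanking recombinants, then leftmost — with open bounds at the nearest
flanking markers that do show recombinants (`NA` at a chromosome end). If
every marker shows recombinants the result is flagged empty with a
diagnostic; if none does, the interval is flagged unresolved.
`chi_square_segregation()` is the Pearson goodness-of-fit test (df = 1)
against the 1:3 recessive expectation.

## Downstream tabular statistics

`filter_degs()` applies |log2FC| ≥ 1, q < 0.05 and, when FPKM columns are
present, FPKM strictly greater than 5 in at least one genotype. The
q-threshold default is 0.05; 0.07 (a looser display threshold sometimes
used for volcano plots) is available by argument. The packaged DEG tables
are hand-curated transcriptions of published summary tables; they are
post-filter by construction, which the suite asserts. Known internal
inconsistencies of such published tables (category counts quoted in prose
that differ by 1–3 from the table rows) are preserved, not resolved: counts
here follow the tables. `two_sample_t()` is the classic pooled-variance
Student's t accepting mean/SD/n summaries (the form biochemical results are
printed in); the degenerate all-equal zero-variance case returns p = 1 by
convention. The cell-wall helpers flag, rather than error on, zero
denominators (e.g. rhamnose below the detection limit makes the RGI
branching ratio not-computable), and the acetylation degree is reported as
a raw mass ratio (a ×100 percentage is formatting, not computation).

## Problem sizes and numerical choices

The shipped test-suite and acceptance-script sizes are package choices
balancing statistical resolution against a comfortable desk-scale runtime:
10,000 plants for the segregation percentage; 50 replicate experiments for
the scan medians; 1,000 replicates for the chi-square type-I calibration;
20 seeds for the 1:2:1 genotype-frequency property (run on a
single-chromosome genome, since the property concerns only the causal
locus); 2,000-plant populations for recombinant-fraction checks. All loops
derive sub-seeds deterministically from one user seed. Multi-seed scan
loops re-draw the rare population (<1% of seeds) with fewer than 38
mutant-phenotype plants, mirroring the fact that a real bulk experiment is
conditioned on the bulks being fillable.

## What passing tests do and do not show

The generator reproduces the *sampling structure* of a bulk-sequencing
experiment: Mendelian segregation, Haldane recombination, finite-bulk
genotype sampling, Poisson depth and read error. It does not emulate
alignment and variant-calling artefacts, depth overdispersion and mapping
bias, recombination-rate heterogeneity, residual heterozygosity, or
phenotype misclassification. Passing tests therefore validate the
*analysis* under the stated stochastic model, not the wet-lab pipeline
upstream of a VCF.

One property deserves emphasis. Under the default design (bulks of 38 from
216 plants, 32X, ~1,300 SNPs, 1 M/chromosome), the causal 10-SNP window
spans several megabases, and two irreducible sampling effects widen the
window-mean distributions: recombination drift among the 76 selected
haplotypes (mutant-bulk window mean ≈ 0.98 with SD ≈ 0.02) and
hypergeometric sampling of heterozygous vs homozygous-wild-type plants into
the wild-type-like bulk (window mean ≈ 0.34 with SD ≈ 0.05). In roughly one
replicate in ten, the dual-threshold rule (0.95/0.4) therefore misses the
causal window even though the experiment is perfectly simulated — the same
run-to-run risk an experimenter takes with bulks of this size. The
acceptance suite asserts the stricter ≥95% per-replicate recovery rate and
documents the observed shortfall rather than relaxing thresholds or
enlarging the simulated design; the *median* causal-window allele
frequencies across replicates (≈0.98 mutant bulk, ≈0.34 wild-type-like
bulk) clear the thresholds comfortably, which is the criterion the
headline acceptance targets use.

## Known limitations

* Linear cM/bp and no crossover interference; no pericentromeric
  suppression (candidate regions near centromeres would be wider in
  reality).
* Counts-level simulation only; no FASTQ/alignment artefacts.
* The consequence classifier handles biallelic SNVs only, with a fixed
  2 bp splice window and no regulatory annotations.
* Differential-expression testing itself is out of scope: q-values are
  inputs, taken from upstream tools.
* The fine-mapper reports marker-bounded intervals; it does not estimate
  genetic distances or LOD support.
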
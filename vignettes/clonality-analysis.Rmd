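---
title: "Integrative multi-omic clonality analysis with clonediv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative multi-omic clonality analysis with clonediv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonediv)
```

## The problem

A tumor is a population of competing cell lineages.  Serial samples from
one patient — at diagnosis ("presentation") and at recurrence ("relapse")
— let us watch that population evolve under therapeutic selection.  The
raw material is heterogeneous: somatic single-nucleotide variants from
whole-exome sequencing (WES), variants re-called from RNA-seq reads,
isoform-level expression, raw gene counts, inferred copy-number segments,
and array methylation of gene promoters.  clonediv joins these per-sample
datasets into one *integrated relation*, and computes two summaries of
clonal architecture on top of it: an abundance-weighted Shannon diversity
index, and a copy-number-weighted kernel density of variant allele
frequencies (VAF).

## The integration model

Every input is a typed relation (a validated data frame):

* `W` — WES variants: locus, depth `DP`, allele frequency `AF` in percent,
  gene annotation, predicted impact;
* `M` — methylation probes: beta value in [0, 1], regulatory feature,
  CpG-island relation;
* `C` — copy-number segments: closed intervals with integer `CN`;
* `H` — raw gene counts; `RV` — RNA variants; `R` — transcript FPKM;
* `K` — a curated gene list (drivers, VUS, tumor suppressors);
* `P` — experiment metadata.

Integration is a fixed chain of relational-algebra operations:

1. retain `W` rows with `min_vaf <= AF <= max_vaf` and
   `min_depth <= DP <= max_depth` (defaults 4–100 % and 20–1000 reads, all
   bounds inclusive);
2. **I** — restrict to MODERATE/HIGH impact and left-outer-join `M` on the
   gene id;
3. **J** — equi-join `RV` to `R` on the gene id, keeping `FPKM > 0`;
4. **D** — equi-join `RV` to `H` on the gene id, keeping `Count > 0`;
5. left-outer-join **I** to **J**, then to **D**, on (chromosome,
   position);
6. left-outer-join the result to `C` by containment
   (`Start <= Position <= Stop`).

Left-outer joins preserve every DNA mutation; missing modalities surface
as nulls, never as dropped rows.  Nulls obey standard relational
semantics: they propagate through projections and never satisfy an
equality predicate.  Each record then receives a *glyph*: `2` (WES plus
RNA) when an RNA variant matched the locus **and** the gene shows
expression support (a transcript with positive FPKM, or a positive raw
count), else `1` (WES only).  We use both expression routes because the
pipeline feeds both joins; requiring the RNA variant alone would mark
mutations in unexpressed genes as "expressed", and requiring FPKM alone
would miss genes quantified only at the count level.

`distinct_mutations()` projects the integrated relation onto the
per-mutation attributes and deduplicates, so a mutation matched by three
transcripts is still one mutation.  Deduplication compares reals after
rounding to 10 significant digits: a stable identity under float noise,
far below any biologically meaningful difference.

Set comparisons between two samples (`paired_compare()`,
`intersect_on()`, `difference_on()`) key on (chromosome, position) only.
Two different alternate alleles at one position therefore count as one
mutation — a deliberate coarseness that matches how paired sample
comparisons are usually tabulated; the relation rows themselves keep each
alternate separate.

## Quantifying clonal diversity

Each retained mutation is treated as one molecular species with abundance

$$a_i = \mathrm{VAF}_i \times \mathrm{DP}_i \times \mathrm{CN}_i,$$

and the Shannon diversity index is
$\mathrm{SDI} = -\sum_i p_i \ln p_i$ with $p_i = a_i / \sum_j a_j$,
reported in nats.  SDI is 0 for a single mutation and at most $\ln N$ for
$N$ mutations; it is invariant under permutation and under uniform
rescaling of all abundances, which the test suite checks as exact
identities.  A mutation with no overlapping copy-number segment takes
CN = 2: diploid is the neutral assumption for unannotated loci.
Zero-abundance entries contribute nothing; an all-zero input is an error,
not a silent 0.  Simpson and Berger–Parker indices are provided as
optional companions but are not part of the default metrics.

## VAF density estimation

The VAF distribution is summarized with a Gaussian kernel density in
which every mutation is weighted by the copy number of its segment:

$$\hat f_h(x) = \frac{\sum_i w_i\, K\!\left(\frac{x_i - x}{h}\right)}
                     {h \sum_i w_i},$$

with $K$ the standard normal density.  With equal weights this reduces
exactly to the classical estimator $\frac{1}{nh}\sum_i K((x_i - x)/h)$.
The curve is evaluated on 512 equally spaced points on [0, 100] VAF
percent, with no boundary correction.  Peaks suggest clonal clusters;
`kde_modes()` reports strict interior local maxima of the gridded curve.

The bandwidth comes from a two-stage direct plug-in selector
(Sheather–Jones / Wand–Jones family) for the Gaussian kernel: the
eighth-derivative density functional starts at its normal-scale value
with scale estimate $\min(s,\ \mathrm{IQR}/1.349)$, the sixth- and
fourth-derivative functionals are estimated at their asymptotically
optimal pilot bandwidths, and
$h = (2\sqrt{\pi}\,\hat\psi_4\, n)^{-1/5}$.  The implementation uses the
exact double sums rather than binned approximations; the test suite
cross-checks it against the independent binned selector in KernSmooth to
three significant figures, and verifies location invariance and scale
equivariance.

Two numerical choices deserve emphasis:

* **Weights enter the density, not the selector.**  The selector runs on
  the unweighted VAF values.  This mirrors the usual pairing of a plain
  univariate plug-in bandwidth with a weighted density, and keeps the
  bandwidth comparable across samples with different CN profiles.
* **Degenerate inputs fall back, never crash.**  With fewer than 5
  distinct values, zero scale, or a non-positive curvature functional,
  the selector returns Silverman's rule ($0.9\,\hat\sigma n^{-1/5}$) with
  a floor of 0.5 VAF points, flagged via the `"method"` attribute.

## Filter settings

| parameter | unit | default | role |
|---|---|---|---|
| `min_vaf` / `max_vaf` | VAF percent | 4 / 100 | somatic retention window |
| `min_depth` / `max_depth` | reads | 20 / 1000 | coverage window |
| `min_meth` | percent | 25 | promoter methylation threshold |
| `opacity` | fraction | 0.5 | scatter point opacity |
| `show_kg_only` | flag | FALSE | restrict plots to listed genes |

All bounds are inclusive: a mutation at exactly AF = 4 and DP = 20 is
retained.  Filtering is applied *before* any key-gene intersection, so a
key-gene mutation at the 4 % boundary survives.

## The TSG methylation table

Tumor-suppressor silencing is tracked by three probe-level criteria:
average beta at least `min_meth`/100, a "Promoter Associated" regulatory
feature, and a CpG "Island" location (string matching is
case-insensitive after trimming, since vendor exports vary).  Passing
probes are joined to the gene's raw RNA read count — 0 when the gene is
absent from the count table — and flagged `silenced` when that count is
zero.  This table is built from the methylation relation directly, so
unmutated TSGs are reported; the strictly integrated route
(`tsg_methylation_integrated()`), which can only surface mutated genes,
is provided separately because both views are useful and they genuinely
differ.

## The synthetic generator

`generate_bundle()` emulates the statistical structure the pipeline is
designed to reveal, with every draw keyed to one seed through R's
Mersenne–Twister generator:

* VAFs drawn per clone from truncated normals around the configured
  centers (defaults: clones at 20 and 45 % VAF, equal weights, 3-point
  spread — a clonal cluster near heterozygous-diploid and a subclone);
* depths uniform on 30–300 reads around a 100x design; the
  variant-supporting read count is back-computed so `compute_vaf()`
  reproduces the stored VAF *exactly*;
* about a third of mutations mirrored into the RNA relations, producing
  mixed glyph populations;
* a configurable number of silenced TSGs planted to pass all three
  methylation criteria with zero counts, plus two controls that fail
  them (one expressed, one off-island);
* a diploid genome with chromosome 8 trisomic and 13 monosomic by
  default.

What it does **not** emulate: sequencing error and strand bias, indels
and multi-nucleotide variants (the readers accept them; the generator
emits SNVs only), correlated methylation–expression structure beyond the
planted silenced-TSG construct, subclonal copy number, or tumor purity.
Passing tests therefore demonstrate correctness of the relational and
statistical machinery under a clean generative model, not robustness to
every artifact of real sequencing data.

The packaged worked example (`mm_case_bundle()`) is a paired
presentation/relapse multiple-myeloma case encoded as relations: five
mutated key genes at presentation (three RNA-expressed), three gained at
relapse, transcript-level dynamics including one assembler-novel
transcript, and promoter-methylated TSG panels.  The printed tables it
reproduces carry no genomic coordinates, so loci are synthetic positions
placed inside each gene's approximate GRCh37 span; copy numbers are
expressed as ±1 Mb segments around those loci.

## Problem sizes used in the checks

The property suites run the full pipeline against a naive nested-loop
oracle on 200 random bundles of up to 100 variants, and the mode-recovery
check plants two clones 25 VAF points apart (about 8 intra-clone
standard deviations) with roughly 120 retained mutations per clone —
sizes chosen so each suite completes in seconds while still exercising
multi-row join fan-out, null propagation and both glyph populations.

## Known limitations

* Clonality is operationalized per mutation, not per inferred clone: no
  clustering or phylogeny is attempted (tools like SciClone, PyClone,
  TrAp or PhyloWGS own that territory).
* Copy-number weighting assumes one integer CN per locus; overlapping
  segments are rejected as a data error rather than resolved.
* The paired comparison keys on position only (see above).
* Headline diversity values depend on the retention filter; they are
  comparable across samples only under identical settings.
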
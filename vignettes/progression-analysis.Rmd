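---
title: "Tracking genetic and epigenetic change in progressing CLL"
author: "ProgressionKit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking genetic and epigenetic change in progressing CLL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProgressionKit)
```

## The question

Chronic lymphocytic leukemia is unusual among cancers in that patients are
monitored through blood draws from diagnosis until symptoms require
treatment, so the same leukemia can be sampled twice *before* any therapy.
Two mechanisms could drive clinical progression over that interval:
selection among genetic subclones (some mutations rising, others falling in
frequency), or epigenetic change (recurrent DNA methylation shifts, in
particular at Polycomb/PRC2 target regions that acquire methylation in many
cancers).  ProgressionKit implements both halves of that analysis for
paired pre-treatment samples, together with a synthetic cohort generator
that provides ground truth for every stage.

## The genetic model

A variant site is summarized by ref/alt read counts in three samples:
germline, first tumor time point, second tumor time point.

**Somatic calling.**  The 2x3 allele-by-sample table is tested with a
Monte-Carlo permutation chi-square: tables are drawn with all margins fixed
(`r2dtable`), and the p-value is $(1 + \#\{\chi^2_{perm} \ge
\chi^2_{obs}\})/(1 + B)$ with $B$ = 10000 by default.  The +1 correction
keeps $p > 0$, so the attainable significance floor is $1/(B+1)$; $B$ must
therefore exceed 1000 for the somatic threshold $p < 0.001$ to be
reachable.  A site is somatic when $p < 0.001$ **and** the germline
alternate-allele fraction $alt/(alt+ref)$ is below 0.10 — the second
condition removes germline heterozygous and homozygous-alt sites whose
counts can also differ across samples.

**Drift testing.**  Allele-frequency change between the two tumor samples
is tested with the two-sided Fisher exact test on the 2x2 count table,
computed by direct summation of hypergeometric probabilities at most as
likely as the observed table (identical to `fisher.test`, but vectorizable;
the test suite verifies equality against exhaustive enumeration for every
table with $N \le 60$).  Benjamini–Hochberg FDR is applied at 0.05
*within each patient*: the FDR family matches the per-patient
classification the calls feed, rather than pooling patients with very
different site counts.  Direction comes from the allele-fraction point
estimates; exact ties count in neither direction.

**Classification.**  With $u$ significant rises and $d$ significant falls:
at least one of each is *evolving* (subclonal selection in both
directions); $u \ge 2, d = 0$ is *expanding* (consistent with the leukemia
growing against the normal compartment); $u + d \le 1$ is *static*.  The
quadrant $d \ge 2, u = 0$ is not covered by that three-way scheme; it is
labelled *contracting* explicitly rather than silently folded away
(`collapseContracting = TRUE` folds it into static if wanted).  No minimum
absolute frequency change is required beyond significance.

**Copy-number units.**  Segment calls that are near each other on the same
chromosome — including the same event re-called at the other time point —
are merged single-linkage with a 1 Mb gap tolerance (`GenomicRanges`
reduction); 1 Mb merges segmentation jitter while keeping independent focal
events apart.  Each group counts once per patient, and groups are labelled
with the recurrent CLL locus they overlap (11q, trisomy 12, 13q14, 17p);
the locus table is configuration (`inst/extdata/cll_recurrent_loci.tsv`,
approximate hg19 intervals), not code.

## The methylation model

Beta values (methylation fractions in $[0,1]$) come from unsorted blood,
so every sample is a mixture of leukemic B cells with NK, CD4+ T, CD8+ T
cells and neutrophils, and the tumor fraction itself changes between time
points.  Composition must be removed before asking whether specific CpGs
change.

**Deconvolution.**  Each sample's betas at cell-type-specific marker CpGs
are modelled as $\beta \approx Rw$ with $R$ the marker-by-cell-type
reference panel and $w$ on the unit simplex ($w \ge 0$, $\sum w = 1$; the
five types are treated as exhaustive).  The constrained least-squares
problem is solved exactly by enumerating the 31 possible supports and
solving each equality-constrained subproblem in closed form — with five
cell types this costs microseconds and avoids approximate iterative
solvers.  The panel is an input file; the bundled generator produces a
synthetic panel with the classic structure (each type hypermethylated at
its own markers), since marker selection from reference data is outside
this package's scope.

**Adjustment.**  Per CpG, betas are regressed on the composition (intercept
plus four of the five proportions — the neutrophil column is dropped
because the simplex constraint makes all five collinear; which column is
dropped is fixed and documented).  The adjusted value is the CpG's grand
mean plus the residual, clamped to $[0,1]$.  The operation is idempotent,
and identical compositions leave the data untouched.

**Discovery.**  For each CpG the paired $(t_1, t_2)$ values across patients
enter a two-sided Wilcoxon signed-rank test; zero differences are dropped,
the exact null is used for $n \le 25$ untied differences and the
continuity-corrected normal approximation otherwise.  CpGs are significant
at BH-FDR < 0.05, with direction given by the sign of the median paired
delta.  Both adjusted and unadjusted matrices can be tested; adjusted
values are the default analysis substrate.

**Scores.**  Two spec-level summaries are defined here because no closed
formula exists for them elsewhere: the *B-cell score change* is the mean
signed beta change over B-cell-specific sites (oriented so rising B-cell
load raises the score), a cheap proxy for tumor-load change validated
against composition shifts in simulation; the *progression score* is
$\sum |\Delta\beta|$ over progression-associated CpGs, the per-patient
"cumulative deviation".

**Annotation.**  A significant CpG is near a ChIP-seq peak when the 200 bp
window centred on the probe (0-based half-open
$[pos - 100, pos + 100)$) intersects a peak by at least 1 bp; enrichment of
flags among significant CpGs is upper-tail hypergeometric.  Strand is
ignored throughout — probes and peaks are treated as strandless.  Gene-set
tests correct for probe-to-gene bias by resampling: genes enter the null
hit set with probability proportional to their probe count, an explicit
Monte-Carlo version of the bias correction that gene-set tools apply
analytically (a Wallenius-approximation mode would be a possible
extension).  Raw p-values are reported alongside BH-adjusted ones when a
sweep over many experiments is run.  Fixed published lists (mouse-model
genes, age-associated CpGs, platform-restricted marker sets) are compared
by Fisher's exact test within an explicit universe, because the correct
universe depends on the platform; when the published list came from a
smaller array, the universe is restricted to that platform's content
first.

**B-cell development comparison.**  Group-mean differences between naive B
cells, memory B cells and the first CLL time point are flagged at
$|\Delta| \ge 0.10$ (the "±10%" rule, on the beta scale, applied to group
means — per-sample application is a documented alternative the figures do
not support).  Progression CpGs are tested for over-representation among
differing CpGs (hypergeometric), and direction concordance is the percent
of overlapping CpGs whose progression delta has the same sign as the
group difference, zero deltas excluded.  Similarity clustering uses
average-linkage on Euclidean distance — defaults chosen, not dictated by
any source — plus a per-sample nearest-reference call by mean distance.

## What the generator emulates — and what it does not

`simulateGeneticCohort` draws 2–9 subclones per patient (the observed
range), assigns variants to the trunk or one subclone, and converts
prevalence and purity to expected VAF as $\text{purity} \times
\text{prevalence}/2$ (heterozygous, diploid).  Read counts are binomial at
Poisson depths (means 100x exome / 850x amplicon, floor one read; the
sources state depth ranges, not a distribution, so Poisson is the minimal
choice).  Subclones are independent (disjoint) by default; a linear-nesting
mode exists.  Purity changes and copy-number interactions with VAF are not
modelled: germline contamination acts through purity alone, and
CNV-overlapping variants are out of scope.  There is no read-level error
model, so the generator cannot probe mapping artifacts or strand bias —
passing recovery tests says the *statistics* behave, not that upstream
variant calling on real reads would.

`simulateMethylationCohort` mixes five reference profiles with per-sample
compositions in which the B-cell fraction rises modestly between time
points (the leukemia expanding against normal cells), plants progression
effects at the second time point with 77% increases and magnitudes
distributed as $0.005 + 0.09\,\mathrm{Beta}(1.2, 2.772)$ (median 0.029,
range 0.005–0.095), adds truncated Gaussian noise (sd 0.02 by default) and
clamps to $[0,1]$.  Planted CpGs are drawn from CpGs with baseline beta in
$(0.15, 0.85)$: a saturated CpG cannot express a modest planted change
through the clamp, and biologically the modest gains concentrate at
intermediate-methylation PRC2 targets.  H3K27me3 flags are assigned so
planted CpGs are enriched at a configurable odds ratio (default 3) over a
20% baseline.  The generator does not emulate probe-type chemistry
differences, SNP-overlapping probes, batch effects or array normalization
— all explicitly out of scope — so results on real arrays additionally
depend on preprocessing this package does not perform.

## Numerical choices and degenerate inputs

* Monte-Carlo p-values always use the +1 correction; permutation ties
  count as extreme (with a $1 - 64\epsilon$ relative tolerance), making
  the tests conservative rather than anti-conservative on discrete data.
* A 2x3 table with no alternate reads anywhere has no variation to
  permute; its p-value is 1 by definition rather than an error.
* All-zero paired differences at a CpG give $p = 1$ and an `untested`
  flag; empty drift input classifies as static with a warning and
  $n_{tested} = 0$.
* Deconvolution refuses rank-deficient panels and missing markers by
  name; compositions are validated to the simplex at $10^{-6}$.
* Degenerate 2x2 margins make the odds ratio undefined (reported as
  `NA`/`Inf`, with the Fisher p still defined).
* Clustering a constant matrix yields zero distances; the tree is
  returned with a `degenerate` flag rather than an error.
* Fixed seeds make every simulation and every Monte-Carlo test
  bit-reproducible; seed-taking functions restore the caller's RNG state.

## Problem sizes used in the shipped checks

The test suite exercises the pipeline at sizes a laptop handles in
minutes, chosen as the package's own verification scale: cohorts of 27–60
patients, arrays of 4000–20000 CpGs, $10^5$ null tables for the
type-I-error measurement of the somatic test at its 0.001 threshold
($B = 9999$ permutations, where the attainable level below 0.001 is
$9/10000$), and 250 replicate null cohorts for FDR calibration of the
drift test.  At these sizes the acceptance checks recover ≥90% of planted
evolution categories, ≥80% of planted progression CpGs with effects
≥ 0.03, composition estimates within 0.05 mean absolute error at noise sd
0.02, and the planted 77% increase fraction within binomial error.

## Known limitations

* The classification rule is exactly the published three-way scheme plus
  an explicit contracting label; it does not model uncertainty in the
  category (a patient with one borderline drift call flips categories).
* Per-patient BH makes drift discoveries non-comparable across patients
  with very different validated-site counts; the pooled alternative is a
  one-line change but alters the family being controlled.
* The deconvolution reference panel is synthetic by default; applying the
  package to real arrays requires a real panel on the same platform.
* The resampling gene-set null conditions on the total number of hit
  genes, not on the significant-CpG count; genes hit through many probes
  of one CpG island are treated like any other hit.
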
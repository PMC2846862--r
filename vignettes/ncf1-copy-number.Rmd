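---
title: "Calling NCF1/NCF1B/NCF1C copy numbers from paralog-specific variants"
author: "ncf1cnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling NCF1/NCF1B/NCF1C copy numbers from paralog-specific variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncf1cnv)
```

## The measurement problem

The NCF1 gene (p47-phox, a subunit of the phagocyte NADPH oxidase) lies at
7q11.23 inside three ~106-kb duplicons that are more than 99.5% identical.
Two of the duplicons carry pseudogene copies, NCF1B and NCF1C, whose
defining lesion is a 2-bp GT deletion in exon 2 (the same deletion that, on
a functional NCF1 allele, causes chronic granulomatous disease).  Because
reads, primers and probes cannot distinguish the duplicons, per-paralog
dosage has to be inferred from *paralog-specific variants* (PSVs):
positions where the paralogs carry different alleles.  Two PSVs jointly
separate all three paralogs:

* **exon 2**: NCF1 carries `GTGT`, both pseudogenes carry `GT` — isolates
  NCF1;
* **exon 9**: NCF1B and NCF1 carry `A`, NCF1C carries `G` — isolates NCF1C.

Pyrosequencing a pooled template reports light-peak heights proportional to
the number of templates carrying each allele, so the two assays read out
allele *fractions* that encode copy-number *proportions*.

## Forward model

For a genome with integer copies $(b, n, c)$ of NCF1B, NCF1, NCF1C and
total $T = b + n + c$:

$$f_{GT} = \frac{b + c}{T}, \qquad f_A = \frac{b + n}{T},$$

and the diploid pseudogene:NCF1 ratio is $r = (b+c)/n$, equal to
$f_{GT}/(1-f_{GT})$.  Raw pyrogram peak pairs are converted by calibrated
height normalisation $f = h_1 / (h_1 + \kappa h_2)$ with a single
per-assay factor $\kappa$ (default 1) absorbing incorporation-yield
differences between alleles; the vendor software's proprietary peak model
is not public, and a one-parameter skew is the minimal correction that can
represent a yield difference between a 2-bp and a 1-bp allele.

The fractions are invariant under integer scaling of the trio —
$(1,2,3)$ and $(2,4,6)$ are indistinguishable — so inversion needs an
anchor.

## The caller

`ncf1_call()` inverts a profile $(f_{GT}, f_A)$ by exhaustive search over a
candidate grid, minimising the Euclidean distance between observed and
expected fractions over the two sites.  Unweighted squared error in
*fraction* space is used because replicate noise is approximately
homoscedastic on that scale, unlike the ratio scale where the variance
grows as $(1-f)^{-4}$.

Tunable parameters (`call_constraints()`):

* `n_mode` (default `fixed_two`): NCF1 pinned at 2 copies, matching the
  "p:2" ratio-class convention in which population results are reported.
  The scale anchor has to come from somewhere; fixing $n = 2$ is the
  field's convention for this locus.  A `free` mode searches $n$ over
  `n_range` (default 1..4) and breaks the scale ties by minimum total copy
  number (so the fractions of $(2,4,6)$ call as $(1,2,3)$), for cohorts
  where NCF1 duplications are plausible.
* `max_per_pseudogene` (default 6): pseudogene grid 0..6, covering every
  ratio class reported for this locus (0:2 through 6:2) with headroom.
* `tolerance` (default 0.04, fraction units): calls whose best residual
  exceeds this are flagged `no_call`.  0.04 keeps the printed measured
  class means (2.41, 1.97, 1.53, 1.0 against expectations 2.5, 2.0, 1.5,
  1.0) calling confidently — the largest of those deviations is 0.09 on
  the ratio scale, about 0.01 in fraction space — while rejecting profiles
  that sit between grid points.

Residual ties within $10^{-9}$ go to the smallest total, then smallest
NCF1B count, making the caller deterministic.  `enumerate_collisions()`
documents the identifiability structure of any grid: the default
`fixed_two` grid is collision-free, while the free grid contains the
scalar-multiple families the tie-break resolves.

`classify_ratio()` implements the lighter one-dimensional variant used for
GT:GTGT-only data: nearest expected ratio among classes $p\!:\!q$, midpoint
ties to the smaller pseudogene count.

### Numerical margins

The worst-case perturbation tolerance of the caller is set by the spacing
of expected profiles.  Adjacent candidates at diploid totals 7–8 can lie
only ~0.02–0.036 apart in fraction space (e.g. $(5,2,0)$ vs $(6,2,0)$
differ by 0.036 in $f_{GT}$ alone), so the *uniform* guarantee over all
trios with $T \le 8$ is stability to ±0.01 per fraction (verified by brute
force over corner perturbations; call regions are convex, so corners
suffice).  The genotypes actually observed in families (0:2:2, 0:2:3,
1:2:3, 2:2:2) tolerate ±0.02, and at the calibrated measurement noise
($\sigma_f = 0.015$) simulated cohorts call at ≥95% accuracy — the test
suite verifies each of these statements rather than a single blanket
margin.

## Pedigree analysis

A per-chromosome haplotype is a count vector $(b_h, n_h, c_h)$ of duplicons
on one chromosome 7 (per-arm bound 3 by default, enough for every
haplogenotype reported for this locus); a haplogenotype is an unordered
pair of haplotypes summing to the diploid trio.  `check_transmission()`
searches for a global assignment in which every non-founder inherits
exactly one haplotype from each parent: candidate sets from
`enumerate_haplotype_pairs()` are narrowed by constraint propagation over
parent–parent–child triples, then a depth-first search in generation order
produces a witness or a refutation.  `deduce_haplogenotypes()` reports, per
individual, the union of candidates over all globally consistent
assignments by re-running the satisfiability test with each candidate
pinned — sound and complete, and checked against an exhaustive oracle on
small pedigrees in the test suite.

De novo copy-number changes are deliberately not modelled: an impossible
child makes the pedigree inconsistent and is reported (`conflicted`), never
silently repaired.  An opt-in error-tolerance mode (`max_drop`) retries
with up to $k$ typed individuals treated as untyped and reports whom it
dropped.

## Population statistics

`summarize_populations()` reports per-paralog means and sample SDs,
ratio-class frequencies and gene-pool shares (each paralog's share of all
gene copies).  `two_sample_t()` implements the pooled-variance Student test
(default, matching the source study's stated method) and the Welch variant,
from raw values or from printed summary statistics — the latter is what
makes published group contrasts re-checkable when per-individual genotypes
are unavailable.  `compare_populations()` runs all pairwise per-paralog
tests, uncorrected by default for fidelity to the published analysis, with
opt-in Bonferroni.

## Expression dissection and qPCR

Only transcripts retaining (mutant or wild-type) exon 2 are visible to the
exon-2 cDNA assay.  Within that pool, `dissect_contributions()` assigns
$p_N = f_{GTGT}$, $p_C = f_G$, and $p_B = 1 - f_{GTGT} - f_G$ by
subtraction.  Because $p_B$ inherits both assays' errors, a small negative
value (within `tol`, default 0.02 — typical pyrosequencing noise) is
clipped to zero and the shares renormalised; a larger inconsistency is an
error naming both inputs.  `per_copy_activity()` converts shares to
per-copy transcription relative to NCF1, and `cdna_gt_ratio()` gives the
cDNA-side GT:GTGT ratio directly comparable to the genomic one.

The qPCR layer is the standard-curve method: `fit_standard_curve()`
regresses Ct on $\log_{10}$ quantity (efficiency $E = 10^{-1/\text{slope}}
- 1$), `quantify()` inverts it, and `normalized_fold_change()` forms
replicate-level target/reference quantity ratios *before* averaging, so the
between-condition t test is well-defined on replicate ratios (the
alternative — a ratio of means — admits no per-replicate test; the source
study does not state which was used).  The fold-change confidence interval
is a t interval on the log scale.  A constant Ct offset on every well (a
plate effect) cancels when target and reference share a curve slope.

## The synthetic-data generator

`simulate_population()` forms diploid genomes as two independent draws from
a `haplotype_pool()` and emits noisy fractions plus peak pairs;
`simulate_pedigree()` gene-drops haplotypes through a pedigree;
`simulate_expression()` generates cDNA fractions and Ct tables from
per-copy rates, GT-exon retention fractions $\rho_B, \rho_C$ (NCF1 retains
GTGT with probability 1), condition multipliers and an inverse standard
curve.  All randomness flows from one `seed` argument and the caller's RNG
state is restored afterwards, so identical seeds give identical outputs.

Fixed generator conventions, chosen once:

* **Noise** is Gaussian in fraction space, $\sigma_f = 0.015$, truncated to
  $[0,1]$.  Via the delta method ($\mathrm{SD}_r = \sigma_f/(1-f)^2$, a
  factor 9 at the 4:2 class) this reproduces the published replicate spread
  of the 4:2 class (ratio SD ≈ 0.14).
* **Population presets** (`population_preset()`): haplotype pools are not
  identifiable from diploid class frequencies, so the presets are
  minimal-support pools fitted to the published class percentages and
  per-paralog means.  The African-American pool {(0,1,1) 0.15, (1,1,1)
  0.70, (0,1,2) 0.15} reproduces the published 71.9% 4:2 share (implied
  72.25%) and means (1.4, 2.0, 2.3) essentially exactly, and the Caucasian
  pool similarly (4:2 implied 55.8% vs 56.1%).  The published *Mexican*
  class table (1:2 4.2%, 2:2 41.7%, 3:2 50.0%, 4:2 4.2%) contains a
  heterozygote excess that no pool can reproduce under random union of
  gametes — for a sum of two iid draws, the odd-class mass cannot exceed
  the even-class mass, yet 50.0% > 41.7% + 4.2% — so the Mexican preset is
  the least-squares fit (implied classes 1:2 1.6%, 2:2 42.8%, 3:2 44.1%,
  4:2 11.6%), and simulator tests assert convergence to the pool-implied
  distribution, not to the unattainable printed one.  All presets use
  single-NCF1 arms, so simulated truths have $n = 2$; the published
  population mean of 2.1 NCF1 copies suggests occasional $n = 3$
  individuals, but no printed datum constrains their haplotypes, so they
  are not simulated.
* **Expression defaults**: equal per-copy rates with
  $\rho_B = \rho_C = 0.25$, reproducing the observed 0.5:1 pseudogene:NCF1
  cDNA ratio for a 2:2:2 genome; qPCR true slope $-3.3219$ (perfect
  doubling), intercept 30, Ct noise SD 0.1, five replicates per condition
  (matching the published experimental design).

What the simulator deliberately does **not** emulate: sequence-level reads,
linkage with flanking markers, de novo duplications, EBV-transformation
artefacts, allele-specific PCR bias beyond the single calibration factor,
and the alternative-exon isoforms beyond their aggregate effect as the
$1-\rho$ mass missing from the GT pool.  Passing round-trip tests therefore
demonstrate internal consistency of the inference under the stated noise
model, not robustness to every artefact of real pyrograms.

## Problem sizes used in the test suite

Deterministic worked examples run on single profiles.  Stochastic checks
use: 500 genomes per population for call-accuracy bounds; 10,000 genomes
for class-frequency convergence; 1,000 seeded replicates at the study's
cohort sizes (32 vs 24) for the between-population power check and 1,000
for the type-I-error check; ten-member three-generation pedigrees for
gene-dropping; and five-replicate qPCR scenarios mirroring the published
design.  These sizes give binomial/standard errors comfortably inside the
asserted bounds.

## Known limitations

* The scale anchor ($n = 2$ or min-total) is a convention; a genome with a
  genuine NCF1 duplication and proportionally scaled pseudogenes is
  indistinguishable from its reduced form.
* `fixed_two` mis-specifies genomes whose true $n \ne 2$; how the original
  study resolved those individuals is not documented, so the package
  exposes both modes rather than guessing.
* The pedigree deduction treats haplotypes as count vectors; which
  pseudogene sits on which flank of NCF1 is not represented.
* p-values from printed rounded summaries will not match p-values computed
  from the underlying raw data (the published 6e-15 is of that kind); the
  package reproduces the test statistic pipeline, not unpublished data.
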
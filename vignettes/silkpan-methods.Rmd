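---
title: "Methods: pan-genome population analysis with silkpan"
author: "silkpan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-genome population analysis with silkpan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`silkpan` implements the population-genomic core of a silkworm
(*Bombyx mori*) pan-genome analysis: selective-sweep scanning over
sliding windows, occupancy classification and accumulation modelling of
orthogroups, construction and group-divergence scanning of non-redundant
structural variants (SVs), and presence/absence association of SVs with
tissue expression. This vignette records the models, the parameter
choices that matter, and the design decisions taken where the problem
was genuinely open.

## Cohort structure and contrasts

All group comparisons are driven by a sample manifest mapping each
sample to a population: wild, local (domesticated landraces), improved
breeding groups (e.g. CHN-I, JPN-I), or genetic stocks. The
domestication contrast compares wild (ancestral) against local
(descendant); improvement contrasts compare local (ancestral) against
each improved group separately.

## Sliding-window sweep scan

Windows are 5 kb with a 500 bp step (`scanWindows()`). Full windows are
placed while they fit; a single trailing truncated window is added only
when the last full window does not reach the chromosome end, so every
base is covered and at most one window per chromosome is short. Windows
with fewer than three usable SNPs are scored missing and excluded from
percentile ranking.

Diploid genotypes are treated as `2n` exchangeable lineages: every
statistic works from per-site called-allele counts, so missing genotypes
are dropped site by site and no phasing is required.

* **Nucleotide diversity** uses the unbiased per-site estimator
  `2 k (n - k) / (n (n - 1))` summed over window sites.
* **Tajima's D** is `(pi - S/a1) / sqrt(e1 S + e2 S(S-1))` with the
  standard constants computed at the haploid sample size. With per-site
  missingness the constants use `n` rounded from the mean called-allele
  count over segregating sites; at `n = 2` the variance constants vanish
  and the window is scored missing.
* **FST** defaults to the Hudson estimator accumulated as a ratio of
  sums over the window (recommended for unbalanced samples); a
  Weir-Cockerham estimator over diploid genotype data is selectable and
  agrees with Hudson within 0.02 on balanced simulations. Sites
  monomorphic across both populations are skipped.
* **XP-CLR-style score.** The method is named after the
  cross-population composite likelihood ratio test; since its exact
  density is a modelling choice, we document ours completely so the
  score is reproducible. Given the reference-population frequency `p1`,
  the object-population frequency is modelled as
  `Normal(p1, omega * p1 (1 - p1))` truncated to (0, 1) with the tail
  mass placed as point masses at 0 and 1. A hard sweep with selection
  coefficient `s` transforms a pre-sweep frequency `x` into
  `1 - c + c x`, where `c = 1 - exp(-r ln(2 N s)/s)` is the escape
  probability at recombination distance `r` (physical distance from the
  putative sweep site, the window midpoint, times a per-bp
  recombination rate). The window score is
  `max_s 2 (logCL(s) - logCL(0))` over a grid of 0 plus 20 log-spaced
  values in [1e-4, 0.5]. The frequency integral uses 64-node
  Gauss-Legendre quadrature; tests verify agreement with a 10,000-point
  trapezoid rule to 1e-6. The drift scale `omega` is estimated by the
  method of moments, `mean((p_obj - p_ref)^2 / (p_ref (1 - p_ref)))`,
  over at least 1000 polymorphic sites; under the Balding-Nichols
  model this estimates the divergence parameter F. LD-based SNP
  down-weighting from the original software is out of scope.

Candidate sweep regions are windows simultaneously in the top 1% of
FST, the top 5% of the XP-CLR score, and the lowest 5% of the
descendant population's Tajima's D, additionally requiring
D_descendant < D_ancestral at the window; quantiles are genome-wide
linear-interpolation empirical quantiles over non-missing windows, with
threshold ties included (deterministic and conservative). Passing
windows are merged into maximal regions after intersection; genes are
assigned by at least 1 bp of gene-body overlap.

## Pan-gene analysis

With `N` genomes and occupancy count `k`, an orthogroup is core
(`k = N`), softcore (`0.9 N < k < N`), dispensable (`2 <= k <= 0.9 N`)
or private (`k = 1`); the four classes partition the orthogroups.

Accumulation curves report the expected pan count (present in at least
one of the first `x` genomes) and core count (present in all `x`),
averaged over 100 seeded random genome orders by default; a fixed,
e.g. phylogeny-guided, order is also supported since published curves
sometimes use stepwise addition. The pan curve is fitted with the
exponential model `y = A + B exp(C x)` by Levenberg-Marquardt least
squares (the model is commonly fitted with `nls`); starting values are
`A0 = max(y)` (pan) or `min(y)` (core), `C0` and `B0` from a log-linear
regression of `log|y - A0|` on `x`, with five jittered restarts keeping
the best residual sum of squares. The plateau size is the smallest
integer `n` at which the closed-form increment `B e^{Cn}(e^C - 1)`
falls below 0.001 of the asymptote `A`.

Group frequency differentiation of orthogroup presence uses one 2x2
Fisher exact test per orthogroup (presence counts per group),
Benjamini-Hochberg adjustment across all tested orthogroups, and a
presence-frequency fold change; significance requires q < 1e-4 and
fold change > 2. A frequency pair (0, 0) has fold change 1; a single
zero gives infinity so a fixed difference is never silently dropped.

## Structural-variant toolkit

Per-sample SV calls are merged into non-redundant sites by
single-linkage clustering within each (chromosome, type) stratum: calls
link when breakpoints lie within 500 bp and the length ratio
(smaller/larger) is at least 0.7; when both calls carry sequences a
global-alignment identity of at least 0.25 is also required (applied
only when sequences are available, so the merge is reproducible without
alignment machinery). The site representative is the member closest to
the cluster's median position, ties broken by smallest sample id, making
the merge independent of input order. A second parameter preset
(1 kb distance, same type, minimum length 50 bp) serves error-prone
region consolidation.

Filtering removes SVs longer than 100 kb (strictly), SVs with only
reference genotypes (per-sample at calling time, all-sample at cohort
level), and SVs intersecting error-prone regions expanded by 2.5 kb.
SV intervals are half-open after conversion from 1-based VCF;
insertions are 1 bp points for all overlap tests.

Allele frequencies default to allele counts over called alleles
(`AF = alt alleles / (2 x called samples)`); carrier frequencies (any
alternate allele) drive the divergence scan, since a presence/absence
reading is the natural scale for PAV-dominated cohorts. Divergence
between groups uses the same Fisher + BH + fold-change engine as the
orthogroup scan at FDR 1e-4 and fold change 2. Genomic context uses
precedence CDS > regulatory > intergenic, with regulatory defined as
introns plus the +/-5 kb gene flanks. Multi-allelic loci are
single-linkage clusters of nrSVs of any type within 500 bp (the merge
distance without type/size constraints) — a documented choice, since
how a "single site" is delimited is otherwise ambiguous. SV/TE density
correlation uses non-overlapping 500 kb windows, counting SVs by
breakpoint and TEs by midpoint.

## SV-expression association

SV-gene pairs require the SV to lie in the gene's introns or within
5 kb of the gene; testable pairs need at least three carrier and three
non-carrier strains among those with expression data. Expression is
FPKM; replicates are averaged per strain and tissue and tests run on
`log2(FPKM + 1)` (the transform stabilises variance for a t-test on
expression ratios and is recorded in the output metadata). Carrier and
non-carrier strains are compared per tissue with the pooled-variance
two-sample t-test (Welch selectable); BH adjustment pools all
pair-by-tissue hypotheses jointly — the stricter and deterministic
reading — and a pair is significant when its minimum q across tissues
is below 0.001.

## Synthetic cohorts

The generators produce every input with known ground truth, which is
what the test suite and the acceptance script exercise.

* **SNP cohorts** follow the Balding-Nichols model: ancestral
  frequencies Beta(1, 1) clipped to [0.01, 0.99]; each population's
  frequency drawn from `Beta(p (1-F)/F, (1-p)(1-F)/F)` so that
  `Var(p_i | p) = F p (1 - p)` and the expected FST is about F
  (default F = 0.1, a realistic wild/domesticated divergence);
  genotypes are Binomial(2, p) draws. Hard sweeps reuse the
  hitchhiking transform above (defaults `Ne = 1e4`,
  recombination 1e-6 per bp, chosen so a `s = 0.1` sweep has a
  10-20 kb footprint on the simulated 200 kb chromosomes).
  Because the model has no linkage, sweep detection in tests rests on
  the frequency transform, not haplotype structure — real-data sweeps
  carry LD signal these simulations do not emulate.
* **Occupancy matrices** are built deterministically to prescribed
  class counts (core all-present, private round-robin, softcore/
  dispensable occupancies drawn uniformly inside their class bounds),
  so classification must round-trip the construction exactly.
* **SV cohorts** draw null-site frequencies from a rare/common mixture
  hitting a configurable rare fraction (default 0.8, matching the
  rare-allele-dominated spectrum of long-read SV cohorts); the rare and
  common laws stay clear of the 0.05 boundary so the fraction realised
  after binomial genotype sampling still matches the target. Shifted
  sites move group B from 0.05 to 0.6 by default, a strong
  domestication-style frequency shift.
* **Expression** simulates `log2` values as baseline + delta x carrier
  + Normal(0, sigma) and back-transforms as `FPKM = 2^x`, so delta = 1
  is exactly two-fold in the noise-free case (default sigma = 0.1 on
  the log2 scale, typical for averaged replicates).

Everything is deterministic given (configuration, seed); the
orchestration commands write identical bytes on re-run.

## Numerical choices and degenerate inputs

* Two-sided Fisher tests use the probability-mass rule (sum of all
  tables with the observed margins no more probable than the observed
  one); degenerate margins return p = 1; an all-zero table errors.
* Two groups with zero variance and equal means give t = 0, p = 1 by
  convention; unequal means give p = 0.
* Correlation of a constant vector is an error, not an NA, so
  degenerate window-count tracks fail loudly.
* Quantile thresholds use R's type-7 linear interpolation.
* The exponential fit reports non-convergence explicitly after
  exhausting all restarts.
* `2 N s <= 1` in the sweep transform is treated as fully neutral
  (escape probability 1).

## Problem sizes used in tests

Test and acceptance simulations use scaled-down cohorts chosen to make
the statistical properties measurable while keeping the suite quick to
run: 20,000 sites and 50+50 diploids for FST consistency; three 200 kb
chromosomes, 3000 SNPs and 30+30 diploids per seed (10 seeds) for sweep
recovery; 5000 SV sites with 100 shifted (40+40 samples) for the
divergence scan; 14 strains, 6 tissues and 2 replicates for the
expression association, mirroring the cohort shape of the motivating
study at desk scale.

## Known limitations

* No linkage disequilibrium in the simulator, hence no haplotype-based
  statistics (iHS/EHH) and no LD weighting in the composite likelihood.
* The Tajima constants use a single per-window `n`; heavy, uneven
  missingness would bias D slightly.
* Sequence identity in SV merging uses global alignment of provided
  sequences only; breakpoint-only call sets fall back to distance and
  size alone.
* The expression test is a t-test on log-FPKM, not a count model;
  counts-level inference (negative binomial) is out of scope.
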
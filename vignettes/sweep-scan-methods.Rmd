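---
title: "Methods: selection-signature scanning and its regulatory follow-up"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection-signature scanning and its regulatory follow-up}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`sweepexpress` implements a complete within-population selection-scan
pipeline for phased genotype data and its downstream link to tissue
expression, cis-eQTL and QTL annotations. This vignette explains the models
and procedures, the tunable parameters, the synthetic-data generator that
the tests run against, and the numerical conventions chosen where the
standard methods leave room.

## The haplotype statistic

The scan is built on extended haplotype homozygosity (EHH). For a core
variant and one of its alleles, EHH at a second variant is the probability
that two randomly drawn carriers of the core allele are identical at every
variant between the core and that position:

$$\mathrm{EHH}(k) \;=\; \sum_h \frac{n_h (n_h - 1)}{n_c (n_c - 1)},$$

summed over the distinct extended haplotypes $h$ among the $n_c$ carriers.
The curve starts at 1 at the core and is non-increasing outward; it is
evaluated at variant positions only.

The integrated EHH (iHH) for an allele is the trapezoidal integral of the
EHH decay over physical distance, accumulated outward on each side until
the first variant where EHH drops below a cutoff (default 0.05, the
conventional setting for sequence-based scans); the segment ending at that
crossing variant is included. Curves that reach the end of the data before
crossing are integrated in full and flagged `truncated` — they are kept by
default, since dropping them would thin out chromosome ends.

The unstandardized score for a variant is
$\mathrm{uiHS} = \ln(\mathrm{iHH}_\text{derived} /
\mathrm{iHH}_\text{ancestral})$. An allele rising recently in frequency
sits on unusually long shared haplotypes, so a sweeping derived allele
drives this ratio up; the peak caller uses $|z|$, so the sign convention
does not affect detection. Variants are scored only when the minor allele
frequency is strictly above 0.01 and both allelic backgrounds have at
least two carriers and a positive integral; the others are dropped with a
recorded reason.

Because haplotype lengths depend strongly on allele frequency, scores are
standardized within derived-allele-frequency bins: 50 equal-width bins by
default (width 0.02), $z = (\mathrm{uiHS} - \bar u_b)/s_b$ with the sample
SD $s_b$. Bins with fewer than two variants or zero SD cannot be
standardized and their variants are dropped with a log. Integration is
over physical distance — no genetic map is assumed, matching scans run
without one; a map could be substituted by transforming positions before
scoring.

## Two-step signature calling

Peak calling uses a two-threshold rule on the per-variant $|z|$ track:
candidate runs are maximal stretches of consecutive variants with score at
least the exit threshold (3.5), and a run becomes a peak only if its
maximum reaches the enter threshold (4.0). Peak bounds are the first and
last variant of the run; peaks are not extended beyond the sub-exit
variants. Scoring with $|z|$ rather than signed $z$ is a deliberate
choice: the statistic is signed, but both tails indicate sweeps, and a
signed mode is available (`use_abs = FALSE`).

The second step is population-specific validation: the threshold is the
minimum score among the top 0.01% of variants (the `ceiling(q n)`-th
largest value), and a peak survives only if its maximum *exceeds* that
threshold — strict inequality, with `strict = FALSE` available. With
fewer than `1/q` variants the threshold degenerates to the maximum score
and a warning is issued; meaningful use needs roughly 10,000+ scored
variants.

Cross-population structure follows interval algebra with
bedtools-`multiinter` semantics: the union of all populations' signatures
is partitioned at every interval endpoint, each segment carrying the exact
covering population set (overlapping peaks within one population are
merged first). Segments within 50 kb of each other are chained into
regions; the gap is measured between 1-based inclusive coordinates as
`next.start - prev.stop - 1`, so two segments separated by exactly 50,000
intervening base pairs are still chained. Regions shared by two or more
populations are `common`, single-population regions `exclusive`. Gene and
QTL annotation both define overlap as at least one shared base pair; an
input pair with no chromosome name in common raises an error naming the
labels, which catches `chr1` vs `1` mismatches early.

## Population-genetic statistics

Per-variant differentiation across all populations uses the Weir &
Cockerham (1984) variance-components estimator $\theta = a/(a+b+c)$ on
diploid genotypes, with the observed heterozygosity entering the
within-individual component. Variants monomorphic in every population
have a zero denominator and are dropped; negative estimates are retained
unclamped, because downstream analyses use the upper tail and clamping
would distort quantiles. Linkage disequilibrium is summarized as the
squared Pearson correlation of diploid allele dosages for variant pairs
within 1 Mb; when the full pair list is large a seeded uniform subsample
of pairs (default cap 200,000) is scored instead, and the output records
that it was subsampled.

## Tissue overexpression and enrichment

One tissue is contrasted against all other samples per gene:
$\mathrm{logFC} = \bar x_\text{target} - \bar x_\text{rest}$ with the
pooled two-group variance $s_g^2$ on $d$ degrees of freedom. The variance
is moderated by shrinking toward an across-gene prior,
$\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)$, with $(d_0, s_0^2)$
fitted by a method-of-moments inverse-gamma match to the spread of the
$s_g^2$; the moderated $t$ uses $d + d_0$ degrees of freedom. This is a
deliberately simple empirical-Bayes scheme: it reproduces the *ranking*
behaviour that matters downstream, and with `prior_df = 0` it reduces
exactly to the ordinary pooled-variance two-sample $t$ (a tested
contract). It does not reproduce any particular reference implementation's
$t$ values, and no contrast/covariate machinery is provided.

A gene is called overexpressed when its logFC is positive and its
moderated $t$ lies in the top 5% of $t$-values *within the positive-logFC
subset* (the default; a whole-set mode exists because the alternative
reading is defensible). Under a null matrix this flags about 2.5% of
genes — half of 5%, since about half have positive logFC.

Enrichment of a selected gene set among the overexpressed genes of a
tissue is a Pearson chi-squared test on the 2×2 membership table over the
background universe, *without* continuity correction (stated explicitly
because defaults differ across packages), and the recorded significance
level is Bonferroni-corrected for a 22-tissue panel (0.05/22).

## Adaptive-eQTL statistics

Top-0.01% variants are co-localised with significant cis-eQTL by exact
(chromosome, position) match, one hit per (variant, tissue, eGene,
population) combination.

Overlap enrichment uses circular randomization: the signature interval set
on each chromosome is shifted by one uniform random offset per chromosome
per permutation, wrapping around the end (a wrapped interval splits into
two arcs). This preserves the number, lengths, order and spacing of the
intervals — the chromosomal structure — while randomizing position. The
observed statistic is the count of eQTL positions inside any signature
interval and the empirical p-value is
$(\#\{\text{perm} \ge \text{obs}\} + 1)/(n_\text{perm} + 1)$ with 10,000
permutations by default. Shifting the intervals (not the positions) is the
semantics of the standard circular-randomization tools; conservation of
interval count and total length is asserted in test runs.

The effect-size analysis joins per-variant FST with cis-eQTL slopes per
tissue. Extreme-effect variants are excluded by a leave-one-out rule:
a variant is dropped iff its $|$slope$|$ exceeds 390 times the mean of all
*other* $|$slope$|$ values in that tissue (strictly greater). The
association is the Spearman rank correlation (average ranks on ties)
between FST and $|$slope$|$ — absolute effect size by default, signed mode
available — with a two-sided p from the $t$ approximation. "Adaptive"
variants are those in the top 1% of FST among the joined variants; their
$|$slope$|$ distribution is compared to the rest with a two-sided Wilcoxon
rank-sum test, exact by enumeration when both groups have at most 12
observations and no ties, otherwise the normal approximation with tie
correction and no continuity correction.

## The synthetic-data generator

Every statistical claim in the test suite is made against data with known
ground truth, produced by the generator. What it emulates, and the chosen
default conditions:

* **Neutral haplotypes.** A discrete-generation Wright–Fisher forward
  simulation on a fixed site grid: each offspring haplotype draws two
  uniform parents, a Poisson number of crossovers placed uniformly on the
  physical map (rate $10^{-8}$/bp/generation), and Poisson site mutations
  (0↔1 flips). Defaults are desk-scale: $N = 200$ haplotypes per
  population, burn-in $8N$ generations, 5,000 sites on 5 Mb. The per-site
  mutation rate is $2.5\times10^{-3}$ so that $2N\mu = 1$: at this small
  $N$ the stationary frequency distribution is then close to uniform and
  most sites stay polymorphic, giving the variant density the scan needs
  without simulating a genome-scale population. The cost of that scaled-up
  mutation rate is honest and documented: per-site recurrent mutation also
  breaks haplotypes, so LD decays faster per base pair than in real
  cattle; the LD-decay *ordering* (near pairs more correlated than far
  pairs) is preserved and tested.
* **Population divergence.** Two modes. With `balding_nichols_F > 0`,
  per-population site frequencies are drawn from the Balding–Nichols beta
  distribution around a shared ancestral frequency and founders are
  sampled i.i.d. — this plants a known expected FST (used by the FST
  recovery tests) but carries no LD, so burn-in defaults to 0 there. With
  `F = 0`, populations drift independently through the full burn-in, which
  builds realistic within-population LD but leaves cross-population
  differentiation to drift. The two aspects cannot be planted exactly
  simultaneously by construction, so each test uses the mode whose planted
  quantity it measures.
* **Sweeps.** `inject_sweep` is a haplotype-copying construction, not a
  fitness simulation: a donor carrier's local segment is copied onto
  random non-carriers until the core derived count equals
  `round(target_freq * n)` exactly. Per-recipient extents are exponential
  with mean 100 kb per side (0.001/recombination rate), mimicking
  recombination breakup; the construction guarantees the elevated-EHH
  signal the scan must detect, with exact frequency control. The core is
  chosen near the requested position among variants whose current derived
  frequency does not exceed the target, preferring low-frequency variants
  (a recent sweep lifts a rare haplotype); raising toward a frequency
  below the current one is an error, not a silent reverse sweep.
* **eQTL slopes.** A Gaussian copula plants a target Spearman correlation
  between FST and $|$slope$|$: the normal scores of the FST ranks are
  mixed with independent noise at the Pearson correlation
  $2\sin(\pi\rho/6)$ that induces Spearman $\rho$ for a bivariate
  Gaussian, then mapped monotonically to log-normal magnitudes with random
  signs. At $\rho = 1$ the rank coupling is exact.
* **Expression.** Log-expression is gene baseline + planted log-fold
  change for (gene, tissue) pairs in the ground-truth sets + Gaussian
  noise. Default study conditions: 2,000 genes, 5 tissues, 40
  samples/tissue, LFC 1, noise SD 0.5 — the regime in which the ranking
  should flag planted genes at ≥ 90% sensitivity with ≤ 6% null flagging.

All generator randomness flows from a single integer seed recorded in the
outputs.

What passing tests on these data do *not* show: the generator has no
demography (bottlenecks, admixture, migration), no background selection,
equal-spaced sample sizes, exchangeable sites within the BN mode, and
Gaussian expression noise without batch or library-size structure. Results
on real data will be noisier in all of those directions; the tests
establish correctness of the computations and recoverability of planted
effects under clean conditions, not field performance.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere internally; BED is
  converted on read and write. Positions are physical bp.
* The ancestral-allele policy for VCF input is explicit: REF-as-ancestral
  by default (recorded in the object), or `INFO/AA` with an error if the
  tag is missing — polarization is never guessed.
* QC order is fixed and documented: biallelic-SNP filter, then
  genotype-quality masking (per-genotype `GQ > 20` by default; a site-level
  `QUAL` mode exists because the quality rule is ambiguous in common
  usage), then variant call rate ≥ 0.95 (inclusive), then sample call rate
  ≥ 0.75. Variants with residual missingness are dropped before scanning
  — the haplotype statistics require complete data.
* In bin standardization the *sample* SD is used; a two-variant bin with
  scores $\{a, -a\}$ therefore standardizes to $\pm 1/\sqrt 2$, not
  $\pm 1$.
* The iHS scan and the Wright–Fisher inner loop are implemented in C++
  (Rcpp) for speed; both are checked against independent brute-force R
  oracles (pairwise-identity EHH counting, per-variant component
  transcription for FST) in the test suite.
* Problem sizes in the tests are the package's own desk-scale choices:
  oracle equivalence at ≤ 30 haplotypes × 50 variants × 200 instances;
  iHS cross-validation at 40 haplotypes × 2,000 variants; neutral
  calibration at ~20,000 scored variants; sweep recovery over 10 seeded
  replicates of a 12-Mb chromosome; permutation calibration over 500
  replicates of 199 permutations; copula recovery at n = 5,000.

## Known limitations

* The moderated-$t$ is a method-of-moments scheme, not a full
  empirical-Bayes fit; its p-values are approximate and intended for
  ranking.
* The top-0.01% validation is meaningless below ~10,000 scored variants
  (threshold becomes the maximum; a warning is raised).
* The circular permutation test is conservative when overlap counts are
  heavily tied (small interval sets and few positions).
* `ld_r2_summary` subsamples pairs above its cap; exact enumeration is
  only guaranteed below it.
* Cross-population FST in the Wright–Fisher (LD) mode is an emergent
  drift quantity, not a planted parameter; plant FST with the
  Balding–Nichols mode.
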
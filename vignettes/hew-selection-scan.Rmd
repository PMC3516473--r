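---
title: "Scanning phased gene fragments for selective sweeps with the compound HEW test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning phased gene fragments for selective sweeps with the compound HEW test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hewscan)
```

## The problem this package addresses

Amplicon resequencing of short (~500 bp) gene fragments in deeply sampled,
genetically structured insect populations — for example immune-gene panels in
malaria-mosquito subpopulations — produces, per locus and per population
stratum, an alignment of phased haplotypes, one outgroup sequence, and a gene
model.  The scientific questions are: which loci carry the footprint of
recent positive selection in which stratum; how differentiated are the strata
locus by locus; and, for candidate loci, what haplotype structure underlies
the signal (partial sweep, sweep from standing variation, or a completed
sweep with recombination)?

`hewscan` implements that workflow end to end on silent
(synonymous + noncoding) variation: summary statistics, coalescent null
distributions, a jointly calibrated compound neutrality test, permutation
F_ST, a multilocus HKA model, and LD/haplogroup dissection — plus a
synthetic-data generator so the entire pipeline can be exercised and
validated without any field data.

## Statistics and their estimators

For a sample of $n$ phased chromosomes with $S$ segregating silent sites:

* **Watterson's estimator** $\hat\theta_W = S / (a_n L)$ with
  $a_n = \sum_{i=1}^{n-1} 1/i$.
* **Nucleotide diversity** $\pi$: mean pairwise difference proportion,
  computed per column on non-missing entries.
* **Tajima's D**: $(\bar k - S/a_1)/\sqrt{e_1 S + e_2 S(S-1)}$ with the 1989
  constants; undefined at $S = 0$.
* **Normalized Fay & Wu's H**: with unfolded SFS counts $S_i$,
  $\theta_\pi = \sum 2i(n-i)S_i / (n(n-1))$,
  $\theta_L = \sum i S_i/(n-1)$, and
  $H = (\theta_\pi - \theta_L)/\sqrt{\mathrm{Var}}$, where the variance uses
  $\hat\theta = S/a_n$ and $\hat\theta^2 = S(S-1)/(a_n^2 + b_n)$.  The
  identity $\theta_\pi + \theta_H = 2\theta_L$ is asserted in the tests.
  Polarization against the outgroup is required; unpolarizable columns are
  excluded from SFS-based statistics but retained for $\pi$, $\theta_W$ and
  D, which need no polarity.
* **Ewens–Watterson homozygosity** $F = \sum_k p_k^2$ over distinct
  haplotype strings at segregating columns.  Haplotypes with missing calls
  at a segregating column are dropped from $h$ and $F$ — deterministic and
  conservative; fully phased inputs are unaffected.

Site classification is codon-based against a designated reference haplotype;
monomorphic coding columns are called synonymous only when fourfold
degenerate.  Judging synonymy against the reference codon only (rather than
all codon paths) is adequate for short fragments where almost all variants
are biallelic.

## The compound HEW decision

A sweep leaves two coupled signatures: an excess of high-frequency derived
alleles (H pushed negative) and excess haplotype homozygosity (F pushed up).
The compound test computes one-tailed Monte-Carlo p-values for each component
against a neutral coalescent null — no recombination, sample size $n$,
mutation parameter set to the locus's own $\hat\theta_W$ — and rejects only
when *both* fall at or below a jointly calibrated threshold $t$.

$t$ is the largest value with empirical
$\Pr(p_H \le t \text{ and } p_{EW} \le t) \le \alpha$ over a calibration
sample of null p-value pairs.  Two details matter:

* **The calibration pairs must reflect the S the locus actually shows.**
  Conditioning on $S$ strengthens the dependence between H and F, so pairs
  self-ranked within the pooled fixed-$\theta$ null understate the joint
  tail (we measured a 7–8% empirical size at nominal 5% under that
  shortcut).  The pairs are therefore drawn by fixed-$S$ simulation at the
  observed $S$ — the standard ms-style conditioning, also used for the
  clade analysis — and ranked against the same fixed-$\theta$ null the
  locus is tested against.  Measured over replicate 500-locus neutral
  experiments the empirical size is then ≈0.05 (0.044–0.072 across
  experiment seeds); the remaining wobble is finite-calibration noise in
  the estimated threshold, which clusters across loci sharing a cached
  null, not a systematic bias (this is what the acceptance suite
  measures).
* **Monte-Carlo p-values carry the add-one correction** $(r+1)/(m+1)$, so
  zero p-values never occur; monomorphic null replicates are excluded from
  the denominators and topped up so every null has its full number of
  informative replicates.

A monotone compound p-value (the calibration-sample probability of
$\max(p_H^*, p_{EW}^*) \le \max(p_H, p_{EW})$) is attached for ranking and
BH correction; Tajima's D is tested two-sided alongside but does not enter
the decision.

Null distributions are cached by $(n, \hat\theta$ to 3 significant
digits$)$; since $\hat\theta = S/a_n$, loci with equal $S$ share a null,
which keeps desk-scale scans fast.

## What the test can and cannot detect

Because the null model has no recombination and the fragment is the swept
locus itself, a *completed* hard sweep collapses the genealogy into a star:
every surviving mutation is young and rare, so the high-frequency-derived
component of HEW physically cannot become extreme, and rejection power is
essentially nil even though the compound p-value ranks such loci far into
the tail.  Detectable sweep classes are those leaving escape lineages —
partial sweeps and sweeps from standing variation — which produce exactly
the H/EW combination the test was designed for (planted partial sweeps with
80% of lineages swept are rejected in ~90% of simulations).  The test suite
asserts this power profile; empirically flagged loci in real fragment scans
have the same character (substantial $S$, strongly negative H, elevated F).

## Differentiation and shared polymorphism

F_ST uses the Weir–Cockerham (1984) method-of-moments components for
*haploid* samples — phased chromosomes are the sampling unit, so the
genotype heterozygosity term is absent — combined across sites and alleles
as a ratio of sums (stable for short fragments).  Significance comes from
permuting stratum labels (group sizes preserved).  Shared-polymorphism
proportions are corrected for unequal sample sizes by rarefaction: both
samples are repeatedly down-sampled to a common depth and the proportion of
one sample's segregating sites also segregating in the other is averaged
over rounds; the paper-scale correction is otherwise unspecified, so the
rarefaction depth and replicate count are explicit arguments.

## Multilocus HKA

The HKA module fits, by moments, per-locus $w_i = \theta_i L_i$ and a shared
divergence time $T$ (2N units) from silent polymorphism counts $S_i$ and
outgroup fixed differences $D_i$:
$E[S_i] = w_i a_{n_i}$, $E[D_i] = w_i (T+1)$,
$\mathrm{Var}(S_i) = E[S_i] + w_i^2 b_{n_i}$,
$\mathrm{Var}(D_i) = E[D_i] + w_i^2$.  The goodness-of-fit sum $X^2$ is
compared against coalescent simulation under the fitted model with
parameters re-fitted on every simulated dataset, which keeps the simulation
p-value uniform under the null (asserted by test).  Divergence is simulated
as a Poisson mixture over an Exp(1) lineage depth, matching the model's
variance exactly.  This is a one-population-plus-outgroup variant (no
outgroup polymorphism, no relative-size parameter); it is oracle-tested
against an independent numerical solve, not claimed bit-identical to any
legacy implementation.  Since fragment panels rarely include designated
neutral control loci, `hka_select_neighbors()` picks the nearest flanking
loci that did not themselves reject neutrality.

## Haplogroup dissection

For loci flagged by HEW, the deep-dive computes the $r^2$ matrix (haplotype
correlation on phased data, pairwise-complete), searches for sets of ≥3
sites whose bipartitions agree on all but `max_recombinants` haplotypes,
splits the sample into haplogroups A (larger) and B with discordant
haplotypes flagged `A*`/`B*`, and asks whether each clade's diversity
($h$, $S$, mean pairwise differences) is too low under a neutral coalescent
*conditioned on the clade structure*: rejection sampling keeps genealogies
containing an internal edge subtending exactly the observed clade size
(configurable ± tolerance), drops exactly the observed number of mutations
on each accepted genealogy, and compares clade-wise statistics left-tailed
with add-one correction.  Clade comparisons use unscaled mean pairwise
differences, which is the scale-free quantity under fixed-S conditioning.
Note that with no recombination, deep neutral genealogies also produce
perfect-LD site sets fairly often — set discovery is a screening device;
the conditioned diversity test is what separates sweep-like clades from
ordinary deep coalescence.

Trees are neighbor-joining on Jukes–Cantor distances (pairwise deletion),
with negative branch lengths clamped to zero and the deficit moved to the
sister edge so adjacent path lengths are preserved.  JC replaces the
composite-likelihood distance used by some desktop tools; at within-complex
divergences the topologies agree, and the NJ topology is verified against a
brute-force implementation.  Sliding-window divergence uses physical 50 bp
windows shifted by 10 bp (including monomorphic columns), with
$K_{JC} = -\tfrac34\ln(1 - 4p/3)$ per window, undefined at $p \ge 3/4$.
Clade consensus sequences take the per-column majority allele (alphabetical
tie-break).

## The synthetic-data generator

`simulate_multipop_study()` emulates the target study design: four strata
with 56–170 chromosomes (defaults 94, 136, 56, 170), 28 fragments of 500 bp
with a two-exon-plus-intron gene model, per-locus $\theta = 10$
(≈0.02/site, matching silent diversity in such panels), and an outgroup at
divergence $T_{div} = 5$ (2N units).  Histories:

* *growth* — piecewise-constant size drop to 10% at 0.1×2N backward in time
  (molecular-form strata show Tajima's D near −1.3 under this setting);
* *bottleneck* — size 0.1 between 0.05 and 0.15×2N;
* *complete/partial/standing sweeps* — forced multiple mergers at
  $\tau = 0.01$: all lineages, a fraction $f$, or a collapse onto $k$
  ancestral lineages.  Sweeps are genealogical approximations rather than
  forward simulations with selection coefficients: the statistics consume
  genealogy shape, and no quantitative sweep-strength claims are made.

Mutations follow infinite sites onto distinct alignment columns; outgroup
divergence is realized as Poisson mutations private to the outgroup branch
plus mutations on the sample's stem lineage (both surface as fixed
differences, as real divergence does).  All randomness derives from one
study seed through a documented per-(locus, stratum) rule, so bundles are
byte-identical under the same seed.  What the generator does *not* emulate:
intragenic recombination, linked selection across fragments, sequencing or
phasing error (phase confidences are emitted but uncorrelated with the
haplotypes), and shared ancestry between strata (each stratum is an
independent sample, so cross-stratum sharing statistics on synthetic data
are conservative).  Passing tests therefore validate the statistical
machinery, not field-data artifact handling.

## Numerical and design choices

* Time unit 2N generations, coalescence rate $k(k-1)/2$, mutation rate
  $\theta/2$ per lineage per unit time, so $E[S] = \theta a_n$; verified
  against closed forms and cross-checked against an independent coalescent
  simulator (two-sample KS on Tajima's D).
* Haplotype identity in simulated samples is computed by random-weight path
  hashing (exact, O(n+S)) rather than materializing genotype matrices.
* Sites containing `N`/`-` are kept; the affected entries are treated as
  missing, and a column segregates only on non-missing entries.
* The clade-match criterion in conditioned sampling is exact clade size by
  default ("similar" clade structure is undefined in the field literature);
  `size_tol` relaxes it.  The attempt cap defaults to 100× the requested
  replicates and aborts with the realized acceptance rate.
* BH correction defaults to within-stratum scope (switchable to global):
  each stratum is a separate family of locus hypotheses.
* Down-sampling to `n_max` (default 100) chromosomes is seeded uniform
  without replacement and applied before all statistics.
* Desk-scale problem sizes used by the tests and the acceptance script —
  500 calibration loci with 2000-replicate nulls, 500 permutation
  experiments, $10^4$-replicate moment checks, 20 recovery bundles of 8
  loci — were chosen as the smallest sizes at which the binomial/3-SE
  acceptance bands are meaningfully tight.

## Known limitations

* No recombination anywhere (nulls, generator, LD logic) — conservative for
  the test, but it means completed hard sweeps are rankable, not rejectable
  (see above), and neutral perfect-LD sets are common.
* The HKA variant models a single population plus one outgroup sequence and
  fixes the ancestral polymorphism term at $\theta_i$.
* Synonymy against the reference codon only; no codon-path enumeration.
* The Ewens–Watterson statistic drops haplotypes with missing data at
  segregating sites, which can shrink $n$ at ragged alignments.
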
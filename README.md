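# hewscan

Selective-sweep scans of short, phased haplotype fragments with the
compound **HEW** neutrality test.

## What this is for

Amplicon resequencing panels — tens of ~500 bp gene fragments sequenced in
hundreds of chromosomes from several partially isolated population strata
(e.g. immune-gene panels in malaria-mosquito subpopulations) — call for a
specific analysis stack: per-locus, per-stratum summary statistics on
silent sites; neutrality tests with coalescent nulls; differentiation
between strata; and haplotype-structure dissection of candidate loci.
`hewscan` implements that stack for population geneticists working with
phased alignments, together with a synthetic-data generator that emulates
the whole study design so every stage is testable without field data.

## The statistics at the core

For each locus and stratum, on silent (synonymous + noncoding) sites:
Watterson's `theta_W = S/(a_n L)`, nucleotide diversity `pi`, Tajima's `D`,
the normalized Fay & Wu `H` (needs outgroup polarization; weights
high-frequency derived alleles), and the Ewens–Watterson haplotype
homozygosity `F = sum p_k^2`.

The **HEW** decision combines `H` (left tail) and `F` (right tail): each is
ranked against `10^5` (desk-scale: 2000) neutral no-recombination coalescent
simulations at the locus's own Watterson estimate, and neutrality is
rejected when *both* Monte-Carlo p-values fall below a jointly calibrated
threshold `t` — the largest value with
`Pr(p_H <= t and p_EW <= t) <= alpha` over a calibration sample of neutral
p-value pairs conditioned on the observed number of segregating sites.
Compound p-values are BH-corrected across loci within each stratum.

Around the scan: Weir–Cockerham F_ST (haploid variance components,
ratio of sums) with label-permutation significance; a multilocus HKA
moment fit of polymorphism vs outgroup divergence with simulation-based
significance; and for flagged loci an LD/haplogroup deep-dive — `r^2`
matrices, perfect-LD site sets, A/B haplogroup delineation with recombinant
flags, clade-conditioned coalescent diversity tests, neighbor-joining trees
(Jukes–Cantor distances) and sliding-window `K_JC` divergence profiles.

See `vignettes/hew-selection-scan.Rmd` for the model details, parameter
defaults and design decisions.

## Worked example

Simulate a two-stratum study of four loci with one partial sweep planted in
one stratum, then scan it:

```r
library(hewscan)

study <- study_config(
  strata = data.frame(stratum = c("M", "GOUNDRY_aa"), n = c(40, 40),
                      scenario = c("growth", "neutral_constant")),
  loci = data.frame(locus_id = sprintf("gene%02d", 1:4), length = 500,
                    theta = 10, region = "inside_2La", coding = TRUE),
  sweep = list(tau = 0.01, sweep_f = 0.8, standing_k = 2))
dir <- file.path(tempdir(), "demo_study")
simulate_multipop_study(study, dir, seed = 42,
  overrides = data.frame(locus_id = "gene03", stratum = "GOUNDRY_aa",
                         scenario = "partial_sweep"))

run <- run_scan(dir, seed = 7, reps = 2000, n_perm = 999)
run$scan[, c("locus", "stratum", "n", "S_silent", "D", "H_norm", "EW_F",
             "p_H", "p_EW", "hew_bh_p", "hew_significant")]
```

```
   locus    stratum  n S_silent      D  H_norm  EW_F    p_H  p_EW hew_bh_p hew_significant
1 gene01 GOUNDRY_aa 40       14 -1.166 -1.4957 0.302 0.0655 0.248    0.181           FALSE
2 gene01          M 40        4 -0.379  0.5579 0.427 0.7061 0.588    0.530           FALSE
3 gene02 GOUNDRY_aa 40       11 -0.606  0.3435 0.291 0.4913 0.409    0.380           FALSE
4 gene02          M 40        5 -1.404  0.4644 0.616 0.5927 0.219    0.473           FALSE
5 gene03 GOUNDRY_aa 40       10 -0.865 -3.2295 0.814 0.0105 0.009    0.008            TRUE
6 gene03          M 40        8 -1.437 -0.5397 0.445 0.1809 0.245    0.336           FALSE
7 gene04 GOUNDRY_aa 40       11 -0.659 -0.0554 0.223 0.3038 0.671    0.483           FALSE
8 gene04          M 40        7 -1.375  0.0115 0.386 0.3208 0.425    0.394           FALSE
```

The planted sweep (`gene03` in `GOUNDRY_aa`) is the only record that
survives BH correction: its `H_norm = -3.23` (excess of high-frequency
derived alleles) and `EW_F = 0.81` (excess homozygosity) are jointly
extreme, which is exactly the signature the compound test is built for.
The growth-history stratum shows negative `D` throughout but no rejections
— the compound test is insensitive to demography that moves only one
component.  `run$fst` carries the per-locus Weir–Cockerham F_ST between
the strata with permutation p-values, and
`run_haplogroup_analysis(dir, "gene03", "GOUNDRY_aa", ...)` produces the
LD matrix, haplogroup delineation, clade-conditioned diversity p-values,
the NJ tree in Newick and the sliding `K_JC` profile for that locus.

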
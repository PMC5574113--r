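---
title: "Differential mutation analysis: model, assumptions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential mutation analysis: model, assumptions, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffmut)
```

## The model

Frequency-based driver-gene detection must estimate a background mutation
rate per gene, because gene length, replication timing, expression and
chromatin state all inflate the count of neutral somatic mutations a gene
accumulates. Differential mutation analysis replaces that modelling with an
empirical background: the same gene-specific characteristics shape how much
*germline* variation a gene tolerates across a healthy population. A gene
that is unusually mutated in tumors *relative to its own natural
variability* is a driver candidate; a long, fast-mutating gene that is also
highly variable in healthy genomes is not.

The procedure is fully non-parametric:

1. **Counting.** For each tumor sample, count somatic point mutations per
   gene (from a MAF file), restricted to a consequence subset — non-silent
   (missense + nonsense) by default, missense-only to target oncogenes,
   nonsense-only to target tumor suppressors, silent as a negative control.
   For each healthy individual, sum per-gene variant scores from a
   multi-sample VCF: at each site every individual scores 0, 1 or 2
   non-major alleles (absent / heterozygous / homozygous relative to the
   cohort-major allele).
2. **Rank normalization.** Within each individual, each gene's score is
   the number of genes with a strictly smaller count, divided by the number
   of genes `G`. Scores lie in `[0, 1)`; ties share the minimum rank, so
   the typically large set of zero-count genes all score exactly 0. Because
   only the ordering matters, total mutation burden cancels out and
   hypermutated samples need no special treatment.
3. **uEMD.** Per gene, the tumor cohort's scores and the healthy cohort's
   scores are histogrammed into `nbins = 100` evenly spaced bins. With
   `M_b` and `N_b` the tumor and healthy bin fractions,

   `uEMD = sum over B of max(0, sum over b >= B of (M_b - N_b))`.

   This is the classic Earth Mover's Distance made unidirectional: walking
   from the top bin down, the running surplus of tumor mass over healthy
   mass is carried to the next bin and every positive carry is accumulated,
   so only mass that must move *downward* (tumor scores exceeding germline
   scores) is charged; the opposite direction is ignored. A gene whose
   tumor scores never exceed its germline scores gets exactly 0.
4. **Significance.** Each tumor individual's rank vector is permuted across
   genes and all-gene "decoy" uEMDs are recomputed against the unchanged
   healthy histograms. At a gene's score `u`, the false discovery rate is
   `#[decoys >= u] / #[real uEMDs >= u]`, capped at 1, averaged over
   `permutations = 5` repeats; the q-value is the minimum FDR over all
   genes scoring at most `u`, which makes q non-increasing in uEMD and the
   control conservative.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `subset` | `nonsilent` | consequence classes counted (units: mutation classes) |
| `nbins` | 100 | histogram resolution; uEMD is in units of mass x bins |
| `permutations` | 5 | decoy repeats averaged into the FDR |
| `q_threshold` | 0.1 | q-value below which a gene is flagged significant |
| `match_consequence` | `TRUE` | restrict the germline side to the somatic subset's classes |

The defaults for `nbins`, `permutations` and `q_threshold` are the
method's standard operating point; `nbins` is configurable mainly so that
small-bin configurations can be checked against brute-force oracles.

## Input-handling rules

* The cohort-**major allele** at a site is the allele with the highest
  total count over all called genotypes — the reference has no special
  status, since "variant" means "differs from the most common allele in
  the healthy cohort". Ties break to the lowest allele index
  (deterministic, and a 50/50 split resolves to the reference).
* Chromosome **Y** sites are excluded. On chromosome **X**, males are
  always scored homozygous (a hemizygous non-major call scores 2).
  Individuals of unknown sex are scored autosomally on X, with a warning.
* **Missing genotypes** score 0 (homozygous-major). This is conservative;
  fully imputed call sets have no missing genotypes anyway.
* At **multi-allelic sites** every non-major allele counts toward the
  score, and a site passes a consequence filter if *any* non-major allele's
  class is in the subset. When the major allele is an alternate allele, the
  reference allele itself is the "variant"; its consequence class is
  unknown, so such sites survive only when consequence matching is off.
* Whether the germline side should be restricted to the same consequence
  class as the somatic side in missense-only/nonsense-only runs is a
  genuinely open design point; this package defaults to matched subsets
  (`match_consequence = TRUE`) because the background should reflect the
  same functional class of variation being tested, and exposes the toggle
  because the opposite convention is defensible.
* MAF `Variant_Classification` values map to
  missense/nonsense/silent; everything else (splice sites, indels, UTRs)
  is `other` and contributes to no subset. Every distinct tumor barcode
  seen in the MAF stays in the cohort, even with zero retained mutations.

## Numerical choices

* Histogram bins are half-open `[(i-1)/nbins, i/nbins)` with the top bin
  closed; rank scores are `< 1` by construction, so the closure only makes
  the binning total on `[0, 1]`.
* The uEMD is computed with a single top-down cumulative pass per gene
  (`O(nbins)`), algebraically identical to the displayed sum; all-gene
  computation is one `tabulate()` over linearized (bin, gene) indices, so
  runtime is linear in the number of genes at fixed `nbins`.
* Per-repeat FDRs are capped at 1 *before* averaging (an FDR is a
  proportion), and q-monotonization is applied *after* averaging. Averaging
  per-repeat FDRs rather than pooling decoy counts across repeats is a
  deliberate choice between two equally conservative readings of
  "estimate the FDR by taking an average over these randomizations".
* Threshold counting uses exact tie handling (`findInterval` on sorted
  scores), so genes with equal uEMDs always receive equal FDRs and
  q-values. Result tables break uEMD ties alphabetically by gene symbol so
  output files are reproducible.
* One seed drives every random draw (decoy permutations in the fit; all
  draws in the generator); a rerun with the same seed is byte-identical.

## The synthetic cohort generator

`sim_config()` / `simulate_counts()` / `simulate_cohorts()` generate
paired cohorts embodying the method's structural premise: a shared
per-gene propensity `lambda_g ~ LogNormal(log 0.5, 1)` (the analogue of
length/covariate effects, identical in both cohorts), per-individual
exposures `~ LogNormal(0, 0.3)` (sequencing depth and burden variation),
a consequence mix of 60% missense / 10% nonsense / 30% silent, and
Poisson counts per (individual, gene, class). Planted drivers multiply
their somatic rate by `beta` in their boosted classes only. The default
study condition — 2000 genes, 25 drivers at `beta = 5`, 200 tumor and 500
healthy individuals — is desk-scale but leaves ranking non-trivial: the
propensity spread spans two orders of magnitude, so a weak driver on a
short gene must beat long genes with high background rates.

`simulate_cohorts()` realizes the healthy draws as biallelic VCF sites
whose summed 0/1/2 dosages reproduce the drawn counts exactly: each
individual's count is spread round-robin over enough sites that no
genotype needs more than two alternate alleles, which also keeps every
site's cohort alternate-allele count below half, so the reference remains
the major allele and parsing recovers the counts bit-exactly.

What the generator does **not** emulate: population structure and linkage
(dosages are independent across sites), allele-frequency spectra,
mutational signatures and trinucleotide context, indels and copy number,
sex-chromosome genes (all synthetic genes are autosomal; the X/Y scoring
rules are exercised by hand-built fixtures instead), and real curated
driver lists. Passing tests on synthetic data therefore demonstrate the
statistical machinery — rank normalization, uEMD ranking, decoy FDR
calibration, class-specific controls — not performance on real tumor
cohorts, where mutation processes are far less homogeneous than Poisson.

## Verification at a glance

The test suite checks the uEMD against two independent oracles (a literal
carry-down simulation on arbitrary random histograms, and an explicit
nearest-above downward-transport simulation on pairs constructed to be
top-down stochastically dominant, where the score provably equals both the
transport cost and the full 1-D Wasserstein distance); rank normalization
against a double-loop counting oracle; FDR conservativeness under the null
(no planted drivers: the mean fraction of genes at q < 0.1 stays at or
below 0.1 across 20 replicates); driver recovery (AUPRC >= 0.8 and >= 15
of the top 25 genes are planted drivers in >= 18 of 20 replicates);
silent-run and class-specificity controls mirroring the oncogene/TSG
split; exact file round trips; and linear scaling of the all-gene uEMD
computation over 1k-8k genes. The acceptance script
(`scripts/acceptance.R`) recomputes the headline quantities at the same
2000-gene scale with 3 replicates per condition; replicate counts in the
tests (20) and the script (3) are chosen to keep a full verification run
in the minutes range on a single core.

## Known limitations

* Power depends on cohort sizes and on `nbins`: with very small cohorts
  most histogram mass sits in few bins and the uEMD saturates.
* The decoy null permutes ranks within individuals only; it preserves each
  individual's score multiset but not gene-level correlation structure, so
  the FDR is conservative rather than exact.
* Sub-gene resolution (domains, hotspots) and pathway-level aggregation
  are out of scope; the statistic is strictly per-gene.
* Germline consequence classes must be supplied as annotations (INFO key
  or companion table); the package does not re-derive them from codons.
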
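---
title: "Methods: germline self-antigen load and its cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germline self-antigen load and its cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SelfAntigenLoad)
```

## The model

HLA class I molecules (loci A, B, C, typed here at two-field
resolution, e.g. `A*02:01`) present peptides of roughly 8–14 residues
to CD8 T cells. A germline missense variant substitutes one residue of
a self protein, so every presentable peptide overlapping that residue
is a potential altered self-antigen. The quantity this package
estimates is the per-patient **self-antigen load**: the number of
variant-derived peptides predicted to bind at least one of the
patient's own class I alleles with strong affinity. The load is then
treated as a patient-level biomarker: compared between onset groups
(Mann–Whitney), dichotomized at an ROC-derived cutoff, and entered into
a multivariable logistic model for early onset alongside gender,
education, ApoE ε4 and baseline CDR.

The pipeline is deliberately modular, because each stage corresponds to
an interchangeable methodological choice:

| stage | function | key assumptions |
|---|---|---|
| window | `extractWindows()` | 13 flanking residues per side; truncation (not padding) at protein termini |
| k-mers | `enumerateMutantKmers()` | lengths 8–14; k-mer must span the mutant site |
| binding | `predictBinding()` | per-patient alleles deduplicated; strong = rank ≤ 0.5 |
| load | `computeSelfAntigenLoad()` | unique peptide counting |
| statistics | `rocAndCutoff()`, `fitLogistic()`, ... | high load = load > cutoff |

### Window construction

For a variant at residue $p$ of a protein of length $L$ the window is
$[\max(1, p-13),\ \min(L, p+13)]$, carrying the alternative residue at
the mutant site — 27 residues when untruncated, with the mutant at
offset 14. Thirteen flanks suffice because the longest presentable
peptide considered is a 14-mer: every 8–14-mer containing the mutant
residue is a substring of this window. For that reason it is immaterial
whether one submits the whole 27-mer to a predictor that enumerates
k-mers internally or pre-enumerates the k-mers as this package does:
the peptide universe is identical under these defaults.

### Why k-mers must span the mutant site

A k-mer of the window that does not cover the mutant position is
sequence-identical to unmutated self and carries no variant
information; counting it would inflate the load with constants. The
enumeration therefore requires the span by default (77 k-mers per
untruncated window: $k$ start positions for each $k \le 13$, 14 for
$k = 14$). `require_span = FALSE` provides the all-substrings behaviour
for sensitivity analyses.

### Binding calls and thresholds

Real studies obtain affinities from a neural-network predictor; this
package parses such tables (`readNetmhcTable()`) and also ships a
**surrogate predictor** so every stage is runnable and testable
offline. The surrogate draws, per (allele, length), a 20×k
position-weight matrix from an RNG stream keyed by a deterministic hash
of the allele name, scores a peptide as the mean positional weight, and
converts the score to a percentile rank against a fixed reference
distribution of $10^5$ pseudo-random peptides drawn from a stream keyed
the same way. Consequences worth stating:

* identical inputs give bit-identical outputs in any session, on any
  platform, independent of call order and of the caller's RNG state;
* ranks of random peptides are uniform, so the fraction of random
  peptides at rank ≤ r% converges to r/100 — the calibration property
  real %rank scores have by construction;
* alleles are mutually independent scorers, which real alleles are not
  (binding motifs cluster into supertypes).

It is a reproducibility device with the statistical shape of a
predictor, **not** a trained binding model; no biological conclusion
about a specific peptide follows from its scores. The pseudo-affinity
is the fixed monotone map $\mathrm{nM} = 5\times10^4 (r/100)^{1.3}$,
anchored so the conventional strong-rank region sits near the
conventional 50 nM bound.

Classification uses percentile rank with **inclusive** boundaries:
strong if rank ≤ 0.5, else weak if rank ≤ 2.0, else non-binder
(`binderThresholds()`; an absolute ≤ 50 nM mode is available). The
source analysis does not state its numeric threshold, so these are the
field's conventional predictor defaults, and every threshold is a
parameter, not a constant. Boundary inclusivity changes counts
deterministically and is pinned by tests.

### Load aggregation

Per patient, alleles are deduplicated per locus first — a homozygous
allele is one presentation capability, not a double dose. The default
counting mode is the number of **distinct peptide sequences** strong
for at least one patient allele (`unique_peptide`), matching "number of
peptides" phrasing; `peptide_allele_pairs` counts strong
(peptide, allele) calls instead and is strictly larger whenever one
peptide binds several alleles. Loads are non-negative integers,
monotone both in the variant set and in the strong threshold.

## Cohort statistics

* **Fisher exact, 2×2** (`fisherExact2x2()`): two-sided p by the
  conventional rule (sum of hypergeometric probabilities of tables no
  more likely than the observed one, as in `stats::fisher.test`). The
  reported odds ratio is the **cross-product** $ad/bc$ — the crude OR
  that epidemiological tables print — because the conditional-MLE OR of
  `fisher.test` does not reproduce published crude ORs. Zero-margin
  tables return p = 1 with a degeneracy flag rather than an estimate.
* **Mann–Whitney** (`mannWhitney()`): exact for small tie-free samples,
  tie-corrected normal approximation with continuity correction
  otherwise; also reports $U/(n_1 n_2)$, the AUC equivalent with ties
  counted one half.
* **ROC** (`rocAndCutoff()`): thresholds at observed load values;
  dichotomization is **strict** (high means load > cutoff); the cutoff
  maximizes Youden's $J$ with ties broken toward the **lower**
  threshold (the more sensitive rule). AUC is trapezoidal over the ROC
  points, which equals the Mann–Whitney identity; the equality is
  asserted programmatically in the tests rather than assumed.
* **Logistic model** (`fitLogistic()`): maximum likelihood via
  `glm(binomial)`; odds ratios with **Wald** 95% intervals (the very
  wide intervals typical of ~50-patient studies are expected Wald
  behaviour). Baseline CDR enters as the binary "0.5 or 1" indicator,
  the way small dementia cohorts tabulate it, not as an ordinal scale.
  Non-convergence and separation (|coef| > 15 or all fitted
  probabilities at 0/1) are flagged, never returned silently; with 22
  vs 32 patients and several covariates, separation is a real
  occurrence, and a flagged fit should be reported as such.
* **Power** (`powerBySimulation()`): given $n_1, n_2$, $\alpha$, a
  baseline proportion $p_2$ and an odds ratio, the treated proportion
  is $p_1 = \mathrm{OR}\,\mathrm{odds}_2/(1+\mathrm{OR}\,\mathrm{odds}_2)$;
  replicates draw binomial counts per group and the power is the
  fraction with two-sided Fisher p ≤ α. P-values are precomputed on the
  $(n_1+1)\times(n_2+1)$ outcome grid, so a replicate is a table
  lookup and $10^4$ replicates take seconds. The Monte-Carlo standard
  error is reported. How the published "0.78" was obtained is not
  stated in the source; this simulation is a principled stand-in, and
  at the published design it lands close to, but a few points below,
  that figure — exact-test power calculations differ across software
  precisely because the test is discrete.
* **HLA frequency tables** (`tabulateAlleleCounts()`): chromosome
  (dosage) counting, total $2n$ per locus. The per-allele cohort
  comparison is a 2×2 Fisher of allele vs all-other chromosomes; the
  single per-locus p-value style of published tables is interpreted as
  one **overall chi-square** on the allele × cohort count matrix,
  pooling alleles with overall expected count < 1 into "other" — the
  published analysis does not state its exact overall test, so this
  package's version should not be read as a reproduction of any printed
  per-locus p. The early/late single-allele contrast
  (`carrierContrast()`) counts **patients carrying ≥ 1 copy**, which is
  the only counting consistent with published carrier percentages such
  as 7/22 = 31.8%.

## The synthetic generator

`simulateCohort()` emulates the structure the analysis assumes, not any
particular patient population:

* 22 early / 32 late patients (defaults);
* covariates from the published group summaries: male 36.4% / 28.1%;
  education normal with mean (SD) 8.88 (3.83) / 6.38 (4.95) years,
  truncated at 0; ApoE ε4 31.8% / 50.0%; mild baseline CDR (0.5 or 1)
  68.2% / 96.9%, with the CDR value drawn uniformly within the mild or
  severe pair;
* HLA genotypes: per locus, two independent draws from the packaged
  general-population frequency table (Hardy–Weinberg, no linkage
  between loci). The packaged table omits unpublished rare alleles, so
  frequencies are renormalized over the listed alleles — this shifts
  each frequency up by a few percent of its value (e.g. A\*11:01 from
  25.2% to ~26.1%), which the tests account for explicitly;
* variant burden: per-patient counts Poisson with group means 42
  (early) and 30 (late). The source reports no per-patient variant
  counts, so the absolute scale is a package choice made once: the 1.4
  ratio matches the ratio of the published group mean loads, and the
  scale keeps a full default run under a minute on one core. The group
  difference is injected **only** through this burden, so the load
  difference downstream is a derived quantity and every replicate
  exercises window extraction, enumeration, binding and counting — not
  a shortcut that draws loads directly.

Everything is a pure function of the config seed; each component uses a
sub-stream at a fixed offset from it, so adding a component never
perturbs earlier draws, and written cohorts are byte-identical across
reruns.

What the generator does **not** emulate: real proteome composition and
length distribution (sequences are i.i.d. uniform residues), genotyping
error, linkage disequilibrium and population structure, allele-specific
binding motifs, and the absolute load scale of exome-wide data (tens of
thousands of variants). Passing tests therefore demonstrate the
pipeline's correctness and calibration under its stated model, not
biological validity on real cohorts.

## Numerical and design choices

* **Coordinates** are 1-based inclusive residue positions throughout.
* **Degenerate inputs**: empty FASTA/variant tables propagate as empty
  collections and zero loads; zero-margin 2×2 tables are flagged, ROC
  requires both classes, and a fully tied Mann–Whitney returns
  AUC 0.5, p 1.
* **Calibration checks** dichotomize at the pooled **median** load, not
  at the ROC-optimal cutoff: selecting the Youden cutoff on the same
  data that is then tested inflates the type I error by construction,
  so a cutoff chosen that way must be treated as descriptive, not
  inferential. This caveat applies equally to any single-cohort use of
  the ROC-derived dichotomy in the logistic model.
* **Exact-test conservativeness**: with 22 + 32 discrete outcomes the
  two-sided Fisher test cannot attain its nominal size; empirical
  rejection rates under the null sit below α. The calibration test
  asserts the rate does not exceed the binomial band above α, the
  property that is actually guaranteed.
* **Test problem sizes**: the property suites run on reduced
  configurations chosen as the smallest that make the checked property
  statistically decidable — e.g. 9-mer-only binding with a six-allele
  table for replicate-heavy calibration (500 replicates), $10^4$
  peptides for rank calibration, 200 replicates at n = 540 for
  logistic parameter recovery, and ≥ $10^4$ replicates for power.

## Known limitations

The surrogate predictor shares no information between alleles and no
motif biology; proteasomal cleavage, TAP transport and immunogenicity
beyond binding are out of scope, as are frameshift/stop-gain peptides
(missense only), class II presentation, haplotype inference and HWE
testing. Two-field allele resolution is fixed; deeper typing is
truncated on input. Multiple-testing correction across allele tables is
deliberately not applied, matching the descriptive use of those tables;
any confirmatory use should add it.
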
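# SelfAntigenLoad

Germline missense variants change single residues of self proteins. When
the altered peptide is presented by a patient's own HLA class I
molecules with high affinity, it is a candidate *self-antigen*; the
count of such strongly presented variant peptides — the **self-antigen
load** (units: peptide number) — has been proposed as a germline
immunogenetic correlate of disease phenotypes such as early- versus
late-onset Alzheimer's disease. This package implements that analysis
end to end, for statisticians and immunogeneticists who want the method
as a tested, reusable R pipeline rather than a one-off script:

1. **Peptide windows** — for a variant at residue *p* of a protein of
   length *L*, extract the window `[max(1, p−13), min(L, p+13)]` (27
   residues when untruncated) carrying the alternative residue at the
   mutant site.
2. **Epitope candidates** — enumerate all 8–14-mers of the window that
   span the mutant residue (77 per untruncated window).
3. **Binding calls** — score every unique peptide against each of the
   patient's distinct HLA-A/B/C alleles, via a deterministic built-in
   surrogate predictor or a parsed NetMHC-style table; a call is
   *strong* when its percentile rank ≤ 0.5 (configurable; absolute
   ≤ 50 nM mode available).
4. **Load** — per patient, the number of distinct strong-binding
   peptides (pair counting available).
5. **Cohort statistics** — HLA allele-frequency tables and case–control
   comparisons (Fisher per allele, overall chi-square, patient-level
   carrier contrasts); Fisher exact / Mann–Whitney group tests;
   ROC/Youden dichotomization of the load (high = load > cutoff,
   J = sensitivity + specificity − 1); adjusted odds ratios from binary
   logistic regression with Wald 95% CIs; and simulation-based power
   for the two-group Fisher design, where the treated proportion is
   implied by the odds ratio: p₁ = OR·odds₂ / (1 + OR·odds₂).

A synthetic-cohort generator (`simulateCohort()`) reproduces the
statistical structure of a two-group study — group-dependent Poisson
variant burden, Hardy–Weinberg HLA genotypes from a packaged
general-population frequency table, and study-like covariates — so the
whole pipeline runs and is tested without any patient data.

## Worked example

The canonical single-variant example — `R331W` at residue 331 of a
protein longer than 344 residues — yields the 27-residue window
spanning positions 318–344 with the mutant residue at its center:

```r
library(SelfAntigenLoad)
prot <- setNames(paste(c(rep("A", 330), "R", rep("G", 69)), collapse = ""), "YAP1")
extractWindow(list(protein_id = "YAP1", position = 331L,
                   ref_aa = "R", alt_aa = "W"), prot)
#>   start end mutant_offset                     peptide
#> 1   318 344            14 AAAAAAAAAAAAAWGGGGGGGGGGGGG
```

A full synthetic run (22 early / 32 late patients, defaults):

```r
report <- runPipeline(pipelineConfig(seed = 7), "antigen_run")
print(report$table1)
#>                                 early          late p_value
#> n                                  22            32
#> Gender (male)              10 (45.5%)     7 (21.9%)   0.081
#> Education (years)         7.71 ± 4.18   6.01 ± 3.86   0.221
#> Self-antigen load       89.00 ± 18.26 62.53 ± 12.70   0.000
#> High self-antigen load     19 (86.4%)      3 (9.4%)   0.000
#> ApoE (e4+)                  5 (22.7%)    17 (53.1%)   0.047
#> Baseline CDR (0.5 or 1)    15 (68.2%)    28 (87.5%)   0.100
```

The early group carries the higher simulated variant burden, so its
load is higher; the ROC-chosen cutoff dichotomizes the load (here
load > 79, AUC 0.897) and the logistic model reports the adjusted odds
ratio of high load for early onset alongside gender, education, ApoE
ε4 and baseline CDR. Every intermediate (inputs, peptide table, call
table, per-patient loads, ROC points, summary tables) is written under
the output directory together with `manifest.json` recording the
configuration, seed and record counts; the same config reproduces
byte-identical outputs.

Design power for a two-group Fisher comparison at the published design
parameters:

```r
powerBySimulation(22, 32, alpha = 0.02, baseline_proportion = 20/32,
                  odds_ratio = 12.6, replicates = 10000, seed = 1)
#> Simulated power = 0.742 (MC SE 0.0044)
#>   n1 = 22, n2 = 32, alpha = 0.02, OR = 12.6, p2 = 0.625 -> p1 = 0.955
```

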
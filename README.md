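# neotrack

Discovery and validation of neo-epitope-specific CD8+ T cells in tumors
with low mutational load — as a tested, reusable R pipeline.

Tumors such as epithelial ovarian cancer carry relatively few somatic
mutations, yet some of those mutations yield *neo-epitopes*: short mutant
peptides presented on HLA class I and recognized by CD8+ T cells. `neotrack`
implements the computational chain around that biology:

1. **Peptide enumeration** — for a missense mutation at protein position
   *p*, every 9-mer and 10-mer window containing the altered residue
   (an interior mutation yields exactly 19 candidates);
2. **Binding filter** — retain (peptide, allele) pairs with predicted
   IC50 ≤ 500 nM on the patient's own HLA-I alleles (inclusive bound),
   and report per-patient predicted neo-epitope loads;
3. **Immune-response calling** — ELISpot positivity when mean spots exceed
   the "No Ag" mean + 3 × SD; ICS polyfunctionality over the seven
   combinations of {IFNγ, TNFα, IL-2} with background subtraction;
4. **Functional avidity** — four-parameter log-logistic EC50
   (*y = A + (D−A)/(1+10^{h(log₁₀EC50 − log₁₀x)})*) with grid-initialized
   Levenberg–Marquardt fitting and seeded bootstrap intervals; specific
   lysis as 100 × (experimental − spontaneous)/(total − spontaneous);
5. **TCR repertoires** — translate amplicon reads (frame 1), drop
   out-of-frame reads, pool reads coding for the same receptor protein,
   remove single-read clonotypes, then track specific clonotypes across
   blood / tumor / TIL compartments against a 0.001% limit of detection,
   with V–J usage matrices in chromosomal order;
6. **Cohort statistics** — per-compartment response prevalence over the
   evaluation roster, the blood/TIL discordance landscape, Fisher's exact
   test (point-probability convention), and the mutational-load vs
   neo-epitope-load regression with a permutation p-value.

A fully seeded synthetic-cohort generator (`simulate_cohort()`,
`simulate_assays()`, `simulate_repertoires()`) emulates the statistical
structure of a 19-patient cohort — 10–129 mutations per patient, a minority
of peptides passing 500 nM, planted ELISpot responders, known EC50s, and
clonotypes spiked across compartments around the detection limit — so the
entire pipeline runs and is testable with no external data.

## Worked example

```r
library(neotrack)
library(dplyr)

cfg    <- cohort_config(seed = 42)
cohort <- simulate_cohort(cfg)

cand <- enumerate_mutant_peptides(cohort$mutations, cohort$proteome,
                                  cfg$peptide_lengths)
hits <- apply_affinity_filter(cand, cohort$affinities,
                              cohort$patient_alleles,
                              cfg$affinity_threshold_nm)
load_summary(predicted_load(hits, unique(cohort$mutations$patient_id)))
#> # A tibble: 1 × 6
#>   n_patients total_peptides total_peptide_allele_pairs min_per_patient
#>        <int>          <int>                      <int>           <int>
#> 1         19           1409                       1499              14
#>   max_per_patient median_per_patient
#>             <int>              <int>
#> 1             182                 58
```

Nineteen synthetic patients yielded 1,409 unique mutant peptides predicted
to bind at ≤ 500 nM (1,499 peptide–allele pairs) — both counts are
reported because a "predicted neo-epitope" can be read either way.

```r
assays <- simulate_assays(cohort)
calls  <- call_elispot(assays$elispot, multiplier = cfg$elispot_sd_multiplier)
resp   <- build_responses(calls, assays$validations)
summarize_prevalence(resp, cohort$roster)
#> # A tibble: 3 × 4
#>   compartment      n_evaluated n_responders fraction
#>   <chr>                  <int>        <int>    <dbl>
#> 1 pbl                       19            6    0.316
#> 2 til_conventional          14            4    0.286
#> 3 til_primed                14            0    0
```

Six of 19 patients respond in blood and 4 of 14 in TILs — the planted
prevalence, recovered by the mean + 3 SD ELISpot rule plus orthogonal
validation. Each fitted EC50 comes back as an object with `tidy()`,
`glance()` and `autoplot()` methods:

```r
f <- fit_ec50(assays$dose_response |> filter(series_id == "DR04"),
              n_bootstrap = 1000, seed = 1)
f
#> 4PL dose-response fit
#>   EC50: 0.05338 ug/mL  (95% CI 0.02981-0.09536, 1000 bootstrap)
#>   hill slope 1.16, asymptotes 0.368 / 96.3, converged: TRUE
```

This clone's planted EC50 was 0.0676 µg/mL; the fitted 0.053 µg/mL sits
inside the seeded bootstrap interval, the expected accuracy for a
single-well nine-dose series at 10% noise.

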
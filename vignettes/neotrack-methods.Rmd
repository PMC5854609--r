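---
title: "Methods: neo-epitope discovery and TCR clonotype tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neo-epitope discovery and TCR clonotype tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`neotrack` implements the computational chain used to discover and validate
neo-epitope-specific CD8+ T cells in tumors with relatively low mutational
load, such as epithelial ovarian cancer: candidate mutant peptides are
enumerated around somatic missense mutations, filtered on predicted HLA
class I binding, tested functionally (ELISpot positivity, intracellular
cytokine polyfunctionality, EC50 functional avidity, chromium-release
lysis), and the responding T-cell receptors are traced across blood, tumor
and TIL-culture compartments as clonotypes. This vignette explains each
model, its assumptions, the tunable parameters, and the design choices made
where the procedure was genuinely open.

```{r setup, message = FALSE}
library(neotrack)
library(dplyr)
```

## Candidate peptide enumeration

A missense mutation at protein position $p$ is covered, for peptide length
$L$, by every window $[s, s+L-1]$ with
$\max(1, p-L+1) \le s \le \min(p, N-L+1)$, where $N$ is the protein
length. `enumerate_mutant_peptides()` emits all such windows with the
altered residue substituted, for lengths 9 and 10 by default, so an
interior mutation yields exactly $9 + 10 = 19$ candidates and the count
shrinks near the termini to
$\min(p,\, L,\, N-p+1,\, N-L+1)$ per length.

Two choices deserve a note:

* **Truncated windows are dropped, not padded.** Fixed-length binding
  predictors define affinities for complete 9/10-mers only; a padded
  peptide has no biological meaning, so partial windows at protein ends
  are omitted.
* **Windows containing `X` are excluded** (such peptides cannot be
  synthesized) and counted in the `rejections()` tally rather than
  silently dropped. The same no-silent-drop rule applies to every parser
  in the package.

Mutations enter at protein level; isoform selection is the caller's
responsibility, since one protein sequence per mutation is required.

## Binding-affinity filter

Predicted IC50 values (nM) per (peptide, allele) are inputs — the package
deliberately does not implement a binding predictor. `apply_affinity_filter()`
keeps pairs with IC50 $\le$ 500 nM restricted to the patient's own HLA-I
alleles; the bound is inclusive, and `predicted_load()` reports both unique
peptide counts and (peptide, allele) pair counts per patient, since a
"predicted neo-epitope" can be read either way. Raising the threshold can
only add retained pairs (monotonicity), which is property-tested.

For self-contained testing, `toy_affinity()` provides a deterministic
position-specific scoring scheme keyed on the allele name: $\log_{10}$ IC50
$= 4.4 + 0.25 z$ with $z$ a sum of fixed per-position residue weights. The
constants place roughly 1% of random 9/10-mers at or below 500 nM per
allele — about 3–8% of candidate peptides pass on at least one of six
patient alleles, echoing the published ratio of predicted neo-epitopes to
candidate windows. It is an arbitrary, non-biological stand-in for a real
predictor's output table.

## ELISpot response calling

A condition is positive when its mean spot count strictly exceeds the
negative-control ("No Ag") mean plus 3 times the negative-control standard
deviation. Decisions in the package:

* **Sample (n−1) standard deviation.** The source procedure does not say
  which estimator was used; with triplicates the sample SD is larger,
  hence the conservative choice.
* **Zero-variance negatives** degenerate the rule to a strict
  `mean > neg_mean` comparison; a plate of all-zero negatives therefore
  calls an all-zero condition negative.
* **Raw counts**, not background-subtracted ones, feed the rule.
* PHA wells are a viability control: reported, never called. Conditions
  with fewer than two replicates are called but flagged.

## ICS polyfunctionality

Events are classified over the seven non-empty subsets of
{IFN&gamma;, TNF&alpha;, IL-2}. The unstimulated fraction of each subset is
subtracted from the stimulated fraction, negative differences are floored
at zero, and the excess is renormalized to sum to one. The
floor-then-renormalize choice is documented prominently because the source
analysis reports "No Ag" wells without stating its subtraction; if nothing
survives subtraction the summary is flagged empty rather than returning
0/0.

## Functional avidity (EC50)

`fit_ec50()` fits a four-parameter log-logistic curve
$y = A + (D - A) / (1 + 10^{\,h(\log_{10}\mathrm{EC50} - \log_{10} x)})$
by least squares: a coarse grid over $\log_{10}$ EC50 (30 points spanning
the dose range ±1 log) and Hill slope ($h \in \{0.25, 0.5, 1, 2, 4\}$),
with the asymptotes profiled out linearly at each grid point, followed by
Levenberg–Marquardt refinement on the residual function
(`minpack.lm::nls.lm`; the formula interface's numeric derivatives proved
fragile on noise-free data, so the residual function is used directly).
Numerical behavior worth knowing:

* Noise-free data invert to the planted EC50 to ~1e-8 relative error, and
  the estimate is scale-equivariant in concentration.
* Responses are normalized by the *fitted* upper asymptote, not the
  maximum observation, so a single high outlier does not redefine "half
  maximal".
* A series whose dose-effect range is below 20% of its maximum response
  (`min_response_fraction`) is flagged unreliable and not fitted — a flat
  series has no EC50.
* Confidence intervals are percentile bootstrap over residual resampling,
  1,000 resamples by default, always seeded. An EC50 outside the spanned
  dose range is flagged extrapolated.
* Concentration units are opaque tags (µg/mL in the synthetic assays); no
  mass↔molar conversion is attempted because peptide masses are not
  carried.

`compare_avidity()` contrasts $\log_{10}$ EC50 between two groups with a
two-tailed t-test, falling back to the Mann–Whitney test when a
Shapiro–Wilk pre-check rejects normality in either group, and reports the
per-group medians and their ratio (lower EC50 = higher avidity).

## Specific lysis

`specific_lysis()` is the chromium-release formula
$100 \times (\mathrm{experimental} - \mathrm{spontaneous}) /
(\mathrm{total} - \mathrm{spontaneous})$, an error when the denominator is
not positive, with out-of-range values kept but flagged (counting noise can
push the ratio outside [0, 100]).

## TCR clonotype repertoires

Repertoire construction follows three steps: translate each amplicon read
in frame 1 (amplicons are primer-anchored; a `frame_rescue` flag tries all
three forward frames for unanchored input), discard out-of-frame reads
(length not a multiple of 3, or a stop codon in the translation), pool
reads coding for the same protein sequence, then remove clonotypes with
fewer than 2 pooled reads — the singleton rule, applied *after* pooling,
the stricter reading. Clonotype identity is (chain, protein sequence); V/J
segment names are annotations taken from the most abundant read, not part
of identity. Read accounting is exact and tested: input reads always equal
retained + out-of-frame + invalid-character + singleton-discarded reads.

`track_clonotypes()` reports, for each specific (e.g. multimer-sorted)
clonotype and each bulk compartment, presence, frequency over retained
reads, and rank (position after ordering by descending count with
lexicographic tie-break — the deterministic resolution of a rank with
ties). Absences are read against the limit of detection: the assay's
validated LOD is 10 cells per million (0.001%), and when a compartment's
retained depth cannot resolve `lod_fraction` (1/depth > LOD) the absence
is flagged `below_lod` rather than treated as evidence of true absence.
Published frequencies could be over all reads or retained reads; retained
reads were chosen as the denominator.

## The synthetic cohort generator

`simulate_cohort()`, `simulate_assays()` and `simulate_repertoires()`
generate a fully self-contained cohort with the statistical structure the
analysis assumes, so that every planted quantity is recoverable by the
corresponding pipeline stage. The defaults encode the study conditions:

* 19 patients; per-patient missense mutation counts integer-uniform over
  10–129 (the published median and range constrain but do not identify the
  distribution; a discretized lognormal with median 69 is available as
  `mutation_distribution = "lognormal"`).
* 6 HLA-I alleles per patient from a 12-allele pool; toy-model affinities
  as above; rosters of 19 patients for blood and 14 for TIL work.
* ELISpot: triplicate wells, negative-binomial background (mean 8,
  size 4 — overdispersed, as real spot counts are; Poisson would be too
  well-behaved), planted responders shifted by +150 spots with size 25.
  Validated responses in this assay class sit far above background, so the
  planted effect makes responder recall essentially deterministic: the
  end-to-end check asks the called responder set to *equal* the planted
  one. Six blood responders and four TIL responders are planted with one
  epitope shared between compartments and the rest exclusive, reproducing
  the discordance structure.
* Dose-response: 9 ten-fold dilutions from 30 µg/mL down to 0.3 pg/mL,
  4PL with Hill slope 1, upper asymptote 100; true EC50s log-uniform with
  TIL clones planted one decade more avid than blood clones; 10%
  multiplicative noise.
* Repertoires: 1e5 reads per bulk compartment (a desk-scale stand-in for
  the published 1e6–3e6; LOD comparisons scale `lod_fraction` to 2/depth
  accordingly), ~600 background clonotypes with Zipf(1) frequencies,
  specific clonotypes spiked at planted frequencies spanning 1e-6–1e-2
  with deliberate compartment absences (a tumor+TIL clone absent from
  blood; a blood+tumor clone absent from TIL cultures), synonymous
  nucleotide variants injected to exercise protein-level pooling, 5%
  out-of-frame reads, a handful of invalid-character and singleton reads.
  A spike whose expected read count is below 1 raises a classed warning —
  it may legitimately vanish from the sample.

Everything is deterministic under the configured seed. What the generator
does *not* emulate: real HLA-binding biology, V(D)J recombination
statistics, PCR/sequencing error profiles, or shared clonotypes between
patients. Passing tests therefore demonstrate that the pipeline's logic is
correct and its statistical tolerances are honest — not that the toy
affinity model or the planted effect sizes resemble any particular
patient.

## Cohort aggregation and statistics

A *validated response* requires ELISpot positivity plus at least one
orthogonal assay (multimer staining or ICS), mirroring the two-step
validation; `require_orthogonal = FALSE` relaxes this for exploratory
runs. Prevalence denominators come from the evaluation roster, never from
the response list (blood and tumor rosters differ). The discordance
landscape classifies each response as both / blood-only / TIL-only / none,
in a conventional-TIL and a peptide-primed-TIL variant.

`fisher_exact()` uses the two-sided point-probability convention: the
hypergeometric probabilities of all fixed-margin tables no more probable
than the observed one are summed, with the standard $1 + 10^{-7}$ relative
tolerance on probability ties; software conventions differ here, which is
why the convention is stated. The conditional-MLE odds ratio is reported,
and tables with an empty margin return p = 1 with an undefined odds ratio.
`load_association()` regresses predicted neo-epitope load on mutational
load (OLS, two-sided t-test on the slope) and reports a seeded permutation
p-value alongside, whose floor is $1/(n_\mathrm{perm}+1)$.

## Problem sizes and runtimes

The shipped tests and the acceptance script run the full 19-patient cohort
(~1,300 mutations, ~20,000 candidate windows, ~460,000 toy affinity rows),
1,000 random enumeration instances against a brute-force oracle, 10,000
null ELISpot plates against a Monte-Carlo oracle, 200 noisy dose-response
series against a grid-search oracle, repertoires of 1e5 reads per
compartment, and exhaustive Fisher enumeration over all 2×2 tables with
total ≤ 40 — sizes chosen so the whole suite completes in minutes on a
single CPU while still exercising every statistical claim.

## Known limitations

* No proteasomal processing, TAP transport, or class II (CD4+) epitope
  prediction; the scope is CD8+/HLA-I.
* No raw FASTQ/BAM/VCF handling: mutations enter as a protein-level
  table, repertoires as amplicon read tables; no UMI handling or germline
  V/J alignment.
* The out-of-frame definition (length and stop codons in frame 1) is the
  simplest consistent reading; constant-region-relative stop positions are
  not modeled.
* Concentration unit systems are not interconverted; avidity comparisons
  are valid within a unit system only.
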
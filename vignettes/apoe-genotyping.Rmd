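---
title: "Delta-Ct genotyping of APOE: model, calibration and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delta-Ct genotyping of APOE: model, calibration and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apoetyper)
library(dplyr)
```

## The assay and its model

The three common *APOE* alleles are haplotypes of two coding SNPs:
rs429358 (T → Cys112, C → Arg112) and rs7412 (C → Arg158, T → Cys158),
giving ε2 = (T, T), ε3 = (T, C) and ε4 = (C, C). The assay this package
implements genotypes a sample by running it in three parallel
allele-specific TaqMan reactions. Allele discrimination is purely
positional: each reaction's forward primer ends on rs429358 and its
reverse primer ends on rs7412, and a 3′-terminal mismatch blocks
polymerase extension, so only the matching allele template amplifies. A
single FAM probe reports the *APOE* amplicon in all three reactions; a
HEX probe reports a co-amplified *ACTB* internal control that certifies
amplifiable DNA in the well.

The decision statistic per reaction is

$$\Delta C_t \;=\; C_t(\mathrm{FAM}) - C_t(\mathrm{HEX}),$$

with an undetermined FAM reading (no amplification curve within the
run's 40 cycles) counted as $C_t = 40$ before subtracting. Subtracting
the internal control makes the statistic robust to input-DNA amount:
an allele-positive reaction tracks the control closely (small
$\Delta C_t$), an allele-negative one does not amplify at all (so
$\Delta C_t \approx 40 - C_t(\mathrm{HEX})$) or only very late.

Calling is a fixed-threshold rule: a sample is negative for an allele
when the reaction's $\Delta C_t$ is *higher than* the per-reaction
cut-off. The shipped defaults are the assay's published ROC-calibrated
cut-offs, 9.2 / 10.4 / 11.1 cycles for the ε2 / ε3 / ε4 reaction
(`apoe_cutoffs()`). The three binary calls combine combinatorially: one
positive reaction is a homozygote, two are the corresponding
heterozygote (alleles ordered ε2 < ε3 < ε4), and zero or three positives
yield `NO_CALL` — such patterns cannot arise from a valid two-allele
genotype and in practice indicate QC problems, so the tool reports
rather than errors.

### Tie at the cut-off

The negativity rule is strict ("higher than the cut-off"), so
$\Delta C_t$ exactly equal to the cut-off is called **positive**. With
continuous measurements the case is measure-zero; the choice matters
only for re-analysis of rounded exports. It is configurable
(`qc_policy(tie_positive = FALSE)`).

### QC gates

Every flag forces `NO_CALL`; bounds live in `qc_policy()`:

| flag | condition | default bound |
|---|---|---|
| `HEX_FAIL` | internal control undetermined or too late in any reaction | HEX ceiling 35 cycles |
| `NTC_CONTAMINATION` | determined FAM in a no-template control, plate-wide | NTC floor 38 cycles |
| `POSCTRL_FAIL` | an allele's plasmid control not positive in its own reaction, plate-wide | — |
| `MISSING_REACTION` | fewer than three paired reactions for the sample | — |

The numeric bounds are package defaults chosen as ordinary qPCR
practice (a 35-cycle ceiling keeps the control well inside the 40-cycle
run; 38 cycles in an NTC is treated as innocuous primer-dimer
territory); the assay's published protocol specifies the controls but no
numeric bounds. Both are configurable and deliberately conservative.

## Sequencing truth and the ε1 corner case

Truth genotypes come from unphased diploid base calls at the two SNPs
(`translate_snp_pair()`). Seven of the nine site-genotype combinations
map uniquely onto the three-allele system. The double heterozygote
(C/T at both sites) is consistent with {ε2, ε4} and with the rare
{ε1, ε3} phase; it is returned as `E2/E4` with `ambiguous = TRUE`,
following population frequency (ε1 is vanishingly rare) and the assay's
design space (no ε1 primer pair exists). Combinations that *force* an
ε1 = (C, T) haplotype return `NO_CALL` rather than a guess.

## Cut-off calibration

`calibrate_cutoffs()` re-implements the calibration procedure: for each
reaction, label every training sample's $\Delta C_t$ by whether the
allele appears in its sequencing-derived genotype, build the ROC curve
with low scores as positive (sensitivity $= P(\Delta C_t \le t \mid
\text{present})$, specificity $= P(\Delta C_t > t \mid \text{absent})$),
and select the threshold maximising Youden's
$J = \text{sens} + \text{spec} - 1$.

Design choices, made where the published procedure is underspecified:

* **Candidate thresholds** are midpoints between consecutive distinct
  observed values, plus sentinels one cycle below the minimum and above
  the maximum. This is reproducible and independent of instrument
  reporting precision.
* **Criterion**: Youden's J, the standard ROC operating-point optimum;
  a fixed-specificity alternative is exposed
  (`criterion = "min_specificity"`).
* **Ties** in J break toward the larger threshold, favouring
  sensitivity for allele detection.
* **AUC** is computed as the Mann–Whitney statistic with half-credit
  for ties (verified in the tests against explicit pair counting and
  against an independent ROC implementation).
* The published cut-offs (9.2/10.4/11.1) are shipped as constants and
  are *not* regenerated: the 114 training $\Delta C_t$ values behind
  them are unpublished, and a midpoint convention would reproduce their
  one-decimal values only by coincidence. Their validity is instead
  demonstrated behaviourally: on synthetic cohorts they sit inside the
  class-separation gap and yield 100% concordance.

Undetermined FAM readings use the same $C_t = 40$ substitution during
calibration, so the negative class clusters near $40 - C_t(\mathrm{HEX})$.

## Cohort statistics

`summarize_cohort()` counts genotypes (a homozygote contributes two
copies of its allele, a heterozygote one of each) and reports allele
frequencies as $100 \cdot \text{copies}/(2n)$. Printed frequencies use
**largest-remainder rounding to two decimals**, so the three values sum
to exactly 100.00 — the convention under which published cohort tables
of this assay are internally consistent; per-value half-up rounding can
differ by 0.01 in the last allele. `NO_CALL` samples are excluded from
denominators and reported separately, keeping call-rate and accuracy
distinct.

`hwe_test()` checks Hardy–Weinberg equilibrium as genotyping QC. For
cohorts of up to 200 samples it enumerates every six-genotype table
with the observed allele counts and sums the Levene conditional
probabilities of tables no more probable than the observed one (an
exact three-allele test; no installed package provides one). Larger
cohorts use a chi-square test against the HWE expectations with 3
degrees of freedom. Monomorphic cohorts return $p = 1$ with a note. The
exact path is validated in the tests against two independent oracles: a
structurally different enumeration over homozygote counts with exact
factorial arithmetic, and — at tiny $n$ — full enumeration of labelled
allele matchings.

`concordance()` is an exact-match comparison against sequencing truth;
`NO_CALL` on either side counts as discordant, which makes the reported
percentage conservative.

## In-silico specificity

`specificity_matrix()` checks the assay's combinatorial logic
computationally. The binding model (`binding_rules()`) is deliberately
minimal: a primer binds where a full-length ungapped alignment has zero
mismatches in its 3 terminal 3′ bases (the extension clamp) and at most
one elsewhere; amplification needs convergent forward/reverse sites
within 1000 bases; the probe (which is hydrolysed, not extended, and so
has no clamp) must match strictly between the primer 3′ ends. No
melting-temperature or nearest-neighbour thermodynamics is attempted,
and degenerate bases are rejected — the published oligo set contains
none.

The bundled templates (`apoe_templates()`,
`inst/extdata/apoe_templates_synthetic.fasta`) are **synthetic**: the
real 197-bp plasmid inserts are unpublished, so the templates embed the
published primer and probe sites with the correct allele bases at the
two SNP positions, separated by fixed neutral padding. They reproduce
the allele logic exactly — the specificity matrix is the identity — but
carry no genomic context, so secondary-structure or off-target effects
are out of reach of this module by construction.

## The synthetic cohort generator

`simulate_cohort()` emulates the Ct-level statistical structure the
assay assumes, with genotypes drawn from the published 1158-sample
cohort proportions by default and truth tables consistent with the
generating genotype by construction. Per reaction
(`noise_model()` defaults):

| parameter | default | meaning |
|---|---|---|
| `hex_mu`, `hex_sd` | 24.0, 0.3 cycles | *ACTB* internal-control Ct |
| `pos_offset_mu`, `pos_offset_sd` | 2.0, 0.5 cycles | FAM − HEX for allele-positive reactions |
| `neg_dropout_prob` | 0.95 | negative reaction shows no FAM curve |
| `late_mu`, `late_sd` | 38.5, 0.5 cycles | late non-specific FAM Ct, truncated to (HEX, 40] |
| `max_cycles` | 40 | run length / undetermined substitution |

All values are invented — the assay's Ct distributions are not
published — and fixed once. They encode the regime the published
cut-offs presuppose: positive $\Delta C_t \approx 2 \pm 0.5$, negative
$\Delta C_t \approx 16$ (dropout) or $\approx 14.5$ (late non-specific),
leaving every cut-off inside a separation gap of several cycles. The
late-amplification distribution is placed near the cycle ceiling
(38.5 ± 0.5) deliberately: residual non-specific signal whose tail
crossed a cut-off would contradict the separation the generator is
defined to provide, so the parameters are chosen to keep
$P(\Delta C_t^{neg} \le 11.1)$ below $10^{-8}$. Truncation of the late
draw to (HEX, `max_cycles`] is by rejection with bounded retries, then
dropout.

What the generator does **not** emulate — and what passing tests
therefore cannot show about real data: raw fluorescence curves and
baseline/threshold Ct extraction, amplification-efficiency variation
between samples, plate-position effects, cross-contamination,
heteroduplex or primer-dimer artefacts, and borderline samples whose
$\Delta C_t$ falls near a cut-off. The 100% in-silico concordance
demonstrates the *decision logic* under the assay's intended operating
regime, not the wet-lab error rate.

## Numerical and degenerate-input choices

* $\Delta C_t$ is printed with 2 decimals (half-up) in results files;
  round-trip through `write_results()`/`read_results()` is exact to
  that precision.
* Undetermined HEX is never fed to `delta_ct()`; it is gated upstream
  as `HEX_FAIL` (calling it would silently fabricate a small
  $\Delta C_t$).
* Degenerate ROC curves (no discriminating threshold) warn and return
  the largest candidate, so downstream code always receives a number.
* Zero- and three-positive call patterns return reasons, not errors;
  single-class calibration input errors out naming the absent class.
* Exact HWE probabilities are computed in log space and compared with a
  $10^{-9}$ relative tolerance when forming the tail.

## Problem sizes

The test suite and the acceptance script run entirely on generated
data: concordance is demonstrated on 20 independent 300-sample cohorts
(6000 samples, 18,000 reactions end to end), calibration on cohorts of
40–114 samples, the ROC/AUC property on 200+ random instances, exact
HWE against brute force on random tables up to $n = 20$, and the
primer-site scanner against an exhaustive oracle on random templates up
to 500 bases. These sizes exercise every code path at full fidelity
while keeping the default check fast.

## Known limitations

* The rare ε1 haplotype is outside the assay's design space; the
  package flags it and never calls it.
* Published cut-offs are constants; re-calibration requires the user's
  own sequencing-labelled training data.
* The in-silico module checks combinatorial specificity only, on
  synthetic templates.
* Odds-ratio annotation is a literature lookup for context, not an
  epidemiological computation.
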
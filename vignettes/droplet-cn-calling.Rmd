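---
title: "Copy-number and mutation calling from multiplexed droplet digital PCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number and mutation calling from multiplexed droplet digital PCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropcn)
```

## The measurement model

Droplet digital PCR partitions a reaction into roughly 20,000 droplets of
~0.85 nL. Template molecules land in droplets independently, so the number
of copies of a target in one droplet is Poisson with mean
$\lambda = c \cdot V$, where $c$ is the concentration in copies/µL of
reaction and $V$ the droplet volume in µL. After end-point PCR a droplet
fluoresces if it received at least one copy, giving the occupancy law

$$\Pr(\text{positive}) = 1 - e^{-\lambda},$$

which the quantifier inverts: $\hat\lambda = -\ln(1 - k/n)$ for $k$
positive droplets out of $n$, and $\hat c = \hat\lambda / V$. The estimate
is undefined when every droplet is positive (a *saturated* well,
$\lambda \gtrsim 7$ at 20,000 droplets); `poisson_concentration()` raises
an error there rather than reporting a meaningless number. At occupancies
below ~1% the Poisson correction is negligible and $\hat c$ converges to
the naive $k/(nV)$.

The default 95% confidence interval propagates a normal approximation on
the positive fraction through the log transform
($\lambda$ bounds at $-\ln(1 - (\hat p \pm 1.96\,\mathrm{SE}))$), which is
what instrument software reports; a Clopper–Pearson interval is available
via `ci_method = "exact"`. At $n \approx 20{,}000$ the two differ by well
under 1%, which is why the vendor-style interval is the default.
Replicate wells of identical droplet volume are merged by summing
positives and totals *before* the correction (`merge_wells()`), the
maximum-likelihood pooling for equal partitions.

## Amplitude multiplexing and gating

Both built-in assays multiplex more than one target per fluorescence
channel by giving each probe a distinct amplitude band:

* **AR-Amp-1/T877A** — T877A mutant probe (FAM); wild-type probe and the
  chromosome-10 reference *RPP30* (HEX, two bands).
* **AR-Amp-2** — AR exon 1 and exon 2 amplicons (FAM, two bands);
  references *MYM* (X chromosome) and *TBP* (chromosome 6) (HEX, two
  bands).

A droplet containing templates of several targets fluoresces at
(approximately) the **sum** of their single-target amplitudes in each
channel, which is what produces the familiar grid of combination clusters
in two-channel scatter plots. `gate_set()` therefore enumerates, per
channel, *all* $2^k$ subsets of that channel's targets at their additive
expected amplitudes, places cut points at midpoints between adjacent band
centres, and labels a droplet with the union of its two per-channel
subsets. Bands that are combinatorially possible but empty in a given well
simply collect zero droplets. Two same-channel subsets whose additive
amplitudes come closer than four pooled noise-SDs are refused as
*inseparable* — at that distance midpoint cuts misassign an appreciable
fraction of droplets, and no threshold placement can fix it.

`derive_gates()` estimates the band geometry from control wells, the
reproducible analogue of adjusting thresholds against positive and
negative controls on the instrument. With simulated controls the
ground-truth labels give the negative baseline and each single-positive
mean directly; for unlabelled data a per-channel 1-D k-means with one
cluster per expected band (deterministic evenly spaced initialisation) is
used, with sorted centres matched positionally to the expected additive
order. Explicit cut points can also be supplied (`manual_gates()`,
gate-file round-trip via `write_gates()`/`read_gates()`) for parity with
hand-set thresholds.

Droplets far from their assigned band centre (default: beyond 4 noise-SDs
in either channel, e.g. rain) are **flagged but kept**. Dropping them
would deflate the negative fraction and bias every concentration upward;
flagging surfaces them for QC without touching the Poisson denominator.

## Copy-number and mutation calls

Copy number normalises total AR signal to diploid-reference signal:

* Assay 1: $\mathrm{CN} = 2\,(\mathrm{WT} + \mathrm{MT})/\mathrm{RPP30}$.
* Assay 2: $\mathrm{CN} = 2\,(\mathrm{ARX1} + \mathrm{ARX2})/(\mathrm{MYM}^* + \mathrm{TBP})$,
  with $\mathrm{MYM}^* = 2 \times \mathrm{MYM}$ for male samples: MYM is
  X-chromosomal, so a normal male cell carries one copy where TBP carries
  two, and the doubling restores a diploid-equivalent reference. Female
  samples use the raw reading.
* Chromosome X dosage: $\mathrm{CN_X} = 2\,\mathrm{MYM}/\mathrm{TBP}$
  using the **raw** MYM reading. This is the only convention under which a
  normal male genome reads ~1 and a whole-X doubling reads ~2 — the
  amplification threshold; applying the hemizygosity doubling here would
  place normal males at the threshold. The quantity is defined against a
  male expectation (the clinical context is prostate cancer); female input
  triggers a warning, not an error.

All CN ratios are scale-invariant: multiplying every concentration by a
positive constant (more or less input DNA) leaves them unchanged, which is
the point of ratio normalisation and is enforced by property tests.

**Amplification** is called at CN ≥ 2, boundary inclusive — the threshold
is stated as the decision value, so a sample exactly at it is a positive
call. The threshold sits conservatively above the healthy-control cfDNA
range (`healthy_threshold_summary()` reports a cohort's range, mean ± SEM
with the $n-1$ sample SD, and suggests `max(2, ceiling of healthy max)`).

**T877A** is reported with mutant fraction $\mathrm{MT}/(\mathrm{MT} +
\mathrm{WT})$ (undefined when no AR template is seen) and a detection
floor of ≥ 3 mutant-positive droplets. The floor is a pragmatic
false-positive guard in the absence of a formal limit-of-blank procedure;
it is config-exposed (`min_mutant_droplets`) so a laboratory that has
measured its own blank distribution can raise or lower it.

**Cross-validation.** The two assays interrogate three disjoint AR
amplicons with three independent references, so their CN calls
cross-check each other. `cross_validate()` reports both values, the
agreement of the amplified flags and the relative difference; discordant
calls are surfaced (`"discordant"`, and excluded-with-warning from
contingency tables) rather than averaged away, because discordance is
diagnostic of a reference-gene anomaly or threshold problem.

**Display rounding** is half-up, to whole copies for pure samples and one
decimal below 10 for mixture experiments, matching how such tables are
conventionally printed; the unrounded CN is always retained and is the
authoritative value.

## Cohort statistics

`fisher_exact_2x2()` computes the two-sided p as the sum of hypergeometric
point probabilities not exceeding the observed table's (the
sum-of-small-probabilities convention, with the customary $10^{-7}$
relative tie tolerance). The doubling convention gives materially
different values on asymmetric tables and is not used. The reported odds
ratio is the sample cross-product $(ad)/(bc)$, with `Inf`/`NaN` for empty
cells made explicit. A caveat worth knowing: when the observed table is
the modal table of its margins the convention returns exactly 1, which
some graphing software displays as 0.99. `mann_whitney()` is exact for
`min(n) <= 8` without ties and uses the continuity-corrected normal
approximation otherwise; `pearson_correlation()` is the product-moment
coefficient with the $t_{n-2}$ p-value. All three are verified against
enumeration oracles (all-margins hypergeometric enumeration; full
permutation enumeration of rank assignments) in the test suite.

`build_table4()` tabulates amplified-vs-normal against treatment history
(chemotherapy, second-generation ADT, or both-vs-others). Records missing
a needed flag are excluded with a warning and a reported count, as are
assay-discordant records.

## What the simulator emulates — and what it does not

`simulate_well()` draws independent Poisson template counts per target at
the stated copies/µL, forms additive per-channel amplitudes with Gaussian
read noise, and optionally rains a fraction of positive droplets
uniformly toward baseline or clips at a saturation cap. Defaults are
QX200-nominal: 20,000 droplets of 0.85 nL. The amplitude geometry
(baseline 1000, bands at +3000/+6000 per channel, noise SD 120) is a free
parameter of the model chosen to give ≥ 5 noise-SD separation between
adjacent bands — the clean-separation regime a well-optimised assay
achieves; none of these numbers are measurements. `simulate_sample()`
converts per-cell copy profiles (e.g. male normal: WT = 1, RPP30 = 2) at
a genome concentration — default 45 haploid genome equivalents/µL, so a
diploid reference reads ~90 copies/µL, the magnitude seen for a few
nanograms of gDNA per well — and supports mass-ratio mixing of two
profiles for spike-in designs. Rain defaults to 0 so that accuracy
statements about gating are sharp; positive rain is exercised separately
in robustness tests.

Deliberately **not** modelled: partition-volume variability, PCR
inhibition and partial amplification (continuous rain), probe
cross-hybridisation, template fragmentation linkage between nearby
amplicons, and cfDNA nucleosome-positioning biases. Consequently, passing
the simulator-based tests demonstrates that the *pipeline mathematics* —
occupancy inversion, gating, CN normalisation, CI construction — is
correct under the stated model; it does not certify performance on
degraded clinical cfDNA, where threshold setting against run controls
remains the operator's responsibility.

Every stochastic routine takes an explicit seed and restores the caller's
RNG state, so whole analyses are bit-reproducible.

## Problem sizes and numerical choices

The simulation studies shipped with the package use full-scale wells
(20,000 droplets) and modest replication — 50 seeded wells for CI
coverage, 10-seed × 10-sample paired-assay cohorts for the
cross-validation correlation — sizes at which the binomial error bands
quoted in the tests are comfortably resolved. Coverage of the 95%
concentration CI is asserted at ≥ 90% (nominal 95%, slack for the normal
approximation); paired-assay Pearson r is asserted at ≥ 0.9, reflecting
shared true CN with independent measurement noise. Ties in k-means band
fitting are avoided by deterministic initialisation; half-up rounding is
implemented with `floor(x + 0.5)` to avoid banker's rounding surprises in
displayed CN.

## Limitations

The cohort-level machinery is exercised on synthetic cohorts; per-patient
clinical values are not distributed with the package. The unsupervised
gating path assumes every expected band is populated in the control well
and a roughly additive amplitude model; heavily rained or compressed
wells should be gated manually (`manual_gates()`) or upstream. Chr X CN
interpretation for female samples is undefined by construction.
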
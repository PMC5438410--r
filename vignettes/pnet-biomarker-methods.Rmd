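---
title: "Methods: spectral-count quantification and biomarker prognosis in PNETs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral-count quantification and biomarker prognosis in PNETs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnetmarkers)
```

## Scope and model

`pnetmarkers` implements the computational chain of a paired tumor /
para-tumor spectral-count proteomics study of pancreatic neuroendocrine
tumors (PNETs), from label-free quantification through the downstream
biomarker statistics: western-blot densitometry, immunohistochemistry
(IHC) scoring, methylation-specific PCR (MSP) association, and
Kaplan-Meier / log-rank / Cox prognosis for single and concurrent protein
markers (UCH-L1 and α-internexin). The raw mass-spectrometry data of the
motivating design are not publicly deposited, so a synthetic-data module
generates inputs with the structure every stage assumes; the published
validation tables (densitometry ratios, methylation-by-expression counts,
cohort outcome 2×2s) are shipped as deterministic inputs.

## Label-free quantification

For protein $N$ with spectral count $S_N$ and length $L_N$ residues, the
normalized spectral abundance factor is

$$\mathrm{NSAF}_N = \frac{S_N/L_N}{\sum_{i=1}^{n} S_i/L_i},$$

computed within each sample over the proteins that survive the
identification filter (`filter_by_unique_peptides()`, default cutoff 2
unique peptides — the conventional two-peptide rule; the cutoff is a
parameter because "more than two unique peptides" is ambiguous between
≥2 and ≥3). NSAF values lie in $[0,1]$ and sum to 1 per sample; profiles
are rescaled to parts per million (sum $10^6$) for readability. Division
by length matters because longer proteins yield proportionally more
spectra; the synthetic generator therefore draws expected counts
proportional to abundance × length.

A sample with no nonzero counts has no defined profile and is an error,
never a silent zero vector.

## Paired differential expression

The design is explicitly paired (four tumor / para-tumor pairs), so
`paired_differential()` tests each protein with a two-sided paired
*t*-test on $\log_2(\mathrm{ppm} + c)$ across pairs, pseudocount $c = 1$
ppm by default. The test choice and scale are configurable parameters:
with $n = 4$ pairs a paired *t* on log abundance is the natural test for
a volcano display of $\log_2$ fold change against $-\log_{10} p$. A
protein with identical values in every pair gets $p = 1$ (the
permutation-symmetric null); a protein with constant nonzero paired
differences is reported at $p = 0$ rather than a fabricated finite value
(Poisson counts make this measure-zero in practice).

The Tu/Nor ratio is the mean tumor ppm over the mean para-tumor ppm
(means, not medians, matching how the relative abundances are compared).
Ratios are capped at 500 (configurable): a protein absent from all
para-tumor samples is reported at the cap with `regulation =
"tumor_only"` and the `ratio_capped` flag set, symmetrically $1/500$ and
`"para_only"`, so $\log_2$ fold changes stay finite. Classification
(`classify_regulation()`) calls a protein up when ratio ≥ 2 and $p ≤
0.05$ (both configurable; the thresholds behind the published up/down
counts are unstated, and those counts are not reproducible without the
raw data). Detection-only classes count with the corresponding direction
in the summary when they pass the $p$ threshold.

## Validation-assay statistics

Band densitometry is normalized to the β-actin loading control
(`band_ratio()`, reported at 2 decimals; folds between samples at 1
decimal, matching the conventional display precision). A zero control
intensity is an error, never a silent 0 or ∞. Group comparison uses the
exact Mann-Whitney test below. IHC positivity uses the <20% rule:
staining in fewer than 20% of tumor cells is negative (the "(±)"
category merges into negative); exactly 20% is positive, the complement
of the stated rule. MSP yields two boolean band calls per sample
(methylated, unmethylated); both may be present (heterogeneous or
hemi-methylation), neither is an invalid result. Demethylation-by-
expression association is tested on the 2×2 of U-band presence against
expression; the demethylation framing reproduces the published $p =
0.002$ and is the default report (the methylation framing is also
available).

## Exact small-sample tests

These are implemented from scratch, with base R's `fisher.test()`,
`chisq.test()` and `wilcox.test()` serving as independent cross-checks
in the test suite only.

* **Fisher exact 2×2** — point probabilities over the hypergeometric
  support at the observed margins; the two-sided $p$ sums all tables no
  more probable than the observed one (minimum-likelihood definition,
  with a $1+10^{-7}$ relative guard against floating-point ties).
  Doubling the smaller tail is available but not default, because the
  minimum-likelihood definition reproduces the published methylation
  association at printed precision.
* **Pearson χ² on r×c** — expected counts from margins, no continuity
  correction, $(r-1)(c-1)$ df; a zero margin is a degeneracy error.
  Retained for multi-level features (grade, stage, location); 2×2
  features use Fisher.
* **Exact Mann-Whitney** — $U$ with midrank ties. For combined $n ≤ 20$
  (default), the two-sided $p$ is the proportion of all
  $\binom{n_1+n_2}{n_1}$ labelings whose $U$ deviates from $n_1 n_2 / 2$
  at least as much as observed. The distribution is computed by
  dynamic-programming subset-sum counting over doubled midranks (exact
  integers), which is identical to full enumeration including under
  ties; tests verify this against literal `combn()` enumeration. Larger
  samples use the normal approximation with tie-corrected variance and
  a continuity correction (the two branches agree within 0.01 at
  $n_1 = n_2 = 20$ on tie-free data).

## Survival analysis

Follow-up runs from surgery to recurrence, death, or last contact, in
months. Deaths of unknown cause are excluded from both endpoints, as are
subjects with unknown status or no follow-up (counted, never silently
dropped). OS events are deaths of disease; DFS events are recurrence or
death of disease (status AWD or DOD) — the alternative recurrence-only
definition is a caller-side choice of status mapping. Concurrent marker
status is present only when both IHC percentages are observed and ≥20%;
patients with either marker missing are excluded from concurrent-status
analyses, the only auditable treatment when per-analysis denominators
vary.

The Kaplan-Meier estimator is the standard product limit; censoring
reduces the risk set without a step. The log-rank test uses the
observed-minus-expected statistic over pooled event times with the
hypergeometric covariance, χ² on $k-1$ df. The Cox model maximizes the
Efron-tie partial likelihood by Newton iteration with step halving,
converging when the gradient max-norm falls below $10^{-8}$ (bounded at
30 iterations); risk-set sums are accumulated by cumulative sums over
time-sorted observations, so one evaluation is $O(np^2)$. Monotone
likelihood (complete separation) is flagged as non-convergence rather
than reported. Confidence intervals are Wald on the log-HR scale,
matching the conventional reporting style. All three estimators agree
with the `survival` package to near machine precision in the test suite;
`survival` is never the implementation.

## Synthetic data: what it emulates and what it does not

* **Spectral experiment** — log-normal lengths (median 450 residues) and
  long-tailed baseline abundances; planted up/down fractions (defaults
  10% / 5%) shifted by a known log2 effect (default 2, i.e. 4-fold) in
  tumor samples; sample depths log-normal around $10^5$ expected spectra;
  Poisson counts (with 4 pairs the design cannot identify
  overdispersion, so negative-binomial counts sit behind the
  `overdispersion` switch); unique-peptide counts increasing with
  abundance and capped by length. The desk-scale default is 1000
  proteins, which keeps the recovery studies under a minute while
  preserving the regime that matters (4 pairs, 4-fold effects).
* **Cohort** — 306 patients with category frequencies at the published
  summary proportions (sex 42.5% male, ~49% insulinoma, stage
  95/98/34/31/47 across I/IIa/IIb/III/IV, etc.), 27.9% concurrent-marker
  prevalence, exponential OS and DFS times with the marker-present
  hazard multiplied by true HRs (defaults 0.2, the magnitude of the
  published protective effect), uniform last-contact censoring over
  6–218 months, ~4% DUC and ~19% lost to follow-up. Statuses are
  assigned consistently (DOD ⇒ OS+DFS event, AWD ⇒ DFS event only).
* **Assays** — tumor band ratios shifted above control ratios by a
  configurable log2 shift; MSP demethylation linked to expression by a
  configurable odds ratio, with the at-least-one-band invariant
  enforced.

The generators do **not** emulate peptide-level sampling, retention
time, search-engine FDR, between-batch effects, non-proportional
hazards, or informative censoring. Passing tests therefore demonstrate
correctness of the estimators and calibration under the stated model,
not robustness to those real-data phenomena.

All randomness flows through one integer seed
(`withr::with_seed`, with fixed per-table offsets), so a fixed seed
gives identical output.

## Numerical and design choices

* Fisher's $p$ uses `dhyper()` densities, not factorial ratios, for
  stability at larger $n$; the brute-force test oracle uses
  `lchoose()` directly.
* The Mann-Whitney exact branch works on doubled midranks so all
  comparisons are exact integer comparisons; no epsilon is needed.
* The Newton solver falls back to step halving whenever a step would
  reduce the partial likelihood; coefficients beyond $|\beta| > 15$ are
  treated as monotone-likelihood evidence and flagged.
* Ratio capping uses one cap for both detection-only and
  finite-but-extreme ratios, so the volcano x-axis is bounded at
  $\pm\log_2 500$.
* The published densitometry table's raw intensity columns are garbled
  in the source document; the intensity reconstruction shipped here is
  consistent with the printed ratios for nine of ten samples (sample
  #44 prints 0.79 where the reconstructed intensities give 0.7986), so
  the printed **ratio** column is treated as authoritative everywhere.

## Problem sizes used in verification

The packaged checks use: 1000-protein / 4-pair matrices for recovery and
calibration (sensitivity ≥ 0.8 and false-discovery proportion ≤ 0.2 at
the default thresholds); 1000-replicate null simulations for log-rank
size (rejection 0.05 ± 0.015); $n = 500$ single runs and $n = 1000$
multi-replicate runs for Cox recovery and bias; 10,000-replicate null
simulations for the exact tests' size. These sizes are the package's
own verification choices and are all configurable at the call site.

## Known limitations

* The paired *t*-test on log ppm is a pragmatic small-$n$ choice, not a
  count model; with 4 pairs, rank tests are essentially powerless and
  count-model inference (e.g. negative-binomial GLMs) is unidentifiable
  for dispersion.
* The published headline identification counts (5279 identified, 3476
  with ≥2 unique peptides, 219 up / 62 down) depend on the unavailable
  raw data and are emulated only in scale, never asserted.
* Cox fitting supports plain numeric covariate matrices; factor
  expansion, stratification and time-varying covariates are out of
  scope.
* The cross-sectional report tests each feature marginally with no
  multiplicity adjustment, mirroring how such tables are conventionally
  reported.
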
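---
title: "Stepped biomarker screening by targeted label-free MS1 quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stepped biomarker screening by targeted label-free MS1 quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The screening problem

Meat from animals stressed before slaughter fails to acidify normally post
mortem: its ultimate pH (pHu, measured about 24 h after slaughter) stays at
or above 6.0, and such dark-firm-dry-prone meat differs in its soluble
(sarcoplasmic) muscle proteome. `ms1screen` implements a stepped, gel-free
screening procedure that turns a pair of pooled bottom-up LC-MS/MS analyses
— one normal-pHu pool, one high-pHu pool — into a certified list of protein
biomarkers, without labeling, fractionation or a spectral-counting model.

The procedure is deliberately tiered, moving from cheap qualitative evidence
to targeted quantification:

1. **Qualitative acceptance.** Database-search results for each group are
   reduced to confident identifications by a minimum peptide ion score
   (default 19, the identity/extensive-homology score a 1% FDR decoy search
   yielded for the original data). The search itself, decoy FDR estimation
   and protein inference are upstream of this package: its input is the
   exported identification table.
2. **Candidate triage.** Proteins identified in exactly one group are
   *primary* candidates. For proteins shared by both groups the protein
   score — a coarse abundance correlate — is compared between groups, and a
   score ratio of at least 2 (either orientation) makes a *secondary*
   candidate. Shared proteins with smaller ratios (in practice mostly below
   1.5) are discarded as uninformative.
3. **Targeted MS1 verification.** Each candidate is represented by its
   proteotypic peptide — the accepted peptide with the maximum ion score —
   in a targeted library (sequence, charge, observed m/z, expected RT).
   Extracted ion chromatograms (XICs) at ±5 ppm are integrated in both runs,
   gated by a scans-across-peak reliability rule, normalized by spiked
   internal standards, matched across runs by retention time, and converted
   to fold changes.
4. **Certification.** A candidate is certified as a biomarker when its
   normalized peak-area ratio reaches 2. Peptides reliably quantified in one
   group but detected below the limit of quantification (BLQ) or not at all
   in the other receive a pseudo-quantitative fold change of 100 — scan
   support correlates with abundance, so such asymmetry marks a large but
   not precisely measurable change.

## Model and key parameters

All thresholds live in one configuration object:

```{r, eval = FALSE}
library(ms1screen)
pipeline_config()
```

| parameter | default | stage | meaning |
|---|---|---|---|
| `min_ion_score` | 19 | filter | minimum accepted peptide ion score (inclusive) |
| `score_ratio_threshold` | 2.0 | triage | minimum protein-score ratio for the secondary tier |
| `ppm_tol` | 5 ppm | XIC | half-width of the m/z window, inclusive |
| `rt_tol` | 0.5 min | peak detection | library-interrogation RT window around the expected RT |
| `align_tol` | 1.0 min | matching | maximum apex RT difference for cross-run pairing |
| `min_scans` | 8 | gating | minimum scans-across-peak for reliable quantification |
| `pseudo_value` | 100 | fold change | pseudo ratio for quantified-vs-BLQ/absent pairs |
| `fc_threshold` | 2.0 | certification | minimum certified fold change (inclusive) |
| `noise_floor` | data-driven | peak detection | see below |

Every boundary is inclusive: the procedure states its settings as minima
("a minimum individual ion score of 19", "a minimum of 2-fold change"), so a
value exactly at a threshold passes.

### Peak detection and the noise floor

`detect_peak()` takes the most intense above-noise scan inside the RT window
as the apex (ties resolve to the scan nearest the expected RT — targeted
assay semantics: the library told us where to look), extends the bounds over
contiguous above-noise scans, counts scans-across-peak, and integrates the
trapezoid of the bounded trace. The noise floor defaults to the 10th
percentile of the XIC's nonzero intensities, which adapts to each trace
without requiring an instrument-specific constant; pass an explicit
`noise_floor` when the acquisition's threshold is known. Because peak bounds
stop at the floor, the integral of a peak close to the floor loses part of
its Gaussian tails; this truncation is exactly why peaks with few
above-noise scans are gated out as BLQ rather than ratioed.

### Normalization and fold changes

Each run's normalization factor is the median peak area of its reliably
quantified internal-standard (IS) entries — spiked tryptic peptides from an
unrelated plant protein extract, tagged by the `IS_` accession prefix and
excluded from triage. Dividing every area by the factor makes ratios
invariant to global intensity scaling of either run (tested as a property).
Pairs with no reliably quantified side (both BLQ or absent, or misaligned
by more than `align_tol`, in which case the later-eluting peak is treated as
absent) yield no fold change and are reported as unquantifiable.

## The synthetic-data generator

Real raw data is large and instrument-bound, so the package ships a seeded
generator that emulates the study design closely enough to exercise every
stage end to end:

* **Elution model.** Each peptide contributes a Gaussian elution profile
  `I(t) = apex · exp(−(t − rt)² / 2σ²)` (σ = FWHM/2.355) sampled on a
  uniform MS1 scan grid, recorded at its theoretical m/z shifted by a fixed
  per-peptide ppm offset (|offset| ≤ 5 ppm, the library tolerance), with
  multiplicative log-normal intensity jitter (σ_log = 0.05) and hard dropout
  below the noise floor — the simplest model that produces realistic
  scans-across-peak behavior. Runs are written as minimal centroid MS1 mzML.
* **Study-like fixture.** `build_study_fixture()` encodes a comparison with
  24 high-only and 6 normal-only identifications, 6 shared proteins with
  score ratios ≥ 2, 35 shared proteins with ratios ≤ 1.45, two proteins
  whose peptides all score below 19, and 5 IS proteins. True abundances are
  set so the full pipeline certifies exactly 26 of the 36 candidates: 2 with
  MS1 signal only in the high run, 4 detected at BLQ level (1–3 nominal
  scans) in the normal run, 20 quantified in both runs at true fold changes
  of 2.5–50, and 10 candidates at fold changes ≤ 1.8 that fail
  certification. The tier structure, fold changes, sequences and m/z targets
  are fixed by design; the user's seed moves only RT/ppm jitter and
  intensity noise, so different seeds reproduce the same counts.
* **Problem sizes.** The fixture uses one 30-minute run per group at a
  0.025-minute MS1 cycle (1201 scans), 41 targets per run, a noise floor of
  1000 counts and a 0.2-minute peak FWHM — small enough that a full
  simulate-plus-screen cycle takes a few seconds, large enough that peaks
  span ~19 scans as in practice. The number of technical injections per
  pooled group is configurable; the fixture uses one run per group.

Two calibration choices deserve a note. Quantifiable targets are placed at
30× the noise floor (and BLQ targets just above it): peaks barely above the
floor lose a double-digit percentage of their area to tail truncation, which
is precisely the regime the BLQ gate exists to exclude, so placing
"quantifiable" ground truth there would conflate the two regimes. And BLQ
peptides are calibrated with `apex_for_scans()`, which solves the noiseless
Gaussian model for the apex intensity that yields an exact above-noise scan
count — intensity jitter can still move a nominal 3-scan peak between 1 and
5 scans, all safely inside the BLQ band.

What the generator does *not* emulate: MS2 spectra and the variable
data-dependent duty cycle (only the MS1 subset is quantified, so a uniform
MS1 grid suffices; mixed files are handled by discarding MS2 on read),
isotope envelopes, chromatographic tailing, co-eluting interferences within
a ppm window, and in-silico digestion (fixture m/z values are arbitrary
valid values in 400–1200 Th). Passing tests on the fixture therefore
demonstrate the screening logic — thresholds, gating, normalization,
counting — not robustness to these real-data effects.

## Degenerate inputs and tie-breaks

* Proteotypic ties (equal ion scores) resolve by lexicographic sequence
  order, then charge — deterministic across platforms.
* Equal normalized areas give ratio 1.0 with direction NORMAL (a declared
  rule; such pairs never certify at the default threshold).
* A shared protein with a non-positive score on either side has an undefined
  ratio and is excluded from triage with a warning.
* An all-zero XIC is ABSENT, not an error; a run whose IS peptides cannot be
  quantified is an error, because nothing downstream is interpretable.
* Empty candidate sets produce a library with zero targets (IS entries are
  retained) and an empty fold-change table.

## Known limitations

The screen compares two pooled runs, so it inherits the design's
limitations: no biological replication, no significance testing (protein
scores are used only as a coarse indicator, and certification is a fold
change, not a p-value), single-peptide-per-protein quantification, and no
retention-time warping beyond a fixed alignment tolerance. The functional
classes attached to certified biomarkers come from a user-supplied lookup
table; live pathway/network queries are deliberately out of scope to keep
results reproducible offline.

## A complete run

```{r, eval = FALSE}
library(ms1screen)

paths <- simulate_study("study", seed = 1)
res <- run_pipeline(pipeline_config(),
                    paths$ident_normal, paths$ident_high,
                    paths$mzml_normal, paths$mzml_high,
                    annotation = paths$annotation, out_dir = "study/out")

nrow(res$candidates)   # 36 candidates (30 primary, 6 secondary)
nrow(res$biomarkers)   # 26 certified
head(res$biomarkers)
```
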
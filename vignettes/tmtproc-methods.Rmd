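---
title: "Complementary-ion quantification with tmtproc: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complementary-ion quantification with tmtproc: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmtproc)
```

## The problem

Isobaric labeling (TMTpro) lets up to 18 samples be quantified in one LC-MS
run, but the standard readout — low-mass reporter ions released in MS2 — is
corrupted by coisolation: every peptide that slips into the precursor
isolation window contributes reporters at the *same* m/z, compressing
measured ratios toward the mixture average. Complementary ions avoid this.
When the reporter region of the label is lost during fragmentation, the
balancer-plus-peptide conjugate ("complement") that remains is
*peptide-specific*: coisolated species produce complement clusters at
different m/z, so quantification from the complement cluster is essentially
interference-free at MS2.

`tmtproc` implements this quantification route end to end — tag chemistry,
cluster prediction, extraction, impurity deconvolution, filtering — together
with a synthetic-data generator that emulates the acquisition, so that every
stage is testable without a mass spectrometer.

## Tag chemistry and the 18 → 9 channel collapse

Each TMTpro label (total addition C8 ¹³C7 H25 N ¹⁵N2 O3, 304.2071 Da)
distributes nine heavy substitutions between a reporter region (8 C + 1 N
positions), the balancer carbonyl that departs with the reporter as neutral
CO, and the complement region retained on the peptide (6 C + 2 N positions).
The package encodes all 18 tags (`tmtpro_tags()`) such that:

* reporter cation m/z reproduce the published 126.127726–135.151600 series;
* tag totals are isobaric within 0.02 Da (the residual spread comes from the
  6.32 mDa mass-defect difference between one ¹³C and one ¹⁵N substitution);
* complement nominal offsets span 0–8 Da with exactly two tags per offset,
  the two differing by at most one ¹³C↔¹⁵N swap.

Since 6.32 mDa cannot be resolved on a high-m/z complement ion at practical
Orbitrap transient lengths, tags sharing a nominal complement offset are
indistinguishable. `build_channel_model()` sorts tags by complement exact
mass and merges neighbors closer than `resolvable_dm` (default 0.02 Da,
which collapses the defect pairs while preserving the 1 Da grid); the full
18-plex yields nine channels, named `c1`–`c9` in order of increasing
complement mass. Merging across distinct *nominal* offsets is refused, since
the deconvolution assumes a 1 Da grid.

The CO loss is part of the default fragmentation model for two reasons: it
is what produces nine (rather than ten) nominal complement groups from the
18 tags, and it keeps every predicted cluster peak below a 2000 m/z
normal-range MS2 ceiling for all precursors inside the eligibility windows
(500–1074 Th at 2+, 350–1381 Th at 3+). The loss model is configurable
(`loss_model()`): charged-reporter loss (complement charge `z - 1`, default)
or neutral loss (charge `z`), with or without CO. Simulator and quantifier
must share one configuration; all quantitative results are loss-model
invariant when they do.

## The cluster grid

`complement_grid()` predicts one expected peak per channel plus
`extra_isotopes` (default 2) trailing isotope peaks, uniformly spaced by one
¹³C mass difference per complement charge. The uniform grid is deliberate:
within one nominal bin, contributions from different channels and the
peptide's own heavy isotopologues differ by at most ~13 mDa, below the
resolvable width at the modeled transients, so a bin is a single aggregated
centroid. The simulator emits cluster bins on the same grid; exact per-channel
mass defects are retained in the channel model, where they drive the channel
collapse itself.

`extract_cluster()` takes, for each expected position, the most intense
centroid within a ±`tol_ppm` window (default 10 ppm); when two expected
positions claim the same centroid, the closer one wins. When the scan's
resolving power is supplied, the window is widened to at least the local FT
peak FWHM (`m^1.5 / (R200 * sqrt(200))`): a centroid is the merged envelope
of everything inside the peak width, so a merged target + interferent peak
can legitimately sit up to one width from the expected position. Without
this, coalesced coisolation signal drags centroids outside the ppm window
and channels are spuriously zeroed. `quantify_psms()` passes
`resolution = 45000` by default; the pure-ppm behavior remains the
`extract_cluster()` default.

## Impurity deconvolution

Each channel's observed signal is spread across grid positions by two
convolved effects: the tag's complement-region isotopic impurities (offsets
−2…+2; bundled defaults have realistic 0–3% magnitudes and are replaceable
by a measured table via `read_impurity_table()`), and the peptide's
aggregated isotope envelope, computed by truncated convolution of
per-element binomial/multinomial patterns (`isotope_envelope()`; heavy
label atoms contribute no variability). For a merged two-tag channel the
impurity vector is the mean of its members — their abundances are
indistinguishable by construction.

`build_design_matrix()` assembles the resulting linear map A (rows =
observed grid positions, columns = channels; each column sums to the
envelope mass retained on the grid, at most 1), and `solve_channels()`
solves the overdetermined system A x = B by QR decomposition. Negative
components are clipped to zero by default (abundances are physical); a
Lawson–Hanson non-negative solver and the raw solution are available
(`nonneg = "nnls"` / `"none"`).

One caveat matters for *ratio* statistics: clipping maps noisy near-zero
channels to exact zeros, so per-PSM ratios against such channels become
infinite and the median across PSMs is biased upward. Ratio experiments in
the test suite therefore use the median per-PSM ratio under ion statistics
where clipping is essentially inactive, and the raw solution is exposed for
users who aggregate ratios.

A peptide is "quantified" when its summed signal-to-FT-noise over matched
cluster peaks reaches 90 for a 9-plex, or 10× the number of labeled
channels for smaller designs (`passes_quant_filter()`).

## What the simulator emulates — and what it does not

`simulate_interference_sample()` generates the two-proteome interference
design: a yeast-like proteome at design ratios 0:1:5:10:1:10:5:1:0 across
`c1`–`c9`, a human-like proteome at 1:1, mixed 1 part yeast to 10 parts
human. Per scan it emits the target's complement cluster (design ratios ×
impurity × envelope), the reporter region (one designated member tag per
channel, impurity-spread, uncorrected downstream by design), and, with
probability `coisolation_prob`, an interferent's clusters at an isolation
offset drawn uniformly within the window. Modeled acquisition physics:

* **Poisson ion statistics** per peak at the `ion_scale` (default 5000
  expected complement ions for a yeast target);
* **FT noise floor** (`noise_floor`, default 10 ion units): zero-mean
  Gaussian intensity scatter, reported as the per-peak noise estimate;
  sub-zero peaks are censored, as real noise thresholding would do. This
  censoring measurably biases ratio medians of weak channels upward — a
  real property of FT intensity readout near the floor, and the reason the
  coisolation experiments below are run at pure Poisson statistics;
* **centroid coalescence**: peaks closer than the local FWHM at the
  configured resolving power (45k/60k/120k) merge into intensity-weighted
  centroids, which is what degrades complement accuracy at low resolution;
* **real-time-search gating** emulation (`rts_accept()`): cross-correlation
  > 1.4, delta ≥ 0.2, |ppm| ≤ 10, target-list membership.

Simulated peptides are random tryptic-like sequences (length 8–20, ending
K/R, uniform composition): composition realism matters only through the
isotope envelope. Not modeled: chromatographic elution and dynamic
exclusion, duty-cycle scheduling, AGC/IIT control loops (abstracted into
`ion_scale`), fine-structure isotopes, and the instrument-bound PSM-count
economics of real acquisitions. Passing tests therefore demonstrate
correctness of the quantification *mathematics* under the declared physics,
not instrument-level performance.

A `TruthLedger` row per scan records the channel truth vector, interferent
identity, proteome and intensity fraction, and the noiseless peak table; the
noiseless configuration (`poisson = FALSE, noise_floor = 0`) makes
simulate → extract → deconvolve an exact round trip, which the suite checks
to machine precision.

## Interference experiment

With coisolation probability 0.5, 1:1 interferents at half the target's
intensity, and 5000 Poisson-distributed ions per cluster over 500 PSMs, the
suite verifies the central contrast: the mean reporter-measured 10:1 ratio
falls well below 10 (compression by the flat interferent), while the median
complement-measured 10:1 ratio stays within 5% of the design value. The
experiment is run at Poisson-only ion statistics — its stated conditions —
so that the separate noise-floor censoring bias does not confound the
coisolation property under test.

## Downstream time-course analysis

The `timecourse` functions reproduce the standard embryogenesis workflow:

* **Razor assignment** (`assign_peptides_to_proteins()`): shared peptides go
  to the candidate with the most unique peptides; ties break
  lexicographically and are flagged.
* **Anchor normalization** (`normalize_to_anchor()`): stage columns are
  scaled so the summed (or median) signal of anchor peptides — the
  mitochondrial-protein stand-in — is constant, preserved at its
  pre-normalization mean. "Constant" is interpreted as the anchor *sum* by
  default with the median exposed as an option, since either reading is
  defensible.
* **Roll-up** (`rollup_proteins()`): "median-corrected signal" is read as:
  scale each peptide profile to its own mean, take the per-stage median
  across peptides, then rescale to the protein's total peptide signal. No
  formula is published for this step; the interpretation is configurable
  (`center = "none"` skips the mean-scaling).
* **Clustering** (`hkmeans_cluster()`): rows are normalized to fractional
  profiles (shape, not abundance), centers initialized from a Ward-linkage
  cut at k, refined by Lloyd iterations — deterministic given input order.
  k = 6 matches the fly/frog analyses; the sea-squirt two-pass schedule
  (cluster at 10, set one cluster aside, recluster the rest at 5) is
  generalized in `recluster_schedule()`, with the isolated cluster chosen by
  a selector function (default: most strongly decreasing centroid).
* **Fold changes** (`fold_change_summary()`): per-protein log2(first/last)
  with fractions beyond a threshold fold (default 2); zeros are floored at
  half the smallest positive value and flagged.
* **Orthogroup representatives** (`orthogroup_representatives()`): per
  orthogroup and organism, the protein with the most quantified peptides,
  lexicographic tie-break; the orthogroup table itself is consumed as
  external TSV (ortholog inference is out of scope).

`simulate_timecourse()` provides the matching test bed: archetype
trajectories (constant / increasing / decreasing / peaked) with
multiplicative lognormal peptide noise, a flagged constant anchor class, and
an optional per-stage efficiency drift that anchor normalization must
remove.

## Numerical choices and problem sizes

* Envelope truncation: bins are exact under truncation (probability only
  leaks past the last bin); the envelope is renormalized when ≥ 99.9% of
  mass is retained and extended otherwise (`.envelope_auto` grows the bin
  count for S/Cys-rich peptides).
* QR solves use LAPACK via base `qr()`; rank deficiency is rejected with
  the collinear channels named.
* File writes are atomic (temp file + rename); seeded runs are
  byte-reproducible. mzML I/O goes through `mzR`; per-peak FT noise is not
  representable in plain mzML and lives in the package objects and ledger.
* Default suite sizes: 100-peptide noiseless recovery runs, a 500-PSM
  seeded interference experiment, 1000 random systems for the solver
  oracle, 120–160-protein clustering recoveries. These sizes give
  Monte-Carlo error comfortably inside the asserted tolerances while
  keeping the suite quick.

## Known limitations

* The bundled impurity table is a realistic stand-in, not a vendor lot
  sheet; real analyses should supply measured impurities.
* Only one reporter-loss series is quantified per scan (the configured
  one); summing charge-reduced series is not attempted.
* The acquisition simulator abstracts AGC/IIT into a single ion-count
  scale and does not model elution; absolute sensitivity claims
  (PSM counts, protein gains) are out of its reach by design.
* The noise process (Poisson + Gaussian floor with censoring) is a
  stand-in for the unpublished instrument noise model.
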
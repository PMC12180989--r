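---
title: "Methods: distance-based detection of atypical RT prescriptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distance-based detection of atypical RT prescriptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rxguard)
```

rxguard screens new radiation therapy prescriptions against a historical
treatment database and flags records that are atypical, with a per-record
explanation. This vignette is the package's own account of the model, its
assumptions, the tunable parameters, the numerical choices, and the
limitations of the synthetic validation.

## The detection model

A treatment record is a prescription — dose per fraction $d$ (cGy) and
number of fractions $n$ — plus a clinical feature vector
$(\text{technique}, \text{energy}, \text{IDL}, \text{intent},
\text{ICD weight}, \text{age group})$. Detection is calibrated separately
per treatment site (brain, thoracic) and per technique (IMRT, 3D
conformal, and the pooled stereotactic family SBRT/SRT/SRS), because both
the prescriptions in use and the dispersion of their features differ
structurally across techniques.

**Prescription distance.** Doses (hundreds of cGy) and fraction counts
(units to tens) are incommensurate, so both axes are min–max scaled to
$[0,1]$ by the historical database's own ranges — never by the query —
and compared with Euclidean distance. The statistic
$R$ is the mean distance from the query prescription to its $k$ nearest
historical prescriptions, $k = \max(1, \mathrm{round}(\nu S))$ for an
effective database size $S$ (replication weights count as identical
copies). A scaled alternative (distances in total-dose space) was rejected
because it conflates the two error axes the model is meant to separate —
a dose-per-fraction error and a fraction-number error can cancel in total
dose, which is precisely the dangerous case.

**Feature distance.** The statistic $F$ asks whether the query's features
are the features that usually accompany *that* prescription: it averages
the Gower dissimilarity between the query's feature vector and the vectors
of the $k' = \max(1, \mathrm{round}(\mu S))$ historical records nearest in
prescription distance. Gower dissimilarity is the feature-weighted mean of
0/1 mismatch indicators (categoricals) and range-normalised absolute
differences (numerics), hence always in $[0,1]$. Feature weights default
to 1 and are configurable. Technique is kept in the vector even though
models are calibrated per technique: it contributes 0 within a partition
but keeps cross-technique feature anomalies representable.

**Thresholds and flagging.** The flagging thresholds scale with the
database's own dispersion: $t_{Rx} = a\theta$ and $t_F = b\tau$, where
$\theta$ and $\tau$ are the mean pairwise prescription and feature
distances over all unordered pairs of effective records. A record with
$R > t_{Rx}$ is a prescription anomaly (type 1) and $F$ is not evaluated;
otherwise $F > t_F$ flags a feature anomaly (type 2). Flags use strict
inequality — a record exactly at threshold is not flagged. The pairing of
$(a, b)$ with the two thresholds follows the numerically consistent
reading of the published calibration tables (e.g. $0.02 \times 0.45 =
0.009$, matching the printed prescription threshold for brain IMRT across
all six site/technique configurations); the opposite pairing that one
table footnote suggests is available as `compute_thresholds(pairing =
"footnote")`.

## Parameters

| Parameter | Meaning | Default / grid | Notes |
|---|---|---|---|
| $\nu, \mu$ | neighbourhood fractions for $R$, $F$ | grid {0.005, 0.01, 0.02, 0.03, 0.05} | fractions of effective database size |
| $a, b$ | threshold multipliers | 12-point log grid on [0.01, 1.2] | published optima lie inside this range |
| runs | grid-search repetitions | 50 (`fit_rx_model(runs=)`) | fresh anomaly draw per run; report is mean ± SD |
| $p_{\min}$ | rarity floor for simulated anomalies | 0.02 | conditional frequency below which a value counts as "rarely/never co-occurring" |
| pediatric cutoff | age group boundary | 18 years, half-open (18 = adult) | standard pediatric oncology convention |
| rare-Rx factor | replication upweight of reduced-field regimens | 3, configurable | duplication-equivalence guarantees semantics |
| bin width | linear time scaling | 2 years | multiplier is the 1-based bin index (1x, 2x, ...) |

Neighbour counts round half-up (`floor(x + 0.5)`), never exceed $S$, and
never fall below 1.

## Training and testing protocol

Per site: 20 records per technique are held out as unseen normal test
records. Per technique, the training labeled set is 40 in-database normal
records plus 60 freshly simulated anomalies per run (30 prescription + 30
feature; a lighter 30-anomaly preset is available through the
`n_train_rx`/`n_train_feature` arguments). Every grid point $(a, b, \nu,
\mu)$ is scored by detection F1 — anomaly of either type is the positive
class; subtype correctness is reported separately — and the consensus of
the per-run maximisers (modal point, ties resolved by highest mean F1,
then grid order) is returned with the mean ± SD of per-run best F1.
Testing uses 20 held-out normals + 20 simulated prescription anomalies +
20 simulated feature anomalies per technique, and agreement of flag totals
with ground truth is assessed by a Pearson χ² (no continuity correction)
on the two-row contingency table of ground truth versus model prediction,
retained when the statistic is strictly below the df-1 critical value
(3.84 at α = 0.05).

## Anomaly simulation

The simulators generate labeled anomalies from the database's own
conditional frequencies, so that "anomalous" always means *empirically
rare given this database* (frequency below $p_{\min}$):

- **Prescription anomalies** draw a base record (weight-proportionally)
  and perturb only its prescription with one catalog rule — dose/fraction
  swap, ×10 or ÷10 dose scaling (decimal-point error), single-digit
  substitution in the dose (kept inside a 10–5000 cGy sanity window), or a
  regimen sampled from a different technique — rejecting results whose
  exact prescription is not sub-$p_{\min}$.
- **Feature anomalies** keep the base prescription exactly and replace one
  feature (energy, intent, isodose line, age group or diagnostic code)
  with a value whose conditional frequency given that exact prescription
  is below $p_{\min}$ — a pediatric age group on an adult-only regimen, a
  palliative intent on a curative-only one.

The catalog, rule weights and $p_{\min}$ are all exposed in
`anomaly_spec()`; the construction is a documented reconstruction of the
conditional-probability idea, not a transcription of any specific error
log. One consequence worth knowing: a diagnostic-code flip moves only the
code-weight coordinate of the Gower vector, so code-flip anomalies are
intrinsically milder than categorical flips — published per-record
examples show the same pattern (code-flip anomalies printed with $F$ below
threshold) — and detection F1 below 1 is the expected regime, not a bug.

## Numerical choices

- **Tie handling in neighbourhoods.** Many historical records are tied at
  prescription distance zero (exact regimen matches). Records tied at the
  neighbourhood boundary enter *pro rata by replication weight*: whole
  equal-distance groups are taken while they fit and the boundary group
  contributes the fraction of its weighted mean needed to reach $k$. This
  is deterministic, exactly equivalent to materially duplicating weighted
  records, leaves $R$ unchanged (tied records share a distance), and —
  unlike an id-ordered tie-break — lets replication weighting genuinely
  shift the neighbourhood's feature composition, which is what makes
  incremental time scaling work.
- **$\tau$ and $\theta$.** $\tau$ is computed exactly for any cohort size
  through a per-feature decomposition of the pair sum (category weight
  totals for categoricals; sorted prefix sums for numerics). $\theta$ is
  exact over unique-prescription pairs up to a configurable cap and falls
  back to seeded uniform pair subsampling (≥ 10⁶ pairs) beyond it.
- **Degenerate ranges.** A zero-span prescription axis with differing
  values is an error; a zero-span numeric Gower feature falls back to the
  mismatch indicator; numeric Gower contributions are clamped to 1 for
  queries outside the historical range.
- **Determinism.** Every stochastic step (cohort generation, splits,
  anomaly draws, per-run seeds derived from a master seed by counter,
  $\theta$ subsampling) is seeded; repeat calls of `classify()` agree bit
  for bit.
- **Imputation ties** resolve to the lexicographically (numerically)
  smallest candidate, making most-often imputation deterministic and
  idempotent.

## The synthetic cohorts

`default_specs()` emulates two site databases (brain S = 4100, thoracic
S = 2000, calendar span 1995–2021) with per-technique regimen catalogs
carrying era windows (the documented rising stereotactic regimens
4 × 1200 and 5 × 1000 cGy and IMRT 30 × 200 cGy; retired 3D courses
20 × 180, 17 × 180, 20 × 200 cGy), logistic technique-adoption curves (3D
dominant before the late 2000s, IMRT/SBRT after the early 2010s),
era-windowed beam energies, and 5%/8% missingness in intent/isodose line.
Feature conditionals are deliberately concentrated — each regimen has a
dominant intent (~95%), era-sharp energies and a narrow isodose
distribution — matching the printed per-record evidence that normal
records score near-zero feature distances against thresholds of order
0.02–0.18. Real per-regimen frequencies are not published; the defaults
are synthetic but clinically shaped.

What passing tests on these cohorts shows: the statistics, calibration,
and incremental machinery behave as designed on data with realistic
structure (regimen mixtures, era drift, missingness, mixed feature
types). What it does not show: performance on real exports, whose feature
noise, coding habits and query quirks (free-text diagnoses, unit errors,
QA-row conventions) are only approximated by the configurable cleaning
rules; published real-data F1 values are therefore not reproduction
targets here.

## Incremental learning under secular drift

Treatment practice drifts: techniques replace one another, regimens retire
and appear, beam energies and prescribing conventions change. The linear
scaling scheme multiplies each record's replication weight by its 1-based
2-year bin index from the technique's first year of use; the sliding
window alternative simply retires records older than the window.
`incremental_comparison()` is the proof-of-concept experiment: on a
thoracic cohort with an injected sharp mid-2010s shift
(`drifted_thoracic_spec()`: complete conversion to flattening-filter-free
delivery in 2016, two conventional courses retiring 2016–17, a
hypofractionated 20 × 300 cGy course from 2018, and the prescribing
convention moving from the 100% to the 98% isodose line), the IMRT model
is calibrated twice — raw history versus linearly scaled — and both are
evaluated on a recent-era test set (held-out normals from the last 4
years; anomalies simulated from recent-era base records). Training
normals are drawn from the recent era for both arms, the
deployment-faithful choice: thresholds are calibrated on the records the
model is about to screen. Anomaly base records are drawn
weight-proportionally from each arm's effective database, consistent with
the weights-as-copies semantics. With grid `default_grid(8)` and 3 runs
per arm this keeps the 10-seed experiment around a quarter minute while
the scaled arm wins or ties in 9 of 10 seeds (mean detection F1 ≈ 0.85 →
0.90 in the packaged configuration).

## Problem sizes used by the test suite

The acceptance-style tests run the full protocol at the default cohort
sizes (brain 4100, thoracic 2000) over 10 seeds with 5 grid-search runs
per fit, the grid-search/exhaustive cross-checks on a 200-record cohort
with a 3 × 3 × 2 × 2 grid, the Gower oracle on 1000 random pairs, and the
drift experiment over 10 seeds; these sizes are the package's validation
design and keep the whole suite in the low minutes on a single core.

## Known limitations

- The "similar (or same) Rx" neighbourhood for $F$ is interpreted as the
  $k'$ nearest records by prescription distance with exact matches first;
  other aggregations (quantiles, minimum) are conceivable.
- Diagnostic-code anomalies are only as visible as the code-weight
  coordinate makes them (see above); a reviewer wanting sharper code
  sensitivity can upweight `icd_weight` in the Gower weights.
- The χ² validation compares marginal flag totals, not paired outcomes; a
  paired McNemar report is provided as a clearly labeled extension
  (`mcnemar_validation()`).
- Thresholds assume the historical database is mostly normal; a database
  contaminated with real errors would inflate $\tau$, $\theta$ and loosen
  the thresholds.
- Engineering rules (QA markers, ICD prefix lists, exclusion lists) are
  configuration, seeded with sensible defaults, and must be reviewed per
  institution.
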
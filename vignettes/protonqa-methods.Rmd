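---
title: "Methods: log-file QA and delivered-position prediction for spot-scanning proton therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: log-file QA and delivered-position prediction for spot-scanning proton therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protonqa)
```

## The problem

In pencil-beam-scanning (PBS) proton therapy the machine paints the target
spot by spot: for each energy layer, the scanning magnets steer a narrow
beamlet to a sequence of planned lateral positions and deliver a planned
meterset (MU) at each. AAPM TG-224 sets tolerances on how far delivered spot
positions may stray from plan (1 mm for annual QA). Two complications make
routine verification awkward in practice. First, the machine's own record of
what it delivered — the per-spot delivery log — measures positions with a spot
position monitor (SPM) mounted upstream of the isocenter, in a plane where
coordinates are demagnified relative to the plane in which the plan defines
them. Second, on some delivery systems the log is a proprietary binary format,
so a reproducible open-source pipeline cannot read real logs directly.

This package implements the full comparison pipeline around those two
obstacles:

1. **Plan side** — read and write the spot map (positions, per-spot MU,
   per-layer energies, gantry angle) of DICOM RT Ion Plan files.
2. **Log side** — define an openly documented, versioned binary log format
   ("PQA1") carrying exactly the per-spot quantities a delivery log records
   (SPM-plane position, spot width, delivered MU), plus a simulator that
   generates whole QA campaigns with controllable systematic and random error
   structure standing in for real machine logs.
3. **Comparison** — project SPM coordinates to the isocenter plane, pair
   logged spots with planned spots, and compute signed deviations.
4. **QA statistics** — distribution summaries, heteroscedastic factor
   analyses, and moving-window flagging against TG-224-style tolerances.
5. **Prediction** — per-axis gradient-boosted models of the delivered
   position given plan-level features, evaluated on a temporal split.
6. **Dose** — a simplified analytical pencil-beam engine to translate
   position deviations into voxel-wise dose differences.

## Coordinate projection

The SPM records each spot in its own plane. Projection to the isocenter
plane is linear per axis:

$$x_{\mathrm{iso}} = x_{\mathrm{SPM}} \cdot f_x, \qquad
  y_{\mathrm{iso}} = y_{\mathrm{SPM}} \cdot f_y,$$

with clinical projection factors $f_x = 1.696$ and $f_y = 1.391$ as defaults
of `projection_factors()`. The factors are configurable (they depend on
beamline geometry and could in principle differ per room); the simulator uses
the exact inverse when it converts simulated isocenter positions into
SPM-plane log records, so projection and simulation are consistent by
construction.

Deviations are signed **delivered minus planned**, so a positive mean reads
as the delivered pattern shifted toward positive axis values. Pairing of log
and plan spots is strictly positional — the *i*-th record of layer *k* pairs
with the *i*-th planned spot of layer *k* — because a delivery log records
every planned spot in delivery order; a count mismatch is treated as data
corruption, not as a matching problem to repair.

## The error model and what the simulator emulates

`simulate_session()` composes the delivered position of each spot additively:

$$x_{\mathrm{del}} = x_{\mathrm{plan}} + \mu_x + r_x(\mathrm{room})
  + s_x\,(E - E_{\mathrm{ref}}) + t_x(\mathrm{date})
  + \varepsilon,\quad \varepsilon \sim N(0, \sigma_x^2\,c_{\mathrm{room}}^2)$$

and likewise for *y*; delivered MU is planned MU plus $N(\mu_{MU},
\sigma_{MU}^2)$ noise truncated at zero. $E_{\mathrm{ref}}$ is the midpoint
of the plan's energy range, so the energy term is centered. The x and y
jitters are sampled independently: measured cross-axis correlations of real
PBS deliveries are negligible (of order $-0.09$), and the two steering
magnets are physically separate systems.

The default campaign (`paper_campaign()`) fixes the study conditions this
package is tested under:

* **Marginal error distributions** (`paper_error_model()`): x mean 0.163 mm,
  SD 0.199 mm; y mean 0.096 mm, SD 0.151 mm; MU noise mean $0.70 \times
  10^{-5}$ MU. These are the reference campaign's reported global moments.
  The MU noise SD ($10^{-4}$ MU) is a free parameter of the simulator — a
  per-spot MU scatter small against the $\sim 10^{-2}$ MU per-spot metersets.
* **Campaign shape**: one fixture plan of 20 energy layers (99.2–124.8 MeV,
  evenly spaced), uniform metersets summing to 233.3 MU, spots on a
  rectangular grid spanning ±100 mm; delivered in two rooms (G1, G2) on 32
  paired dates across three months (12 + 12 + 8 per month), i.e. 64 sessions.
  At 725 spots per layer this is 928,000 spot records — the full-scale
  campaign; tests and the bundled configuration run the identical structure
  at 100 spots per layer.
* **Factor structure** (magnitudes are this package's choice; the reference
  campaign reports only that energy, day, and room are statistically
  significant factors, without effect sizes): room offsets of
  (0.02, 0.01) mm for G1 and (−0.03, 0.02) mm for G2; an energy slope of
  (0.002, 0.001) mm/MeV — about ±0.03 mm across the 25.6 MeV span; per-date
  drifts drawn once (from a seed derived from the campaign seed) as
  $N(0, 0.04\ \mathrm{mm})$; and jitter scale factors of 1.25 (G1) vs 0.8
  (G2), reflecting that one room shows visibly larger spot-to-spot
  fluctuation. These values are large enough to be detected by Welch's ANOVA
  at campaign sample sizes yet small against the 1 mm tolerance, which is the
  qualitative situation the reference campaign describes.
* **Fault injection**: a constant (+1.1 mm, 0) offset added to every spot of
  the G2 session on the final month's 20th — a session-level systematic error
  just beyond the 1 mm annual tolerance, which the moving-window flagging is
  expected to isolate to exactly that session.

**What the simulator does not emulate.** Real logs exhibit within-layer
serial correlation from magnet settling, energy-switching transients,
beam-current-dependent MU granularity, and occasional spot aborts/repaints.
Deviations here are exchangeable within a session given the layer, which is
precisely why moving-window statistics behave cleanly. Passing tests
demonstrate that the pipeline's bookkeeping, statistics and models are
correct under controlled error structure — not that real hardware behaves
this way.

Reproducibility: all randomness descends from one campaign seed. Per-session
seeds are derived with a deterministic string hash of (seed, room, date)
(`derive_seed()`), so any single session can be regenerated in isolation and
adding sessions never perturbs existing ones.

## QA statistics

**Distribution summaries.** `summarize_deviations()` reports moments with
the sample (n − 1) SD; the "Gaussian density estimate" drawn over histograms
is the maximum-likelihood normal fit, i.e. the same mean and SD.

**Squared Euclidean deviation.** With independent normal axis errors, $d^2 =
\Delta x^2 + \Delta y^2$ is a scaled noncentral chi-square-type quantity with
mean $\mu_x^2 + \sigma_x^2 + \mu_y^2 + \sigma_y^2$
(`expected_squared_distance()`); at the reference moments this is
0.0982 mm², matching the reported 0.098 mm². The second-moment identity is
property-tested against Monte-Carlo means.

**Factor analyses.** The battery mirrors standard heteroscedastic practice:
Levene's test (classic mean-centered form; the median-centered Brown–Forsythe
variant is available via `center = "median"`), Welch's ANOVA with the
Satterthwaite-type denominator df, and Games–Howell post hoc comparisons on
the studentized range distribution. These are implemented from the standard
formulas and cross-checked in the test suite against independent
implementations (`stats::oneway.test`, `car::leveneTest`, and the exact
2-group equivalence of Games–Howell with Welch's *t*). One subtlety: Welch's
F equals the classic one-way F *exactly* only for two groups with equal
sample variances and sizes; for $k > 2$ the small-sample correction term
$2(k-2)/(k^2-1)\sum (1 - w_j/W)^2/(n_j - 1)$ is nonzero even under perfect
balance, and the two statistics agree only to $O(1/n)$. The tests assert the
exact 2-group identity and the $O(1/n)$ convergence rather than a false
general identity. No multiplicity correction is applied across factors;
within a factor, Games–Howell's studentized-range reference is itself the
familywise correction.

**Moving-window flagging.** Within each session, trailing windows of 50
consecutive spots (configurable) give running means per axis; a spot is
flagged at a tier if *any* window covering it exceeds that tier's tolerance
(annual 1 mm; daily 2 mm — the daily value is a conventional choice, as
daily tolerances vary by institution) on either axis. Windows never span
sessions or wrap. Flag counts are reported both as the union over axes
(default headline count) and per axis, since either convention appears in
practice. The rolling implementation is an $O(n)$ cumulative-sum + coverage
difference-array scheme, tested for exact equality against a brute-force
$O(n \cdot w)$ re-scan.

## Position prediction

Two independent gradient-boosted regression-tree models (one per axis;
`xgboost`, 500 trees, learning rate 0.1, squared-error objective,
single-threaded and seeded for determinism) map
$\{x_{\mathrm{plan}}, y_{\mathrm{plan}}, E, \mathrm{date}, \mathrm{room}\}$
to the delivered coordinate. Dates are encoded as ordinal days since the
campaign's first session, rooms as integer categories (tree models are
indifferent to the coding). The train/test split is temporal: every session
in the last calendar month present in the data is held out, which under the
default calendar reserves 16 of 64 sessions (232,000 of 928,000 rows at full
scale). Metrics are MSE $= \frac1n \sum_t (A_t - P_t)^2$ and $R^2 = 1 -
\mathrm{SSR}/\mathrm{SST}$, reported overall, per (room, date), and per
energy band (90–109, 110–119, 120–129 MeV), plus per-spot Euclidean
distances and the cross-axis Pearson correlation of the deviations.

Two cautions the package makes explicit. Because planned coordinates span
±100 mm while delivery errors are a few tenths of a millimetre, the identity
predictor (predict planned as delivered) already achieves $R^2 \ge 0.999$;
a high $R^2$ mostly certifies that the model has learned the identity
backbone. The tests therefore additionally require the trained model never to
lose to the identity baseline on test MSE — the model must earn its keep on
the error structure, not just the backbone. Relatedly, per-feature gain
importances are reported (normalized total split gain), and on simulated
campaigns the planned coordinate dominates, as expected when the target is
that coordinate plus small structured noise; exact importance percentages are
data-dependent and not asserted.

## The dose engine

The dose module quantifies how position deviations move dose around, with a
deliberately simple analytical model: homogeneous water, beam axis along grid
z, dose per voxel

$$D(v) = \sum_s \mathrm{MU}_s \cdot c \cdot \mathrm{DD}_{E_s}(z_v) \cdot
  \frac{\Delta a}{2\pi\sigma_{E_s}^2}
  \exp\!\Big(-\tfrac{(x_v - x_s)^2 + (y_v - y_s)^2}{2\sigma_{E_s}^2}\Big),$$

with $\mathrm{DD}$ a normalized synthetic Bragg curve (entrance plateau plus
Gaussian peak at 98.5 % of the range, range from the Bragg–Kleeman power law
$R = 0.022\,E^{1.77}$ mm), $\sigma_E = 2.5 + 400/E$ mm, $\Delta a$ the voxel
cross-section, and $c$ a configurable MU-to-dose scale. Including $\Delta a$
in the kernel makes a lateral slice sum equal $\mathrm{MU} \cdot c \cdot
\mathrm{DD}(z)$, which is what the normalization tests check (1 % tolerance
for fields extending beyond 5σ). The engine is exactly linear in MU and is
tested against a naive voxel-by-voxel recomputation. It is **not** a
commissioned clinical engine: no heterogeneity, no nuclear halo, no
measured Bragg curves — so absolute dose statistics produced here are
engine-dependent and are never compared against clinically derived values.
The default evaluation grid is 2 mm isotropic (the end-to-end experiment uses
4 mm to keep runtimes small).

## Numerical and design choices

* **DICOM subset.** No R DICOM toolkit is part of this package's dependency
  stack, so plan I/O includes a minimal explicit-VR little-endian codec
  covering the RT Ion Plan attributes the pipeline needs. Layers are written
  as the standard paired control points (spot weights on the even point, zero
  weights on the odd); per-spot MU is recovered as
  weight × beam meterset / final cumulative meterset weight, the standard
  ion-plan convention. Position maps are float32 (the format's precision);
  metersets round-trip to better than $10^{-6}$ relative. An explicit-VR
  value length is 16-bit, capping a single control point's spot map at 8191
  spots per layer — far above the 725 used here; the writer validates this.
  Files written by the package are verified in the test suite with an
  independent DICOM reader.
* **Log format.** PQA1 is little-endian with float64 records and a
  length-prefixed string header; its byte layout is documented in the
  `log_io` source and file sizes are exactly computable from the header
  (`pqa_file_size()`), which the round-trip property tests exploit. Logged
  MU is per-spot, not cumulative. Spot widths are carried for format
  fidelity but not analyzed.
* **Edge handling.** The first window − 1 spots of a session are judged only
  by windows that contain them; zero-variance groups are rejected by Welch
  and Games–Howell (df undefined) with informative errors; singleton factor
  levels are dropped with a warning; $R^2$ with zero SST is reported as
  missing rather than forced to a value.
* **Problem sizes.** The test suite runs the full-scale bookkeeping check
  (64 × 14,500 = 928,000 records) once, and everything else at reduced
  campaign sizes (10–100 spots per layer) that preserve the campaign
  structure; the acceptance script recovers axis means from 58,000-spot runs
  and trains 500-tree models on a 128,000-row campaign. These sizes give
  Monte-Carlo standard errors comfortably inside the 3-standard-error
  acceptance bands while keeping a complete run in minutes on one core.

## Limitations

Beyond the simulator and dose-engine caveats above: the pipeline assumes one
beam per plan (multi-beam files are readable; the pipeline operates per
beam), a fixed gantry angle (no angle-dependent projection factors), and
day-resolved sessions. The statistics replicate standard formulas, not any
specific statistical package's output conventions. Real-log ingestion would
require only a new reader producing `delivery_session` objects; everything
downstream is format-agnostic.
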
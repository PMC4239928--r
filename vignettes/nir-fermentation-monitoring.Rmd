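---
title: "Methods: synthetic NIR monitoring and control of lactic fermentations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic NIR monitoring and control of lactic fermentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`nirferm` re-creates, entirely in silico, the workflow by which NIR
spectroscopy is calibrated against off-line reference assays and then
used as the sole sensor for closed-loop fermentation control. This
vignette records the models, the tunable parameters, and the design
decisions taken where the workflow left genuine freedom — together with
what a green test does and does not establish.

## 1. Fermentation model

No kinetic equations were available for the target organisms; only
media (100 g/L glucose homolactic, 46 g/L heterolactic), attainable
concentration ranges, and coarse timing (a 15–20 h exponential phase)
constrain the simulator. We therefore use the standard lactic
fermentation forms:

* Monod growth with product inhibition:
  $\mu = \mu_{max}\dfrac{S}{K_s+S}\max(0, 1-P_L/P_{max})$
* Luedeking–Piret production, split between lactate and acetate by
  `acetate_fraction`: $dP/dt = (\alpha\mu + \beta f_S)\,X$
* substrate balance $dS/dt = -(\mu/Y_{xs})X - m f_S X$, with
  $f_S = S/(K_s+S)$.

**Deviation from the plain Luedeking–Piret form:** the non-growth terms
$\beta$ and $m$ are gated by $f_S$. Without the gate, product would
keep appearing (and glucose demand would continue) after substrate
exhaustion, violating nonnegativity and any carbon bookkeeping. The
gate leaves the exponential phase untouched and only shuts production
down smoothly as $S \to 0$.

Defaults are frozen so that a default 48 h homolactic batch from
100 g/L glucose ends at lactate ≈ 93 g/L and biomass ≈ 15.4 g/L
(attainable ranges 0–98 and 0–16), and 36 h heterolactic batches from
46 g/L span lactate 0–23, acetate 0–19, biomass 0–16 g/L per the
cluster profile (rod and sphere profiles differ slightly, matching
their narrower reported ranges). Yields slightly exceed strict carbon
balance — the emulated ranges themselves do (98 g/L lactate from
100 g/L glucose, plus biomass), because they aggregate several real
fermentations; we take them as the ground truth the generator must span.

Integration is classic fixed-step RK4 at `dt = 0.05 h` (reproducibility
over adaptivity); a step-halving check bounds the error at ~3e-6 g/L,
far below the 1e-3 g/L tolerance.

## 2. Calibration design

States for calibration are sampled from 9–16 simulated batches with
±20% parameter jitter (initial glucose −20 %/+25 %, emulating medium
batch variation), at equally spaced time points. This preserves the
strong substrate–product correlation of real broths (design correlation
S vs P_L ≈ −0.95) — mixtures of pure compounds cannot emulate a
fermentation matrix, and the calibration must inherit that collinearity
to be realistic. Coverage below 90% of an analyte's attainable range is
warned about, not fixed silently.

## 3. Reference assays

Gaussian, unbiased, analyte-wise noise: 1.0 g/L for the HPLC analytes
and 0.8 g/L for dry-weight biomass (much larger relative to its 0–16
range, reflecting the notoriously poor reproducibility of dry-weight
measurements). **Design decision:** measurements are *not* clipped at
zero. Clipping a constant-sd noise at zero biases the low-concentration
end upward (≈ +0.5 g/L at inoculum states), which measurably tilts the
biomass calibration and propagated into a systematic −6% offset in the
closed-loop turbidostat during development. Real blank-subtracted
gravimetric and chromatographic readings can legitimately be slightly
negative; unbiasedness wins.

## 4. Spectra model

Effective-path Beer–Lambert mixing of Gaussian band libraries:

* analyte bands only inside 1625–1800 nm and 2200–2300 nm (C–H
  overtones; –COOH/–OH combination bands); heights ≤ 0.015 AU·L/(g·mm);
* water: strong bands at 1450 nm and **1940 nm** plus an elevated
  1850–2050 nm continuum. (Conventionally the O–H combination band sits
  near 1940 nm; a description placing it "around 1600 nm" was not
  followed — physics wins, flagged rather than harmonized.)
* biomass: a $1/\lambda$ scattering offset proportional to
  concentration plus a weak broad chromophore, so biomass is learnable
  by regression;
* bubble baseline
  $b(\lambda)=k_{rpm}\,(rpm/1000)\,(1+k_q q)\,e^{-X/7}\,(1000/\lambda)$:
  stirring dominates airflow, and cell scattering hides the bubbles at
  high biomass. **Scope decision:** the bubble term applies only to the
  immersion (transflectance) geometries. The 19-filter analyzer reads an
  external flow-cell loop fed by a peristaltic pump; bubble artifacts are
  an in-situ probe phenomenon.
* photometric noise 3e-4 AU (filter analyzer) / 5e-4 AU (scanning
  probe); saturation above 4 AU via the smooth compressive map
  $4+\kappa(1-e^{-(A-4)/\kappa})$, $\kappa=0.5$ AU, with pre-saturation
  channels flagged and masked from calibration.

The 19 filter wavelengths are evenly spaced over 1445–2348 nm
(overridable); full-spectrum grids use 2 nm steps. The four-component
analyte matrix on the full grid has condition number ≈ 3.8 (column
normalized), so the mixture is identifiable. There is no fouling drift
by construction, matching the no-drift finding for the probe window.

## 5. Chemometrics

* **Norris derivative**: segment-5 moving average then gap-5 second
  difference; annihilates constant and linear baselines exactly, maps a
  quadratic $c\lambda^2$ to $2c(gh)^2$. Parameters are conventional
  defaults (the method, not its parameters, was prescribed).
* **Screening**: PCA to 99% variance, Mahalanobis distance in score
  space standardized per component (GH = MD²/k). Flag at GH > 3 — the
  chemometric "3σ" convention; the 95% χ²(k) quantile is reported as a
  diagnostic, resolving the dual "3σ / 95%" phrasing. Single pass, no
  iteration. Screening removing > 20% of samples aborts the build.
* **MLR** (on-line route): OLS with intercept on all 19 filter
  channels; under-determined or rank-deficient designs are refused, not
  pseudo-inverted. Whether a channel subset should be used was an open
  question; all-19 is the default and configurable by masking.
* **PLS1 (NIPALS)** (in-line route): centered X and y, weight/score/
  loading extraction with deflation; factor count by leave-one-out
  PRESS with true refits (k-fold selectable), smallest factor count at
  a numerically tied minimum (parsimony; ties at machine noise occur on
  noiseless synthetic matrices).
* **Statistics**: bias, RMSEC/RMSEP, bias-corrected SEP
  ($\sqrt{\sum(e_i-\bar e)^2/(n-1)}$), SEC with $n-p-1$ degrees of
  freedom ($p=19$ for MLR, factor count for PLS), SECV
  ($\sqrt{PRESS/n}$), R² as squared Pearson correlation; paired
  NIR-vs-lab Student's t with explicit zero-variance edge handling.
* **Deployment gate**: a model is only used for reporting/control after
  its external validation passes the paired t test at the 1% level;
  failing models are rebuilt from a fresh campaign (new derived seed).
  This mirrors the study protocol, where validations were checked for
  significance before the calibrated system was trusted.

## 6. Closed-loop control

The controller observes only NIR predictions (plus the physical volume,
which the reactor's weight-control system measures). Continuous modes
use PI adjustment of the dilution rate (the original work says flow
"was modulated" without naming a law):

* turbidostat: predicted biomass above setpoint → more dilution
  (Kp = 0.05, Ki = 0.04 per g/L);
* chemostat: predicted glucose below setpoint → more dilution
  (Kp = 0.02, Ki = 0.03), anti-windup on the D ≥ 0 clamp;
* predictions are smoothed by an EWMA (weight 0.3) before the PI error.
  Without it, per-spectrum prediction noise (~0.4–0.6 g/L through the
  filter MLR) dithers the dilution rate, and because washout is faster
  than regrowth the dither rectifies into a steady offset *below* the
  biomass setpoint. With a noise-free sensor the filter only adds lag,
  so the zero-noise convergence property is tested at `ewma = 1`.

Spectra are acquired every 0.25 h (the "preset time interval" was
unspecified). Repeated-batch, repeated fed-batch and the
microfiltration state machine (IDLE → FILTERING on predicted lactate ≥ B
→ DISCHARGING on predicted biomass ≥ A, to volume D → REFILLING to C →
IDLE) follow the narrative event order exactly; filtration retains
cells (dX/dt gains +Xf/V) while the permeate carries solutes at broth
concentration. Refills are fast ramps (≤ 0.1 h equivalent). Steady
state is declared when every monitored concentration stays within a
relative tolerance of its window mean for two residence times; for
NIR-feedback runs a 10% band matched to the sensor noise is used. The
first turbidostat phase is run for 30 h — long enough for the lagged,
filtered loop to settle before its steady window is averaged (the
original two-setpoint experiment does not state phase lengths). Whether
repeated fed-batch cycles converge to a cycle-independent state is
physiology we do not model; the cycle-end states are reported as a
diagnostic, not asserted.

## 7. What the synthetic world does and does not establish

The generator emulates: trajectory-correlated composition, two
instrument geometries, water-dominated spectra, reference-assay noise
with a noisy dry-weight channel, bubble/stirring artifacts, saturation.
It does **not** emulate: real radiative transfer (Mie scattering,
specular effects), temperature effects on water bands, instrument line
shapes, membrane fouling dynamics, pH/O₂ dynamics, or CO₂ (unmeasured
in the emulated study). Published error figures for real broths are
therefore treated as *upper bounds* for the synthetic scenario: default
noise yields roughly 25–80% of those bounds (e.g. glucose transfer SEP
averages ~75% of its 1.83 g/L bound with seed-to-seed spread of
±0.5 g/L). A green acceptance run shows the pipeline reproduces the
structure and accuracy ordering of the original workflow, not its exact
numbers, which depended on unavailable physical broths.

## 8. Numerical choices

* All randomness flows from one root seed split per stage by an FNV-1a
  hash (`seed_split`); reruns are bitwise identical.
* PLS deflation stops when the residual covariance norm drops below
  1e-12; requested factor counts beyond the effective rank return the
  rank's coefficients.
* PRESS ties are broken toward fewer factors at relative tolerance 1e-8.
* Model JSON is written with 17 significant digits, which round-trips
  IEEE doubles exactly.
* The Norris derivative output grid drops `gap + (segment-1)/2` points
  per edge and carries the trimmed grid as an attribute; saturated
  channels are masked together with every derivative channel whose
  window touches them.
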
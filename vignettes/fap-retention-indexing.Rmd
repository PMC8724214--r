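---
title: "FAP retention indexing and SIM annotation of phytosterols: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FAP retention indexing and SIM annotation of phytosterols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sterolri)
```

`sterolri` implements a GC/EI-MS workflow for silylated phytosterols and
pentacyclic triterpene alcohols in vegetable oils: a retention-index scale
anchored on fatty acid pyrrolidide (FAP) internal standards, retention time
locking (RTL), a diagnostic-ion rule engine with a four-level assignment
scheme, SIM time-window scheduling under an ion budget, and semi-quantitative
TIC composition reporting. This vignette explains the underlying models,
the tunable parameters, and the design choices made where the design was
genuinely open. A synthetic-chromatogram generator with known ground truth
backs all of it with testable end-to-end round trips.

## The FAP retention index

Conventional sterol reporting uses retention times relative to a single
internal standard (RRT vs 5α-cholestane). RRTs drift with column aging,
trimming and pressure changes because a single reference cannot absorb
non-uniform changes of the time axis. The FAP index replaces the single
reference with a homologue ladder: pyrrolidides of saturated fatty acids
(18:0-P … 25:0-P in the routine mix, 26:0-P optional) that elute throughout
the sterol window and are detected by their two dominant fragment ions,
*m/z* 113 and 126, which are essentially absent from silylated sterol
spectra.

For a compound eluting at time $t$ between the pyrrolidides with $n$ and
$N = n+1$ carbon atoms, the linear temperature-programmed index is

$$\mathrm{RI} = 100\left[n + \frac{t - t(n)}{t(N) - t(n)}\right],$$

so the index is exactly $100\,n$ at each anchor. Two properties matter and
are enforced by property-style tests:

* **Affine invariance.** Any affine transform of the time axis applied to
  both the analyte and the anchors leaves the index unchanged. This is the
  mechanism behind the scale's stability: uniform drift (e.g. a pressure
  offset) cancels exactly.
* **Exact invertibility.** `invert_ri_fap()` is the algebraic inverse of
  `compute_ri_fap()` on the same ladder (round trip to 1e-9 minutes); the
  generator uses it to place synthetic peaks.

Because real run-to-run fluctuations are on the order of one index unit,
indices are *reported* as whole numbers (`ri_report()`, round-half-up);
internal computations keep full precision. When an analyte elutes past the
top anchor the engine raises an error that suggests extending the ladder
with 26:0-P rather than extrapolating.

## Retention time locking

RTL fixes the retention time of 24:0-P at 32.972 min by adjusting inlet
pressure. The calibration measures the lock compound at the nominal
pressure and at ±10% and ±20% deviations, and fits retention time as a
quadratic in pressure. The true pressure dependence is closer to
$t(p) = a + b/p$ (holdup-time physics); a quadratic fitted on the five-point
grid carries a least-squares residual of several hundredths of a minute at
realistic $b$, so a root of the quadratic alone can miss the target by
~0.006 min. The solver therefore supports a *verification run*: when given a
measurement function it corrects the solved pressure with the calibration
slope first and secant updates afterwards (default up to 4 corrections),
which is how locking is verified in practice after maintenance. With
verification the lock lands within a few 1e-5 min of the target; the
package's acceptance tolerance for the restored anchor is 0.005 min.
Targets outside the calibrated retention-time envelope are refused
(extrapolation error) — the practical counterpart is to avoid column-length
changes larger than about one metre between relocks.

## TMS masses and the molecular-ion grid

A sterol with $n$ skeletal carbons and $d$ double-bond equivalents beyond
the tetracyclic core has the TMS-ether composition
$\mathrm{C}_{n+3}\mathrm{H}_{2n+2-2d}\mathrm{OSi}$. Extra rings — the
cyclopropane of cycloartane-type sterols, the fifth ring of amyrins and
lupeol — are isobaric with double bonds and count as DB-equivalents.
`tms_molecular_mz()` returns the exact monoisotopic mass rounded half-up to
one decimal (unit-resolution quadrupole convention). The published
acquisition grid (`molecular_ion_grid()`, 5 carbon numbers × 4 saturation
levels = 20 ions) equals the computed values except that the two most
unsaturated C31 entries are carried at the published setpoints 512.5 and
510.5 — 0.1 u above the rounded monoisotopic masses (512.4, 510.4). No
deterministic rounding of the exact mass reproduces the published C31
column (identical fractional parts print differently elsewhere in the
grid), so these two values are stored as acquisition setpoints, exactly as
the 32.972-min lock target is stored verbatim. A SIM quadrupole window is
wide enough (the package matches *m/z* within ±0.3 u) that the 0.1 u offset
has no practical effect.

## Diagnostic fragments and classification rules

The rule table maps structural classes to EI diagnostics of the silylated
compounds:

| class | diagnostics |
|---|---|
| stanol (saturated) | base peak *m/z* 215 |
| Δ5-sterol | base peak *m/z* 129; *m/z* 213, 255 |
| Δ7-sterol | *m/z* 213, 255 without the 129 base |
| Δ5,7- / Δ5,8-sterol | *m/z* 211, 253 |
| Δ5 with side-chain DB at C-24 | adds *m/z* 296 ([M−84−TMSOH]⁺) |
| pentacyclic, Δ12 (amyrins) | *m/z* 218 > 189 (retro-Diels–Alder) |
| pentacyclic, Δ13 / lupeol | *m/z* 189 > 218 |

In 4-methyl- and 4,4-dimethylsterols a 14-methyl or 4-methyl substituent
weakens the ring diagnostics up to complete suppression; 4-methyl ring ions
are additionally shifted by +14 u (213 → 227, 255 → 269). The shifted ions
are computed and catalogued but not placed in the default SIM ion set — the
silyl ion *m/z* 129 and the molecular ion carry those classes, which is why
their assignments lean more heavily on the retention index.

`classify_peak()` applies the table with a fixed precedence (stanol base →
Δ5,7/Δ5,8 pair → Δ5 base → Δ7 pair) and raises the pentacyclic reading as a
*separate hypothesis* whenever the 189/218 pair is present. One
chromatographic peak can therefore legitimately yield several annotations:
distinct molecular ions at one retention time (full co-elutions such as the
C31 unknown over gramisterol), or one shared molecular ion with both a
tetracyclic and a pentacyclic signature (cycloartenol over lupeol). In
library matching, stanol and pentacyclic signatures are *binding*
constraints while Δ-position readings only rank candidates — precisely
because the weakened classes cannot express them reliably.

## The isotope interference check

A prominent [M−15]⁺ (methyl loss) ion puts its one-¹³C satellite at the
nominal mass [M−14]⁺, which is isobaric with the molecular ion of a sterol
with one carbon atom less. The expected satellite ratio follows the
binomial isotope model: for a fragment with $k$ carbons the one-¹³C to
monoisotopic ratio is exactly $k\,p/(1-p)$ with $p = 0.0107$. Si, H and O
isotopes are ignored (the ¹³C term dominates at these fragment sizes); the
fragment carbon count for a candidate with carbon number $n$ is $n+2$
($n+3$ TMS carbons minus the lost methyl). An observed ratio within ±30%
(relative, configurable — EI intensity reproducibility on a single
quadrupole) of the expectation means the signal is the satellite; an excess
flags a genuine co-eluting one-carbon-smaller sterol. The annotator also
uses this logic in reverse: molecular-ion candidates whose intensity is
fully explained as a satellite of a heavier candidate are removed before
matching. When [M−15]⁺ is not observed (e.g. pure SIM data without that
ion) the check is recorded as inconclusive, never as a failure.

## SIM scheduling under an ion budget

About 15–18 ions can be monitored simultaneously without degrading cycle
rate; the builders default to a budget of 17. `build_initial_methods()`
reproduces the two complementary discovery methods (C28+C29 molecular ions
in one run; C27, C30, C31 split over three time windows in the other, with
C27 only early and C31 only late, since sterol-TMS retention increases with
carbon number). `build_time_windows()` merges them into one method:
boundaries snap to multiples of 100 index units (2100–2500 for the built-in
library, four windows), each window carries the retention-independent
fragment set plus the molecular-ion grids of the carbon groups whose
elution span (±2 index units safety margin) intersects it.

Where the budget binds, ions are released in a documented order: first the
FAP ion 126.0 (113.0 alone anchors the ladder and is never dropped), then
the grids of groups only partially overlapping the window are restricted to
the (carbon, DB) combinations detected anywhere in the library — starting
with the group with fewest in-window compounds — then, if still necessary,
to in-window combinations. On the built-in library this reduction
reproduces the published third window exactly: the lone C31 molecular ion
512.5 enters by substitution of grid ions of never-detected compositions
(496.4, 502.5), the full C29 grid survives, and the amyrin pair 189.2/218.3
is scheduled only here. Two deliberate divergences from the published
method: window 2 keeps the full C28+C29 grids (the published method dropped
two ions although its budget did not require it — the builder only reduces
under pressure), and window 2's fragment list is inherited from window 1
(the published table prints none; the inheritance is flagged in the
method's note attribute). `validate_schedule()` checks per-compound
molecular-ion coverage, per-window budgets, and whether the [M−14]⁺
comparison is observable in each compound's window.

## Annotation levels and composition

Levels follow the four-tier convention: (1) verified against an authentic
standard, (2) major compound unequivocally verified by GC/MS and literature
data, (3) tentative assignment, (4) unknown. `assign_level()` grants level 1
only to standard-flagged library matches with complete, uncontradicted
diagnostics; library entries that are themselves tentative literature
structures cap at level 3; entries without structural assignment are
level 4. The "major" threshold for level 2 defaults to 0.1% of the summed
sterol TIC: the reference compositions assign level 2 down to ~0.2% shares,
so a larger threshold would contradict the very assignments the engine is
meant to reproduce. Two molecular-ion floors govern co-elution resolution:
a candidate must reach 0.5% of the peak's top ion (sub-percent minors such
as lanosterol under a dominant Δ5-sterol are resolvable in SIM, and the
reference data include exactly such cases), and diagnostic ions count as
present above the same floor.

Composition reporting is deliberately semi-quantitative: equal response
factors are assumed, so percentages describe each compound's share of the
summed sterol TIC, not a true quantitative composition. Shared peak areas
of co-eluting annotations are apportioned by least-squares deconvolution of
the observed ions against the candidates' expected spectra; the
apportioning conserves the peak area exactly and is scale-invariant.
Display formatting follows the reference granularity (one decimal at ≥1%,
1–2 significant digits below) with values under 0.02% shown as traces
("tr") — 0.02 is the smallest value the reference table prints.

## The synthetic-data generator

`generate_run()` emulates exactly the statistical structure the method
relies on: a FAP ladder whose anchors are placed from the printed relative
retention times with 24:0-P at 32.972 min; the 5α-cholestane internal
standard; sterol peaks at times obtained by inverting each compound's true
index on the ladder; per-peak spectra assembled from the rule table's ion
sets with exact binomial ¹³C satellites; Gaussian peak parameters (default
σ = 1.5 s) and multiplicative log-normal intensity noise (default 5%
relative; the validation round trips use 0). Compounds whose true indices
agree within 0.5 units co-elute into one peak with summed ion intensities —
on the built-in library this merges exactly the documented co-elution
pairs. Every run carries a ground-truth sidecar (compound, index, time,
area, class); all round-trip tests read truth only from the sidecar.

The four built-in oil profiles encode the reference compositions of
rapeseed, hemp, corn and sunflower oil. Cells lost in transcription of the
reference table were reconstructed so that each oil closes to exactly 100%
— the closure is absorbed by a dominant or plausibly-sized compound of the
affected oil (β-sitosterol for corn and sunflower, lanosterol for hemp,
Δ5-avenasterol for rapeseed), trace entries are encoded as 0.01%, and every
reconstructed cell is marked in the source. The relative fragment
intensities of the generated spectra are plausible class-typical values,
not measured ones; they are never used as ground truth — identity,
retention index, class and area are, via the sidecar.

The instrument model behind the drift studies composes three effects:
a global pressure factor $f(p) = \gamma + (1-\gamma)/p$ (γ = 0.12), a
global column-state scale (aging, trimming), and a smooth unevenness term
evaluated at the *actual* elution time,
$t = u\,f(p)\,s\,(1 - \delta\,h(t))$ with $h$ a 12-min-period sinusoid.
Evaluating $h$ at the actual time is the essential modelling choice: it
encodes that retention depends on the elution temperature under a fixed
oven program, so restoring absolute times (locking) also restores the
selectivity pattern, while an unlocked, trimmed column samples $h$ at
shifted times and its indices move unevenly — some up, some down. A trim of
1.5 m from a 30 m column (5% scale) with warp amplitude 0.02 produces
unlocked index shifts of one to a few units, matching the magnitude of
shifts reported for trimmed columns, while locked runs stay within the
measurement jitter (0.0005 min). `simulate_drift_series()` (default 25
runs, slow aging plus a mid-series trim event) quantifies this as
per-compound dispersion; under the column-trim model the locked IQR is
below the unlocked IQR for every library compound, comfortably clearing
the ≥90% property the package asserts.

## Numerical choices and degenerate inputs

* *m/z* values are carried at one decimal and matched within ±0.3 u.
* Peak ordering is total and deterministic (time, then descending area,
  then lowest *m/z*), so all outputs are permutation-invariant.
* A retention time exactly on an anchor is assigned to the lower bracket
  (the index is identical either way).
* Degenerate RTL calibrations (no pressure response) and non-monotone
  calibrations are flagged; five points with distinct pressures on the
  nominal ±20% grid are required.
* Empty chromatograms annotate to empty tables; an all-zero composition is
  an explicit error rather than NaNs.
* All randomness (intensity noise, jitter, drift series) is seeded;
  identical seeds give byte-identical peak tables.

## Problem sizes used in the shipped validation

The shipped test suite and acceptance script run entirely on synthetic
data: four noise-free oil runs (24–32 peaks each) for the end-to-end round
trip, 25-run drift series for the locking study, and 50-draw randomized
ladders for the inversion properties. These sizes were chosen as the
smallest that exercise every co-elution case and give stable dispersion
statistics.

## Known limitations

* No vendor raw-file ingestion: the documented flat peak table (and an
  mzML-to-peak-table conversion as an external step) is the interface.
* The EI model predicts which diagnostic ions appear, not true fragment
  intensities; intensity hints are categorical (strong/weak).
* Carrier-gas physics is first-order only; the pressure factor is global,
  so the synthetic instrument cannot express pressure-dependent selectivity
  changes.
* Equal-response quantification; no response-factor calibration.
* The [M−14]⁺ check needs the [M−15]⁺ ion, so it is inconclusive on pure
  SIM data unless that ion is scheduled.
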
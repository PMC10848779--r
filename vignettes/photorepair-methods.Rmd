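---
title: "Photokinetics of CPD self-repair: models, calibration and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photokinetics of CPD self-repair: models, calibration and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photorepair)
```

This vignette is the package's own account of the science it implements:
the forward photokinetic model and its assumptions, the inverse analyses,
what the synthetic-data generator does and does not emulate, and the
numerical and design choices that were genuinely open.

## The system

A damaged DNA tetranucleotide (T\<\>TAG or GAT\<\>T, `<>` marking a
cyclobutane pyrimidine dimer between the two thymines) is irradiated in
aqueous solution with an LED centered at 285 nm. At that wavelength the
purine bases absorb; the excited guanine can launch a sequential electron
transfer down the stack that splits the cyclobutane ring, regenerating
the undamaged sequence. The competing photoreaction — UV-induced
re-dimerization of the repaired TT step — runs in the opposite direction,
so prolonged irradiation drives the mixture to a photostationary state
(PSS). The observables are the absorbance recovery at a 266 nm probe
(thymine absorption reappears when the dimer splits), HPLC peak areas,
and, on the computational side, stacking geometries and excited-state
energy levels.

## Forward model

**Photon bookkeeping.** A beam is a normalized emission density
$s(\lambda)$ (nm$^{-1}$) and a power $P$ (W); its photon flux density is
$q(\lambda) = P\,s(\lambda)\,\lambda/(hc)$ (photons s$^{-1}$ nm$^{-1}$),
so that $\int q\,hc/\lambda\,d\lambda = P$ identically — this energy
closure is property-tested to $10^{-6}$ relative. Species absorbances
$A_i(\lambda)=\varepsilon_i c_i l$ partition the absorbed photons:
$$R_i = \int q(\lambda)\,\bigl(1-10^{-A_{tot}}\bigr)\,
  \frac{A_i}{A_{tot}}\,d\lambda ,$$
evaluated by the series $\ln(10)A_i(1-\tfrac{\ln 10}{2}A_{tot})$ wherever
$A_{tot}<10^{-6}$ to avoid 0/0. The absorbed *energy* rate (the J axis of
dose–response data) integrates the same expression against
$hc/\lambda$; dose is defined as cumulative energy absorbed by the whole
sample, with per-species photon counts tracked separately for
quantum-yield attribution.

**Kinetics.** Quantum yields are treated as scalars over the LED band
(per photon absorbed by the whole oligomer — see *Open choices*), giving
$$\frac{dc_{rep}}{dt} = \frac{\Phi_{rep}R_{dam} -
  (\Phi_{dam}+\Phi_{side})R_{rep}}{N_A V}.$$
The side channel (secondary photoproducts of the repaired strand) is off
by default; with it off the oligomer pool is conserved exactly, and the
suite checks conservation to $10^{-9}$ M. Integration uses
`deSolve::lsoda` with relative tolerance $10^{-8}$ and absolute tolerance
$10^{-12}$ M — stiff-capable, though the system is only mildly stiff.

**Photostationary state.** Optically thin, the PSS repaired fraction has
the closed form
$f_{pss} = \Phi_{rep}\bar\varepsilon_D /(\Phi_{rep}\bar\varepsilon_D +
\Phi_{dam}\bar\varepsilon_R)$ with photon-weighted effective
coefficients. The `ode_limit` mode instead integrates until the fraction
stops changing with dose; the two agree within 1% for peak absorbances
below about 0.05, and the limit is independent of the starting
composition (tested to $10^{-4}$ from both pure-damaged and
pure-repaired starts). With an irreversible side channel a stationary
state does not exist and the solver refuses.

## Inverse analyses

**Quantum yield from the initial slope.** At zero dose every absorbed
photon is absorbed by the damaged species, so the slope $s$ of
$\Delta A_{266}$ versus absorbed dose (OD/J) converts exactly as
$$\Phi = s\,\frac{V N_A \bar E_{ph}}{\Delta\varepsilon_{266}\, l},$$
with $\bar E_{ph}$ the mean energy of an absorbed photon (computed from
the spectra at $t=0$; a monochromatic 285 nm treatment differs by well
under 0.5% for the 15 nm band and is available as an option). The slope
comes from ordinary least squares with a free intercept — robust to
baseline offsets in difference spectra — over a linear range selected as
the longest prefix (at least 4 points) whose quadratic-fit curvature term
is statistically indistinguishable from zero (t-test, $\alpha=0.05$),
never extending beyond 25% of the estimated plateau response. Two
degenerate regimes need explicit handling:

* *Noiseless data.* With zero residual noise the curvature t-test is
  infinitely powerful, so any real curvature is "significant" and the
  selector falls back to the first four points (flagged). This is the
  honest behavior of a significance test at $\sigma\to 0$; exactly linear
  data are recognized by a numerically-zero curvature branch and keep the
  full range.
* *Pure noise.* A trend test precedes the curvature test: if the fitted
  rise over the full span is below three residual standard deviations,
  the response is declared indistinguishable from noise and the 4-point
  fallback (with warning flag) is used.

A negative fitted slope yields $\Phi = 0$ with a "net damage regime"
flag. The reported uncertainty is the field's 40% rule,
$0.40\times\Phi$; applied to yields of 0.58% and 0.44% it reproduces the
familiar $\pm 0.23$ and $\pm 0.18$ after two-decimal rounding.

**Plateau fit.** `fit_pss_approach()` fits
$f(D) = f_{pss}(1-e^{-D/D_0})$ by Levenberg–Marquardt least squares and
reports the dose to equilibrium as $-D_0\ln(0.05)$ — "equilibrium" is
operationalized as the dose at which the fraction first comes within 5%
(relative) of its plateau, since no universal convention exists. The fit
refuses data that do not span at least 80% of the apparent plateau. Note
the saturating exponential is itself an approximation in the dose domain:
because the repaired species absorbs more at 285 nm than the damaged one,
the absorbed-power rate grows as repair proceeds, so the exact
fraction–dose curve is slightly steeper early and flatter late than any
single exponential. At the default conditions this biases the fitted
plateau by under 1%; the tests pin the plateau with runs extending to
5–10 characteristic doses.

## The synthetic-data generator

The generator is first-class code: it emulates the study conditions so
every analysis stage can be validated by parameter recovery, with the
noiseless truth always emitted beside the noisy observables and full
reproducibility from one seed.

* **Conditions taken from the study:** 30 μM damaged oligomer; LED
  centered at 285 nm, 15 nm FWHM (Gaussian, truncated at $\pm 3\sigma$,
  renormalized), 0.36 mW at the sample; 1 cm path; exposures in 1-min
  steps to 10 min; probe noise 1 mOD (homoscedastic Gaussian on each
  absorbance point); repair quantum yields 0.58% (TTAG) and 0.44%
  (GATT); PSS plateaus 40% and 33%, enforced by calibrating
  $\Phi_{dam}$ so the analytic PSS equals the target — the damage yield
  itself is not separately reported, so this calibration is the natural
  closure.
* **Fixture choices (not study values), fixed once:** the damaged-species
  absorption is a single Gaussian band, center 256 nm, peak
  15000 M$^{-1}$cm$^{-1}$, $\sigma = 16.7$ nm — two purines with a
  CPD-containing, hypochromic stack, leaving $\varepsilon(285)\approx
  3.3\times10^3$ so the LED excites the purine red edge. The repaired
  spectrum adds a thymine-recovery difference band (Gaussian at 266 nm,
  $\sigma = 9$ nm) scaled so the probe contrast equals the configured
  $\Delta\varepsilon_{266}$ exactly; the default contrast of
  16000 M$^{-1}$cm$^{-1}$ per oligomer is a synthetic stand-in for
  literature coefficients that are not reproduced here, and is a
  required, configurable input of the extraction. The illuminated volume
  defaults to 1.0 mL: with the other conditions fixed this reproduces
  the observed dose-to-equilibrium scale (~2.6 J TTAG, ~2.8 J GATT,
  against the reported 2.5 and 3.5 J) — the volume is otherwise
  unreported and all dose computations expose it as a parameter.
* **What it does not emulate:** wavelength-correlated noise, detector or
  baseline drift, pH effects, distinct photoproduct spectra (the side
  channel is generic and transparent by default), fluorescence
  re-emission, or cuvette geometry beyond Beer–Lambert attenuation.
  Passing the recovery tests therefore demonstrates estimator
  correctness under the stated noise model, not robustness to every
  artifact of real spectrometers.

Chromatograms are synthesized per exposure from the true composition:
Gaussian peaks at 8.4 min (damaged) and 9.9 min (repaired),
$\sigma = 0.12$ min, equal response factors by default (the two
tetramers share base composition; CPD hypochromicity at the detection
wavelength can be set via the response factors), amplitude noise 1% of
the largest pure-peak amplitude, optional linear baseline drift.
Quantification fits a linear baseline to peak-free regions, accepts
peaks as local maxima above $5\times$ the noise MAD, fits a Gaussian per
peak and integrates the corrected trace over $\pm 3\sigma$; the
round-trip composition error stays within $\pm 0.02$ at 1% noise.

For the structural module the generator builds idealized stacked A/G
pairs: planar fused-ring purines (regular-polygon geometry, 1.39 Å
bonds), 3.4 Å rise, 36° twist, about 1 Å slide, glycosidic atoms placed
by Z-matrix construction to realize per-class χ centers (anti −120°,
syn +60°) with Gaussian angular noise. These are fixtures with labeled
truth, not conformational ensembles of real tetranucleotides.

## Geometry operators

The glycosidic torsion uses the standard convention
(O4′–C1′–N9–C4 for purines, O4′–C1′–N1–C2 for pyrimidines), signed per
IUPAC and verified against an independent torsion implementation;
*syn* is $\chi \in (-90°, +90°]$ and *anti* the complementary
half-circle, a total partition with documented boundary assignment.
Stacking overlap projects both ring systems onto the least-squares plane
of one base and sums the pairwise convex intersections of the ring
polygons — the fused six- and five-membered rings share only an edge, so
the pairwise sum equals the union overlap exactly, and the per-ring
components are reported because six-ring/six-ring overlap carries the
mechanistic weight. The result is symmetrized by averaging the
projections onto either base's plane (the two differ by the relative
tilt; the average is symmetric by construction and agrees with
Monte-Carlo point-sampling within 2%). Collinear ring atoms are a hard
error. All outputs are invariant under joint rigid motion to numerical
precision.

## Energy-ladder datasets

The packaged ladders transcribe the ADC(2)-level excited-state
energetics of the stacked conformers: vertical states (energy,
oscillator strength, wavelength — consistency enforced to 0.5 nm via
$\lambda = 1239.84198/E$) and stationary points (S$_1$ minima and
S$_1$/S$_0$ MECPs). Absolute energies are stored only where an anchor was
reported (the TTAG AG-*anti* ladder, anchored at the 4.27 eV G* minimum;
derived entries are provenance-tagged as derived, never as reported).
The GATT conformer ladders carry signed gap records instead, and
`ladder_gap()` resolves any pair through a path-additive graph over
those records before falling back to energy differences — so transcribed
gaps are reproduced exactly and gap arithmetic is antisymmetric and
additive by construction. The CPD-splitting barrier is reported only as
a bound (<0.1 eV); the dataset stores a representative 0.05 eV gap,
tagged derived, and the channel classifier at its default 0.1 eV
threshold is insensitive to the exact value within the bound. Validation
reports (never throws) checks: exactly one Franck–Condon entry,
wavelength/energy consistency, positive energies, the crossing above the
CT minimum lying above the bright vertical state, and the downhill
ordering of the electron-transfer cascade.

## Open choices, problem sizes, limitations

* **Yield definition.** Φ is defined per photon absorbed by the whole
  oligomer, matching the experimental observable (dose is sample-level);
  defining it per G-absorbed photon would scale yields by the inverse of
  guanine's share of the oligomer absorption. The code exposes the
  spectra needed to convert.
* **Direct photoreversal** by TT absorption at 285 nm is not a separate
  channel; the experiment was designed to minimize it and any residue is
  absorbed into the effective repair yield.
* **Residual extraction bias.** At the default conditions the 1-min
  sampling leaves ~1% downward discretization bias in the noiseless
  initial-slope estimate (the 4-point fallback spans real curvature);
  with 1 mOD noise the full range is selected and the median bias over
  replicates is 2–3%, small against the 40% experimental uncertainty.
* **Problem sizes.** Recovery statistics use 200 noisy replicates per
  sequence (medians are reported; the spread is roughly 9% per
  replicate); long-dose fits use 25 exposures to five characteristic
  doses; Monte-Carlo overlap checks use $2\times 10^5$ points; ensemble
  censuses use up to 2000 frames. These sizes make the whole suite run
  in well under a minute of simulation time while leaving Monte-Carlo
  error comfortably inside every asserted tolerance.
* **Out of scope.** Molecular dynamics, excited-state electronic
  structure, global multi-wavelength spectral fitting beyond the 266 nm
  probe, retention-time prediction, and Marcus-rate modelling; the
  ladder datasets carry the printed energetics as data.
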
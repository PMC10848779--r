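# photorepair

Photokinetic analysis of UV-driven **self-repair of cyclobutane pyrimidine
dimers (CPDs)** in short DNA oligonucleotides.

CPDs are the most common UV photolesions in DNA. In specific short
sequences — the damaged tetranucleotides GAT<>T and T<>TAG, where `<>`
marks the dimerized TT — absorption of a ~285 nm photon by the purine
bases can trigger sequential electron transfer (G → A → T<>T) through the
base stack and split the cyclobutane ring, regenerating the undamaged
sequence without any enzyme. The package is aimed at photochemists and
origins-of-life researchers who quantify this process from steady-state
irradiation experiments: LED irradiation of a ~30 μM solution, the
absorbance recovery at the 266 nm probe, and HPLC controls.

## What it computes

**Forward model.** With per-wavelength photon flux
`q(λ) = P s(λ) λ / (hc)` and Beer–Lambert competitive absorption
`A_i = ε_i c_i l`, species *i* absorbs photons at
`R_i = ∫ q(λ) (1 − 10^(−A_tot)) A_i / A_tot dλ`, and the reversible
photoreaction evolves as

    dc_rep/dt = [Φ_rep R_dam − (Φ_dam + Φ_side) R_rep] / (N_A V)

with quantum yields Φ per absorbed photon. Under continuous irradiation
the composition approaches a photostationary state (PSS); optically thin,

    f_pss = Φ_rep ε̄_D / (Φ_rep ε̄_D + Φ_dam ε̄_R)

with photon-weighted effective coefficients ε̄.

**Inverse analysis.** `fit_quantum_yield()` recovers the repair quantum
yield from the initial slope *s* of ΔA₂₆₆ versus absorbed energy dose
(OD/J), via `Φ = s V N_A Ē_ph / (Δε₂₆₆ l)`, with an automatically
selected linear range and the field's 40% relative uncertainty rule.
`fit_pss_approach()` fits the saturating approach
`f(D) = f_pss (1 − e^(−D/D₀))` and reports the plateau and the dose to
equilibrium. Both return classed model objects with `print`, `summary`,
`coef`, `predict`, `residuals` and `plot` methods.

**Supporting modules.** HPLC-style chromatogram synthesis/quantification
(peaks at 8.4 min damaged / 9.9 min repaired); glycosidic torsion χ,
syn/anti classification, base-stacking overlap areas and conformer
censuses from (multi-model) PDB structures; validated excited-state
energy ladders for the sequential electron transfer mechanism with gap
arithmetic and channel-accessibility classification; and a
seed-reproducible synthetic-data generator that emulates the full
irradiation experiment so every stage is testable by parameter recovery.

## Worked example

Simulate a TTAG irradiation experiment (285 nm LED, 0.36 mW, 15 nm FWHM,
30 μM, 1-min exposures to 10 min, 1 mOD probe noise) and recover the
quantum yield:

```r
library(photorepair)
cfg <- scenario_config("TTAG", rng_seed = 1)
sim <- simulate_experiment(cfg)
recover_quantum_yield(sim)
#> Quantum-yield fit (initial-slope dose-response analysis)
#>   Phi = 0.62 % (+/- 0.25 %, 40% rule)
#>   slope = 0.2329 OD/J, intercept = -0.000208 OD, R^2 = 0.9574
#>   linear range: points 1-11 of 11
```

A single noisy replicate recovers 0.62% against the generating truth of
0.58%; the uncertainty is the 40% rule applied to the estimate. Extending
to a long-dose schedule and fitting the photostationary approach:

```r
cfgL <- with_long_dose_schedule(cfg, n_points = 25, multiple = 5)
simL <- simulate_experiment(cfgL)
fit_pss_approach(simL$dose_response, delta_eps_266 = cfgL$delta_eps_266,
                 c0_M = cfgL$c0_M)
#> Photostationary-state fit: f(D) = f_pss (1 - exp(-D/D0))
#>   plateau repair fraction = 40.1 %
#>   D0 = 0.975 J; dose to equilibrium (5% convention) = 2.92 J
```

At the photostationary state ~40% of the lesions are repaired, reached
after ~3 J of absorbed dose. The packaged TTAG energy ladder answers
mechanistic questions directly:

```r
lad <- load_set_ladder("ttag_ag_anti")
ladder_gap(lad, "G*", "MECP_G")            # +0.75 eV: direct G decay hindered
classify_channel(lad, "TT-AG+", "MECP_CPD") # "accessible": ring splitting easy
validate_ladder(lad)                        # all consistency checks pass
```

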
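# coraloptics

Tools for analysing the **optical feedback** mechanism in coral bleaching:
as corals lose their photosynthetic symbionts (*Symbiodinium*), the white
aragonite skeleton reflects progressively more light back through the
remaining pigments, so the survivors absorb more excess light per cell and
bleaching accelerates. How strongly this feedback engages depends on the
skeleton's *microscopic reduced scattering coefficient* μ′<sub>S,m</sub>
(mm⁻¹), which governs short-path light transport in the top ~100 µm of
skeleton. The package is aimed at coral ecophysiologists who collect PAM
chlorophyll fluorometry, diffuse reflectance spectra and pigment-density
time series in factorial heat/light stress experiments.

## What it implements

**Two-pass absorption model.** Incident light absorbed by symbiont pigments
is split into a first (downwelling) pass *I*<sub>a1</sub> and a
skeleton-dependent reflected pass *I*<sub>a2</sub>. With
*R*′ = *R*<sub>H</sub>/*R*<sub>S</sub> (holobiont over bare-skeleton
reflectance) the forward model is

    R_H = (R_S / β) (1 − I_a1)(1 − α I_a1)

and inversion takes the negative root of
α *I*² − (1+α) *I* + (1 − β*R*′) = 0:

    I_a1 = (1 + α − sqrt((1+α)² − 4α(1 − βR′))) / (2α)
    I_a2 = (1 − I_a1) ((α/β) I_a1 + γ (β−1)/β) R_S

α ≥ 1 amplifies absorption via path elongation, β = *R*<sub>S</sub>/*R*₁
and γ ∈ (0, 1] encode non-flatness and reentry. α = β = γ = 1 is a
conservative lower bound on *I*<sub>a2</sub> and the default analysis
setting. The per-pigment series *I*<sub>a2</sub>/ρ and the feedback rate
−Δ(*I*<sub>a2</sub>/ρ|<sub>HL</sub> − *I*<sub>a2</sub>/ρ|<sub>CL</sub>)/Δρ
quantify how fast remaining symbionts gain excess light as pigment ρ
declines; across species that rate is fit as an inverse power law in
μ′<sub>S,m</sub>.

**Photophysiology.** Fv/Fm = (Fm − F0)/Fm; steady-state induction-curve
partition Φ_PSII + Φ_NPQ + Φ_NO = 1; maximum excitation pressure
Q_m = 1 − Φ_PSII(peak)/(Fv/Fm at dawn).

**Bleaching-rate statistics.** Per-ramet temporal slopes (PE) of Fv/Fm or
Q_m; first-order Taylor-expansion differencing ΔPE across treatment cells
that cancels ramet-constant confounders, isolating light- or
temperature-dependent effects; species-level regression of ΔPE on
μ′<sub>S,m</sub>; clustered longitudinal group-rate models (random
intercept per colony via lme4, or cluster-robust OLS); marginal per-day and
baseline comparisons.

**Synthetic experiment generator.** A seeded simulator of the full
10-species × 4-treatment (CT/HT × CL/HL) × 8-ramet repeated-measures
design, with piecewise-linear yield trajectories, exponential pigment
decay, and holobiont reflectance produced through the forward optical
model — so every analysis stage can be validated against known ground
truth.

## Worked example

```r
library(coraloptics)
library(dplyr)

# invert one reflectance pair under lower-bound parameters
infer_absorption(r_h = 0.26, r_s = 0.71)
#>     r_h   r_s r_prime  i_a1  i_a2   i_a   r_1   a_2 flag
#> 1  0.26  0.71   0.366 0.395 0.170 0.565  0.71 0.395 ok

# simulate the default experiment and estimate group bleaching rates
cfg <- generator_config()
obs <- generate_experiment(cfg, seed = 1)
stress <- filter(as_tibble(obs), temperature == "HT", light == "HL")
clustered_rate_model(stress, "fvfm", profiles = cfg$profiles)
#> Clustered longitudinal model of `fvfm` (lmm engine, 10 colony clusters)
#>   group   slope       se         p
#> 1 low   -0.0324 0.000374 2.37e-322
#> 2 high  -0.0146 0.000305 6.38e-198
#> group x day interaction p = 7.498e-151

# feedback rates per species and the cross-species power law
fb <- feedback_by_species(obs, cfg$profiles)
fit_feedback_power_law(fb)
#> Inverse power law: y = 0.02092 * x^(-1.309)  (r2 = 0.903, n = 10)
```

The inversion says a holobiont at 26 % reflectance over a 71 %-reflective
skeleton absorbs 56.5 % of incident light, 17 percentage points of it
skeleton-derived. In the simulated stress experiment the low-scattering
group loses photochemical efficiency at −0.032 day⁻¹ versus −0.015 day⁻¹
for the high-scattering group, and the per-species feedback rates fall off
as roughly μ′<sub>S,m</sub><sup>−1.3</sup>.

The whole analysis can also be run end to end, with every stage exchanging
delimited-text artifacts:

```sh
Rscript scripts/run_pipeline.R --outdir out --seed 1
```

## Package layout

- `R/observations.R`, `R/optical-profiles.R` — tidy observation tables,
  schema validation, delimited IO, scattering-group classification
- `R/photophysiology.R` — PAM metrics
- `R/reflectance.R` — white-standard normalisation, band means, replicate
  statistics
- `R/absorption.R`, `R/feedback.R` — the two-pass model, inversion,
  feedback rates, power-law fits
- `R/rates.R`, `R/models.R` — PE slopes, ΔPE, clustered and marginal
  inference
- `R/generator.R` — the synthetic experiment
- `R/pipeline.R`, `R/plots.R` — orchestration and figures
- `vignettes/optical-feedback.Rmd` — the methods vignette
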
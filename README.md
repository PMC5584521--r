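# alkflux

Carbon and electron partitioning between methanogenesis and sulfate
reduction in anaerobic alkane-degrading cultures.

When a methanogenic enrichment degrades an n-alkane in the presence of
sulfate, the reducing equivalents can flow to two terminal sinks —
methane production or sulfate reduction. alkflux turns the routine
measurements of such incubations (cumulative headspace CH₄, remaining
sulfate, endpoint residual alkane, δ¹³C of CH₄ and CO₂) into a complete,
background-corrected partitioning analysis. It is written for
biogeochemists and bioprocess researchers running long-term anaerobic
hydrocarbon incubations, and for anyone who needs the underlying
stoichiometric bookkeeping on its own.

## What it computes

**Stoichiometry.** Complete oxidation of C<sub>n</sub>H<sub>2n+2</sub>
balances as

    CnH2n+2 + (n−1)/2 H2O        → (3n+1)/4 CH4 + (n−1)/4 CO2            (methanogenic)
    CnH2n+2 + (3n+1)/4 SO4²⁻
            + (3n+1)/2 H⁺        → (3n+1)/4 H2S + n CO2 + (n+1) H2O      (sulfidogenic)

Both pathways carry 6n+2 electron equivalents per mole (8 e⁻ per CH₄
formed or SO₄²⁻ reduced), so the shared coefficient Y = (3n+1)/4 — 12.25
for hexadecane — makes net methane produced (M) and net sulfate reduced
(S) directly comparable.

**Mass balance.** Background-corrected M and S; carbon recovery
100·(M+S)/(Y·Δhex); the electron-flow split 100·M/(M+S) vs 100·S/(M+S);
the alkane-normalised pathway contributions E_M and E_S (which sum to the
recovery); and the partition ratio S/M — all per replicate, then averaged.

**Kinetics.** The maximum specific methane production rate μ_max as the
rate constant k of a logistic fit y(t) = a/(1+exp(−k(t−t_c))) to the
cumulative methane curve (month⁻¹).

**Isotopes.** The apparent fractionation factor
α_app = (δ¹³CO₂+1000)/(δ¹³CH₄+1000), its plateau, and a coarse
classification of the dominant methanogenic pathway (thresholds 1.025 and
1.065).

**Sulfate response.** OLS regression of S/M on initial sulfate at each
sampling day, with a cross-day slope-stability summary.

**Synthetic experiments.** A seeded generator producing complete
observation tables with known partition slope, kinetics, recovery and
isotope behaviour, so every stage is testable end to end without external
data.

## Worked example

The package ships a plain-text table of endpoint treatment means from a
421-day hexadecane enrichment incubated at 0.5–25 mM initial sulfate:

```r
library(alkflux)

methanogenic_yields("C16H34")
#> Complete methanogenic oxidation of C16H34 (per mol alkane)
#>  species   mol     role
#>      CH4 12.25 produced
#>      CO2  3.75 produced
#>      H2O -7.50 consumed
#> electron equivalents: 98 mol e-/mol

m <- endpoint_means()
round(carbon_recovery(m$combined_ratio), 1)
#> [1]  91.7  82.1  89.7 101.0  96.9  98.0

fit <- fit_sm_regression(m$initial_sulfate_mM,
                         sm_ratio(m$methane_mmol, m$sulfate_consumed_mmol))
fit
#> Sulfate-response regression: S/M ~ initial sulfate
#>   slope     0.0855 (S/M) per mM (SE 0.0053, p = 8.33e-05)
#>   intercept -0.0337
#>   R-squared 0.985 over 6 points
```

The recovery column says 82–101% of the consumed hexadecane carbon is
accounted for by the combined stoichiometric equivalents of methane and
sulfate reduction. The regression says the partition ratio S/M rises by
about 0.09 per mM of initial sulfate, with the initial sulfate
concentration explaining 98.5% of the variance — sulfate sets the
partition. The pathway contributions make the shift explicit:

```r
round(pathway_contributions(m$methane_mmol, m$sulfate_consumed_mmol,
                            m$hexadecane_consumed_mmol), 1)
#>    E_M  E_S
#> 1 86.5  2.4     # 0.5 mM sulfate: almost purely methanogenic
#> ...
#> 6 31.4 65.8     # 25 mM sulfate: two-thirds sulfidogenic
```

And the isotope index for the low- vs high-sulfate groups:

```r
p <- isotope_plateaus()
round(alpha_app(p$d13co2_permil, p$d13ch4_permil), 3)
#> [1] 1.047 1.029
```

Both values sit in the intermediate band (1.025–1.065): a mixed
methanogenic pathway, shifted toward aceticlastic at high sulfate.

A full report (balance summary, contributions, per-day regression, α_app
table, kinetics, log) is produced by `run_report(obs, "results/")`, and a
synthetic experiment with known truth by
`generate_experiment(simulation_config(seed = 42))`.

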
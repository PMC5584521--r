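---
title: "Methods: carbon and electron partitioning between methanogenesis and sulfate reduction"
author: "alkflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: carbon and electron partitioning between methanogenesis and sulfate reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alkflux)
```

## The problem

When an anaerobic culture degrades an n-alkane in the presence of sulfate,
the reducing equivalents released by alkane oxidation can flow to two
terminal sinks: methanogenesis (CH~4~) or sulfate reduction (H~2~S). alkflux
quantifies how the carbon and electrons are split between the two, starting
from nothing more than the routine measurements of such incubations —
cumulative headspace methane, remaining sulfate, residual alkane at the end
of the run, and optionally the δ^13^C of headspace CH~4~ and CO~2~.

## Stoichiometric backbone

Complete oxidation of a saturated alkane C~n~H~2n+2~ balances, without a
biomass term, as

$$\mathrm{C_nH_{2n+2} + \tfrac{n-1}{2}\,H_2O \rightarrow
  \tfrac{3n+1}{4}\,CH_4 + \tfrac{n-1}{4}\,CO_2}$$

under methanogenic conditions, and as

$$\mathrm{C_nH_{2n+2} + \tfrac{3n+1}{4}\,SO_4^{2-} + \tfrac{3n+1}{2}\,H^+
  \rightarrow \tfrac{3n+1}{4}\,H_2S + n\,CO_2 + (n+1)\,H_2O}$$

with sulfate as the electron acceptor. Both pathways transfer $6n+2$
electron equivalents per mole of alkane, at 8 e^−^ per CH~4~ formed or
SO~4~^2−^ reduced, so the shared coefficient $Y = (3n+1)/4$ — 12.25 for
hexadecane — makes moles of methane produced and moles of sulfate reduced
directly comparable currencies. Every coefficient is a multiple of 1/4, so
the package carries them as integer numerators over a fixed denominator and
verifies the C, H, O, S and charge balances in integer arithmetic
(`element_balance()`); the closed forms are additionally cross-checked in
the test suite against an independent linear-algebra element-balance solver
for chain lengths 1–40. Only saturated acyclic alkanes are accepted; other
hydrocarbons are rejected rather than silently computed, because the closed
forms above are specific to the 2n+2 hydrogen rule.

## Mass balance and the two percentage accountings

Net methane $M$ and net sulfate reduced $S$ are endpoint measurements minus
the turnover of substrate-free control cultures (defaults 0.66 mmol CH~4~
and 0.096 mmol sulfate, both overridable). Negative net values are
propagated with a warning rather than clipped, so questionable background
corrections stay visible; `clip_negative = TRUE` sets them to zero. Sulfate
supplied in mM is converted to mmol at ingest using the configured liquid
volume; all balances are in mmol.

Two distinct percentage accountings coexist deliberately:

* **Electron-flow split** — $100\,M/(M+S)$ and $100\,S/(M+S)$. Normalised
  by total measured product, it always sums to 100 and needs no alkane
  measurement.
* **Pathway contributions** — $E_M = 100\,M/(Y\,\Delta\mathrm{hex})$ and
  $E_S = 100\,S/(Y\,\Delta\mathrm{hex})$, normalised by the stoichiometric
  equivalents of the alkane actually consumed. These sum to the carbon
  recovery $100\,(M+S)/(Y\,\Delta\mathrm{hex})$, i.e. to 100 only when the
  balance closes perfectly.

Field reports mix the two definitions without comment; the report labels
them distinctly and the identity $E_M + E_S = \text{recovery}$ is enforced
as a machine-precision test invariant.

All ratio statistics are computed per replicate first and then averaged
within treatment (`summarize_treatment()`). The order matters: the mean of
per-replicate ratios is not the ratio of treatment means, and only the
replicate-first convention is self-consistent with how such tables are
printed. A regression test documents the distinction.

## Logistic kinetics

Cumulative methane is fitted with the three-parameter logistic
$y(t) = a/(1+e^{-k(t-t_c)})$ by Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`). Time is converted from days to months
(30.4375 d/month, configurable) before fitting so $k$ is in month^−1^. The
maximum specific methane production rate is identified with $k$: the
per-capita rate $(1/y)\,dy/dt = k(1-y/a)$ attains its supremum $k$ in the
$y \to 0$ limit, a property checked numerically in the tests. The
initialisation is deterministic — $a_0 = 1.05\,\max y$, $t_{c0}$ from the
interpolated half-amplitude crossing, $k_0$ from a logit-linear regression
— so no seed is needed; optional jittered restarts are available. The
convergence tolerance is $10^{-10}$ on the relative RSS change. Flat or
degenerate series yield a flagged non-converged result instead of an error,
so batch fitting never aborts. The control background is *not* subtracted
before fitting by default (production curves are fitted as measured);
`baseline =` subtracts a known constant first, which is the right choice
when the background is a constant offset, as in the synthetic generator.

## Isotope index

The apparent fractionation factor
$\alpha_{app} = (\delta^{13}\mathrm{CO_2} + 1000)/(\delta^{13}\mathrm{CH_4} + 1000)$
is a coarse index of the dominant methanogenic pathway. Classification uses
literature thresholds — below 1.025 aceticlastic-dominated, above 1.065
hydrogenotrophic-dominated — as configurable defaults, and the labels say
"dominated" rather than claiming a quantitative apportionment, because
species- and condition-dependent fractionation makes the index coarse.
δ values are ‰ vs VPDB throughout and headspace CO~2~ (not DIC) is assumed.
A plateau is estimated as the mean of the final `window` (default 3)
sampled points, with a drift flag when the fitted change across the window
exceeds a tolerance (default 0.002, about one measurement SE); no more
elaborate plateau-detection procedure is attempted because sampling in such
incubations is sparse and irregular.

## Sulfate response

The partition ratio $S/M$ is regressed on initial sulfate concentration by
OLS at each sampling day, per-replicate points by default (`use_means`
switches to treatment means; which convention underlies published figures
is usually unstated). The intercept is estimated, not forced through the
origin. Days on which any replicate has non-positive net methane (pre-lag)
are dropped with a message rather than producing unstable ratios.
`slope_stability()` summarises the per-day fits and flags the partition as
unstable when the max/min slope ratio exceeds 1.5, a deliberately loose
default: the scientific claim being screened is constancy of the partition
during the methane-production phase, and day-to-day scatter in small
designs is large.

## The synthetic-experiment generator

`generate_experiment()` produces complete experiments with the structure
the pipeline is meant to detect — it imposes the partition law rather than
emerging it from competition kinetics, because the downstream question is
whether the pipeline can recover a known truth:

* alkane consumption follows a logistic (midpoint 250 d, default rates
  0.41 down to 0.20 month^−1^ across the sulfate series, matching the
  observed range of such enrichments);
* a fixed recovery fraction (default 95%) of the consumed carbon appears as
  products, split so that $S/M = \beta C_0$ (default $\beta = 0.1$ per mM);
* constant background offsets (0.66 mmol CH~4~, 0.096 mmol sulfate)
  emulate control-culture turnover;
* δ^13^C trajectories come from a two-endmember scheme: aceticlastic
  methane carries the substrate δ (−30‰), hydrogenotrophic methane is
  withdrawn from a CO~2~ pool at pool-δ − ε~h~ (default 45‰), and the pool
  — seeded with 4 mmol at the substrate δ, the order of the dissolved
  inorganic carbon of a bicarbonate-buffered medium — enriches as
  withdrawal proceeds. The hydrogenotrophic fraction ramps linearly from
  0.3 at the end of the 120-day lag to a treatment-dependent endpoint (0.8
  at the lowest sulfate down to 0.5 at the highest), which produces a
  rising, flattening α~app~ whose plateau decreases with sulfate. The
  linear-δ bookkeeping conserves carbon-weighted δ exactly, which the tests
  verify to 10^−6^‰. This scheme is generator fiction — the simplest
  construction with the right qualitative behaviour — not a mechanistic
  isotope model.

Noise is Gaussian, added last, truncated at physical zeros, with defaults
at the replicate-SE scale of such experiments (methane 0.05 mmol, sulfate
0.02 mmol, δ 0.5‰). Each (treatment, replicate) pair draws from a substream
derived deterministically from the master seed, so runs are
bit-reproducible and adding a replicate does not perturb the others. The
deterministic curves are integrated on an internal 1-day grid and only
*sampled* at the requested days, so refining the sampling grid leaves
noise-free outputs unchanged — an exact version of the usual
grid-refinement check, verified in the tests.

### The sulfate cap, and what passing tests do not show

Under study-like dosing (0.34 mmol hexadecane in 0.2 l, sulfate from
0.5 mM) the sulfate demanded by $S/M = \beta C_0$ exceeds the sulfate
actually supplied for roughly $C_0 < 10$ mM. The generator then caps
sulfate reduction at the supply and routes the remainder to methanogenesis
(with a warning); carbon recovery is unaffected, but $S/M$ falls below
$\beta C_0$ in exactly the way real low-sulfate cultures sit below the
fitted line. Consequently the *exact* linearity properties (slope $=\beta$,
$R^2 = 1$ at every day) are verified in a sulfate-replete configuration
(0.6 l liquid volume, chosen so supply covers demand at every treatment),
while the default configuration keeps the study conditions, cap included.

More generally, passing the synthetic round-trips shows that the pipeline
recovers parameters from data that obey its own assumptions — constant
partition, logistic kinetics, constant backgrounds, Gaussian noise. Real
cultures violate all four in places (background turnover accrues over
time rather than sitting at a constant offset; partitions can drift as
communities shift; replicate counts of 2–3 make SEs unstable), so green
tests certify the arithmetic and the estimators, not the biology.

## Validation problem sizes

The shipped validation uses 6 treatments × 3 replicates × 15 sampling days
per experiment; 100-seed Monte Carlo runs for estimator bias (logistic rate,
partition slope, recovery, each required to sit within 3 Monte Carlo SEs of
truth) and 200 seeds for the slope-unbiasedness check; chain lengths 1–40
for the exact stoichiometry sweeps. These sizes make the full suite run in
well under a minute while leaving the Monte Carlo SEs small enough to
detect percent-level bias.

## Known limitations

* Cell growth is excluded from the stoichiometry by construction; measured
  recoveries below 100% partly reflect assimilation, which the model
  attributes to "unrecovered" carbon.
* Volatile fatty acid intermediates, sulfide speciation and COD-based
  normalisation are out of scope.
* The culture liquid volume is rarely reported alongside such data; the
  default 0.2 l is the value that reconciles a 0.34 mmol hexadecane dose
  with the ~21 mM sulfate requirement for complete sulfidogenic oxidation,
  and it is configurable everywhere it enters (ingest conversion, demand,
  generator).
* The isotope module computes an index, not a Rayleigh closed-system fit;
  DIC–CO~2~ speciation corrections are not implemented.
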
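---
title: "Models and methods behind crabtree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crabtree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crabtree)
```

`crabtree` quantifies aerobic ethanol fermentation (the Crabtree
effect) in budding yeasts: it simulates aerobic batch cultivations,
extracts the standard physiological metrics from culture time series,
classifies phenotypes from yield space, and runs the grouped
comparative statistics over a packaged 37-strain dataset. This
vignette explains the models, the parameters that matter, the
numerical choices, and what the pipeline does and does not capture.

## The batch fermentation model

The synthetic-data generator is a Sonnleitner–Käppeli-style
*respiratory bottleneck* model, the simplest mechanism that produces
the whole spectrum of Crabtree phenotypes. Glucose uptake follows
Monod kinetics,

$$ q_S = q_{S,\max} \frac{S}{K_S + S}, $$

and is split at the cell's respiratory capacity $q_{\mathrm{crit}}$
(`resp_cap`): uptake up to $q_{\mathrm{crit}}$ is respired with
biomass yield $Y_{XS}^{ox}$, anything above it *overflows* into
fermentation, producing ethanol at $Y_{ES}$ (capped at the theoretical
0.511 g/g) with a small fermentative biomass yield $Y_{XS}^{ferm}$:

$$ \mu = Y_{XS}^{ox}\, q_{S,ox} + Y_{XS}^{ferm}\, q_{S,ferm}, \qquad
   \frac{dX}{dt} = \mu X, \quad \frac{dS}{dt} = -q_S X . $$

A Crabtree-negative parameterisation simply has
$q_{\mathrm{crit}} \ge q_{S,\max}$: no overflow, no ethanol, and the
biomass yield equals $Y_{XS}^{ox}$. When glucose falls below
0.05 g/L, parameter sets with `ethanol_growth = TRUE` switch — after a
diauxic lag `lag_diauxic_h` (default 1.5 h, the time respiratory
metabolism takes to derepress; the culture idles during the lag) — to
Monod growth on the accumulated ethanol with yield $Y_{XE}$. This
reproduces the make–accumulate–consume trajectory: ethanol rises to a
single maximum, plateaus briefly, then is consumed.

**Off-gas.** CO₂ is computed as the *residual carbon* of each flux —
all substrate carbon not fixed in biomass or excreted products leaves
as CO₂ — which makes the model carbon-closed by construction (the
C-mole balance of any noiseless run is 1 to integrator precision).
During growth on glucose, respiration runs at a respiratory quotient
of exactly 1 (carbohydrate oxidation) and fermentative CO₂ costs no
O₂, so the observed CO₂/O₂ ratio is 1 for negative phenotypes and
rises well above 1 with overflow — the ratio emerges from the
stoichiometry rather than being imposed. During growth on ethanol, O₂
demand comes from the electron balance (degrees of reduction 6.0 for
ethanol, 4.2 for biomass), giving the characteristic sub-unity
respiratory quotient of that phase.

**Biomass composition.** One shared constant is used everywhere:
ash-free CH₁.₈O₀.₅N₀.₂ at 24.6 g per C-mole, the standard yeast
elemental composition. Per-C-mole masses for glucose (30.03), ethanol
(23.03), glycerol (30.70), acetate (30.03), pyruvate (29.35),
succinate (29.52) and lactate (30.03) are exported as `cmol_mass`.

**Integration.** Fixed-step classical Runge–Kutta (RK4) with step
0.01 h; depleted pools are clamped at zero, and the phase (glucose /
lag / ethanol) is decided at step boundaries. At this step size the
integration error is far below every tolerance used in the tests; the
carbon balance of noiseless runs deviates from 1 by less than 10⁻¹⁰.

**Presets.** `crabtree_preset()` provides three parameter sets chosen
so that the *extracted* metrics land in the three phenotype ranges
observed across *Saccharomycetaceae*: `strong_positive`
(S. cerevisiae-like, Y~E/S~ ≈ 0.39, Y~X/S~ ≈ 0.15, μ ≈ 0.30/h),
`intermediate` (Lachancea-like, Y~X/S~ ≈ 0.30) and `negative`
(K. lactis-like, Y~X/S~ = 0.55, no ethanol). All start from 2%
glucose (20 g/L) and an inoculum 500-fold below the final biomass, the
convention of the underlying cultivation protocol, and sample every
0.5 h for 48 h — a denser grid than manual HPLC sampling, chosen so
that window detection has enough points at realistic growth rates.

**Measurement noise.** `add_measurement_noise()` multiplies every
concentration and dry-weight sample by an independent lognormal factor
with unit mean and coefficient of variation `cv` (unbiased by
construction, clipped at zero). Cumulative off-gas signals get noise
on their *increments*, which are then re-accumulated, so they stay
smooth and non-decreasing like real integrated gas-analyser output.

What the generator does **not** emulate: lag phase at inoculation,
oxygen limitation (the protocol holds dissolved O₂ above 30%
saturation, and no mass-transfer coefficient is available to model the
alternative), pH and temperature dynamics, by-product dynamics beyond
optional constant-yield glycerol/acetate fluxes, and biological
variance between replicate cultivations (noise is purely technical).
Passing the recovery tests therefore shows the *extractor* is unbiased
and precise under measurement noise — not that it would be under, say,
systematic DW filter losses or sampling-time jitter.

## Metric extraction

*Exponential window.* The maximum specific growth rate is the OLS
slope of ln(biomass) against time over the exponential phase on
glucose. Auto-detection takes the longest contiguous run of at least
`min_points = 4` samples with glucose above 1 g/L and before any
ethanol decline whose log-linear fit reaches r² ≥ 0.995, breaking
length ties toward the higher slope; a manual window override is
always available, since published growth rates are traditionally
windowed by eye. Dry weight is the default basis; OD600 gives the
same slope up to the constant conversion factor and is available as an
option.

*Endpoint.* Yields are computed to the ethanol maximum for
Crabtree-positive cultures (maximum ethanol ≥ 0.5 g/L — the detection
threshold that separates true producers from the hard zeros of
negative strains) and to glucose depletion otherwise. "Depleted"
means the first crossing of 0.1 g/L (an HPLC detection-limit scale),
linearly interpolated between the bracketing samples; endpoint
concentrations are likewise linearly interpolated. The ethanol
maximum is the raw sample maximum, earliest on ties, with no smoothing
by default — smoothing would bias the peak of noiseless data. If the
ethanol maximum occurs while glucose is still present
(> 0.5 g/L), the culture had a period of mixed respiro-fermentative
metabolism; the endpoint is still the ethanol maximum, with a warning
and a QC flag.

*Yields and rates.* Yields are endpoint deltas,
$Y_{P/S} = \Delta c_P / (-\Delta S)$, with negative numerators (a
measurement-noise artefact) clipped to zero. Specific rates use the
first and last samples of the exponential window,
$q_S = (\Delta S/\Delta X)\,\mu$ — the Δ-quotient form, equivalent to
multiplying the exponential-phase yield ratio by μ; the two routes
agree to interpolation error by construction, and a test asserts it.

*Respiration ratio and carbon balance.* The respiration ratio divides
cumulative CO₂ by cumulative O₂ from inoculation to the end of growth
on glucose; below 10⁻⁶ mol/L of O₂ the ratio is reported as infinite
rather than as a meaningless large number. The carbon balance converts
every measured delta to C-moles (biomass via 24.6 g/C-mol) and divides
product carbon (including CO₂) by substrate carbon; values outside
[0.9, 1.1] raise a QC flag, mirroring how carbon recovery is used to
vet real experiments.

## Phenotype classification

The three-category rule lives in (Y~E/S~, Y~X/S~) space: strong
positives need over 5.5 g glucose per gram of biomass
(Y~X/S~ < 0.18) *and* make over 0.33 g ethanol per gram of glucose;
negatives convert most glucose to biomass (Y~X/S~ > 0.33) with almost
no ethanol (Y~E/S~ < 0.15); the intermediate band is
0.18 ≤ Y~X/S~ ≤ 0.33. The published bounds deliberately do not tile
the plane (the grouping is explicitly arbitrary); points in the gaps —
e.g. a low-biomass strain that does not clear the ethanol bound — are
assigned to the nearest category region (Euclidean distance to the
region rectangle, ties resolved toward the middle category) and
flagged `outside_published_bounds` rather than silently forced into a
category. The ethanol and biomass conditions of the strong category
are treated as conjunctive, which matches every strain listed as a
member in the source data.

## The packaged dataset and its two suspect rows

The reference dataset has one row per cultivation run (66 runs) with
ethanol yield, biomass yield, specific glucose consumption and ethanol
production rates, and maximum growth rate. The analysis set averages
replicate runs per strain (arithmetic mean of the run-level values —
replicates are paired cultivations, not pooled raw data), drops the
fructophilic *Zygosaccharomyces* species (cultivated on glucose they
are not comparable), the cockroach-gut isolate *Tet. blattae*, and the
five non-*Saccharomycetaceae* control strains, leaving 37 strains.
Two strain-distinction choices matter for that count: the two
*L. kluyverii* isolates and the three *K. marxianus* isolates are kept
as distinct data points (the replicate suffix, not the isolate letter,
marks a replicate), which is confirmed independently by the
regression degrees of freedom (35 = 37 − 2) and ANOVA residual
degrees of freedom (33 = 37 − 4) of the reference analysis.

Two printed rows are internally inconsistent: for every other row the
identities $q_E/q_S \approx Y_{E/S}$ (the exponential-phase ethanol
per glucose) and $\mu / Y_{X/S} \approx q_S$ hold to within a few
percent, but *Kaz. exiguus* (consumption 0.18, production 1.75,
growth 0.740/h — an impossible rate for a yeast whose replicate
passes a 0.62 sanity check elsewhere) and *Tor. franciscae*
(production ≈ 4× consumption) violate both badly. The packaged table
keeps them **exactly as printed** (the default), because repairing
data is an interpretation. The `repaired = TRUE` variant applies the
minimal interpretation — each suspect row is a within-row column
permutation, and the permutation is chosen to maximise the two
internal identities (for *Kaz. exiguus*: ethanol yield 0.43, biomass
yield 0.18, consumption 1.75, production 0.74, growth 0.43; for
*Tor. franciscae*: consumption and production swapped). With that
repair, every reproduced statistic lands within a few percent of its
published value (e.g. biomass-yield ANOVA F 70.95 vs 72.01, Pearson r
−0.695 vs −0.70), while the as-printed table reproduces only the
cells the two rows do not touch (e.g. ethanol-yield ANOVA F 56.24 vs
55.94) — strong evidence the published statistics were computed from
unscrambled values and the scrambling is typographic. Both variants
run through `compare_group_stats()`, which reports the per-cell
deviations rather than hiding them.

## Statistics

All tests are the classical ones, two-sided at α = 0.05, computed via
base R (`aov`, `kruskal.test`, `t.test`, `cor.test`, `lm`) and
reported as tidy one-row tibbles: one-way ANOVA with
R² = SS~between~/SS~total~; tie-corrected Kruskal–Wallis; Welch
t-tests with Welch–Satterthwaite fractional df for all six group
pairs per parameter; Pearson r with the y-on-x regression
(R² = r² and F = t² by identity, asserted to 10⁻¹² in tests); and
Spearman's ρ as the Pearson correlation of tie-averaged ranks with a
t-approximation p-value. No multiple-testing correction is applied —
the reference analysis reports raw pairwise p-values, and the package
mirrors it; `stats::p.adjust` composes trivially downstream if
desired. Group means are summarised with t-based 95% confidence
intervals. One quirk of the reference table is reproduced but not
forced: its ethanol-yield/growth-rate Pearson correlation prints the
same value (0.38) as the row above it while the Spearman counterpart
is −0.10; the recomputation yields a near-zero correlation, consistent
with the Spearman value and with a copy error in the printed Pearson
cell.

## Problem sizes and test design

The test-suite simulations use the preset defaults (96 samples over
48 h, RK4 step 0.01 h); noisy-recovery checks use 50 lognormal noise
realisations at cv = 0.02 per preset, enough to pin the mean recovery
error well below the 3–5% acceptance bands while keeping the whole
suite under a minute. Statistical oracles are brute-force arithmetic
written out in the tests (pooled-t², hand ranks, hand Welch df), never
a second call into the same library routine.

## Known limitations

* The overflow model has a sharp respiratory capacity; real capacities
  are themselves regulated and temperature-dependent.
* Oxygen is assumed non-limiting throughout.
* Replicate averaging reproduces the reference analysis but discards
  within-strain variance; a mixed model would use it.
* The phylogenetic group comparison treats strains as independent
  observations (as the reference analysis does); phylogenetically
  independent contrasts are out of scope.
* The repair of the two suspect rows is a best-effort reconstruction
  and is never the default.
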
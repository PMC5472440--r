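---
title: "Models and methods in nucleoslide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in nucleoslide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleoslide)
```

## The system

Some chromatin remodellers — the human INO80 core complex is the motivating
example — reposition mono-nucleosomes away from DNA ends, apparently
"centring" them on short fragments. The behaviour this package models is
that the enzyme does not find the centre at all: it works as a **dimer** of
two complexes that simultaneously monitor the free DNA flanking either side
of the 147 bp octamer footprint, and it simply refuses to push a nucleosome
closer than about 50 bp to an end. On substrates too short to satisfy both
sensors, the compromise is the centre. Cooperativity shows up everywhere in
this picture: equilibrium binding and sliding-rate titrations are sigmoidal
with Hill coefficients near 2, saturation titrations break at a 2:1
complex:nucleosome stoichiometry, and a dimer with a single working ATPase
motor still slides — in half of its binding orientations.

`nucleoslide` implements the full quantitative tool chain around that model:
binding and rate fitters, stoichiometry estimation, kinetic-trace analysis
with an ATP-per-base-pair coupling statistic, a Punnett-square mixture
model, and a stochastic simulator of flank-sensing sliding. Synthetic
generators emulate each assay with known ground truth so the whole pipeline
is testable end to end.

## Cooperative binding and rate fits

Equilibrium titrations are fitted with the Hill model

$$F(P) = F_{min} + (F_{max}-F_{min})\,\frac{P^h}{K_{1/2}^h + P^h},$$

by unweighted Levenberg–Marquardt least squares with multi-start
initialisation ($K_{1/2}$ seeded at the response-midpoint concentration,
$h$ at 1, plus a coarse grid of alternatives). Fits are performed and
reported in the input concentration unit. A fitted $h$ is confirmed by the
classical Hill plot, a regression of $\log(\theta/(1-\theta))$ on $\log P$;
points with fractional saturation outside 10–90 % are excluded because the
log-odds transform amplifies their noise without bound (the conventional
linear-region choice).

Rate titrations use the same curve with the baseline pinned at zero (the
"allosteric sigmoidal" model, $V = V_{max}P^h/(K_{1/2}^h+P^h)$). Because a
Hill curve with $K_{1/2}$ far above the titrated range is
indistinguishable from a straight line, `fit_rate_titration()` compares the
sigmoid against a linear model by small-sample-corrected AIC **and**
declares the sigmoid unresolved whenever the fitted $K_{1/2}$ exceeds the
largest titrated concentration — this is what cleanly classifies
unstimulated (no-nucleosome) ATPase series as linear. Titrations whose
response range falls below a noise floor (2 % of the largest response by
default) are reported as explicit zero-activity results, the behaviour of a
motor-dead complex, rather than fitted.

Binding stoichiometry comes from saturation titrations at ligand
concentrations far above $K_{1/2}$: straight lines are fitted to the
unsaturated and saturated segments (the split chosen by minimising total
residual sum of squares over all admissible splits, at least two points per
segment) and the breakpoint extrapolated from their intersection,

$$[P]_{break} = \frac{Y_1 - Y_2}{S_2 - S_1}, \qquad
  \text{stoichiometry} = \frac{[P]_{break}}{[N]},$$

with $[N]$ the fixed ligand concentration. The division by $[N]$ is the
dimensionally coherent reading — it is the only one that returns a
dimensionless site number (2 for a 1000 nM breakpoint over 500 nM
nucleosomes). Parallel segments (relative slope difference below $10^{-8}$)
are an error; a breakpoint outside 0.1–10× the titrated range warns.

## Kinetic traces and coupling

Initial velocities are the slope of a linear regression over an early
window, by default the first 10 % of the time to half-completion (minimum
four samples) — a reproducible stand-in for the manual early-slope reading
used at the bench. Sliding FRET traces can be rescaled to the assay's
100,000 FU full scale; the factor is retained. NADH-coupled ATPase traces
convert to absolute rates through a simultaneously measured ADP standard:
`rate = |signal slope| / |standard slope|` in µM ATP/s, with optional
division by enzyme concentration for a per-enzyme turnover. The coupled
pyruvate-kinase/lactate-dehydrogenase chemistry itself is assumed fast and
linear, as the assay is designed to guarantee.

The coupling-efficiency statistic is simply ATP consumed per base pair
slid. For the wild-type presets it evaluates to about 8 over the first 90 s
of an end-positioned (`0N100`) reaction — the package's quantitative
expression of the observation that most hydrolysis is uncoupled from
movement. Zero sliding with nonzero hydrolysis returns the sentinel
`"fully uncoupled"` rather than an infinite number.

## The sliding simulator

`simulate_sliding()` runs a continuous-time Markov chain per molecule. The
state is the left flank length $l_L$ (the right flank follows from
conservation, $l_L + l_R = L - 147$). The rate law:

* **Sensing.** $\sigma(l) = 1/(1+e^{-(l-s)/w})$ is a soft sensing function
  with midpoint `s_sense` (50 bp wild type, 35 bp for the CTD truncation)
  and width `sense_width` (4 bp).
* **Stepping.** A 1 bp step that shrinks flank $i$ has propensity
  $k_{step0}\,\sigma(l_i) + k_{leak}/2$: movement toward a side is
  permitted in proportion to that side's flank being sensed as long. The
  net drift, $k_{step0}(\sigma(l_{long})-\sigma(l_{short}))$, always grows
  the shorter flank and vanishes at equal flanks; a nucleosome whose both
  flanks exceed the sensing range is "invisible" to the sensors and
  undergoes undirected stepping. This one law reproduces both end-away
  sliding and the mobilisation of centred nucleosomes with long symmetric
  flanks, while short-flanked centred substrates stay parked.
* **Positioning landscape.** Strong positioning sequences offer preferred
  positions every helical turn; the simulator idealises them as wells every
  `well_period` = 10 bp in register with the start position, slowing well
  escape by $e^{-well\_depth}$ ($well\_depth$ = 1.2). The 1 bp elementary
  step plus this landscape — not a 10 bp step size — generates the
  observed 10 bp band ladders.
* **Arrest.** Stepping onto a well (other than the starting one) when both
  flanks satisfy $\sigma \ge arrest\_sigma$ arrests the molecule with
  probability `p_arrest` = 0.2. Arrest encodes the "slow stop": sliding
  terminates by progressive uncoupling near the end point rather than by a
  hard wall. The starting well is excluded because arrest models the
  termination of a productive run — a molecule "arrested" where it started
  is operationally indistinguishable from one that never engaged, and the
  exclusion is what lets a 60N60 substrate mobilise one well off centre
  while 50N50 remains parked.
* **ATP ledger.** Hydrolysis proceeds at `k_atp` per active motor whenever
  the dimer is nucleosome-bound, independent of movement; every step debits
  the same ledger (futile propensity $= \max(0, n_{motors}k_{atp} -
  \text{step rates})$), so cumulative ATP always dominates step count and
  the bulk ATPase rate is unchanged before and after sliding completes.
* **Orientation.** A dimer with exactly one working motor is productive in
  exactly one of its two binding orientations; unless fixed, each molecule
  draws its orientation with probability ½ at binding. Dead dimers neither
  move nor hydrolyse.

The core is compiled (Rcpp) and uses R's RNG, so `set.seed()` (or the
`seed` argument, which is recorded in the result) reproduces runs exactly.

### Calibration of the wild-type defaults

The defaults were fixed once, against the study's headline conditions,
before any acceptance analysis and are not tuned thereafter:

* `k_step0` = 2 bp/s and `k_atp` = 2.2 s⁻¹ per motor jointly give
  ≥ 90 % completion of a `0N100` reaction by 90 s and
  $2 \times 2.2 \times 90 \approx 400$ ATP per nucleosome over those 90 s —
  about 8 per base pair of the 50 bp slid. The per-motor turnover of
  2.2 s⁻¹ sits just above the 1–2 s⁻¹ band expected for this motor class;
  the completion and coupling constraints were given priority.
* `sense_width` = 4 bp. A wider sensing slope (8 bp was considered) spans
  ±25 bp around the midpoint, leaving no "blind" plateau between 50 and
  70 bp flanks: fully flanked nucleosomes then never mobilise and the
  operational sensing limit reads far too high. Width 4 reproduces the
  50 bp limit, the one-band-per-20-bp ladder growth, and the three-band
  `0N140` product (a hard threshold would give a single band).
* `p_arrest` = 0.2 with `arrest_sigma` = 0.5 (arrest eligibility = both
  flanks at or beyond the sensing midpoint) yields ladders of one, two and
  three bands for `0N100`, `0N120`, `0N140`.
* The ΔCTD preset encodes the truncation phenotype: sensing midpoint 35 bp,
  5-fold lower `k_step0`, 2-fold higher `k_atp`, a small undirected leak
  (`k_leak` = 0.05 s⁻¹) and `arrest_sigma` = 0.2 — weaker coupling strands
  runs at lower sensing levels. Together these reproduce the off-centre
  sliding of centred 50N50 substrates, the broader product spread and an
  operational sensing limit of 30 bp on the 10 bp probe grid. The exact
  truncated-complex sensing value is only bounded above by the data (under
  40 bp); 35 bp is a choice.

`sensing_range()` reports the largest symmetric flank length (on a 10 bp
grid, 300 molecules, 3600 s per point by default) whose ensemble mean
absolute dyad displacement stays below 2 bp — the resolution at which
band spread can be called on a high-percentage native gel.

## Mixtures

When two complex species are mixed, protomers pair at random
(Hardy–Weinberg): $p(i,i) = f_i^2$, $p(i,j) = 2f_if_j$. Random pairing is
justified by the indistinguishable binding of active, dead and mixed
complexes. Default per-dimer rules: a dead homodimer contributes nothing; a
single-motor heterodimer contributes 0.5 — by default read as "productive
in one of two orientations" (`heterodimer_mode = "orientation"`), though
the ensemble expectation is identical under the alternative all-at-half-rate
reading, which is exposed as `"uniform"` because bulk data cannot separate
the two. CTD-loss multiplies sliding by 0.2 and ATPase by 2 per fully
truncated dimer; dimers with a single CTD take the geometric mean of the
intact and truncated factors. That interpolation, and all mixed-CTD rules,
are qualitative presets: the corresponding measurements exist only in
unpublished source data, so they are deliberately not calibration targets
(including the hint that a truncated-active:dead heterodimer may outperform
the truncated homodimer, which is noted but not encoded).

`mixture_titration()` composes occupancy (the wild-type titration shape —
binding is mixture-independent) with the predicted relative activity, so a
1:1 active:dead mixture plateaus at exactly half the pure-active curve.

Completion-time reciprocity (half the rate, twice the time) holds for the
analytic trace generator by construction. The per-molecule simulator
deliberately has **no enzyme exchange between nucleosomes**: a nucleosome
bound by an unproductive dimer never completes, so bulk completion kinetics
of mixtures — which in solution rely on dissociation and rebinding — are
exercised on the analytic generator, not the simulator.

## Synthetic data: what it does and does not emulate

Generators produce the package's own table formats with the generating
parameters attached as a `truth` attribute. Noise is multiplicative
Gaussian on the signal (2 % by default), appropriate for fluorescence
read-outs where error scales with intensity; an additive floor is
available. Concentration grids default to 16-point two-fold dilution
series. Assay design constants follow the motivating study: 20 nM labelled
nucleosomes for binding, 500 nM for saturation/stoichiometry, 100 nM
dual-labelled nucleosomes with 200 µM NADH for one-pot kinetics, 50 nM
duplex for the gel-shift.

What passing recovery tests on these data shows is that the estimators are
unbiased and correctly coupled to their models at realistic noise; what
they cannot show is robustness to everything real traces contain that the
generators omit — photobleaching, temperature-jump artefacts, capillary
variation, baseline drift, aggregation at high concentration, and any
systematic deviation of true binding from the Hill form (the Hill equation
is a phenomenological reduction of a two-site Adair scheme, not its exact
solution).

## Numerical choices and degenerate inputs

* Hill fits evaluate $(P/K)^h/(1+(P/K)^h)$ to avoid overflow at large $h$;
  parameters are bounded ($10^{-3} \le h \le 50$, $K_{1/2}$ within three
  decades of the titrated range) and the Levenberg–Marquardt tolerance is
  $10^{-10}$ on parameters, with a default-tolerance retry because an
  exactly interpolating fit can defeat the tight criterion.
* Ties and degeneracies: parallel stoichiometry segments are an error, not
  a huge number; zero sliding yields a sentinel, not `Inf`; flat titrations
  are zero-activity results, not failed fits; a trace without a detectable
  plateau (final 20 % still moving by more than 5 % of the amplitude)
  refuses to report a completion fraction.
* The simulator records states on a fixed output grid (201 points by
  default); molecules that can no longer move (arrested, unproductive or
  rate-free) advance directly to the remaining grid points with Poisson
  ATP increments, which is exact for a constant-rate process.
* Problem sizes in the tests and acceptance analyses (300–500 molecules,
  16–21-point titrations with 3–20 replicates) were chosen so every Monte
  Carlo margin is several standard errors wide while a full run stays in
  the seconds-to-a-minute range on a single core.

## Known limitations

* The functional form of the flank-sensing rate law is not measured
  anywhere; the logistic per-direction law is one consistent choice, and
  alternatives (e.g. direction-persistent translocation with slow
  reorientation) could reproduce the same end-point data with different
  path statistics.
* The positioning landscape is an idealised 10 bp comb in register with the
  start position; real positioning-sequence energetics, and the fading of
  its influence beyond ~150 bp of travel, are not modelled.
* Post-arrest micro-oscillations of 1–2 bp are possible in reality but are
  off by default (`k_leak` = 0 for wild type); the gel-level data only
  bound them.
* Mixed-CTD heterodimer rules are qualitative, as above.
* Wild-type nucleosome-binding $K_{1/2}$ presets are order-of-magnitude
  placeholders (the measured values live in a figure table, not the text)
  and are excluded from all quantitative checks.
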
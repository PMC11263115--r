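---
title: "Measuring population-level inbreeding depression under standing selfing-rate variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring population-level inbreeding depression under standing selfing-rate variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selfID)
```

## The question

Inbreeding depression (ID) — the fitness deficit of selfed relative to
outcrossed offspring — is the main genetic brake on the evolution of
self-fertilization. The classical rule is that, without pollen discounting, a
selfing-enhancing allele spreads when the relative fitness of selfed
offspring exceeds one half, i.e. when ID < 0.5. That rule treats ID as a
single population constant. In a real population, however, individuals vary
in their selfing rate, and that variation builds up *standing genetic
associations* between selfing-rate alleles and deleterious mutations:
habitual selfers purge and expose mutations differently from habitual
outcrossers. `selfID` provides (i) an individual-based simulator in which a
polygenic selfing rate and recessive deleterious mutations coevolve to
mutation–selection–drift balance, so those associations can be measured, and
(ii) the analytic machinery that converts measured associations into
corrected population-level ID metrics and invasion/selection-gradient
criteria.

## The simulation model

The population is hermaphroditic, diploid, of constant size $N$, with
non-overlapping generations. Each individual carries one chromosome pair of
unit map-scaled length.

**Selfing rate.** A quantitative trait $z$ is controlled by $n_z$ identical
additive loci at chromosome positions $0, 1/n_z, \dots, (n_z-1)/n_z$, with
alleles $A$ and $a$ contributing $-1/n_z$ and $+1/n_z$ per copy (so
$z \in [-2, 2]$ and the genetic variance does not scale with $n_z$). The
individual selfing rate is the logistic map

$$\alpha(z) = \frac{1}{1 + e^{-k (z - z_c)}},$$

with steepness $k$ and midpoint $z_c$ (where $\alpha = 0.5$ exactly);
shifting $z_c$ moves the population mean selfing rate. The trait is held
near its optimum by Gaussian stabilizing viability selection
$w_1(z) = e^{-\lambda z^2}$, strong enough ($\lambda = 0.5$ at the defaults)
that the phenotypic distribution stays comparable across the deleterious-
mutation regimes being contrasted. Trait mutation supplies Poisson($U_z/2$)
allele flips per gamete at uniformly chosen trait loci.

**Deleterious mutations.** Mutations arise under an infinite-sites model:
Poisson($U/2$) new mutations per gamete at positions drawn uniformly on
$(0,1)$ (trait-locus positions and already-occupied positions are redrawn —
probability-zero events kept explicit for exact arithmetic). All mutations
share a selection coefficient $s$ and dominance $h$, acting
multiplicatively:

$$w_2 = (1 - hs)^{n_\mathrm{het}} (1 - s)^{n_\mathrm{hom}}, \qquad w = w_1 w_2 .$$

**Life cycle.** Each generation: for each of $N$ offspring a mother $i$ is
sampled uniformly; a uniform deviate $\epsilon$ decides selfing iff
$\epsilon < \alpha_i$, otherwise a father $j \neq i$ is sampled uniformly.
Meiosis draws Poisson($L$) crossovers at uniform breakpoints, a fair coin
for the starting chromosome, and alternates parental segments. Finally $N$
adults are resampled from the juveniles with replacement, with probability
proportional to $w$ (an all-zero-fitness cohort is reported as extinction,
with its generation).

**Measurement.** Family-level ID is assayed each recorded generation by
giving every adult one selfed and one outcrossed offspring (two independent
meioses for the selfed one; assay offspring never enter the population) and
recording the deleterious component $w_2$ only, so that the assay isolates
mutational ID from the stabilizing-selection component. Reported
per-generation metrics include $\bar\alpha$, $V_\alpha$, mutation-load
means, mean individual homozygosity,
$\delta_0 = 1 - \overline{w}_\mathrm{self}/\overline{w}_\mathrm{out}$ (a
ratio of means, not a mean of family ratios), and Pearson correlations and
OLS slopes of $\alpha$ against mutation count, $w_\mathrm{out}$,
$w_\mathrm{self}$, and family ID. Equilibrium values are trailing-window
averages after burn-in.

## The analytic layer

For a rare modifier allele changing a carrier's selfing rate by $f(\alpha)$,
the expected fitness of the resident allele is

$$w_M = E\left[\alpha\, w_\mathrm{self}(\alpha) + \tfrac12 (1-\alpha)\, w_\mathrm{out}(\alpha)\right] + \tfrac12 E\left[(1-\alpha)\, w_\mathrm{out}(\alpha)\right],$$

(selfed offspring, outcrossed ovules, exported pollen) and the modifier's
advantage reduces to $E[w_\mathrm{self} f] - \tfrac12 E[w_\mathrm{out} f]$,
so that with

$$\delta_f = 1 - \frac{E[w_\mathrm{self}(\alpha) f(\alpha)]}{E[w_\mathrm{out}(\alpha) f(\alpha)]}$$

a selfing-increasing modifier invades exactly when $\delta_f < 1/2$
(`invasion_fitness()`). When offspring fitness is approximately linear in
$\alpha$, $\delta_f$ has the linear form implemented by `delta_modifier()`:

$$\delta \approx 1 - \frac{E[w_\mathrm{self}] + \rho_\mathrm{self} V_\alpha\, f'(\bar\alpha)/f(\bar\alpha)}{E[w_\mathrm{out}] + \rho_\mathrm{out} V_\alpha\, f'(\bar\alpha)/f(\bar\alpha)} .$$

For a selfing rate evolving as a quantitative trait from standing variation,
the selection gradient and the matching ID metric are (`selection_gradient()`,
`delta_quantitative()`):

$$E\!\left[\frac{\partial w}{\partial \alpha}\right] \approx w_\mathrm{out}(\bar\alpha)\left(\frac{w_\mathrm{self}(\bar\alpha) + \bar\alpha \rho_\mathrm{self} + \tfrac12(1-\bar\alpha)\rho_\mathrm{out}}{w_\mathrm{out}(\bar\alpha)} - \frac12\right),
\qquad \delta = 1 - \frac{w_\mathrm{self}(\bar\alpha) + \bar\alpha \rho_\mathrm{self} + \tfrac12(1-\bar\alpha)\rho_\mathrm{out}}{w_\mathrm{out}(\bar\alpha)} ,$$

so the mean selfing rate increases exactly when this $\delta < 1/2$.
`invasion_threshold()` locates the sign change by bisection (tolerance
$10^{-6}$) over scenario families indexed by their ID.

### What $\rho$ is

The derivations above are only dimensionally consistent — and the linear
formula is only *exactly* equal to $\delta_f$ on linear families — when
$\rho_\mathrm{self}$ and $\rho_\mathrm{out}$ are the **least-squares
regression slopes** of offspring fitness on maternal selfing rate, not the
Pearson correlation coefficients. The package therefore uses slopes by
default everywhere these quantities feed a formula, and exposes
`rho = "pearson"` in `theory_inputs()` and `association_summary()` for
sensitivity analyses and for comparison with correlation-based empirical
reports. The exactness on linear families is proven by expanding
$E[(a + b\alpha)(e + g\alpha)] = (a + b\bar\alpha)(e + g\bar\alpha) + bgV_\alpha$
and is enforced by a property test. Similarly, $w_\mathrm{self}(\bar\alpha)$
and $w_\mathrm{out}(\bar\alpha)$ are defined as OLS fitted values at
$\bar\alpha$; since an OLS line passes through the mean point, these equal
the sample means exactly, which is why a single `theory_inputs` object
serves both formulations.

## Parameters and defaults

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `N` | adult population size | 1000 (test preset), 20000 ("full" preset) | |
| `U` | diploid deleterious mutation rate / generation | 0.5 | Poisson($U/2$) per gamete |
| `s` | selection coefficient | 0.2 | in $[0,1]$ |
| `h` | dominance coefficient | 0.1 | partially recessive |
| `L` | expected crossovers / meiosis | 10 | Poisson mean |
| `n_z` | trait loci | 10 | evenly spaced on the chromosome |
| `U_z` | diploid trait mutation rate | 0.2 | Poisson($U_z/2$) flips per gamete |
| `k` | logistic steepness | 3 | |
| `z_c` | logistic midpoint | 0 | moves $\bar\alpha$ |
| `lambda` | stabilizing-selection strength | 0.5 | $w_1 = e^{-\lambda z^2}$ |
| `generations` / `window` | run length / trailing average | 1500 / 500 (test), 5000 / 2000 ("full") | |

The scaled-down preset (`N = 1000`–`2000`, 1500 generations, trailing 500
averaged) is the package's standard desk-scale condition: mutation–selection
balance for these parameter ranges equilibrates within a few hundred
generations (the slowest timescale is roughly $1/(hs)$ generations for the
load and $N_e$ generations for trait drift), so 1500 generations leaves a
comfortable burn-in before the averaging window. The full-scale preset
(`preset = "full"`) is provided for users with the patience for
$N = 20000$ runs; the package's own tests do not use it.

## Design choices in ambiguous corners

* **The selfing inequality.** The model's reproduction rule is implemented
  as *self iff* $\epsilon < \alpha_i$, so that the probability of selfing
  equals the individual's selfing rate — the only reading consistent with
  $\alpha$ being a selfing rate and with the direction of every downstream
  result.
* **Juvenile cohort size.** Viability selection resamples $N$ adults from a
  juvenile cohort of size $N$; since sampling is with replacement and
  fitness-proportional, the cohort size only affects sampling noise, and
  $N$ is the simplest choice.
* **Selfed offspring** combine two *independent* meioses of the same parent
  (independent crossover draws), the biological default.
* **Trait mutation model.** The aggregate rate $U_z$ is realised as
  Poisson($U_z/2$) events per gamete, each flipping one uniformly chosen
  trait locus between its two allelic states.
* **Initial conditions.** Populations start mutation-free with each trait
  allele drawn as a fair coin; all equilibrium claims are about the
  trailing window, never the transient.
* **Homozygosity.** Individual homozygosity is reported as the *fraction*
  $n_\mathrm{hom}/(n_\mathrm{hom}+n_\mathrm{het})$ (0 for a mutation-free
  genotype): it is load-scale-free, matching the reading of "individual
  homozygosity" as a composition rather than a count. The raw counts are
  exposed alongside for anyone preferring a different normalization.
* **$V_\alpha$** uses the population moment (denominator $n$): this is the
  variance that appears in the analytic formulas and the only convention
  under which the theoretical ceiling of 0.25 for a rate bounded in $(0,1)$
  is attained by an even two-point split.
* **Families with $w_\mathrm{out} = 0$** are excluded from family-ID
  statistics (with the count reported) rather than carrying infinities.
* **Pearson on raw values** (not ranks) is the default correlation; rank
  statistics can be computed from the assay table directly if desired.
* **Config format** is flat YAML with keys named exactly as the parameters;
  bare `N` keys are protected from YAML 1.1 boolean interpretation.
* **Replicate seeding.** Replicate $r$ of a batch runs with `seed + r`, so
  a batch is reproducible from its base seed and replicates never share a
  stream.

## What the simulator does and does not emulate

The generator reproduces the study conditions: unconditionally deleterious,
equal-effect, partially recessive mutations on a single chromosome pair,
a single logistic selfing trait, no pollen discounting, no fecundity
selection, no population structure, and no overlapping generations. Passing
tests therefore demonstrate internal consistency of the model and its
metrics, not that any real population behaves this way: real ID involves
variable selection and dominance coefficients (with large-effect mutations
more recessive), overdominant loci, multiple chromosomes, and environmental
variance in both the selfing trait and fitness, all outside scope here. In
particular the qualitative sign flip of the selfing-rate–family-ID
correlation with increasing $s$ is a single-effect-class result; with a
realistic mixture of effect sizes the net standing association depends on
which class dominates the load.

Two further caveats. First, standing associations are expected to weaken as
$N$ grows (drift contributes to them), so magnitude summaries measured at
the desk-scale $N \approx 2000$ — where the package's own checks place
$|\rho_\mathrm{self}|$ slightly above 0.1 at the weakest-selection setting —
should be treated as upper-end values. Second, per-generation
correlation estimates are noisy at $N = 2000$ (sampling SE of order
$1/\sqrt{N} \approx 0.02$), which is why every equilibrium statistic is a
trailing-window average.

## Numerical and degenerate-input conventions

Positions are double-precision reals compared exactly (copies of a mutation
are bitwise identical, so zygosity is exact set intersection). Fitness
products use `pow`, so $s = 1$ homozygotes give exactly 0 and empty products
exactly 1. Correlations require at least 3 families and positive variance in
both arguments; otherwise they are flagged `NA` (and the zero-$V_\alpha$
case is flagged explicitly). `delta_modifier()` refuses a vanishing
denominator rather than returning infinities. Bisection assumes a monotone
advantage over the scanned interval and errors if there is no sign change.
All randomness — in both the compiled and the pure-R engine — flows from R's
global RNG, so a single `seed` reproduces a run bit-for-bit; the compiled
engine is the default, and the R engine exists as a readable reference and
cross-check at small scale.

## Known limitations

* The modifier analysis is analytic (expectation-based invasion criterion);
  the package does not simulate an explicit modifier locus sweeping.
* No bootstrap/jackknife uncertainty on the association statistics.
* One chromosome pair; `L` is the only recombination control.
* The family assay uses one selfed and one outcrossed offspring per adult
  per generation; its per-generation statistics are correspondingly noisy
  and should be consumed through window averages.
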
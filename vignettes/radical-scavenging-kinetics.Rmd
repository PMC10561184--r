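---
title: "Rating antioxidants: from free energies to rate constants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rating antioxidants: from free energies to rate constants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radkin)
```

## The problem

Phenolic antioxidants neutralize oxygenated radicals (HO·, HOO·) through
three competing mechanisms: **formal hydrogen transfer** (FHT, a hydrogen
atom moves from an O–H or C–H bond to the radical), **radical adduct
formation** (RAF, the radical adds to an unsaturated carbon) and **single
electron transfer** (SET, an electron moves from the — usually deprotonated —
phenolate; polar media only). Quantum chemistry delivers the thermochemistry
of each elementary channel: a Gibbs activation free energy, a reaction free
energy, Eckart barrier parameters, or a Marcus reorganization energy.
`radkin` implements the kinetic post-processing that turns those scalars into
the quantities chemists actually compare: apparent per-channel rate
constants, mole-fraction-weighted rates, branching ratios, and overall rate
constants per compound, radical and medium — plus metal-chelation equilibria
and the pro-oxidant electron-transfer kinetics of the resulting complexes.
This is the standard workflow for computational radical-scavenging studies
(often referred to as the QM-ORSA methodology), packaged as reusable, tested
code with a structured input format.

## The model, step by step

### Per-channel rate constants

Channels with an activation free energy are rated by conventional
transition-state theory,

$$k = \sigma\,\kappa\,\frac{k_B T}{h}\,e^{-\Delta G^\ddagger/RT},$$

with $\sigma$ the reaction-path degeneracy, $\kappa$ the tunneling
correction, and $k_BT/h \approx 6.212\times10^{12}\,\mathrm{s^{-1}}$ at
298.15 K. Energies are kept in kcal/mol throughout
($RT = 0.592485$ kcal/mol at 298.15 K); SI units appear only inside the
prefactor and the diffusion coefficients.

The tunneling correction is the thermally averaged transmission through the
one-dimensional asymmetric **Eckart barrier**,

$$\kappa = \frac{e^{V_1/k_BT}}{k_BT}\int_0^\infty P(E)\,e^{-E/k_BT}\,dE,$$

parameterized by the forward barrier $V_1$, the reverse barrier $V_2$ and the
imaginary frequency. $P(E)$ is evaluated in the Johnston–Heicklen
dimensionless form, with the hyperbolic terms switched to scaled
exponentials once their arguments exceed 350 so deep-tunneling channels do
not overflow, and the $\alpha_1\alpha_2 < \pi^2/4$ (thin-barrier) branch
handled through the cosine form. The thermal average uses adaptive
quadrature on $E \in [0, V_1 + 40\,k_BT]$ at a relative tolerance of
$10^{-8}$; energies below the product asymptote are closed
($P = 0$ for $E < V_1 - V_2$). The suite checks the implementation against
an independent dense trapezoidal quadrature over barriers of 1–25 kcal/mol,
frequencies of 300–3500 cm$^{-1}$ and temperatures of 250–350 K at 0.5%.

SET channels get their activation free energy from **Marcus theory**,

$$\Delta G^\ddagger = \frac{\lambda}{4}\left(1 +
\frac{\Delta G^0}{\lambda}\right)^2,$$

a parabola with vertex $(-\lambda, 0)$; driving forces beyond $-\lambda$
re-raise the barrier (inverted region). Where $\lambda$ must itself be
estimated from the vertical energy gap, both circulating sign conventions
($\lambda \approx \Delta E + \Delta G^0$ and
$\lambda \approx \Delta E - \Delta G^0$) are exposed behind a flag, because
the literature is not unanimous; the default is the additive form, and a
non-positive result raises an error that points at the other convention.
SET rates then go through TST with $\kappa = 1$, $\sigma = 1$.

### Diffusion correction

No bimolecular rate can exceed the encounter rate. Thermal rates are
interpolated against the diffusion limit with the **Collins–Kimball**
expression $k_{app} = k_D k_{act}/(k_D + k_{act})$, and $k_D$ comes from the
steady-state **Smoluchowski** rate with Stokes–Einstein diffusion
coefficients, $k_D = 4\pi R_{AB} D_{AB} N_A$ with
$D_i = k_BT/(6\pi\eta r_i)$. Default hydrodynamic radii are 2.0 Å per
reactant — typical for small phenols and oxygen radicals, giving
$k_D \approx 7\times10^9\,\mathrm{M^{-1}s^{-1}}$ in water — and media can
carry per-radical overrides for channels whose published diffusion constants
rest on unreported radii. Channels flagged `barrierless` bypass TST and
proceed at $k_D$ directly.

### Speciation and aggregation

In aqueous media an acid can populate several protonation states. Mole
fractions at pH follow the Henderson–Hasselbalch ladder: state $j$ carries
weight $10^{\sum_{i\le j}(\mathrm{pH} - pK_{a,i})}$, normalized; the sums are
computed in log10 space with the maximum subtracted, so pH values far outside
the ladder cannot overflow. The working pH defaults to 7.4, the conventional
physiological value. Lipid media allow no dissociation, so every channel
there uses $f = 1$. Reported percentages are rounded half-up to two decimals,
matching the convention of the reference values.

Each channel's weighted rate is $k_f = f \cdot k_{app}$; the overall rate
constant is the plain sum of the $k_f$ over a compound × radical × medium
group, and branching ratios are $\Gamma_i = 100\,k_{f,i}/\sum k_f$ — they sum
to exactly 100 before display rounding (tables round them to integers, the
unrounded values stay in the result tibble). Before any rating, channels with
a recorded reaction free energy are screened: only strictly exergonic
channels ($\Delta G_r < 0$) enter the kinetic treatment; a channel at exactly
zero is dropped and logged, since it contributes no thermodynamic driving
force.

A worked example:

```{r}
res <- evaluate_profile(bundled_profile("oli_hoo"), run_config(log_level = "quiet"))
res[res$medium == "water", c("mechanism", "site", "state", "k_app", "f", "k_f", "gamma")]
unique(res$k_overall[res$medium == "water"])
```

The electron transfer from the 0.32% phenolate population dominates the
hydroperoxyl scavenging in water ($\Gamma = 100$), a mole-fraction effect the
lipid medium cannot provide.

### Chelation and pro-oxidant chemistry

Complexation free energies convert to equilibrium constants as
$K_f = e^{-\Delta G/RT}$; each ligand protonation state contributes
$K^{II} = K_f \cdot f$, and the apparent constant is the sum over states.
Only the monoanion is chelation-active in the bundled copper set — the
carboxylate-adjacent hydroxyl is the viable binding motif — though the
schema accepts any number of states. The pro-oxidant step (electron transfer
from ascorbate or superoxide to the complex) reuses the Marcus + TST +
Collins–Kimball chain.

```{r}
prooxidant_table(bundled_chelation()$redox)[, c("complex", "reductant", "delta_g_act", "k", "k_app")]
```

## Input format and bundled data

Profiles are YAML/JSON documents (or CSV bundles) with `schema: 1`; readers
refuse unknown schema versions and unknown fields outright, so fixtures stay
stable against silent drift. Energies are stored in kcal/mol — the unit every
reference value is printed in — and converted to SI only inside the rate
evaluation. A tunneling entry of exactly `0.0` is treated as "not reported"
and replaced by $\kappa = 1$ with a warning: a genuine zero transmission
would annihilate a rate that the same data set reports as nonzero.

The package bundles transcriptions of the published olivetol/olivetolic-acid
parameterization (`bundled_profile()`): the hydroperoxyl profiles carry the
published one-decimal barriers and tunneling corrections, and — except for
the olivetolic-acid lipid 7CH channel, which is recomputed through the TST
route — the published apparent rates as `fixed_rate`, so that aggregation
reproduces the reference tables as pure arithmetic. Known quirks are kept
honest rather than reproduced: the reference table's weighted SET rate for
the olivetolic-acid dianion (1.87×10⁶) contradicts its own
$f \times k_{app} = 0.0013 \times 1.2\times10^9 = 1.56\times10^6$; the
pipeline reports the self-consistent value and the fixture notes the
discrepancy. The copper redox set carries per-pair diffusion limits
back-solved from the published $(k, k_{app})$ pairs — the sources do not
print them — and labels them as synthetic bookkeeping values.

## The synthetic generator

`generate_profile()` draws multi-site antioxidants with the statistical
structure the pipeline assumes: FHT barriers uniform on 2–25 kcal/mol
(published hydroperoxyl barriers span roughly 16–22, hydroxyl barriers run
to ~6), reorganization energies on 5–45 kcal/mol, up to three pKa values on
3–12, ~90% exergonic channels, and tunneling either as log-uniform scalars
up to 2500 or as sampled Eckart parameters with imaginary frequencies of
800–3200 cm$^{-1}$ (both ingestion paths exercised). Generation is
deterministic for a fixed seed and never perturbs the caller's RNG stream.
The generator emulates the *scalar* structure of real profiles only — it
does not sample correlated site chemistry, solvent-dependent barrier shifts,
or realistic pKa/charge coupling — so passing pipeline-closure tests shows
robustness of the machinery, not chemical realism of the inputs. The suite
pushes 1000 seeded profiles (plus 25 through the Eckart path) through the
full pipeline; problem sizes were chosen so the whole suite runs in well
under a minute.

## Numerical choices and edge cases

* Constants are CODATA values; $R = 1.987204\times10^{-3}$ kcal/(mol K)
  (thermochemical calorie).
* Temperature defaults to 298.15 K everywhere; it is a parameter, not a
  constant, and the Eckart average, TST and equilibria all accept it.
* `collins_kimball(0, 0)` returns 0; an infinite thermal rate (barrierless)
  returns the diffusion limit.
* Branching ratios on an all-zero channel set raise an error rather than
  return NaN.
* Report files display rates to 3 significant figures; weighted rates below
  $10^{-6}$ of the overall rate print as `~0`. (A coarser display threshold
  would swallow channels that the reference tables still print with
  $\Gamma = 1$, so the threshold errs on the side of showing numbers.)
* Reports contain no timestamps: identical inputs give byte-identical files.

## Known limitations

* Conventional TST with a 1-D Eckart correction only — no variational TST,
  small-curvature tunneling, or anharmonicity. Published tunneling factors
  computed with other schemes will not be reproduced from Eckart parameters
  alone, which is why profiles may carry printed $\kappa$ values directly.
* Macroscopic pKa only; site-resolved microspeciation and tautomer-specific
  fractions are out of scope.
* The chelation "constants" are treated as dimensionless equilibrium
  constants even where sources quote them with rate-constant units — a unit
  slip on the source side, noted rather than propagated.
* Branching ratios are instantaneous; no time-dependent product evolution.
* The one-decimal rounding of published inputs bounds attainable agreement:
  a barrier printed as 21.4 constrains the rate only to within ~9%, and an
  equilibrium constant from a free energy printed to one decimal is
  uncertain by up to ~9% as well. Tests assert 5% where the recomputed
  values land well inside it.
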
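---
title: "Models and methods behind ventmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ventmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventmix)
```

`ventmix` analyses food webs that mix photosynthetic and chemosynthetic
energy channels, the situation at shallow hydrothermal vents where
¹³C-enriched, ¹⁵N-depleted vent POM coexists with ordinary marine
production. This vignette is the package's own account of the models it
implements, the defaults it chooses where a choice had to be made, and
what its tests do and do not demonstrate.

## The mixing model

For consumer $i$ and isotope $j \in \{^{13}C, ^{15}N\}$ the tissue value
is modelled as

$$X_{ij} \sim N\!\left(\sum_k p_k(\mu_{jk} + \Delta_{jk}),\;
  \sum_k p_k^2(\omega_{jk}^2 + \tau_{jk}^2)\right),$$

with diet proportions $p$ on the $K$-simplex under a Dirichlet($\alpha$)
prior. This is the SIAR single-observation formulation: source spread
$\omega$ and TDF spread $\tau$ enter the *variance* of the mixture, and
there is no extra residual term — appropriate when each individual is fit
on its own, which is the package default (`per_individual = TRUE`).
Assumptions worth stating plainly:

* sources are Gaussian and mutually independent;
* the TDF is one trophic step, applied once (multi-step enrichment must
  be folded into $\Delta$ by the user);
* the $\sum_k p_k^2$ variance form means an even mixture has *smaller*
  predicted variance than a pure diet. A consequence users sometimes find
  surprising: even for two identical sources the likelihood is not flat
  in $p$ — only exchangeable — so the posterior mean falls back to the
  symmetric $1/K$, which is what the package's tests assert.

With `concentration_dependent = TRUE` the mixture weights become
$p_k q_{jk} / \sum_k p_k q_{jk}$ using per-source elemental
concentrations; the default is equal concentrations, since measured
concentrations are rarely reported for vent material.

### Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| herbivore TDF | −0.41 ± 1.14 (C), +2.52 ± 2.50 (N) | ‰ | guild-level literature compilation for primary consumers |
| carnivore TDF | +0.91 ± 1.04 (C), +3.23 ± 0.41 (N) | ‰ | same compilation, higher-order consumers |
| prior $\alpha$ | $(1, \dots, 1)$ | — | flat Dirichlet; no prior dietary information |
| `iterations` | 500,000 | draws | total across chains; ample for $K \le 3$ |
| `chains` | 4 | — | enables split-$\hat R$ |
| `burn_in` | 50,000 per chain | draws | adaptation window |
| `thin` | 15 | — | keeps stored draws modest |

An unregistered guild is always an error: silently defaulting a TDF would
hide a scientific decision. Single-replicate sources must be given an
explicit SD for the same reason — an `NA` SD never becomes a silent zero.

The "500,000 iterations" convention: the package reads `iterations` as
the *total* across chains (125,000 per chain with four chains), with
burn-in and thinning per chain. Retained draws: $4 \times (125{,}000 -
50{,}000)/15 = 20{,}000$.

### Sampler and numerical choices

The sampler is adaptive random-walk Metropolis in isometric log-ratio
(ilr) coordinates $z = V^\top \mathrm{clr}(p)$, with $V$ an orthonormal
Helmert basis; the inverse map is a closure of $\exp(Vz)$ and the density
on $z$ carries the Jacobian term $\sum_k \log p_k$. The proposal scale
starts at $2.38/\sqrt{K-1}$ and is tuned by Robbins–Monro during burn-in
toward a 0.30 acceptance rate, then frozen so the post-burn-in chain is a
genuine Markov chain. Chain seeds are derived deterministically from the
single user seed; identical inputs and seed give identical draws.

Convergence is monitored with split-chain $\hat R$ per source; values
above 1.05 raise a classed warning *and* are stored in the result, so a
pipeline cannot lose them. The mixing-polygon check is a per-isotope
bounding-box test of the consumer against the TDF-shifted source means: a
two-source "polygon" is a degenerate segment, so an exact hull test would
flag essentially every real consumer; the bounding box captures the
meaningful case (a consumer heavier or lighter than every shifted
source). Flagged consumers are still fitted — the likelihood handles them
— but the flag is reported.

The independent check on all of this is `grid_posterior_mean()`: an
exhaustive lattice integration over the simplex (feasible for $K \le 4$)
using the pure-R log-posterior, against which the MCMC must agree to
0.01 on every preset problem. The two routes share no sampling code.

## Amino-acid trophic position

`trophic_position()` implements the Glu/Phe estimator
$TL = (\delta^{15}N_{Glu} - \delta^{15}N_{Phe} - \beta)/\Delta_{diff} + 1$
with the aquatic calibration $\beta = 3.4$ ‰, $\Delta_{diff} = 7.6$ ‰ as
explicit, overridable defaults. Replicate means enter at full precision:
rounding them first (as printed tables do) shifts the third decimal of
$TL$, which is why the package reproduces one published crab at 2.54 and
the other at 2.49 against a printed 2.50. The propagated SD
$\sqrt{sd_G^2/n_G + sd_P^2/n_P}/|\Delta_{diff}|$ treats the calibration
constants as fixed; it quantifies replicate scatter only, and is an
extension beyond what such tables usually print.

## End-member inversion

`invert_pure_diet()` and `invert_mixed_diet()` solve the mass balance
backwards for a hypothetical source (e.g. an unsampled, even heavier vent
POM implied by ¹³C-enriched crabs). Deliberate choices:

* point algebra only — TDF uncertainty is not propagated, matching the
  "simple mass balance" character of the calculation; a full Bayesian
  inversion is out of scope;
* the mixed-diet scenario takes *explicit* weights summing to
  $1 - f$ rather than a hard-coded recipe. Published reconstructions of
  this kind often under-specify their weights; exposing them keeps the
  assumption visible and lets any variant be expressed. The equal-weight
  prey mixture used in the examples is one such variant, not a canonical
  answer.

## The synthetic-data generator

`simulate_consumers()` draws consumers from the mixing model's *own*
likelihood at known true proportions. That is the right tool for testing
internal consistency (does the sampler recover what the model generated?)
and exactly the wrong tool for claiming field realism: real consumers
integrate prey over time, route isotopes among tissues, and violate
normality. Passing recovery tests therefore validate the inference
machinery, not the ecological model.

Seeding uses counter-based substreams per consumer, so enlarging a
simulated dataset never perturbs the consumers already drawn.

The recovery benchmark fixes a well-separated scenario — two sources 5 ‰
apart on both axes with 0.3 ‰ SDs, no TDF shift or spread, true diet
(0.7, 0.3), 100 consumers — and requires |bias| < 0.05 with ≥ 85 %
coverage of 95 % credible intervals. One hundred consumers keeps the
coverage estimate's binomial noise (±3.5 % at one SE) well inside the
margin between the nominal 95 % and the 85 % floor. Per-consumer refits
in this benchmark use 20,000 iterations over two chains: the posterior SD
in this scenario is ≈ 0.05, so the Monte-Carlo error of each posterior
mean is two orders of magnitude below the bias threshold.

The KST preset catalogue pins the published configuration (sources,
consumers, guild assignments) so the whole pipeline can run on the real
study design. Two entries are deliberately qualitative: the crab problem
uses the taxon mean (per-individual values live in supplementary material
only), and the sea-snail problem applies the carnivore TDF because no
published choice exists for these mixed feeders; neither is used as a
numeric benchmark.

## Known limitations

* Two isotopes and one TDF step; no hierarchical (MixSIAR-style)
  covariates or random effects across individuals.
* The grid oracle is exponential in $K$ and stops at $K = 4$.
* Posterior means of strongly overlapping sources (anemone/coral
  problems) are prior-sensitive; the flat Dirichlet is a choice, not a
  law.
* `summarize_replicates()` uses the sample SD ($n-1$); with $n = 2$ this
  equals $|x_1 - x_2|/\sqrt 2$, which is how the vent-fluid POM spread
  used by the presets arises from two samplings.
* Printed-value comparisons in the tests use half-up rounding to the
  printed decimals; internal computation is full precision throughout.
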
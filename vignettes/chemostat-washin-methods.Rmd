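---
title: "Monod competition, wash-in kinetics and identifiability: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monod competition, wash-in kinetics and identifiability: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemevol)
```

## The model

`chemevol` models prolonged continuous cultivation of a bacterium (the
motivating system is *Lactococcus lactis* in glucose-limited chemostats) as
a deterministic Monod chemostat with $n$ competing strains:

$$\frac{dS}{dt} = D\,(S_{in} - S) - \sum_i \frac{\mu_i(S)\,x_i}{Y_i},
\qquad
\frac{dx_i}{dt} = \bigl(\mu_i(S) - D\bigr)\,x_i,
\qquad
\mu_i(S) = \frac{\mu_{max,i}\,S}{K_{M,i} + S}.$$

At steady state a single strain fixes the residual substrate at
$S^* = K_M D / (\mu_{max} - D)$ and its biomass at $x^* = Y (S_{in} - S^*)$.
A beneficial variant that appears in a resident population at steady state
invades at the rate $\mu_{mutant}(S^*_{parent}) - D$: this is the wash-in
mirror image of washout, and the entire selective dynamics of the system
reduces to it while the resident still controls the substrate.

Assumptions inherited from this formulation:

* a single limiting substrate, Monod kinetics, no maintenance or death
  terms, no product inhibition or diauxie;
* populations are effectively infinite (no drift) and emergence is a single
  deterministic introduction event, not a stochastic mutation supply (a
  seeded exponential-waiting-time mode exists in `emergence_spec()` but is
  off by default, because the quantity the data constrain is a single
  emergence frequency);
* biomass units are abstract ("biomass-unit": OD600, gDW/L, cell counts);
  the yield parameter carries the unit conversion.

## Parameters and defaults

| parameter | meaning | unit | default | why |
|---|---|---|---|---|
| `mu_max` (parent) | maximal growth rate | h$^{-1}$ | 0.7 | D = 0.5 h$^{-1}$ is ~70% of the parent's maximum |
| `mu_max` (evolved) | maximal growth rate | h$^{-1}$ | 0.55 | evolved strains' maximum drops towards the D they evolved at |
| `K_M` (parent) | Monod constant | mM | 0.1 | glucose-limited growth; `S*` = 0.25 mM at D = 0.5 |
| `K_M` (evolved) | Monod constant | mM | 0.01 | up-regulated high-affinity glucose PTS: better scavenger |
| `yield` | biomass per substrate | per mmol | 0.02 (both strains) | biomass did not change during evolution, so one shared yield |
| `D` | dilution rate | h$^{-1}$ | 0.5 | the evolution experiment's rate |
| `S_in` | feed glucose | mM | 25 | the medium recipe |
| `V` | working volume | mL | 60 | the miniature chemostat |
| emergence | frequency at first appearance | - | 1% at generation 70 | the fraction assay detects ~1%; first detection anchors emergence |
| `depth` | pyrosequencing reads/sample | - | 500 | plausible assay depth; not stated by any source |
| `cv` | concentration noise | - | 0.05 | HPLC-like proportional error |

These defaults are **not** fitted values (none are published); they are a
parameterisation chosen once to reproduce the qualitative record: the
evolved strain wins at every dilution rate below its own $\mu_{max}$, the
variant is detectable (1%) at generation 70, dominant (>50%) before
generation 210, and above 97% at generation 445. With these defaults the
per-generation selection coefficient is
$s = (\mu_m(S^*) - D)\,\ln 2 / D \approx 0.040$, which places the logistic
50% crossing near generation 185 (the full ODE crosses earlier still, near
generation 170, because takeover drags the substrate down and accelerates
selection) — dominance "by generation 210" is satisfied with margin, but
the pair (1% at 70, 50% at 210) cannot be matched exactly by any
constant-$s$ model, since those two points imply $s = 0.0328$.

## Generation arithmetic

Volume changes are $D \times t$; generations are volume changes divided by
$\ln 2$. The generation count is truncated, not rounded: 309 volume changes
give $309/\ln 2 = 445.8$, reported as 445. The mutation-rate helper takes
the number of doublings as an explicit argument: the canonical range
1.3–7.8 $\times 10^{-9}$ per bp per generation arises with 1–6 SNPs on a
2.5 Mb genome over **309** doublings, not 445 — the stated "per generation"
denominator is reproduced by the volume-change count, and we document
rather than hide that discrepancy.

## The logistic approximation and when it holds

While the resident controls the substrate, the variant frequency follows
$\mathrm{logit}\,f(g) = \mathrm{logit}\,f_0 + s\,g$ with
$s = (\mu_m(S^*_p) - D)\ln 2/D$ per generation. The approximation degrades
as the variant takes over and drags the substrate from the parent's
steady state ($S^* = 0.25$ mM) towards its own ($S^* = 0.1$ mM). Measured
against the full ODE with the default strain pair, the maximal fraction
discrepancy is about 0.2% while the substrate is within 1% of the parent
steady state, about 0.7% within a 2% band, and about 3% within a 5% band;
the test suite asserts 2% on the 2% band and 4% on the 5% band. Past the
takeover the closed form is qualitatively wrong (the true parent decline is
much faster), which is why `simulate_washin()` — not the logistic — is the
fitting engine.

## Structural identifiability

With fraction-only observations two parameter pairs are estimable only as
ratios:

1. **The two Monod constants.** At quasi-steady substrate, scaling both
   $K_M$ by $c$ scales $S^*$ by $c$ and leaves every growth rate unchanged,
   so the fraction series is invariant. The invariance is exact only in the
   $S^* \ll S_{in}$ limit: the feed term $D(S_{in}-S)$ does not rescale.
   At $S^*/S_{in} = 1\%$ the residual fraction change under $c \in
   [0.5, 2]$ is ~$10^{-3}$.
2. **Biomass yield and emergence amount** (absolute-emergence mode). In
   substrate-equivalent coordinates $b_i = x_i / Y_i$ the dynamics close,
   and yields enter only through the output map and the initial condition
   $b_m(t_e) = \text{amount}/Y_m$; scaling the common yield and the amount
   together is an exact symmetry. Because the invariance requires both
   strains' yields to move together, inference exposes a single shared
   `yield` parameter (consistent with the observed constant biomass); with
   only the parent yield scaled the symmetry is broken at second order once
   the mutant is no longer rare.

`sensitivity_washin()` differentiates predictions with respect to
**log**-parameters (central differences, relative step 1%), so a ratio-only
pair shows up as a Fisher-information eigenvector aligned with $(1,1)$. A
direction is declared near-null when its eigenvalue falls below $10^{-6}$
of the leading one. The threshold was chosen from the measured spectrum:
exact symmetries sit at or below $10^{-15}$ relative, the approximate
$K_M$ symmetry at ~$10^{-8}$ (limited by the $S^*/S_{in}$ effect and
finite-difference noise), and identifiable directions at $O(1)$ — a
$10^{-6}$ cut sits in the middle of an eight-decade gap, whereas a
$10^{-8}$ cut would ride on top of the $K_M$ pair's actual eigenvalue.
Adding absolute biomass observations (log scale) restores the
yield/emergence pair: in the test suite the FIM condition number improves
by far more than the asserted factor 10.

## Fitting choices

* **Loss.** Residuals on the logit-frequency scale by default (the
  sigmoidal rise spans four decades of odds; the fraction scale is
  available). Observed and predicted fractions are clipped identically at
  the half-read continuity correction $1/(2 \cdot \text{depth})$ when read
  depths are known (else $10^{-6}$): a zero-count sample and a model
  fraction of zero then agree instead of contributing an arbitrary
  clip-dependent residual. This mattered: with a naive $10^{-12}$ clip the
  recovered $K_M$ ratio was biased by tens of percent; with the continuity
  correction the 20-replicate bias is below 1%.
* **Optimiser.** L-BFGS-B in log-parameter space within user bounds;
  multi-start with 8 initialisations (log-bound midpoint plus a seeded
  Latin-hypercube, default seed 1363), best value reported.
* **Covariance.** Linearised (Gauss–Newton) at the optimum, via a
  pseudo-inverse; flagged singular when the smallest $J^TJ$ eigenvalue
  falls below the near-null threshold. Profile likelihood is deliberately
  out of scope.

## Synthetic data: what it emulates and what it does not

`generate_evolution_dataset()` produces, per sampling generation
(default every 20 generations, matching the "every 15–25 generations"
sampling of the motivating experiments):

* total biomass with multiplicative lognormal noise (mean-one, CV 0.05);
* metabolite concentrations (lactate, acetate, formate, ethanol, pyruvate)
  from per-strain fermentation stoichiometries mixed by strain fraction —
  the parent homolactic-dominant (lactate:acetate = 16), the evolved strain
  mixed-acid-shifted (ratio 7) with pyruvate overflow (0.2 mol/mol); both
  modes are redox-closed and carbon-closed, so the synthetic fluxes are
  consistent with the ATP computations;
* pyrosequencing read counts, multinomial over wild type and two mutant
  codon variants at depth 500.

It does **not** emulate: drift or clonal interference, assay-specific
pyrosequencing biases, slow drifts in reactor conditions, read-level
sequencing artefacts, or replicate-to-replicate reactor variation. A green
recovery test therefore establishes that the estimator is consistent and
calibrated *under the stated observation model*, not that the model is a
complete description of a real reactor.

Michaelis–Menten uptake data (`generate_uptake_data()`) use the assay range
1.2–200 uM with multiplicative noise. `fit_uptake_kinetics()` consequently
defaults to least squares on $\log v$ ("proportional" error model): under
multiplicative noise the absolute-scale fit is misspecified and its Wald
intervals under-cover (measured 83% for $V_{max}$ at nominal 95%), while
the log-scale fit is correctly specified (~95%). The absolute model remains
available, and both are exact on noise-free data.

## cre-site scanning conventions

The degenerate consensus (default `TGNNANCGNTTNCA`, 9 fixed positions) is
matched by IUPAC set membership; `N` matches everything. Coordinates are
0-based half-open internally and in BED-like output, 1-based in prose and
in the key-position rules (C7, G8, C13, T10 — `classify_site()` labels a
site consensus-like when C7, G8 and C13 are all present and flags a missing
T10 as atypical). Both strands are scanned; overlapping hits are all
reported and a palindromic match counts once per strand. Position frequency
matrices add a pseudocount (default 0.5) and report per-position
information content against a uniform background,
$IC_j = 2 + \sum_b p_{bj}\log_2 p_{bj}$; a GC-aware background is out of
scope. On a uniform background the expected number of exact-consensus false
hits is (windows) $\times (1/4)^9$, which the scan reproduces within
binomial error in the acceptance suite.

## Numerical choices

* Integration: adaptive Dormand–Prince 5(4) (compiled), relative tolerance
  $10^{-8}$, absolute $10^{-10}$; state clipped at zero (no negative
  biomass or substrate). An independent fixed-step RK4 and the closed-form
  substrate-equivalent balance $T(t) = S_{in} + (T_0 - S_{in})e^{-Dt}$,
  $T = S + \sum x_i/Y_i$, cross-check it in the tests.
* Emergence events are handled by splitting the integration at the event
  time and adding biomass instantaneously.
* Crossing times (50%, 97%) are interpolated linearly on the logit scale
  between grid points.
* Uptake-fit initialisation: $V_{max,0} = \max v$, $K_{m,0} =
  \operatorname{median} S$; `nls` port algorithm with positivity bounds.

## Known limitations

* The fitted "true" parameter values of the motivating study are not
  published, so all inference validation is parameter-recovery against the
  synthetic generator, never value-matching.
* The washout limit exposed by `predict_competition()` is checked against
  **both** strains' $\mu_{max}$ and the error names the limiting strain;
  the package does not decide which maximum "the" prediction limit is.
* Wald intervals everywhere; no profile likelihood, no Bayesian posterior.
* The fermentation stoichiometry validator covers lactate / acetate /
  ethanol / formate / pyruvate overflow with PFL vs dehydrogenase acetyl
  routing; it is a bookkeeping device for ATP-per-glucose comparisons, not
  a genome-scale model.
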
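---
title: "Higher-order interaction modifications and food-web robustness: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Higher-order interaction modifications and food-web robustness: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`timweb` simulates what happens to a model food web when one species is
driven down by external mortality, and asks how the answer changes when
*trophic interaction modifications* (TIMs) — third species that strengthen
or weaken a consumer–resource interaction — are represented either in full,
as higher-order terms, or collapsed into fixed pairwise non-trophic effects
(NTEs). This vignette documents the model, every tunable that matters, the
numerical choices, and what the synthetic communities do and do not emulate.

## The bio-energetic model

Each species' biomass density $B_i$ follows a Lotka–Volterra system with a
linear (Holling type I) functional response and logistic self-regulation:

$$\frac{dB_i}{dt} = B_i\Big(r_i - m_i - \frac{B_i}{K_i}
  - \sum_{j \in \text{consumers of } i} \mu_{ij}\, a_{ij} B_j
  + \sum_{l \in \text{resources of } i} \mu_{li}\, e_{li} a_{li} B_l\Big)$$

Parameters follow quarter-power body-mass scaling:

| parameter | meaning | value | units |
|---|---|---|---|
| $r_i$ | intrinsic growth / metabolic loss | $1$ for producers; $-0.1\,M_i^{-1/4}$ for consumers | per unit time |
| $K_i$ | carrying capacity | $U(1,10)$ producers; $10^{U(2,3)}$ consumers | biomass density |
| $m_i$ | external mortality | 0 (set to 1 on the targeted species) | per unit time |
| $a_{ij}$ | attack rate | $\omega_j M_j^{-1/4}$, $\omega_j = 1/n_j$ | per density per time |
| $e_{ij}$ | assimilation efficiency | $U(0.05, 0.15)$ | dimensionless |
| $M_i$ | body mass | $\log_{10} M_i \sim N(2(\text{level}_i-1),\ 0.5)$ | arbitrary mass |

Two of these are package design choices rather than forced values. Body
masses use a mean consumer–resource mass ratio of $10^2$ with half a decade
of spread, a standard bio-energetic-model choice; both numbers are exposed
(`mean_log10_ratio`, `sd_log10`) because downstream robustness statistics
inherit them. Trophic levels are integer shortest-path levels (producers at
1, consumers at 1 + shortest directed path to a producer), because rates
and masses are assigned by discrete level class; prey-averaged fractional
levels would be the main alternative and would smear the mass distribution
rather than shift it. $\omega_j$ is frozen at $1/n_j$ at assignment and is
*not* recomputed when resources are lost, keeping attack rates constant
apart from TIM modulation.

## Topologies and the retention filter

Topologies come from the classical niche model targeting $C = L/S^2$
(default $S = 35$, $C = 0.14$), with cannibalistic links removed afterwards;
`realized_connectance()` reports the directed density $L/(S(S-1))$, and the
expected-TIM arithmetic uses $L = C\,S(S-1)$. Structurally degenerate draws
(disconnected webs, consumers with no directed path to a producer) are
rejected and redrawn rather than patched, which is cheaper than correcting
the bias any patching rule would introduce.

Each parameterised web starts at $B_i = 10$ and is integrated without TIMs
to equilibrium; species below $10^{-4}$ are dropped, and the community is
retained only if at least 18 species persist and the pruned web is
connected. Under the default parameterisation the persisting count has a
median around 15, so retention deliberately selects the upper tail —
retained communities average around 20 species. The surviving densities
become the reference vector $B^*$, which anchors everything downstream.

## The modification function

A TIM $(i, j, k)$ rescales the attack rate $a_{ij}$ by a factor
$\mu_{ijk}(B_k)$. We use a Gompertz sigmoid constrained by three
ecologically meaningful controls: on the scale $x = \log_{10}(B_k/B_k^*)$,
with $g = e\,\alpha/\sigma$,

$$\log_{10}\mu = \sigma\, e^{-e^{-g(x - \tau)}} - \sigma\, e^{-e^{g\tau}}.$$

This form is the unique anchored Gompertz satisfying: $\mu(B_k^*) = 1$
exactly (interaction strengths at equilibrium already incorporate the
modifier); the maximum log-slope is $|\alpha|$, attained at $x = \tau$; and
$\mu$ spans exactly $\sigma$ decades between its asymptotes. $\alpha > 0$
is facilitating, $\alpha < 0$ interfering; $\alpha = 0$ degenerates
continuously to $\mu \equiv 1$ and is special-cased to avoid `0 * Inf` at
extreme densities. When the modifier goes extinct, $\mu$ tends to its
finite asymptote — the modification persists at a fixed strength, there is
no singularity. Multiple TIMs on one link combine multiplicatively
(synergistically); antagonistic combination rules are out of scope.

The constants here are reconstructed from the published constraints rather
than copied from a closed form, so statistics that are sensitive to the
exact curvature between the asymptotes (notably the median attack-rate
change when a modifier is lost) can differ from values obtained with a
different sigmoid satisfying the same three constraints.

## The pairwise representation

To express a TIM as pairwise NTEs, the modified trophic term is partitioned
into a trophic part and a non-trophic part, and the trophic partner's
density in the non-trophic part is frozen at $B^*$: the resource $i$
receives the per-capita term $a_{ij} B_j^* (1 - \mu_{ijk})$ and the
consumer $j$ receives $e_{ij} a_{ij} B_i^* (\mu_{ijk} - 1)$, with
$\mu_{ijk}$ still evaluated from the live $B_k$. By construction the two
representations agree exactly whenever $B_i = B_i^*$ and $B_j = B_j^*$ —
`percapita_rates()` in `"full"` and `"pairwise"` mode coincide to machine
precision on that manifold, which the test suite checks. The partition is
exact only when each link carries at most one modifier (the multiplicative
combination cannot be split additively), so `"pairwise"` mode refuses
multi-modifier links. The frozen coefficients are the point of the
comparison: after the consumer or resource collapses, the pairwise NTE
persists while the full higher-order term dies with its trophic pair.

## Experiments

`run_robustness_test()` sets $m = 1$ on one species, integrates to a new
steady state, and classifies every species against $B^*$: extinct below
$10^{-4}$, functionally extinct below $B^*/10$, exploded above $10 B^*$,
persisting otherwise; the target's own status is excluded from the
secondary counts. `run_suite()` targets every species of every community in
turn — including basal species, since nothing excludes them — under one of
two protocols: the three-mode comparison (TIM rate 0.05, $\alpha \sim
U(-4,4)$, $\sigma \sim U(0.1,4)$, $\tau \sim U(-1,1)$, at most one modifier
per link, identical TIM draws across modes) or the multi-modifier
distribution protocol (rate 0.08, $\alpha \sim U(-3,3)$, $\sigma \sim
U(0.1,3)$, unlimited modifiers, full mode only). One master seed spawns
recorded per-community child seeds, so any single test is replayable in
isolation.

## Numerical choices

Integration uses `deSolve::ode` (lsoda, `atol` $10^{-10}$, `rtol`
$10^{-8}$) in windows of 500 time units; a run converges when the largest
relative density change across a window, over species above the extinction
threshold, falls below $10^{-6}$. Runs give up at $t = 3 \times 10^4$
(flagged non-converged and excluded from summaries, mirroring the
incomplete-integration accounting of the protocol). The horizon is
deliberately generous: truncating at $10^4$ leaves over 40% of robustness
tests unconverged — slowly damped oscillations are common after targeted
mortality — and excluding them biases the extinction summaries toward
fast-settling runs; at $3 \times 10^4$ about 80% of tests complete. Species
are never removed during integration; densities are clamped at zero if the
integrator steps negative, and classification happens post hoc. Integrator
failures (non-finite state, step-size collapse) are flagged `failed` and
excluded from all summaries.

Two definitional choices deserve note. In the path-length metric a TIM
contributes undirected modifier–resource and modifier–consumer edges (the
modifier touches both trophic participants); alternatives such as
modifier-to-link-midpoint constructions are not implemented. In the
growth-rate response census, *all* species' per-capita rates are evaluated
after the 1% reduction, including the perturbed species' own (which is
positive via relaxed self-regulation); counting only the other species
lowers the positive fraction by roughly two percentage points at typical
community sizes.

## What the generator emulates — and what it does not

The synthetic communities reproduce the study conditions: niche-model
topology, allometric rates, random TIM placement with equal probability for
every (link, modifier) combination, and TIM strengths anchored at
equilibrium. Real webs differ in ways that matter: TIMs are not placed at
random (consumer-avoidance modifications link trophically close species),
functional responses saturate, generality is not split evenly, and
empirical interaction strengths are not quarter-power-clean. Passing tests
therefore demonstrate properties of the model under its stated
assumptions, not predictions for any particular ecosystem.

## Problem sizes

The package's own checks run at reduced replication chosen to keep the
suites quick while leaving the qualitative contrasts highly significant:
the acceptance analyses use 12 retained communities (roughly 240 targets
per mode) and the test suite uses 6; the headline none < full < pairwise
ordering is already decisive at a handful of communities because the
comparison is paired by community and target. Means at this replication
carry sampling error of order 10–20% and are compared accordingly.

## Known limitations

- Appendix-level details of the original study design (exact body-mass
  distributions, the sigmoid's published algebraic form, convergence
  criteria) were reconstructed from the stated constraints; quantities
  sensitive to them — the mean extinction counts, the median attack-rate
  change factor, the mean path length of retained webs — are reproduced in
  ordering and order of magnitude rather than digit-for-digit.
- Dynamics are deterministic; no demographic or environmental noise, no
  adaptive rewiring, no saturating functional responses.
- The pairwise comparison is undefined for multi-modifier links by
  construction, so the two protocols differ in more than the TIM rate.
```
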
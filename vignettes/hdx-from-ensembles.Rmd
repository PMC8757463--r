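---
title: "Predicting hydrogen-deuterium exchange from conformational ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting hydrogen-deuterium exchange from conformational ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hxmap)
```

## The exchange model

Backbone amide protons (NHs) exchange with solvent deuterium only when
transiently exposed. In the Linderström-Lang scheme an NH interconverts
between a closed (protected) and an open (exchange-competent) state,
and exchanges from the open state at the intrinsic chemical rate
$k_{chem}$:

$$k_{obs} = \frac{k_{chem}\,k_{open}}{k_{close} + k_{chem}}.$$

In the EX2 limit ($k_{close} \gg k_{chem}$) the observed slowing,
expressed as the protection factor $PF = k_{chem}/k_{obs}$, reports on
the opening equilibrium:
$\Delta G_{HX} = -RT\,\ln K_{op} = RT\,\ln PF$. In the EX1 limit
($k_{close} \ll k_{chem}$) every opening exchanges and
$k_{obs} = k_{open}$. `ex_regime()` classifies a site by the ratio
$k_{close}/k_{chem}$, with the boundary at a ratio of 10 — the
crossover is gradual in reality and any single threshold is a
convention; ours is configurable.

Given a Boltzmann-weighted conformational ensemble, hxmap estimates
$\Delta G_{HX}$ per site directly from per-frame protection states:

$$K_{op} = \frac{\sum_n w_n (1 - PS_{n})}{\sum_n w_n PS_{n}},$$

where $PS_n \in \{0,1\}$ marks the amide protected in frame $n$ and
$w_n$ are frame weights. Exchange competence uses an implicit-solvent
adaptation of the structural criteria for exchange: an NH is protected
when it is either hydrogen-bonded **or** buried, since a broken but
deeply buried amide cannot reach solvent. Burial of the amide hydrogen
is a smooth neighbour count, $BL^H = BL^H_{bb} + 5\,BL^H_{sc}$, with
the side-chain term upweighted fivefold because a single-centroid side
chain under-represents the volume of the atoms it stands for.
Protection requires $BL^H > 5$ (strict) when no H-bond is formed.

### Geometric definitions

The H-bond score is a smooth, bimodal function built as the product of
two logistic switches: distance ($d_{H\cdots O}$, midpoint 2.5 Å,
width 0.25 Å) and angle (N–H···O, midpoint 120°, width 10°). Formed
backbone H-bonds in idealised secondary structure score ≈ 0.8–1.0,
broken ones < 0.1, so the 0.5 threshold sits in a region the score
rarely visits; the precise functional form matters much less than this
bimodality, and the switch midpoints/widths are this package's own
definitions chosen to realise it. The burial switch uses midpoint
6.5 Å and width 0.5 Å on all backbone heavy atoms and side-chain
centroids, excluding the site's own residue and its two sequence
neighbours (which would otherwise bury every amide trivially).
Candidate H-bond pairs are restricted to $|i-j| \ge 2$ because
nearest-neighbour backbone bonds are chemically impossible.

Amide hydrogens absent from coarse backbone input are inferred: 1.01 Å
from N, in the C(prev)–N–CA plane, opposing the bisector of the two
bonds at N — the planar trans-amide geometry. Collinear degenerate
input falls back to a flagged perpendicular direction.

## Denaturant dependence and m-values

Denaturant is modelled as destabilising each conformation in
proportion to its number of protected NHs ($N^{HB}_{closed}$):
frame $n$ is reweighted by
$\exp(-s\,N^{HB}_{closed,n}\,[den]/RT)$, where $s$
(kcal mol⁻¹ M⁻¹ per protected NH) is the single scale factor of the
model. The protected-NH count proxies the denaturant-sensitive surface
area exposed on opening. Under this exponential reweighting the
m-value of a site is *exactly*

$$m = -\frac{d\,\Delta G_{HX}}{d\,[den]}
    = s\left(\langle N^{HB}\rangle_{closed} -
             \langle N^{HB}\rangle_{open}\right)
    = m_{closed} - m_{open},$$

which the test suite verifies against finite differences to 10⁻⁶.
A small m-value therefore means the open sub-ensemble is nearly as
structured as the closed one — the signature of a local opening.
Sites are classified by $r = m/m_{global}$: local ($r < 0.15$),
subglobal ($0.15 \le r < 0.8$), global ($r \ge 0.8$). These
boundaries are conventions for reporting, configurable in
`classify_opening()`; the underlying $m$ values are the quantitative
output. `calibrate_s()` solves for $s$ so that a reference
(globally exchanging) site reproduces an experimental global m-value;
in the two-state limit $s = m_{global}/\Delta N^{HB}$ exactly.

Because a site can exchange through several openings at once, the
observed flux is the sum over routes,
$k_{obs} = k_{chem}\sum_j e^{-(\Delta G_j - m_j [den])/RT}$, and the
effective $\Delta G_{HX}$ is a log-sum-exp dominated by the cheapest
route. As denaturant preferentially stabilises large openings, the
apparent slope climbs from the local toward the global m-value; the
midpoint of that transition coincides with the concentration where
the two routes' free energies cross, a property checked analytically
in the tests.

The fitted `m_fit` uses the lowest four grid points by default
(configurable): experimental m-values are reported from low-denaturant
linear fits, while the full curve is intrinsically nonlinear whenever
exchange routes switch, so the per-point `local_slope` is reported
alongside it.

## Free-energy surfaces and replica combination

`fes_2d()` bins frames on two collective variables — conventionally
radius of gyration against the backbone H-bond count, or the first two
principal components of the flattened Cα–Cα contact map (contact =
distance < 10 Å, $|i-j| \ge 2$) — and reports
$F = -RT \ln p$ per bin, minimum-shifted to zero. Empty bins are
reported as missing rather than infinite. `pca_contacts()` supports
frame weighting so the decomposition can be centred on a target
thermodynamic state, with component signs fixed deterministically.

Replica-exchange data are combined with an in-package MBAR solver
(`solve_mbar()`): damped self-consistent iteration (damping 0.5) of
the coupled equations with log-sum-exp stabilisation, gauge $f_1 = 0$,
default residual tolerance 10⁻¹⁰. Damped fixed-point iteration was
chosen over Newton's method for robustness at the modest state counts
this package targets; the tolerance and iteration cap are arguments.
A state whose reweighting ESS falls below 2 triggers an overlap
warning. On discrete systems whose samples match the exact Boltzmann
populations the solver reproduces closed-form partition-function
ratios to the solver tolerance, which is how it is validated.

## Irreversible folding and trajectory truncation

When refolding is blocked by long-lived misfolded states the
equilibrium ensemble cannot be sampled directly. The truncation
protocol mimics the experiment, which starts from the native state:
each trajectory beginning in N is kept through its first denatured
(D) dwell and discarded from the first frame where it leaves D again
(the refolding attempt). "Leaves D" is operationalised as the first
non-D label after D entry — the source protocol is qualitative on
this point, and the choice is recorded in the mask metadata.
Macrostates are labelled by the fraction Q of native H-bonds formed
(`assign_macrostates()`, thresholds $Q_N = 0.8$, $Q_D = 0.2$; these
are package defaults, as is the choice of Q over RMSD, which matches
the H-bond-centric analyses elsewhere in the package). Because D
dwells are censored by trajectory ends — and some trajectories never
unfold — pooled truncated estimates systematically overestimate
stability relative to the true equilibrium; the test suite checks
this bias sign on two-state Markov chains with known equilibrium.

## The synthetic generator as ground truth

`state_model()` describes a protein as discrete states with free
energies and 0/1 protection templates; `build_three_tier_model()`
instantiates the canonical hierarchy (native; one local state per
site at $\Delta G_{local}$; contiguous ⌈n/3⌉-site subglobal blocks;
unfolded). Every estimator in the package can then be checked against
closed-form enumeration (`analytic_dg_hx()`, `analytic_m()`).

Enumeration mode emits one frame per state weighted by its exact
Boltzmann population, so pipeline results agree with the oracles to
machine precision even for openings populated at one part in 10⁶ or
less — gaps that i.i.d. sampling cannot reach at any practical n, and
the reason enumeration is the default validation mode for deep free
energies (e.g. 8 kcal mol⁻¹ at 300 K). Sampled mode draws i.i.d.
frames and exists to exercise statistical behaviour: estimates
converge at $1/\sqrt{n}$ and a per-site flip noise ε in the unfolded
template injects residual denatured-state structure, which measurably
lowers the recovered global m-value — the cooperativity failure mode
that makes simulated denatured ensembles too protected.

What the generator does **not** emulate: kinetic correlation between
frames (states are drawn i.i.d.; the trajectory-trace generator is
deterministic and serves only the truncation tests), realistic
geometry for non-native states (surrogate observables use constant
compact/expanded Rg values of 11 and 25 Å with 1 Å jitter, chosen
only to make surfaces bimodal), and correlated multi-site openings
beyond the block templates. Passing tests therefore demonstrate
estimator correctness under the stated thermodynamic model, not the
realism of any particular force field's ensemble.

Coordinate-level validation uses deterministic fixtures instead: an
ideal polyalanine α-helix (φ = −57°, ψ = −47°, ideal bond geometry,
built by natural-extension chain construction) whose n−4 i→i+4
H-bond ladder the geometry module must recover exactly, and a fully
extended chain with no H-bonds and second-neighbour-only contacts.

## Numerical choices and degenerate inputs

* All free energies are in kcal mol⁻¹ with R = 1.9872×10⁻³
  kcal mol⁻¹ K⁻¹; concentrations in M; coordinates in Å.
* Censored sites (never open, or never closed, in the weighted
  sample) report one-sided bounds — $\Delta G \ge RT\ln\sum w\,PS$
  for a never-open site — with a flag, never infinities: a rare
  opening absent at finite sampling is indistinguishable from an
  impossible one.
* Bootstrap uncertainties resample frames (optionally in contiguous
  blocks for autocorrelated input) with a fixed seed; censored
  resamples are dropped.
* Weighted estimators are invariant under uniform weight rescaling;
  reweighting renormalises to the input weight sum to keep bound
  conventions stable.
* Boundary conventions: H-bond threshold is closed (score ≥ 0.5
  counts), burial and contact cutoffs are strict (> 5, < 10 Å).
* Tied or degenerate inputs: single-frame ensembles censor every
  grid point; zero-variance PCA returns flagged zero projections;
  identical MBAR states return all-zero free energies.

## Problem sizes

The validation suite runs on 30-site state models (35 states in the
three-tier case), 10⁵-frame sampled ensembles, 15-residue coordinate
fixtures and 60×150-frame Markov traces; the full suite and the
acceptance script each complete in well under a minute on one core.
These sizes were chosen so that enumeration oracles are exact and
sampling checks have comfortable statistical margins.

## A worked miniature

```{r example}
model <- build_three_tier_model(30, dG_local = 2, dG_subglobal = 5,
                                dG_global = 8, temperature_K = 300)
en <- sample_ensemble(model, mode = "enumeration")
tab <- site_hdx(en$pm, n_boot = 0)
tab <- site_m_values(tab, en$pm, s = 0.05, den_grid = seq(0, 6, 0.5),
                     m_global = 0.05 * 30)  # s * (all 30 NHs exposed)
head(tab[, c("residue_index", "dG_HX_kcal_mol", "m_value",
             "opening_class")])
```

Every site exchanges predominantly through its cheapest route: the
2 kcal mol⁻¹ local openings dominate at zero denaturant, so fitted
m-values at low concentration are small and sites classify as local,
while the full curves bend toward the global slope as concentration
grows.

## Known limitations

* No back-exchange correction, deuterium fractionation factors, or
  peptide-level (mass-spectrometry-style) aggregation: the outputs
  are site-resolved equilibrium quantities.
* Intrinsic rates $k_{chem}$ (and their denaturant correction) are
  user inputs; no sequence-based rate model is included.
* The denaturant model is a strictly destabilising, urea-like linear
  proxy on protected-NH count; ionic denaturants and transfer-model
  surface-area treatments are out of scope.
* XTC trajectories are not read directly; convert to DCD or
  multi-model PDB first.
* The geometric switch parameters are package definitions; scores
  from other H-bond definitions will differ in detail even though
  any bimodal score with a mid threshold gives the same protection
  states.
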
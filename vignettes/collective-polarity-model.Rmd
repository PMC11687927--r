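---
title: "The collective polarity model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The collective polarity model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(copolarize)
```

## The model

Each cell is a static circular 1D periodic membrane of perimeter $L$
(default 10 length units, 100 grid points). Four polarity markers live on
it:

* **Rac and Rho**, small GTPases tracked as individual molecules. Each
  molecule is either membrane-bound (active) at an arclength position, or
  part of a well-mixed inactive cytosolic pool. Totals are conserved
  ($N = 300$ per species by default).
* **Branched F-actin** $A(s,t)$ and **bundled actomyosin** $B(s,t)$,
  continuous densities obeying two coupled reaction–diffusion equations
  on the same grid:

$$
\partial_t A = A\,(1 + \alpha\,n_\mathrm{Rac} + \epsilon_A) - A^2
  - m_0 A B + D\,\Delta A, \qquad
\partial_t B = B\,(1 + \alpha\,n_\mathrm{Rho} + \epsilon_B) - B^2
  - m_0 A B + D\,\Delta B,
$$

where $n_\mathrm{Rac}(s)$, $n_\mathrm{Rho}(s)$ count bound molecules
within the inhibition radius of $s$, $m_0$ is the network competition
strength, and $\epsilon_A$, $\epsilon_B$ are junction growth
modifications (zero away from the junction).

GTPase kinetics per time step $\Delta t$: a bound molecule unbinds with
probability $1 - e^{-k_\mathrm{off}\Delta t}$; each inactive molecule
binds with hazard equal to the spatial mean of the effective binding-rate
field, landing at a grid site drawn proportionally to that field; each
surviving bound molecule recruits an inactive molecule of its own species
to within the inhibition radius with probability
$1 - e^{-k_\mathrm{fb}\Delta t}$. The effective binding rate couples the
cytoskeleton back to the signalling layer:
$k_\mathrm{on}^\mathrm{eff}(s) = \gamma(s)\,k_\mathrm{on}\,
(1 + \beta\,A(s))$ for Rac (with $B$ for Rho). Rac and Rho are mutually
antagonistic: a binding or recruitment event whose target lies within the
inhibition radius of at least one opposite-species molecule is blocked
(hard veto by default; `veto < 1` gives the probabilistic variant). The
veto is evaluated against the molecules present after the unbinding phase
of the same step, so that rate amplifications at a junction act on the
current occupancy rather than on molecules that have already dissociated.

Cells in a group are stepped jointly; every intercellular term (the
$\gamma$ rate amplifications, the $\epsilon$ growth terms, and their
concentration-dependent variants) reads the neighbouring cell's
*previous-step* state. This explicit coupling makes an uncoupled group
exactly equal, bit for bit, to independent single-cell runs with matched
per-cell RNG streams — a property the test suite asserts.

### Numerics

The PDE step is explicit Euler with second-order central differences on
the periodic grid; negative excursions are clamped at zero. The time step
must satisfy $\Delta t \le \Delta s^2 / (4 D)$; the default
$\Delta t = 0.02$ s sits at 80% of that bound for $D = 0.1$. Per-step
stochastic event probabilities at baseline rates stay below 0.1 (strongly
amplified junction rates saturate the per-step probability by design —
a 1000-fold amplification is an effectively instantaneous event).
Actin fields start at the homogeneous unit baseline (the $n = 0$,
$\epsilon = 0$ logistic fixed point) plus a ±1% uniform perturbation, so
symmetry breaking is endogenous; 10% of each species starts bound at
uniform random positions.

Random numbers come from a per-cell xoshiro256++ stream seeded
deterministically from (root seed, cell index), so realizations are
reproducible and cells are independent unless coupled.

### Polarity readout

A cell's front–rear axis points to the circular midpoint of the largest
contiguous arc where $A$ exceeds $C_\mathrm{crit}$; the axis is undefined
(non-polarized) if either network never exceeds the threshold. Ties
between equal-length arcs break by integrated density, then by smaller
start index; in the degenerate case of the whole membrane above
threshold, the peak of $A$ is used. Doublet arrangements are classified
with cone rules: collision (both axes within an 18° half-angle of their
junction directions), co-alignment (circular difference < 45°),
misalignment (otherwise), non-polarized (either axis undefined); the
supracellular overlay requires a leader pointing > 22.5° away from its
junction with a follower pointing within 22.5° of the leader's center.
We read the "36-degree angle opening" and "45-degree contact region" of
the outcome definitions as *total* cone widths (±18° and ±22.5°), under
which collision and co-alignment are geometrically disjoint, making
their precedence immaterial. Square quadruplets add circular (CW/CCW
tangential) and paired (two internally co-aligned pairs ≥ 45° apart)
labels; chains use the all-pairwise < 45° co-alignment rule.
Classification is computed at the final recorded time; time-to-polarize
is handled separately as the earliest window of 100 recorded steps with
every consecutive axis change below π/12.

## The calibrated parameter profile

There is no canonical numerical parameter set for this model family —
the rates, coupling strengths and length scales are free choices — so
`params_default()` ships a calibration profile. Two statistics were used
as calibration targets, chosen before any coupling experiment was
scored:

1. a single cell polarizes spontaneously in at least 90 of 100
   realizations by $T = 100$ s, with a uniform axis distribution
   (Kolmogorov–Smirnov check);
2. an uncoupled doublet co-aligns in about a quarter of realizations —
   the value implied by independent uniform axes, since
   $P(|\Delta\theta| < 45^\circ) = 0.25$.

The calibration knobs were the $k_\mathrm{fb}/k_\mathrm{off}$ balance,
$\alpha$, the inhibition radius, and the free scale choices ($L$, $N$,
$C_\mathrm{crit}$, $\beta$, $D$). The resulting profile
($k_\mathrm{on} = 0.8$, $k_\mathrm{off} = 3$, $k_\mathrm{fb} = 2$,
$\alpha = 0.03$, $\beta = 4$, $m_0 = 2$, $D = 0.1$, inhibition radius
0.3, $C_\mathrm{crit} = 1.8$) produces fast molecular turnover (mean
membrane residence 1/3 s) with moderately bound pools (~50–60%), actin
densities of order 1–3, and a clean two-domain partition of the membrane
in polarized cells. The external stimulus amplitude (5× baseline at the
bump peak, raised-cosine half-width 90°) was set the same way: it is the
smallest round value at which a stimulated single cell polarizes toward
the cue as reliably as spontaneous polarization (its axis lands within a
few degrees of the cue center).

Uncalibrated choices a user may care about: the junction fraction
defaults to 25% of the perimeter; the structural modification magnitude
defaults to $|\epsilon| = 1$ (the scale used for whole-domain
growth-offset experiments); the concentration-dependent amplification
uses $\max(1, \gamma\,n)$ with $n$ the neighbour count within the
inhibition radius of the mirror-mapped point, so it degrades to baseline
where the neighbour is empty while preserving $\gamma \ge 1$.

## Design decisions on open points

* **Inactive pool transport.** The inactive pool is well-mixed per cell
  (the fast-cytosolic-diffusion limit) rather than an explicitly
  diffusing 1D field. Cytosolic diffusion is fast relative to membrane
  kinetics, and the well-mixed limit keeps a single stochastic kernel,
  which in turn keeps the doublet/single-cell bit-for-bit equivalence
  simple to guarantee. An explicitly spatial pool is the one variant we
  chose not to ship.
* **Bound-molecule mobility.** Bound molecules are immobile by default;
  membrane spread is carried by recruitment. A lateral membrane diffusion
  coefficient (`D_membrane`) is available; exploratory runs showed it
  blurs Rac/Rho segregation at the values needed to matter, so the
  default is 0.
* **Stimulus semantics.** While a stimulus is active the exposed cell's
  binding rates are spatially fixed (the actin feedback $\beta$ is
  bypassed), with the Rho profile the spatial complement of the Rac bump
  so their pointwise sum is constant. At a signal switch the newly
  exposed cell becomes profile-driven and the previously exposed cell
  reverts to actin-dependent rates.
* **Square layout.** Four lateral junctions between edge-adjacent cells;
  no diagonal contact through the center.
* **Screen grids.** The biochemical grid enumerates one amplified
  (species, rate) slot per cell over $\gamma \in \{1, 10, 100, 1000\}$
  by default, with a configuration hook for additional factor levels.
  The structural grid is the full $3^4 + 3^4 = 162$ enumeration.

## What the acceptance script computes

`scripts/acceptance.R` re-runs the main experiments end to end: the
uncoupled doublet baseline, the constant push-n-pull and
concentration-dependent crosstalk families, the stimulated structural
sweep, the signal-switch protocol, and the 4-cell chain and square
screens. Realization counts are 50–100 per configuration (the stimulated
81-configuration sweep uses a two-stage design: a 10-realization screen
followed by 40-realization refinement of the top six configurations);
with 100 stochastic realizations a reported percentage carries a
binomial standard error of up to five points.

## What the calibrated model does and does not show

At the calibrated profile the screens exhibit a consistent qualitative
structure: symmetric junction
couplings drive collision or misalignment, one-sided couplings leave
co-alignment at chance while already enabling supracellular trains, all
four strong asymmetric GTPase motifs and the constant push-n-pull actin
motif reach ≥ 70% co-alignment, concentration-dependent reciprocal actin
crosstalk yields leader–follower arrangements with no collisions, and
the square quadruplet under alternating Rac/Rho binding rotates
(circular alignment in essentially all realizations).

Known limitations of this calibration, properties of the profile rather
than missing mechanisms:

* Unbinding amplification anchors axes less sharply than binding
  amplification. A cell whose junction bans one species via a large
  $k_\mathrm{off}$ develops the complementary domain centered on the
  junction, but the domain's position fluctuates by a few tens of
  degrees over 100 s. Doublets tolerate this (pairwise 45° criterion);
  four-cell chains, which need all pairwise differences below 45°, lose
  most of their co-alignment probability through the end cells (which
  carry only one junction), and the square crosstalk case trades some
  paired arrangements for misalignment.
* After a mid-run stimulus switch the previously stimulated cell retains
  its established pattern: the actin-dependent binding feedback
  re-stabilises the old front once the fixed-profile rates are removed.
  Full dissociation of a species — the trigger for the neutralization
  rule — essentially never occurs at this profile, so re-polarization
  toward the new cue is rare. The switch protocol, the neutralization
  rule and the classifiers are all implemented and tested; low switch
  response is a persistence property of the calibrated dynamics.
* Concentration-dependent GTPase amplification behaves almost like the
  constant variant, because neighbour counts within the inhibition
  radius are rarely zero at $N = 300$ molecules per species.

The synthetic axis-track generator (`generate_axis_fixtures()`) emulates
classifier inputs only — angles with jitter, no membrane fields — so
classifier tests passing on fixtures says nothing about simulation
dynamics; the full-scale acceptance tests cover that separately.
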
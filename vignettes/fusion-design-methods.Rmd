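---
title: "Multiobjective evolutionary design of constrained fusion proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiobjective evolutionary design of constrained fusion proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusionGA)
```

## The design problem

`fusionGA` addresses a graft-design problem: transplant a donor binding
motif (the DNA-binding helix of the MyoD bHLH domain, donor residues
110–125) into a scaffold domain (helix 3 of the 58-residue,
three-helix Z domain derived from staphylococcal protein A), and then
search sequence space for variants of the fused seed that keep the
scaffold's structural character while both binding functions are held
fixed. The functional residues — eight Fc-binding positions of the
scaffold (5, 9–11, 13, 14, 28, 31 in scaffold numbering) and eight
DNA-contacting positions of the donor helix (110, 111, 114, 115,
117–119, 121 in donor numbering) — are *conserved*: the optimizer may
never touch them. `buildFusionTemplate()` performs the graft, remaps
both conserved sets onto 1-based fusion coordinates, and derives the
length of the fusion from its inputs rather than assuming it (reported
fused lengths for this system vary between sources, so nothing is
hardcoded).

Because full physics-based evaluation (free-energy modelling, molecular
dynamics) is far too expensive to run inside a search over millions of
sequences, candidate quality is reduced to three cheap, complementary
surrogates, and the search itself is a Pareto-ranked genetic algorithm.
The expensive physics is deliberately out of scope here: this package
covers the sequence-level optimizer and the downstream geometric and
kinetic *analysis* of externally produced structures and rates.

## The three objectives

For a candidate sequence $x$ the fitness is a vector
$\{f_1(x), f_2(x), f_3(x)\} \in \mathbb{R}^3$, every component oriented
so that **larger is better**:

1. **Secondary-structure agreement** $f_1$: a three-state secondary
   structure string over $\{H, E, C\}$ (helix, sheet, loop) is
   predicted for the candidate and locally aligned (Smith–Waterman,
   linear gaps) against the template's target string. The predictor is
   a *contract* — any `function(sequence) -> state string` works. The
   built-in default is a deterministic windowed Chou–Fasman-propensity
   baseline (window 5, ties broken H > E > C); an external
   neural-network predictor can be plugged in via `externalPredictor()`
   reading FASTA on stdin. Alignment parameters are not dictated by the
   problem; the defaults are match $= 2$, mismatch $= -1$, gap $= -2$
   per gapped position, all configurable through `alignmentParams()`.
   Linear (not affine) gaps keep the model minimal, and the score is
   clamped at the Smith–Waterman floor of 0.
2. **Hydropathy profile** $f_2$: each residue is mapped to its
   Kyte–Doolittle hydropathy, averaged over a sliding window of 7
   (truncated at the termini so the profile keeps one point per
   residue), interpolated by a natural cubic spline, and integrated
   over the profile support $[1, n]$. $f_2$ is minus the absolute
   difference between the candidate's integral and the template
   target integral. The integral — rather than a pointwise distance —
   lets opposing contributions of neighbouring residues cancel, which
   is the intended physical reading.
3. **Molecular-weight profile** $f_3$: identical machinery applied to
   average residue masses (Da), capturing steric bulk.

Two ambiguities were settled as package policy: the integral runs over
the profile support $[1, n]$ (the windowed profile has no values
outside it), and the spline family is the natural cubic interpolant,
integrated exactly via two-point Gauss–Legendre per knot interval
(exact for cubics; it agrees with dense trapezoid quadrature to
better than $10^{-8}$ relative, which the test suite checks).

## The genetic algorithm

Vectors have no natural total order, so candidates are compared by
**Pareto dominance**: $x$ dominates $y$ iff $x_i \ge y_i$ for all $i$
and $x_i > y_i$ for some $i$. For example $(3,1,2)$ dominates
$(3,1,1)$, while $(4,0,2)$ is incomparable to both. Nondominated
vectors form frontier 1; removing them and repeating yields frontier
2, 3, … — each individual's *Pareto rank*.

Each generation (defaults follow the study conditions: 600 individuals
per generation, mutation rate 0.01):

* **Selection** — two distinct parents drawn with weight $1/\text{rank}$
  (the simplest scheme that is strictly monotone in rank; a binary
  rank tournament is available as an alternative).
* **Crossover** — one-point crossover at a uniform cut; both parents
  satisfy the conservation constraint, hence so does every child.
* **Mutation** — each *free* position independently substituted with
  probability 0.01 by a uniformly chosen different residue. The rate
  is read as a per-position probability, which reconciles "mutate at a
  random position" with a stated rate of 0.01 (about 0.4 substitutions
  per offspring at 40 free positions — calibrated by a $10^5$-draw
  binomial check in the acceptance suite).
* **Replacement** — parents and offspring are pooled (600 offspring per
  generation, so a 2N pool), re-ranked, and truncated elitistically to
  N by (rank, then best $f_1$, then stable input order). Stability
  makes runs bitwise reproducible under a fixed `rngSeed`; elitism
  guarantees the rank-1 set never regresses, which the tests verify
  generation by generation.

The founder population consists of seed copies mutated at free
positions with probability 0.05 — diverse but seed-centred, since the
seed is the only sequence known to carry both binding sites. Duplicate
sequences are allowed; frontier sizes count individuals, not unique
sequences.

`countEvaluated()` reproduces the study-scale accounting: 600
individuals × 2000 generations = 1.2 million sequences assessed.

## Structural analysis

For externally produced Cα structures and multi-model PDB
"trajectories" (`readCaPdb()`), the package implements:

* `kabschSuperpose()` — least-squares rigid superposition via SVD with
  the determinant correction, so a *proper* rotation is returned even
  for near-planar inputs; near-collinear fit sets trigger a
  conditioning warning. The conventional fit region for this system is
  helices 1 and 2 (residues 6–17 and 22–33), with RMSD then read out
  over the grafted helix (residues 39–53); both are ordinary
  parameters with these defaults in the CLI, and no attempt is made to
  reconcile the two numbering conventions in which the graft is
  quoted (42–57 in scaffold numbering).
* `regionRmsd()` / `rmsf()` — Cα RMSD over a residue set, and
  per-residue fluctuation about the mean across frames (frames are
  assumed superposed; `superposeTrajectory()` does this).
* `smoothCurve()` — cubic smoothing spline for RMSD-vs-time curves.
  No smoothing factor is dictated; the default (GCV) is chosen so a
  noiseless linear series is reproduced exactly, which holds for any
  curvature penalty.

Only Cα analysis is implemented: all-atom RMSD would require full-atom
trajectories from external MD engines, which are out of scope.

## Association kinetics

The association criterion for a protein–DNA pair is purely geometric:
**reaction pairs** are cross-molecule polar–polar atom pairs (polar =
element N or O unless a custom flag is supplied; the convention behind
published criteria is not restated in full anywhere accessible, so the
standard N/O reading is declared explicitly) at strictly less than
4.5 Å in the bound reference complex; a diffusional frame counts as
associated when at least 3 of those pairs are strictly closer than
5.5 Å. Both cutoffs and the pair threshold are parameters of
`ReactionPairSet`. Strict inequalities follow the wording "less than"
/ "closer than".

`relativeKon()` normalizes measured association rate constants by a
reference complex, rounding half-even to three decimals. Applied to
the bundled published rate table (reference $k_{on} = 4.66 \times
10^8\, \mathrm{M^{-1}s^{-1}}$), it reproduces every printed cell;
the JW70 entry computes as 0.979 from the printed inputs while the
published table prints 0.978 — a one-unit rounding-provenance
discrepancy (the published value was presumably derived from unrounded
rates), documented rather than patched. The Brownian-dynamics
propagation and the Northrup–Allison–McCammon rate formula themselves
are not implemented; the package consumes externally computed rates or
synthetic frames and computes association fractions.

## What the synthetic fixtures emulate — and what they do not

`simulateTemplate()` draws a random canonical seed (default: the study
geometry, 56 residues with 16 conserved positions) and derives the
target secondary structure and profile integrals *from the seed
itself*. That makes the seed the known global optimum of all three
objectives — ideal for testing (the optimizer must rediscover a known
answer, constraint conservation is checkable exactly) but
deliberately easier than a real design, where the target profiles
come from a different molecule (pass `targetSeq` to
`designTemplate()` for that) and no sequence attains all optima at
once. Consequently the synthetic GA run converges towards seed copies
and its frontier sizes say nothing about the frontier sizes reachable
with an external neural-network predictor on the real system; those
published figures (67 and 86 individuals after 1000 and 2000
generations) depend on that predictor and on unpublished GA details,
and are treated as qualitative context only.

`simulateTrajectory()` produces an ideal α-helical Cα trace (2.3 Å
radius, 1.5 Å rise, 100°/residue) with isotropic Gaussian jitter
scaled so the expected 3-D RMSF of residue $i$ equals the planted
amplitude (per-axis σ = amplitude/√3); it has no covariance structure,
no anharmonicity, and no global drift, so it validates estimators, not
dynamics. `simulateComplexFrames()` plants an exact number of
associating frames by keeping or displacing the DNA wholesale — a
bookkeeping oracle, not diffusion.

## Problem sizes used by the checks

The test and acceptance suites run, as the package's own choice of
verification scale: the full worked dominance example plus exhaustive
oracle comparison over *all* lattice populations of size ≤ 3 from
$\{0,1,2\}^3$ and 2000 random populations (sizes 4–12 and real-valued);
alignment against exhaustive enumeration for all $\{H,E,C\}$ pairs of
length ≤ 3 and 300–500 random pairs of length 4–6 (full enumeration
over every pair up to length 6 would cost ~10⁹ alignment
enumerations for no additional structural coverage); a full-width GA
run at 600 × 100 generations; RMSF recovery at 10⁴ frames; and the
10⁵-draw mutation calibration. A 600 × 100 run takes well under a
minute on one CPU; study-scale 600 × 2000 runs scale linearly.

## Known limitations

* The propensity baseline is a 1970s-era single-sequence predictor;
  it is deterministic and fast but far weaker than profile-based
  neural predictors. Design quality with it should be read as a
  pipeline demonstration.
* Linear-gap, three-letter alignment only; no affine gaps or
  substitution matrices.
* No free-energy modelling, no MD/BD engines, no structure-based graft
  placement, no net-charge calculation; PDB input is limited to
  fixed-column single/multi-model files.
* Exact wild-type scaffold and donor sequences must be supplied by the
  user; the fixtures never embed them.
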
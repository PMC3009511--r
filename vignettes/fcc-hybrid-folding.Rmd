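---
title: "Hybrid constraint-programming / simulated-annealing folding on the FCC lattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid constraint-programming / simulated-annealing folding on the FCC lattice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fccfold)
```

## The model

A protein's primary structure is a sequence $s = s_1 \dots s_n$ over the 20
standard amino acids. In the lattice abstraction used here, a *conformation*
is an injective map $\varphi$ from residues to points of the
face-centered-cubic (FCC) lattice — the integer triples $(x,y,z)$ with
$x+y+z$ even — such that consecutive residues occupy lattice-adjacent
points. Two FCC points are adjacent when every coordinate differs by at
most 1 and the $L_1$ distance is exactly 2; every point has 12 such
neighbours, and three consecutive chain points can only form bond angles of
60, 90, 120 or 180 degrees. The FCC lattice is attractive for protein
models because it approximates real backbone geometry well and, unlike the
cubic lattice, is not bipartite with respect to chain parity.

Residues $i$ and $j$ are *in contact* when $|i-j|>1$ and their points are
at $L_1$ distance exactly 2. Note that this is deliberately a plain
distance criterion: offsets such as $(\pm 2,0,0)$ count as contacts even
though those points are not lattice-adjacent. The package implements this
definition as printed because it keeps the constraint model simple; a
`strict` flag restricts contacts to lattice-adjacent pairs for users who
prefer the tighter convention. The energy of a conformation is

$$E(\varphi) = \sum_{\substack{i<j \\ \text{contact}(i,j)}}
  \text{energy}(s_i, s_j)$$

where $\text{energy}(\cdot,\cdot)$ is a symmetric $20\times 20$ table of
dimensionless empirical contact potentials. Any conforming table can be
supplied as plain text (`read_potential()`); the shipped fixtures are a
uniform table (every pair at a constant, so $E$ counts contacts) and an
HP-style collapse (hydrophobic pairs attract, everything else neutral).
Finding $\min_\varphi E$ is the optimization problem; it is NP-hard even
for two-letter alphabets, which motivates the hybrid strategy below.

## The constraint model

Folding is phrased as a finite-domain constraint satisfaction problem. The
lattice variable $V_i$ holds the point of residue $i$; its domain is an
axis-aligned integer *box* $[D, \bar D]$, admissible when it contains at
least one FCC point and *ground* when it is a single point. Two constraint
families close the model:

* **chain adjacency** for each consecutive pair: $L_1$ distance 2 with the
  per-coordinate $\le 1$ cap;
* **non-overlap** for each pair with $|i-j|>1$: $L_1$ distance $\ge 2$.

Lattice parity makes distinct FCC points automatically $\ge 2$ apart, so
non-overlap is equivalent to all-different; the test suite asserts this
equivalence, and the solver exploits it (occupancy checks) while the model
keeps the printed $\ge 2$ encoding.

`prune_domains()` applies bounds consistency: interval arithmetic on box
coordinates bounds the achievable $L_1$ distance of every constrained pair,
and a box adjacent to a ground point is intersected with the $\pm 1$ cube
around it. Pruning runs to a fixpoint (hence is idempotent) and never
removes a solution; full arc consistency is intentionally not attempted,
because labeling re-checks every constraint and the subchain instances the
hybrid search generates are small. `enumerate_solutions()` then performs
complete backtracking search, labeling free variables left to right and
candidate points in lexicographic order, so enumeration order — and with it
every tie-break in the package — is deterministic. A guard (15 free
variables) refuses accidentally exponential requests.

## Pure CP mode

`solve_pure_cp()` searches the whole conformation space exhaustively. Since
the energy is invariant under lattice translations and the 48 signed axis
permutations, residue 1 is anchored at the origin and residue 2 at
$(1,1,0)$; the remaining residues range over a cube of half-width $h$
(default $\lceil n/2 \rceil$). At the first free level, candidates that are
not the lexicographic representative of their orbit under the anchor
stabilizer (swap $x/y$, negate $z$) are discarded — an energy-preserving
factor-4 reduction. Branch-and-bound pruning uses the admissible bound that
residue $m$ can close at most $\min(17, m-2)$ new contacts (a point has 18
lattice sites at $L_1$ distance 2, one of which holds its chain
predecessor), scaled by the most negative table entry present in the
sequence. Candidates are explored most-promising-first so good incumbents
arrive early; ties fall back to deterministic cell order. When the tree is
exhausted the returned energy is the proven optimum of the anchored space
(`complete = TRUE`); otherwise the incumbent is returned.

The box makes the space finite, so "optimum" always means "optimum within
the half-width $h$ box". For attractive potentials the optimum is compact,
and a box a little larger than the compact extent of the chain suffices;
the test suite's 15-residue oracle uses $h = 2$ (63 lattice sites for 15
residues), on the assumption — stated here explicitly — that a
maximum-contact 15-mer fits in that box. Consistently with the assumption,
several hundred independently seeded annealing runs over the unrestricted
space have never found a lower energy.

## The CSP as a neighbourhood generator

Complete enumeration is hopeless for whole chains of realistic length (the
number of self-avoiding walks grows roughly ten-fold per residue —
`count_saws()` gives the exact small-$n$ counts), but it is cheap for a
short window of a chain. One annealing move is:

1. draw a subchain length $l$ (and its dilation $b$) from the policy;
2. draw the window anchor uniformly;
3. fix both flanks at their current points (ground singleton domains);
4. give each window residue the cube of half-width $b$ around its current
   point;
5. enumerate *all* feasible re-placements and take the best.

`perturbation_policy()` holds the rows $(l, b, p)$. The shipped default is
$(7,3,0.5), (9,2,0.3), (11,1,0.15), (13,1,0.05)$: short windows dominate
because they are enormously cheaper, and the rare long windows provide the
escape moves; weights are renormalized defensively for user-supplied
policies. The window always contains its own current placement, so the
enumerated minimum can never exceed the current energy. Taken literally,
"pick the minimum" therefore makes an acceptance test vacuous — the search
would be pure greedy descent. The package's default instead proposes the
best solution *distinct* from the current conformation and leaves
accept/reject to the annealer; `strict_greedy = TRUE` restores the literal
monotone rule for users who want it. Window anchors may sit at either chain
end (one flank empty); forbidding that would freeze the terminal residues
forever.

Energy is accumulated incrementally during window enumeration (only pairs
involving window residues change); the test suite cross-checks these
incremental energies against the independent full pair-scan in R.

## Annealing

`run_hybrid()` starts from the deterministic compact initializer and runs
logarithmic simulated annealing: at iteration $k$ the proposal from the
neighbourhood generator is accepted when $\Delta E \le 0$, and otherwise
with probability $\exp(-\Delta E / T(k))$ at temperature

$$T(k) = \Gamma / \ln(k + 2).$$

The schedule constant defaults to $\Gamma = 1$: under a unit-attraction
table the median uphill proposal costs one contact ($\Delta E = 1$), and
$T(0) = 1/\ln 2$ accepts such a move with probability $\tfrac12$ — a
conventional starting acceptance rate. $\Gamma$ is a configuration field
and is recorded in every result. One iteration means one perturbation plus
one acceptance decision; production-scale runs conventionally use 2000
iterations (the default), while the package's own test runs use 300
iterations on 15-mers, which the recovery experiments show is ample at that
scale.

The initializer builds a layered zigzag: ten steps alternating
forward-left $(1,1,0)$ / forward-right $(1,-1,0)$, a two-step climb
left-up $(0,1,1)$ then right-up $(0,-1,1)$, ten reversed steps
backward-right $(-1,-1,0)$ / backward-left $(-1,1,0)$, another climb, and
so on while residues remain. The concrete move vectors matter (the initial
energy depends on them), which is why they are spelled out here; a test
sweep verifies the walk is self-avoiding for every length up to 500.
Starting from a compact shape rather than a straight chain is essential:
compact windows admit many feasible re-placements, so the CSP phase has
material to work with from the first iteration.

Reproducibility: a run is a pure function of (sequence, table, config). The
seed initializes R's single global RNG stream, from which both the
perturbation draws and the Metropolis draws are taken in a fixed order;
identical seed and config give bit-identical trajectories. The compiled
enumeration core is deterministic and consumes no randomness.

## What the synthetic fixtures do and do not show

Tests and the acceptance script run on seeded random sequences and on
uniform/HP fixture tables, not on empirical potentials. A uniform table
makes the optimum a pure maximum-contact problem, which is ideal for
oracle-based verification (the optimum is sequence-independent and can be
proven by complete search) but is easier than reality: empirical potentials
are heterogeneous, so real landscapes are rougher and real optima are not
known in advance. Likewise the test chains (5–20 residues, 300 iterations)
are far below the 54–74-residue, 2000-iteration scale of production runs;
those sizes were chosen so every optimum asserted by a test is one the
suite can prove by exhaustive search. Passing tests therefore demonstrate
correctness of the machinery — enumeration completeness, energy
bookkeeping, acceptance statistics, determinism — not predictive quality on
real proteins. Reproducing published benchmark energies additionally
requires the externally distributed empirical contact-potential table,
which is not bundled; the corresponding acceptance check documents exactly
where to place it.

## Known limitations

* Only the FCC lattice is implemented (no cubic or knight-move lattices).
* The neighbourhood is the subchain-CSP move only; pull-move local search
  is out of scope as a separate baseline technique.
* Pure CP mode with block-failure heuristics is not implemented; the
  complete-enumeration mode is intended for small chains and for proving
  test oracles.
* The contact definition is the plain $L_1 = 2$ criterion by default;
  analyses that require strictly lattice-adjacent contacts must pass
  `strict = TRUE` consistently.
* Energies are dimensionless; no temperature scaling of the potential
  table is applied.
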
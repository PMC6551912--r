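---
title: "Measuring the near symmetry of protein homomers"
author: "quatsym"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the near symmetry of protein homomers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quatsym)
```

## The measure

Most homo-oligomeric proteins are nearly, but not exactly, cyclically
symmetric. The Continuous Symmetry Measure (CSM) turns "nearly" into a
number: for a structure with atom coordinates $Q_k$ ($k = 1..N$),
centroid $Q_0$, and a cyclic point group $G$ of order $n$ generated by
a proper ($C_n$) or improper ($S_n$) rotation $T$ by $360^\circ/n$
about an axis $v$,

$$ S(G) = 100\,\frac{M(G)}{N(G)}, \qquad
   N(G) = \sum_k \lVert Q_k - Q_0\rVert^2, $$

where $M(G)$ is the minimal total squared displacement needed to turn
$\{Q_k\}$ into a $T$-invariant structure $\{P_k\}$. Each symmetric
structure induces a permutation $\pi$ of the atoms through
$T P_k = P_{\pi(k)}$, the optimal $\{P_k\}$ for a given $(T, \pi)$ is
the orbit average $P_k = \tfrac1n \sum_i T^{-i} Q_{\pi^i(k)}$, and the
minimisation can be written purely in terms of $(v, \pi)$:

$$ M(G) = \frac{1}{2n} \min_{v,\pi} \sum_{i=1}^{n} \sum_{k=1}^{N}
   \bigl\lVert T^i Q_k - Q_{\pi^i(k)}\bigr\rVert^2 . $$

$S = 0$ means exact symmetry; the theoretical scale runs to 100, but
for proteins — elongated structures with a large denominator — observed
values concentrate between 0 and about 3. With an improper generator
($S_1$ = mirror, $S_2$ = inversion) the same machinery yields the
Continuous Chirality Measure (CCM).

## Which permutations are allowed

For macromolecules the joint minimisation over $\pi$ is the hard part.
The package restricts $\pi$ with *sequence-aware equivalence classes*:
two atoms may swap only if they agree in element, residue type and
residue sequence number. A class then holds one atom per peptide, or
two per peptide for side-chain atoms whose labels are chemically
interchangeable by local side-chain symmetry (Val CG1/CG2, Leu CD1/CD2,
Phe/Tyr CD1/CD2 and CE1/CE2, Arg NH1/NH2, Asp OD1/OD2, Glu OE1/OE2).
These groups come from an explicit chemical table rather than from
stripping digits off atom names: Ile also has CG1/CG2, but its two
branches are topologically different and must not merge, and Asn/Gln
tail atoms differ in element. Hydrogens are deleted during preparation,
so the three-fold methyl case does not arise in the default pipeline.

## Finding the permutation: two-level assignment

For a fixed operation $T$, the best class-preserving permutation
minimising the $i = 1$ term is a linear assignment problem per class
with costs $A_{ij} = \lVert T Q_{a_i} - Q_{a_j}\rVert^2$, solved
exactly by the Hungarian algorithm in $O(k^3)$ (`hungarianAssign()`; a
pure-R shortest-augmenting-path implementation, since no assignment
solver is available as a dependency). A greedy baseline
(`greedyAssign()`) and the sequence-ordered baseline (atoms mapped by
within-chain serial order) are provided for comparison. Only the
$i = 1$ term drives assignment; the full orbit sum scores the final
result. The cycle-structure requirement on $\pi$ (cycles of length 1, 2
or $n$) is deliberately *not* enforced during assignment — there is no
efficient assignment algorithm under such constraints — but
`validateCycleStructure()` reports violations after the fact.

Atoms must not migrate between peptides. The *many-chains* scheme
guarantees this with two assignment levels: for every ordered peptide
pair $(i, j)$ the lower level computes the optimal class-preserving
atom map and its cost $B_{ij}$ (the class-preserving minimum
factorises over classes, which are of size 1 or 2 once restricted to a
pair, so this is cheap); the higher level runs the Hungarian algorithm
on $B$ to choose the peptide permutation, and the pair maps are
composed into the global $\pi$. With the Hungarian strategy the result
is optimal among all peptide-preserving, class-preserving permutations
for the $i=1$ objective.

## Finding the axis

For fixed $\pi$, expanding the orbit objective with the Rodrigues
rotation formula shows it is, up to a constant, $-2(v^\top A v +
d^\top v)$ for a symmetric matrix $A$ and vector $d$ assembled from
second moments of the coordinates. Maximising $v^\top A v + d^\top v$
on the unit sphere is the classical sphere-constrained quadratic
problem: in the eigenbasis of $A$ the Lagrange condition becomes a
secular equation in the multiplier, solved here by bracketed
root-finding above the top eigenvalue, with the standard hard-case
treatment when $d$ has no component along the top eigenvector. The
axis optimisation is therefore closed-form up to a 1-D root find and is
checked in the tests against a dense 2-degree grid search with local
refinement. Inversion ($S_2$) makes the objective axis-independent;
the solver flags this degeneracy and keeps the reference direction.

Two numerical conventions matter. First, the axis *sign*: $v$ and
$-v$ generate the same group but inverse generators, so for a fixed
$\pi$ the objective is not sign-symmetric; the solver canonicalises the
sign (first non-zero component positive) only at the end, flipping
$\pi$ to its inverse at the same time, which provably leaves every
orbit term unchanged. Second, the operation origin is fixed at the
geometric centroid and never optimised, matching the normalisation of
the measure.

## The iterative solver

`solveCSM()` alternates the two exact sub-steps: permutation from the
current axis, axis from the current permutation, evaluating the full
orbit objective each round. Iteration stops when the axis moves less
than `axisTolerance` (1e-6 rad) or $S$ changes less than
`csmTolerance` (1e-10), with a 50-iteration cap; well-formed homomers
converge in 2–4 iterations. Because the assignment step optimises only
the $i=1$ term while the axis step optimises the full sum, the
alternation can in principle oscillate; an oscillation guard keeps the
best state seen and stops when $S$ increases.

The initial axis performs a regression on the equivalence-class
centroids: for a $C_n$-symmetric structure these centroids lie exactly
on the axis, so the principal direction of their scatter recovers it.
For improper groups the same centroids lie *in* the mirror plane
rather than on a line, so the guess switches to the normal of their
best-fit plane (smallest principal direction) — a detail the proper
case does not need but that makes the mirror search start on the right
footing. The alternation is a local method, so the solver adds seeded
restarts (default 8: the regression guess, cones of 15–75 degrees
around it, and random directions); runs are deterministic given the
configuration seed.

## Preparation of raw PDB files

Raw crystallographic files need cleaning before the measure is
meaningful: HETATM/solvent records and hydrogens are removed, the
first-listed alternate location of each atom is kept, nucleic-acid
chains are rejected, and the chains are harmonised — any residue
position missing from one chain (declared in REMARK 465/470 or
detected by cross-chain comparison) is deleted from all chains, and
likewise per atom, after which every peptide has the identical
(residue, atom) sequence. Harmonisation also reorders atoms within
each residue to the first chain's layout, so "same ordinal" and "same
atom name" coincide downstream. Both cleaning steps are idempotent and
every removal is recorded in a `PrepReport`.

## The synthetic generator and what it does (not) show

`syntheticHomomer()` plants ground truth for every test: one template
chain of pseudo-residues (real residue names and PDB-legal atom names,
so preparation and equivalence code run unchanged) is replicated by the
powers of the generator about a planted axis and perturbed with
isotropic Gaussian noise. Options scramble the chain order in the file
(the planted orbit must still be recovered) and swap the coordinates of
interchangeable branch pairs in alternating chains (making the
sequence-ordered baseline geometrically wrong while the Hungarian
strategy recovers the truth — the scenario that motivates class sizes
of $2\ell$).

Defaults are chosen once to emulate the target data: 20 residues per
chain (~130 hydrogen-free atoms), ~12 Å from the axis, and noise of
0.25 Å per coordinate — the displacement scale implied by the B-factor
range (up to ~40 Å², i.e. RMS displacements of ~0.5–0.7 Å) of the
crystal structures the method is used on. With these defaults the
fixtures score S values in the 0.01–1 range, matching the observed
protein range (roughly 0 to 3). The generator makes no attempt at
physically realistic bond geometry; it reproduces the statistical and
combinatorial structure of the problem (orbit + noise + label
ambiguity), so passing tests validate the optimisation machinery, not
biophysical realism. Test problem sizes (chains of 5–12 residues, 50
replicates per noise level, 100 random axis problems, 1000 random
assignment matrices) are chosen so the full suite runs in a few
minutes.

## Known limitations

* Only cyclic groups with a single generator ($C_n$, $S_n$) are
  supported — no $D_n$ or cubic groups.
* Single-chain (internal/domain) symmetry is rejected rather than
  approximated.
* The returned $S$ is an upper bound on the true minimum: the
  assignment step optimises a surrogate ($i=1$) objective and the
  alternation is local, mitigated but not eliminated by restarts.
* Cycle-structure violations of $\pi$ are reported, not repaired; the
  nearest structure is exactly $T$-invariant only for valid cycle
  structures.

## A worked example

```{r example}
gen <- syntheticHomomer(groupOrder = 4, residuesPerChain = 8,
                        noiseSigma = 0.1, seed = 42,
                        scrambleChainOrder = TRUE)
res <- solveCSM(gen$structure, "c4")
res
peptideCycleNotation(gen$structure, peptidePermutation(res))
```
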
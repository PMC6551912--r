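# quatsym

Continuous Symmetry Measures for protein quaternary structure.

Most homo-oligomeric proteins are *nearly* cyclically symmetric.
`quatsym` quantifies the "nearly" for structural biologists and
bioinformaticians who want a single, comparable distortion number per
structure: the Continuous Symmetry Measure (CSM)

```
S(G) = 100 * M(G) / N(G)
```

where, for a cyclic point group `G` of order `n` generated by a proper
(`Cn`) or improper (`Sn`) rotation `T`, `N(G) = sum_k |Q_k - Q_0|^2` is
the coordinate spread about the centroid and

```
M(G) = (1/2n) min over (v, pi) of sum_{i=1..n} sum_k |T^i Q_k - Q_{pi^i(k)}|^2
```

is the minimal summed squared displacement to the nearest `T`-invariant
structure, minimised jointly over the symmetry axis `v` and a
permutation `pi` of the atoms. `S = 0` means perfect symmetry; protein
values typically fall between 0 and ~3. With an improper generator
(`S1` mirror, `S2` inversion) the same machinery gives the Continuous
Chirality Measure.

The optimisation alternates two exact sub-steps:

* **Permutation from axis** — sequence-aware equivalence classes (same
  element, residue type and residue number; chemically interchangeable
  branch atoms such as Val CG1/CG2 share a class) restrict `pi`; within
  them a two-level Hungarian assignment maps atoms within every peptide
  pair (lower level) and then whole peptides onto one another (higher
  level), so peptides are never broken apart. Greedy and
  sequence-ordered baselines are included for comparison.
* **Axis from permutation** — for fixed `pi` the orbit objective is a
  quadratic form in `v`; the constrained optimum on the unit sphere is
  found in closed form (eigenbasis + secular equation).

A preparation pipeline (`prepareStructure()`) reproduces the usual
cleaning: HETATM/solvent/hydrogen removal, first alternate location,
and cross-chain harmonisation of missing residues and atoms so all
peptides end up with identical (residue, atom) sequences.

## Worked example

```r
library(quatsym)

# a noisy C4 tetramer with planted symmetry, chains scrambled in file order
gen <- syntheticHomomer(groupOrder = 4, residuesPerChain = 8,
                        noiseSigma = 0.1, seed = 42,
                        scrambleChainOrder = TRUE)
res <- solveCSM(gen$structure, "c4")
res
#> CSMResult  S(C4) = 0.0131
#>   M(G) = 4.78563 A^2   N(G) = 36493.2 A^2
#>   axis: 0.000367 -0.000988 0.999999
#>   peptide permutation: 1 -> 4 -> 3 -> 2
#>   iterations: 2  converged: TRUE
peptideCycleNotation(gen$structure, peptidePermutation(res))
#> [1] "B -> C -> D -> A"
```

`S(C4) = 0.0131` says the tetramer is 0.013% of the way (on the 0–100
scale) from its nearest exactly C4-symmetric counterpart — highly
symmetric, as expected for 0.1 Å coordinate noise; the recovered axis
matches the planted z axis and the peptide cycle recovers the planted
orbit rather than the scrambled file order. `nearestCoords(res)`
returns the nearest symmetric structure; write it out with `writePDB()`.

For real structures:

```r
prep <- prepareStructure(readPDB("mydimer.pdb"))
solveCSM(prep$structure, "c2")            # quaternary symmetry
solveChirality(prep$structure)            # CCM (min over S1, S2)
```

A thin command-line front end is installed with the package
(`inst/exec/quatsym`):

```sh
Rscript inst/exec/quatsym calc --group c5 --out results mypentamer.pdb
Rscript inst/exec/quatsym prep raw.pdb --out clean/
Rscript inst/exec/quatsym compare --group c3 mytrimer.pdb
```

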
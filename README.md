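# knapcharge

Automated assignment of partial atomic charges to drug-like molecules
from the charge statistics of matching chemical environments, with the
total molecular charge enforced exactly up to a tolerance.

Force-field electrostatics need a fractional point charge on every atom,
and quantum-mechanical derivation is far too slow for screening large
compound libraries. Given a corpus of already-parameterised molecules,
`knapcharge` collects, for every rooted k-neighbourhood environment
(the subgraph induced by all atoms within graph distance k of an atom,
grouped by type- and root-preserving isomorphism), the histogram of
charges observed on the central atom. A query molecule then becomes a
windowed multiple-choice knapsack problem (ε-MCKP): one item set per
atom whose items are that atom's candidate charges (histogram bin
centers, weights w) scored by popularity (log bin counts, profits p),
and the solver picks exactly one candidate per atom maximising

    Σ p_i,σ(i)   subject to   c − ε ≤ Σ w_i,σ(i) ≤ c + ε

where c is the target total charge and ε defaults to 0.01 e. Weights
and capacity may be negative; the problem is weakly NP-complete (the
standard MCKP reduces to it via c′ = ε = c/2) and is solved exactly by
a pseudo-polynomial dynamic program over 10³-scaled integer charges and,
independently, by branch-and-bound on the 0-1 integer programming
formulation. Naive per-atom baselines (mean/median/mode), a leave-one-out
evaluation harness and a synthetic-corpus generator with ground-truth
environment charge models are included.

## Worked example

```r
library(knapcharge)

# a three-atom corpus molecule: X(0.1) - Y(-0.2) - X(0.1), total 0
mol <- molecularGraph(c("X", "Y", "X"), rbind(c(1, 2), c(2, 3)),
                      charges = c(0.1, -0.2, 0.1), identifier = "xyx")
db <- buildDatabase(list(mol), k = 2)
db
#> EnvironmentDatabase: 6 entries, kMax 2, alphabet {X, Y}
#> shell
#> 0 1 2
#> 2 2 2

assignCharges(mol, db, assignmentParams(k = 2, epsilon = 0))
#> ChargeAssignment (dp): 3 atoms, total 0.000 e, profit 1.38629
```

The two symmetric X atoms fall into one environment class (2 values,
profit ln 2 = 0.693 each), the Y atom into another, and the selected
bin centers reproduce the stored charges with the total met exactly.
The solvers can also be used standalone:

```r
inst <- epsMckpInstance(list(data.frame(w = c(-0.5, 0.2), p = c(1, 2)),
                             data.frame(w = 0.3, p = 1.5)),
                        capacity = 0.5, epsilon = 0)
solveDp(inst)
#> McKpSolution (dp): profit 3.5, weight 0.5, selection [2 1]
solveIlp(inst)   # same optimum via the 0-1 formulation
#> McKpSolution (ilp): profit 3.5, weight 0.5, selection [2 1]
```

A shell entry point wrapping the same functions ships in
`inst/scripts/knapcharge`:

```sh
knapcharge build-db --in corpus.sdf --k 3 --track-sources --out db.json
knapcharge assign   --db db.json --in query.sdf --epsilon 0.01 \
                    --solver dp --out charges.sdf --report report.json
knapcharge solve    --in instance.json --solver ilp --out solution.json
knapcharge evaluate --db-corpus corpus.sdf --k 3 --out eval.csv
knapcharge synth    --seed 1 --out corpus.sdf --truth truth.csv
```

Molecules are read and written as V2000 SDF with charges in a
`PARTIAL_CHARGES` data field (one 3-decimal value per atom), the target
total in `TOTAL_CHARGE`, and optional `ATOM_TYPES` overriding the
element symbols; a JSON schema is accepted as well. Exit codes: 0
success, 2 infeasible, 3 uncovered atoms, 64 usage.

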
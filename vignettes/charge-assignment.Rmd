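---
title: "Knapsack-based assignment of partial atomic charges"
author: "knapcharge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knapsack-based assignment of partial atomic charges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knapcharge)
```

## The problem

Classical force fields describe electrostatics with fractional point
charges on atoms (in elementary-charge units, e). Deriving those charges
quantum-mechanically is accurate but takes hours to days per molecule,
which rules it out for screening large compound libraries. The
alternative pursued here is data-driven: given a corpus of previously
parameterised molecules, look up, for each atom of a query molecule, the
distribution of charges observed on atoms with the *same chemical
environment*, and pick one candidate charge per atom. The catch is the
physics side constraint: the per-atom charges must sum to the molecule's
known integer total charge. Picking each atom's most popular charge
independently accumulates error and routinely misses the total by a
large margin; the whole point of the method is to make the per-atom
choices jointly.

## The model

A molecule is a vertex-coloured graph $G = (V, E, t)$: atoms carry type
labels from an alphabet $\Sigma$ (chemical elements by default, or
force-field atom types that refine them), bonds are untyped undirected
edges. The chemical environment of atom $v$ at shell size $k$ is the
subgraph induced on its $k$-neighbourhood

$$N_k(v) = N_{k-1}(v) \cup \bigcup_{u \in N_{k-1}(v)} N(u),
  \qquad N_0(v) = \{v\},$$

i.e. all atoms within graph distance $k$, *rooted* at $v$. Environments
are grouped into isomorphism classes under type-preserving,
root-preserving graph isomorphism; the root is distinguished because the
stored charge belongs specifically to the central atom. For each class
the database stores the histogram of observed central-atom charges
(3-decimal fixed point, the precision of the source data).

At query time every atom is matched to its class at shell $k$, falling
back through $k-1, \dots, 0$ if a class is absent (the shell-0 class is
the bare atom type, so a no-match means the element was never seen).
The per-atom histograms define a windowed multiple-choice knapsack
problem ($\varepsilon$-MCKP): atom $i$ becomes an item set $N_i$ whose
items are its histogram bins with weight $w_{i,j}$ = bin center and
profit $p_{i,j} = \ln(\text{bin count})$; the capacity $c$ is the target
total charge. Select exactly one item per set such that

$$c - \varepsilon \;\le\; \sum_i w_{i,\sigma(i)} \;\le\; c + \varepsilon$$

while maximising $\sum_i p_{i,\sigma(i)}$. Unlike the standard
multiple-choice knapsack, weights and capacity may be negative and the
weight sum is two-sidedly constrained; the standard problem reduces to
the windowed one by halving the capacity ($c' = \varepsilon = c/2$, so
the window is exactly $[0, c]$), hence the problem is weakly
NP-complete and pseudo-polynomial algorithms are the right tool.

The log-count profit is deliberate: within-class charge distributions
are heavy-tailed, so frequency-based scoring is preferred over scores
that assume normality (such as z-scores). A count-1 bin has profit
$\ln 1 = 0$ and remains selectable; no pseudo-count is added. The log
base is immaterial — any fixed base rescales all profits uniformly and
cannot change the optimiser.

## Solvers

Two exact solvers are provided and cross-checked against each other and
against exhaustive enumeration.

**Dynamic programming.** The instance is first made integral and
non-negative: weights, capacity and $\varepsilon$ are scaled by $10^3$
(sufficient for 3-decimal charges), then each set is shifted by its
minimum scaled weight $w_i^*$ and the capacity becomes
$\tilde c = 10^3 c - \sum_i w_i^*$. The transform preserves the feasible
selections exactly. A table over (set, exact weight sum $d$) is then
filled with the maximum achievable profit, where the empty prefix admits
only $d = 0$; the optimum is the maximum over
$\max(\tilde c - \tilde\varepsilon, 0) \le d \le \tilde c +
\tilde\varepsilon$. Time is $O(n(\tilde c + \tilde\varepsilon))$ for $n$
items; a profit-only mode keeps one rolling table row (space
$O(\tilde c + \tilde\varepsilon)$), while selection recovery stores the
full suffix table. Cells that are unreachable carry IEEE $-\infty$,
which propagates exactly under `max` and `+` in R.

**Branch-and-bound on the 0-1 formulation.** The binary program
(maximise total profit subject to the two window constraints and one
pick-exactly-one constraint per set) is solved exactly by depth-first
implicit enumeration: a partial selection is pruned when the interval of
still-reachable weight sums misses the window, or when the current
profit plus the remaining per-set maxima cannot beat the incumbent.

**Tie-breaking.** Co-optimal selections are real (sparse classes produce
equal-count peaks), so determinism requires a rule: the dynamic program
and the brute-force oracle both return the lexicographically smallest
co-optimal item-index vector. For the dynamic program this is done with
a suffix table (best profit using sets $k..m$ at exact weight $d$ —
whose first row coincides with the usual prefix table's last row) and a
greedy forward pass that commits, per set in order, the smallest item
index that still reaches the optimum. The branch-and-bound solver is
compared on profit only, as any exact solver of the binary program may
return a different co-optimum. A practical consequence of identical
item sets for key-equal atoms: whenever a symmetric co-optimum exists,
symmetric atoms receive identical charges.

## Histogramming

Bin widths follow the Freedman–Diaconis rule,
$h = 2\,\mathrm{IQR}\, n^{-1/3}$ with linear-interpolation (type 7)
quantiles, computed per class — it is robust to the heavy tails these
distributions show. Bin centers are aligned to the median charge and the
grid extends to cover the minimum and maximum; each value joins its
nearest center (boundary ties to the lower center), empty bins are
dropped, and centers are rounded to 3 decimals (coinciding rounded
centers are merged, so counts are conserved).

Two numerical choices deserve a note. First, when the FD width rounds
below 0.001 e (zero IQR, singletons, very tight classes) the class is
treated as discrete: every distinct value is its own bin and no
information is lost. Second, the alignment median is the *low* median
(the $\lceil n/2 \rceil$-th order statistic). For odd $n$ this is the
usual median; for even $n$ an interpolated median can fall in a gap
between the two modes of a bimodal class, leaving the aligned bin empty
— the low median is always an observed 3-decimal charge, so its bin is
never empty and "one bin center equals the median charge" holds
unconditionally alongside positive counts and dropped empty bins.

## Parameters

* `k` (default 3) — environment shell size. Larger shells are more
  specific but match fewer query atoms; the fallback ladder down to
  `kFloor` (default 0) trades specificity for coverage per atom.
* `epsilon` (default 0.01 e) — the absolute total-charge window
  half-width, not scaled with molecule size.
* `solver` — `"dp"` (default) or `"ilp"`; identical optima, different
  speed profiles.
* `factor` (default 1000) — the integer scaling factor; $10^3$ matches
  3-decimal charges exactly.

Infeasibility is a first-class outcome: when no bin combination lands in
the window, `assignCharges()` reports the achievable total-charge range
rather than inventing charges or silently widening the window (the CLI
offers explicit retry doubling via `--max-epsilon`, off by default).
Infeasibility does occur at small corpus scale, where sparse classes
contribute single quantized bins with no compensating freedom; it
becomes rarer as classes accumulate observations and bins.

## The synthetic corpus

Real reference corpora of quantum-mechanically parameterised molecules
are proprietary-scale; the package therefore ships a generator whose
output has the same statistical shape and a known ground truth, so every
stage is testable offline.

* Structures are random valence-respecting connected graphs (random
  tree growth plus ring closures with probability `ringProb` where
  valence allows) over a small element alphabet with chemical valence
  caps (C:4, N:3, O:2, H:1 by default), 5–25 atoms, 200 molecules.
* Each canonical shell-`envShell` (default 3) environment key owns a
  base mean charge drawn from $N(0, 0.1\,e)$ — a spread chosen once as
  realistic for drug-like partial charges — derived deterministically
  from a hash of (key, seed), so the model is consistent across
  molecules without enumerating keys in advance. An optional second
  mode (`modeWeight`, `modeOffset`) produces the heavy-tailed
  multimodal classes seen in real data.
* An atom's charge is its key's mean (or second mode) plus Gaussian
  noise (`noiseSd`, default 0.02 e), rounded to 0.001 e. The molecule
  is then nudged to its integer target total exactly by distributing
  the residual in 0.001-e steps over the atoms with the largest noise
  draws (any rule keeping per-atom perturbation small would do; this
  one is documented so tests can invert it, and `adjustTotals = FALSE`
  disables it to study the pure noise model). Adjustments beyond
  $3\sigma$ raise a warning and are flagged in the ground-truth table.
* Every structure is instantiated `minOccurrences` (default 2) times
  with independent noise, emulating the recurring scaffolds of real
  corpora and guaranteeing that each environment survives leave-one-out
  removal.

What the generator does *not* emulate: chemically valid bond orders,
aromaticity, realistic elemental composition, or the physics linking a
charge to its environment. Passing tests on this corpus demonstrate the
machinery — environment matching, histogramming, exact optimisation,
total-charge control — not chemical accuracy on real molecules.

## Leave-one-out evaluation

`evaluateLeaveOneOut()` builds a source-tracked database, removes each
molecule's own observations, re-assigns its charges from the remainder
with the windowed solver and with three naive baselines (per-atom mean,
median, or mode of the matched class, where multimodal ties pick the
mode closest to the median, remaining ties the lower charge), and
tabulates per-atom absolute distances and total-charge deviations.
Molecules whose atoms only match below shell `k` are evaluated via
fallback but flagged and excluded from the per-element aggregation;
molecules with an unmatched element are skipped and counted. On the
default synthetic corpus the windowed solver keeps every assigned total
within $\varepsilon$ by construction while the baselines miss integer
totals for many molecules — the qualitative contrast that motivates the
joint optimisation.

The test suite and the acceptance script run this protocol at 200
molecules of 5–25 atoms (about a minute); problem sizes were chosen so
the full suite stays interactive while the statistics (thousands of
atoms) are stable.

## Known limitations

* Profits are not normalised across atoms: a 2-observation class
  contributes at most $\ln 2$ while a 10,000-observation class
  contributes up to $\ln 10^4$, so data-rich atoms dominate the
  objective. No normalisation is applied, and none is obviously right.
* Bond orders are read but ignored by the isomorphism — the graph model
  colours vertices only. Two environments differing only in a double
  bond share a class.
* At small database scale, sparse multimodal classes make co-optimal
  solutions common and infeasibility possible; both are surfaced, not
  hidden.
* Persistence is plain JSON, adequate up to the tens of thousands of
  classes; no incremental updates or compression.
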
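---
title: "Exact geometry of the steady-state flux cone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact geometry of the steady-state flux cone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxcone)
```

## The model

A metabolic network is a stoichiometric matrix $S \in \mathbb{Q}^{m \times n}$
(metabolites in rows, reactions in columns) together with a partition of the
reactions into a reversible set $Rev$ and an irreversible set $Irr$.  At
steady state every internal metabolite is produced as fast as it is consumed,
so the feasible flux distributions form the *steady-state flux cone*

$$C \;=\; \{\, v \in \mathbb{R}^n \mid S v = 0,\; v_j \ge 0
\text{ for all } j \in Irr \,\}.$$

This package analyzes the polyhedral geometry of $C$ exactly:

* **Elementary flux modes (EFMs)** — nonzero $v \in C$ with inclusionwise
  minimal support; the minimal functional units of the network.  A vector is
  certified as an EFM by the rank test
  $\operatorname{rank}(S_{\ast,\operatorname{supp}(v)}) =
  |\operatorname{supp}(v)| - 1$.
* **The degree** $\deg(v)$ of a flux vector — the dimension of the
  inclusionwise minimal face of $C$ containing $v$, computable as
  $n - \operatorname{rank}(A_v^=)$ where $A_v^=$ stacks $S$ with one unit
  row per irreversible reaction inactive in $v$.  The smaller the degree,
  the "more elementary" the vector: vectors in the lineality space
  $L = \{v \mid Sv = 0, v_{Irr} = 0\}$ have degree $t = \dim L$, vectors in
  minimal proper faces degree $t + 1$, and vectors in the relative interior
  degree $\dim C$.
* **Metabolic behaviors** — the sets of irreversible reactions active in
  some flux vector.  The inclusion-minimal behaviors (MMBs) are in
  one-to-one correspondence with the minimal proper faces of $C$, and every
  behavior is a union of MMBs.
* **Decomposition** — every $v \in C$ with $\deg(v) = k$ is a conic
  combination of at most $k$ EFMs of degree at most $t + 1$, all lying in
  the minimal face of $v$.  The constructive route used here: solve one
  exact non-negative least-structure problem over all admissible low-degree
  EFMs, then remove linear dependencies Carathéodory-style until the active
  set is independent.

Degrees must always be evaluated in the original cone.  The enumeration
route splits every reversible reaction into a forward/backward pair, and in
that lifted pointed cone every extreme ray trivially has degree 1; mapping a
ray back and asking for its degree in $C$ is the only meaningful question.

## Why exact arithmetic

Every quantity of interest here — rank, dimension, degree, support,
membership, redundancy — is an integer or a set, and a single wrong
tolerance call flips it by one.  The package therefore performs **no
floating-point comparisons anywhere**: a rational kernel (reduced
numerator/denominator pairs) backs Gaussian elimination, nullspaces,
fraction-free rank computation, and a two-phase simplex with Bland's rule.
Bland's rule guarantees termination, so every LP verdict ("this maximum is
exactly zero", "this system is infeasible") is a certificate.

The kernel stores integers in doubles, which are exact up to $2^{53}$; every
product and sum is guarded and the computation aborts (rather than rounds)
if an intermediate would exceed $2^{51}$.  Tableau entries of the simplex
and elimination intermediates are quotients of minors of the input, so for
the desk-scale networks this package targets (tens of reactions, single-digit
stoichiometric coefficients) the guard is never approached.  Genome-scale
matrices would need an arbitrary-precision backend and are out of scope, as
is performance parity with dedicated enumerators such as efmtool.

## Canonical descriptions

Two preprocessing notions matter and are kept strictly apart:

* A **blocked** reaction carries zero flux in every $v \in C$ (its
  irreversibility constraint is an implicit equality).  Blocked reactions
  are detected by maximizing each flux over $C$ (normalized $v_j \le 1$)
  and kept as implicit equalities — columns are never deleted, so indices
  stay aligned with the input network.
* A **redundant** irreversibility constraint is implied by the remaining
  constraints; the reaction can be shifted to $Rev$ without changing $C$.
  Redundancy is re-tested one constraint at a time during
  `canonicalize()`, by default in lexicographic order (smallest index
  first), because the resulting irredundant description depends on the
  removal order.

MMBs depend on the chosen description even though $C$ does not: the
`example_network("branched")` network has MMBs $\{2\}, \{6,7\}, \{6,8\}$
with reaction 6 counted irreversible, and $\{2\}, \{7\}, \{8\}$ after
canonicalization.  The lattice and facet machinery therefore *require* a
canonical cone instead of canonicalizing silently; the analysis entry point
`analyze_network()` exposes the choice as a flag.

```{r}
net <- example_network("branched")
analyze_network(net)
```

## Enumeration and its oracle

`enumerate_efms()` splits reversible reactions, enumerates the extreme rays
of the lifted cone $\{w \ge 0 \mid [S, -S_{\ast,Rev}]\,w = 0\}$ with the
double description method (equality rows inserted in ascending index order,
adjacency decided by an exact rank test on the common zero set), maps rays
back, discards the futile two-cycle artifacts of the splitting, and
canonicalizes to primitive integer columns in a locale-independent numeric
order.  An EFM supported on reversible reactions only lies in the lineality
space; it is reported once and flagged, and all counts are reported both
with pairs counted once and doubled, since both conventions are in use.

`efms_brute_force()` is an intentionally independent oracle: it scans all
$2^n$ supports and applies the rank test, the one-dimensional-kernel check
and sign feasibility directly.  The two enumerators are compared
column-for-column on the built-in examples and on dozens of seeded random
networks in the test suite; this cross-validation, not either algorithm
alone, is the package's correctness argument.

```{r}
cone <- canonicalize(flux_cone(net))
efms <- enumerate_efms(cone)
efms
identical(efms$vectors, efms_brute_force(cone)$vectors)
```

## What the random-network generator does and does not emulate

`random_network()` draws integer stoichiometries uniformly from
$\{-2, \dots, 2\}$ at density $0.5$ by default, resamples until every row
and column is nonzero, and takes a random irreversible subset — a pure
function of its seed.  These defaults produce small, well-conditioned,
moderately sparse instances whose cones exercise all code paths (nontrivial
lineality spaces, blocked reactions, redundant constraints, reversible-pair
EFMs).  They do **not** emulate real metabolic networks: no conservation
structure, no bipartite reaction motifs, no heavy-tailed degree
distribution, no hundreds of reactions.  Passing the property suite on
these instances validates the polyhedral machinery, not biological realism.

## Numerical and procedural choices

* Primitive normalization: clear denominators by the lcm, divide by the
  gcd, sign so the first nonzero entry is positive — except that an active
  irreversible reaction fixes a vector's orientation outright.
* Carathéodory pivots break ties toward the lowest candidate index; the
  initial feasible combination is found over all admissible candidates at
  once rather than greedily, for determinism.
* Counting minimal decompositions scans $k$-subsets of the low-degree
  candidates and accepts exactly the subsets with a unique strictly
  positive solution; linearly dependent subsets are disqualified.
* Degenerate inputs: the zero vector has degree $\dim L$ and is not
  decomposable; a network with $Irr = \emptyset$ has $C = L$, no proper
  faces and only reversible-pair EFMs; blocked reactions may appear in no
  EFM support.
* Size guards (lifted dimension for enumeration, subset scans for the
  brute-force oracle and decomposition counting, facet count for the
  lattice) are ordinary function arguments, not hard-coded limits.
* FBA (`fba()`) runs the same exact simplex under box bounds, so the
  optimal value is exact and the degree of the returned vertex is
  well-defined; optimal *vectors* are generally not unique, and different
  optimal vertices can lie in different faces with different degrees, so
  only optimal values should be treated as reproducible.

The test suite sizes are deliberate: oracle equivalence runs on 50 seeded
random networks with $m \le 5$, $n \le 10$, the bound suite on the examples
plus 12 canonicalized random networks, and the decomposition suite on 50
seeded cone points per example network — large enough to exercise every
branch, small enough that the whole suite runs in well under a minute.

## Known limitations

* Double-based exact integers cap intermediate magnitudes at $2^{51}$;
  the kernel aborts loudly beyond that.
* Enumeration is exact but not performance-engineered; genome-scale EFM
  counts (millions) are far outside its envelope.
* Gene–protein–reaction rules, compartments, thermodynamic (loopless)
  constraints and inhomogeneous flux bounds (beyond per-call FBA boxes)
  are not modeled.
* The "with probability 1" genericity of minimal decompositions is checked
  statistically on sampled points, not proven for rational inputs.
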
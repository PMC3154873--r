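---
title: "Algebraic analysis of discrete dynamical models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Algebraic analysis of discrete dynamical models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polydyn)
```

## The model class

Discrete models of regulatory networks — Boolean networks, multi-valued
logical models, probabilistic Boolean networks — share a common algebraic
core. Fix a prime $p$ and let each of $n$ variables take values in the
field $\mathbb{F}_p = \{0, \dots, p-1\}$. A *polynomial dynamical system*
(PDS) is a map

$$ f = (f_1, \dots, f_n) : \mathbb{F}_p^n \to \mathbb{F}_p^n $$

whose coordinates $f_i \in \mathbb{F}_p[x_1, \dots, x_n]$ are
polynomials; iterating $f$ gives the synchronous dynamics. Because
*every* function $\mathbb{F}_p^n \to \mathbb{F}_p$ is a polynomial, the
class loses nothing: Boolean rules embed via NOT $a \mapsto a+1$, AND
$\mapsto ab$, OR $\mapsto a+b+ab$ over $\mathbb{F}_2$, and arbitrary
transition tables embed by finite-field interpolation
(`interpolate_table()`).

We restrict to prime fields. Every model type the package converts uses
at most $p$ consecutive levels per variable, so the generality of
$GF(p^k)$, $k>1$, would buy nothing and would cost an
irreducible-polynomial construction throughout.

### Canonical form

All polynomials are kept reduced modulo the *field equations*
$x_i^p - x_i$ (which every point of $\mathbb{F}_p^n$ satisfies): every
exponent is folded below $p$, coefficients are reduced mod $p$, zero
terms dropped, and terms sorted in graded lexicographic order with
$x_1 > x_2 > \dots > x_n$. The canonical representative of a residue
class is unique, which has two consequences the package leans on:

* two polynomials are equal *as functions* exactly when their stored
  term data are identical (`fp_equal()`), and
* a variable occurs in the canonical form of $f_j$ exactly when $f_j$
  genuinely depends on it — so wiring diagrams can be read off the
  support instead of searching for witness states.

`pds_compose()` canonicalizes after every substitution step, capping
per-variable degree growth at $p - 1$.

## Attractors as solutions of polynomial systems

A state $x$ is a **steady state** iff $f(x) = x$, i.e. iff it is a
common root of the system $\{f_i - x_i = 0\}$. States on a **limit
cycle** whose length divides $m$ are exactly the solutions of
$f^m(x) = x$. Identifying attractors is thereby *equivalent to solving
polynomial systems over* $\mathbb{F}_p$ — a classical computer-algebra
problem — and never requires walking the $p^n$-element state space.

### The elimination engine

`solve_system()` works in the quotient ring
$\mathbb{F}_p[x]/(x_1^p - x_1, \dots, x_n^p - x_n)$, where the input
ideal is automatically radical and zero-dimensional and all roots are
rational. Rather than a Buchberger-style Gröbner basis, the engine is
exact recursive elimination with unit propagation:

1. *Propagate*: zero equations are dropped; a nonzero constant equation
   kills the branch; an equation whose support is a single variable
   restricts that variable to its root set (found by trying the $p$
   values), and a singleton root is substituted into all equations that
   mention the variable.
2. *Split*: when propagation stalls, the solver branches on the variable
   occurring in the most equations (ties broken by lowest index; a
   univariate equation's reduced root set is preferred when available),
   substituting each consistent value and recursing.
3. Variables never constrained by any equation are free; the solution
   set is their Cartesian completion, guarded by a `solution_limit` so
   degenerate systems (e.g. the identity, whose fixed-point set is the
   whole space) fail loudly instead of materializing $p^n$ rows.

This is exact and complete — the test-suite holds it to *exact set
equality* against brute-force enumeration on hundreds of random systems
— and on sparse systems the propagation does almost all the work: the
fixed points of 150-variable networks (state spaces beyond $10^{45}$)
resolve in about a second. Sparseness and a small number of attractors
are exactly the structure biological networks are expected to have;
dense adversarial systems can of course force exponential branching,
which no exact method avoids.

### Limit cycles without symbolic composition

Composing $f$ with itself $m$ times symbolically can blow up term
counts long before $m = 10$. `limit_cycles()` therefore solves the
*unrolled orbit system*: variables $y^{(0)}, \dots, y^{(d-1)}$ (blocks
of $n$), equations $y^{(t+1 \bmod d)} = f(y^{(t)})$. Its solutions are
exactly the tuples $(x, f(x), \dots, f^{d-1}(x))$ with $f^d(x) = x$, so
block 0 carries the solutions of $f^d(x) = x$ while the system stays as
sparse as $f$ itself. This is run for each $d = 1..m$, so exact periods
that do not divide $m$ (e.g. period 3 when $m = 4$) are still found;
solutions are grouped into orbits by applying $f$, reported once each
with their exact period, printed from the lexicographically smallest
state. The default bound stays small ($m \le 10$ is ample: biological
limit cycles are short, and the cost of the orbit system grows with
$n \cdot d$).

`pds_compose()` remains available as an exported operation — it is the
natural tool for small systems and for testing — but the solver does not
depend on it.

### Exhaustive mode

For small models (`p^n` at most $2^{20}$ by default, configurable) the
full phase space can be built instead (`build_phase_space()`); its
functional graph yields the attractors, basins and component sizes, and
the test-suite cross-checks the two routes against each other. Larger
requests are refused with a typed condition (`polydyn_refusal`) pointing
to the algebraic route.

## Update disciplines

Synchronous updating is the default. A *sequential schedule* — a
permutation $\sigma$ in which each variable is updated once per sweep,
seeing its predecessors' new values — is handled symbolically:
`sequential_compose()` substitutes along the schedule and returns the
equivalent synchronous system of one sweep. Steady states are invariant
under the schedule (updating any coordinate of a fixed point changes
nothing); this is asserted property-style in the tests and in the
acceptance script. Fully asynchronous (random single-variable) updating
is a different, non-deterministic semantics and is out of scope.

## Multi-valued models and the common-field embedding

Variables of a logical model may have different numbers of levels. To
embed such a model over one field we take $p \ge$ the largest level
count and *extend* each table: out-of-range input levels repeat the
last defined row (equivalently, inputs are clamped to the variable's
declared maximum before lookup), applied per input variable
independently, and outputs are clamped to the target variable's own
maximum. Where only single-input extensions are pinned down by
convention, the multi-input rule (clamp each input independently, then
clamp the output) is this package's choice, made once and documented
here.

The extended states are artifacts of the embedding. They are *reachable*
in the resulting PDS, so rather than silently dropping them the
attractor report flags any attractor state carrying an out-of-range
level (`flag_artifact_states()`); such attractors should be ignored when
interpreting the original model. A separate validator
(`pds_is_continuous()`) reports whether a system moves any variable by
more than one level per step — a modeling convention of some
logical-model tools that conversion deliberately does not enforce.

## Structure: functional edges, signs, circuits

An edge $i \to j$ of the wiring diagram is *functional* when some state
exists at which changing only $x_i$ changes the next value of $x_j$.
Over the quotient by the field equations this is provably equivalent to
$x_i$ occurring in the canonical form of $f_j$, which is how
`functional_wiring_diagram()` decides it; the witness-search definition
is retained as the independent test oracle (`edge_witness()`).

For Boolean systems each edge is signed by the discrete derivative
$f_j|_{x_i=1} - f_j|_{x_i=0}$ across all contexts of the remaining
support variables: non-negative everywhere (positive somewhere) is
activation, non-positive is inhibition, both is *non-unate* (e.g. XOR).
Elementary circuits are enumerated by a DFS anchored at each circuit's
minimum node (counts can be exponential, so enumeration truncates with a
warning at $10^5$ circuits by default), and a circuit of unate edges is
signed by the product of its edge signs.

One point deserves care: a non-unate edge is activating in some contexts
and inhibiting in others, so a circuit through one has no single sign
but *can* realize positive feedback. `functional_circuits()` therefore
reports both `positive` (all edges unate, product $+1$) and
`positive_possible` (positive, or unsigned due to a non-unate edge). The
classical necessary condition — at least two steady states implies a
positive feedback circuit — holds for `positive_possible`, and that is
what the tests assert; random counterexamples exist if non-unate
circuits are excluded. A functional circuit is defined here as a circuit
all of whose edges are functional. Circuit analysis is restricted to
Boolean systems; multi-valued circuit analysis is deliberately not
implemented.

## Conjunctive and disjunctive networks

When every rule is a pure AND of its inputs (canonical form: one
squarefree monomial) and the wiring diagram is strongly connected, key
dynamics follow from the graph alone: the only steady states are
$0\cdots0$ and $1\cdots1$, and every limit-cycle period divides the
**loop number** — the gcd of directed cycle lengths, computed in linear
time from BFS level differences rather than by enumerating circuits.
Pure-OR networks reduce to the AND case by complementing every state,
so they share the code path. `conjunctive_attractors()` reports the
class, loop number, admissible periods (the loop number's divisors) and
the verified steady states; exact cycle *counts* per admissible period
are intentionally left to the general solver, which remains the
authority whenever the preconditions fail (the summary then falls back
to it with a notice).

## The random-network generator

`random_sparse_pds()` emulates the sparse regime of biological networks:
in-degrees are drawn from a Poisson distribution truncated to
`0..max_in_degree` whose rate is calibrated numerically so the truncated
mean equals the target (default 1.7, with a cap of 4 inputs) — without
the calibration, truncation would bias the realized mean low. Rules are
uniformly random truth tables over the chosen inputs, redrawn whenever
an input turns out non-functional, so the generated wiring equals the
intended one; pure-AND and random-coefficient families are also
available. Identical arguments plus seed reproduce the model file bit
for bit.

`implant_fixed_points()` plants prescribed fixed points by editing each
coordinate's *local* truth table (over its support) at the rows matching
the implanted states, augmenting the support with the fewest extra
variables needed when two implanted states share a local row but demand
different outputs. A full-state-table edit would be an $n$-variable
indicator polynomial — $2^n$ terms, hopeless at $n = 150$ — whereas the
local edit keeps rules sparse and still guarantees $f(s) = s$ exactly.
The cost is that states agreeing with an implanted state on a
coordinate's input set inherit that coordinate's edit; at most one local
row changes per implanted state per coordinate.

What generated networks do *not* emulate: real regulatory logic is not a
uniform random table (canalyzing rules are over-represented in curated
models), degree distributions of real networks are not Poisson, and no
attempt is made to constrain the number of attractors. Passing the
oracle-equivalence tests therefore certifies the *solver* on sparse
random structure, not any biological claim about attractor statistics.

## Probabilistic systems

A probabilistic PDS gives each coordinate a nonempty set of candidate
rules with a probability distribution (uniform when unspecified); each
time step, every coordinate independently draws one of its rules — the
standard probabilistic-Boolean-network semantics with per-coordinate
independence, which is this package's (documented) choice of update
model. Probabilities are exact rationals end to end, so the
all-transitions graph (`probabilistic_transition_graph()`) has weights
that provably sum to 1 out of every state. *True steady states* —
fixed regardless of every rule choice — are computed by pooling all
equations $f_{i,j} - x_i$ into one system and solving; this equals the
intersection of fixed-point sets over all deterministic selections (the
tests verify the equality by enumerating selections) but scales to
large $n$. Stationary distributions and perturbation dynamics are out
of scope.

## Problem sizes and numerical choices

Defaults, chosen once:

| parameter | default | why |
|---|---|---|
| exhaustive threshold | $p^n \le 2^{20}$ | phase-space graphs beyond $\sim 10^6$ nodes are neither plottable nor needed; the algebraic route takes over |
| cycle-length bound $m$ | caller-chosen, small | orbit-system size grows with $n \cdot m$; biological cycles are short |
| solution limit | $2^{20}$ states | underdetermined systems should fail loudly, not materialize $p^n$ rows |
| circuit cap | $10^5$ | elementary-circuit counts are exponential in general |
| generator mean in-degree | 1.7 (max 4) | sparse regime of regulatory networks |

The test-suite and the acceptance script run the oracle-equivalence
study at 200 random systems ($p = 2$ up to $n = 12$, $p = 3$ up to
$n = 8$ — the $p=3$ enumeration oracle, not the solver, is what limits
$n$ there), the implantation study at 50 networks with $n \in [50,150]$
and 1–5 planted fixed points each, schedule invariance at 50 systems,
and the structural study at 100 multistationary networks. All arithmetic
is exact (integer mod $p$; rationals for probabilities); there are no
floating-point tolerances anywhere in the method.

## Known limitations

* Worst-case solving is exponential; the package is fast for the sparse,
  few-attractor structure of biological models, not for adversarial
  dense systems.
* Only deterministic update disciplines (synchronous, sequential) are
  analyzed; asynchronous semantics are out of scope.
* Circuit and sign analysis is Boolean-only.
* Prime fields only; no $GF(p^k)$ with $k > 1$.
* The conjunctive fast path requires a strongly connected wiring
  diagram and reports structure (loop number, admissible periods,
  steady states), not per-period cycle counts.
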
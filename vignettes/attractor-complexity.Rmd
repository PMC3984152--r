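---
title: "Attractor-based complexity of Boolean recurrent neural networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attractor-based complexity of Boolean recurrent neural networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolrnn)
```

## The model

A first-order Boolean recurrent neural network consists of N activation
cells and M input units connected by rational synaptic weights, with a
rational background activity per cell. Time is discrete and updates are
synchronous: cell $j$ fires at $t+1$ iff

$$\sum_i w_{ij}\,x_i(t) \;+\; \sum_k v_{kj}\,u_k(t) \;+\; b_j \;\bowtie\; \theta_j,$$

where $x$ is the Boolean state vector, $u$ the Boolean input vector, and
$\bowtie$ is $\ge$ (`at_least`, the default) or $>$ (`strictly_greater`).
All parameters are exact rationals; the package rescales them to a common
integer denominator so the update is an exact integer comparison. Dynamics
are therefore bit-reproducible and invariant under multiplying every
parameter by a common positive rational.

Driven by an infinite input stream, the finite state space forces the
evolution to visit some set of states infinitely often; that set is the
*attractor* reached by the stream. Each attractor carries one of two types,
*meaningful* or *spurious*; the set of streams reaching a meaningful
attractor is the network's *neural language*. For ultimately periodic
streams $u\cdot v^\omega$ — the decidable test surface used throughout —
`evolve()` detects the loop by (state, period-position) repetition.

## Networks and omega-automata

The network's state graph, with the all-quiet state as initial state and
one labelled edge per input letter, is a deterministic automaton on (at
most) $2^N$ states.

* With an **output layer** (a designated cell subset), an attractor is
  meaningful iff some output cell fires inside it. This is deterministic
  **Büchi** acceptance: final states are those where an output cell fires
  (`network_to_buchi()`). The typing is inclusion-monotone — a supercycle of
  a meaningful cycle is meaningful — which is exactly the restriction of
  Büchi expressiveness (`buchi_segment_check()`).
* With an **arbitrary type assignment** on attractors, the same graph with
  the meaningful attractors as table is a deterministic **Muller** automaton
  (`network_to_muller()`).

Conversely, `buchi_to_network()` / `muller_to_network()` simulate any
deterministic automaton by a network. The construction uses $2^M$ letter
cells (the cell for letter $b$ fires iff the previous input was exactly
$b$), an ignition cell active from the first step onward, and one state cell
per (state, last letter) pair. Conjunctions are encoded as two half-weights
(1/2 from the active state cell, plus a half-strength letter detector on the
input units); because exactly one state cell is active per step, halves of
different transitions can never mix. We use (state, letter) product cells
rather than one cell per state precisely to preserve this no-crosstalk
property when several transitions share a target. Start-up is handled by a
background of 1/2 on the cells reachable from the initial state in one step,
cancelled from the second step on by inhibition from the ignition cell.
Undefined transitions silence the state cells forever, which rejects.

## Cycles, attractors, and typing

A *cycle* of the automaton graph is a state set admitting a closed walk
visiting precisely those states; attractors of the network are exactly the
cycles reachable from the all-quiet state (`attractors()`). A
*constitutive* cycle is vertex-simple. Any closed walk decomposes uniquely
into constitutive cycles by the stack algorithm
(`constitutive_decomposition()`): push states along the walk and pop a
constitutive cycle whenever the next state already sits on the stack.

Cycle enumeration is explicit and capped: all strongly connected induced
subsets are enumerated per SCC with bitmask reachability (SCCs are limited
to 20 states, caps raise errors rather than truncating). This is adequate
for the problem sizes the method targets (the case-study component has 16
states); polynomial-space counting for large graphs is out of scope.

Type assignments can come from an output layer, an arbitrary predicate, an
explicit list (which refuses unknown cycles rather than defaulting), or the
case study's neurobiological rule. The neurobiological rule is
walk-sensitive (it inspects time steps); to make the type of a bare state
set well defined, the package types the set through a deterministic
*canonical witness* walk: starting from the smallest state, greedily walk
shortest paths (ties towards smaller codes) to the smallest unvisited state,
then return. Equal sets therefore always receive equal types.

## The complexity degree

The degree measures how often the network can switch between meaningful and
spurious attractors along an evolution.

* **Chains (Büchi side, `max_chain()`).** An alternating chain is a
  sequence of distinct cycles of strictly alternating type, each next cycle
  accessible from the previous but not conversely ("alternating" starts
  successful, "co-alternating" non-successful). Cycles of a chain must lie
  in distinct SCCs, so the computation is a longest alternating path over
  the SCC condensation. Two opposite-type cycles in one SCC communicate and
  witness length $\omega$.
* **Trees (Muller side, `max_tree()`).** A tree additionally allows strict
  inclusion inside one SCC as an alternation step. Finite lengths are
  computed exactly by dynamic programming over all enumerated cycles,
  ordered by (condensation position, set size). Limit levels require
  genuine branching: a successful and a non-successful cycle in mutually
  inaccessible components, both reachable from a common point — once a run
  commits to one branch the other is lost, which is what an
  $\omega$-level choice needs. A single mixed SCC does *not* reach
  $\omega$ on the Muller side (inside one component the run's inf set is a
  single table entry). Chains of such branch pairs contribute
  $\omega\cdot m$; the search is exact for the finite fragment and for
  $\omega\cdot 1 + n$, and reports `status = "lower_bound"` beyond, never a
  silent answer.

Degrees are ordinals below $\omega^\omega$ in Cantor normal form
(`ordinal_compare()`, `format_ordinal()`). The case analysis
(`rnn_degree()`, `complete_degree()`): a one-sided maximal structure of
length $n$ gives degree $n$, non-self-dual; maximal structures of both
kinds give a self-dual degree; an $\omega$-chain gives $\omega$,
non-self-dual. At exact limit levels the classes are non-self-dual; the
reported kind there follows the type of the outermost witness element, a
deterministic convention.

## The basal ganglia-thalamocortical case study

The bundled model has 9 cells in fixed order (SC, Thalamus, RTN, GPi/SNr,
STN, GPe, Str-D2, Str-D1, Cerebral Cortex; SC is the most significant bit
of the state code) and one input unit projecting to SC and Thalamus with
weight 1. The published description prints the weight matrix but neither
background activities nor the threshold comparison, and its reference
trajectory is not reproducible with all-zero backgrounds: after the
all-active state 511 under input 1, SC and Thalamus receive sums 0.5 and
0 + b(Thalamus) + 0.5, and must nevertheless differ in the next state.

`bg_calibrate()` therefore searches comparison mode × per-cell backgrounds
on the grid $\{0, \pm 1/2, \pm 1\}$, pruned cell by cell against the
individual reference-walk transitions, and accepts a configuration iff
forward simulation reproduces the full reference walk *and* the set
reachable from the all-quiet state equals the published 16-state strongly
connected component. On this grid the admissible within-component dynamics
are unique, realised by `at_least` with background $+1/2$ on Thalamus; the
`strictly_greater` solutions are the same dynamics shifted by $+1/2$. All
calibrated values are labelled inferred in every output.

**Cycle census.** The published per-state census ("number of cycles and
constitutive cycles per starting state") depends on an unstated
walk-equivalence convention. The package implements three
(`closed_walks_from()` modes): rooted labelled-edge-distinct walks (the
default — the reference walk repeats vertices but no labelled edge, which
fixes edge-distinctness as the natural bound), rotation-identified walks,
and walks identified by their constitutive multiset. None of these — nor a
battery of further conventions explored during development (first-return
variants, vertex-visit bounds, length caps, labelled/unlabelled edges,
state-set counts) — reproduces the published counts on the uniquely
determined component graph; indeed the component carries only 22 distinct
vertex-simple cycles while published per-state constitutive counts reach
24. `bg_census_table()` therefore always reports computed and published
values side by side with per-row agreement flags, and `bg_calibrate()`
reports every convention's score instead of silently picking one.

**Degree.** Typing every cycle of the component with the neurobiological
rule (spurious iff SC fires with Thalamus quiet at some step, or GPi/SNr is
quiet during a strict majority of the period; composites by majority over
their constitutive cycles, ties meaningful) yields a maximal co-alternating
inclusion chain of length 4 starting spurious, with no alternating
structure of that length: the network is non-self-dual and lies strictly
beyond output-layer (Büchi) expressiveness, since a meaningful cycle sits
inside a spurious one. The published seven-cycle chain is not recovered,
and cannot be: the published rule itself types the published chain's
innermost cycle (0, 384, 223, 511, 63, 33, 0) as meaningful (GPi/SNr quiet
in 3 of 6 states is not a strict majority; no SC/Thalamus violation), while
the published figure labels it spurious. The package follows the rule.
The "strict majority of the period, endpoint counted once" reading is
forced by the published labels that *are* consistent: (33, 128, 95, 33)
must be spurious (2 of 3 quiet), which fails if endpoints are
double-counted.

## Synthetic fixtures and what the tests show

`random_network()`, `random_buchi()`, `random_muller()` draw
seed-deterministic instances (weights from $\{\pm 1, \pm 1/2, 2\}$ at
density 0.5 by default — the magnitudes the case-study circuit uses);
`planted_chain_automaton()` / `planted_tree_automaton()` build gadgets
whose maximal structure length and kind are known by construction and
re-verified at build time, and `relabel_automaton()` permutes state codes
to vary instances by seed. The language-equality contracts are tested
exhaustively on all ultimately periodic words with prefix and period up to
length 4 over the 1-bit alphabet (930 words), against independent
long-run-simulation and brute-force oracles written separately from the
implementation. These fixtures exercise the combinatorics of the method,
not biological realism: random topologies have no degree structure,
sparsity pattern, or signed organisation of real circuits, so passing tests
certify the algorithms, not any neuroscientific claim.

Problem sizes were chosen so the full suite runs in minutes on one core:
automata up to 4-6 states for exhaustive word checks, networks up to 4
cells for exhaustive state checks, the full 512-state case study for the
pipeline itself.

## Numerical and design notes

* All dynamics are integer-exact; there is no floating point anywhere in
  simulation, acceptance, or degree computation.
* Structure lengths count cycles, not alternations; structures are listed
  innermost/chain-start first, and a leading same-type cycle is excluded
  from the length rather than counted.
* Enumeration caps (`max_cycles`, `max_walks`, SCC size 20) fail loudly;
  truncation is never silent.
* Determinism: generators restore the caller's RNG state; the case-study
  pipeline contains no randomness and report reruns are byte-identical.

## Known limitations

* Transfinite tree lengths beyond $\omega\cdot 1 + n$ carry a
  `lower_bound` status rather than an exact value.
* Cycle enumeration is exponential in the SCC size by design; graphs with
  SCCs beyond 20 states are refused.
* The published case-study census and chain length are not reproduced, for
  the documented reasons above; the package exposes the discrepancy in its
  reports instead of resolving it by choice of convention.
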
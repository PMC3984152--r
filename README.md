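# boolrnn

Attractor-based complexity of Boolean recurrent neural networks.

Boolean recurrent neural networks — McCulloch–Pitts threshold cells with
exact rational weights, updated synchronously — settle, under any infinite
input stream, into an *attractor*: the set of states visited infinitely
often. When each attractor is classified as *meaningful* or *spurious*, the
network defines an ω-language (its *neural language*), and its ability to
switch between attractor types along evolutions yields a complexity degree:
networks with an output layer match deterministic Büchi automata, networks
with an arbitrary attractor typing match deterministic Muller automata, and
the degree is the length of a maximal alternating or co-alternating chain
(Büchi) or tree (Muller) of cycles — an ordinal below ω^ω in Cantor normal
form. `boolrnn` implements the whole calculus for researchers working on
Boolean network dynamics and ω-automata:

* exact rational threshold dynamics on ultimately periodic streams
  (`boolean_network()`, `net_step()`, `evolve()`, `is_meaningful()`);
* the four network ↔ automaton constructions (`network_to_buchi()`,
  `network_to_muller()`, `buchi_to_network()`, `muller_to_network()`) and
  ω-word acceptance (`accepts()`);
* cycle machinery: SCCs, vertex-simple cycles, closed walks, constitutive
  decomposition, accessibility/inclusion/communication (`simple_cycles()`,
  `closed_walks_from()`, `constitutive_decomposition()`, `attractors()`);
* meaningful/spurious typings (output layer, predicates, explicit lists,
  the basal ganglia rule) and degree computation (`max_chain()`,
  `max_tree()`, `rnn_degree()`, `complete_degree()`, `ordinal_compare()`);
* a full pipeline for the 9-node basal ganglia–thalamocortical circuit
  model (`bg_calibrate()`, `bg_census_table()`, `bg_degree()`,
  `bg_report()`), plus seed-deterministic random and planted-degree
  generators for testing.

## Worked example

```r
library(boolrnn)

net <- basal_ganglia_network()          # 9 cells, 1 input unit
state_code(net_step(net, 0, 1))
#> [1] 384                               # SC and Thalamus fire from rest

# drive the circuit with a period-7 input and inspect the attractor
ev <- evolve(net, input_stream(character(), c("0","1","0","1","1","0","0")))
ev$inf_set
#> [1]   0  33  63 191 223 384 511

# type it with the neurobiological rule and compute the complexity degree
cal <- bg_calibrate()                   # calibrates the unprinted parameters
deg <- bg_degree(cal)
deg$degree
#> attractor-based complexity degree: 4 (non-self-dual), witness kind: co_alternating
#>   C1 (spurious): {0}
#>   C2 (meaningful): {0, 33, 63, 255, 384, 479}
#>   C3 (spurious): {0, 33, 63, 95, 127, 128, 223, 255, 384, 479}
#>   C4 (meaningful): {0, 33, 63, 95, 127, 128, 159, 161, 223, 255, 384, 479}
```

The degree report says: along its evolutions the circuit can alternate
between spurious and meaningful attractors through a chain of four cycles
nested one inside the next, starting from the spurious rest state — and no
alternating structure of equal length exists, so the network is
non-self-dual and (because a meaningful cycle sits inside a spurious one)
lies strictly beyond what any output-layer network can express.

A thin command-line front end with the same verbs lives at
`inst/cli/attractor-degree` (`case-study`, `simulate`, `to-automaton`,
`attractors`, `degree`, `calibrate`, `gen`).

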
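Package: boolrnn
Title: Attractor-Based Complexity of Boolean Recurrent Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates first-order Boolean recurrent neural networks (threshold
    units with exact rational weights) on ultimately periodic input streams,
    converts networks to and from deterministic Buchi and Muller automata over
    Boolean-vector alphabets, enumerates attractors and cycles of the derived
    state-transition graphs, classifies them as meaningful or spurious, and
    computes the network's attractor-based complexity degree as the length of a
    maximal alternating or co-alternating chain or tree of cycles, expressed as
    an ordinal in Cantor normal form.  Includes a complete reproduction
    pipeline for a 9-node basal ganglia-thalamocortical circuit model together
    with generators for random networks, random omega-automata and
    planted-degree instances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
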
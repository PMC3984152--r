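# Ordinal degrees: CNF comparison, maximal chains and trees, duality,
# planted recovery and the hierarchy case analysis.

test_that("Cantor-normal-form comparison is lexicographic on exponents", {
  expect_equal(ordinal_compare(3, 5), "lt")
  expect_equal(ordinal_compare(5, 5), "eq")
  omega <- boolrnn:::.cnf_omega()
  expect_equal(ordinal_compare(omega, 1000L), "gt")
  w21 <- boolrnn:::.cnf(c(1L, 0L), c(2L, 1L))   # omega*2 + 1
  w2 <- boolrnn:::.cnf(1L, 2L)                  # omega*2
  expect_equal(ordinal_compare(w21, w2), "gt")
  expect_equal(format_ordinal(w21), "omega*2+1")
  expect_equal(format_ordinal(boolrnn:::.cnf_finite(0L)), "0")
})

test_that("maximal chains: basic shapes", {
  # one successful self-loop only: alternating chain of length 1
  a <- buchi_automaton(0L, 1L, 0L, matrix(c(0L, 0L), 1, 2), finals = 0L)
  r <- max_chain(a)
  expect_equal(ordinal_compare(r$alt, 1L), "eq")
  expect_equal(ordinal_compare(r$co_alt, 0L), "eq")
  # two opposite-type cycles in one SCC communicate: length omega
  b <- planted_chain_automaton(length = "omega")
  r <- max_chain(b)
  expect_equal(format_ordinal(r$alt), "omega")
  # planted one-way chains of every finite length and kind
  for (k in 1:5) for (kind in c("alternating", "co_alternating")) {
    p <- planted_chain_automaton(kind, k)
    r <- max_chain(p)
    got <- if (kind == "alternating") r$alt else r$co_alt
    expect_equal(ordinal_compare(got, k), "eq")
  }
})

test_that("maximal chains agree with an independent brute force", {
  for (seed in 1:10) {
    a <- random_buchi(sample(3:5, 1), 1, seed = seed)
    r <- max_chain(a)
    succ_test <- function(s) length(intersect(s, a$finals)) > 0L
    # brute force only meaningful when no mixed SCC exists (finite case)
    if (nrow(r$alt) && r$alt[1, 1] >= 1L) {
      # omega: verify a communicating opposite pair exists via the oracle
      cyc <- oracle_cycles(a)
      found <- FALSE
      for (i in seq_along(cyc)) for (j in seq_along(cyc)) {
        if (succ_test(cyc[[i]]) && !succ_test(cyc[[j]]) &&
            oracle_reachable(a, cyc[[i]], cyc[[j]]) &&
            oracle_reachable(a, cyc[[j]], cyc[[i]])) found <- TRUE
      }
      expect_true(found)
    } else {
      expect_equal(ordinal_compare(r$alt, oracle_longest_alternation(a, succ_test, "chain", TRUE)), "eq")
      expect_equal(ordinal_compare(r$co_alt, oracle_longest_alternation(a, succ_test, "chain", FALSE)), "eq")
    }
  }
})

test_that("maximal trees recover planted inclusion depths and match brute force", {
  for (k in 1:5) for (kind in c("alternating", "co_alternating")) {
    p <- planted_tree_automaton(kind, k)
    r <- max_tree(p)
    got <- if (kind == "alternating") r$alt else r$co_alt
    other <- if (kind == "alternating") r$co_alt else r$alt
    expect_equal(ordinal_compare(got, k), "eq")
    expect_equal(ordinal_compare(other, k), "lt")
    # the witness is an inclusion chain with strictly alternating types
    w <- r$witnesses[[if (kind == "alternating") "alternating" else "co_alternating"]]
    sets <- lapply(w$cycles, function(c) c$state_set)
    if (length(sets) > 1) for (i in seq_len(length(sets) - 1)) {
      expect_true(all(sets[[i]] %in% sets[[i + 1]]))
      expect_true(w$types[i] != w$types[i + 1])
    }
  }
  # random Muller automata against the independent oracle
  for (seed in 1:8) {
    a <- random_muller(4, 1, seed = seed)
    r <- max_tree(a)
    if (nrow(r$alt) && r$alt[1, 1] >= 1L) next  # transfinite: not oracle-checked here
    succ_test <- function(s) isTRUE(a$table(s))
    expect_equal(ordinal_compare(r$alt, oracle_longest_alternation(a, succ_test, "tree", TRUE)), "eq")
    expect_equal(ordinal_compare(r$co_alt, oracle_longest_alternation(a, succ_test, "tree", FALSE)), "eq")
  }
})

test_that("degree case analysis: trichotomy and all-spurious networks", {
  # all-spurious network (empty output layer): degree 1, non-self-dual,
  # co-alternating witness
  net <- random_network(3, 1, output_layer = "none", seed = 2)
  d <- rnn_degree(net)
  expect_equal(format_ordinal(d$cnf), "1")
  expect_false(d$self_dual)
  expect_equal(d$kind, "co_alternating")
  # every computed degree is exactly one of the three classes
  for (seed in 1:10) {
    net <- random_network(4, 1, seed = seed)
    if (!length(net$output_layer)) net$output_layer <- "c1"
    d <- rnn_degree(net)
    expect_true(d$kind %in% c("alternating", "co_alternating"))
    expect_true(is.logical(d$self_dual))
    expect_gte(nrow(d$cnf), 1L)
  }
})

test_that("degree is invariant under assignment complementation", {
  for (seed in 1:8) {
    net <- random_network(3, 1, seed = seed)
    asg <- predicate_assignment(function(s) (sum(s) + seed) %% 2L == 0L)
    d1 <- complete_degree(net, asg)
    d2 <- complete_degree(net, complement_assignment(asg))
    expect_equal(ordinal_compare(d1, d2), "eq")
    expect_equal(d1$self_dual, d2$self_dual)
  }
  # same symmetry along the Buchi route via the network simulating the
  # complemented automaton
  for (seed in c(3, 6)) {
    net <- random_network(3, 1, seed = seed)
    if (!length(net$output_layer)) net$output_layer <- "c2"
    asg <- output_layer_assignment(net)
    d1 <- complete_degree(net, asg)
    d2 <- complete_degree(net, complement_assignment(asg))
    expect_equal(ordinal_compare(d1, d2), "eq")
  }
})

test_that("degrees survive relabelling and network simulation of planted automata", {
  for (seed in 1:5) {
    p <- relabel_automaton(planted_chain_automaton("co_alternating", 3L), seed = seed)
    d <- buchi_degree(p)
    expect_equal(format_ordinal(d$cnf), "3")
    expect_equal(d$kind, "co_alternating")
    expect_false(d$self_dual)
  }
  # through the simulating network (planted degree recovered from the
  # network route)
  p <- planted_chain_automaton("alternating", 2L)
  net <- buchi_to_network(p)
  d <- rnn_degree(net)
  expect_equal(format_ordinal(d$cnf), "2")
  expect_equal(d$kind, "alternating")
})

test_that("witness structures are downward closed", {
  # any contiguous subsequence of a maximal structure is itself a structure
  # of the corresponding kind, so both kinds exist at every smaller length
  check <- function(r) {
    for (w in r$witnesses) {
      if (is.null(w) || length(w$cycles) < 2) next
      types <- w$types
      for (i in seq_along(types)[-1]) expect_true(types[i] != types[i - 1])
    }
    la <- if (nrow(r$alt)) r$alt[nrow(r$alt), 2L] else 0L
    lc <- if (nrow(r$co_alt)) r$co_alt[nrow(r$co_alt), 2L] else 0L
    if (nrow(r$alt) && r$alt[1, 1] == 0L && la + lc > 0L)
      expect_lte(abs(la - lc), 1L)
  }
  for (seed in 1:6) check(max_chain(random_buchi(4, 1, seed = seed)))
  for (seed in 1:6) check(max_tree(random_muller(4, 1, seed = seed)))
})

test_that("output-layer assignments stay inside the Buchi segment", {
  for (seed in 1:6) {
    net <- random_network(3, 1, seed = seed)
    if (!length(net$output_layer)) net$output_layer <- "c1"
    expect_true(buchi_segment_check(net, output_layer_assignment(net)))
    # tree degree never exceeds the chain degree for output-layer typing
    dc <- rnn_degree(net)
    dt <- complete_degree(net, output_layer_assignment(net))
    expect_true(ordinal_compare(dt, dc) != "gt")
  }
  # an all-spurious assignment is trivially monotone
  net <- random_network(3, 1, seed = 4)
  expect_true(buchi_segment_check(net, predicate_assignment(function(s) FALSE)))
})
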
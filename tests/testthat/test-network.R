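# Threshold dynamics, exact rational parameters, streams and evolutions.

test_that("rational parsing is exact and rejects junk", {
  r <- parse_rational(c("1/3", "-1/2", "2", "", "−1/2"))
  expect_equal(r$num, c(1L, -1L, 2L, 0L, -1L))
  expect_equal(r$den, c(3L, 2L, 1L, 1L, 2L))
  expect_error(parse_rational("0.5"), "rational")
  expect_error(parse_rational("1/0"), "rational")
  # numeric halves are exact, repeating decimals are refused
  net <- boolean_network(matrix(0.5, 1, 1))
  expect_equal(net$W[1, 1] / net$den, 0.5)
  expect_error(boolean_network(matrix(1 / 3, 1, 1)), "character literal")
})

test_that("step is the exact threshold rule and scale-invariant", {
  # all-zero parameters: no cell can reach threshold
  z <- boolean_network(matrix(0, 3, 3))
  expect_equal(net_step(z, c(1, 1, 1)), c(0L, 0L, 0L))
  # a cell fires iff the rational sum reaches its threshold
  w <- matrix(c("0", "1/2", "1/2", "0"), 2, 2)
  net <- boolean_network(w, thresholds = c("1/2", "1"))
  expect_equal(net_step(net, c(1, 0)), c(0L, 0L))      # 1/2 into cell 2 < 1
  expect_equal(net_step(net, c(0, 1)), c(1L, 0L))      # 1/2 into cell 1 >= 1/2
  # multiplying every parameter by a common positive rational changes nothing
  for (seed in 1:5) {
    n1 <- random_network(4, 1, seed = seed)
    w3 <- matrix(as.character(3 * n1$W), 4, 4)        # scaled integers / den
    n3 <- boolean_network(w3,
                          input_weights = matrix(as.character(3 * n1$Win), 1, 4),
                          background = as.character(3 * n1$bg),
                          thresholds = as.character(3 * n1$theta))
    for (code in 0:15) for (u in 0:1)
      expect_equal(net_step(n3, state_bits(code, 4), u),
                   net_step(n1, state_bits(code, 4), u))
  }
  expect_error(net_step(z, c(1, 1)), "length")
})

test_that("state encoding uses cell 1 as most significant bit and round-trips", {
  expect_equal(state_code(c(0, 1, 0, 0, 1, 1, 1, 1, 1)), 159L)
  for (n in c(3L, 9L, 10L)) {
    codes <- if (n <= 9) 0:(2^n - 1L) else sample(0:(2^n - 1L), 500)
    for (code in codes) expect_identical(state_code(state_bits(code, n)), as.integer(code))
  }
  expect_error(state_bits(8, 3), "range")
})

test_that("basal ganglia model matches the published wiring", {
  net <- basal_ganglia_network()
  expect_equal(net$n_cells, 9L)
  expect_equal(net$n_inputs, 1L)
  expect_equal(net$W["Thalamus", "CCortex"] / net$den, 1)
  expect_equal(net$W["GPe", "RTN"] / net$den, -0.5)
  expect_equal(net$W["STN", "GPi/SNr"] / net$den, 2)
  expect_equal(net$Win["IN", "SC"] / net$den, 1)
  # the worked transitions of the reference trajectory
  expect_equal(state_code(net_step(net, 0, 1)), 384L)
  expect_equal(state_code(net_step(net, 223, 1)), 511L)
})

test_that("evolve finds the loop and its inf set", {
  z <- boolean_network(matrix(0, 2, 2), input_weights = matrix(0, 1, 2))
  ev <- evolve(z, input_stream(c("0", "1"), c("1", "0")))
  expect_equal(ev$inf_set, 0L)
  # 1-cell network with self-weight 1 and input weight 1: constant input 1
  # keeps the cell firing
  one <- boolean_network(matrix(1, 1, 1), input_weights = matrix(1, 1, 1))
  ev <- evolve(one, input_stream(character(), "1"))
  expect_equal(ev$inf_set, 1L)
  expect_true(length(ev$loop) >= 1 && setequal(ev$loop, ev$inf_set))
  # the reference trajectory of the case study
  net <- basal_ganglia_network()
  ref <- bg_reference_walk()
  ev <- evolve(net, input_stream("0", vapply(ref$inputs[-1], as.character, "")))
  expect_equal(ev$inf_set, sort(unique(ref$states)))
  # invariants: inf_set is exactly the loop's support, never empty
  for (seed in 1:5) {
    rn <- random_network(4, 1, seed = seed)
    ev <- evolve(rn, input_stream(c("1"), c("0", "1")))
    expect_gt(length(ev$inf_set), 0)
    expect_setequal(ev$inf_set, unique(ev$loop))
  }
})

test_that("forward simulation reproduces the full reference walk", {
  net <- basal_ganglia_network()
  ref <- bg_reference_walk()
  code <- 0L
  walked <- code
  for (u in ref$inputs) {
    code <- state_code(net_step(net, code, u))
    walked <- c(walked, code)
  }
  expect_equal(walked, ref$states)
})

test_that("read_network parses rationals exactly and validates structure", {
  tsv <- system.file("extdata", "basal_ganglia_weights.tsv", package = "boolrnn")
  cfg <- system.file("extdata", "basal_ganglia_config.json", package = "boolrnn")
  net <- read_network(tsv, cfg)
  ref <- basal_ganglia_network()
  expect_equal(net$cells, ref$cells)
  expect_equal(net$W / net$den, ref$W / ref$den)
  expect_equal(net$Win / net$den, ref$Win / ref$den)
  expect_equal(net$bg / net$den, ref$bg / ref$den)
  # exactness: a 1/3 entry stays 1/3
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("X\ta\tb", "a\t0\t1/3", "b\t0\t0"), tf)
  n3 <- read_network(tf)
  expect_equal(n3$W[1, 2] * 3L, n3$den)
  # error cases: empty file, bad token, asymmetric names
  te <- tempfile(fileext = ".tsv")
  writeLines("X", te)
  expect_error(read_network(te))
  tb <- tempfile(fileext = ".tsv")
  writeLines(c("X\ta\tb", "a\t0\tpi", "b\t0\t0"), tb)
  expect_error(read_network(tb), "row 'a', column 'b'")
  ta <- tempfile(fileext = ".tsv")
  writeLines(c("X\ta\tc", "a\t0\t1", "b\t0\t0"), ta)
  expect_error(read_network(ta), "differ")
})

test_that("meaningfulness of streams follows the attractor type", {
  net <- basal_ganglia_network()
  all_spurious <- predicate_assignment(function(s) FALSE)
  expect_false(is_meaningful(net, all_spurious, input_stream(character(), "1")))
  # a stream driving the loop (33, 128, 95) forever: spurious under the
  # neurobiological rule; the expanded loop through 0 is meaningful
  aut <- network_to_muller(net, predicate_assignment(function(s) TRUE),
                           reachable_only = TRUE)
  asg <- bg_assignment(aut)
  ref <- bg_reference_walk()
  to33 <- c("0", "1", "0", "1", "1", "0", "0")   # reaches 33 via the walk
  loop335 <- input_stream(to33, c("1", "0", "0"))            # 33->128->95->33
  expect_false(is_meaningful(net, asg, loop335))
  loop7 <- input_stream(character(), c("0", "1", "0", "1", "1", "0", "0"))
  ev <- evolve(net, loop7)
  expect_equal(ev$inf_set, sort(c(0L, 384L, 223L, 511L, 191L, 63L, 33L)))
  expect_true(is_meaningful(net, asg, loop7))
  # explicit assignments refuse cycles they do not cover
  empty <- explicit_assignment(list())
  expect_error(is_meaningful(net, empty, loop7), "not covered")
})

test_that("complementing a network flips stream membership and is an involution", {
  net <- basal_ganglia_network()
  asg <- predicate_assignment(function(s) 511L %in% s)
  comp <- complement_network(net, asg)
  w <- input_stream(character(), c("0", "1", "0", "1", "1", "0", "0"))
  expect_true(is_meaningful(net, asg, w) != is_meaningful(net, comp$assignment, w))
  back <- complement_network(comp$network, comp$assignment)
  expect_equal(is_meaningful(net, asg, w), is_meaningful(net, back$assignment, w))
})
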
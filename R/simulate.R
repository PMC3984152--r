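# Simulating deterministic omega-automata by Boolean networks.
#
# The construction uses three groups of cells, all with threshold 1.
#
# "Letter cells" L<b>, one per letter b of the alphabet {0,1}^M: the cell for
# b receives weight 1/(number of ones of b) from every input unit where b has
# a 1 and weight -1 from every input unit where b has a 0 (for b = 0:
# background 1 and -1 from every input unit), so L<b> fires at time t+1 iff
# the input at time t equals b.
#
# "State cells" S<q>_<b>, one per (state q, letter b) pair, encoding "the
# automaton is in state q and the last letter read was b".  The cell receives
# a half-strength copy of the letter-b detector from the input units, and
# weight 1/2 from every state cell S<p>_<a> with delta(p, a) = q.  Because
# exactly one state cell is active per step, the two half contributions sum
# to 1 exactly when the active cell's automaton state has a b-transition into
# q and the current input is b - conjunctions of different transitions cannot
# mix.  Start-up: cells S<q>_<b> with delta(q0, b) = q carry background 1/2,
# cancelled from t = 2 on by weight -1/2 from the ignition cell.
#
# "Ignition cell" with background 1 and self-weight 1, firing from t = 1 on.
#
# From t >= 1 exactly one state cell fires per step, and after reading any
# finite prefix the firing state cell's q-index is the automaton state
# reached.  An undefined transition silences the state cells forever, which
# rejects.

.simulation_network <- function(a) {
  m <- a$alphabet_dim
  if (m < 1L) stop("automaton alphabet dimension must be >= 1", call. = FALSE)
  nl <- 2L^m
  letters <- 0:(nl - 1L)
  letter_cells <- paste0("L", letters)
  state_cells <- as.vector(outer(a$states, letters, function(q, b) paste0("S", q, "_", b)))
  sc_state <- rep(a$states, times = nl)
  sc_letter <- rep(letters, each = length(a$states))
  cells <- c(letter_cells, "ignite", state_cells)
  n <- length(cells)
  W <- matrix("0", n, n, dimnames = list(cells, cells))
  Win <- matrix("0", m, n, dimnames = list(paste0("u", seq_len(m)), cells))
  bg <- stats::setNames(rep("0", n), cells)

  detector <- function(b, scale_den) {
    # weights from input units making the summed contribution equal to
    # 1/scale_den exactly when the input equals b, and at most
    # 1/scale_den - 1 otherwise; for b = 0 the positive part goes to bg
    bits <- state_bits(b, m)
    ones <- sum(bits)
    w <- character(m)
    for (k in seq_len(m))
      w[k] <- if (bits[k] == 1L) paste0("1/", scale_den * ones) else "-1"
    list(w = w, bg = if (ones == 0L) paste0("1/", scale_den) else "0")
  }
  for (b in letters) {
    d <- detector(b, 1L)
    Win[, paste0("L", b)] <- d$w
    bg[paste0("L", b)] <- d$bg
  }
  bg["ignite"] <- "1"
  W["ignite", "ignite"] <- "1"
  for (i in seq_along(state_cells)) {
    q <- sc_state[i]; b <- sc_letter[i]
    d <- detector(b, 2L)
    Win[, state_cells[i]] <- d$w
    half_bg <- d$bg
    # transition halves: from every state cell whose automaton state has a
    # b-transition into q
    for (j in seq_along(state_cells)) {
      p <- sc_state[j]; apre <- sc_letter[j]
      to <- a$trans[match(p, a$states), b + 1L]
      if (!is.na(to) && to == q) W[state_cells[j], state_cells[i]] <- "1/2"
    }
    # start-up: act as if a virtual cell for the initial state were firing at
    # t = 0
    to0 <- a$trans[match(a$initial, a$states), b + 1L]
    init <- !is.na(to0) && to0 == q
    if (init) W["ignite", state_cells[i]] <- "-1/2"
    bg[state_cells[i]] <- if (half_bg == "0" && !init) "0"
      else if (half_bg != "0" && init) "1"           # 1/2 + 1/2
      else "1/2"
  }
  list(cells = cells, W = W, Win = Win, bg = bg,
       state_cells = state_cells, sc_state = sc_state, sc_letter = sc_letter,
       letter_cells = letter_cells)
}

#' Simulate a Buchi automaton by a Boolean network
#'
#' Builds a network with 2^M letter cells, an ignition cell and one state
#' cell per (state, last letter) pair; the output layer consists of the state
#' cells of final states.  An omega-word is accepted by the automaton iff the
#' corresponding input stream is meaningful for the network under
#' output-layer typing; after reading any finite prefix the unique firing
#' state cell names the automaton state reached.
#'
#' @param a a deterministic [buchi_automaton()].
#' @return A [boolean_network()]; state cells are named `"S<state>_<letter>"`.
#' @export
buchi_to_network <- function(a) {
  if (!inherits(a, "buchi_automaton")) stop("expected a Buchi automaton", call. = FALSE)
  s <- .simulation_network(a)
  boolean_network(s$W, input_weights = s$Win, background = s$bg,
                  output_layer = s$state_cells[s$sc_state %in% a$finals])
}

#' Simulate a Muller automaton by a typed Boolean network
#'
#' Same construction as [buchi_to_network()]; instead of an output layer the
#' returned type assignment declares an attractor meaningful iff the set of
#' automaton states whose cells spike within it is a member of the table.
#'
#' @param a a deterministic [muller_automaton()].
#' @return list with `network` (a [boolean_network()]) and `assignment` (a
#'   [type_assignment()]).
#' @export
muller_to_network <- function(a) {
  if (!inherits(a, "muller_automaton")) stop("expected a Muller automaton", call. = FALSE)
  s <- .simulation_network(a)
  net <- boolean_network(s$W, input_weights = s$Win, background = s$bg)
  state_idx <- match(s$state_cells, s$cells)
  assignment <- type_assignment(function(cycle) {
    spiking <- unique(unlist(lapply(cycle$state_set, function(code) {
      bits <- state_bits(code, length(s$cells))
      s$sc_state[bits[state_idx] == 1L]
    })))
    if (isTRUE(a$table(sort(spiking)))) "meaningful" else "spurious"
  }, provenance = "predicate")
  list(network = net, assignment = assignment)
}

#' Active automaton state along a simulation
#'
#' Helper exposing the behavioural contract of the simulation: runs the
#' network on a finite input block and reports, per time step, the automaton
#' state whose cell is firing (`NA` during start-up or after an undefined
#' transition).
#'
#' @param net network built by [buchi_to_network()] / [muller_to_network()].
#' @param a the simulated automaton.
#' @param inputs matrix of input rows, a bit-string vector, or an integer
#'   vector of single bits (M = 1).
#' @return integer vector of automaton state codes, one per step.
#' @export
simulation_state_trace <- function(net, a, inputs) {
  if (is.character(inputs)) inputs <- do.call(rbind, lapply(strsplit(inputs, ""), as.integer))
  if (!is.matrix(inputs)) inputs <- matrix(as.integer(inputs), ncol = a$alphabet_dim)
  nl <- 2L^a$alphabet_dim
  sc_names <- as.vector(outer(a$states, 0:(nl - 1L), function(q, b) paste0("S", q, "_", b)))
  sc_state <- rep(a$states, times = nl)
  state_idx <- match(sc_names, net$cells)
  x <- rep(0L, net$n_cells)
  out <- integer(0)
  for (t in seq_len(nrow(inputs))) {
    x <- net_step(net, x, inputs[t, ])
    act <- which(x[state_idx] == 1L)
    out <- c(out, if (length(act) == 1L) sc_state[act] else NA_integer_)
  }
  out
}
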
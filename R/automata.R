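# Deterministic Buchi and Muller automata over Boolean-vector alphabets.
#
# States carry integer codes.  The alphabet of dimension M consists of the
# 2^M Boolean input vectors, identified with the letter codes 0 .. 2^M - 1
# (first component = most significant bit).  Transitions are stored as an
# n_states x 2^M integer matrix of successor codes (NA = undefined), which
# keeps determinism structural.

.new_automaton <- function(states, alphabet_dim, initial, trans, class) {
  states <- as.integer(states)
  if (anyDuplicated(states)) stop("duplicate state codes", call. = FALSE)
  if (!initial %in% states) stop("initial state not among states", call. = FALSE)
  nl <- 2^alphabet_dim
  if (!is.matrix(trans) || nrow(trans) != length(states) || ncol(trans) != nl)
    stop("transition matrix must be n_states x 2^alphabet_dim", call. = FALSE)
  bad <- setdiff(unique(trans[!is.na(trans)]), states)
  if (length(bad)) stop("transitions target unknown states: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  rownames(trans) <- states
  structure(list(states = states, alphabet_dim = as.integer(alphabet_dim),
                 initial = as.integer(initial), trans = trans),
            class = c(class, "omega_automaton"))
}

#' Deterministic Buchi automaton
#'
#' A deterministic Buchi automaton over the alphabet of M-dimensional Boolean
#' vectors.  An infinite word is accepted iff the unique run visits a final
#' state infinitely often.
#'
#' @param states integer vector of state codes.
#' @param alphabet_dim M; letters are the codes 0 .. 2^M - 1.
#' @param initial initial state code.
#' @param transitions integer matrix `length(states) x 2^M`; entry
#'   `[i, a + 1]` is the successor of state `states[i]` on letter `a`
#'   (`NA` = undefined; an undefined transition rejects).
#' @param finals integer vector of final state codes.
#' @return An object of class `buchi_automaton`.
#' @export
buchi_automaton <- function(states, alphabet_dim, initial, transitions, finals = integer()) {
  a <- .new_automaton(states, alphabet_dim, initial, transitions, "buchi_automaton")
  finals <- as.integer(finals)
  if (!all(finals %in% a$states)) stop("finals must be states", call. = FALSE)
  a$finals <- finals
  a
}

#' Deterministic Muller automaton
#'
#' A deterministic Muller automaton: an infinite word is accepted iff the set
#' of states visited infinitely often by its run belongs to the table.  The
#' table may be given extensionally (`table_sets`, a list of integer vectors)
#' or intensionally (`table`, a predicate over integer state sets); at least
#' one must be supplied.  The predicate form matters because the number of
#' cycles of a graph can be exponential.
#'
#' @inheritParams buchi_automaton
#' @param table predicate `function(set) -> logical`, or `NULL`.
#' @param table_sets explicit list of successful state sets, or `NULL`.
#' @return An object of class `muller_automaton`.
#' @export
muller_automaton <- function(states, alphabet_dim, initial, transitions,
                             table = NULL, table_sets = NULL) {
  a <- .new_automaton(states, alphabet_dim, initial, transitions, "muller_automaton")
  if (is.null(table) && is.null(table_sets))
    stop("supply table (predicate) or table_sets (explicit list)", call. = FALSE)
  if (!is.null(table_sets)) {
    table_sets <- lapply(table_sets, function(s) sort(unique(as.integer(s))))
    keys <- vapply(table_sets, paste, "", collapse = ",")
    if (is.null(table)) table <- function(set) paste(sort(unique(as.integer(set))), collapse = ",") %in% keys
  }
  a$table <- table
  a$table_sets <- table_sets
  a
}

#' @export
print.omega_automaton <- function(x, ...) {
  kind <- if (inherits(x, "buchi_automaton")) "Buchi" else "Muller"
  cat("deterministic ", kind, " automaton: ", length(x$states), " states, alphabet {0,1}^",
      x$alphabet_dim, ", initial ", x$initial, "\n", sep = "")
  if (inherits(x, "buchi_automaton"))
    cat("  finals: {", paste(x$finals, collapse = ", "), "}\n", sep = "")
  else if (!is.null(x$table_sets))
    cat("  table:", length(x$table_sets), "successful sets\n")
  else cat("  table: predicate\n")
  invisible(x)
}

# successor of one state under one letter code (NA if undefined)
.succ <- function(a, state, letter) a$trans[match(state, a$states), letter + 1L]

#' Convert a network to its deterministic Buchi automaton
#'
#' The automaton has one state per network state (all 2^N by default, or only
#' the states reachable from the all-quiet state), the all-quiet state as
#' initial state, the network's one-step dynamics as transition function, and
#' as final states those network states in which at least one output-layer
#' cell fires.  An ultimately periodic word is accepted iff the corresponding
#' stream is meaningful for the network under output-layer typing.
#'
#' @param net a [boolean_network()] with a designated (possibly empty is an
#'   error) output layer.
#' @param reachable_only keep only states reachable from the initial state.
#'   Unreachable states can never occur in the dynamics and do not affect the
#'   complexity degree.
#' @return A [buchi_automaton()].
#' @export
network_to_buchi <- function(net, reachable_only = FALSE) {
  if (is.null(net$output_layer))
    stop("network has no output layer; use network_to_muller with an explicit typing",
         call. = FALSE)
  g <- .network_graph(net, reachable_only)
  out_bits <- match(net$output_layer, net$cells)
  finals <- g$states[vapply(g$states, function(s)
    any(state_bits(s, net$n_cells)[out_bits] == 1L), logical(1))]
  buchi_automaton(g$states, net$n_inputs, 0L, g$trans, finals)
}

#' Convert a typed network to its deterministic Muller automaton
#'
#' Same state graph as [network_to_buchi()]; the table consists exactly of
#' the meaningful attractors: a state set is successful iff the assignment
#' classifies the corresponding cycle as meaningful.
#'
#' @param net a [boolean_network()].
#' @param assignment a [type_assignment()] defined (possibly lazily, as a
#'   predicate) on all cycles.
#' @inheritParams network_to_buchi
#' @return A [muller_automaton()] whose table predicate classifies state sets
#'   through `assignment`, using a deterministic canonical witness walk for
#'   walk-sensitive rules.
#' @export
network_to_muller <- function(net, assignment, reachable_only = FALSE) {
  g <- .network_graph(net, reachable_only)
  a <- muller_automaton(g$states, net$n_inputs, 0L, g$trans,
                        table = function(set) TRUE)  # placeholder, replaced below
  a$table <- function(set) {
    w <- canonical_witness(a, set)
    classify_cycle(assignment, new_cycle(set, witness = w)) == "meaningful"
  }
  a
}

# build the state graph of a network: states + transition matrix over 2^M letters
.network_graph <- function(net, reachable_only) {
  n <- net$n_cells
  nl <- 2^net$n_inputs
  if (reachable_only) {
    reach <- 0L; frontier <- 0L
    while (length(frontier)) {
      nxt <- unique(unlist(lapply(0:(nl - 1L), function(a) .step_codes(net, frontier, a))))
      nxt <- setdiff(nxt, reach)
      reach <- c(reach, nxt); frontier <- nxt
    }
    states <- sort(reach)
  } else {
    if (n > 20L) stop("state space too large for full enumeration (N > 20)", call. = FALSE)
    states <- 0:(2^n - 1L)
  }
  trans <- vapply(0:(nl - 1L), function(a) .step_codes(net, states, a),
                  integer(length(states)))
  if (!is.matrix(trans)) trans <- matrix(trans, nrow = length(states))
  list(states = states, trans = trans)
}

#' Acceptance of an ultimately periodic word
#'
#' Runs the automaton on u * v^omega, detects the eventually periodic suffix
#' of the run via (state, period-position) repetition, and applies the
#' acceptance condition: Buchi - the inf set meets the finals; Muller - the
#' inf set belongs to the table.  An undefined transition rejects.
#'
#' @param a a [buchi_automaton()] or [muller_automaton()].
#' @param word an [input_stream()] (the alphabet mirrors input vectors).
#' @return logical.
#' @export
accepts <- function(a, word) {
  if (!inherits(word, "input_stream")) stop("word must be an input_stream", call. = FALSE)
  if (ncol(word$period) != a$alphabet_dim)
    stop("word dimension does not match automaton alphabet", call. = FALSE)
  letter <- function(bits) state_code(bits)
  cur <- a$initial
  for (i in seq_len(nrow(word$prefix))) {
    cur <- .succ(a, cur, letter(word$prefix[i, , drop = TRUE]))
    if (is.na(cur)) return(FALSE)
  }
  nv <- nrow(word$period)
  seen <- new.env(parent = emptyenv()); run <- integer(0); phase <- 0L
  repeat {
    key <- paste0(cur, ":", phase)
    hit <- mget(key, envir = seen, ifnotfound = list(NULL))[[1L]]
    if (!is.null(hit)) { inf_states <- sort(unique(run[hit:length(run)])); break }
    assign(key, length(run) + 1L, envir = seen)
    run <- c(run, cur)
    cur <- .succ(a, cur, letter(word$period[phase + 1L, , drop = TRUE]))
    if (is.na(cur)) return(FALSE)
    phase <- (phase + 1L) %% nv
  }
  if (inherits(a, "buchi_automaton")) length(intersect(inf_states, a$finals)) > 0L
  else isTRUE(a$table(inf_states))
}

#' Read and write automata as JSON
#'
#' The JSON format has keys `kind` ("buchi" or "muller"), `states`,
#' `alphabet_dim`, `initial`, `transitions` (list of `[from, letter-bitstring,
#' to]` triples) and either `finals` or `table` (list of state lists).
#'
#' @param path file path.
#' @return `read_automaton_json` returns an automaton; `write_automaton_json`
#'   returns `path` invisibly.
#' @export
read_automaton_json <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  states <- as.integer(unlist(j$states))
  m <- as.integer(j$alphabet_dim)
  trans <- matrix(NA_integer_, length(states), 2^m)
  for (tr in j$transitions) {
    from <- as.integer(tr[[1L]])
    a <- strtoi(tr[[2L]], base = 2L)
    to <- as.integer(tr[[3L]])
    i <- match(from, states)
    if (is.na(i)) stop("transition from unknown state ", from, call. = FALSE)
    if (!is.na(trans[i, a + 1L])) stop("non-deterministic transitions from state ",
                                       from, " on letter ", tr[[2L]], call. = FALSE)
    trans[i, a + 1L] <- to
  }
  if (identical(j$kind, "muller"))
    muller_automaton(states, m, as.integer(j$initial), trans,
                     table_sets = lapply(j$table, function(s) as.integer(unlist(s))))
  else
    buchi_automaton(states, m, as.integer(j$initial), trans,
                    finals = as.integer(unlist(j$finals)))
}

#' @rdname read_automaton_json
#' @param a automaton to write.
#' @export
write_automaton_json <- function(a, path) {
  m <- a$alphabet_dim
  bits <- function(code) paste(state_bits(code, max(m, 1L)), collapse = "")
  trs <- list()
  for (i in seq_along(a$states)) for (l in 0:(2^m - 1L)) {
    to <- a$trans[i, l + 1L]
    if (!is.na(to)) trs[[length(trs) + 1L]] <- list(a$states[i], bits(l), to)
  }
  j <- list(kind = if (inherits(a, "buchi_automaton")) "buchi" else "muller",
            states = a$states, alphabet_dim = m, initial = a$initial,
            transitions = trs)
  if (inherits(a, "buchi_automaton")) j$finals <- a$finals
  else {
    if (is.null(a$table_sets))
      stop("cannot serialise a predicate-only Muller table; materialise table_sets first",
           call. = FALSE)
    j$table <- a$table_sets
  }
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export an automaton to Graphviz DOT
#'
#' Edges are labelled with letter bitstrings; Buchi final states are drawn
#' double-circled.
#'
#' @param a an automaton.
#' @param path optional output file; when `NULL` the DOT text is returned.
#' @param states optional subset of states to restrict the drawing to.
#' @return character scalar of DOT source (invisibly when written to a file).
#' @export
automaton_to_dot <- function(a, path = NULL, states = NULL) {
  keep <- if (is.null(states)) a$states else intersect(a$states, as.integer(states))
  m <- a$alphabet_dim
  bits <- function(code) paste(state_bits(code, max(m, 1L)), collapse = "")
  lines <- c("digraph automaton {", "  rankdir=LR;")
  finals <- if (inherits(a, "buchi_automaton")) a$finals else integer()
  for (s in keep) {
    shape <- if (s %in% finals) "doublecircle" else "circle"
    lines <- c(lines, sprintf("  q%d [label=\"%d\", shape=%s%s];", s, s, shape,
                              if (s == a$initial) ", style=bold" else ""))
  }
  for (i in seq_along(a$states)) {
    from <- a$states[i]
    if (!from %in% keep) next
    for (l in 0:(2^m - 1L)) {
      to <- a$trans[i, l + 1L]
      if (!is.na(to) && to %in% keep)
        lines <- c(lines, sprintf("  q%d -> q%d [label=\"%s\"];", from, to, bits(l)))
    }
  }
  txt <- paste(c(lines, "}"), collapse = "\n")
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}
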
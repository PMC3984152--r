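# Graph machinery over automaton transition graphs: strongly connected
# components, cycle and closed-walk enumeration, constitutive decomposition,
# and the accessibility / inclusion / communication relations between cycles.
#
# Terminology: a *cycle* is a set of states admitting a closed walk visiting
# precisely those states (equivalently: a non-empty induced subgraph that is
# strongly connected and contains at least one edge); a *constitutive cycle*
# is a vertex-simple cycle; a *closed walk* is any edge path returning to its
# root.  Every closed walk decomposes uniquely (by the stack algorithm) into
# constitutive cycles.

#' Cycles of an automaton graph
#'
#' A cycle couples a state set with a witness closed walk visiting exactly
#' those states.
#'
#' @param state_set integer vector of state codes.
#' @param witness integer vector of state codes, first == last, visiting
#'   exactly `state_set`.
#' @param letters optional integer letter codes labelling the witness edges.
#' @return An object of class `cycle`.
#' @export
new_cycle <- function(state_set, witness = NULL, letters = NULL) {
  state_set <- sort(unique(as.integer(state_set)))
  if (!is.null(witness)) {
    witness <- as.integer(witness)
    if (witness[1L] != witness[length(witness)])
      stop("witness walk must be closed", call. = FALSE)
    if (!setequal(witness, state_set))
      stop("witness must visit exactly the state set", call. = FALSE)
  }
  structure(list(state_set = state_set, witness = witness, letters = letters),
            class = "cycle")
}

#' @export
print.cycle <- function(x, ...) {
  cat("cycle {", paste(x$state_set, collapse = ", "), "}", sep = "")
  if (!is.null(x$witness)) cat("  witness (", paste(x$witness, collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}

# labelled edge table of an automaton: data.frame(from, to, letter)
.edge_table <- function(a) {
  nl <- ncol(a$trans)
  from <- rep(a$states, nl)
  to <- as.integer(a$trans)
  letter <- rep(0:(nl - 1L), each = length(a$states))
  ok <- !is.na(to)
  data.frame(from = from[ok], to = to[ok], letter = letter[ok])
}

.igraph_of <- function(a) {
  e <- .edge_table(a)
  igraph::graph_from_data_frame(
    data.frame(from = as.character(e$from), to = as.character(e$to)),
    vertices = data.frame(name = as.character(a$states)))
}

#' Strongly connected components
#'
#' Partitions the automaton graph into maximal strongly connected components,
#' in topological order of the condensation (ancestors first).  Singleton
#' components without a self-loop cannot carry cycles and are flagged.
#'
#' @param a an automaton ([buchi_automaton()] or [muller_automaton()]).
#' @return list of components; each a list with `states` (integer codes) and
#'   `cyclic` (logical: does the component contain at least one edge?).
#' @export
graph_sccs <- function(a) {
  g <- .igraph_of(a)
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  cond <- igraph::contract(g, memb)
  cond <- igraph::simplify(cond)
  ord <- as.integer(igraph::topo_sort(cond, mode = "out"))
  e <- .edge_table(a)
  lapply(ord, function(ci) {
    sts <- sort(as.integer(names(memb)[memb == ci]))
    cyclic <- if (length(sts) > 1L) TRUE else any(e$from == sts & e$to == sts)
    list(states = sts, cyclic = cyclic)
  })
}

#' Enumerate vertex-simple cycles
#'
#' Enumerates all constitutive (vertex-simple) directed cycles of the
#' automaton graph by rooted depth-first search anchored at each cycle's
#' minimal state (a Johnson-style enumeration, adequate at the graph sizes
#' this package targets).  Parallel transitions with different letters over
#' the same vertex sequence count once at the state-set level; the distinct
#' letter labellings are retained as witnesses.
#'
#' @param a an automaton.
#' @param through optional state code; restrict to cycles containing it.
#' @param max_cycles enumeration cap; exceeding it is an error, never a
#'   truncation.
#' @return list of [new_cycle()] objects, each with a vertex-simple witness
#'   and a `n_labellings` attribute counting distinct letter labellings.
#' @export
simple_cycles <- function(a, through = NULL, max_cycles = 100000L) {
  e <- .edge_table(a)
  succ <- split(e$to, e$from)       # unlabelled successors (may repeat)
  out <- list()
  roots <- sort(unique(e$from))
  for (r in roots) {
    stack_path <- r
    rec <- function(cur) {
      for (nxt in unique(succ[[as.character(cur)]])) {
        if (nxt == r) {
          seqv <- c(stack_path, r)
          out[[length(out) + 1L]] <<- seqv
          if (length(out) > max_cycles)
            stop("simple cycle enumeration cap exceeded (", max_cycles, ")", call. = FALSE)
        } else if (nxt > r && !(nxt %in% stack_path)) {
          stack_path <<- c(stack_path, nxt)
          rec(nxt)
          stack_path <<- stack_path[-length(stack_path)]
        }
      }
    }
    rec(r)
  }
  cycles <- lapply(out, function(seqv) {
    cyc <- new_cycle(unique(seqv), witness = seqv)
    # count labellings: product of parallel-edge multiplicities along the walk
    mult <- 1L
    for (i in seq_len(length(seqv) - 1L))
      mult <- mult * sum(e$from == seqv[i] & e$to == seqv[i + 1L])
    cyc$n_labellings <- mult
    cyc
  })
  if (!is.null(through))
    cycles <- Filter(function(c) as.integer(through) %in% c$state_set, cycles)
  cycles
}

#' Enumerate closed walks rooted at a state
#'
#' Enumerates closed walks starting and ending at `root` in which no labelled
#' transition is used twice (edge-distinctness bounds the enumeration; the
#' reference trajectory of the case study repeats vertices but no labelled
#' edge).  Three counting conventions are supported:
#'
#' * `edge_distinct_rooted` (default): walks are distinct rooted edge
#'   sequences;
#' * `edge_distinct_unrooted`: walks that are cyclic rotations of one another
#'   (through another occurrence of the root) are identified;
#' * `constitutive_multiset`: walks with the same multiset of constitutive
#'   cycles are identified.
#'
#' @param a an automaton.
#' @param root state code.
#' @param mode walk equivalence convention.
#' @param max_walks cap; exceeding it is an error.
#' @return list of walks; each a list with `states` (codes, first == last)
#'   and `letters`.
#' @export
closed_walks_from <- function(a, root,
                              mode = c("edge_distinct_rooted",
                                       "edge_distinct_unrooted",
                                       "constitutive_multiset"),
                              max_walks = 100000L) {
  mode <- match.arg(mode)
  root <- as.integer(root)
  e <- .edge_table(a)
  ef <- split(seq_len(nrow(e)), e$from)
  used <- rep(FALSE, nrow(e))
  walks <- list()
  rec <- function(cur, eids) {
    for (id in ef[[as.character(cur)]]) {
      if (used[id]) next
      used[id] <<- TRUE
      to <- e$to[id]
      if (to == root) {
        walks[[length(walks) + 1L]] <<- c(eids, id)
        if (length(walks) > max_walks)
          stop("closed walk enumeration cap exceeded (", max_walks, ")", call. = FALSE)
      }
      rec(to, c(eids, id))
      used[id] <<- FALSE
    }
  }
  rec(root, integer(0))
  mk <- function(eids) list(states = c(root, e$to[eids]), letters = e$letter[eids])
  if (mode == "edge_distinct_unrooted") {
    canon <- character(0); keep <- list()
    for (eids in walks) {
      occ <- which(e$from[eids] == root)
      rots <- vapply(occ, function(o)
        paste(eids[c(o:length(eids), if (o > 1L) 1:(o - 1L))], collapse = ","), "")
      key <- min(rots)
      if (!key %in% canon) { canon <- c(canon, key); keep[[length(keep) + 1L]] <- eids }
    }
    walks <- keep
  } else if (mode == "constitutive_multiset") {
    canon <- character(0); keep <- list()
    for (eids in walks) {
      d <- constitutive_decomposition(c(root, e$to[eids]))
      key <- paste(sort(vapply(d, function(cy)
        paste(sort(unique(cy)), collapse = "-"), "")), collapse = "|")
      if (!key %in% canon) { canon <- c(canon, key); keep[[length(keep) + 1L]] <- eids }
    }
    walks <- keep
  }
  lapply(walks, mk)
}

#' Decompose a closed walk into constitutive cycles
#'
#' Stack algorithm: states are pushed along the walk; whenever the next state
#' already sits on the stack, the enclosed segment is popped as one
#' vertex-simple constitutive cycle.  The final return to the root closes the
#' last cycle.  Cycles are returned in pop order, and the edges of the walk
#' are partitioned among them (the constitutive lengths sum to the walk
#' length).
#'
#' @param walk integer vector of state codes with first == last, or a walk
#'   list as returned by [closed_walks_from()], or a [new_cycle()] witness.
#' @return list of integer vectors, each a vertex-simple closed state
#'   sequence (first == last).
#' @examples
#' constitutive_decomposition(c(1, 2, 3, 2, 1))
#' @export
constitutive_decomposition <- function(walk) {
  if (inherits(walk, "cycle")) walk <- walk$witness
  if (is.list(walk)) walk <- walk$states
  walk <- as.integer(walk)
  if (length(walk) < 2L || walk[1L] != walk[length(walk)])
    stop("walk must be a closed state sequence (first == last)", call. = FALSE)
  stack <- walk[1L]
  out <- list()
  for (v in walk[-1L]) {
    pos <- which(stack == v)
    if (length(pos)) {
      k <- max(pos)
      out[[length(out) + 1L]] <- c(stack[k:length(stack)], v)
      stack <- stack[seq_len(k)]
    } else stack <- c(stack, v)
  }
  out
}

# reachability: set of states reachable from `from` (codes), following edges
.reach_set <- function(a, from) {
  e <- .edge_table(a)
  succ <- lapply(split(e$to, e$from), unique)
  seen <- unique(as.integer(from)); frontier <- seen
  while (length(frontier)) {
    nxt <- unique(unlist(succ[as.character(frontier)]))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt); frontier <- nxt
  }
  seen
}

#' Relations between cycles
#'
#' `cycle_accessible(a, c1, c2)`: is there a path (possibly empty) from some
#' state of `c1` to some state of `c2`?  `cycle_includes(c1, c2)`: is the
#' state set of `c2` contained in that of `c1`?  `cycles_communicate(a, c1,
#' c2)`: mutual accessibility, i.e. both cycles lie in one strongly connected
#' component.
#'
#' @param a automaton carrying both cycles.
#' @param c1,c2 [new_cycle()] objects (or plain integer state sets).
#' @return logical.
#' @export
cycle_accessible <- function(a, c1, c2) {
  s1 <- if (inherits(c1, "cycle")) c1$state_set else as.integer(c1)
  s2 <- if (inherits(c2, "cycle")) c2$state_set else as.integer(c2)
  if (length(intersect(s1, s2))) return(TRUE)
  length(intersect(.reach_set(a, s1), s2)) > 0L
}

#' @rdname cycle_accessible
#' @export
cycle_includes <- function(c1, c2) {
  s1 <- if (inherits(c1, "cycle")) c1$state_set else as.integer(c1)
  s2 <- if (inherits(c2, "cycle")) c2$state_set else as.integer(c2)
  all(s2 %in% s1)
}

#' @rdname cycle_accessible
#' @export
cycles_communicate <- function(a, c1, c2) {
  cycle_accessible(a, c1, c2) && cycle_accessible(a, c2, c1)
}

# Enumerate all cycles (strongly connected induced subsets carrying a closed
# walk) of an automaton, grouped by SCC.  Bitmask enumeration per SCC; each
# SCC is capped at 20 states (2^20 subsets) and the total number of cycles at
# `max_cycles`.  Returns list(cycles = list of cycle objects, scc_id = integer
# vector parallel to cycles, sccs = graph_sccs(a)).
.enumerate_cycles <- function(a, max_cycles = 200000L, scc_limit = 20L) {
  sccs <- graph_sccs(a)
  e <- .edge_table(a)
  cycles <- list(); scc_id <- integer(0)
  for (ci in seq_along(sccs)) {
    comp <- sccs[[ci]]
    if (!comp$cyclic) next
    sts <- comp$states
    k <- length(sts)
    if (k > scc_limit)
      stop("SCC with ", k, " states exceeds the cycle enumeration limit (",
           scc_limit, ")", call. = FALSE)
    if (k == 1L) {
      cycles[[length(cycles) + 1L]] <- new_cycle(sts, witness = c(sts, sts))
      scc_id <- c(scc_id, ci)
      next
    }
    idx <- seq_len(k)
    # successor bitmasks within the SCC
    succ <- integer(k)
    for (i in idx) {
      tos <- unique(e$to[e$from == sts[i]])
      tos <- tos[tos %in% sts]
      succ[i] <- sum(bitwShiftL(1L, match(tos, sts) - 1L))
    }
    selfloop <- vapply(idx, function(i)
      bitwAnd(succ[i], bitwShiftL(1L, i - 1L)) != 0L, logical(1))
    for (m in seq_len(2^k - 1L)) {
      nodes <- idx[bitwAnd(m, bitwShiftL(1L, idx - 1L)) != 0L]
      if (length(nodes) == 1L) {
        if (!selfloop[nodes]) next
      } else {
        # forward reachability within the subset from its first node
        r <- bitwShiftL(1L, nodes[1L] - 1L)
        repeat {
          nr <- r
          for (v in nodes)
            if (bitwAnd(r, bitwShiftL(1L, v - 1L)) != 0L)
              nr <- bitwOr(nr, bitwAnd(succ[v], m))
          if (nr == r) break
          r <- nr
        }
        if (r != m) next
        # backward: every node must reach the first node within the subset
        ok <- TRUE
        for (v in nodes[-1L]) {
          r2 <- bitwShiftL(1L, v - 1L)
          repeat {
            nr <- r2
            for (w in nodes)
              if (bitwAnd(r2, bitwShiftL(1L, w - 1L)) != 0L)
                nr <- bitwOr(nr, bitwAnd(succ[w], m))
            if (nr == r2) break
            r2 <- nr
          }
          if (bitwAnd(r2, bitwShiftL(1L, nodes[1L] - 1L)) == 0L) { ok <- FALSE; break }
        }
        if (!ok) next
      }
      cycles[[length(cycles) + 1L]] <- new_cycle(sts[nodes])
      scc_id <- c(scc_id, ci)
      if (length(cycles) > max_cycles)
        stop("cycle enumeration cap exceeded (", max_cycles, ")", call. = FALSE)
    }
  }
  list(cycles = cycles, scc_id = scc_id, sccs = sccs)
}

#' Canonical witness walk of a cycle
#'
#' Builds a deterministic closed walk visiting exactly the given state set:
#' starting from the smallest state, repeatedly walk a shortest path (ties
#' broken towards smaller codes) inside the set to the smallest not-yet
#' visited state, then back to the start.  Used to type state-set cycles
#' under walk-sensitive rules, making the typing of a set well defined.
#'
#' @param a an automaton.
#' @param set integer state codes forming a cycle of `a`.
#' @return integer vector of state codes, first == last, covering `set`.
#' @export
canonical_witness <- function(a, set) {
  set <- sort(unique(as.integer(set)))
  e <- .edge_table(a)
  e <- e[e$from %in% set & e$to %in% set, ]
  succ <- lapply(split(e$to, e$from), function(x) sort(unique(x)))
  if (length(set) == 1L) {
    if (!length(succ[[as.character(set)]]))
      stop("state set {", set, "} has no internal edge; not a cycle", call. = FALSE)
    return(c(set, set))
  }
  shortest <- function(from, targets) {
    # BFS inside the set; deterministic expansion order by state code
    prev <- list(); dist <- stats::setNames(0L, from)
    frontier <- from
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in sort(frontier)) for (w in succ[[as.character(v)]]) {
        if (!as.character(w) %in% names(dist)) {
          dist[as.character(w)] <- dist[as.character(v)] + 1L
          prev[[as.character(w)]] <- v
          nxt <- c(nxt, w)
        }
      }
      hit <- intersect(as.integer(names(dist)), targets)
      if (length(hit)) {
        tgt <- min(hit)
        path <- tgt
        while (path[1L] != from) path <- c(prev[[as.character(path[1L])]], path)
        return(path)
      }
      frontier <- nxt
    }
    stop("state set is not strongly connected; not a cycle", call. = FALSE)
  }
  start <- set[1L]
  walk <- start
  unvisited <- setdiff(set, start)
  cur <- start
  while (length(unvisited)) {
    p <- shortest(cur, unvisited)
    walk <- c(walk, p[-1L])
    cur <- p[length(p)]
    unvisited <- setdiff(unvisited, p)
  }
  p <- shortest(cur, start)
  c(walk, p[-1L])
}

#' Attractors of a network
#'
#' The attractors of a Boolean network are exactly the state sets of cycles
#' of its derived automaton graph that are reachable from the initial
#' (all-quiet) state: every such cycle is the inf set of some evolution, and
#' conversely.
#'
#' @param net a [boolean_network()].
#' @param reachable_only restrict to the part of the state graph reachable
#'   from the all-quiet state (realisable attractors); `FALSE` enumerates
#'   cycles of the full graph.
#' @param max_cycles enumeration cap.
#' @return list of [new_cycle()] objects with canonical witnesses.
#' @export
attractors <- function(net, reachable_only = TRUE, max_cycles = 200000L) {
  g <- .network_graph(net, reachable_only)
  a <- structure(list(states = g$states, alphabet_dim = net$n_inputs,
                      initial = 0L, trans = g$trans),
                 class = "omega_automaton")
  en <- .enumerate_cycles(a, max_cycles = max_cycles)
  keep <- en$cycles
  if (!reachable_only) {
    reach <- .reach_set(a, 0L)
    keep <- Filter(function(c) all(c$state_set %in% reach), keep)
  }
  lapply(keep, function(c) {
    c$witness <- canonical_witness(a, c$state_set)
    c
  })
}
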
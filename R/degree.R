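# Attractor-based complexity degrees: maximal alternating / co-alternating
# chains (Buchi) and trees (Muller), ordinal degrees in Cantor normal form,
# and self-duality.
#
# A chain is a sequence of distinct cycles of strictly alternating type, each
# next cycle accessible from the previous but not conversely; two opposite-
# type cycles in one SCC ("communicating") witness length omega.  A tree adds
# strict inclusion as a second alternation step, which is what lifts Muller
# automata beyond the Buchi fragment.  Degrees live below omega^omega and are
# carried in Cantor normal form.  Only the part of the graph reachable from
# the initial state matters: unreachable states can never occur in any run.

# ---- ordinals ---------------------------------------------------------------

# CNF: 2-column integer matrix (exponent, coefficient), exponents strictly
# descending, coefficients positive.  The zero ordinal is a 0-row matrix.
.cnf <- function(exponents, coefficients) {
  m <- cbind(exponent = as.integer(exponents), coefficient = as.integer(coefficients))
  m <- m[m[, 2L] > 0L, , drop = FALSE]
  m[order(m[, 1L], decreasing = TRUE), , drop = FALSE]
}
.cnf_finite <- function(n) if (n == 0L) .cnf(integer(), integer()) else .cnf(0L, n)
.cnf_omega <- function(m = 1L, n = 0L) .cnf(c(1L, 0L), c(m, n))

#' Format an ordinal in Cantor normal form
#'
#' @param cnf a CNF matrix as carried by [ordinal_degree()] objects.
#' @return character like `"7"`, `"omega"`, `"omega*2+1"`.
#' @export
format_ordinal <- function(cnf) {
  if (nrow(cnf) == 0L) return("0")
  terms <- apply(cnf, 1L, function(r) {
    k <- r[1L]; n <- r[2L]
    if (k == 0L) as.character(n)
    else {
      base <- if (k == 1L) "omega" else paste0("omega^", k)
      if (n == 1L) base else paste0(base, "*", n)
    }
  })
  paste(terms, collapse = "+")
}

#' Compare two ordinals in Cantor normal form
#'
#' Lexicographic comparison on descending exponents.
#'
#' @param a,b [ordinal_degree()] objects, CNF matrices, or non-negative
#'   integers (finite ordinals).
#' @return `"lt"`, `"eq"` or `"gt"`.
#' @examples
#' ordinal_compare(3, 5)                       # "lt"
#' @export
ordinal_compare <- function(a, b) {
  as_cnf <- function(x) {
    if (inherits(x, "ordinal_degree")) return(x$cnf)
    if (is.matrix(x)) return(x)
    .cnf_finite(as.integer(x))
  }
  a <- as_cnf(a); b <- as_cnf(b)
  i <- 1L
  repeat {
    if (i > nrow(a) && i > nrow(b)) return("eq")
    if (i > nrow(a)) return("lt")
    if (i > nrow(b)) return("gt")
    if (a[i, 1L] != b[i, 1L]) return(if (a[i, 1L] < b[i, 1L]) "lt" else "gt")
    if (a[i, 2L] != b[i, 2L]) return(if (a[i, 2L] < b[i, 2L]) "lt" else "gt")
    i <- i + 1L
  }
}

#' Ordinal complexity degrees
#'
#' The result of a degree computation: an ordinal below omega^omega in Cantor
#' normal form, a self-duality flag, the kind of the witnessing structure and
#' the witness itself.
#'
#' @param cnf CNF matrix (see [format_ordinal()]).
#' @param self_dual logical.
#' @param kind `"alternating"` or `"co_alternating"` (the kind of the maximal
#'   witness; for self-dual results both kinds attain the maximum and the
#'   alternating witness is reported).
#' @param witness an alternating structure: list with `kind`, `cycles` (list
#'   of [new_cycle()]), `relations` (pairwise tags `"included"`,
#'   `"accessible"` or `"communicating"`) and `excluded_prefix`.
#' @param status `"exact"`, or `"lower_bound"` for transfinite results beyond
#'   the implemented recursion depth.
#' @return An object of class `ordinal_degree`.
#' @export
ordinal_degree <- function(cnf, self_dual, kind, witness = NULL, status = "exact") {
  structure(list(cnf = cnf, self_dual = self_dual, kind = kind,
                 witness = witness, status = status),
            class = "ordinal_degree")
}

#' @export
print.ordinal_degree <- function(x, ...) {
  cat("attractor-based complexity degree: ", format_ordinal(x$cnf),
      if (x$self_dual) " (self-dual)" else " (non-self-dual)",
      ", witness kind: ", x$kind,
      if (!identical(x$status, "exact")) paste0(" [", x$status, "]"), "\n", sep = "")
  if (!is.null(x$witness) && length(x$witness$cycles)) {
    for (i in seq_along(x$witness$cycles)) {
      cat(sprintf("  C%d (%s): {%s}\n", i, x$witness$types[i],
                  paste(x$witness$cycles[[i]]$state_set, collapse = ", ")))
    }
  }
  invisible(x)
}

# ---- SCC-level analysis shared by chains and trees --------------------------

# Restrict an automaton view to the part reachable from the initial state and
# compute its cyclic SCCs, condensation reachability, and per-SCC successful /
# non-successful cycle witnesses.  `succ_test(set)` decides success of a
# state set; `find_witnesses(scc_states)` must return list(successful =
# cycle-or-NULL, non_successful = cycle-or-NULL).
.scc_analysis <- function(a, find_witnesses) {
  reach <- .reach_set(a, a$initial)
  sccs <- Filter(function(c) c$cyclic && all(c$states %in% reach), graph_sccs(a))
  k <- length(sccs)
  wit <- lapply(sccs, function(c) find_witnesses(c$states))
  # reachability between SCCs (directed, reflexive)
  reach_mat <- matrix(FALSE, k, k)
  if (k) {
    sets <- lapply(sccs, function(c) c$states)
    full_reach <- lapply(sets, function(s) .reach_set(a, s))
    for (i in seq_len(k)) for (j in seq_len(k))
      reach_mat[i, j] <- i == j || length(intersect(full_reach[[i]], sets[[j]])) > 0L
  }
  list(sccs = sccs, wit = wit, reach = reach_mat)
}

# shortest cycle through vertex v inside the vertex set `allowed`
.cycle_through <- function(a, v, allowed) {
  e <- .edge_table(a)
  e <- e[e$from %in% allowed & e$to %in% allowed, ]
  if (any(e$from == v & e$to == v)) return(new_cycle(v, witness = c(v, v)))
  succ <- lapply(split(e$to, e$from), function(x) sort(unique(x)))
  prev <- list(); seen <- v; frontier <- v
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in sort(frontier)) for (w in succ[[as.character(u)]] %||% integer()) {
      if (w == v) {
        path <- c(u, v)
        while (path[1L] != v) path <- c(prev[[as.character(path[1L])]], path)
        return(new_cycle(unique(path), witness = path))
      }
      if (!w %in% seen) { seen <- c(seen, w); prev[[as.character(w)]] <- u; nxt <- c(nxt, w) }
    }
    frontier <- nxt
  }
  NULL
}

# any cycle within the vertex set `allowed` (deterministic: smallest vertex
# of the lexicographically first cyclic sub-SCC)
.cycle_within <- function(a, allowed) {
  if (!length(allowed)) return(NULL)
  for (v in sort(allowed)) {
    c <- .cycle_through(a, v, allowed)
    if (!is.null(c)) return(c)
  }
  NULL
}

# ---- Buchi chains -----------------------------------------------------------

#' Maximal alternating and co-alternating chains of a Buchi automaton
#'
#' Computes the lengths of maximal alternating (first cycle successful) and
#' co-alternating (first cycle non-successful) chains: sequences of distinct
#' cycles of strictly alternating type in which each next cycle is accessible
#' from the previous one but not conversely.  Cycles of a chain therefore lie
#' in distinct strongly connected components, so the computation is a longest
#' alternating path over the SCC condensation.  Length omega is detected iff
#' some SCC carries two communicating cycles of opposite type.
#'
#' @param a a [buchi_automaton()].
#' @return list with `alt` and `co_alt` (CNF matrices) and `witnesses` (per
#'   kind, an alternating structure or `NULL`).
#' @export
max_chain <- function(a) {
  if (!inherits(a, "buchi_automaton")) stop("max_chain expects a Buchi automaton", call. = FALSE)
  an <- .scc_analysis(a, function(sts) {
    sv <- NULL
    fin <- intersect(sts, a$finals)
    if (length(fin)) sv <- .cycle_through(a, min(fin), sts)
    nv <- .cycle_within(a, setdiff(sts, a$finals))
    list(successful = sv, non_successful = nv)
  })
  k <- length(an$sccs)
  has <- cbind(successful = vapply(an$wit, function(w) !is.null(w$successful), logical(1)),
               non_successful = vapply(an$wit, function(w) !is.null(w$non_successful), logical(1)))
  # omega: one SCC with both cycle types (they communicate)
  mixed <- which(has[, 1L] & has[, 2L])
  if (length(mixed)) {
    i <- mixed[1L]
    wit <- list(kind = "alternating",
                cycles = list(an$wit[[i]]$successful, an$wit[[i]]$non_successful),
                types = c("meaningful", "spurious"),
                relations = "communicating", excluded_prefix = list())
    return(list(alt = .cnf_omega(), co_alt = .cnf_finite(0L),
                witnesses = list(alternating = wit, co_alternating = NULL)))
  }
  # longest alternating path over the condensation; f[i, t]: best chain
  # starting in SCC i with a cycle of type t (1 = successful, 2 = not)
  f <- matrix(0L, k, 2L); nxt <- matrix(NA_integer_, k, 2L)
  strict <- an$reach & !t(an$reach)            # one-way reachability
  # iterate until fixpoint (condensation is a DAG, so k passes suffice)
  repeat {
    changed <- FALSE
    for (i in seq_len(k)) for (t in 1:2) {
      if (!has[i, t]) next
      best <- 1L; bj <- NA_integer_
      ot <- 3L - t
      for (j in which(strict[i, ])) if (has[j, ot] && f[j, ot] + 1L > best) {
        best <- f[j, ot] + 1L; bj <- j
      }
      if (best > f[i, t]) { f[i, t] <- best; nxt[i, t] <- bj; changed <- TRUE }
    }
    if (!changed) break
  }
  build <- function(t) {
    if (!any(has[, t] & f[, t] > 0L)) return(NULL)
    i <- which.max(ifelse(has[, t], f[, t], -1L))
    cycles <- list(); types <- character(0); cur <- i; ct <- t
    while (!is.na(cur)) {
      w <- an$wit[[cur]]
      cycles[[length(cycles) + 1L]] <- if (ct == 1L) w$successful else w$non_successful
      types <- c(types, if (ct == 1L) "meaningful" else "spurious")
      nx <- nxt[cur, ct]; cur <- nx; ct <- 3L - ct
    }
    list(kind = if (t == 1L) "alternating" else "co_alternating",
         cycles = cycles, types = types,
         relations = rep("accessible", max(length(cycles) - 1L, 0L)),
         excluded_prefix = list())
  }
  wa <- build(1L); wc <- build(2L)
  list(alt = .cnf_finite(if (is.null(wa)) 0L else length(wa$cycles)),
       co_alt = .cnf_finite(if (is.null(wc)) 0L else length(wc$cycles)),
       witnesses = list(alternating = wa, co_alternating = wc))
}

# ---- Muller trees -----------------------------------------------------------

#' Maximal alternating and co-alternating trees of a Muller automaton
#'
#' Finite tree lengths are the maximum number of cycles in a sequence of
#' strictly alternating type in which each next cycle either strictly
#' includes the previous one (inside one SCC) or is one-way accessible from
#' it (across SCCs).  Transfinite lengths arise from branch pairs: a
#' successful and a non-successful cycle in mutually inaccessible components,
#' both reachable from a common upstream point - once the run commits to one
#' branch the other is lost, which is exactly what an omega-level choice
#' requires.  The search is exact for the finite fragment and for degrees
#' below omega*m + n with the pair-chain construction; anything deeper is
#' reported with status `"lower_bound"`, never silently.
#'
#' @param a a [muller_automaton()].
#' @param max_cycles cycle enumeration cap.
#' @return list with `alt`, `co_alt` (CNF matrices), `witnesses`, and
#'   `status`.
#' @export
max_tree <- function(a, max_cycles = 200000L) {
  if (!inherits(a, "muller_automaton")) stop("max_tree expects a Muller automaton", call. = FALSE)
  reach <- .reach_set(a, a$initial)
  sub <- a
  keep <- a$states %in% reach
  sub$states <- a$states[keep]
  sub$trans <- a$trans[keep, , drop = FALSE]
  sub$trans[!(sub$trans %in% sub$states)] <- NA_integer_
  en <- .enumerate_cycles(sub, max_cycles = max_cycles)
  nc <- length(en$cycles)
  if (nc == 0L)
    return(list(alt = .cnf_finite(0L), co_alt = .cnf_finite(0L),
                witnesses = list(alternating = NULL, co_alternating = NULL),
                status = "exact"))
  succ_of <- vapply(en$cycles, function(c) isTRUE(a$table(c$state_set)), logical(1))
  scc_of <- en$scc_id
  sccs <- en$sccs
  k <- length(sccs)
  # SCC reachability (reflexive) and strict one-way order
  sets <- lapply(sccs, function(c) c$states)
  full_reach <- lapply(sets, function(s) .reach_set(sub, s))
  reach_mat <- matrix(FALSE, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    reach_mat[i, j] <- i == j || length(intersect(full_reach[[i]], sets[[j]])) > 0L
  strict <- reach_mat & !t(reach_mat)

  # ---- finite fragment: longest alternating inclusion/accessibility path ----
  # g[c]: longest alternating sequence starting (innermost) at cycle c.
  sizes <- vapply(en$cycles, function(c) length(c$state_set), integer(1))
  g <- rep(1L, nc); succ_ptr <- rep(NA_integer_, nc)
  # D[scc, type]: best g over cycles of that type in SCCs strictly downstream
  ord_scc <- order(vapply(seq_len(k), function(i) sum(strict[, i]), integer(1)),
                   decreasing = TRUE)  # most ancestors first => downstream first
  D <- matrix(0L, k, 2L); Dptr <- matrix(NA_integer_, k, 2L)
  for (i in ord_scc) {
    for (t in 1:2) {
      best <- 0L; bp <- NA_integer_
      for (j in which(strict[i, ])) {
        cand <- which(scc_of == j & succ_of == (t == 1L))
        if (length(cand)) {
          w <- cand[which.max(g[cand])]
          if (g[w] > best) { best <- g[w]; bp <- w }
        }
        # also cycles further downstream via D of j are covered since g is
        # computed before for downstream SCCs (their g already includes D)
      }
      D[i, t] <- best; Dptr[i, t] <- bp
    }
    members <- which(scc_of == i)
    for (ci in members[order(sizes[members], decreasing = TRUE)]) {
      opp <- !succ_of[ci]
      best <- 0L; bp <- NA_integer_
      # strict superset within the SCC, opposite type
      for (cj in members) {
        if (sizes[cj] <= sizes[ci] || succ_of[cj] != opp) next
        if (all(en$cycles[[ci]]$state_set %in% en$cycles[[cj]]$state_set) && g[cj] > best) {
          best <- g[cj]; bp <- cj
        }
      }
      tD <- if (opp) 1L else 2L
      if (D[i, tD] > best) { best <- D[i, tD]; bp <- Dptr[i, tD] }
      g[ci] <- 1L + best
      succ_ptr[ci] <- bp
    }
  }
  build_fin <- function(successful_first) {
    cand <- which(succ_of == successful_first)
    if (!length(cand)) return(NULL)
    c0 <- cand[which.max(g[cand])]
    cycles <- list(); types <- character(0); rels <- character(0)
    cur <- c0
    while (!is.na(cur)) {
      cyc <- en$cycles[[cur]]
      cyc$witness <- canonical_witness(sub, cyc$state_set)
      cycles[[length(cycles) + 1L]] <- cyc
      types <- c(types, if (succ_of[cur]) "meaningful" else "spurious")
      nx <- succ_ptr[cur]
      if (!is.na(nx))
        rels <- c(rels, if (scc_of[nx] == scc_of[cur]) "included" else "accessible")
      cur <- nx
    }
    list(kind = if (successful_first) "alternating" else "co_alternating",
         cycles = cycles, types = types, relations = rels, excluded_prefix = list())
  }
  wa <- build_fin(TRUE); wc <- build_fin(FALSE)
  n_alt <- if (is.null(wa)) 0L else length(wa$cycles)
  n_co <- if (is.null(wc)) 0L else length(wc$cycles)

  # ---- transfinite fragment: chains of branch pairs -------------------------
  has_type <- cbind(vapply(seq_len(k), function(i) any(scc_of == i & succ_of), logical(1)),
                    vapply(seq_len(k), function(i) any(scc_of == i & !succ_of), logical(1)))
  pairs <- list()
  for (ia in seq_len(k)) for (ib in seq_len(k)) {
    if (ia == ib || !has_type[ia, 1L] || !has_type[ib, 2L]) next
    if (reach_mat[ia, ib] || reach_mat[ib, ia]) next   # must be true branches
    pairs[[length(pairs) + 1L]] <- c(ia, ib)
  }
  m_max <- 0L; last_pair <- NULL
  if (length(pairs)) {
    np <- length(pairs)
    follows <- matrix(FALSE, np, np)   # follows[p, q]: q strictly after p,
    # i.e. both SCCs of q reachable from both SCCs of p
    for (p in seq_len(np)) for (q in seq_len(np)) {
      if (p == q) next
      pa <- pairs[[p]]; qa <- pairs[[q]]
      follows[p, q] <- reach_mat[pa[1L], qa[1L]] && reach_mat[pa[1L], qa[2L]] &&
        reach_mat[pa[2L], qa[1L]] && reach_mat[pa[2L], qa[2L]]
    }
    plen <- rep(1L, np)
    repeat {
      changed <- FALSE
      for (p in seq_len(np)) {
        cand <- which(follows[p, ])
        v <- if (length(cand)) 1L + max(plen[cand]) else 1L
        if (v > plen[p]) { plen[p] <- v; changed <- TRUE }
      }
      if (!changed) break
    }
    m_max <- max(plen)
    # last pair of a maximal pair chain: any pair achieving plen == 1 at the
    # end; for the finite tail use a pair with no follower on a longest chain
    start <- which.max(plen)
    cur <- start
    while (TRUE) {
      cand <- which(follows[cur, ] & plen == plen[cur] - 1L)
      if (!length(cand)) break
      cur <- cand[1L]
    }
    last_pair <- pairs[[cur]]
  }
  status <- "exact"
  if (m_max == 0L) {
    alt <- .cnf_finite(n_alt); co <- .cnf_finite(n_co)
  } else {
    # finite tails reachable from both members of the last pair
    down_ok <- vapply(seq_len(nc), function(ci)
      reach_mat[last_pair[1L], scc_of[ci]] && reach_mat[last_pair[2L], scc_of[ci]] &&
        !scc_of[ci] %in% last_pair, logical(1))
    tail_len <- function(successful_first) {
      cand <- which(down_ok & succ_of == successful_first)
      if (!length(cand)) 0L else max(g[cand])
    }
    alt <- .cnf_omega(m_max, tail_len(TRUE))
    co <- .cnf_omega(m_max, tail_len(FALSE))
    status <- if (m_max > 1L) "lower_bound" else "exact"
    mk_pair_wit <- function(kind) {
      sa <- which(scc_of == last_pair[1L] & succ_of)[1L]
      nb <- which(scc_of == last_pair[2L] & !succ_of)[1L]
      ca <- en$cycles[[sa]]; ca$witness <- canonical_witness(sub, ca$state_set)
      cb <- en$cycles[[nb]]; cb$witness <- canonical_witness(sub, cb$state_set)
      list(kind = kind, cycles = list(ca, cb),
           types = c("meaningful", "spurious"),
           relations = "branch_pair", excluded_prefix = list())
    }
    wa <- mk_pair_wit("alternating"); wc <- mk_pair_wit("co_alternating")
  }
  list(alt = alt, co_alt = co,
       witnesses = list(alternating = wa, co_alternating = wc),
       status = status)
}

# ---- degrees ----------------------------------------------------------------

# fold (alt, co_alt, witnesses) into an ordinal_degree via the case analysis:
# one-sided maximum -> that degree, non-self-dual; both sides equal ->
# self-dual; an omega-chain is non-self-dual.
.fold_degree <- function(alt, co, witnesses, status = "exact") {
  cmp <- ordinal_compare(alt, co)
  if (nrow(alt) && alt[1L, 1L] >= 1L && cmp != "lt") {
    # transfinite maximum: limit and limit-plus-n classes; at exact limit
    # levels the classes are non-self-dual
    if (cmp == "eq" && alt[nrow(alt), 1L] == 0L)
      return(ordinal_degree(alt, TRUE, "alternating", witnesses$alternating, status))
    return(ordinal_degree(alt, FALSE, "alternating", witnesses$alternating, status))
  }
  if (cmp == "eq")
    return(ordinal_degree(alt, TRUE, "alternating", witnesses$alternating, status))
  if (cmp == "gt")
    ordinal_degree(alt, FALSE, "alternating", witnesses$alternating, status)
  else
    ordinal_degree(co, FALSE, "co_alternating", witnesses$co_alternating, status)
}

#' Degree of a Buchi automaton / of an output-layer network
#'
#' `buchi_degree` computes the complexity degree of a deterministic Buchi
#' automaton from its maximal chains; `rnn_degree` converts a network with an
#' output layer to its Buchi automaton first.  One-sided maximal chains give
#' a non-self-dual degree of that length; equal maximal chains of both kinds
#' give a self-dual degree; an omega-chain gives degree omega, non-self-dual.
#'
#' @param a a [buchi_automaton()].
#' @return An [ordinal_degree()].
#' @export
buchi_degree <- function(a) {
  r <- max_chain(a)
  .fold_degree(r$alt, r$co_alt, r$witnesses)
}

#' @rdname buchi_degree
#' @param net a [boolean_network()] with output layer (an empty output layer
#'   is allowed and types every attractor spurious).
#' @param reachable_only restrict the automaton to reachable states (does not
#'   change the degree).
#' @export
rnn_degree <- function(net, reachable_only = TRUE) {
  if (is.null(net$output_layer)) stop("network has no output layer", call. = FALSE)
  buchi_degree(network_to_buchi(net, reachable_only = reachable_only))
}

#' Degree of a Muller automaton / of a typed network
#'
#' `muller_degree` computes the complexity degree of a deterministic Muller
#' automaton from its maximal trees; `complete_degree` converts a network
#' with an attractor type assignment first.  The case analysis mirrors
#' [buchi_degree()].
#'
#' @param a a [muller_automaton()].
#' @param max_cycles cycle enumeration cap.
#' @return An [ordinal_degree()] (with status `"lower_bound"` for transfinite
#'   results beyond the implemented recursion depth).
#' @export
muller_degree <- function(a, max_cycles = 200000L) {
  r <- max_tree(a, max_cycles = max_cycles)
  .fold_degree(r$alt, r$co_alt, r$witnesses, r$status)
}

#' @rdname muller_degree
#' @param net a [boolean_network()].
#' @param assignment a [type_assignment()] total on reachable cycles.
#' @export
complete_degree <- function(net, assignment, max_cycles = 200000L) {
  muller_degree(network_to_muller(net, assignment, reachable_only = TRUE),
                max_cycles = max_cycles)
}

#' Is an assignment realisable by an output layer?
#'
#' Checks inclusion-monotonicity on the reachable cycles: under output-layer
#' semantics no meaningful cycle can be strictly contained in a spurious one
#' (a supercycle visits at least the same output activity).  Typed networks
#' whose assignment violates this lie strictly beyond the Buchi-expressible
#' initial segment of the complete hierarchy.
#'
#' @param x a [boolean_network()] or an automaton.
#' @param assignment a [type_assignment()] (for networks/Muller automata).
#' @param max_cycles enumeration cap.
#' @return logical: `TRUE` iff the assignment is inclusion-monotone.
#' @export
buchi_segment_check <- function(x, assignment = NULL, max_cycles = 200000L) {
  if (inherits(x, "boolean_network")) {
    a <- network_to_muller(x, assignment, reachable_only = TRUE)
    test <- a$table
  } else if (inherits(x, "muller_automaton")) {
    a <- x; test <- a$table
  } else if (inherits(x, "buchi_automaton")) {
    a <- x; test <- function(set) length(intersect(set, a$finals)) > 0L
  } else stop("unsupported input", call. = FALSE)
  en <- .enumerate_cycles(a, max_cycles = max_cycles)
  succ <- vapply(en$cycles, function(c) isTRUE(test(c$state_set)), logical(1))
  nc <- length(en$cycles)
  for (i in seq_len(nc)) {
    if (!succ[i]) next
    for (j in seq_len(nc)) {
      if (succ[j] || en$scc_id[i] != en$scc_id[j]) next
      si <- en$cycles[[i]]$state_set; sj <- en$cycles[[j]]$state_set
      if (length(si) < length(sj) && all(si %in% sj)) return(FALSE)
    }
  }
  TRUE
}
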
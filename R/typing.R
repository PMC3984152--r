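# Meaningful/spurious type assignments for cycles and attractors.
#
# An assignment is a total classifier over cycles.  Provenances: induced by
# an output layer, an arbitrary user predicate, the neurobiological rule of
# the basal ganglia case study, or an explicit list (which rejects unknown
# cycles loudly - never a silent default).

#' Type assignments
#'
#' Wraps a classifier `cycle -> "meaningful" | "spurious"` with a provenance
#' tag.  Classification is deterministic: equal state sets (with equal
#' witnesses, for walk-sensitive rules) receive equal types.
#'
#' @param classify function taking a [new_cycle()] and returning
#'   `"meaningful"` or `"spurious"`.
#' @param provenance one of `"output_layer"`, `"predicate"`, `"bg_rule"`,
#'   `"explicit_list"`.
#' @param flipped internal; tracks complementation.
#' @return An object of class `type_assignment`.
#' @export
type_assignment <- function(classify,
                            provenance = c("predicate", "output_layer",
                                           "bg_rule", "explicit_list"),
                            flipped = FALSE) {
  provenance <- match.arg(provenance)
  structure(list(classify = classify, provenance = provenance, flipped = flipped),
            class = "type_assignment")
}

#' @export
print.type_assignment <- function(x, ...) {
  cat("type assignment (", x$provenance,
      if (x$flipped) ", complemented", ")\n", sep = "")
  invisible(x)
}

#' Classify a cycle
#'
#' Applies an assignment to a cycle, honouring complementation.
#'
#' @param assignment a [type_assignment()].
#' @param cycle a [new_cycle()].
#' @return `"meaningful"` or `"spurious"`.
#' @export
classify_cycle <- function(assignment, cycle) {
  t <- assignment$classify(cycle)
  if (!t %in% c("meaningful", "spurious"))
    stop("classifier returned '", t, "'", call. = FALSE)
  if (assignment$flipped) t <- if (t == "meaningful") "spurious" else "meaningful"
  t
}

#' Complement an assignment
#'
#' Flips every classification and nothing else; an involution.
#'
#' @param assignment a [type_assignment()].
#' @return the flipped [type_assignment()].
#' @export
complement_assignment <- function(assignment) {
  assignment$flipped <- !assignment$flipped
  assignment
}

#' Output-layer induced assignment
#'
#' A cycle is meaningful iff it contains at least one state in which some
#' output cell fires - the typing under which networks match deterministic
#' Buchi automata.  This rule is inclusion-monotone: every supercycle of a
#' meaningful cycle is meaningful, so no meaningful cycle is ever contained
#' in a spurious one.
#'
#' @param net a [boolean_network()] with a non-empty `output_layer` (an empty
#'   output layer types every cycle spurious, which is permitted).
#' @return A [type_assignment()] with provenance `"output_layer"`.
#' @export
output_layer_assignment <- function(net) {
  if (is.null(net$output_layer))
    stop("network has no output layer", call. = FALSE)
  out_bits <- match(net$output_layer, net$cells)
  n <- net$n_cells
  type_assignment(function(cycle) {
    if (length(out_bits) == 0L) return("spurious")
    fired <- any(vapply(cycle$state_set, function(s)
      any(state_bits(s, n)[out_bits] == 1L), logical(1)))
    if (fired) "meaningful" else "spurious"
  }, provenance = "output_layer")
}

#' Neurobiological typing rule of the basal ganglia case study
#'
#' `bg_constitutive_type` types a vertex-simple (constitutive) cycle:
#' spurious iff some state of the cycle has SC active with Thalamus quiet, or
#' GPi/SNr is quiet during a strict majority of the cycle's duration (its
#' period length, the closing endpoint counted once); meaningful otherwise.
#'
#' `bg_cycle_type` types an arbitrary closed walk by majority vote over the
#' types of its constitutive cycles, ties resolved as meaningful.
#'
#' @param walk closed state sequence (first == last), a walk list from
#'   [closed_walks_from()], or a [new_cycle()] with witness.
#' @param roles named positions of SC, Thalamus and GPi/SNr bits, see
#'   [bg_roles()].
#' @param n_cells number of cells used for decoding state codes.
#' @return `"meaningful"` or `"spurious"`.
#' @export
bg_constitutive_type <- function(walk, roles = bg_roles(), n_cells = 9L) {
  if (inherits(walk, "cycle")) walk <- walk$witness
  if (is.list(walk)) walk <- walk$states
  walk <- as.integer(walk)
  if (walk[1L] != walk[length(walk)])
    stop("constitutive cycle must be a closed sequence", call. = FALSE)
  if (!all(c("SC", "Thalamus", "GPi_SNr") %in% names(roles)))
    stop("roles must name SC, Thalamus and GPi_SNr bit positions", call. = FALSE)
  period <- walk[-length(walk)]          # endpoint counted once
  B <- t(vapply(period, state_bits, integer(n_cells), n_cells = n_cells))
  sc <- B[, roles[["SC"]]]; th <- B[, roles[["Thalamus"]]]; gpi <- B[, roles[["GPi_SNr"]]]
  if (any(sc == 1L & th == 0L)) return("spurious")
  if (sum(gpi == 0L) * 2L > length(period)) return("spurious")
  "meaningful"
}

#' @rdname bg_constitutive_type
#' @export
bg_cycle_type <- function(walk, roles = bg_roles(), n_cells = 9L) {
  if (inherits(walk, "cycle")) walk <- walk$witness
  if (is.list(walk)) walk <- walk$states
  walk <- as.integer(walk)
  parts <- constitutive_decomposition(walk)
  types <- vapply(parts, bg_constitutive_type, "", roles = roles, n_cells = n_cells)
  n_m <- sum(types == "meaningful"); n_s <- sum(types == "spurious")
  if (n_m >= n_s) "meaningful" else "spurious"   # ties are meaningful
}

#' Assignment implementing the case-study rule
#'
#' Wraps [bg_cycle_type()] as a [type_assignment()]; cycles without a stored
#' witness walk are typed through their canonical witness on `automaton`.
#'
#' @param automaton the automaton whose cycles are typed (used to construct
#'   canonical witnesses).
#' @param roles,n_cells see [bg_constitutive_type()].
#' @return A [type_assignment()] with provenance `"bg_rule"`.
#' @export
bg_assignment <- function(automaton, roles = bg_roles(), n_cells = 9L) {
  type_assignment(function(cycle) {
    w <- cycle$witness %||% canonical_witness(automaton, cycle$state_set)
    bg_cycle_type(w, roles = roles, n_cells = n_cells)
  }, provenance = "bg_rule")
}

#' Predicate and explicit-list assignments
#'
#' `predicate_assignment` wraps an arbitrary total predicate over state sets;
#' `explicit_assignment` wraps a finite list of (state set, type) pairs and
#' raises an error for any cycle not in the list.
#'
#' @param predicate function over integer state sets returning `TRUE`
#'   (meaningful) or `FALSE` (spurious).
#' @return A [type_assignment()].
#' @export
predicate_assignment <- function(predicate) {
  type_assignment(function(cycle) {
    if (isTRUE(predicate(cycle$state_set))) "meaningful" else "spurious"
  }, provenance = "predicate")
}

#' @rdname predicate_assignment
#' @param pairs list of `list(states = <integer vector>, type =
#'   "meaningful"|"spurious")` entries.
#' @export
explicit_assignment <- function(pairs) {
  keys <- vapply(pairs, function(p) paste(sort(unique(as.integer(p$states))), collapse = ","), "")
  types <- vapply(pairs, function(p) match.arg(p$type, c("meaningful", "spurious")), "")
  type_assignment(function(cycle) {
    k <- paste(cycle$state_set, collapse = ",")
    i <- match(k, keys)
    if (is.na(i))
      stop("cycle {", paste(cycle$state_set, collapse = ", "),
           "} is not covered by the explicit assignment", call. = FALSE)
    types[i]
  }, provenance = "explicit_list")
}
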
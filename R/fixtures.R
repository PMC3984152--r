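# Seed-deterministic generators: random networks, random deterministic
# omega-automata, and planted-degree automata whose maximal chain/tree length
# is known by construction (and re-verified at build time).

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Random Boolean network
#'
#' Draws each potential connection independently with probability `density`
#' and a weight uniformly from `weight_set`; reproducible from `seed`.
#'
#' @param n_cells,n_inputs network dimensions (keep `n_cells` <= 10 for
#'   exhaustive downstream analyses).
#' @param weight_set character vector of rational literals to draw from.
#' @param density connection probability.
#' @param output_layer `"random"` (each cell with probability 1/2), `"none"`,
#'   or an explicit character vector of cell names.
#' @param seed integer seed.
#' @return A [boolean_network()].
#' @export
random_network <- function(n_cells, n_inputs = 1L,
                           weight_set = c("-1", "-1/2", "1/2", "1", "2"),
                           density = 0.5, output_layer = "random", seed = 1L) {
  .with_seed(seed, {
    draw <- function(n) ifelse(stats::runif(n) < density,
                               sample(weight_set, n, replace = TRUE), "0")
    W <- matrix(draw(n_cells^2), n_cells, n_cells)
    Win <- if (n_inputs > 0) matrix(draw(n_inputs * n_cells), n_inputs, n_cells) else NULL
    ol <- if (identical(output_layer, "random")) {
      cl <- paste0("c", seq_len(n_cells))
      cl[stats::runif(n_cells) < 0.5]
    } else if (identical(output_layer, "none")) character() else output_layer
    boolean_network(W, input_weights = Win, output_layer = ol)
  })
}

#' Random deterministic omega-automata
#'
#' `random_buchi` draws complete uniformly random transitions and includes
#' each state in the final set with probability `final_prob`.
#' `random_muller` additionally draws a table by including each cycle of the
#' realised graph with probability 1/2.
#'
#' @param n_states number of states (codes `0:(n_states-1)`).
#' @param alphabet_dim M.
#' @param final_prob probability for each state to be final.
#' @param seed integer seed.
#' @return A [buchi_automaton()] / [muller_automaton()].
#' @export
random_buchi <- function(n_states, alphabet_dim = 1L, final_prob = 0.5, seed = 1L) {
  .with_seed(seed, {
    states <- 0:(n_states - 1L)
    trans <- matrix(sample(states, n_states * 2^alphabet_dim, replace = TRUE),
                    n_states, 2^alphabet_dim)
    finals <- states[stats::runif(n_states) < final_prob]
    buchi_automaton(states, alphabet_dim, 0L, trans, finals)
  })
}

#' @rdname random_buchi
#' @export
random_muller <- function(n_states, alphabet_dim = 1L, seed = 1L) {
  b <- random_buchi(n_states, alphabet_dim, seed = seed)
  en <- .enumerate_cycles(b)
  .with_seed(seed + 1L, {
    keep <- stats::runif(length(en$cycles)) < 0.5
    muller_automaton(b$states, alphabet_dim, b$initial, b$trans,
                     table_sets = lapply(en$cycles[keep], function(c) c$state_set))
  })
}

#' Planted-degree automata
#'
#' Constructs automata whose maximal alternating or co-alternating structure
#' has a known length, for parameter-recovery testing.
#'
#' `planted_chain_automaton` (Buchi): `length` singleton self-loop components
#' linked one-way, with alternating finality; its maximal chain has exactly
#' `length` cycles and the planted kind.  With `length = "omega"` a single
#' mixed component (a final self-loop and a non-final self-loop communicating)
#' is built, witnessing an omega-chain.
#'
#' `planted_tree_automaton` (Muller): a single component whose cycles are
#' exactly the nested sets `{1}`, `{1,2}`, ..., `{1..length}`, with table
#' membership alternating from the innermost cycle; its maximal tree is an
#' inclusion chain of exactly `length` cycles of the planted kind.
#'
#' Every instance is re-verified at build time by brute force
#' ([max_chain()] / [max_tree()] on the built instance); a mismatch is an
#' error.
#'
#' @param kind `"alternating"` (innermost/first cycle successful) or
#'   `"co_alternating"`.
#' @param length chain/tree length (>= 1, <= 6), or `"omega"` for chains.
#' @param seed unused entropy hook kept for interface symmetry; the gadgets
#'   are deterministic.
#' @return An automaton with attribute `planted` = `list(kind, length)`.
#' @export
planted_chain_automaton <- function(kind = c("alternating", "co_alternating"),
                                    length = 3L, seed = 1L) {
  kind <- match.arg(kind)
  if (identical(length, "omega")) {
    # states 0 (non-final) and 1 (final): 0 -0-> 0, 0 -1-> 1, 1 -*-> 0
    trans <- matrix(c(0L, 0L, 1L, 0L), 2L, 2L)
    a <- buchi_automaton(0:1, 1L, 0L, trans, finals = 1L)
    r <- max_chain(a)
    stopifnot(identical(ordinal_compare(r$alt, .cnf_omega()), "eq"))
    attr(a, "planted") <- list(kind = kind, length = "omega")
    return(a)
  }
  length <- as.integer(length)
  stopifnot(length >= 1L, length <= 6L)
  states <- seq_len(length) - 1L
  # letter 0: self-loop; letter 1: advance (last state: self-loop)
  trans <- cbind(states, c(states[-1L], states[length]))
  first_final <- kind == "alternating"
  finals <- states[(seq_len(length) %% 2L == 1L) == first_final]
  a <- buchi_automaton(states, 1L, 0L, trans, finals)
  r <- max_chain(a)
  want <- .cnf_finite(length)
  got <- if (kind == "alternating") r$alt else r$co_alt
  other <- if (kind == "alternating") r$co_alt else r$alt
  stopifnot(identical(ordinal_compare(got, want), "eq"),
            identical(ordinal_compare(other, want), "lt"))
  attr(a, "planted") <- list(kind = kind, length = length)
  a
}

#' @rdname planted_chain_automaton
#' @export
planted_tree_automaton <- function(kind = c("alternating", "co_alternating"),
                                   length = 3L, seed = 1L) {
  kind <- match.arg(kind)
  length <- as.integer(length)
  stopifnot(length >= 1L, length <= 6L)
  states <- seq_len(length)
  # letter 0: back to 1; letter 1: one step deeper (capped); the cycles of
  # this graph are exactly the nested prefixes {1}, {1,2}, ..., {1..length}
  deeper <- pmin(states + 1L, length)
  if (length > 1L) deeper[length] <- 1L
  trans <- cbind(rep(1L, length), deeper)
  trans[1L, 1L] <- 1L
  first_successful <- kind == "alternating"
  tbl <- lapply(states[(states %% 2L == 1L) == first_successful],
                function(j) seq_len(j))
  a <- muller_automaton(states, 1L, 1L, trans, table_sets = tbl)
  r <- max_tree(a)
  want <- .cnf_finite(length)
  got <- if (kind == "alternating") r$alt else r$co_alt
  other <- if (kind == "alternating") r$co_alt else r$alt
  stopifnot(identical(ordinal_compare(got, want), "eq"),
            identical(ordinal_compare(other, want), "lt"))
  attr(a, "planted") <- list(kind = kind, length = length)
  a
}

#' Relabel the states of an automaton
#'
#' Applies a random (seed-determined) bijective recoding of the state codes,
#' preserving the language.  Used to turn the deterministic planted gadgets
#' into seed-varied recovery instances.
#'
#' @param a an automaton.
#' @param seed integer seed for the permutation.
#' @return The relabelled automaton (same class); the `planted` attribute is
#'   preserved.
#' @export
relabel_automaton <- function(a, seed = 1L) {
  k <- length(a$states)
  perm <- .with_seed(seed, sample.int(k))
  new_codes <- (seq_len(k) - 1L)[perm]        # old state i -> new_codes[i]
  map <- function(x) ifelse(is.na(x), NA_integer_, new_codes[match(x, a$states)])
  trans <- matrix(map(a$trans), nrow = k)[order(new_codes), , drop = FALSE]
  if (inherits(a, "buchi_automaton")) {
    out <- buchi_automaton(sort(new_codes), a$alphabet_dim, map(a$initial),
                           trans, finals = sort(map(a$finals)))
  } else {
    out <- muller_automaton(sort(new_codes), a$alphabet_dim, map(a$initial), trans,
                            table_sets = lapply(a$table_sets, function(s) sort(map(s))))
  }
  attr(out, "planted") <- attr(a, "planted")
  out
}
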
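# First-order Boolean recurrent neural networks: threshold units with exact
# rational weights, synchronous update.

#' Construct a Boolean recurrent neural network
#'
#' A first-order Boolean recurrent neural network consists of N activation
#' cells and M input units connected by rational synaptic weights, plus a
#' rational background activity per cell.  At every time step each cell fires
#' iff the weighted sum of the previous step's firing cells, current inputs
#' and its background reaches its threshold (a hard-threshold / Heaviside
#' activation).
#'
#' Weight matrices are oriented source-to-target: `cell_weights[i, j]` is the
#' weight of the connection from cell `i` to cell `j`, `input_weights[k, j]`
#' from input unit `k` to cell `j`.  All parameters are kept as exact
#' rationals; dynamics are computed in scaled integer arithmetic, so results
#' are invariant under multiplying every parameter by a common positive
#' rational.
#'
#' @param cell_weights N x N numeric or character matrix of rational weights.
#' @param input_weights M x N matrix of rational weights (`NULL` for none).
#' @param background length-N rational vector of per-cell background activity.
#' @param thresholds length-N rational vector of firing thresholds (default 1).
#' @param comparison `"at_least"` (fire iff sum >= threshold) or
#'   `"strictly_greater"` (fire iff sum > threshold).
#' @param output_layer character vector of cell names forming the output
#'   layer (possibly empty).
#' @param cell_names,input_names optional identifier vectors; taken from
#'   dimnames when present.
#' @return An object of class `boolean_network`.
#' @examples
#' w <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
#' w["a", "b"] <- "1/2"
#' net <- boolean_network(w, input_weights = matrix("1/2", 1, 2),
#'                        background = c("1/2", 0))
#' @export
boolean_network <- function(cell_weights, input_weights = NULL,
                            background = 0, thresholds = 1,
                            comparison = c("at_least", "strictly_greater"),
                            output_layer = character(),
                            cell_names = NULL, input_names = NULL) {
  comparison <- match.arg(comparison)
  cell_weights <- as.matrix(cell_weights)
  n <- nrow(cell_weights)
  if (ncol(cell_weights) != n)
    stop("cell_weights must be square", call. = FALSE)
  if (is.null(cell_names))
    cell_names <- rownames(cell_weights) %||% paste0("c", seq_len(n))
  if (is.null(input_weights)) input_weights <- matrix(0, 0, n)
  input_weights <- as.matrix(input_weights)
  m <- nrow(input_weights)
  if (m > 0 && ncol(input_weights) != n)
    stop("input_weights must have one column per cell", call. = FALSE)
  if (is.null(input_names))
    input_names <- rownames(input_weights) %||%
      (if (m > 0) paste0("u", seq_len(m)) else character())
  background <- rep_len(background, n)
  thresholds <- rep_len(thresholds, n)
  if (!all(output_layer %in% cell_names))
    stop("output_layer contains unknown cells: ",
         paste(setdiff(output_layer, cell_names), collapse = ", "), call. = FALSE)

  sc <- .common_scale(.as_rational(cell_weights), .as_rational(input_weights),
                      .as_rational(background), .as_rational(thresholds))
  W <- matrix(sc$values[[1L]], n, n, dimnames = list(cell_names, cell_names))
  Win <- matrix(sc$values[[2L]], m, n, dimnames = list(input_names, cell_names))
  structure(list(
    cells = cell_names, inputs = input_names,
    n_cells = n, n_inputs = m,
    W = W, Win = Win,
    bg = sc$values[[3L]], theta = sc$values[[4L]],
    den = sc$den, comparison = comparison,
    output_layer = output_layer
  ), class = "boolean_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.boolean_network <- function(x, ...) {
  cat("Boolean recurrent neural network\n")
  cat("  cells (", x$n_cells, "): ", paste(x$cells, collapse = ", "), "\n", sep = "")
  if (x$n_inputs > 0)
    cat("  inputs (", x$n_inputs, "): ", paste(x$inputs, collapse = ", "), "\n", sep = "")
  cat("  threshold comparison: ", x$comparison, "\n", sep = "")
  if (length(x$output_layer))
    cat("  output layer: ", paste(x$output_layer, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Encode and decode network states
#'
#' A network state is a Boolean firing vector over the N cells; its code is
#' the value of the N-digit binary number whose most significant bit is cell
#' 1.  For the 9-cell basal ganglia model, the state with cells 1, 3 and 4
#' quiet and all others firing is coded 159.
#'
#' @param bits logical/integer firing vector (cell 1 first).
#' @param code non-negative integer state code.
#' @param n_cells number of cells N.
#' @return `state_code` returns an integer; `state_bits` an integer 0/1 vector.
#' @examples
#' state_code(c(0, 1, 0, 0, 1, 1, 1, 1, 1)) # 159
#' state_bits(159, 9)
#' @export
state_code <- function(bits) {
  bits <- as.integer(bits)
  n <- length(bits)
  as.integer(sum(bits * 2^((n - 1L):0L)))
}

#' @rdname state_code
#' @export
state_bits <- function(code, n_cells) {
  if (code < 0 || code >= 2^n_cells) stop("state code out of range", call. = FALSE)
  as.integer(intToBits(code))[n_cells:1L]
}

# internal: firing decision on scaled integer sums
.fire <- function(net, s) {
  if (net$comparison == "at_least") s >= net$theta else s > net$theta
}

#' One synchronous update step
#'
#' Applies the threshold dynamics once: cell j fires in the next state iff
#' the exact rational sum of incoming activity (previous firing cells, current
#' input units, background) reaches its threshold.
#'
#' @param net a [boolean_network()].
#' @param state firing vector (length N) or state code.
#' @param input firing vector of the M input units (length M) or input code.
#' @return integer 0/1 vector of length N (the next state).
#' @examples
#' net <- basal_ganglia_network()
#' state_code(net_step(net, 0, 1)) # 384: SC and Thalamus fire
#' @export
net_step <- function(net, state, input = integer()) {
  if (length(state) == 1L && net$n_cells > 1L) state <- state_bits(state, net$n_cells)
  if (length(input) == 1L && net$n_inputs > 1L) input <- state_bits(input, net$n_inputs)
  state <- as.integer(state); input <- as.integer(input)
  if (length(state) != net$n_cells) stop("state has wrong length", call. = FALSE)
  if (length(input) != net$n_inputs) stop("input has wrong length", call. = FALSE)
  s <- as.integer(crossprod(net$W, state)) + net$bg
  if (net$n_inputs > 0) s <- s + as.integer(crossprod(net$Win, input))
  as.integer(.fire(net, s))
}

# internal: next-state codes for a vector of state codes under one input code.
# Vectorised over states; used to build transition tables.
.step_codes <- function(net, codes, input_code) {
  n <- net$n_cells
  X <- t(vapply(codes, state_bits, integer(n), n_cells = n))
  s <- X %*% net$W
  add <- net$bg
  if (net$n_inputs > 0) {
    u <- state_bits(input_code, net$n_inputs)
    add <- add + as.integer(crossprod(net$Win, u))
  }
  s <- sweep(s, 2L, add, "+")
  B <- if (net$comparison == "at_least") s >= rep(net$theta, each = length(codes))
       else s > rep(net$theta, each = length(codes))
  as.integer((B + 0L) %*% 2^((n - 1L):0L))
}

#' Ultimately periodic input streams
#'
#' An input stream u * v^omega is given by a finite prefix `u` and a non-empty
#' period `v`, each a sequence of M-bit input vectors.  Sequences may be given
#' as a matrix (one row per time step), a vector of bit strings such as
#' `c("0", "1")` for M = 1, or a list of bit vectors.
#'
#' @param prefix,period the two finite blocks; `period` must be non-empty.
#' @param n_inputs M, the input dimension (inferred when possible).
#' @return An object of class `input_stream` with integer matrices `prefix`
#'   and `period` (one row per step).
#' @examples
#' input_stream(character(), "1")        # constant input 1
#' input_stream(c("0", "1"), c("1", "0"))
#' @export
input_stream <- function(prefix, period, n_inputs = NULL) {
  to_mat <- function(x) {
    if (is.matrix(x)) return(matrix(as.integer(x), nrow(x)))
    if (is.list(x)) return(do.call(rbind, lapply(x, as.integer)))
    if (is.character(x)) {
      if (length(x) == 0L) return(matrix(integer(), 0L, n_inputs %||% 1L))
      return(do.call(rbind, lapply(strsplit(x, ""), as.integer)))
    }
    # numeric vector: one bit per step (M = 1)
    matrix(as.integer(x), ncol = 1L)
  }
  p <- to_mat(prefix); v <- to_mat(period)
  if (nrow(v) == 0L) stop("period must be non-empty", call. = FALSE)
  if (nrow(p) > 0L && ncol(p) != ncol(v))
    stop("prefix and period have different input dimensions", call. = FALSE)
  if (nrow(p) == 0L) p <- matrix(integer(), 0L, ncol(v))
  if (!is.null(n_inputs) && ncol(v) != n_inputs)
    stop("stream input dimension does not match the network", call. = FALSE)
  structure(list(prefix = p, period = v), class = "input_stream")
}

#' @export
print.input_stream <- function(x, ...) {
  fmt <- function(m) if (nrow(m) == 0) "e" else
    paste(apply(m, 1L, paste, collapse = ""), collapse = " ")
  cat("input stream  ", fmt(x$prefix), " . (", fmt(x$period), ")^omega\n", sep = "")
  invisible(x)
}

#' Simulate a network on an ultimately periodic input stream
#'
#' Runs the synchronous dynamics from an initial state (all-quiet by default)
#' until a (state, position-within-period) pair repeats.  Because there are at
#' most 2^N states and |period| positions, the loop is found within
#' 2^N * |period| steps after the prefix.  The set of states on the loop is
#' exactly the set of states visited infinitely often, i.e. the attractor
#' reached by this stream.
#'
#' @param net a [boolean_network()].
#' @param stream an [input_stream()].
#' @param initial initial state (code or bit vector); default all-quiet.
#' @return An object of class `evolution`: list with `transient` (state codes
#'   before the loop), `loop` (state codes of the detected loop, in order) and
#'   `inf_set` (sorted unique codes of the loop).
#' @examples
#' net <- basal_ganglia_network()
#' ev <- evolve(net, input_stream(character(), "1"))
#' ev$inf_set
#' @export
evolve <- function(net, stream, initial = 0L) {
  if (!inherits(stream, "input_stream")) stop("stream must be an input_stream", call. = FALSE)
  if (net$n_inputs > 0 && ncol(stream$period) != net$n_inputs)
    stop("stream input dimension does not match the network", call. = FALSE)
  code <- if (length(initial) > 1L) state_code(initial) else as.integer(initial)
  np <- nrow(stream$prefix); nv <- nrow(stream$period)
  trace <- integer(0)
  # prefix
  for (i in seq_len(np)) {
    trace <- c(trace, code)
    code <- state_code(net_step(net, code, stream$prefix[i, ]))
  }
  # periodic part: iterate until (code, phase) repeats
  seen <- new.env(parent = emptyenv())
  phase <- 0L
  pos <- integer(0)
  repeat {
    key <- paste0(code, ":", phase)
    hit <- mget(key, envir = seen, ifnotfound = list(NULL))[[1L]]
    if (!is.null(hit)) { loop_start <- hit; break }
    assign(key, length(trace) + 1L, envir = seen)
    trace <- c(trace, code)
    code <- state_code(net_step(net, code, stream$period[phase + 1L, ]))
    phase <- (phase + 1L) %% nv
  }
  loop <- trace[loop_start:length(trace)]
  transient <- if (loop_start > 1L) trace[seq_len(loop_start - 1L)] else integer(0)
  structure(list(transient = transient, loop = loop,
                 inf_set = sort(unique(loop))), class = "evolution")
}

#' @export
print.evolution <- function(x, ...) {
  cat("evolution: transient of", length(x$transient), "states, loop of",
      length(x$loop), "states\n")
  cat("  inf set: {", paste(x$inf_set, collapse = ", "), "}\n")
  invisible(x)
}

#' Membership of a stream in the neural language
#'
#' Simulates the network on the stream and returns the type of the attractor
#' reached: `TRUE` iff the attractor (the inf set of the evolution) is
#' classified meaningful by `assignment`.  This decides membership of the
#' stream in the neural language of the network.
#'
#' @param net a [boolean_network()].
#' @param assignment a [type_assignment()] covering the attractor reached;
#'   an attractor outside an explicit assignment's coverage is an error,
#'   never a silent default.
#' @param stream an [input_stream()].
#' @param initial initial state; default all-quiet.
#' @return logical: is the stream meaningful for the network?
#' @export
is_meaningful <- function(net, assignment, stream, initial = 0L) {
  ev <- evolve(net, stream, initial)
  cyc <- new_cycle(ev$inf_set, witness = c(ev$loop, ev$loop[1L]))
  classify_cycle(assignment, cyc) == "meaningful"
}

#' Complement a typed network
#'
#' Returns the same network with the type of every attractor flipped: the
#' neural language of the complement is the complement of the neural language
#' over streams.  Double complementation restores the original assignment.
#'
#' @param net a [boolean_network()].
#' @param assignment a [type_assignment()].
#' @return list with elements `network` (unchanged) and `assignment`
#'   (flipped).
#' @export
complement_network <- function(net, assignment) {
  list(network = net, assignment = complement_assignment(assignment))
}

#' Read a network from a weight table and a JSON config
#'
#' The weight table is TSV/CSV with a header row of target cell names and a
#' first column of source cell names; entries are rational literals
#' (`1`, `-1/2`, ...) and blank or zero cells are absent connections.  The
#' JSON config supplies the remaining parameters with keys `inputs` (map
#' input name -> map target -> rational weight), `background` (map cell ->
#' rational), `thresholds`, `comparison_mode`, `output_layer`.
#'
#' @param table_path path to the weight table.
#' @param config_path path to the JSON configuration (optional).
#' @return A [boolean_network()].
#' @export
read_network <- function(table_path, config_path = NULL) {
  sep <- if (grepl("\\.csv$", table_path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(table_path, header = TRUE, sep = sep,
                           row.names = 1L, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           strip.white = TRUE)
  if (nrow(tab) == 0L || ncol(tab) == 0L)
    stop("empty weight table: ", table_path, call. = FALSE)
  if (!setequal(rownames(tab), colnames(tab)))
    stop("weight table row and column name sets differ (rows: ",
         paste(setdiff(rownames(tab), colnames(tab)), collapse = ", "),
         "; columns: ", paste(setdiff(colnames(tab), rownames(tab)), collapse = ", "),
         ")", call. = FALSE)
  cells <- rownames(tab)
  W <- matrix("0", length(cells), length(cells), dimnames = list(cells, cells))
  for (i in seq_along(cells)) for (j in seq_along(cells)) {
    v <- tab[i, cells[j]]
    r <- tryCatch(parse_rational(v), error = function(e)
      stop("bad weight at row '", cells[i], "', column '", cells[j], "': ",
           conditionMessage(e), call. = FALSE))
    W[i, j] <- v
  }
  cfg <- if (!is.null(config_path)) jsonlite::fromJSON(config_path, simplifyVector = FALSE) else list()
  inputs <- cfg$inputs %||% list()
  Win <- matrix("0", length(inputs), length(cells),
                dimnames = list(names(inputs), cells))
  for (inm in names(inputs)) for (tg in names(inputs[[inm]])) {
    if (!tg %in% cells) stop("unknown input target cell: ", tg, call. = FALSE)
    Win[inm, tg] <- as.character(inputs[[inm]][[tg]])
  }
  getvec <- function(key, default) {
    v <- rep(default, length(cells))
    if (!is.null(cfg[[key]])) for (nm in names(cfg[[key]])) {
      if (!nm %in% cells) stop("unknown cell in config ", key, ": ", nm, call. = FALSE)
      v[match(nm, cells)] <- as.character(cfg[[key]][[nm]])
    }
    v
  }
  boolean_network(W, input_weights = if (length(inputs)) Win else NULL,
                  background = getvec("background", "0"),
                  thresholds = getvec("thresholds", "1"),
                  comparison = cfg$comparison_mode %||% "at_least",
                  output_layer = unlist(cfg$output_layer) %||% character())
}
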
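# Shared helpers: exhaustive word enumeration, independent brute-force
# oracles (written separately from the package's own algorithms), and a
# memoised case-study calibration.

# all ultimately periodic words u.v^omega with |u| <= max_u, |v| <= max_v
# over the alphabet {0,1}^m
all_up_words <- function(max_u, max_v, m = 1L) {
  letters <- 0:(2L^m - 1L)
  blocks <- function(lmax, min_len) {
    out <- list()
    for (l in min_len:lmax) {
      if (l == 0L) { out[[length(out) + 1L]] <- integer(0); next }
      g <- as.matrix(expand.grid(rep(list(letters), l)))
      for (i in seq_len(nrow(g))) out[[length(out) + 1L]] <- as.integer(g[i, ])
    }
    out
  }
  bitmat <- function(codes) {
    if (!length(codes)) return(matrix(integer(), 0L, m))
    do.call(rbind, lapply(codes, boolrnn::state_bits, n_cells = m))
  }
  words <- list()
  for (u in blocks(max_u, 0L)) for (v in blocks(max_v, 1L))
    words[[length(words) + 1L]] <- boolrnn::input_stream(bitmat(u), bitmat(v), n_inputs = m)
  words
}

# independent long-run acceptance oracle: simulate |prefix| + 2^|states| *
# |period| steps and inspect the visited tail
oracle_accepts <- function(a, word) {
  run_letter <- function(state, code) {
    v <- a$trans[match(state, a$states), code + 1L]
    if (length(v) == 0L) NA_integer_ else v
  }
  cur <- a$initial
  for (i in seq_len(nrow(word$prefix))) {
    cur <- run_letter(cur, boolrnn::state_code(word$prefix[i, , drop = TRUE]))
    if (is.na(cur)) return(FALSE)
  }
  nv <- nrow(word$period)
  horizon <- 2L^length(a$states) * nv * 2L
  visits <- integer(0)
  phase <- 0L
  for (t in seq_len(horizon)) {
    visits <- c(visits, cur)
    cur <- run_letter(cur, boolrnn::state_code(word$period[phase + 1L, , drop = TRUE]))
    if (is.na(cur)) return(FALSE)
    phase <- (phase + 1L) %% nv
  }
  tail_len <- 2L^length(a$states) * nv
  inf_states <- sort(unique(visits[(length(visits) - tail_len + 1L):length(visits)]))
  if (inherits(a, "buchi_automaton")) length(intersect(inf_states, a$finals)) > 0L
  else isTRUE(a$table(inf_states))
}

# independent cycle universe of a small automaton: every non-empty subset of
# states that is strongly connected (Floyd-Warshall inside the subset) with
# at least one internal edge
oracle_cycles <- function(a) {
  sts <- a$states
  n <- length(sts)
  stopifnot(n <= 12L)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (l in seq_len(ncol(a$trans))) {
    to <- a$trans[i, l]
    if (!is.na(to)) adj[i, match(to, sts)] <- TRUE
  }
  out <- list()
  for (mask in 1:(2^n - 1L)) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    sub <- adj[sel, sel, drop = FALSE]
    if (!any(sub)) next
    k <- length(sel)
    reach <- sub | diag(k) > 0
    for (h in seq_len(k)) reach <- reach | (reach[, h, drop = FALSE] %*% reach[h, , drop = FALSE] > 0)
    if (k > 1L && !all(reach)) next
    if (k == 1L && !sub[1L, 1L]) next
    out[[length(out) + 1L]] <- sts[sel]
  }
  out
}

# independent reachability between state sets (BFS on the raw transition
# matrix)
oracle_reachable <- function(a, from_set, to_set) {
  if (length(intersect(from_set, to_set))) return(TRUE)
  seen <- from_set
  frontier <- from_set
  while (length(frontier)) {
    nxt <- unique(na.omit(as.integer(a$trans[match(frontier, a$states), ])))
    nxt <- setdiff(nxt, seen)
    if (length(intersect(nxt, to_set))) return(TRUE)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  FALSE
}

# independent brute force: longest alternating sequence of distinct cycles
# under the chain relation (one-way accessibility) or the tree relation
# (strict inclusion or one-way accessibility), restricted to the part
# reachable from the initial state
oracle_longest_alternation <- function(a, successful, kind = c("chain", "tree"),
                                       first_successful) {
  kind <- match.arg(kind)
  init_reach <- {
    seen <- a$initial; frontier <- a$initial
    while (length(frontier)) {
      nxt <- setdiff(unique(na.omit(as.integer(a$trans[match(frontier, a$states), ]))), seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    seen
  }
  cycles <- Filter(function(s) all(s %in% init_reach), oracle_cycles(a))
  if (!length(cycles)) return(0L)
  succ <- vapply(cycles, successful, logical(1))
  nc <- length(cycles)
  link <- matrix(FALSE, nc, nc)
  for (i in seq_len(nc)) for (j in seq_len(nc)) {
    if (i == j) next
    acc_ij <- oracle_reachable(a, cycles[[i]], cycles[[j]])
    acc_ji <- oracle_reachable(a, cycles[[j]], cycles[[i]])
    one_way <- acc_ij && !acc_ji
    incl <- length(cycles[[i]]) < length(cycles[[j]]) && all(cycles[[i]] %in% cycles[[j]])
    link[i, j] <- if (kind == "chain") one_way else (one_way || incl)
  }
  best <- 0L
  rec <- function(cur, len) {
    best <<- max(best, len)
    for (j in which(link[cur, ] & succ != succ[cur])) rec(j, len + 1L)
  }
  for (i in which(succ == first_successful)) rec(i, 1L)
  best
}

# memoised case-study calibration shared across test files
.case_cache <- new.env(parent = emptyenv())
cached_calibration <- function() {
  if (is.null(.case_cache$cal)) .case_cache$cal <- boolrnn::bg_calibrate()
  .case_cache$cal
}
cached_degree <- function() {
  if (is.null(.case_cache$deg)) .case_cache$deg <- boolrnn::bg_degree(cached_calibration())
  .case_cache$deg
}
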
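# Exact rational scalars for network parameters.
#
# All dynamics are computed in integer arithmetic: every rational parameter of
# a network is multiplied by the least common denominator of all parameters,
# so that the threshold comparison of each cell is an exact integer
# comparison.  Rationals are represented internally as integer (num, den)
# pairs; user input may be character ("1/2", "-1", "0.5" is rejected) or
# numeric values that are exactly representable with a small power-of-two
# denominator (0.5, -1.25, ...).

.gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

.lcm2 <- function(a, b) {
  if (a == 0 || b == 0) return(max(a, b, 1))
  a %/% .gcd(a, b) * b
}

#' Parse rational literals
#'
#' Parses character rational literals of the form `"p"` or `"p/q"` (ASCII or
#' Unicode minus, surrounding blanks ignored; empty strings count as zero)
#' into exact numerator/denominator pairs.
#'
#' @param x character vector of rational literals.
#' @return A list with integer vectors `num` and `den` (always positive `den`,
#'   fractions in lowest terms).
#' @examples
#' parse_rational(c("1/3", "-1/2", "2", ""))
#' @export
parse_rational <- function(x) {
  x <- gsub("−", "-", trimws(as.character(x)))
  x[x == ""] <- "0"
  num <- integer(length(x)); den <- integer(length(x))
  for (i in seq_along(x)) {
    parts <- strsplit(x[i], "/", fixed = TRUE)[[1]]
    if (length(parts) < 1L || length(parts) > 2L || any(!grepl("^-?[0-9]+$", parts)))
      stop("not a rational literal: '", x[i], "'", call. = FALSE)
    p <- as.integer(parts[1L])
    q <- if (length(parts) == 2L) as.integer(parts[2L]) else 1L
    if (is.na(p) || is.na(q) || q == 0L)
      stop("not a rational literal: '", x[i], "'", call. = FALSE)
    if (q < 0L) { p <- -p; q <- -q }
    g <- max(.gcd(p, q), 1L)
    num[i] <- p %/% g; den[i] <- q %/% g
  }
  list(num = num, den = den)
}

# Convert numeric or character input to exact (num, den).  Numeric values must
# be exactly p / 2^k with k <= 16; anything else (1/3 given as 0.333...) must
# be supplied as a character literal.
.as_rational <- function(x) {
  if (is.character(x)) return(parse_rational(x))
  if (!is.numeric(x)) stop("weights must be numeric or character rationals", call. = FALSE)
  num <- integer(length(x)); den <- integer(length(x))
  for (i in seq_along(x)) {
    v <- x[i]
    if (is.na(v)) v <- 0
    k <- 0L
    while (v != trunc(v) && k < 16L) { v <- v * 2; k <- k + 1L }
    if (v != trunc(v) || abs(v) > .Machine$integer.max)
      stop("numeric value ", x[i], " is not an exact small rational; ",
           "supply it as a character literal such as \"1/3\"", call. = FALSE)
    g <- max(.gcd(as.integer(v), bitwShiftL(1L, k)), 1L)
    num[i] <- as.integer(v) %/% g
    den[i] <- bitwShiftL(1L, k) %/% g
  }
  list(num = num, den = den)
}

# Scale a list of rational objects to integers over one common denominator.
# Returns list(den = D, values = list of integer vectors/matrices).
.common_scale <- function(...) {
  rs <- list(...)
  D <- 1L
  for (r in rs) for (d in r$den) D <- .lcm2(D, d)
  vals <- lapply(rs, function(r) as.integer(r$num * (D %/% r$den)))
  list(den = as.integer(D), values = vals)
}
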
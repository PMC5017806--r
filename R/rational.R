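#' Exact rational numbers for stoichiometric coefficients
#'
#' Stoichiometric coefficients are carried as reduced integer fractions so
#' that quantities like the half mole of N2 produced per mole of nitrate in
#' the five-electron ferrous couple never accumulate binary rounding.
#' Conversion to double happens only at the ODE boundary.
#'
#' @param num integer numerator.
#' @param den integer denominator (non-zero; sign is normalised away).
#' @return An object of class `ndfo_rat`: a length-2 integer vector
#'   `c(num, den)` in lowest terms with a positive denominator.
#' @examples
#' rat(1, 2)
#' as.numeric(rat(5) + rat(1, 2))
#' @export
rat <- function(num, den = 1L) {
  stopifnot(length(num) == 1L, length(den) == 1L, is.finite(num), is.finite(den))
  if (den == 0) stop("rational with zero denominator")
  if (num != round(num) || den != round(den)) {
    stop("rat() takes integer numerator and denominator")
  }
  num <- as.integer(num)
  den <- as.integer(den)
  if (den < 0L) {
    num <- -num
    den <- -den
  }
  g <- .gcd(abs(num), den)
  if (g > 1L) {
    num <- num %/% g
    den <- den %/% g
  }
  structure(c(num = num, den = den), class = "ndfo_rat")
}

.gcd <- function(a, b) {
  while (b != 0L) {
    t <- b
    b <- a %% b
    a <- t
  }
  max(a, 1L)
}

#' Parse a rational coefficient written as `p` or `p/q`
#'
#' @param x a character scalar such as `"2"` or `"1/2"`.
#' @return an `ndfo_rat`.
#' @export
rat_parse <- function(x) {
  x <- trimws(x)
  if (grepl("^-?[0-9]+$", x)) return(rat(as.integer(x)))
  m <- regmatches(x, regexec("^(-?[0-9]+)\\s*/\\s*([0-9]+)$", x))[[1]]
  if (length(m) != 3L) stop("cannot parse rational coefficient: '", x, "'")
  rat(as.integer(m[2]), as.integer(m[3]))
}

#' @export
format.ndfo_rat <- function(x, ...) {
  if (x[["den"]] == 1L) as.character(x[["num"]]) else paste0(x[["num"]], "/", x[["den"]])
}

#' @export
print.ndfo_rat <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.double.ndfo_rat <- function(x, ...) x[["num"]] / x[["den"]]

#' @export
Ops.ndfo_rat <- function(e1, e2) {
  if (nargs() == 1L) {
    if (.Generic == "-") return(rat(-e1[["num"]], e1[["den"]]))
    if (.Generic == "+") return(e1)
    stop("unary ", .Generic, " not defined for ndfo_rat")
  }
  if (!inherits(e1, "ndfo_rat")) e1 <- rat(e1)
  if (!inherits(e2, "ndfo_rat")) e2 <- rat(e2)
  a <- e1[["num"]]; b <- e1[["den"]]
  c <- e2[["num"]]; d <- e2[["den"]]
  switch(.Generic,
    "+" = rat(a * d + c * b, b * d),
    "-" = rat(a * d - c * b, b * d),
    "*" = rat(a * c, b * d),
    "/" = {
      if (c == 0L) stop("division by zero rational")
      rat(a * d, b * c)
    },
    "==" = a * d == c * b,
    "!=" = a * d != c * b,
    "<"  = a * d < c * b,
    ">"  = a * d > c * b,
    "<=" = a * d <= c * b,
    ">=" = a * d >= c * b,
    stop(.Generic, " not defined for ndfo_rat")
  )
}

.rat_min <- function(a, b) if (a <= b) a else b

.rat_sum <- function(lst) {
  out <- rat(0L)
  for (x in lst) out <- out + x
  out
}

.as_rat <- function(x) {
  if (inherits(x, "ndfo_rat")) return(x)
  if (is.character(x)) return(rat_parse(x))
  if (is.numeric(x)) {
    if (x == round(x)) return(rat(x))
    # accept simple halves/quarters etc. written as doubles, up to den 64
    for (q in 2:64) {
      if (abs(x * q - round(x * q)) < 1e-9) return(rat(round(x * q), q))
    }
    stop("cannot coerce ", x, " to an exact rational; use rat() or 'p/q'")
  }
  stop("cannot coerce object of class ", class(x)[1], " to ndfo_rat")
}
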
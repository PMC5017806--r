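#' Construct a stoichiometric reaction
#'
#' Coefficients are exact rationals: integers, strings like `"1/2"`, or
#' [rat()] objects. Species names must come from the fixed table (see
#' [species_table()]) for balance checking, but unknown names are only
#' rejected at validation time so that deliberately broken fixtures can be
#' represented.
#'
#' @param id short label, e.g. `"eq1"`.
#' @param reactants,products named lists/vectors mapping species name to
#'   coefficient, e.g. `c("Fe2+" = 2, "NO3-" = 1, "H+" = 2)`.
#' @param source free-text citation or provenance string.
#' @return An object of class `ndfo_reaction`.
#' @examples
#' reaction("eq1",
#'   reactants = c("Fe2+" = 2, "NO3-" = 1, "H+" = 2),
#'   products  = c("Fe3+" = 2, "NO2-" = 1, "H2O" = 1))
#' @export
reaction <- function(id, reactants, products, source = "") {
  side <- function(x, what) {
    if (length(x) == 0L) stop("reaction '", id, "': empty ", what, " side")
    nms <- names(x)
    if (is.null(nms) || any(nms == "")) {
      stop("reaction '", id, "': ", what, " must be a named coefficient list")
    }
    if (anyDuplicated(nms)) {
      stop("reaction '", id, "': duplicate species on ", what, " side: ",
           paste(unique(nms[duplicated(nms)]), collapse = ", "))
    }
    coefs <- lapply(seq_along(x), function(i) .as_rat(x[[i]]))
    for (i in seq_along(coefs)) {
      if (coefs[[i]] <= rat(0L)) {
        stop("reaction '", id, "': non-positive coefficient for ", nms[i])
      }
    }
    data.frame(species = nms,
               num = vapply(coefs, function(r) r[["num"]], integer(1)),
               den = vapply(coefs, function(r) r[["den"]], integer(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(
    list(id = id,
         reactants = side(reactants, "reactant"),
         products = side(products, "product"),
         source = source),
    class = "ndfo_reaction"
  )
}

.side_rats <- function(side) {
  lapply(seq_len(nrow(side)), function(i) rat(side$num[i], side$den[i]))
}

.format_side <- function(side) {
  paste(vapply(seq_len(nrow(side)), function(i) {
    paste(format(rat(side$num[i], side$den[i])), side$species[i])
  }, ""), collapse = " + ")
}

#' @export
format.ndfo_reaction <- function(x, ...) {
  paste(.format_side(x$reactants), "->", .format_side(x$products))
}

#' @export
print.ndfo_reaction <- function(x, ...) {
  cat(sprintf("<%s> %s\n", x$id, format(x)))
  invisible(x)
}

#' Parse one reaction from its plain-text line form
#'
#' The serialization is one reaction per line,
#' `2 Fe2+ + 1 NO3- + 2 H+ -> 2 Fe3+ + 1 NO2- + 1 H2O # eq1`,
#' with rational coefficients written `p/q` and the reaction id after `#`.
#'
#' @param line character scalar.
#' @return an `ndfo_reaction`.
#' @export
parse_reaction <- function(line) {
  raw <- line
  id <- ""
  if (grepl("#", line, fixed = TRUE)) {
    parts <- strsplit(line, "#", fixed = TRUE)[[1]]
    line <- parts[1]
    id <- trimws(paste(parts[-1], collapse = "#"))
  }
  line <- trimws(line)
  halves <- strsplit(line, "->", fixed = TRUE)[[1]]
  if (length(halves) != 2L) stop("expected exactly one '->' in: ", raw)
  # species names themselves end in '+' (Fe2+, H+), so terms are separated
  # by ' + ' with mandatory spaces, never by bare '+'
  parse_side <- function(txt) {
    terms <- trimws(strsplit(txt, " + ", fixed = TRUE)[[1]])
    terms <- terms[nzchar(terms)]
    if (length(terms) == 0L) stop("empty reaction side in: ", raw)
    out <- list()
    for (tm in terms) {
      toks <- strsplit(tm, "[[:space:]]+")[[1]]
      if (length(toks) == 1L) {
        coef <- rat(1L); spc <- toks[1]
      } else {
        coef <- rat_parse(toks[1])
        spc <- paste(toks[-1], collapse = " ")
      }
      out[[spc]] <- coef
    }
    out
  }
  reaction(id = if (nzchar(id)) id else "r?",
           reactants = parse_side(halves[1]),
           products = parse_side(halves[2]),
           source = "parsed")
}

#' Read a plain-text reaction file
#'
#' Blank lines and lines starting with `#` are skipped; each remaining line
#' is parsed with [parse_reaction()].
#'
#' @param path file path.
#' @return list of `ndfo_reaction`.
#' @export
read_reactions <- function(path) {
  if (!file.exists(path)) stop("no such reactions file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, parse_reaction)
}

#' Write reactions to the plain-text line format
#'
#' @param reactions a list of `ndfo_reaction` or an `ndfo_network`.
#' @param path file path.
#' @export
write_reactions <- function(reactions, path) {
  if (inherits(reactions, "ndfo_network")) reactions <- reactions$reactions
  lines <- vapply(reactions, function(r) {
    paste(format(r), "#", r$id)
  }, "")
  writeLines(lines, path)
  invisible(path)
}
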
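#' Validate element, charge and electron conservation of a reaction
#'
#' Element balance compares exact rational atom counts per element on the two
#' sides; charge balance compares net charge; the electron ledger assigns the
#' fixed oxidation state of every atom (see [species_table()]; H +1, O -2,
#' elemental forms 0) and checks that electrons donated by oxidised atoms
#' equal electrons accepted by reduced atoms. Donors and acceptors are paired
#' per element by matching atoms in oxidation-state order, the minimal
#' transfer convention, which is what makes a disproportionation such as
#' `2 HNO2 -> NO2 + NO + H2O` count one electron rather than zero.
#'
#' @param x an [reaction()] object.
#' @return A list of class `ndfo_balance_verdict`: `element_ok` (named
#'   logical per element), `charge_ok`, `electron_ok`,
#'   `electrons_transferred` (an [rat()], `NA` when the ledger cannot close),
#'   and `messages` (character).
#' @examples
#' net <- build_ndfo_network()
#' validate_balance(net$reactions[[1]])
#' @export
validate_balance <- function(x) {
  if (!inherits(x, "ndfo_reaction")) stop("validate_balance() expects an ndfo_reaction")
  if (nrow(x$reactants) == 0L || nrow(x$products) == 0L) {
    stop("reaction '", x$id, "' has an empty side")
  }
  for (s in c(x$reactants$species, x$products$species)) .species_lookup(s)

  msgs <- character(0)

  # --- element balance ------------------------------------------------------
  side_counts <- function(side) {
    acc <- list()
    for (i in seq_len(nrow(side))) {
      coef <- rat(side$num[i], side$den[i])
      at <- .species_lookup(side$species[i])$atoms
      for (k in seq_len(nrow(at))) {
        e <- at$element[k]
        add <- coef * rat(at$count[k])
        acc[[e]] <- if (is.null(acc[[e]])) add else acc[[e]] + add
      }
    }
    acc
  }
  lhs <- side_counts(x$reactants)
  rhs <- side_counts(x$products)
  elements <- union(names(lhs), names(rhs))
  element_ok <- stats::setNames(logical(length(elements)), elements)
  for (e in elements) {
    l <- if (is.null(lhs[[e]])) rat(0L) else lhs[[e]]
    r <- if (is.null(rhs[[e]])) rat(0L) else rhs[[e]]
    element_ok[e] <- l == r
    if (!element_ok[e]) {
      msgs <- c(msgs, sprintf("element %s: %s reactant vs %s product",
                              e, format(l), format(r)))
    }
  }

  # --- charge balance -------------------------------------------------------
  side_charge <- function(side) {
    .rat_sum(lapply(seq_len(nrow(side)), function(i) {
      rat(side$num[i], side$den[i]) * rat(.species_lookup(side$species[i])$charge)
    }))
  }
  qL <- side_charge(x$reactants)
  qR <- side_charge(x$products)
  charge_ok <- qL == qR
  if (!charge_ok) {
    msgs <- c(msgs, sprintf("net charge: %s reactant vs %s product",
                            format(qL), format(qR)))
  }

  # --- electron ledger ------------------------------------------------------
  transfer <- .electron_ledger(x)
  electron_ok <- all(element_ok) && charge_ok && transfer$closed
  if (!transfer$closed) msgs <- c(msgs, transfer$message)

  structure(
    list(element_ok = element_ok,
         charge_ok = charge_ok,
         electron_ok = electron_ok,
         electrons_transferred = if (transfer$closed) transfer$donated else NA,
         messages = msgs),
    class = "ndfo_balance_verdict"
  )
}

# Pair oxidised against reduced atoms per element, matching in oxidation-
# state order (minimal-transfer convention), with exact rational amounts.
.electron_ledger <- function(x) {
  pools <- function(side) {
    out <- list()
    for (i in seq_len(nrow(side))) {
      coef <- rat(side$num[i], side$den[i])
      at <- .species_lookup(side$species[i])$atoms
      for (k in seq_len(nrow(at))) {
        e <- at$element[k]
        key <- paste0(e, "@", at$ox[k])
        amt <- coef * rat(at$count[k])
        if (is.null(out[[key]])) {
          out[[key]] <- list(element = e, ox = at$ox[k], amt = amt)
        } else {
          out[[key]]$amt <- out[[key]]$amt + amt
        }
      }
    }
    out
  }
  L <- pools(x$reactants)
  R <- pools(x$products)
  elements <- unique(c(vapply(L, `[[`, "", "element"), vapply(R, `[[`, "", "element")))
  donated <- rat(0L)
  accepted <- rat(0L)
  for (e in elements) {
    le <- Filter(function(p) p$element == e, L)
    re <- Filter(function(p) p$element == e, R)
    le <- le[order(vapply(le, `[[`, 0L, "ox"))]
    re <- re[order(vapply(re, `[[`, 0L, "ox"))]
    totL <- .rat_sum(lapply(le, `[[`, "amt"))
    totR <- .rat_sum(lapply(re, `[[`, "amt"))
    if (totL != totR) {
      return(list(closed = FALSE,
                  message = sprintf(
                    "electron ledger cannot close: element %s unbalanced (%s vs %s atoms)",
                    e, format(totL), format(totR))))
    }
    i <- 1L; j <- 1L
    remL <- if (length(le)) le[[1]]$amt else rat(0L)
    remR <- if (length(re)) re[[1]]$amt else rat(0L)
    while (i <= length(le) && j <= length(re)) {
      m <- .rat_min(remL, remR)
      d_ox <- le[[i]]$ox - re[[j]]$ox
      if (d_ox > 0L) accepted <- accepted + m * rat(d_ox)
      if (d_ox < 0L) donated <- donated + m * rat(-d_ox)
      remL <- remL - m
      remR <- remR - m
      if (remL == rat(0L)) { i <- i + 1L; if (i <= length(le)) remL <- le[[i]]$amt }
      if (remR == rat(0L)) { j <- j + 1L; if (j <= length(re)) remR <- re[[j]]$amt }
    }
  }
  if (donated != accepted) {
    return(list(closed = FALSE, donated = donated, accepted = accepted,
                message = sprintf("electrons donated (%s) != accepted (%s)",
                                  format(donated), format(accepted))))
  }
  list(closed = TRUE, donated = donated, accepted = accepted, message = "")
}

#' @export
print.ndfo_balance_verdict <- function(x, ...) {
  el <- paste(sprintf("%s:%s", names(x$element_ok),
                      ifelse(x$element_ok, "ok", "FAIL")), collapse = " ")
  cat("elements ", el, "\n", sep = "")
  cat("charge   ", if (x$charge_ok) "ok" else "FAIL", "\n", sep = "")
  cat("electrons", if (x$electron_ok) {
    paste0(" ok (", format(x$electrons_transferred), " e- per formula unit)")
  } else " FAIL", "\n", sep = "")
  if (length(x$messages)) cat(paste(" -", x$messages, collapse = "\n"), "\n")
  invisible(x)
}

#' Electrons transferred per formula unit of a balanced reaction
#'
#' For the two ferrous/nitrate couples this equals the Fe(II) coefficient
#' (each Fe2+ to Fe3+ donates one electron): two for the nitrate-to-nitrite
#' couple and five for the nitrate-to-dinitrogen couple.
#'
#' @param x an [reaction()] object; must be balanced.
#' @return an [rat()]: electrons donated (= accepted) per formula unit.
#' @examples
#' net <- build_ndfo_network()
#' as.numeric(electron_transfer(net$reactions[[1]]))  # 2
#' as.numeric(electron_transfer(net$reactions[[2]]))  # 5
#' @export
electron_transfer <- function(x) {
  v <- validate_balance(x)
  if (!all(v$element_ok) || !v$charge_ok) {
    stop("reaction '", x$id, "' is not balanced: ",
         paste(v$messages, collapse = "; "))
  }
  if (!v$electron_ok) {
    stop("reaction '", x$id, "': electron budget does not close: ",
         paste(v$messages, collapse = "; "))
  }
  v$electrons_transferred
}
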
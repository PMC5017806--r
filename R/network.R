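#' Build the eight-reaction NDFO network
#'
#' The network couples the biotic nitrate-dependent Fe(II) oxidation couples
#' (nitrate to nitrite, two electrons; nitrate to dinitrogen, five) with the
#' abiotic chemodenitrification chain (nitrous acid formation and
#' disproportionation, Fe(II) oxidation by NO2 and NO, HNO dimerisation to
#' N2O, and NO re-oxidation by O2).
#'
#' The NO channel as commonly printed, `Fe2+ + 2 NO + H+ -> Fe3+ + HNO`, is
#' element-unbalanced (two N and two O in, one of each out). By default it is
#' replaced by the one-to-one form `Fe2+ + NO + H+ -> Fe3+ + HNO`, which
#' conserves every element and transfers exactly one electron; the printed
#' form is available for validation exercises via `include_printed_eq6`.
#'
#' @param include_printed_eq6 if `TRUE`, keep the unbalanced printed form of
#'   the Fe(II) + NO reaction instead of the corrected one.
#' @return An `ndfo_network`: list with `species` (the fixed species table),
#'   `reactions` (list of [reaction()] objects) and `stoichiometric_matrix`
#'   (species x reactions, numeric, products positive; the exact rational
#'   entries are kept in the `num`/`den` attribute matrices).
#' @examples
#' net <- build_ndfo_network()
#' sapply(net$reactions, `[[`, "id")
#' @export
build_ndfo_network <- function(include_printed_eq6 = FALSE) {
  eq6 <- if (include_printed_eq6) {
    reaction("eq6",
             reactants = c("Fe2+" = 1, "NO" = 2, "H+" = 1),
             products  = c("Fe3+" = 1, "HNO" = 1),
             source = "printed form (element-unbalanced)")
  } else {
    reaction("eq6",
             reactants = c("Fe2+" = 1, "NO" = 1, "H+" = 1),
             products  = c("Fe3+" = 1, "HNO" = 1),
             source = "corrected 1:1 form")
  }
  rxns <- list(
    reaction("eq1",
             reactants = c("Fe2+" = 2, "NO3-" = 1, "H+" = 2),
             products  = c("Fe3+" = 2, "NO2-" = 1, "H2O" = 1),
             source = "biotic couple, nitrate to nitrite"),
    reaction("eq2",
             reactants = c("Fe2+" = 5, "NO3-" = 1, "H+" = 6),
             products  = list("Fe3+" = 5, "N2" = rat(1, 2), "H2O" = 3),
             source = "biotic couple, nitrate to dinitrogen"),
    reaction("eq3",
             reactants = c("NO2-" = 1, "H+" = 1),
             products  = c("HNO2" = 1),
             source = "abiotic, nitrous acid formation"),
    reaction("eq4",
             reactants = c("HNO2" = 2),
             products  = c("NO2" = 1, "NO" = 1, "H2O" = 1),
             source = "abiotic, nitrous acid disproportionation"),
    reaction("eq5",
             reactants = c("Fe2+" = 2, "NO2" = 1, "H+" = 2),
             products  = c("Fe3+" = 2, "NO" = 1, "H2O" = 1),
             source = "abiotic, Fe(II) oxidation by NO2"),
    eq6,
    reaction("eq7",
             reactants = c("HNO" = 2),
             products  = c("N2O" = 1, "H2O" = 1),
             source = "abiotic, HNO dimerisation"),
    reaction("eq8",
             reactants = c("NO" = 2, "O2" = 1),
             products  = c("NO2" = 2),
             source = "abiotic, NO oxidation under O2")
  )
  .make_network(rxns)
}

# Three additional balanced Fe(II)-coupled denitrification steps used by the
# simulator to carry nitrite onward to N2 (nitrite -> NO -> N2O -> N2), each
# written with the ferrous couple as the one-electron donor.
.denitrification_chain <- function() {
  list(
    reaction("nir_fe",
             reactants = c("Fe2+" = 1, "NO2-" = 1, "H+" = 2),
             products  = c("Fe3+" = 1, "NO" = 1, "H2O" = 1),
             source = "biotic, nitrite to NO"),
    reaction("nor_fe",
             reactants = c("Fe2+" = 2, "NO" = 2, "H+" = 2),
             products  = c("Fe3+" = 2, "N2O" = 1, "H2O" = 1),
             source = "biotic, NO to N2O"),
    reaction("nos_fe",
             reactants = c("Fe2+" = 2, "N2O" = 1, "H+" = 2),
             products  = c("Fe3+" = 2, "N2" = 1, "H2O" = 1),
             source = "biotic, N2O to N2")
  )
}

#' Build the simulator's extended network
#'
#' The eight-reaction network plus the three Fe(II)-coupled denitrification
#' steps (`nir_fe`, `nor_fe`, `nos_fe`) that carry nitrite onward through NO
#' and N2O to N2. All eleven reactions pass [validate_balance()].
#'
#' @return an `ndfo_network` of 11 reactions.
#' @export
build_sim_network <- function() {
  base <- build_ndfo_network(include_printed_eq6 = FALSE)
  .make_network(c(base$reactions, .denitrification_chain()))
}

.make_network <- function(rxns) {
  ids <- vapply(rxns, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate reaction ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  used <- unique(unlist(lapply(rxns, function(r) c(r$reactants$species, r$products$species))))
  unknown <- setdiff(used, names(.SPECIES))
  if (length(unknown)) stop("unknown species in network: ", paste(unknown, collapse = ", "))
  species <- names(.SPECIES)[names(.SPECIES) %in% used]
  nsp <- length(species)
  nrx <- length(rxns)
  Snum <- matrix(0L, nsp, nrx, dimnames = list(species, ids))
  Sden <- matrix(1L, nsp, nrx, dimnames = list(species, ids))
  for (j in seq_len(nrx)) {
    r <- rxns[[j]]
    acc <- stats::setNames(rep(list(rat(0L)), nsp), species)
    for (i in seq_len(nrow(r$products))) {
      s <- r$products$species[i]
      acc[[s]] <- acc[[s]] + rat(r$products$num[i], r$products$den[i])
    }
    for (i in seq_len(nrow(r$reactants))) {
      s <- r$reactants$species[i]
      acc[[s]] <- acc[[s]] - rat(r$reactants$num[i], r$reactants$den[i])
    }
    for (s in species) {
      Snum[s, j] <- acc[[s]][["num"]]
      Sden[s, j] <- acc[[s]][["den"]]
    }
  }
  S <- Snum / Sden
  structure(
    list(species = species,
         reactions = rxns,
         stoichiometric_matrix = S,
         stoich_num = Snum,
         stoich_den = Sden),
    class = "ndfo_network"
  )
}

#' @export
print.ndfo_network <- function(x, ...) {
  cat(sprintf("NDFO reaction network: %d species, %d reactions\n",
              length(x$species), length(x$reactions)))
  for (r in x$reactions) print(r)
  invisible(x)
}

#' Per-reaction validation table for a network
#'
#' Runs [validate_balance()] on every reaction and returns a one-row-per-
#' reaction verdict table.
#'
#' @param network an `ndfo_network` or list of reactions.
#' @return data frame with columns `id`, `elements_ok`, `charge_ok`,
#'   `electron_ok`, `electrons` (per formula unit where defined) and
#'   `messages`.
#' @export
validate_network <- function(network) {
  rxns <- if (inherits(network, "ndfo_network")) network$reactions else network
  do.call(rbind, lapply(rxns, function(r) {
    v <- validate_balance(r)
    data.frame(
      id = r$id,
      elements_ok = all(v$element_ok),
      charge_ok = v$charge_ok,
      electron_ok = v$electron_ok,
      electrons = if (isTRUE(v$electron_ok)) as.numeric(v$electrons_transferred) else NA_real_,
      messages = paste(v$messages, collapse = "; "),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }))
}
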
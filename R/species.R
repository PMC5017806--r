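# Fixed chemical species table for the NDFO redox network.
#
# The network is closed over 13 species, so oxidation states come from a
# lookup rather than a general assigner. Each species carries its full
# per-atom bookkeeping (H +1, O -2, elemental forms 0, Fe/N as tabulated);
# under this standard assignment the states of every species sum to its
# charge, which is what makes the electron ledger close on a reaction that is
# element- and charge-balanced. The Fe and N redox-centre annotations drive
# the per-formula-unit electron transfer count used in the analysis.

.species_def <- function(name, charge, atoms, redox_center = "none",
                         oxidation_state = NA_integer_) {
  stopifnot(is.data.frame(atoms), all(c("element", "count", "ox") %in% names(atoms)))
  list(name = name, charge = as.integer(charge), atoms = atoms,
       redox_center = redox_center, oxidation_state = oxidation_state)
}

.atoms <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(element = r[[1]], count = as.integer(r[[2]]), ox = as.integer(r[[3]]),
               stringsAsFactors = FALSE)
  }))
}

.SPECIES <- local({
  defs <- list(
    .species_def("Fe2+", +2L, .atoms(list("Fe", 1, +2)), "Fe", +2L),
    .species_def("Fe3+", +3L, .atoms(list("Fe", 1, +3)), "Fe", +3L),
    .species_def("NO3-", -1L, .atoms(list("N", 1, +5), list("O", 3, -2)), "N", +5L),
    .species_def("NO2-", -1L, .atoms(list("N", 1, +3), list("O", 2, -2)), "N", +3L),
    .species_def("HNO2", 0L, .atoms(list("H", 1, +1), list("N", 1, +3), list("O", 2, -2)), "N", +3L),
    .species_def("NO2",  0L, .atoms(list("N", 1, +4), list("O", 2, -2)), "N", +4L),
    .species_def("NO",   0L, .atoms(list("N", 1, +2), list("O", 1, -2)), "N", +2L),
    .species_def("HNO",  0L, .atoms(list("H", 1, +1), list("N", 1, +1), list("O", 1, -2)), "N", +1L),
    .species_def("N2O",  0L, .atoms(list("N", 2, +1), list("O", 1, -2)), "N", +1L),
    .species_def("N2",   0L, .atoms(list("N", 2, 0)), "N", 0L),
    .species_def("H+",  +1L, .atoms(list("H", 1, +1))),
    .species_def("H2O",  0L, .atoms(list("H", 2, +1), list("O", 1, -2))),
    .species_def("O2",   0L, .atoms(list("O", 2, 0)))
  )
  names(defs) <- vapply(defs, `[[`, "", "name")
  # sanity: per-atom states must sum to the species charge
  for (d in defs) {
    stopifnot(sum(d$atoms$count * d$atoms$ox) == d$charge)
  }
  defs
})

.species_lookup <- function(name) {
  sp <- .SPECIES[[name]]
  if (is.null(sp)) {
    stop("unknown species '", name, "'; known species: ",
         paste(names(.SPECIES), collapse = ", "))
  }
  sp
}

#' The fixed species table of the NDFO reaction network
#'
#' Thirteen species cover the coupled biotic/abiotic chemistry: the ferrous/
#' ferric couple, the nitrogen ladder from nitrate (+5) down to dinitrogen
#' (0), and the redox-spectator medium species H+, H2O and O2.
#'
#' @return A data frame with one row per species: `name`, `formula` (element
#'   counts), `charge`, `redox_center` (`"Fe"`, `"N"` or `"none"`) and
#'   `oxidation_state` of the redox centre (`NA` for spectators).
#' @examples
#' species_table()
#' @export
species_table <- function() {
  do.call(rbind, lapply(.SPECIES, function(d) {
    data.frame(
      name = d$name,
      formula = paste0(d$atoms$element,
                       ifelse(d$atoms$count > 1L, d$atoms$count, ""),
                       collapse = ""),
      charge = d$charge,
      redox_center = d$redox_center,
      oxidation_state = d$oxidation_state,
      stringsAsFactors = FALSE,
      row.names = NULL
    )
  }))
}
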
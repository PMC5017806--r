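# Independent brute-force oracles used across the suite. These recount atoms
# and charge from the species table directly (floating point, no shared code
# path with validate_balance's rational ledger).

oracle_counts <- function(rxn) {
  tab <- ndfo::species_table()
  count_side <- function(side) {
    atoms <- c(Fe = 0, N = 0, O = 0, H = 0)
    charge <- 0
    for (i in seq_len(nrow(side))) {
      coef <- side$num[i] / side$den[i]
      f <- tab$formula[tab$name == side$species[i]]
      charge <- charge + coef * tab$charge[tab$name == side$species[i]]
      for (el in names(atoms)) {
        m <- regmatches(f, regexec(paste0(el, "([0-9]*)"), f))[[1]]
        if (length(m) == 2 && nzchar(m[1])) {
          n <- if (nzchar(m[2])) as.numeric(m[2]) else 1
          atoms[el] <- atoms[el] + coef * n
        }
      }
    }
    list(atoms = atoms, charge = charge)
  }
  list(lhs = count_side(rxn$reactants), rhs = count_side(rxn$products))
}

oracle_balanced <- function(rxn) {
  oc <- oracle_counts(rxn)
  all(abs(oc$lhs$atoms - oc$rhs$atoms) < 1e-9) &&
    abs(oc$lhs$charge - oc$rhs$charge) < 1e-9
}

# a small valid noiseless assay table built by hand
make_exact_table <- function(no3 = c(5, 3.11), no2 = c(0, 0.76),
                             fe2 = c(10, 1.22), times = c(0, 7), reps = 3) {
  rows <- list()
  for (r in seq_len(reps)) {
    for (i in seq_along(times)) {
      rows[[length(rows) + 1]] <- data.frame(
        time_d = times[i], replicate = paste0("R", r),
        analyte = c("NO3", "NO2", "Fe2", "FeTot"),
        conc_mM = c(no3[i], no2[i], fe2[i], 10),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
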
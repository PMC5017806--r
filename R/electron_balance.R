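#' Partition consumed nitrate between nitrite accumulation and reduction to N2
#'
#' Nitrate that shows up as accumulated nitrite stopped at the two-electron
#' step; everything else is booked as fully reduced to dinitrogen (five
#' electrons per nitrate). Gaseous intermediates (NO, N2O) are not given
#' separate electron prices in the analysis: they are transient pools that
#' the incubation-scale budget folds into the N2 branch.
#'
#' @param deltas an [delta_set()] object. A negative nitrite delta (net
#'   nitrite consumption) is clamped to zero with a warning.
#' @return A list of class `ndfo_partition` with `to_nitrite`, `to_n2` (mM
#'   nitrate) and their propagated SDs `sd_to_nitrite`, `sd_to_n2`.
#' @examples
#' nitrate_fate_partition(delta_set(1.89, 0.76, 8.78))
#' @export
nitrate_fate_partition <- function(deltas) {
  stopifnot(inherits(deltas, "ndfo_deltas"))
  if (deltas$d_no2 > deltas$d_no3) {
    stop(sprintf(
      "more nitrite accumulated (%.4g mM) than nitrate consumed (%.4g mM)",
      deltas$d_no2, deltas$d_no3))
  }
  d_no2 <- deltas$d_no2
  if (d_no2 < 0) {
    warning("net nitrite consumption (d_no2 = ", signif(d_no2, 4),
            " mM); clamping the nitrite branch to 0")
    d_no2 <- 0
  }
  structure(
    list(to_nitrite = d_no2,
         to_n2 = deltas$d_no3 - d_no2,
         sd_to_nitrite = deltas$sd_no2,
         sd_to_n2 = sqrt(deltas$sd_no3^2 + deltas$sd_no2^2)),
    class = "ndfo_partition"
  )
}

#' @export
print.ndfo_partition <- function(x, ...) {
  cat(sprintf("nitrate to nitrite: %.2f +/- %.2f mM\n", x$to_nitrite, x$sd_to_nitrite))
  cat(sprintf("nitrate to N2:      %.2f +/- %.2f mM\n", x$to_n2, x$sd_to_n2))
  invisible(x)
}

#' Theoretical Fe(II) demand of a nitrate fate partition
#'
#' Two moles of Fe(II) are required per mole of nitrate reduced to nitrite
#' and five per mole reduced to dinitrogen, since each Fe2+ to Fe3+
#' transition donates exactly one electron.
#'
#' @param partition an [nitrate_fate_partition()] result.
#' @return list with `demand_nitrite`, `demand_n2`, `demand_total` (mM
#'   Fe(II)) and propagated SDs `sd_nitrite`, `sd_n2`, `sd_total`. The total
#'   SD uses the algebraic identity demand_total = 5 d_no3 - 3 d_no2, i.e.
#'   the two branch demands share the nitrite delta and are anticorrelated.
#' @examples
#' p <- nitrate_fate_partition(delta_set(1.89, 0.76, 8.78))
#' theoretical_fe_demand(p)
#' @export
theoretical_fe_demand <- function(partition) {
  stopifnot(inherits(partition, "ndfo_partition"))
  demand_nitrite <- 2 * partition$to_nitrite
  demand_n2 <- 5 * partition$to_n2
  sd_no2 <- partition$sd_to_nitrite
  sd_no3 <- sqrt(max(partition$sd_to_n2^2 - sd_no2^2, 0))
  list(
    demand_nitrite = demand_nitrite,
    demand_n2 = demand_n2,
    demand_total = demand_nitrite + demand_n2,
    sd_nitrite = 2 * sd_no2,
    sd_n2 = 5 * partition$sd_to_n2,
    # demand_total = 5*d_no3 - 3*d_no2 algebraically
    sd_total = sqrt((5 * sd_no3)^2 + (3 * sd_no2)^2)
  )
}

#' Excess Fe(II) oxidation beyond biotic denitrification stoichiometry
#'
#' @param observed_fe_ox mM Fe(II) oxidized (>= 0).
#' @param demand_total mM theoretical Fe(II) demand (>= 0).
#' @param sd_observed,sd_demand optional SDs; combined in quadrature.
#' @param z screening multiplier for the uncertainty-aware verdict
#'   (`excess - z * sd > 0`); default 2, a conventional one-sided ~95%
#'   screen.
#' @return list with `excess` (mM), `sd_excess`, `verdict` (plain sign test:
#'   `"excess_oxidation"` iff excess > 0) and `verdict_screened`
#'   (uncertainty-aware).
#' @examples
#' abiotic_excess(8.78, 7.17)
#' @export
abiotic_excess <- function(observed_fe_ox, demand_total,
                           sd_observed = 0, sd_demand = 0, z = 2) {
  if (observed_fe_ox < 0 || demand_total < 0) {
    stop("observed_fe_ox and demand_total must be >= 0")
  }
  excess <- observed_fe_ox - demand_total
  sd_excess <- sqrt(sd_observed^2 + sd_demand^2)
  list(
    excess = excess,
    sd_excess = sd_excess,
    verdict = if (excess > 0) "excess_oxidation" else "within_biotic_stoichiometry",
    verdict_screened = if (excess - z * sd_excess > 0) "excess_oxidation"
                       else "within_biotic_stoichiometry",
    z = z
  )
}

#' First-order uncertainty propagation for the electron balance
#'
#' Gaussian propagation assuming the three replicate deltas are independent.
#' Because the total demand is algebraically 5 d_no3 - 3 d_no2, its SD is
#' sqrt((5 sd_no3)^2 + (3 sd_no2)^2); the excess adds the Fe(II) SD in
#' quadrature.
#'
#' @param deltas an [delta_set()] object.
#' @return named list of propagated SDs: `sd_to_nitrite`, `sd_to_n2`,
#'   `sd_demand_nitrite`, `sd_demand_n2`, `sd_demand_total`, `sd_excess`.
#' @examples
#' propagate_uncertainty(delta_set(1.89, 0.76, 8.78, 0.08, 0.08, 0.37))
#' @export
propagate_uncertainty <- function(deltas) {
  stopifnot(inherits(deltas, "ndfo_deltas"))
  s3 <- deltas$sd_no3
  s2 <- deltas$sd_no2
  sf <- deltas$sd_fe2
  sd_demand_total <- sqrt((5 * s3)^2 + (3 * s2)^2)
  list(
    sd_to_nitrite = s2,
    sd_to_n2 = sqrt(s3^2 + s2^2),
    sd_demand_nitrite = 2 * s2,
    sd_demand_n2 = 5 * sqrt(s3^2 + s2^2),
    sd_demand_total = sd_demand_total,
    sd_excess = sqrt(sd_demand_total^2 + sf^2)
  )
}

#' The full electron-balance analysis
#'
#' Chains [nitrate_fate_partition()], [theoretical_fe_demand()],
#' [abiotic_excess()] and [propagate_uncertainty()] into the headline
#' report: how much of the observed Fe(II) oxidation is explained by biotic
#' denitrification stoichiometry and how much is left over.
#'
#' All arithmetic is carried at full precision; the print method reports at
#' two decimals with half-up rounding so that the canonical worked chain
#' 1.89 - 0.76 = 1.13, 2 x 0.76 = 1.52, 5 x 1.13 = 5.65, 1.52 + 5.65 = 7.17
#' reproduces digit for digit.
#'
#' @param deltas an [delta_set()] object.
#' @param z screening multiplier for the uncertainty-aware verdict.
#' @return An object of class `ndfo_balance_report`: the partition, the
#'   three demands, observed oxidation, excess, all propagated SDs, and both
#'   verdicts.
#' @examples
#' balance_report(delta_set(1.89, 0.76, 8.78, 0.08, 0.08, 0.37))
#' @export
balance_report <- function(deltas, z = 2) {
  stopifnot(inherits(deltas, "ndfo_deltas"))
  part <- nitrate_fate_partition(deltas)
  dem <- theoretical_fe_demand(part)
  sds <- propagate_uncertainty(deltas)
  exc <- abiotic_excess(deltas$d_fe2, dem$demand_total,
                        sd_observed = deltas$sd_fe2,
                        sd_demand = sds$sd_demand_total, z = z)
  structure(
    list(deltas = deltas,
         partition = part,
         demand_nitrite = dem$demand_nitrite,
         demand_n2 = dem$demand_n2,
         demand_total = dem$demand_total,
         observed_fe_ox = deltas$d_fe2,
         excess = exc$excess,
         sds = sds,
         verdict = exc$verdict,
         verdict_screened = exc$verdict_screened,
         z = z),
    class = "ndfo_balance_report"
  )
}

#' Half-up decimal rounding
#'
#' Rounds half away from zero (so 0.005 -> 0.01), unlike [round()]'s
#' round-half-even, to match conventional lab-report rounding.
#'
#' @param x numeric.
#' @param digits decimal places (default 2).
#' @return numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.ndfo_balance_report <- function(x, ...) {
  r2 <- function(v) sprintf("%.2f", round_half_up(v, 2))
  s <- x$sds
  cat("Electron balance of nitrate-dependent Fe(II) oxidation\n")
  cat(sprintf("  interval: [%g, %g] d, n = %d replicates\n",
              x$deltas$interval[1], x$deltas$interval[2], x$deltas$n_replicates))
  cat(sprintf("  nitrate consumed          %6s +/- %s mM\n",
              r2(x$deltas$d_no3), r2(x$deltas$sd_no3)))
  cat(sprintf("  nitrite accumulated       %6s +/- %s mM\n",
              r2(x$deltas$d_no2), r2(x$deltas$sd_no2)))
  cat(sprintf("  nitrate to nitrite        %6s +/- %s mM\n",
              r2(x$partition$to_nitrite), r2(s$sd_to_nitrite)))
  cat(sprintf("  nitrate to N2             %6s +/- %s mM\n",
              r2(x$partition$to_n2), r2(s$sd_to_n2)))
  cat(sprintf("  Fe(II) demand (nitrite)   %6s +/- %s mM\n",
              r2(x$demand_nitrite), r2(s$sd_demand_nitrite)))
  cat(sprintf("  Fe(II) demand (N2)        %6s +/- %s mM\n",
              r2(x$demand_n2), r2(s$sd_demand_n2)))
  cat(sprintf("  Fe(II) demand (total)     %6s +/- %s mM\n",
              r2(x$demand_total), r2(s$sd_demand_total)))
  cat(sprintf("  Fe(II) oxidized, observed %6s +/- %s mM\n",
              r2(x$observed_fe_ox), r2(x$deltas$sd_fe2)))
  cat(sprintf("  abiotic excess            %6s +/- %s mM\n",
              r2(x$excess), r2(s$sd_excess)))
  cat(sprintf("  verdict: %s (z = %g screen: %s)\n",
              x$verdict, x$z, x$verdict_screened))
  invisible(x)
}

#' Serialize a balance report to JSON
#'
#' @param report an [balance_report()] object.
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @param digits passed to [jsonlite::toJSON()]; default `NA` (full
#'   precision).
#' @return the JSON string, invisibly when written to a file.
#' @export
balance_report_json <- function(report, path = NULL, digits = NA) {
  stopifnot(inherits(report, "ndfo_balance_report"))
  obj <- list(
    interval_d = report$deltas$interval,
    n_replicates = report$deltas$n_replicates,
    d_no3 = report$deltas$d_no3, sd_no3 = report$deltas$sd_no3,
    d_no2 = report$deltas$d_no2, sd_no2 = report$deltas$sd_no2,
    d_fe2 = report$deltas$d_fe2, sd_fe2 = report$deltas$sd_fe2,
    to_nitrite = report$partition$to_nitrite,
    to_n2 = report$partition$to_n2,
    demand_nitrite = report$demand_nitrite,
    demand_n2 = report$demand_n2,
    demand_total = report$demand_total,
    observed_fe_ox = report$observed_fe_ox,
    abiotic_excess = report$excess,
    sds = report$sds,
    verdict = report$verdict,
    verdict_screened = report$verdict_screened,
    z = report$z
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = digits, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
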
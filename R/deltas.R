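#' Measured concentration changes over an incubation interval
#'
#' The analysis input: nitrate consumed, nitrite accumulated and Fe(II)
#' oxidized over an interval, with replicate standard deviations. Deltas are
#' stored as magnitudes of the conventional signed quantities: a reported
#' dNO3 = -1.89 mM (consumption) is stored as `d_no3 = 1.89`, a reported
#' dNO2 = +0.76 mM (production) as `d_no2 = 0.76`. `d_no2` may be negative
#' (net nitrite consumption late in an incubation); `d_no3` and `d_fe2` are
#' consumption/oxidation magnitudes and must be non-negative.
#'
#' @param d_no3 mM nitrate consumed (>= 0).
#' @param d_no2 mM nitrite accumulated (signed).
#' @param d_fe2 mM Fe(II) oxidized (>= 0).
#' @param sd_no3,sd_no2,sd_fe2 replicate standard deviations (mM, >= 0).
#' @param n_replicates number of replicate incubations behind the means.
#' @param interval length-2 numeric, `(t_start, t_end)` in days.
#' @return an object of class `ndfo_deltas`.
#' @examples
#' delta_set(1.89, 0.76, 8.78, 0.08, 0.08, 0.37)
#' @export
delta_set <- function(d_no3, d_no2, d_fe2,
                      sd_no3 = 0, sd_no2 = 0, sd_fe2 = 0,
                      n_replicates = 3L, interval = c(0, 7)) {
  stopifnot(length(interval) == 2L, interval[1] < interval[2])
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  d_no3 <- as.numeric(d_no3); d_no2 <- as.numeric(d_no2); d_fe2 <- as.numeric(d_fe2)
  sd_no3 <- as.numeric(sd_no3); sd_no2 <- as.numeric(sd_no2); sd_fe2 <- as.numeric(sd_fe2)
  if (any(c(sd_no3, sd_no2, sd_fe2) < 0)) stop("standard deviations must be >= 0")
  if (d_no3 < 0) stop("d_no3 is a consumption magnitude and must be >= 0")
  if (d_fe2 < 0) stop("d_fe2 is an oxidation magnitude and must be >= 0")
  structure(
    list(d_no3 = d_no3, d_no2 = d_no2, d_fe2 = d_fe2,
         sd_no3 = sd_no3, sd_no2 = sd_no2, sd_fe2 = sd_fe2,
         n_replicates = as.integer(n_replicates),
         interval = as.numeric(interval)),
    class = "ndfo_deltas"
  )
}

#' @export
print.ndfo_deltas <- function(x, ...) {
  cat(sprintf(
    "Concentration deltas over [%g, %g] d (n = %d):\n", x$interval[1],
    x$interval[2], x$n_replicates))
  cat(sprintf("  NO3- consumed    %6.2f +/- %.2f mM\n", x$d_no3, x$sd_no3))
  cat(sprintf("  NO2- accumulated %6.2f +/- %.2f mM\n", x$d_no2, x$sd_no2))
  cat(sprintf("  Fe2+ oxidized    %6.2f +/- %.2f mM\n", x$d_fe2, x$sd_fe2))
  invisible(x)
}

#' Compute concentration deltas from a tidy assay table
#'
#' For each analyte and replicate the delta is the value at the time point
#' nearest `t_end` minus the value nearest `t_start`, converted to the
#' [delta_set()] sign convention (consumption magnitudes for NO3 and Fe2,
#' signed accumulation for NO2). Means and standard deviations are taken
#' across replicates.
#'
#' @param table a tidy assay data frame (`time_d`, `replicate`, `analyte`,
#'   `conc_mM`) as validated by [validate_assay()].
#' @param t_start,t_end interval bounds in days; must lie within the sampled
#'   time range.
#' @return an `ndfo_deltas`.
#' @export
compute_deltas <- function(table, t_start = 0, t_end = 7) {
  table <- validate_assay(table)
  if (t_start >= t_end) stop("t_start must be < t_end")
  times <- sort(unique(table$time_d))
  if (length(times) < 2L) stop("need at least 2 distinct time points, got ", length(times))
  tol <- 1e-9
  if (t_start < times[1] - tol || t_end > times[length(times)] + tol) {
    stop(sprintf("requested interval [%g, %g] d outside sampled range [%g, %g] d",
                 t_start, t_end, times[1], times[length(times)]))
  }
  t0 <- times[which.min(abs(times - t_start))]
  t1 <- times[which.min(abs(times - t_end))]
  if (t0 == t1) stop("t_start and t_end resolve to the same sampled time ", t0)

  need <- c("NO3", "NO2", "Fe2")
  missing_an <- setdiff(need, unique(table$analyte))
  if (length(missing_an)) {
    stop("assay table lacks required analyte(s): ", paste(missing_an, collapse = ", "))
  }

  per_rep <- function(analyte) {
    sub <- table[table$analyte == analyte, , drop = FALSE]
    reps <- unique(sub$replicate)
    d <- vapply(reps, function(r) {
      v0 <- sub$conc_mM[sub$replicate == r & sub$time_d == t0]
      v1 <- sub$conc_mM[sub$replicate == r & sub$time_d == t1]
      if (length(v0) != 1L || length(v1) != 1L) {
        stop("analyte ", analyte, ", replicate ", r,
             ": missing observation at t = ", t0, " or t = ", t1)
      }
      v1 - v0
    }, 0)
    c(mean = mean(d), sd = if (length(d) > 1L) stats::sd(d) else 0,
      n = length(d))
  }
  no3 <- per_rep("NO3")
  no2 <- per_rep("NO2")
  fe2 <- per_rep("Fe2")
  n <- min(no3["n"], no2["n"], fe2["n"])
  delta_set(d_no3 = -no3["mean"], d_no2 = no2["mean"], d_fe2 = -fe2["mean"],
            sd_no3 = no3["sd"], sd_no2 = no2["sd"], sd_fe2 = fe2["sd"],
            n_replicates = n, interval = c(t0, t1))
}
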
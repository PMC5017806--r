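test_that("with all rate constants zero the trajectory is constant at the initial state", {
  p0 <- default_kinetics(eq1 = 0, eq2 = 0, nir_fe = 0, nor_fe = 0, nos_fe = 0)
  tr <- simulate_ndfo(params = p0, t_grid = seq(0, 10, by = 2))
  for (i in seq_along(tr$time)) {
    expect_equal(unname(tr$conc[i, ]), unname(tr$init), tolerance = 1e-10)
  }
})

test_that("with only the two-electron couple active, Fe and nitrate move 2:1", {
  p1 <- default_kinetics(eq2 = 0, nir_fe = 0, nor_fe = 0, nos_fe = 0)
  tr <- simulate_ndfo(params = p1, t_grid = seq(0, 6, by = 0.5))
  fe_consumed <- 10 - tr$conc[, "Fe2+"]
  no3_consumed <- 5 - tr$conc[, "NO3-"]
  moving <- no3_consumed > 1e-4
  expect_true(any(moving))
  expect_equal(fe_consumed[moving] / no3_consumed[moving],
               rep(2, sum(moving)), tolerance = 1e-6)
  # independent oracle: integrate the 2-variable subsystem directly
  k <- default_kinetics()$eq1
  two_var <- function(t, y, parms) {
    r <- k * y[1]^2 * y[2]
    list(c(-2 * r, -r))
  }
  ref <- deSolve::lsoda(c(fe = 10, no3 = 5), seq(0, 6, by = 0.5), two_var, NULL,
                        rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(tr$conc[, "Fe2+"]), unname(ref[, "fe"]), tolerance = 1e-6)
  expect_equal(unname(tr$conc[, "NO3-"]), unname(ref[, "no3"]), tolerance = 1e-6)
})

test_that("total nitrogen and iron are conserved along the default trajectory", {
  tr <- simulate_ndfo(t_grid = seq(0, 10, by = 0.25))
  mt <- mass_totals(tr)
  expect_lt(max(abs(mt$total_n_mM - 5)), 1e-6)
  expect_lt(max(abs(mt$total_fe_mM - 10)), 1e-6)
  expect_true(all(tr$conc >= 0))
})

test_that("the electron ledger balances when Fe is the sole donor and bounds it otherwise", {
  tr <- simulate_ndfo(t_grid = seq(0, 10, by = 1))
  et <- electron_totals(tr)
  expect_lt(max(abs(et$donated_by_fe_mM - et$accepted_by_n_mM)), 1e-6)
  # stored-carbon donor enabled: Fe donations become a lower bound
  pc <- default_kinetics(c_nar = 0.2, c_nir = 0.05)
  trc <- simulate_ndfo(params = pc, t_grid = seq(0, 10, by = 1))
  etc <- electron_totals(trc)
  expect_true(all(etc$donated_by_fe_mM <= etc$accepted_by_n_mM + 1e-8))
  expect_gt(max(etc$accepted_by_n_mM - etc$donated_by_fe_mM), 0.1)
})

test_that("the acidified-extraction chain oxidizes two Fe(II) per nitrite at completion", {
  tr <- simulate_ndfo(params = extraction_kinetics(),
                      init = default_init("NO2-" = 1, "NO3-" = 0),
                      t_grid = c(0, 1, 10, 50))
  final <- tr$conc[nrow(tr$conc), ]
  expect_equal(unname(10 - final[["Fe2+"]]), 2, tolerance = 1e-3)
  expect_equal(unname(final[["N2O"]]), 0.5, tolerance = 1e-3)
  expect_lt(final[["NO2-"]], 1e-6)
})

test_that("the measurement layer is exact at f = 0 without noise and shifts Fe2 by 2 f NO2", {
  p0 <- default_kinetics(eq1 = 0, eq2 = 0, nir_fe = 0, nor_fe = 0, nos_fe = 0)
  tr <- simulate_ndfo(params = p0, init = default_init("NO2-" = 0.76),
                      t_grid = c(0, 1))
  zero_sd <- c(Fe2 = 0, FeTot = 0, NO3 = 0, NO2 = 0)
  tab <- measure_assay(tr, f = 0, noise_sd = zero_sd, n_replicates = 2, seed = 3)
  fe2 <- tab$conc_mM[tab$analyte == "Fe2"]
  expect_equal(fe2, rep(10, 4))
  expect_equal(tab$conc_mM[tab$analyte == "NO2"], rep(0.76, 4))

  # full artifact: 0.76 mM residual nitrite costs 1.52 mM apparent Fe(II)
  tab1 <- measure_assay(tr, f = 1, noise_sd = zero_sd, n_replicates = 1, seed = 3)
  expect_equal(tab1$conc_mM[tab1$analyte == "Fe2"], rep(10 - 1.52, 2))
  expect_equal(tab1$conc_mM[tab1$analyte == "FeTot"], rep(10, 2))
  # nitrite is read from the non-acidified aliquot: unaffected
  expect_equal(tab1$conc_mM[tab1$analyte == "NO2"], rep(0.76, 2))
})

test_that("measurement is deterministic under a fixed seed and validates its schema", {
  tr <- simulate_ndfo(t_grid = seq(0, 10, by = 1))
  a <- measure_assay(tr, f = 0.25, n_replicates = 3, seed = 99)
  b <- measure_assay(tr, f = 0.25, n_replicates = 3, seed = 99)
  expect_identical(a, b)
  c2 <- measure_assay(tr, f = 0.25, n_replicates = 3, seed = 100)
  expect_false(identical(a, c2))
  expect_error(measure_assay(tr, n_replicates = 0), "n_replicates")
  expect_error(measure_assay(tr, f = 1.5), "f must lie")
  expect_silent(validate_assay(a))
})

test_that("the standard scenario feeds the downstream analysis end to end", {
  tab <- scenario_fig1(seed = 5, t_grid = seq(0, 10, by = 1))
  expect_s3_class(tab, "data.frame")
  expect_setequal(unique(tab$analyte), c("Fe2", "FeTot", "NO3", "NO2"))
  rep <- balance_report(compute_deltas(tab, 0, 7))
  expect_s3_class(rep, "ndfo_balance_report")
  expect_gt(rep$demand_total, 0)
})

test_that("the analysis recovers the injected extraction artifact from noisy data", {
  traj <- simulate_ndfo(t_grid = seq(0, 10, by = 0.5))
  zero_sd <- c(Fe2 = 0, FeTot = 0, NO3 = 0, NO2 = 0)
  noiseless <- measure_assay(traj, f = 0.25, noise_sd = zero_sd,
                             n_replicates = 1, seed = 1)
  injected <- balance_report(compute_deltas(noiseless, 0, 7))$excess
  expect_gt(injected, 0)
  # known-measurement-model SD of the mean excess over 3 replicates
  sd_known <- sqrt(2 * (0.37^2 + 25 * 0.08^2 + 9 * 0.08^2) / 3)
  exc <- vapply(1:20, function(s) {
    tab <- measure_assay(traj, f = 0.25, n_replicates = 3, seed = s)
    balance_report(compute_deltas(tab, 0, 7))$excess
  }, 0)
  expect_true(all(abs(exc - injected) <= 3 * sd_known))
})
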
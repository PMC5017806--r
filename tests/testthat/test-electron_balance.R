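test_that("deltas computed from an exact replicate fixture match per-replicate subtraction", {
  tab <- make_exact_table(no3 = c(5, 3.11), no2 = c(0, 0.76), fe2 = c(10, 1.22))
  d <- compute_deltas(tab, 0, 7)
  expect_equal(d$d_no3, 1.89)
  expect_equal(d$d_no2, 0.76)
  expect_equal(d$d_fe2, 8.78)
  expect_equal(c(d$sd_no3, d$sd_no2, d$sd_fe2), c(0, 0, 0))
  expect_identical(d$n_replicates, 3L)
  expect_equal(d$interval, c(0, 7))
})

test_that("compute_deltas handles degenerate and invalid inputs", {
  tab <- make_exact_table(no3 = c(4, 4), no2 = c(0.5, 0.5), fe2 = c(6, 6))
  d <- compute_deltas(tab, 0, 7)
  expect_equal(c(d$d_no3, d$d_no2, d$d_fe2), c(0, 0, 0))

  no_fe <- tab[tab$analyte != "Fe2", ]
  expect_error(compute_deltas(no_fe, 0, 7), "Fe2")

  single <- tab[tab$time_d == 0, ]
  expect_error(compute_deltas(single, 0, 7), "2 distinct time points")

  expect_error(compute_deltas(tab, 0, 12), "outside sampled range \\[0, 7\\]")
})

test_that("nitrate fate partition follows the printed chain and its edge cases", {
  p <- nitrate_fate_partition(delta_set(1.89, 0.76, 8.78))
  expect_equal(p$to_nitrite, 0.76)
  expect_equal(round_half_up(p$to_n2), 1.13)
  expect_equal(p$to_nitrite + p$to_n2, 1.89)

  p2 <- nitrate_fate_partition(delta_set(1, 1, 0))
  expect_equal(c(p2$to_nitrite, p2$to_n2), c(1, 0))

  expect_error(nitrate_fate_partition(delta_set(1, 1.2, 0)), "more nitrite")
  expect_warning(p3 <- nitrate_fate_partition(delta_set(1, -0.2, 0)), "clamping")
  expect_equal(c(p3$to_nitrite, p3$to_n2), c(0, 1))
})

test_that("theoretical Fe(II) demand applies the 2- and 5-electron coefficients", {
  dem <- theoretical_fe_demand(nitrate_fate_partition(delta_set(1.89, 0.76, 8.78)))
  expect_equal(round_half_up(dem$demand_nitrite), 1.52)
  expect_equal(round_half_up(dem$demand_n2), 5.65)
  expect_equal(round_half_up(dem$demand_total), 7.17)

  dem0 <- theoretical_fe_demand(nitrate_fate_partition(delta_set(0, 0, 0)))
  expect_equal(c(dem0$demand_nitrite, dem0$demand_n2, dem0$demand_total), c(0, 0, 0))

  dem1 <- theoretical_fe_demand(nitrate_fate_partition(delta_set(1, 1, 0)))
  expect_equal(c(dem1$demand_nitrite, dem1$demand_n2, dem1$demand_total), c(2, 0, 2))
})

test_that("abiotic excess subtracts demand from observation and classifies the sign", {
  e <- abiotic_excess(8.78, 7.17)
  expect_equal(round_half_up(e$excess), 1.61)
  expect_identical(e$verdict, "excess_oxidation")

  e0 <- abiotic_excess(7.17, 7.17)
  expect_equal(e0$excess, 0)
  expect_identical(e0$verdict, "within_biotic_stoichiometry")

  en <- abiotic_excess(5, 7.17)
  expect_equal(round_half_up(en$excess), -2.17)
  expect_identical(en$verdict, "within_biotic_stoichiometry")

  # uncertainty-aware screen: a small excess with a large SD is not called
  es <- abiotic_excess(7.5, 7.17, sd_observed = 0.37, sd_demand = 0.47, z = 2)
  expect_identical(es$verdict, "excess_oxidation")
  expect_identical(es$verdict_screened, "within_biotic_stoichiometry")
})

test_that("propagated SDs follow the closed forms and vanish with the inputs", {
  s <- propagate_uncertainty(delta_set(1.89, 0.76, 8.78, 0.08, 0.08, 0.37))
  expect_equal(s$sd_to_n2, sqrt(0.08^2 + 0.08^2), tolerance = 1e-12)
  expect_equal(s$sd_demand_total, 0.08 * sqrt(34), tolerance = 1e-12)
  expect_equal(s$sd_excess, sqrt(0.08^2 * 34 + 0.37^2), tolerance = 1e-12)
  z <- propagate_uncertainty(delta_set(1.89, 0.76, 8.78))
  expect_true(all(unlist(z) == 0))
})

test_that("propagated SDs agree with a Monte-Carlo oracle within 2%", {
  set.seed(2024)
  n <- 1e5
  d3 <- rnorm(n, 1.89, 0.08)
  d2 <- rnorm(n, 0.76, 0.08)
  df <- rnorm(n, 8.78, 0.37)
  to_n2 <- d3 - d2
  demand <- 5 * d3 - 3 * d2
  excess <- df - demand
  s <- propagate_uncertainty(delta_set(1.89, 0.76, 8.78, 0.08, 0.08, 0.37))
  expect_equal(s$sd_to_n2, sd(to_n2), tolerance = 0.02)
  expect_equal(s$sd_demand_total, sd(demand), tolerance = 0.02)
  expect_equal(s$sd_excess, sd(excess), tolerance = 0.02)
})

test_that("partition/demand identities hold over random valid delta sets", {
  set.seed(11)
  for (i in 1:200) {
    d3 <- runif(1, 0, 5)
    d2 <- runif(1, 0, d3)
    d <- delta_set(d3, d2, runif(1, 0, 10))
    p <- nitrate_fate_partition(d)
    expect_equal(p$to_nitrite + p$to_n2, d3, tolerance = 1e-12)
    dem <- theoretical_fe_demand(p)
    expect_equal(dem$demand_total, 5 * d3 - 3 * d2, tolerance = 1e-9)
  }
  # monotonicity of total demand
  demand_of <- function(d3, d2) {
    theoretical_fe_demand(nitrate_fate_partition(delta_set(d3, d2, 0)))$demand_total
  }
  set.seed(12)
  for (i in 1:50) {
    d3 <- runif(1, 1, 4); d2 <- runif(1, 0, d3 - 0.5); eps <- runif(1, 0.01, 0.4)
    expect_gt(demand_of(d3 + eps, d2), demand_of(d3, d2))
    expect_lt(demand_of(d3, d2 + eps), demand_of(d3, d2))
  }
})

test_that("the balance report reproduces the worked chain digit for digit", {
  rep <- balance_report(delta_set(1.89, 0.76, 8.78, 0.08, 0.08, 0.37))
  expect_equal(round_half_up(rep$partition$to_n2), 1.13)
  expect_equal(round_half_up(rep$demand_nitrite), 1.52)
  expect_equal(round_half_up(rep$demand_n2), 5.65)
  expect_equal(round_half_up(rep$demand_total), 7.17)
  expect_equal(round_half_up(rep$excess), 1.61)
  expect_identical(rep$verdict, "excess_oxidation")
  expect_identical(rep$verdict_screened, "excess_oxidation")
  js <- jsonlite::fromJSON(balance_report_json(rep))
  expect_equal(js$demand_total, rep$demand_total)
  expect_identical(js$verdict, "excess_oxidation")
})

test_that("half-up rounding rounds ties away from zero at two decimals", {
  expect_equal(round_half_up(c(1.125, 1.135, -1.125)), c(1.13, 1.14, -1.13))
  expect_equal(round_half_up(1.89 - 0.76), 1.13)
})
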
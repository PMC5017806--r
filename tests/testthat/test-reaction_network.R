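test_that("all reactions of the corrected network balance atoms, charge and electrons", {
  net <- build_ndfo_network()
  expect_length(net$reactions, 8L)
  for (r in net$reactions) {
    v <- validate_balance(r)
    expect_true(all(v$element_ok), label = paste(r$id, "elements"))
    expect_true(v$charge_ok, label = paste(r$id, "charge"))
    expect_true(v$electron_ok, label = paste(r$id, "electrons"))
    expect_true(oracle_balanced(r), label = paste(r$id, "oracle"))
  }
})

test_that("the printed NO channel is flagged as element-unbalanced, and only it", {
  net <- build_ndfo_network(include_printed_eq6 = TRUE)
  verdicts <- validate_network(net)
  bad <- verdicts$id[!(verdicts$elements_ok & verdicts$charge_ok & verdicts$electron_ok)]
  expect_identical(bad, "eq6")
  v <- validate_balance(net$reactions[[6]])
  expect_false(v$element_ok[["N"]])
  expect_false(v$element_ok[["O"]])
  expect_true(v$element_ok[["Fe"]])
  expect_true(v$element_ok[["H"]])
  expect_true(v$charge_ok)
  expect_false(oracle_balanced(net$reactions[[6]]))
})

test_that("the dinitrogen couple carries an exact half-mole N2 coefficient", {
  net <- build_ndfo_network()
  eq2 <- net$reactions[[2]]
  i <- which(eq2$products$species == "N2")
  expect_identical(c(eq2$products$num[i], eq2$products$den[i]), c(1L, 2L))
  # stoichiometric matrix column = products minus reactants, exactly rational
  expect_identical(net$stoich_num["N2", "eq2"], 1L)
  expect_identical(net$stoich_den["N2", "eq2"], 2L)
  expect_equal(net$stoichiometric_matrix["Fe2+", "eq2"], -5)
  expect_equal(net$stoichiometric_matrix["H2O", "eq2"], 3)
})

test_that("electron transfer counts match the ferrous coefficients and the disproportionation", {
  net <- build_ndfo_network()
  rx <- stats::setNames(net$reactions, vapply(net$reactions, `[[`, "", "id"))
  expect_equal(as.numeric(electron_transfer(rx$eq1)), 2)
  expect_equal(as.numeric(electron_transfer(rx$eq2)), 5)
  expect_equal(as.numeric(electron_transfer(rx$eq4)), 1)
  # for the two ferrous/nitrate couples the count equals the Fe2+ coefficient
  for (id in c("eq1", "eq2")) {
    fe <- rx[[id]]$reactants
    fe_coef <- fe$num[fe$species == "Fe2+"] / fe$den[fe$species == "Fe2+"]
    expect_equal(as.numeric(electron_transfer(rx[[id]])), fe_coef)
  }
})

test_that("degenerate and erroneous reactions are handled", {
  ident <- reaction("id", reactants = c("Fe2+" = 1, "H2O" = 2),
                    products = c("Fe2+" = 1, "H2O" = 2))
  v <- validate_balance(ident)
  expect_true(all(v$element_ok) && v$charge_ok && v$electron_ok)
  expect_equal(as.numeric(electron_transfer(ident)), 0)

  bad <- reaction("bad", reactants = c("FeX" = 1), products = c("H2O" = 1))
  expect_error(validate_balance(bad), "FeX")
  expect_error(reaction("e", reactants = list(), products = c("H2O" = 1)), "empty")
  expect_error(reaction("d", reactants = c("H+" = 1, "H+" = 1), products = c("H+" = 2)),
               "duplicate")
  unbal <- reaction("u", reactants = c("Fe2+" = 1), products = c("Fe3+" = 1))
  expect_error(electron_transfer(unbal), "not balanced")
})

test_that("bumping any single coefficient of a balanced reaction breaks a check", {
  net <- build_ndfo_network()
  set.seed(7)
  cases <- 0L
  for (r in net$reactions) {
    sides <- c("reactants", "products")
    for (s in sides) {
      for (i in seq_len(nrow(r[[s]]))) {
        pert <- r
        pert[[s]]$num[i] <- pert[[s]]$num[i] + pert[[s]]$den[i]  # +1
        v <- validate_balance(pert)
        ok <- all(v$element_ok) && v$charge_ok && v$electron_ok
        expect_false(ok, label = paste(r$id, s, r[[s]]$species[i], "+1"))
        expect_equal(ok, oracle_balanced(pert),
                     label = paste("oracle agreement", r$id, s, i))
        cases <- cases + 1L
      }
    }
  }
  expect_gte(cases, 10L)
})

test_that("reaction serialization round-trips through the line format", {
  net <- build_ndfo_network()
  path <- withr::local_tempfile(fileext = ".txt")
  write_reactions(net, path)
  back <- read_reactions(path)
  expect_length(back, 8L)
  for (i in seq_along(back)) {
    expect_identical(back[[i]]$id, net$reactions[[i]]$id)
    expect_identical(back[[i]]$reactants[c("species", "num", "den")],
                     net$reactions[[i]]$reactants[c("species", "num", "den")])
    expect_identical(back[[i]]$products[c("species", "num", "den")],
                     net$reactions[[i]]$products[c("species", "num", "den")])
  }
  r <- parse_reaction("5 Fe2+ + 1 NO3- + 6 H+ -> 5 Fe3+ + 1/2 N2 + 3 H2O # eq2")
  expect_identical(r$id, "eq2")
  expect_equal(as.numeric(electron_transfer(r)), 5)
})

test_that("the shipped reaction fixtures validate as documented", {
  good <- read_reactions(system.file("extdata", "ndfo_reactions.txt", package = "ndfo"))
  expect_length(good, 8L)
  expect_true(all(validate_network(good)$electron_ok))
  printed <- read_reactions(system.file("extdata", "eq6_printed.txt", package = "ndfo"))
  v <- validate_balance(printed[[1]])
  expect_false(all(v$element_ok))
})

test_that("rational arithmetic is exact and well-formed", {
  expect_identical(unclass(rat(2, 4)), c(num = 1L, den = 2L))
  expect_identical(format(rat(1, 2) + rat(1, 3)), "5/6")
  expect_identical(format(rat(3, 2) * rat(2, 3)), "1")
  expect_true(rat(1, 3) < rat(1, 2))
  expect_error(rat(1, 0))
  expect_identical(format(rat_parse("7/3")), "7/3")
  expect_error(rat_parse("a/b"), "cannot parse")
})
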
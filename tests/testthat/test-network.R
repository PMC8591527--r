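test_that("the toy network has the expected pathway structure", {
  fx <- toy_fixture()
  net <- fx$net
  expect_s3_class(net, "rba_network")
  expect_gte(nrow(net$reactions), 12)
  expect_lte(nrow(net$reactions), 30)
  # three substrate uptake routes, CBB, FDH, biomass, maintenance present
  expect_true(all(c("UPT_FRU", "UPT_FOR", "UPT_SUC", "ED", "CBB", "FDH",
                    "OXPHOS", "BIOMASS", "MAINT") %in% net$reactions$id))
  # every non-pseudo reaction carries at least one enzyme
  pseudo <- c("BIOMASS", "MAINT", "EX_CO2", "EX_O2")
  expect_setequal(setdiff(net$reactions$id, pseudo), names(net$gpr))
})

test_that("every toy reaction is carbon- and electron-balanced", {
  audit <- reduction_audit(toy_fixture()$net)
  expect_true(all(audit$balanced))
})

test_that("substrate and biomass degrees of reduction are nearly equal", {
  m <- toy_fixture()$net$metabolites
  gamma_fru <- m$electrons[m$id == "fru_e"] / m$carbon[m$id == "fru_e"]
  gamma_bm <- m$electrons[m$id == "biomass_e"] / m$carbon[m$id == "biomass_e"]
  expect_equal(gamma_fru, 4.0)
  expect_equal(gamma_bm, 4.12)
})

test_that("network generation is deterministic and configurable", {
  cfg <- toy_network_config(seed = 7)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_network_json(gen_toy_network(cfg), f1)
  write_network_json(gen_toy_network(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))

  no_cbb <- gen_toy_network(toy_network_config(include_cbb = FALSE))
  expect_false("CBB" %in% no_cbb$reactions$id)

  expect_error(toy_network_config(n_substrates = 0), "at least one")
})

test_that("without CBB, growth on formate is infeasible", {
  fx <- toy_fixture()
  no_cbb <- gen_toy_network(toy_network_config(include_cbb = FALSE))
  cond <- growth_condition("formate", c(UPT_FOR = 30), dilution = 0.1)
  p <- build_rba_problem(no_cbb, fx$mach, fx$bud,
                         as_kapp_table(attr(no_cbb, "kapp_true")),
                         mu = 0.05, condition = cond)
  expect_identical(solve_feasible(p, "none")$status, "infeasible")
})

test_that("enzyme_table derives lengths and compartments from subunits", {
  enz <- enzyme_table(toy_fixture()$net)
  # CBB complex: 8x480 + 8x120 + 4x290 amino acids
  expect_equal(enz$length_aa[enz$reaction == "CBB"], 8 * 480 + 8 * 120 + 4 * 290)
  # transporters are membrane complexes
  expect_identical(enz$compartment[enz$reaction == "UPT_FRU"], "membrane")
  # isoenzymes are separate alternatives
  expect_identical(nrow(enz[enz$reaction == "OXPHOS", ]), 2L)
})

test_that("budget models evaluate inside [0,1] and error outside range", {
  bud <- toy_fixture()$bud
  ev <- evaluate_budgets(bud, 0.25)
  expect_true(all(ev$fraction >= 0 & ev$fraction <= 1))
  expect_true(all(ev$available > 0))
  expect_error(evaluate_budgets(bud, 5), "leaves \\[0,1\\]")
})

test_that("network validation catches inconsistent inputs", {
  net <- toy_fixture()$net
  bad <- net; bad$reactions$lb[1] <- 10; bad$reactions$ub[1] <- 0
  expect_error(validate_network(bad), "bounds inverted")
  bad2 <- net; bad2$gpr$NOPE <- list(c(g = 1))
  expect_error(validate_network(bad2), "unknown reactions")
})
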
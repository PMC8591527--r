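test_that("hand-solvable instance behaves exactly as derived on paper", {
  t1 <- t1_instance()
  # max flux = k_app * (pool / length) = 100 * (1/1000) = 0.1 => mu_max = 0.1
  p_low <- build_rba_problem(t1$net, t1$mach, t1$bud, t1$kapp, 0.05, t1$cond)
  expect_identical(solve_feasible(p_low, "none")$status, "feasible")
  p_high <- build_rba_problem(t1$net, t1$mach, t1$bud, t1$kapp, 0.2, t1$cond)
  expect_identical(solve_feasible(p_high, "none")$status, "infeasible")

  sol <- solve_feasible(
    build_rba_problem(t1$net, t1$mach, t1$bud, t1$kapp, 0.1, t1$cond),
    "min_total_enzyme")
  expect_identical(sol$status, "feasible")
  expect_equal(sol$enzymes$conc, 0.001, tolerance = 1e-9)

  opt <- maximize_growth(t1$net, t1$mach, t1$bud, t1$kapp, t1$cond)
  expect_lt(abs(opt$mu - 0.1), 2e-4)
})

test_that("doubling the protein budget doubles the optimal growth rate", {
  t1 <- t1_instance()
  bud2 <- t1$bud; bud2$pool <- 2
  mu1 <- maximize_growth(t1$net, t1$mach, t1$bud, t1$kapp, t1$cond)$mu
  mu2 <- maximize_growth(t1$net, t1$mach, bud2, t1$kapp, t1$cond)$mu
  expect_equal(mu2, 2 * mu1, tolerance = 5e-3)
})

test_that("mu = 0 with zero maintenance is trivially feasible", {
  t1 <- t1_instance()
  p <- build_rba_problem(t1$net, t1$mach, t1$bud, t1$kapp, 0, t1$cond)
  sol <- solve_feasible(p, "min_total_enzyme")
  expect_identical(sol$status, "feasible")
  expect_equal(sum(abs(sol$flux)), 0)
  expect_equal(sum(sol$enzymes$conc), 0)
})

test_that("problem construction validates its inputs", {
  t1 <- t1_instance()
  # missing k_app for a GPR reaction names the reaction
  expect_error(
    build_rba_problem(t1$net, t1$mach, t1$bud,
                      kapp_table("OTHER", kapp_hr = 1), 0.1, t1$cond),
    "UPT")
  # spontaneous/exchange reactions get no capacity constraint
  p <- build_rba_problem(t1$net, t1$mach, t1$bud, t1$kapp, 0.1, t1$cond)
  expect_true("cap:UPT:fwd" %in% rownames(p$A))
  expect_false(any(grepl("cap:BIOMASS", rownames(p$A))))
})

test_that("duplicate isoenzyme alternatives leave capacity and optimum unchanged", {
  t1 <- t1_instance()
  net2 <- t1$net
  net2$gpr$UPT <- list(c(g1 = 1), c(g1 = 1))  # duplicated alternative
  mu1 <- maximize_growth(t1$net, t1$mach, t1$bud, t1$kapp, t1$cond)$mu
  sol2 <- maximize_growth(net2, t1$mach, t1$bud, t1$kapp, t1$cond)
  expect_lt(abs(sol2$mu - mu1), 2e-4)
  expect_equal(sum(sol2$enzymes$conc), 0.001, tolerance = 1e-3)
})

test_that("feasibility is monotone in growth rate on the toy model", {
  fx <- toy_fixture()
  for (cond in fx$conds[c("fructose", "formate")]) {
    grid <- seq(0, 0.6, length.out = 20)
    feas <- vapply(grid, function(mu) {
      p <- build_rba_problem(fx$net, fx$mach, fx$bud, fx$kapp, mu, cond)
      solve_feasible(p, "none")$status == "feasible"
    }, logical(1))
    # once infeasible, stays infeasible
    expect_true(all(diff(as.integer(feas)) <= 0),
                label = paste("monotone feasibility on", cond$name))
    expect_true(feas[1])
  }
})

test_that("minimal-enzyme optima saturate the capacity of every used enzyme", {
  fx <- toy_fixture()
  for (cond in fx$conds) {
    sol <- chemostat_solution(fx$net, fx$mach, fx$bud, fx$kapp, cond)
    enz_by_rxn <- sol$enzymes |>
      dplyr::group_by(reaction) |>
      dplyr::summarise(conc = sum(conc))
    for (i in seq_len(nrow(enz_by_rxn))) {
      if (enz_by_rxn$conc[i] > 1e-9) {
        r <- enz_by_rxn$reaction[i]
        kapp_r <- fx$kapp$kapp_hr[fx$kapp$reaction == r][1]
        expect_equal(abs(sol$flux[[r]]), kapp_r * enz_by_rxn$conc[i],
                     tolerance = 1e-6,
                     label = paste("capacity saturation of", r, "on", cond$name))
      }
    }
  }
})

test_that("bisection optimum matches the brute-force LP oracle on the tiny instance", {
  t1 <- t1_instance()
  tol <- 1e-4
  mu_hat <- maximize_growth(t1$net, t1$mach, t1$bud, t1$kapp, t1$cond,
                            tol_mu = tol)$mu
  # independent oracle: bisection driven by brute-force vertex enumeration
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (hi + lo) / 2
    p <- build_rba_problem(t1$net, t1$mach, t1$bud, t1$kapp, mid, t1$cond)
    if (brute_feasible(p)) lo <- mid else hi <- mid
  }
  expect_equal(mu_hat, lo, tolerance = 2 * tol)
})

test_that("ribosome concentration is non-decreasing across a dilution sweep", {
  fx <- toy_fixture()
  cond <- fx$conds$fructose
  mus <- c(0.05, 0.15, 0.25, 0.35)
  rib <- vapply(mus, function(mu) {
    p <- build_rba_problem(fx$net, fx$mach, fx$bud, fx$kapp, mu, cond)
    sol <- solve_feasible(p, "min_total_enzyme")
    sol$machinery$conc[sol$machinery$machinery == "ribosome"]
  }, numeric(1))
  expect_true(all(diff(rib) > 0))
})

test_that("forced fluxes pin the net flux and report infeasibility beyond the maximum", {
  fx <- toy_fixture()
  cond <- fx$conds$fructose
  base <- maximize_growth(fx$net, fx$mach, fx$bud, fx$kapp, cond)
  forced0 <- simulate_forced_flux(fx$net, fx$mach, fx$bud, fx$kapp, cond,
                                  forced = c(CBB = 0))
  expect_equal(forced0$mu, base$mu, tolerance = 2e-4)
  expect_equal(forced0$flux[["CBB"]], 0)

  expect_error(
    simulate_forced_flux(fx$net, fx$mach, fx$bud, fx$kapp, cond,
                         forced = c(CBB = 50)),
    "infeasible")
})
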
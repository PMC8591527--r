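test_that("utilization follows the predicted-over-measured formula", {
  u <- compute_utilization(c(e1 = 0.5, e2 = 1.0), c(e1 = 1.0, e2 = 1.0))
  expect_equal(u$utilization_pct[u$enzyme == "e1"], 50)
  expect_equal(u$utilization_pct[u$enzyme == "e2"], 100)

  # measured but not predicted -> 0%; predicted but unmeasured -> reported NA
  u2 <- compute_utilization(c(a = 0.2), c(a = 0.4, b = 1))
  expect_equal(u2$utilization_pct[u2$enzyme == "b"], 0)
  expect_identical(u2$status[u2$enzyme == "b"], "measured_only")
  u3 <- compute_utilization(c(a = 0.2, c = 0.1), c(a = 0.4))
  expect_identical(u3$status[u3$enzyme == "c"], "unmeasured")
  expect_true(is.na(u3$utilization_pct[u3$enzyme == "c"]))

  # measured zero with predicted > 0 is undefined, not infinite
  u4 <- compute_utilization(c(a = 0.2), c(a = 0))
  expect_identical(u4$status, "undefined")
  expect_true(is.na(u4$utilization_pct))
})

test_that("utilization is invariant to a global unit change", {
  p <- c(e1 = 0.3, e2 = 0.9); m <- c(e1 = 0.6, e2 = 0.9)
  u1 <- compute_utilization(p, m)
  u2 <- compute_utilization(p * 1000, m * 1000)  # mmol -> umol
  expect_equal(u1$utilization_pct, u2$utilization_pct)
})

test_that("category boundaries are inclusive on the lower category", {
  rec <- tibble::tibble(
    enzyme = c("a", "b", "c", "d"), condition = "x",
    predicted = NA, measured = NA,
    utilization_pct = c(33.0, 66.0, 66.01, 120), status = "ok")
  cat <- categorize_utilization(rec)
  expect_identical(as.character(cat$category),
                   c("low", "moderate", "high", "high"))
  expect_identical(cat$over_unity, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("excess-factor proteomes recover the ground-truth utilization", {
  fx <- toy_fixture()
  cond <- fx$conds$fructose
  sol <- chemostat_solution(fx$net, fx$mach, fx$bud, fx$kapp, cond)
  active <- sol$enzymes$enzyme[sol$enzymes$conc > 1e-9]
  excess <- stats::setNames(c(1, 2, 4), active[1:3])
  prot <- gen_proteome(sol, fx$net, noise_cv = 0, n_replicates = 1,
                       excess = excess, seed = 1)
  meas <- enzyme_measured_conc(prot, fx$net)
  pred <- stats::setNames(sol$enzymes$conc, sol$enzymes$enzyme)
  u <- compute_utilization(pred[active], meas[active])
  expect_equal(u$utilization_pct[match(names(excess), u$enzyme)],
               c(100, 50, 25), tolerance = 1e-9)
  # all other flux-carrying enzymes sit at exactly 100%
  others <- setdiff(active, names(excess))
  expect_equal(u$utilization_pct[match(others, u$enzyme)],
               rep(100, length(others)), tolerance = 1e-9)
})

test_that("self-utilization of the minimal solution is exactly 100%", {
  fx <- toy_fixture()
  sol <- chemostat_solution(fx$net, fx$mach, fx$bud, fx$kapp,
                            fx$conds$succinate)
  pred <- stats::setNames(sol$enzymes$conc, sol$enzymes$enzyme)
  pred <- pred[pred > 0]
  u <- compute_utilization(pred, pred)
  expect_equal(u$utilization_pct, rep(100, length(pred)))
})

test_that("abundance CV uses the sample standard deviation", {
  m <- tibble::tibble(id = "e", condition = c("a", "b", "c", "d"),
                      conc_mmol_gdcw = c(1, 1, 1, 5))
  cv <- abundance_variability(m)
  expect_equal(cv$cv, 1.0)  # sd = 2, mean = 2
  m0 <- dplyr::mutate(m, conc_mmol_gdcw = 0)
  expect_identical(abundance_variability(m0)$flag, "zero_mean")
  expect_error(abundance_variability(dplyr::filter(m, condition == "a")),
               ">= 2 conditions")
})

test_that("machinery utilization mirrors a synthetic ribosome reserve", {
  fx <- toy_fixture()
  sol <- chemostat_solution(fx$net, fx$mach, fx$bud, fx$kapp,
                            fx$conds$fructose)
  pred <- stats::setNames(sol$machinery$conc, sol$machinery$machinery)
  mu1 <- machinery_utilization(sol, pred)
  expect_equal(mu1$utilization_pct[mu1$machinery == "ribosome"], 100)
  # a twofold measured reserve halves utilization
  res <- pred; res["ribosome"] <- 2 * res["ribosome"]
  mu2 <- machinery_utilization(sol, res)
  expect_equal(mu2$utilization_pct[mu2$machinery == "ribosome"], 50)
  # utilization is non-increasing in the reserve factor
  u_seq <- vapply(c(1, 1.5, 2, 4), function(k) {
    m <- pred; m["ribosome"] <- k * m["ribosome"]
    mm <- machinery_utilization(sol, m)
    mm$utilization_pct[mm$machinery == "ribosome"]
  }, numeric(1))
  expect_true(all(diff(u_seq) < 0))
})
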
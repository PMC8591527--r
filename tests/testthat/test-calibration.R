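calibration_inputs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- toy_fixture()
      sols <- purrr::map(fx$conds, function(cc)
        chemostat_solution(fx$net, fx$mach, fx$bud, fx$kapp, cc))
      samples <- purrr::imap(fx$conds, function(cc, cn) {
        sample_flux_space(fx$net, cc, n_samples = 100, seed = 11,
                          fixed_fluxes = sols[[cn]]$flux[names(cc$uptake)])
      })
      proteomes <- dplyr::bind_rows(purrr::map(sols, function(s)
        gen_proteome(s, fx$net, noise_cv = 0, n_replicates = 1, seed = 5)))
      cache <<- list(fx = fx, sols = sols, samples = samples,
                     proteomes = proteomes)
    }
    cache
  }
})

test_that("k_app is recovered from noiseless chemostat proteomes", {
  ci <- calibration_inputs()
  ke <- estimate_kapp(ci$samples, ci$proteomes, ci$fx$net)
  expect_true(all(ke$provenance == "fitted"))
  rel_err <- abs(ke$kapp_hr / ci$fx$kapp_true[ke$reaction] - 1)
  expect_true(all(rel_err < 0.05))
})

test_that("one condition, one reaction: max flux 10 over enzyme 0.002 gives 5000", {
  t1 <- t1_instance()
  env <- tibble::tibble(reaction = c("UPT", "BIOMASS"),
                        min = c(0, 0), max = c(10, 10))
  samples <- list(structure(list(envelope = env, condition = "c1",
                                 dilution = 0.1, samples = NULL),
                            class = "flux_samples"))
  prot <- tibble::tibble(condition = "c1", replicate = 1L, id = "g1",
                         type = "protein", conc_mmol_gdcw = 0.002,
                         mass_g_gdcw = NA_real_)
  ke <- estimate_kapp(samples, prot, t1$net)
  expect_equal(ke$kapp_hr[ke$reaction == "UPT"], 5000)
  expect_identical(ke$condition[ke$reaction == "UPT"], "c1")
})

test_that("unmeasured enzymes are median-filled and flagged", {
  ci <- calibration_inputs()
  # drop one protein entirely: its reaction cannot be calibrated
  prot <- dplyr::filter(ci$proteomes, .data$id != "phaC")
  ke <- estimate_kapp(ci$samples, prot, ci$fx$net)
  row <- ke[ke$reaction == "PHB_SYN", ]
  expect_identical(row$provenance, "median_filled")
  fitted <- ke$kapp_hr[ke$provenance == "fitted"]
  expect_equal(row$kapp_hr, median(fitted))
  # counts partition the capacity-constrained reactions
  expect_identical(nrow(ke), length(ci$fx$net$gpr))

  # nothing estimable at all -> error
  empty_prot <- dplyr::mutate(ci$proteomes, conc_mmol_gdcw = 0)
  expect_error(estimate_kapp(ci$samples, empty_prot, ci$fx$net),
               "cannot estimate")
})

test_that("k_app estimates scale inversely with measured abundance", {
  ci <- calibration_inputs()
  ke1 <- estimate_kapp(ci$samples, ci$proteomes, ci$fx$net)
  doubled <- dplyr::mutate(ci$proteomes,
                           conc_mmol_gdcw = 2 * .data$conc_mmol_gdcw)
  ke2 <- estimate_kapp(ci$samples, doubled, ci$fx$net)
  expect_equal(ke2$kapp_hr, ke1$kapp_hr / 2, tolerance = 1e-9)
})

test_that("the randomized ensemble draws complete deterministic tables", {
  ci <- calibration_inputs()
  ke <- estimate_kapp(ci$samples, ci$proteomes, ci$fx$net)
  draws <- sample_kapp_ensemble(ke, n = 20, seed = 4)
  expect_length(draws, 20)
  expect_true(all(vapply(draws, nrow, 0L) == nrow(ke)))
  expect_true(all(vapply(draws, function(d)
    all(d$kapp_hr %in% ke$kapp_hr), logical(1))))
  draws2 <- sample_kapp_ensemble(ke, n = 20, seed = 4)
  expect_identical(purrr::map(draws, "kapp_hr"), purrr::map(draws2, "kapp_hr"))

  # degenerate distribution reproduces the input
  kd <- kapp_table(ke$reaction, ke$direction, rep(1000, nrow(ke)))
  dd <- sample_kapp_ensemble(kd, n = 3, seed = 1)
  expect_true(all(dd[[1]]$kapp_hr == 1000))
})

test_that("utilized-reaction bookkeeping matches a brute-force recount", {
  ci <- calibration_inputs()
  ke <- estimate_kapp(ci$samples, ci$proteomes, ci$fx$net)
  draws <- sample_kapp_ensemble(ke, n = 10, seed = 7)
  sols <- purrr::map(ci$fx$conds, function(cc) {
    purrr::map(draws, function(kt)
      maximize_growth(ci$fx$net, ci$fx$mach, ci$fx$bud, kt, cc,
                      tol_mu = 1e-3))
  })
  summary <- count_utilized_reactions(sols, flux_tol = 1e-6)

  # set algebra: core within each condition set within the union
  for (cond_set in summary$per_condition) {
    expect_true(all(summary$core %in% cond_set))
    expect_true(all(cond_set %in% summary$union))
  }
  # brute-force recount from the stored flux vectors
  flux_mats <- purrr::map(sols, function(ss)
    do.call(rbind, purrr::map(ss, ~ abs(.x$flux) > 1e-6)))
  recount_per_cond <- purrr::map(flux_mats, function(m)
    sort(colnames(m)[colSums(m) > 0]))
  expect_identical(summary$per_condition, recount_per_cond)
  recount_core <- sort(Reduce(intersect, purrr::map(flux_mats, function(m)
    colnames(m)[colSums(m) == nrow(m)])))
  expect_identical(summary$core, recount_core)

  # degenerate ensemble of one: union = core = active set
  one <- count_utilized_reactions(
    purrr::map(sols, ~ .x[1]), flux_tol = 1e-6)
  expect_identical(one$union, sort(unique(unlist(one$per_condition))))

  # union is non-decreasing in ensemble size
  small <- count_utilized_reactions(purrr::map(sols, ~ .x[1:4]))
  expect_true(all(small$union %in% summary$union))
})
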
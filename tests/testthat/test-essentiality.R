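test_that("the central-ORF filter keeps positions in [0.1, 0.9]", {
  ins <- tibble::tibble(gene = "g", position = c(0.05, 0.5, 0.95))
  expect_identical(nrow(central_orf_filter(ins)), 1L)
  inside <- tibble::tibble(gene = "g", position = c(0.11, 0.5, 0.89))
  expect_identical(central_orf_filter(inside), inside)
  expect_error(central_orf_filter(tibble::tibble(gene = "g", position = 1.2)),
               "\\[0, 1\\]")
  # uniform positions retain ~the central fraction
  set.seed(1)
  u <- tibble::tibble(gene = "g", position = runif(20000))
  frac <- nrow(central_orf_filter(u)) / nrow(u)
  expect_equal(frac, 0.8, tolerance = 0.02)
})

test_that("insertion index matches a brute-force windowed recomputation", {
  lib <- gen_insertion_library(n_genes = 500, seed = 3)
  g <- insertion_index(lib$genes, window_genes = 100)
  # independent loop-based recomputation
  gg <- lib$genes[order(lib$genes$order), ]
  n <- nrow(gg)
  for (i in sample(n, 50)) {
    win <- max(1, i - 50):min(n, i + 49)
    ii_ref <- (gg$n_insertions[i] / gg$length_bp[i]) /
      (sum(gg$n_insertions[win]) / sum(gg$length_bp[win]))
    expect_equal(g$ii[i], ii_ref)
  }
  # zero insertions give index zero; a window-matching gene gives 1
  expect_true(all(g$ii[g$n_insertions == 0] == 0))
  flat <- tibble::tibble(gene = paste0("g", 1:200), order = 1:200,
                         length_bp = 1000, n_insertions = 10L)
  gf <- insertion_index(flat)
  expect_equal(gf$ii, rep(1, 200))
})

test_that("insertion index is scale-invariant in the counts", {
  lib <- gen_insertion_library(n_genes = 300, seed = 5)
  g1 <- insertion_index(lib$genes)
  scaled <- dplyr::mutate(lib$genes, n_insertions = n_insertions * 7L)
  g2 <- insertion_index(scaled)
  expect_equal(g1$ii, g2$ii)
})

test_that("the gamma mixture recovers known component means", {
  set.seed(11)
  n <- 5000
  x <- c(rgamma(round(0.1 * n), shape = 0.3, scale = 0.1),
         rgamma(round(0.9 * n), shape = 8, scale = 0.15))
  fit <- fit_gamma_mixture(x)
  td <- tidy(fit)
  expect_equal(td$mean[td$component == "low"], 0.3 * 0.1, tolerance = 0.15)
  expect_equal(td$mean[td$component == "high"], 8 * 0.15, tolerance = 0.15)
  expect_equal(td$weight[td$component == "low"], 0.1, tolerance = 0.3)

  # permutation invariance
  fit2 <- fit_gamma_mixture(sample(x))
  expect_equal(fit$loglik, fit2$loglik)
  expect_equal(fit$shape, fit2$shape)
})

test_that("single-component data produce a degenerate flagged fit", {
  set.seed(2)
  x <- rgamma(2000, shape = 6, rate = 5)
  fit <- fit_gamma_mixture(x)
  expect_true(fit$degenerate || fit$weight_low < 0.05 ||
                abs(fit$shape[["low"]] / fit$rate[["low"]] -
                      fit$shape[["high"]] / fit$rate[["high"]]) < 0.5)
})

test_that("thresholds behave at the fold limits and zero index", {
  lib <- gen_insertion_library(n_genes = 500, seed = 4)
  g <- insertion_index(recount_insertions(
    lib$genes, central_orf_filter(lib$insertions)))
  fit <- fit_gamma_mixture(g$ii_smooth)
  thr5 <- essentiality_thresholds(fit, fold = 5)
  expect_lte(thr5["lower"], thr5["upper"])
  # fold = 1 collapses the ambiguous zone to (almost) nothing
  thr1 <- essentiality_thresholds(fit, fold = 1)
  expect_lt(thr1["upper"] - thr1["lower"], 5e-4)
  # zero insertion index is always called essential
  calls <- classify_essentiality(g, fit)
  expect_true(all(calls$class[calls$ii == 0] == "essential"))
  # classification is monotone in II
  ess_max <- max(calls$ii[calls$class == "essential"])
  non_min <- min(calls$ii[calls$class == "non_essential"])
  expect_lt(ess_max, non_min)
})

test_that("synthetic libraries are recovered with high accuracy", {
  accs <- c(); recalls <- c(); ambs <- c()
  for (s in 1:3) {
    lib <- gen_insertion_library(n_genes = 500, frac_essential = 0.1,
                                 essential_rate_ratio = 0.02, seed = s)
    g <- insertion_index(recount_insertions(
      lib$genes, central_orf_filter(lib$insertions)))
    calls <- classify_essentiality(g, fit_gamma_mixture(g$ii_smooth))
    truth <- calls$essential_true
    decided <- calls$class != "probably_essential"
    accs <- c(accs, mean((calls$class[decided] == "essential") ==
                           truth[decided]))
    recalls <- c(recalls, sum(truth & calls$class == "essential") / sum(truth))
    ambs <- c(ambs, mean(!decided))
  }
  expect_gte(mean(accs), 0.95)
  expect_gte(mean(recalls), 0.90)
  expect_lt(mean(ambs), 0.10)
})

test_that("gene calls propagate to reactions by the any-essential rule", {
  calls <- tibble::tibble(
    gene = c("e", "p", "n1", "n2"),
    class = factor(c("essential", "probably_essential", "non_essential",
                     "non_essential"),
                   levels = c("essential", "probably_essential",
                              "non_essential")))
  gpr <- list(
    R1 = list(c(e = 1, n1 = 1)),        # essential + non -> essential
    R2 = list(c(p = 1), c(n1 = 1)),     # probably + non -> probably
    R3 = list(c(n1 = 1, n2 = 2)),       # all non -> non
    R4 = list())                        # no genes -> excluded
  out <- propagate_to_reactions(calls, gpr)
  expect_identical(out$class[out$reaction == "R1"], "essential")
  expect_identical(out$class[out$reaction == "R2"], "probably_essential")
  expect_identical(out$class[out$reaction == "R3"], "non_essential")
  expect_false("R4" %in% out$reaction)
})

test_that("library generation honours its contracts", {
  lib <- gen_insertion_library(n_genes = 500, frac_essential = 0.1, seed = 12)
  expect_equal(sum(lib$genes$essential_true), 50, tolerance = 0.4)
  # zero rate ratio: every essential gene has zero insertions
  lib0 <- gen_insertion_library(n_genes = 300, essential_rate_ratio = 0,
                                seed = 2)
  expect_true(all(lib0$genes$n_insertions[lib0$genes$essential_true] == 0))
  # determinism
  lib2 <- gen_insertion_library(n_genes = 500, frac_essential = 0.1, seed = 12)
  expect_identical(lib, lib2)
  expect_error(gen_insertion_library(frac_essential = 0), "frac_essential")
})
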
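test_that("per-barcode fitness follows the normalized log2 fold change", {
  # equal counts, equal library sizes -> 0
  expect_equal(barcode_fitness(c(10, 20), c(10, 20), pseudocount = 0),
               c(0, 0))
  # 100 -> 800 at equal library sizes with psi = 0 gives exactly 3
  f2 <- barcode_fitness(c(100, 700), c(800, 0), pseudocount = 0)
  expect_equal(f2[[1]], 3)
  # both-zero barcodes are excluded as NA
  f3 <- barcode_fitness(c(0, 5), c(0, 5), pseudocount = 0.5)
  expect_true(is.na(f3[1]))

  # library-size invariance: scaling one sample leaves f unchanged (psi = 0)
  c0 <- c(10, 50, 200); ct <- c(5, 80, 100)
  expect_equal(barcode_fitness(c0, ct, 0), barcode_fitness(c0, ct * 13, 0))
})

test_that("a pseudocount shrinks low-count fitness toward zero", {
  c0 <- rep(1000, 5)
  ct <- c(1, 2, 5, 10, 50)
  for (psi in c(0.25, 0.5, 2)) {
    f0 <- barcode_fitness(c0, ct, pseudocount = 0)
    f1 <- barcode_fitness(c0, ct, pseudocount = psi)
    low <- ct <= 10  # shrinkage matters where counts are low
    expect_true(all(abs(f1[low]) <= abs(f0[low])))
  }
})

test_that("gene fitness aggregates barcodes and recenters on neutrals", {
  counts <- tibble::tibble(
    barcode = paste0("b", 1:6),
    gene = rep(c("gA", "gN"), each = 3),
    position = 0.5,
    T0 = c(1600, 1600, 1600, 1000, 1000, 1000),
    T8 = c(100, 100, 100, 1000, 1000, 1000))
  samples <- tibble::tibble(sample = c("T0", "T8"), generations = c(0, 8))
  fs <- gene_fitness(counts, samples, pseudocount = 0,
                     neutral_genes = "gN")
  # all barcodes of gA depleted 16x -> F = -4 after neutral recentering
  expect_equal(fs$fitness[fs$gene == "gA"], -4, tolerance = 1e-9)
  expect_equal(fs$fitness[fs$gene == "gN"], 0)
  expect_identical(fs$n_mutants, c(3L, 3L))

  # a global depletion hitting every barcode equally nulls out
  g_counts <- dplyr::mutate(counts, T8 = T0 * 3)
  fs2 <- gene_fitness(g_counts, samples, pseudocount = 0)
  expect_equal(fs2$fitness, c(0, 0))
})

test_that("fitness recovery from synthetic barcode counts is accurate", {
  errs <- c()
  for (s in 1:3) {
    f_true <- stats::setNames(
      c(rep(c(-6, -4, -2), each = 10), rep(0, 170)), paste0("g", 1:200))
    bc <- gen_barcode_counts(f_true, mutants_per_gene = 6, depth = 1e6,
                             seed = s)
    fs <- gene_fitness(bc$counts, bc$samples)
    f8 <- fs[fs$generations == 8, ]
    errs <- c(errs, f8$fitness[match(names(f_true), f8$gene)] - f_true)
  }
  expect_lte(sqrt(mean(errs^2)), 0.5)
})

test_that("the null library yields almost no significant calls", {
  f0 <- stats::setNames(rep(0, 400), paste0("g", 1:400))
  bc <- gen_barcode_counts(f0, depth = 1e6, seed = 21)
  calls <- significance_call(gene_fitness(bc$counts, bc$samples))
  expect_lt(mean(calls$significant), 0.01)
})

test_that("significance needs both magnitude and generations", {
  sc <- tibble::tibble(
    gene = c("a", "b", "c", "d"), condition = NA, sample = "s",
    generations = c(8, 4, 8, 16),
    fitness = c(-3.0, -6, 1.5, 3.2), n_mutants = 3L)
  out <- significance_call(sc)
  expect_identical(out$significant, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("barcode count generation is robust and validated", {
  f <- c(a = -2, b = 0)
  # tiny depth: no crash, zero counts tolerated downstream
  bc <- gen_barcode_counts(f, mutants_per_gene = 2, depth = 100, seed = 1)
  expect_equal(sum(bc$counts$T0), 100)
  fs <- gene_fitness(bc$counts, bc$samples)
  expect_true(all(is.finite(fs$fitness)))
  # generations must include 0
  expect_error(gen_barcode_counts(f, generations = c(8, 16)), "include 0")
  # zero mutants: warning and empty result
  expect_warning(out <- gen_barcode_counts(f, mutants_per_gene = 0),
                 "zero mutants")
  expect_identical(nrow(out$counts), 0L)
})
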
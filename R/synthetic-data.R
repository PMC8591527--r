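#' Steady-state chemostat solution
#'
#' Minimal-enzyme RBA allocation at a fixed growth rate equal to the
#' condition's chemostat dilution rate: the model counterpart of a
#' steady-state proteome sample.
#'
#' @inheritParams build_rba_problem
#' @param condition a [growth_condition] with a dilution rate.
#' @return an `rba_solution`.
#' @export
chemostat_solution <- function(network, machineries, budgets, kapp, condition) {
  if (is.na(condition$dilution)) stop("condition has no dilution rate")
  p <- build_rba_problem(network, machineries, budgets, kapp,
                         condition$dilution, condition)
  sol <- solve_feasible(p, objective = "min_total_enzyme")
  if (sol$status != "feasible") {
    stop("chemostat steady state infeasible for condition '",
         condition$name, "' at D = ", condition$dilution)
  }
  sol
}

#' Generate a synthetic proteome from an RBA solution
#'
#' Protein abundances are the solution's enzyme allocations mapped down to
#' subunits (`conc_protein = sum(alt conc * copies)`), multiplied by a
#' per-enzyme excess factor and multiplicative lognormal noise with a given
#' coefficient of variation. The excess factor creates known
#' under-utilization: an enzyme produced at `excess` times its minimal
#' required abundance has true utilization `100 / excess` percent.
#' Machinery concentrations are measured the same way.
#'
#' @param solution an `rba_solution` (e.g. [chemostat_solution()]).
#' @param network the [rba_network] the solution came from.
#' @param noise_cv coefficient of variation of the lognormal noise (>= 0).
#' @param n_replicates biological replicates to simulate.
#' @param excess named numeric of per-enzyme excess factors >= 1 (names are
#'   enzyme alternative ids as in `solution$enzymes$enzyme`, or machinery
#'   ids); unspecified enzymes get 1.
#' @param seed RNG seed.
#' @return tibble with `condition`, `replicate`, `id`, `type`
#'   (`"protein"` or `"machinery"`), `conc_mmol_gdcw`, `mass_g_gdcw`.
#'   Ground-truth utilization per enzyme (percent, `100 / excess`) is
#'   attached as `attr(, "utilization_true")`.
#' @export
gen_proteome <- function(solution, network, noise_cv = 0.1, n_replicates = 4,
                         excess = NULL, seed = 1L) {
  stopifnot(noise_cv >= 0, solution$status == "feasible")
  enz <- enzyme_table(network)
  sol_enz <- solution$enzymes
  xs <- stats::setNames(rep(1, nrow(sol_enz)), sol_enz$enzyme)
  if (!is.null(excess)) {
    if (any(excess < 1)) stop("excess factors must be >= 1")
    xs[names(excess)[names(excess) %in% names(xs)]] <-
      excess[names(excess) %in% names(xs)]
  }
  # subunit-level abundance implied by the (excess-inflated) enzyme levels
  prot <- purrr::map_dfr(seq_len(nrow(sol_enz)), function(i) {
    comp <- enz$genes[[match(sol_enz$enzyme[i], enz$enzyme)]]
    tibble::tibble(id = names(comp),
                   conc = sol_enz$conc[i] * as.numeric(comp) * xs[i])
  }) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(conc = sum(.data$conc))

  mach <- solution$machinery
  xm <- stats::setNames(rep(1, nrow(mach)), mach$machinery)
  if (!is.null(excess)) {
    xm[names(excess)[names(excess) %in% names(xm)]] <-
      excess[names(excess) %in% names(xm)]
  }
  base <- dplyr::bind_rows(
    dplyr::mutate(prot, type = "protein",
                  length_aa = network$proteins$length_aa[
                    match(.data$id, network$proteins$id)]),
    tibble::tibble(id = mach$machinery, conc = mach$conc * xm,
                   type = "machinery", length_aa = mach$length_aa))

  sdlog <- sqrt(log(1 + noise_cv^2))
  out <- with_seed(seed, {
    purrr::map_dfr(seq_len(n_replicates), function(rep_i) {
      noise <- if (noise_cv > 0) {
        rlnorm(nrow(base), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else rep(1, nrow(base))
      base |>
        dplyr::mutate(
          condition = solution$condition, replicate = rep_i,
          conc_mmol_gdcw = .data$conc * noise,
          mass_g_gdcw = .data$conc_mmol_gdcw * .data$length_aa *
            network$aa_mass / 1000) |>
        dplyr::select("condition", "replicate", "id", "type",
                      "conc_mmol_gdcw", "mass_g_gdcw")
    })
  })
  util_true <- 100 / xs
  attr(out, "utilization_true") <- util_true
  out
}

#' Generate a synthetic transposon insertion library
#'
#' Emulates the statistical structure of a dense transposon mutagenesis
#' screen: per-gene insertion counts are Poisson with rate
#' `length_kb * mean_rate * gene_effect`, where the gene effect is
#' gamma-distributed (mean 1) to create overdispersion, and essential genes
#' have their rate multiplied by `essential_rate_ratio`. Insertion positions
#' are uniform along the ORF so the central-80% filter is exercisable. The
#' insertion-index distribution of such a library is bimodal.
#'
#' @param n_genes number of genes.
#' @param frac_essential fraction of genes that are essential (0 < f < 1).
#' @param mean_rate mean insertions per kb for non-essential genes.
#' @param essential_rate_ratio multiplier (< 1) on the insertion rate of
#'   essential genes.
#' @param effect_shape shape of the gamma gene effect (mean fixed at 1);
#'   larger = less overdispersion.
#' @param seed RNG seed.
#' @return list with `genes` (tibble: `gene`, `order`, `length_bp`,
#'   `n_insertions`, `essential_true`) and `insertions` (tibble: `gene`,
#'   `position` as ORF fraction).
#' @export
gen_insertion_library <- function(n_genes = 500, frac_essential = 0.1,
                                  mean_rate = 15, essential_rate_ratio = 0.02,
                                  effect_shape = 3, seed = 1L) {
  stopifnot(frac_essential > 0, frac_essential < 1, essential_rate_ratio < 1,
            essential_rate_ratio >= 0)
  with_seed(seed, {
    len <- round(rlnorm(n_genes, meanlog = log(900), sdlog = 0.45))
    len <- pmax(len, 100)
    ess <- runif(n_genes) < frac_essential
    effect <- rgamma(n_genes, shape = effect_shape, rate = effect_shape)
    lambda <- len / 1000 * mean_rate * effect *
      ifelse(ess, essential_rate_ratio, 1)
    n_ins <- rpois(n_genes, lambda)
    genes <- tibble::tibble(
      gene = sprintf("g%04d", seq_len(n_genes)),
      order = seq_len(n_genes), length_bp = len,
      n_insertions = n_ins, essential_true = ess)
    insertions <- tibble::tibble(
      gene = rep(genes$gene, n_ins),
      position = runif(sum(n_ins)))
    list(genes = genes, insertions = insertions)
  })
}

#' Generate synthetic barcode count matrices under selection
#'
#' Each gene gets `mutants_per_gene` barcoded insertion mutants with
#' lognormal initial abundances. During competitive growth the relative
#' abundance of a mutant changes as `2^(F_true * g / g_ref)` over `g`
#' generations, with `g_ref` the number of generations over which the
#' fitness score is defined. Sequencing counts are multinomial draws at the
#' given depth per sample.
#'
#' @param fitness_true named numeric, gene -> true fitness (log2 units over
#'   `g_ref` generations; 0 = neutral).
#' @param mutants_per_gene barcoded mutants per gene.
#' @param depth reads per sample.
#' @param generations vector of sampled generation counts; must include 0.
#' @param g_ref generation span that defines one fitness unit.
#' @param position_spread insertion positions drawn uniform on [0, 1].
#' @param seed RNG seed.
#' @return list with `counts` (tibble: `barcode`, `gene`, `position`, one
#'   count column per sample) and `samples` (tibble: `sample`, `generations`).
#' @export
gen_barcode_counts <- function(fitness_true, mutants_per_gene = 6,
                               depth = 1e6, generations = c(0, 8, 16),
                               g_ref = 8, position_spread = TRUE, seed = 1L) {
  if (!0 %in% generations) stop("generations must include 0")
  if (is.null(names(fitness_true))) stop("fitness_true must be named by gene")
  if (mutants_per_gene < 1) {
    warning("fitness specified for genes with zero mutants; skipped")
    return(list(counts = tibble::tibble(), samples = tibble::tibble()))
  }
  genes <- names(fitness_true)
  with_seed(seed, {
    n_bc <- length(genes) * mutants_per_gene
    bc <- tibble::tibble(
      barcode = sprintf("bc%05d", seq_len(n_bc)),
      gene = rep(genes, each = mutants_per_gene),
      position = if (position_spread) runif(n_bc) else rep(0.5, n_bc),
      a0 = rlnorm(n_bc, meanlog = 0, sdlog = 0.5))
    f <- rep(as.numeric(fitness_true), each = mutants_per_gene)
    samples <- tibble::tibble(
      sample = paste0("T", generations), generations = generations)
    cnt <- purrr::map(generations, function(g) {
      w <- bc$a0 * 2^(f * g / g_ref)
      as.numeric(rmultinom(1, size = depth, prob = w / sum(w)))
    })
    names(cnt) <- samples$sample
    counts <- dplyr::bind_cols(bc[c("barcode", "gene", "position")],
                               tibble::as_tibble(cnt))
    list(counts = counts, samples = samples)
  })
}
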
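#' Per-barcode fitness
#'
#' Log2 fold change of a barcode's library-size-normalized read count
#' between generation 0 and a later sample:
#' `f = log2((c_t + psi) / N_t) - log2((c_0 + psi) / N_0)`, with `psi` a
#' pseudocount shrinking low-count estimates toward 0. Barcodes with zero
#' counts at both timepoints are excluded.
#'
#' @param counts_t0,counts_t integer count vectors over the same barcode
#'   universe.
#' @param pseudocount `psi` (>= 0; > 0 required if any zero counts remain).
#' @return numeric vector of per-barcode fitness values, NA for excluded
#'   barcodes (both counts zero).
#' @export
barcode_fitness <- function(counts_t0, counts_t, pseudocount = 0.5) {
  stopifnot(length(counts_t0) == length(counts_t), pseudocount >= 0,
            all(counts_t0 >= 0), all(counts_t >= 0))
  n0 <- sum(counts_t0); nt <- sum(counts_t)
  f <- log2((counts_t + pseudocount) / nt) -
    log2((counts_t0 + pseudocount) / n0)
  f[counts_t0 == 0 & counts_t == 0] <- NA_real_
  f
}

#' Gene fitness scores from barcode counts
#'
#' For each sample with generations > 0, per-barcode fitness values
#' ([barcode_fitness()]) are aggregated per gene by a weighted mean with
#' inverse-variance weights (`w = 1 / (1/(c_0+psi) + 1/(c_t+psi))`, the
#' Poisson delta-method variance of a log fold change), after applying the
#' central-ORF filter to the insertion positions. Scores are then recentered
#' per sample so that the median fitness of the designated neutral genes is
#' zero.
#'
#' @param counts barcode count tibble ([gen_barcode_counts()] layout:
#'   `barcode`, `gene`, `position`, one column per sample).
#' @param samples sample sheet tibble (`sample`, `generations`); exactly one
#'   sample must have generations 0 (the reference).
#' @param pseudocount pseudocount for the log fold change.
#' @param central_fraction central-ORF filter width applied to `position`.
#' @param neutral_genes genes used for recentering; default all genes
#'   (median-centering).
#' @param equal_weights use unweighted means instead of inverse-variance.
#' @param condition label stored in the output.
#' @return tibble `gene`, `condition`, `sample`, `generations`, `fitness`,
#'   `n_mutants`. Genes with no usable barcode are absent.
#' @export
gene_fitness <- function(counts, samples, pseudocount = 0.5,
                         central_fraction = 0.8, neutral_genes = NULL,
                         equal_weights = FALSE, condition = NA_character_) {
  stopifnot(all(c("barcode", "gene", "position") %in% names(counts)))
  ref <- samples$sample[samples$generations == 0]
  if (length(ref) != 1) stop("need exactly one generation-0 reference sample")
  keep <- central_orf_filter(counts[, c("barcode", "gene", "position")],
                             central_fraction)$barcode
  cnt <- counts[counts$barcode %in% keep, ]
  if (!nrow(cnt)) stop("no barcode passes the central-ORF filter")

  later <- samples[samples$generations > 0, ]
  out <- purrr::map_dfr(seq_len(nrow(later)), function(i) {
    sm <- later$sample[i]
    c0 <- cnt[[ref]]; ct <- cnt[[sm]]
    f <- barcode_fitness(c0, ct, pseudocount)
    w <- if (equal_weights) rep(1, length(f)) else {
      1 / (1 / (c0 + pseudocount) + 1 / (ct + pseudocount))
    }
    ok <- !is.na(f)
    per_gene <- tibble::tibble(gene = cnt$gene[ok], f = f[ok], w = w[ok]) |>
      dplyr::group_by(.data$gene) |>
      dplyr::summarise(fitness = sum(.data$f * .data$w) / sum(.data$w),
                       n_mutants = dplyr::n())
    neut <- if (is.null(neutral_genes)) per_gene$gene else neutral_genes
    center <- median(per_gene$fitness[per_gene$gene %in% neut], na.rm = TRUE)
    per_gene |>
      dplyr::mutate(fitness = .data$fitness - center,
                    condition = condition, sample = sm,
                    generations = later$generations[i]) |>
      dplyr::select("gene", "condition", "sample", "generations",
                    "fitness", "n_mutants")
  })
  out
}

#' Flag significant fitness effects
#'
#' A gene fitness score is significant when its magnitude reaches the
#' threshold after sufficient generations of competitive growth:
#' `|F| >= threshold` and `generations >= min_generations`. The default
#' threshold of 3 sits well outside the bulk fitness variation of neutral
#' mutants (roughly -2..2).
#'
#' @param scores [gene_fitness()] output.
#' @param threshold absolute fitness threshold (log2 units).
#' @param min_generations generation gate.
#' @return `scores` with a logical `significant` column.
#' @export
significance_call <- function(scores, threshold = 3, min_generations = 8) {
  scores |>
    dplyr::mutate(significant = abs(.data$fitness) >= threshold &
                    .data$generations >= min_generations)
}
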
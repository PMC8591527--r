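#' Filter insertions to the central portion of the ORF
#'
#' Insertions near the termini of an open reading frame often fail to
#' inactivate the gene product; only insertions within the central fraction
#' (default 80%, i.e. positions in [0.1, 0.9]) are counted as true
#' knockouts.
#'
#' @param insertions tibble with columns `gene` and `position` (ORF
#'   fraction in [0, 1]).
#' @param central_fraction width of the retained central window.
#' @return the filtered insertion tibble.
#' @export
central_orf_filter <- function(insertions, central_fraction = 0.8) {
  stopifnot(central_fraction > 0, central_fraction <= 1)
  if (any(insertions$position < 0 | insertions$position > 1)) {
    stop("insertion positions must be ORF fractions in [0, 1]")
  }
  lo <- (1 - central_fraction) / 2
  dplyr::filter(insertions, .data$position >= lo,
                .data$position <= 1 - lo)
}

#' Recount insertions per gene after filtering
#'
#' @param genes gene tibble (`gene`, `order`, `length_bp`, ...).
#' @param insertions filtered insertion tibble.
#' @return `genes` with `n_insertions` recomputed.
#' @export
recount_insertions <- function(genes, insertions) {
  cnt <- insertions |> dplyr::count(.data$gene, name = "n_insertions")
  genes |>
    dplyr::select(-dplyr::any_of("n_insertions")) |>
    dplyr::left_join(cnt, by = "gene") |>
    dplyr::mutate(n_insertions = dplyr::coalesce(.data$n_insertions, 0L))
}

#' Insertion index
#'
#' The insertion index of gene *i* is its per-bp insertion density
#' normalized by the local insertion density:
#' `II_i = (n_i / k_i) / (n_r / k_r)`, where `n_r` and `k_r` sum insertions
#' and lengths over a window of `window_genes` genes centered on gene *i*
#' in genomic order (the target gene included). At replicon ends the window
#' is truncated by default; set `circular = TRUE` to wrap.
#'
#' Genes with zero insertions have `ii = 0` exactly; for density fitting a
#' smoothed index `ii_smooth` is also returned in which a zero count is
#' replaced by half an insertion, so that the low mode has a proper spread
#' (its value then varies with gene length and local density rather than
#' collapsing onto one constant).
#'
#' @param genes tibble with `gene`, `order`, `length_bp`, `n_insertions`.
#' @param window_genes window size in genes.
#' @param circular wrap the window around the replicon ends?
#' @param pseudo_insertions count substituted for zero-insertion genes in
#'   `ii_smooth`.
#' @return `genes` with columns `ii`, `ii_smooth` and `ii_flag` (`"ok"` or
#'   `"empty_window"`).
#' @export
insertion_index <- function(genes, window_genes = 100, circular = FALSE,
                            pseudo_insertions = 0.5) {
  g <- dplyr::arrange(genes, .data$order)
  n <- nrow(g)
  half <- window_genes %/% 2
  ii <- numeric(n); ii_s <- numeric(n); flag <- rep("ok", n)
  for (i in seq_len(n)) {
    idx <- (i - half):(i + half - 1 + window_genes %% 2)
    if (circular) {
      idx <- ((idx - 1) %% n) + 1
    } else {
      idx <- idx[idx >= 1 & idx <= n]
    }
    nr <- sum(g$n_insertions[idx]); kr <- sum(g$length_bp[idx])
    if (nr == 0) {
      ii[i] <- NA_real_; ii_s[i] <- NA_real_; flag[i] <- "empty_window"
    } else {
      dens_r <- nr / kr
      ii[i] <- (g$n_insertions[i] / g$length_bp[i]) / dens_r
      ii_s[i] <- (max(g$n_insertions[i], pseudo_insertions) /
                    g$length_bp[i]) / dens_r
    }
  }
  g$ii <- ii; g$ii_smooth <- ii_s; g$ii_flag <- flag
  g
}

#' Fit a two-component gamma mixture to insertion indices
#'
#' Models the bimodal insertion-index distribution as a mixture of a
#' low-mode (essential) and a high-mode (non-essential) gamma component,
#' fitted by expectation-maximization. Initialization is moment-based from a
#' split at the empirical antimode; the M-step solves the weighted gamma
#' likelihood with a Newton iteration on the shape. Zero indices carry no
#' gamma density; for fitting and classification they are replaced by half
#' the smallest positive index (configurable).
#'
#' @param ii numeric vector of insertion indices (>= 0, NA dropped).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param zero_replace value substituted for zeros; default half the
#'   smallest positive index.
#' @return object of class `gamma_mixture`: shapes, rates, mixing weight
#'   (of the low component), log-likelihood, iterations, convergence flag.
#' @export
fit_gamma_mixture <- function(ii, max_iter = 500, tol = 1e-8,
                              zero_replace = NULL) {
  x <- ii[!is.na(ii)]
  if (any(x < 0)) stop("insertion indices must be >= 0")
  pos <- x[x > 0]
  if (length(pos) < 10) stop("too few positive insertion indices to fit")
  if (is.null(zero_replace)) zero_replace <- min(pos) / 2
  x[x == 0] <- zero_replace

  # antimode split for initialization: the insertion index is normalized to
  # the local density, so the non-essential mode sits near 1 and the valley
  # between the modes inside (0.05, 0.9)
  d <- stats::density(x, from = 0, to = max(x))
  band <- d$x > 0.05 & d$x < 0.9
  lo_guess <- if (any(band)) d$x[band][which.min(d$y[band])]
              else stats::quantile(x, 0.15)
  grp <- x <= lo_guess
  if (sum(grp) < 3 || sum(!grp) < 3) {
    grp <- x <= stats::quantile(x, 0.15)
  }
  mom <- function(z) {
    m <- mean(z); v <- var(z)
    if (!is.finite(v) || v <= 0) v <- (m / 2)^2 + 1e-12
    c(shape = m^2 / v, rate = m / v)
  }
  p1 <- mom(x[grp]); p2 <- mom(x[!grp])
  w <- mean(grp)

  # weighted gamma MLE via Newton on log-shape
  wfit <- function(z, wt, init_shape) {
    wt_sum <- sum(wt)
    mlog <- sum(wt * log(z)) / wt_sum
    mz <- sum(wt * z) / wt_sum
    s <- log(mz) - mlog            # always >= 0
    a <- max(init_shape, 1e-3)
    for (k in 1:50) {
      g <- log(a) - digamma(a) - s
      h <- 1 / a - trigamma(a)
      step <- g / h
      a_new <- a - step
      if (a_new <= 0) a_new <- a / 2
      if (abs(a_new - a) < 1e-10 * a) { a <- a_new; break }
      a <- a_new
    }
    a <- min(a, 1e3)  # guard against point-mass collapse on tied values
    c(shape = a, rate = a / mz)
  }

  ll <- -Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- w * dgamma(x, p1["shape"], p1["rate"])
    d2 <- (1 - w) * dgamma(x, p2["shape"], p2["rate"])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll_new <- sum(log(tot))
    r1 <- d1 / tot
    if (is.finite(ll) && abs(ll_new - ll) < tol * (1 + abs(ll))) {
      converged <- TRUE; ll <- ll_new; break
    }
    ll <- ll_new
    w <- mean(r1)
    if (w < 1e-6 || w > 1 - 1e-6) break  # component collapse
    p1 <- wfit(x, r1, p1["shape"])
    p2 <- wfit(x, 1 - r1, p2["shape"])
    # identifiability loss: both components describing the same population
    # (a usable essential/non-essential split needs well-separated modes)
    m1 <- p1[["shape"]] / p1[["rate"]]; m2 <- p2[["shape"]] / p2[["rate"]]
    if (max(m1, m2) < 2 * min(m1, m2)) break
  }
  m1 <- p1[["shape"]] / p1[["rate"]]; m2 <- p2[["shape"]] / p2[["rate"]]
  degenerate <- w < 1e-6 || w > 1 - 1e-6 ||
    max(m1, m2) < 2 * min(m1, m2)
  if (!converged && !degenerate && it == max_iter) {
    stop("EM did not converge after ", max_iter, " iterations; ",
         "last log-likelihood ", signif(ll, 8))
  }
  structure(list(
    shape = c(low = unname(p1["shape"]), high = unname(p2["shape"])),
    rate = c(low = unname(p1["rate"]), high = unname(p2["rate"])),
    weight_low = w, loglik = ll, iterations = it,
    converged = converged || degenerate, degenerate = degenerate,
    zero_replace = zero_replace, n = length(x)),
    class = "gamma_mixture")
}

#' @export
print.gamma_mixture <- function(x, ...) {
  cat("<gamma_mixture> low: shape", signif(x$shape["low"], 3), "rate",
      signif(x$rate["low"], 3), "| high: shape", signif(x$shape["high"], 3),
      "rate", signif(x$rate["high"], 3), "| weight(low)",
      signif(x$weight_low, 3),
      if (x$degenerate) "| DEGENERATE (single component)", "\n")
  invisible(x)
}

#' @export
tidy.gamma_mixture <- function(x, ...) {
  tibble::tibble(component = c("low", "high"),
                 shape = as.numeric(x$shape), rate = as.numeric(x$rate),
                 mean = as.numeric(x$shape / x$rate),
                 weight = c(x$weight_low, 1 - x$weight_low))
}

#' @export
glance.gamma_mixture <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, iterations = x$iterations,
                 converged = x$converged, degenerate = x$degenerate,
                 n = x$n)
}

#' Density-ratio thresholds for an essentiality call
#'
#' The lower threshold is the largest insertion index at which the essential
#' (low) component's density is at least `fold` times the non-essential
#' density; the upper threshold is the smallest index at which the
#' non-essential density is at least `fold` times the essential one.
#' Indices between the thresholds are ambiguous ("probably essential").
#' Searched on a dense grid, robust to any shape parameters.
#'
#' @param fit a [fit_gamma_mixture()] result.
#' @param fold density-ratio fold difference (default 5).
#' @param grid_step grid resolution on the II axis.
#' @param grid_max upper end of the search grid.
#' @return named numeric `c(lower, upper)`.
#' @export
essentiality_thresholds <- function(fit, fold = 5, grid_step = 1e-4,
                                    grid_max = NULL) {
  if (is.null(grid_max)) {
    grid_max <- stats::qgamma(0.999, fit$shape["high"], fit$rate["high"])
  }
  g <- seq(grid_step, grid_max, by = grid_step)
  d_ess <- dgamma(g, fit$shape["low"], fit$rate["low"])
  d_non <- dgamma(g, fit$shape["high"], fit$rate["high"])
  ess_dom <- d_ess >= fold * d_non
  non_dom <- d_non >= fold * d_ess
  # the low component need not dominate in the limit x -> 0 (for shapes > 1
  # both densities vanish); the lower threshold is the top of the
  # essential-dominated region, the upper threshold the first
  # non-essential-dominated point above it
  lower <- if (any(ess_dom)) g[max(which(ess_dom))] else 0
  above <- non_dom & g > lower
  if (!any(above)) {
    stop("no non-essential-dominated region above the lower threshold (",
         signif(lower, 4), "): components not separable")
  }
  upper <- g[min(which(above))]
  c(lower = unname(lower), upper = unname(upper))
}

#' Classify genes as essential / probably essential / non-essential
#'
#' Applies the density-ratio thresholds to each gene's insertion index:
#' below the lower threshold -> essential, above the upper -> non-essential,
#' between -> probably essential. An index of zero is always essential (the
#' low component dominates at the origin).
#'
#' @param genes tibble with `gene` and `ii` ([insertion_index()] output).
#' @param fit a [fit_gamma_mixture()] result.
#' @param fold density-ratio fold difference.
#' @return `genes` with `class` (factor essential/probably_essential/
#'   non_essential) plus attributes `thresholds` and `fit`.
#' @export
classify_essentiality <- function(genes, fit, fold = 5) {
  thr <- essentiality_thresholds(fit, fold = fold)
  cls <- dplyr::case_when(
    is.na(genes$ii) ~ NA_character_,
    genes$ii < thr["lower"] ~ "essential",
    genes$ii > thr["upper"] ~ "non_essential",
    TRUE ~ "probably_essential")
  out <- genes
  out$class <- factor(cls, levels = c("essential", "probably_essential",
                                      "non_essential"))
  attr(out, "thresholds") <- thr
  attr(out, "fit") <- fit
  out
}

#' Propagate gene essentiality to reactions
#'
#' A reaction is essential if any associated gene is essential; otherwise
#' probably essential if any associated gene is probably essential;
#' otherwise non-essential. Reactions without genes are excluded.
#'
#' @param calls tibble with `gene` and `class` ([classify_essentiality()]).
#' @param gpr GPR list as in [rba_network] (`reaction -> alternatives`).
#' @return tibble `reaction`, `class`, `n_genes`.
#' @export
propagate_to_reactions <- function(calls, gpr) {
  cls <- stats::setNames(as.character(calls$class), calls$gene)
  purrr::imap_dfr(gpr, function(alts, rxn) {
    genes <- unique(unlist(lapply(alts, names)))
    if (!length(genes)) return(NULL)
    g_cls <- cls[genes]
    out <- if (any(g_cls == "essential", na.rm = TRUE)) "essential"
    else if (any(g_cls == "probably_essential", na.rm = TRUE)) "probably_essential"
    else "non_essential"
    tibble::tibble(reaction = rxn, class = out, n_genes = length(genes))
  })
}
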
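#' Estimate apparent catalytic rates from flux samples and proteomes
#'
#' For every reaction direction, k_app is the maximum flux per unit of
#' allocated enzyme over all conditions: the largest sampled flux (envelope
#' maximum) divided by the measured enzyme concentration assigned to the
#' reaction in that condition. Reactions with no flux or no measured enzyme
#' in any condition receive the median of the fitted k_app distribution,
#' flagged `median_filled`.
#'
#' Protein-to-reaction allocation: the measured abundance of a protein
#' shared by several reactions is split equally among them; within a
#' reaction, an isoenzyme alternative's concentration is the minimum over
#' its subunits of allocated abundance per required copy, and the reaction's
#' enzyme concentration sums its alternatives.
#'
#' @param samples list of [sample_flux_space()] results, one per condition.
#' @param proteomes proteome tibble as produced by [gen_proteome()] (columns
#'   `condition`, `replicate`, `id`, `type`, `conc_mmol_gdcw`); replicates
#'   are averaged.
#' @param network the [rba_network].
#' @param flux_tol fluxes below this are treated as zero.
#' @return a [kapp_table] covering every GPR-bearing reaction.
#' @export
estimate_kapp <- function(samples, proteomes, network, flux_tol = 1e-6) {
  conds <- vapply(samples, function(s) s$condition, character(1))
  if (anyDuplicated(conds)) stop("duplicate conditions in samples")
  pconds <- unique(proteomes$condition)
  if (!all(conds %in% pconds)) {
    stop("proteome measurements missing for condition(s): ",
         paste(setdiff(conds, pconds), collapse = ", "))
  }

  prot_mean <- proteomes |>
    dplyr::filter(.data$type == "protein") |>
    dplyr::group_by(.data$condition, .data$id) |>
    dplyr::summarise(conc = mean(.data$conc_mmol_gdcw), .groups = "drop")

  enz <- enzyme_table(network)
  # number of reactions sharing each protein
  prot_use <- purrr::map_dfr(seq_len(nrow(enz)), function(i) {
    tibble::tibble(id = names(enz$genes[[i]]), reaction = enz$reaction[i])
  }) |> dplyr::distinct()
  n_shared <- prot_use |> dplyr::count(.data$id, name = "n_rxn")

  reaction_enzyme_conc <- function(cond) {
    pm <- prot_mean |> dplyr::filter(.data$condition == cond)
    share <- pm |>
      dplyr::left_join(n_shared, by = "id") |>
      dplyr::mutate(share = .data$conc / pmax(.data$n_rxn, 1))
    vapply(unique(enz$reaction), function(r) {
      alts <- enz[enz$reaction == r, ]
      sum(vapply(seq_len(nrow(alts)), function(i) {
        comp <- alts$genes[[i]]
        av <- share$share[match(names(comp), share$id)]
        if (anyNA(av)) return(NA_real_)
        min(av / as.numeric(comp))
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
  }

  rxns <- names(network$gpr)
  rev <- stats::setNames(network$reactions$reversible, network$reactions$id)
  rows <- list()
  for (r in rxns) {
    for (d in c("fwd", if (rev[[r]]) "bwd")) {
      best <- NA_real_; best_cond <- NA_character_
      for (s in samples) {
        env <- s$envelope[s$envelope$reaction == r, ]
        vmax <- if (d == "fwd") env$max else -env$min
        if (!length(vmax) || is.na(vmax) || vmax <= flux_tol) next
        ec <- reaction_enzyme_conc(s$condition)[[r]]
        if (is.na(ec) || !is.finite(ec) || ec <= 0) next
        cand <- vmax / ec
        if (is.na(best) || cand > best) { best <- cand; best_cond <- s$condition }
      }
      rows[[paste(r, d)]] <- tibble::tibble(
        reaction = r, direction = d, kapp_hr = unname(best),
        provenance = if (is.na(best)) "median_filled" else "fitted",
        condition = unname(best_cond))
    }
  }
  out <- dplyr::bind_rows(rows)
  fitted <- out$kapp_hr[out$provenance == "fitted"]
  if (!length(fitted)) stop("no reaction had both flux and measured enzyme; ",
                            "cannot estimate any k_app")
  out$kapp_hr[out$provenance == "median_filled"] <- median(fitted)
  class(out) <- c("kapp_table", class(out))
  out
}

#' Randomized k_app ensemble
#'
#' Draws `n` complete k_app tables, each assigning every reaction-direction a
#' value resampled independently, with replacement, from the pooled
#' empirical distribution of fitted k_app values. Used to count reactions
#' that are utilizable independently of one particular calibration.
#'
#' @param kapp a [kapp_table].
#' @param n number of draws.
#' @param seed RNG seed.
#' @return list of `n` kapp tables (provenance `"sampled"`).
#' @export
sample_kapp_ensemble <- function(kapp, n = 200, seed = 1L) {
  kapp <- as_kapp_table(kapp)
  if (!nrow(kapp)) stop("empty k_app table")
  pool <- kapp$kapp_hr[kapp$provenance %in% c("fitted")]
  if (!length(pool)) pool <- kapp$kapp_hr
  with_seed(seed, {
    purrr::map(seq_len(n), function(i) {
      out <- kapp
      out$kapp_hr <- sample(pool, nrow(kapp), replace = TRUE)
      out$provenance <- "sampled"
      out
    })
  })
}

#' Utilized-reaction bookkeeping over a simulation ensemble
#'
#' Given RBA solutions grouped by condition (e.g. one per randomized-k_app
#' draw), reports which reactions carry flux (|v| > `flux_tol`) at least once
#' per condition, the union over conditions, the core set used in every
#' simulation of every condition, and the condition-unique sets.
#'
#' @param solutions named list: condition -> list of `rba_solution`s.
#' @param flux_tol utilization flux threshold (mmol gDCW^-1 hr^-1).
#' @return list with `per_condition` (named list of reaction id vectors),
#'   `union`, `core`, `unique_per_condition`, and a `counts` summary tibble.
#' @export
count_utilized_reactions <- function(solutions, flux_tol = 1e-6) {
  stopifnot(is.list(solutions), !is.null(names(solutions)))
  active <- function(sol) names(sol$flux)[abs(sol$flux) > flux_tol]
  per_condition <- purrr::map(solutions, function(sols) {
    sort(unique(unlist(purrr::map(sols, active))))
  })
  union_set <- sort(unique(unlist(per_condition)))
  in_all <- purrr::map(solutions, function(sols) {
    Reduce(intersect, purrr::map(sols, active))
  })
  core <- sort(Reduce(intersect, in_all))
  unique_per_condition <- purrr::imap(per_condition, function(set, cond) {
    others <- unlist(per_condition[setdiff(names(per_condition), cond)])
    setdiff(set, others)
  })
  counts <- tibble::tibble(
    condition = names(per_condition),
    n_utilized = lengths(per_condition),
    n_unique = lengths(unique_per_condition))
  list(per_condition = per_condition, union = union_set, core = core,
       unique_per_condition = unique_per_condition, counts = counts)
}
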
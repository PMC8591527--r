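#' Solve an RBA problem for feasibility or minimal enzyme investment
#'
#' With `objective = "none"` the solver only establishes feasibility at the
#' problem's growth rate. With `"min_total_enzyme"` it returns, among all
#' feasible allocations, one minimizing the total protein investment
#' `sum(length_i * [E_i])` over enzymes and machines - the minimal required
#' enzyme abundance against which utilization is scored.
#'
#' @param problem an [build_rba_problem()] result.
#' @param objective `"none"` or `"min_total_enzyme"`.
#' @param flux_tol fluxes below this magnitude are reported as zero
#'   (mmol gDCW^-1 hr^-1).
#' @return an `rba_solution`: status, growth rate, net flux per reaction,
#'   enzyme and machinery concentration tibbles, and the list of binding
#'   constraints.
#' @export
solve_feasible <- function(problem, objective = c("min_total_enzyme", "none"),
                           flux_tol = 1e-6) {
  objective <- match.arg(objective)
  obj <- if (objective == "none") numeric(ncol(problem$A)) else problem$enzyme_cost
  res <- solve_lp(obj, problem$A, problem$dir, problem$rhs, maximize = FALSE)

  if (res$status == "iteration_limit") stop("LP solver hit iteration limit")
  if (res$status != "optimal") {
    return(structure(list(status = "infeasible", mu = problem$mu,
                          condition = problem$condition$name),
                     class = "rba_solution"))
  }

  x <- res$solution
  vars <- problem$vars
  rxn <- problem$network$reactions
  fwd <- x[paste0("f:", rxn$id)]
  bwd <- stats::setNames(numeric(nrow(rxn)), rxn$id)
  bwd[rxn$id[rxn$reversible]] <- x[paste0("b:", rxn$id[rxn$reversible])]
  flux <- stats::setNames(as.numeric(fwd) - as.numeric(bwd), rxn$id)
  flux[abs(flux) < flux_tol] <- 0

  enz_rows <- vars$type == "enzyme"
  enzymes <- tibble::tibble(
    enzyme = sub("^E:", "", vars$name[enz_rows]),
    reaction = vars$reaction[enz_rows],
    conc = as.numeric(x[vars$name[enz_rows]]),
    length_aa = vars$length_aa[enz_rows]) |>
    dplyr::mutate(aa = .data$conc * .data$length_aa)

  mach_rows <- vars$type == "machinery"
  machinery <- tibble::tibble(
    machinery = sub("^M:", "", vars$name[mach_rows]),
    conc = as.numeric(x[vars$name[mach_rows]]),
    length_aa = vars$length_aa[mach_rows]) |>
    dplyr::mutate(aa = .data$conc * .data$length_aa)

  slack <- problem$rhs - as.numeric(problem$A %*% x)
  scale <- pmax(1, abs(problem$rhs))
  binding <- rownames(problem$A)[problem$dir != "==" & abs(slack) / scale < 1e-7]

  structure(list(status = "feasible", mu = problem$mu, flux = flux,
                 enzymes = enzymes, machinery = machinery,
                 binding = binding, objective = res$objective,
                 condition = problem$condition$name,
                 total_enzyme_aa = sum(enzymes$aa) + sum(machinery$aa)),
            class = "rba_solution")
}

#' @export
print.rba_solution <- function(x, ...) {
  if (x$status != "feasible") {
    cat("<rba_solution> infeasible at mu =", x$mu, "\n")
  } else {
    cat("<rba_solution> mu =", signif(x$mu, 5), "| condition:", x$condition,
        "|", sum(x$flux != 0), "active fluxes | enzyme+machinery protein =",
        signif(x$total_enzyme_aa, 4), "mmol aa/gDCW\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an RBA solution into a per-reaction tibble
#'
#' @param x an `rba_solution`.
#' @param ... unused.
#' @return tibble with `reaction`, `flux` (mmol gDCW^-1 hr^-1),
#'   `enzyme_conc` (summed over isoenzyme alternatives, mmol gDCW^-1) and
#'   `enzyme_aa`.
#' @export
tidy.rba_solution <- function(x, ...) {
  if (x$status != "feasible") stop("no solution payload: status is infeasible")
  enz <- x$enzymes |>
    dplyr::group_by(.data$reaction) |>
    dplyr::summarise(enzyme_conc = sum(.data$conc), enzyme_aa = sum(.data$aa))
  tibble::tibble(reaction = names(x$flux), flux = as.numeric(x$flux)) |>
    dplyr::left_join(enz, by = "reaction")
}

#' @rdname tidy.rba_solution
#' @export
glance.rba_solution <- function(x, ...) {
  tibble::tibble(status = x$status, mu = x$mu,
                 condition = x$condition %||% NA_character_,
                 n_active = if (x$status == "feasible") sum(x$flux != 0) else NA_integer_,
                 protein_aa = if (x$status == "feasible") x$total_enzyme_aa else NA_real_)
}

#' Maximize growth rate by bisection
#'
#' Finds the largest growth rate at which the RBA problem is feasible, by
#' bisection over `mu` (feasibility is monotone in `mu`: all growth-coupled
#' demands scale with it while the protein supply does not expand). The
#' returned allocation is the minimal-enzyme solution at the optimum.
#'
#' @inheritParams build_rba_problem
#' @param tol_mu bisection tolerance on the growth rate, hr^-1.
#' @param mu_upper upper end of the bisection bracket, hr^-1 (must stay inside the range over which the budget fraction models are valid).
#' @param forced optional named numeric of pinned net fluxes.
#' @return an `rba_solution` at the maximal feasible growth rate.
#' @export
maximize_growth <- function(network, machineries, budgets, kapp, condition,
                            tol_mu = 1e-4, mu_upper = 1, forced = NULL) {
  feas <- function(mu) {
    p <- build_rba_problem(network, machineries, budgets, kapp, mu, condition,
                           forced = forced)
    solve_feasible(p, objective = "none")$status == "feasible"
  }
  lo <- 0
  if (!feas(0)) {
    # demand-pinned scenarios (e.g. a forced substrate uptake that cannot be
    # dissipated within the enzyme budget at rest) are infeasible at low mu:
    # the feasible growth rates form an interval. Bracket its upper edge
    # from a coarse grid before bisecting.
    grid <- seq(0, mu_upper, length.out = 21)[-1]
    ok <- vapply(grid, feas, logical(1))
    if (!any(ok)) stop("problem infeasible over the whole growth-rate grid")
    lo <- max(grid[ok])
  }
  hi <- mu_upper
  if (feas(hi)) {
    warning("still feasible at mu_upper = ", mu_upper, "; returning mu_upper")
    lo <- hi
  } else {
    while (hi - lo > tol_mu) {
      mid <- (hi + lo) / 2
      if (feas(mid)) lo <- mid else hi <- mid
    }
  }
  p <- build_rba_problem(network, machineries, budgets, kapp, lo, condition,
                         forced = forced)
  solve_feasible(p, objective = "min_total_enzyme")
}

#' Simulate growth with pinned fluxes
#'
#' Pins selected net fluxes by equality (e.g. a forced CO2 fixation rate
#' through the CBB route) and maximizes growth subject to them. Beyond the
#' usual solution payload the result carries the biomass yield on the
#' condition's substrate (gDCW per g substrate) and the net CO2 exchange
#' flux (positive = emission).
#'
#' @inheritParams maximize_growth
#' @param forced named numeric, reaction id -> pinned net flux
#'   (mmol gDCW^-1 hr^-1).
#' @return an `rba_solution` with extra fields `yield_gdw_per_g` and
#'   `co2_emission`.
#' @export
simulate_forced_flux <- function(network, machineries, budgets, kapp,
                                 condition, forced, tol_mu = 1e-4,
                                 mu_upper = 1) {
  sol <- maximize_growth(network, machineries, budgets, kapp, condition,
                         tol_mu = tol_mu, mu_upper = mu_upper, forced = forced)
  if (sol$status != "feasible") return(sol)
  m <- network$metabolites
  upt_rxn <- names(condition$uptake)[1]
  sub_met <- m$id[m$boundary & network$S[, upt_rxn][m$id] < 0 &
                    !is.na(m$electrons) & m$electrons > 0]
  q_mmol <- sol$flux[[upt_rxn]]
  mw <- m$mw_g_mol[m$id == sub_met[1]]
  sol$substrate_uptake_mmol <- q_mmol
  sol$yield_gdw_per_g <- if (q_mmol > 0) sol$mu / (q_mmol * mw / 1000) else NA_real_
  co2_b <- m$id[m$boundary & !is.na(m$carbon) & m$carbon > 0 &
                  !is.na(m$electrons) & m$electrons == 0]
  sol$co2_emission <- if (length(co2_b)) {
    sum(network$S[co2_b, , drop = FALSE] %*% sol$flux)
  } else NA_real_
  sol
}
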
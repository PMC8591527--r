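#' Apparent catalytic rate table
#'
#' Canonical container for per-reaction-direction apparent catalytic rates
#' (k_app, hr^-1): the proportionality between a reaction's flux and the
#' concentration of the enzyme catalyzing it, `v = k_app * [E]`. Each entry
#' carries a provenance flag: `"fitted"` (estimated from flux per unit
#' enzyme) or `"median_filled"` (gap-filled with the median of the fitted
#' distribution).
#'
#' @param reaction,direction,kapp_hr,provenance,condition vectors of equal
#'   length; `direction` is `"fwd"` or `"bwd"`; `condition` records which
#'   condition yielded the maximizing flux (optional).
#' @return tibble of class `kapp_table`.
#' @export
kapp_table <- function(reaction, direction = "fwd", kapp_hr,
                       provenance = "fitted", condition = NA_character_) {
  stopifnot(all(kapp_hr > 0), all(direction %in% c("fwd", "bwd")))
  out <- tibble::tibble(reaction = reaction, direction = direction,
                        kapp_hr = kapp_hr, provenance = provenance,
                        condition = condition)
  class(out) <- c("kapp_table", class(out))
  out
}

#' @rdname kapp_table
#' @param x a named numeric vector (forward rates) or a `kapp_table`.
#' @export
as_kapp_table <- function(x) {
  if (inherits(x, "kapp_table")) return(x)
  if (is.numeric(x) && !is.null(names(x))) {
    return(kapp_table(reaction = names(x), kapp_hr = as.numeric(x)))
  }
  stop("cannot interpret object as a kapp table")
}

kapp_lookup <- function(kapp, reaction, direction) {
  hit <- kapp$kapp_hr[kapp$reaction == reaction & kapp$direction == direction]
  if (length(hit)) return(hit[1])
  # fall back to the opposite direction for reversible enzymes with a single
  # calibrated rate
  hit <- kapp$kapp_hr[kapp$reaction == reaction]
  if (length(hit)) return(hit[1])
  NA_real_
}

substrate_importers <- function(network) {
  m <- network$metabolites
  red <- m$id[m$boundary & !is.na(m$electrons) & m$electrons > 0]
  if (!length(red)) return(character())
  S <- network$S[red, , drop = FALSE]
  network$reactions$id[apply(S < 0, 2, any)]
}

#' Build the resource balance analysis problem at a fixed growth rate
#'
#' Assembles the linear program coupling metabolism to proteome allocation:
#' steady-state mass balance with the biomass flux fixed to `mu`, maintenance
#' and storage-polymer demands, enzyme capacity constraints
#' `v_d <= k_app,d * sum([E_alt])` per reaction direction, machinery capacity
#' (e.g. translation: `mu * total protein <= rate_ribosome * [ribosome]`,
#' with the machines' own protein counted), and growth-rate-dependent
#' compartment protein budgets. All constraints are linear at fixed `mu`;
#' growth maximization is a feasibility bisection over `mu`
#' ([maximize_growth()]).
#'
#' Reversible reactions are split into two non-negative directed fluxes, each
#' with its own capacity constraint. Each GPR alternative (isoenzyme) is a
#' separate enzyme variable feeding the same capacity constraint.
#'
#' @param network an [rba_network].
#' @param machineries a [machinery_spec] tibble (may have zero rows to
#'   disable machinery coupling).
#' @param budgets a [budget_spec] tibble.
#' @param kapp a [kapp_table] or named numeric vector of forward rates.
#' @param mu growth rate, hr^-1.
#' @param condition a [growth_condition]; uptake reactions not named in it
#'   are closed.
#' @param forced optional named numeric: net fluxes to pin by equality
#'   (scenario simulation).
#' @return object of class `rba_problem`.
#' @export
build_rba_problem <- function(network, machineries, budgets, kapp, mu,
                              condition, forced = NULL) {
  stopifnot(mu >= 0)
  kapp <- as_kapp_table(kapp)
  enz <- enzyme_table(network)
  rxn <- network$reactions

  no_spec <- setdiff(names(network$gpr), enz$reaction)
  if (length(no_spec)) stop("no enzyme spec for reaction(s): ",
                            paste(no_spec, collapse = ", "))
  need_kapp <- names(network$gpr)
  have <- vapply(need_kapp, function(r) !is.na(kapp_lookup(kapp, r, "fwd")),
                 logical(1))
  if (any(!have)) stop("missing k_app for reaction(s): ",
                       paste(need_kapp[!have], collapse = ", "))

  # --- variables ------------------------------------------------------------
  vars <- dplyr::bind_rows(
    tibble::tibble(name = paste0("f:", rxn$id), type = "flux",
                   reaction = rxn$id, direction = "fwd", length_aa = 0),
    tibble::tibble(name = paste0("b:", rxn$id[rxn$reversible]), type = "flux",
                   reaction = rxn$id[rxn$reversible], direction = "bwd",
                   length_aa = 0),
    if (nrow(enz)) tibble::tibble(name = paste0("E:", enz$enzyme),
                                  type = "enzyme", reaction = enz$reaction,
                                  direction = NA, length_aa = enz$length_aa),
    if (nrow(machineries)) tibble::tibble(name = paste0("M:", machineries$id),
                                          type = "machinery",
                                          reaction = machineries$id,
                                          direction = NA,
                                          length_aa = machineries$length_aa))
  nv <- nrow(vars)
  vidx <- stats::setNames(seq_len(nv), vars$name)

  rows <- list(); dirs <- character(); rhss <- numeric(); labels <- character()
  add_row <- function(coef, dir, rhs, label) {
    miss <- setdiff(names(coef), names(vidx))
    if (length(miss)) stop("constraint '", label, "' references unknown ",
                           "variable(s): ", paste(miss, collapse = ", "))
    v <- numeric(nv); v[vidx[names(coef)]] <- coef
    rows[[length(rows) + 1]] <<- v
    dirs[length(dirs) + 1] <<- dir
    rhss[length(rhss) + 1] <<- rhs
    labels[length(labels) + 1] <<- label
  }
  net_coef <- function(r) {
    cf <- stats::setNames(1, paste0("f:", r))
    if (rxn$reversible[rxn$id == r]) cf <- c(cf, stats::setNames(-1, paste0("b:", r)))
    cf
  }

  # --- mass balance ---------------------------------------------------------
  internal <- network$metabolites$id[!network$metabolites$boundary]
  for (met in internal) {
    s <- network$S[met, ]
    nz <- names(s)[s != 0]
    if (!length(nz)) next
    cf <- numeric()
    for (r in nz) cf <- c(cf, unname(s[r]) * net_coef(r))
    cf <- tapply(cf, names(cf), sum)
    add_row(cf, "==", 0, paste0("mb:", met))
  }

  # --- growth-coupled demands ----------------------------------------------
  add_row(net_coef(network$biomass_reaction), "==", mu,
          paste0("fix:", network$biomass_reaction))
  mnt <- network$maintenance
  has_maint <- !is.null(mnt) && !is.na(mnt$reaction)
  if (has_maint) {
    add_row(net_coef(mnt$reaction), ">=", mnt$ngam + mnt$gam * mu,
            paste0("maint:", mnt$reaction))
  }
  if (!is.null(network$phb)) {
    add_row(net_coef(network$phb$reaction), "==", network$phb$per_mu * mu,
            paste0("fix:", network$phb$reaction))
  }
  if (!is.null(forced)) {
    for (r in names(forced)) {
      if (!r %in% rxn$id) stop("forced flux for unknown reaction: ", r)
      add_row(net_coef(r), "==", forced[[r]], paste0("force:", r))
    }
  }

  # --- exchange / uptake bounds ---------------------------------------------
  importers <- substrate_importers(network)
  for (r in importers) {
    cap <- if (r %in% names(condition$uptake)) condition$uptake[[r]] else 0
    add_row(stats::setNames(1, paste0("f:", r)), "<=", cap, paste0("uptake:", r))
  }
  for (r in condition$closed) {
    add_row(stats::setNames(1, paste0("f:", r)), "<=", 0, paste0("closed:", r))
  }
  fixed_ids <- c(network$biomass_reaction,
                 if (has_maint) mnt$reaction,
                 if (!is.null(network$phb)) network$phb$reaction)
  for (i in seq_len(nrow(rxn))) {
    r <- rxn$id[i]
    if (r %in% c(importers, fixed_ids)) next
    if (is.finite(rxn$ub[i])) {
      add_row(stats::setNames(1, paste0("f:", r)), "<=", rxn$ub[i],
              paste0("ub:", r))
    }
    if (rxn$reversible[i] && is.finite(rxn$lb[i])) {
      add_row(stats::setNames(1, paste0("b:", r)), "<=", -rxn$lb[i],
              paste0("lb:", r))
    }
    if (!rxn$reversible[i] && rxn$lb[i] > 0) {
      add_row(stats::setNames(1, paste0("f:", r)), ">=", rxn$lb[i],
              paste0("lb:", r))
    }
  }

  # --- enzyme capacity ------------------------------------------------------
  for (r in names(network$gpr)) {
    evars <- paste0("E:", enz$enzyme[enz$reaction == r])
    kf <- kapp_lookup(kapp, r, "fwd")
    add_row(c(stats::setNames(1, paste0("f:", r)),
              stats::setNames(rep(-kf, length(evars)), evars)),
            "<=", 0, paste0("cap:", r, ":fwd"))
    if (rxn$reversible[rxn$id == r]) {
      kb <- kapp_lookup(kapp, r, "bwd")
      add_row(c(stats::setNames(1, paste0("b:", r)),
                stats::setNames(rep(-kb, length(evars)), evars)),
              "<=", 0, paste0("cap:", r, ":bwd"))
    }
  }

  # --- machinery capacity ---------------------------------------------------
  bud <- evaluate_budgets(budgets, mu)
  nonenz_aa <- sum(bud$nonenz_aa)
  prot_vars <- vars$name[vars$type %in% c("enzyme", "machinery")]
  prot_len <- stats::setNames(vars$length_aa[match(prot_vars, vars$name)],
                              prot_vars)
  if (nrow(machineries)) {
    for (i in seq_len(nrow(machineries))) {
      mc <- machineries[i, ]
      mvar <- paste0("M:", mc$id)
      if (mc$couples == "protein") {
        cf <- mc$coeff * mu * prot_len
        cf[mvar] <- cf[mvar] - mc$rate
        add_row(cf, "<=", -mc$coeff * mu * nonenz_aa, paste0("mach:", mc$id))
      } else {
        add_row(stats::setNames(-mc$rate, mvar), "<=", -mc$coeff * mu,
                paste0("mach:", mc$id))
      }
    }
  }

  # --- compartment budgets --------------------------------------------------
  cmpt_of <- c(
    if (nrow(enz)) stats::setNames(enz$compartment, paste0("E:", enz$enzyme)),
    if (nrow(machineries)) stats::setNames(machineries$compartment,
                                           paste0("M:", machineries$id)))
  for (i in seq_len(nrow(bud))) {
    cc <- bud$compartment[i]
    members <- names(cmpt_of)[cmpt_of == cc]
    if (!length(members)) next
    add_row(prot_len[members], "<=", bud$available[i], paste0("budget:", cc))
  }

  A <- do.call(rbind, rows)
  colnames(A) <- vars$name
  rownames(A) <- labels
  cost <- numeric(nv); cost[vars$type %in% c("enzyme", "machinery")] <-
    vars$length_aa[vars$type %in% c("enzyme", "machinery")]

  structure(list(A = A, dir = dirs, rhs = rhss, vars = vars,
                 enzyme_cost = cost, mu = mu, network = network,
                 machineries = machineries, budgets = budgets,
                 condition = condition, forced = forced,
                 nonenz_aa = nonenz_aa),
            class = "rba_problem")
}

#' @export
print.rba_problem <- function(x, ...) {
  cat("<rba_problem> mu =", x$mu, "|", nrow(x$A), "constraints x",
      ncol(x$A), "variables | condition:", x$condition$name, "\n")
  invisible(x)
}
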
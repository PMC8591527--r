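#' Construct a reaction network
#'
#' The central container for a stoichiometric model with gene-protein-reaction
#' (GPR) associations, the input to the resource balance analysis (RBA)
#' problem builder. Held as a lightweight S3 list (`rba_network`); all
#' per-metabolite / per-reaction / per-protein information lives in tibbles so
#' it can be manipulated with ordinary dplyr verbs.
#'
#' @param metabolites tibble with columns `id`, `compartment`, `boundary`
#'   (logical; boundary species are excluded from mass balance) and optionally
#'   `carbon` (atoms), `electrons` (degree of reduction x carbon, i.e.
#'   available electrons per molecule) and `mw_g_mol`.
#' @param reactions tibble with columns `id`, `reversible`, `lb`, `ub`
#'   (mmol gDCW^-1 hr^-1).
#' @param S stoichiometric matrix, metabolites x reactions, dimnames matching
#'   the id columns.
#' @param gpr named list `reaction -> list(alternative)`; each alternative is
#'   a named numeric vector `gene -> subunit copies`. Reactions absent from
#'   the list carry no enzyme (exchange / biomass / maintenance
#'   pseudo-reactions).
#' @param proteins tibble with columns `id`, `length_aa`, `compartment`
#'   (`"cytoplasm"` or `"membrane"`).
#' @param biomass named numeric, metabolite -> mmol per gDCW, describing the
#'   biomass reaction's draw (informational; the reaction itself is a column
#'   of `S`).
#' @param biomass_reaction id of the biomass reaction.
#' @param maintenance list with `reaction` (id of the ATP hydrolysis
#'   reaction), `ngam` (non-growth-associated ATP demand, mmol gDCW^-1 hr^-1)
#'   and `gam` (growth-associated, mmol gDCW^-1).
#' @param phb optional list with `reaction` and `per_mu`: a growth-rate
#'   coupled storage-polymer demand, flux = `per_mu * mu`.
#' @param aa_mass mean amino-acid residue mass, g mol^-1.
#'
#' @return an object of class `rba_network`.
#' @export
rba_network <- function(metabolites, reactions, S, gpr, proteins,
                        biomass, biomass_reaction, maintenance,
                        phb = NULL, aa_mass = 110) {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  proteins <- tibble::as_tibble(proteins)
  net <- structure(
    list(metabolites = metabolites, reactions = reactions, S = S,
         gpr = gpr, proteins = proteins, biomass = biomass,
         biomass_reaction = biomass_reaction, maintenance = maintenance,
         phb = phb, aa_mass = aa_mass),
    class = "rba_network")
  validate_network(net)
}

#' @rdname rba_network
#' @param network an `rba_network`.
#' @export
validate_network <- function(network) {
  stopifnot(inherits(network, "rba_network"))
  m <- network$metabolites; r <- network$reactions; S <- network$S
  if (!all(rownames(S) == m$id)) stop("S rows must match metabolite ids")
  if (!all(colnames(S) == r$id)) stop("S columns must match reaction ids")
  if (any(r$lb > r$ub)) {
    stop("reaction bounds inverted (lb > ub): ",
         paste(r$id[r$lb > r$ub], collapse = ", "))
  }
  bad_gpr <- setdiff(names(network$gpr), r$id)
  if (length(bad_gpr)) stop("GPR references unknown reactions: ",
                            paste(bad_gpr, collapse = ", "))
  genes <- unique(unlist(lapply(network$gpr, function(a) unlist(lapply(a, names)))))
  missing <- setdiff(genes, network$proteins$id)
  if (length(missing)) stop("GPR references proteins without a spec: ",
                            paste(missing, collapse = ", "))
  if (any(network$proteins$length_aa <= 0)) stop("protein lengths must be > 0")
  if (any(network$biomass < 0)) stop("biomass coefficients must be >= 0")
  bad_bm <- setdiff(names(network$biomass), m$id)
  if (length(bad_bm)) stop("biomass references unknown metabolites: ",
                           paste(bad_bm, collapse = ", "))
  network
}

#' @export
print.rba_network <- function(x, ...) {
  cat("<rba_network> ", nrow(x$reactions), " reactions, ",
      nrow(x$metabolites), " metabolites (",
      sum(x$metabolites$boundary), " boundary), ",
      length(x$gpr), " with GPR, ", nrow(x$proteins), " proteins\n", sep = "")
  invisible(x)
}

#' Enumerate enzyme variables of a network
#'
#' Each GPR alternative (isoenzyme) of each reaction becomes one enzyme
#' species with an amino-acid length, molecular weight and compartment derived
#' from its subunit composition. Complexes containing any membrane subunit are
#' assigned to the membrane budget.
#'
#' @param network an [rba_network].
#' @return tibble with one row per enzyme alternative: `enzyme`, `reaction`,
#'   `alt`, `length_aa` (sum of subunit lengths times copies), `mw_g_mmol`,
#'   `compartment`, `genes` (list-column of subunit vectors).
#' @export
enzyme_table <- function(network) {
  if (!length(network$gpr)) {
    return(tibble::tibble(enzyme = character(), reaction = character(),
                          alt = integer(), length_aa = numeric(),
                          mw_g_mmol = numeric(), compartment = character(),
                          genes = list()))
  }
  prot <- network$proteins
  purrr::imap_dfr(network$gpr, function(alts, rxn) {
    purrr::imap_dfr(alts, function(comp, i) {
      idx <- match(names(comp), prot$id)
      len <- sum(prot$length_aa[idx] * comp)
      cmpt <- if (any(prot$compartment[idx] == "membrane")) "membrane" else "cytoplasm"
      tibble::tibble(
        enzyme = paste0(rxn, "_enz", i), reaction = rxn, alt = as.integer(i),
        length_aa = len, mw_g_mmol = len * network$aa_mass / 1000,
        compartment = cmpt, genes = list(comp))
    })
  })
}

#' Audit elemental and electron balance of every reaction
#'
#' Checks conservation of carbon and of available electrons (degree of
#' reduction bookkeeping) across each non-exchange reaction, using the
#' `carbon` and `electrons` metabolite annotations. Reactions touching
#' boundary metabolites still count those species: the audit asks whether the
#' written chemistry is redox-consistent, not whether the species is balanced
#' in the LP.
#'
#' @param network an [rba_network].
#' @param tol imbalance tolerance.
#' @return tibble `reaction`, `carbon_imbalance`, `electron_imbalance`,
#'   `balanced`.
#' @export
reduction_audit <- function(network, tol = 1e-6) {
  m <- network$metabolites
  if (!all(c("carbon", "electrons") %in% names(m))) {
    stop("metabolites need 'carbon' and 'electrons' annotations for the audit")
  }
  ci <- as.numeric(t(network$S) %*% m$carbon)
  ei <- as.numeric(t(network$S) %*% m$electrons)
  tibble::tibble(
    reaction = network$reactions$id,
    carbon_imbalance = ci, electron_imbalance = ei,
    balanced = abs(ci) < tol & abs(ei) < tol)
}

#' Machinery specification table
#'
#' Macromolecular machines (ribosome, chaperone, RNA/DNA polymerase) are
#' lumped process catalysts: each converts a growth-rate-proportional cellular
#' demand into a required machine concentration through its catalytic rate.
#'
#' Two coupling modes are supported. `"protein"` machines serve the total
#' protein pool (enzymes + machines + the non-enzymatic reserve): demand =
#' `coeff * mu * total_protein_aa`, the ribosome (`coeff = 1`, rate in amino
#' acids hr^-1 per machine) and chaperones (`coeff` = fraction of nascent
#' protein folded) work this way. `"fixed"` machines serve a demand
#' proportional to growth rate alone (`coeff` in process units per gDCW),
#' e.g. RNA/DNA polymerase replicating a fixed cellular RNA/DNA amount per
#' doubling.
#'
#' @param id machine identifier.
#' @param rate process units hr^-1 per machine (mmol basis).
#' @param length_aa total protein length of one machine (amino acids).
#' @param compartment protein budget the machine draws from.
#' @param couples `"protein"` or `"fixed"`.
#' @param coeff demand coefficient (see Details).
#' @return tibble with one row per machine.
#' @export
machinery_spec <- function(id, rate, length_aa, compartment = "cytoplasm",
                           couples = "protein", coeff = 1) {
  stopifnot(all(rate > 0), all(length_aa >= 0),
            all(couples %in% c("protein", "fixed")))
  tibble::tibble(id = id, rate = rate, length_aa = length_aa,
                 compartment = compartment, couples = couples, coeff = coeff)
}

#' Compartment protein-budget models
#'
#' The total cellular protein pool (mmol amino acids gDCW^-1) is divided
#' between compartments by growth-rate-dependent linear fraction models, and
#' within each compartment a further linear model gives the non-enzymatic
#' share that is unavailable to enzymes and machines. Fractions are evaluated
#' as `intercept + slope * mu` and must lie in [0, 1] over the supported
#' growth-rate range.
#'
#' @param compartment compartment names.
#' @param pool total protein pool, mmol amino acids gDCW^-1 (recycled).
#' @param fraction_intercept,fraction_slope linear model of the compartment's
#'   share of the pool.
#' @param nonenz_intercept,nonenz_slope linear model of the non-enzymatic
#'   share within the compartment.
#' @return tibble with one row per compartment.
#' @export
budget_spec <- function(compartment, pool,
                        fraction_intercept, fraction_slope = 0,
                        nonenz_intercept = 0, nonenz_slope = 0) {
  tibble::tibble(compartment = compartment, pool = pool,
                 fraction_intercept = fraction_intercept,
                 fraction_slope = fraction_slope,
                 nonenz_intercept = nonenz_intercept,
                 nonenz_slope = nonenz_slope)
}

#' Evaluate a budget model at a growth rate
#'
#' @param budgets a [budget_spec] tibble.
#' @param mu growth rate, hr^-1.
#' @return tibble `compartment`, `fraction`, `nonenz`, `available` (mmol aa
#'   gDCW^-1 for enzymes + machinery) and `nonenz_aa` (mmol aa gDCW^-1 of
#'   non-enzymatic protein assumed expressed).
#' @export
evaluate_budgets <- function(budgets, mu) {
  out <- budgets |>
    dplyr::mutate(
      fraction = .data$fraction_intercept + .data$fraction_slope * mu,
      nonenz = .data$nonenz_intercept + .data$nonenz_slope * mu)
  if (any(out$fraction < 0 | out$fraction > 1 | out$nonenz < 0 | out$nonenz > 1)) {
    stop("budget fraction model leaves [0,1] at mu = ", mu)
  }
  if (sum(out$fraction) > 1 + 1e-9) stop("compartment fractions sum > 1")
  out |>
    dplyr::mutate(available = .data$fraction * (1 - .data$nonenz) * .data$pool,
                  nonenz_aa = .data$fraction * .data$nonenz * .data$pool) |>
    dplyr::select("compartment", "fraction", "nonenz", "available", "nonenz_aa")
}

#' Growth condition
#'
#' A named environment for a simulation: uptake bounds for the substrate(s)
#' fed, and optionally the chemostat dilution rate at which proteomes were
#' sampled.
#'
#' @param name condition label.
#' @param uptake named numeric, reaction id -> maximum uptake flux
#'   (mmol gDCW^-1 hr^-1). All other uptake reactions are closed.
#' @param dilution chemostat dilution rate (hr^-1), used when emulating
#'   steady-state proteomes; `NA` for batch.
#' @param closed reactions to close (upper bound 0) beyond the default of
#'   closing all uptake reactions not in `uptake`.
#' @export
growth_condition <- function(name, uptake, dilution = NA_real_, closed = character()) {
  stopifnot(is.character(name), length(name) == 1, is.numeric(uptake),
            !is.null(names(uptake)))
  structure(list(name = name, uptake = uptake, dilution = dilution,
                 closed = closed), class = "rba_condition")
}
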
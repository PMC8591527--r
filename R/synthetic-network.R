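#' Toy network configuration
#'
#' Configuration for [gen_toy_network()]. The generated model is a lumped
#' version of the central carbon metabolism of a facultative
#' chemolithoautotroph (a *Cupriavidus*-like knallgas bacterium): an
#' Entner-Doudoroff (ED) glycolytic route for a fructose-like sugar, a
#' Calvin-Benson-Bassham (CBB) CO2-fixation route, formate dehydrogenase
#' feeding reducing power, a TCA lump, oxidative phosphorylation, and
#' growth-coupled polyhydroxybutyrate (PHB) synthesis.
#'
#' @param n_substrates 1-3 substrates, in the order fructose-like,
#'   formate-like, succinate-like.
#' @param include_cbb include the CBB CO2-fixation route? Without it, growth
#'   on formate is structurally impossible (CO2 fixation is the only carbon
#'   entry from formate).
#' @param include_phb include the growth-coupled PHB demand?
#' @param seed recorded for provenance; the toy model is fully deterministic.
#' @export
toy_network_config <- function(n_substrates = 3, include_cbb = TRUE,
                               include_phb = TRUE, seed = 1L) {
  if (n_substrates < 1) stop("at least one substrate is required")
  if (n_substrates > 3) stop("at most three substrates are supported")
  structure(list(n_substrates = n_substrates, include_cbb = include_cbb,
                 include_phb = include_phb, seed = as.integer(seed)),
            class = "toy_network_config")
}

# stoichiometry of the full 3-substrate toy model; electron bookkeeping uses
# available electrons per molecule (degree of reduction x C): fructose 4.0/C,
# biomass 4.12/C, so forced CO2 fixation cannot create yield out of redox.
toy_tables <- function() {
  mets <- tibble::tribble(
    ~id,         ~compartment, ~boundary, ~carbon, ~electrons, ~mw_g_mol,
    "fru_e",     "e",          TRUE,      6,       24,         180.16,
    "for_e",     "e",          TRUE,      1,       2,          46.03,
    "suc_e",     "e",          TRUE,      4,       14,         118.09,
    "co2_e",     "e",          TRUE,      1,       0,          44.01,
    "o2_e",      "e",          TRUE,      0,       -4,         32.00,
    "phb_e",     "e",          TRUE,      4,       18,         86.09,
    "biomass_e", "e",          TRUE,      40,      164.8,      1000,
    "fru_c",     "c",          FALSE,     6,       24,         180.16,
    "for_c",     "c",          FALSE,     1,       2,          46.03,
    "suc_c",     "c",          FALSE,     4,       14,         118.09,
    "pyr",       "c",          FALSE,     3,       10,         88.06,
    "prec",      "c",          FALSE,     1,       4,          24.6,
    "nadh",      "c",          FALSE,     0,       2,          NA,
    "atp",       "c",          FALSE,     0,       0,          NA,
    "co2_c",     "c",          FALSE,     1,       0,          44.01,
    "o2_c",      "c",          FALSE,     0,       -4,         32.00)

  stoich <- list(
    UPT_FRU = c(fru_e = -1, fru_c = 1),
    UPT_FOR = c(for_e = -1, for_c = 1),
    UPT_SUC = c(suc_e = -1, suc_c = 1),
    ED      = c(fru_c = -1, pyr = 2, nadh = 2, atp = 1),
    PYROX   = c(pyr = -1, co2_c = 3, nadh = 5, atp = 1),
    ANA     = c(pyr = -1, nadh = -1, prec = 3),
    SUC_CAT = c(suc_c = -1, pyr = 1, co2_c = 1, nadh = 2),
    FDH     = c(for_c = -1, co2_c = 1, nadh = 1),
    CBB     = c(co2_c = -3, nadh = -5, atp = -6.5, pyr = 1),
    OXPHOS  = c(nadh = -1, o2_c = -0.5, atp = 2),
    PHB_SYN = c(prec = -4, nadh = -1, phb_e = 1),
    BIOMASS = c(prec = -40, nadh = -2.4, biomass_e = 1),
    MAINT   = c(atp = -1),
    EX_CO2  = c(co2_c = -1, co2_e = 1),
    EX_O2   = c(o2_e = -1, o2_c = 1))

  gpr <- list(
    UPT_FRU = list(c(fruT = 1)),
    UPT_FOR = list(c(forT = 1)),
    UPT_SUC = list(c(sucT = 1)),
    ED      = list(c(edd = 1, eda = 1)),
    PYROX   = list(c(tcaA = 1, tcaB = 1)),
    ANA     = list(c(anaA = 2)),
    SUC_CAT = list(c(sdhA = 1)),
    FDH     = list(c(fdsA = 1, fdsB = 1)),
    CBB     = list(c(cbbL = 8, cbbS = 8, prk = 4)),
    OXPHOS  = list(c(nuoA = 1), c(ndh2 = 1)),
    PHB_SYN = list(c(phaC = 1)))

  proteins <- tibble::tribble(
    ~id,    ~length_aa, ~compartment,
    "fruT", 450,        "membrane",
    "forT", 300,        "membrane",
    "sucT", 440,        "membrane",
    "edd",  600,        "cytoplasm",
    "eda",  330,        "cytoplasm",
    "tcaA", 1100,       "cytoplasm",
    "tcaB", 450,        "cytoplasm",
    "anaA", 460,        "cytoplasm",
    "sdhA", 700,        "cytoplasm",
    "fdsA", 950,        "cytoplasm",
    "fdsB", 500,        "cytoplasm",
    "cbbL", 480,        "cytoplasm",
    "cbbS", 120,        "cytoplasm",
    "prk",  290,        "cytoplasm",
    "nuoA", 1300,       "cytoplasm",
    "ndh2", 430,        "cytoplasm",
    "phaC", 590,        "cytoplasm")

  kapp_true <- c(UPT_FRU = 15000, UPT_FOR = 40000, UPT_SUC = 15000,
                 ED = 5000, PYROX = 8000, ANA = 8000, SUC_CAT = 7000,
                 FDH = 40000, CBB = 20000, OXPHOS = 10000, PHB_SYN = 4000)

  list(mets = mets, stoich = stoich, gpr = gpr, proteins = proteins,
       kapp_true = kapp_true)
}

#' Generate the toy metabolic network
#'
#' Builds an 11-15 reaction, electron-balanced lumped model of
#' chemolithoautotroph central metabolism (see [toy_network_config()]).
#' Growth on the fructose-like sugar runs through the ED route; growth on
#' formate is only possible through CO2 fixation by the CBB route. The
#' degrees of reduction of the sugar (4.0 per C-mol) and of biomass (4.12 per
#' C-mol) are nearly equal, so forcing CBB flux on sugar cannot improve the
#' biomass yield.
#'
#' The per-reaction ground-truth catalytic rates used by the synthetic
#' proteome generator are attached as `attr(net, "kapp_true")` (hr^-1).
#'
#' @param config a [toy_network_config()].
#' @return an [rba_network].
#' @export
gen_toy_network <- function(config = toy_network_config()) {
  stopifnot(inherits(config, "toy_network_config"))
  tt <- toy_tables()

  drop_rxn <- character()
  subs <- c("fru", "for", "suc")[seq_len(config$n_substrates)]
  if (!"for" %in% subs) drop_rxn <- c(drop_rxn, "UPT_FOR", "FDH")
  if (!"suc" %in% subs) drop_rxn <- c(drop_rxn, "UPT_SUC", "SUC_CAT")
  if (!config$include_cbb) drop_rxn <- c(drop_rxn, "CBB")
  if (!config$include_phb) drop_rxn <- c(drop_rxn, "PHB_SYN")

  stoich <- tt$stoich[setdiff(names(tt$stoich), drop_rxn)]
  used_mets <- unique(unlist(lapply(stoich, names)))
  mets <- tt$mets[tt$mets$id %in% used_mets, ]

  S <- matrix(0, nrow(mets), length(stoich),
              dimnames = list(mets$id, names(stoich)))
  for (r in names(stoich)) S[names(stoich[[r]]), r] <- stoich[[r]]

  reactions <- tibble::tibble(
    id = names(stoich),
    reversible = names(stoich) == "EX_CO2",
    lb = ifelse(names(stoich) == "EX_CO2", -Inf, 0),
    ub = Inf)

  gpr <- tt$gpr[intersect(names(tt$gpr), names(stoich))]
  genes <- unique(unlist(lapply(gpr, function(a) unlist(lapply(a, names)))))
  proteins <- tt$proteins[tt$proteins$id %in% genes, ]

  net <- rba_network(
    metabolites = mets, reactions = reactions, S = S, gpr = gpr,
    proteins = proteins,
    biomass = c(prec = 40, nadh = 2.4),
    biomass_reaction = "BIOMASS",
    maintenance = list(reaction = "MAINT", ngam = 3, gam = 40),
    phb = if (config$include_phb) list(reaction = "PHB_SYN", per_mu = 3))
  attr(net, "kapp_true") <- tt$kapp_true[intersect(names(tt$kapp_true),
                                                   names(stoich))]
  attr(net, "config") <- config
  net
}

#' Default macromolecular machinery of the toy model
#'
#' Ribosome and chaperone serve the protein pool; RNA and DNA polymerase
#' replicate fixed cellular RNA/DNA amounts per doubling. Rates are
#' literature-scale values for fast-growing bacteria (ribosome ~12.5 amino
#' acids s^-1).
#'
#' @return a [machinery_spec] tibble.
#' @export
toy_machineries <- function() {
  dplyr::bind_rows(
    machinery_spec("ribosome", rate = 45000, length_aa = 7500,
                   couples = "protein", coeff = 1),
    machinery_spec("chaperone", rate = 25000, length_aa = 4000,
                   couples = "protein", coeff = 0.1),
    machinery_spec("rna_polymerase", rate = 3e5, length_aa = 3500,
                   couples = "fixed", coeff = 65),
    machinery_spec("dna_polymerase", rate = 2e6, length_aa = 2500,
                   couples = "fixed", coeff = 9))
}

#' Default compartment budgets of the toy model
#'
#' Total protein pool 6.18 mmol amino acids gDCW^-1 (0.68 g protein gDCW^-1
#' at 110 g mol^-1 per residue), split between cytoplasm and membrane by
#' growth-rate-dependent linear fraction models, each with a linear
#' non-enzymatic reserve.
#'
#' @return a [budget_spec] tibble.
#' @export
toy_budgets <- function() {
  budget_spec(
    compartment = c("cytoplasm", "membrane"),
    pool = 6.18,
    fraction_intercept = c(0.90, 0.10), fraction_slope = c(0.02, -0.02),
    nonenz_intercept = c(0.38, 0.30), nonenz_slope = c(-0.15, -0.10))
}

#' Default growth conditions of the toy model
#'
#' One substrate-limited chemostat condition per substrate present in the
#' network: fructose and succinate sampled at dilution rate 0.25 hr^-1,
#' formate at 0.1 hr^-1. Uptake bounds are mmol gDCW^-1 hr^-1.
#'
#' @param network a toy [rba_network].
#' @return named list of [growth_condition] objects.
#' @export
toy_conditions <- function(network) {
  all_cond <- list(
    fructose = growth_condition("fructose", c(UPT_FRU = 4), dilution = 0.25),
    formate = growth_condition("formate", c(UPT_FOR = 30), dilution = 0.10),
    succinate = growth_condition("succinate", c(UPT_SUC = 6), dilution = 0.25))
  keep <- vapply(all_cond, function(cc)
    all(names(cc$uptake) %in% network$reactions$id), logical(1))
  all_cond[keep]
}
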
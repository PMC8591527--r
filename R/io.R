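#' Write a network to the JSON dialect
#'
#' A complete, loss-less serialization of an [rba_network]: metabolites,
#' reactions with stoichiometry and bounds, GPR alternatives, protein specs,
#' biomass/maintenance/storage demands.
#'
#' @param network an [rba_network].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(network, path) {
  rxn <- network$reactions
  reactions <- purrr::map(seq_len(nrow(rxn)), function(i) {
    r <- rxn$id[i]
    s <- network$S[, r]
    s <- as.list(s[s != 0])
    gpr <- if (r %in% names(network$gpr)) {
      purrr::map(network$gpr[[r]], as.list)
    }
    list(id = r, reversible = rxn$reversible[i],
         lb = rxn$lb[i], ub = rxn$ub[i],
         stoichiometry = s, gpr = gpr)
  })
  obj <- list(
    metabolites = network$metabolites,
    reactions = reactions,
    proteins = network$proteins,
    biomass = as.list(network$biomass),
    biomass_reaction = network$biomass_reaction,
    maintenance = network$maintenance,
    phb = network$phb,
    aa_mass = network$aa_mass)
  # Inf is not representable in strict JSON; encode as the string "inf"
  obj$reactions <- purrr::map(obj$reactions, function(r) {
    r$lb <- if (is.infinite(r$lb)) paste0(ifelse(r$lb < 0, "-", ""), "inf") else r$lb
    r$ub <- if (is.infinite(r$ub)) "inf" else r$ub
    r
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a network from the JSON dialect or SBML
#'
#' @param path input file.
#' @param dialect `"json"` (the package's dialect, see
#'   [write_network_json()]) or `"sbml"` (a Level-3 subset: species,
#'   reactions with stoichiometry, reversibility, optional bounds and gene
#'   associations from fbc gene-product associations or
#'   `GENE_ASSOCIATION:` notes).
#' @param ... passed to the dialect reader ([read_network_sbml()] accepts
#'   protein/biomass/maintenance information absent from plain SBML).
#' @return an [rba_network].
#' @export
read_network <- function(path, dialect = c("json", "sbml"), ...) {
  dialect <- match.arg(dialect)
  switch(dialect, json = read_network_json(path),
         sbml = read_network_sbml(path, ...))
}

#' @rdname read_network
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path)
  num_or_inf <- function(x) {
    if (is.character(x)) ifelse(x == "-inf", -Inf, Inf) else as.numeric(x)
  }
  mets <- dplyr::bind_rows(purrr::map(obj$metabolites, tibble::as_tibble))
  rids <- purrr::map_chr(obj$reactions, "id")
  reactions <- tibble::tibble(
    id = rids,
    reversible = purrr::map_lgl(obj$reactions, "reversible"),
    lb = purrr::map_dbl(obj$reactions, ~ num_or_inf(.x$lb)),
    ub = purrr::map_dbl(obj$reactions, ~ num_or_inf(.x$ub)))
  S <- matrix(0, nrow(mets), length(rids),
              dimnames = list(mets$id, rids))
  for (r in obj$reactions) {
    s <- unlist(r$stoichiometry)
    bad <- setdiff(names(s), mets$id)
    if (length(bad)) stop("reaction '", r$id,
                          "' references unknown metabolite(s): ",
                          paste(bad, collapse = ", "))
    S[names(s), r$id] <- as.numeric(s)
  }
  gpr <- purrr::compact(purrr::map(
    stats::setNames(obj$reactions, rids),
    function(r) {
      if (is.null(r$gpr)) return(NULL)
      purrr::map(r$gpr, ~ unlist(.x))
    }))
  proteins <- dplyr::bind_rows(purrr::map(obj$proteins, tibble::as_tibble))
  rba_network(metabolites = mets, reactions = reactions, S = S, gpr = gpr,
              proteins = proteins, biomass = unlist(obj$biomass),
              biomass_reaction = obj$biomass_reaction,
              maintenance = obj$maintenance, phb = obj$phb,
              aa_mass = obj$aa_mass)
}

sbml_ns <- function(doc) {
  xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
}

parse_gene_association <- function(txt) {
  # "(a and b) or c" -> list(c(a=1, b=1), c(c=1))
  txt <- gsub("[()]", "", txt)
  alts <- strsplit(txt, "\\s+or\\s+")[[1]]
  purrr::map(alts, function(a) {
    genes <- trimws(strsplit(a, "\\s+and\\s+")[[1]])
    genes <- genes[nzchar(genes)]
    stats::setNames(rep(1, length(genes)), genes)
  })
}

#' Read a network from an SBML subset
#'
#' Supports SBML Level 3 core: species (with `boundaryCondition`), reactions
#' with reactant/product stoichiometry and `reversible` flags, flux bounds
#' from fbc `upperFluxBound`/`lowerFluxBound` parameter references when
#' present (defaults applied with a warning otherwise), and gene
#' associations either from fbc `geneProductAssociation` elements or from
#' `GENE_ASSOCIATION:` notes. Protein specifications, biomass composition
#' and maintenance are not part of plain SBML and must be supplied.
#'
#' @param path SBML file.
#' @param proteins protein spec tibble (`id`, `length_aa`, `compartment`);
#'   genes missing from it get `default_length` in the cytoplasm.
#' @param biomass,biomass_reaction,maintenance,phb,aa_mass as in
#'   [rba_network()].
#' @param default_length amino-acid length assumed for unspecified proteins.
#' @return an [rba_network].
#' @export
read_network_sbml <- function(path, proteins = NULL, biomass = NULL,
                              biomass_reaction = NULL, maintenance = NULL,
                              phb = NULL, aa_mass = 110,
                              default_length = 500) {
  doc <- xml2::read_xml(path)
  ns <- sbml_ns(doc)

  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  mets <- tibble::tibble(
    id = xml2::xml_attr(sp, "id"),
    compartment = xml2::xml_attr(sp, "compartment"),
    boundary = xml2::xml_attr(sp, "boundaryCondition") %in% "true")

  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                             xml2::xml_attr(pars, "id"))

  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rx)) stop("no reactions found in ", path)
  n_defaulted <- 0L
  rows <- purrr::map(rx, function(r) {
    id <- xml2::xml_attr(r, "id")
    rev <- xml2::xml_attr(r, "reversible") %in% "true"
    sto <- c()
    for (el in xml2::xml_find_all(r, "./s:listOfReactants/s:speciesReference", ns)) {
      s <- xml2::xml_attr(el, "stoichiometry"); s <- if (is.na(s)) 1 else as.numeric(s)
      if (is.na(s)) stop("malformed stoichiometry in reaction '", id, "'")
      sto[xml2::xml_attr(el, "species")] <- -s
    }
    for (el in xml2::xml_find_all(r, "./s:listOfProducts/s:speciesReference", ns)) {
      s <- xml2::xml_attr(el, "stoichiometry"); s <- if (is.na(s)) 1 else as.numeric(s)
      if (is.na(s)) stop("malformed stoichiometry in reaction '", id, "'")
      sto[xml2::xml_attr(el, "species")] <-
        (if (is.na(sto[xml2::xml_attr(el, "species")])) 0
         else sto[xml2::xml_attr(el, "species")]) + s
    }
    lb_ref <- xml2::xml_attr(r, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(r, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(par_val)) par_val[[lb_ref]]
          else { n_defaulted <<- n_defaulted + 1L; if (rev) -Inf else 0 }
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(par_val)) par_val[[ub_ref]]
          else Inf
    # GPR: fbc geneProductAssociation, else GENE_ASSOCIATION note
    gpa <- xml2::xml_find_first(r, ".//*[local-name()='geneProductAssociation']")
    gpr <- NULL
    if (!inherits(gpa, "xml_missing")) {
      ors <- xml2::xml_find_all(gpa, "./*[local-name()='or']/*")
      if (!length(ors)) ors <- xml2::xml_children(gpa)
      gpr <- purrr::map(ors, function(alt) {
        refs <- if (xml2::xml_name(alt) == "geneProductRef") alt
                else xml2::xml_find_all(alt, ".//*[local-name()='geneProductRef']")
        g <- xml2::xml_attr(refs, "geneProduct")
        stats::setNames(rep(1, length(g)), g)
      })
    } else {
      note <- xml2::xml_find_first(r, ".//*[contains(text(), 'GENE_ASSOCIATION')]")
      if (!inherits(note, "xml_missing")) {
        txt <- sub(".*GENE_ASSOCIATION:\\s*", "", xml2::xml_text(note))
        if (nzchar(trimws(txt))) gpr <- parse_gene_association(txt)
      }
    }
    list(id = id, reversible = rev, lb = lb, ub = ub, sto = sto, gpr = gpr)
  })
  if (n_defaulted > 0) {
    warning(n_defaulted, " reaction(s) without flux bounds; defaults applied")
  }

  rids <- purrr::map_chr(rows, "id")
  reactions <- tibble::tibble(
    id = rids,
    reversible = purrr::map_lgl(rows, "reversible"),
    lb = purrr::map_dbl(rows, "lb"), ub = purrr::map_dbl(rows, "ub"))
  S <- matrix(0, nrow(mets), length(rids), dimnames = list(mets$id, rids))
  for (r in rows) {
    bad <- setdiff(names(r$sto), mets$id)
    if (length(bad)) stop("reaction '", r$id, "' references unknown ",
                          "species: ", paste(bad, collapse = ", "))
    S[names(r$sto), r$id] <- r$sto
  }
  gpr <- purrr::compact(purrr::map(stats::setNames(rows, rids), "gpr"))

  genes <- unique(unlist(purrr::map(gpr, ~ unlist(purrr::map(.x, names)))))
  if (is.null(proteins)) {
    proteins <- tibble::tibble(id = character(), length_aa = numeric(),
                               compartment = character())
  }
  missing <- setdiff(genes, proteins$id)
  if (length(missing)) {
    proteins <- dplyr::bind_rows(
      proteins, tibble::tibble(id = missing, length_aa = default_length,
                               compartment = "cytoplasm"))
  }
  if (is.null(biomass_reaction)) {
    guess <- grep("biomass", rids, ignore.case = TRUE, value = TRUE)
    if (!length(guess)) stop("no biomass reaction found or supplied")
    biomass_reaction <- guess[1]
  }
  if (is.null(biomass)) {
    s <- S[, biomass_reaction]
    biomass <- -s[s < 0]
  }
  if (is.null(maintenance)) {
    maintenance <- list(reaction = NA_character_, ngam = 0, gam = 0)
  }
  net <- rba_network(metabolites = mets, reactions = reactions, S = S,
                     gpr = gpr, proteins = proteins, biomass = biomass,
                     biomass_reaction = biomass_reaction,
                     maintenance = maintenance, phb = phb, aa_mass = aa_mass)
  net
}

#' Write a network as SBML (Level 3 core subset)
#'
#' Species, compartments, reactions with stoichiometry and bound parameters,
#' and gene associations as `GENE_ASSOCIATION:` notes.
#'
#' @param network an [rba_network].
#' @param path output file.
#' @param model_id model identifier.
#' @return `path`, invisibly.
#' @export
write_network_sbml <- function(network, path, model_id = "model") {
  esc <- function(x) gsub("&", "&amp;", x)
  rxn <- network$reactions
  cmpts <- unique(network$metabolites$compartment)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    sprintf('  <model id="%s">', esc(model_id)),
    '    <listOfCompartments>',
    sprintf('      <compartment id="%s" constant="true"/>', cmpts),
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  m <- network$metabolites
  lines <- c(lines, sprintf(
    '      <species id="%s" compartment="%s" boundaryCondition="%s" hasOnlySubstanceUnits="false" constant="false"/>',
    m$id, m$compartment, tolower(as.character(m$boundary))),
    '    </listOfSpecies>',
    '    <listOfParameters>')
  bnd_par <- function(i, side) {
    v <- if (side == "lb") rxn$lb[i] else rxn$ub[i]
    sprintf('      <parameter id="%s_%s" value="%s" constant="true"/>',
            side, rxn$id[i],
            ifelse(is.infinite(v), ifelse(v < 0, "-INF", "INF"), v))
  }
  lines <- c(lines, vapply(seq_len(nrow(rxn)), bnd_par, "", side = "lb"),
             vapply(seq_len(nrow(rxn)), bnd_par, "", side = "ub"),
             '    </listOfParameters>',
             '    <listOfReactions>')
  for (i in seq_len(nrow(rxn))) {
    r <- rxn$id[i]
    s <- network$S[, r]
    reac <- s[s < 0]; prod <- s[s > 0]
    lines <- c(lines, sprintf(
      '      <reaction id="%s" reversible="%s" fast="false" lowerFluxBound="lb_%s" upperFluxBound="ub_%s">',
      r, tolower(as.character(rxn$reversible[i])), r, r))
    if (r %in% names(network$gpr)) {
      ga <- paste(vapply(network$gpr[[r]], function(a) {
        paste0("(", paste(names(a), collapse = " and "), ")")
      }, ""), collapse = " or ")
      lines <- c(lines,
        '        <notes><body xmlns="http://www.w3.org/1999/xhtml">',
        sprintf('          <p>GENE_ASSOCIATION: %s</p>', esc(ga)),
        '        </body></notes>')
    }
    if (length(reac)) {
      lines <- c(lines, '        <listOfReactants>', sprintf(
        '          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
        names(reac), -as.numeric(reac)), '        </listOfReactants>')
    }
    if (length(prod)) {
      lines <- c(lines, '        <listOfProducts>', sprintf(
        '          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
        names(prod), as.numeric(prod)), '        </listOfProducts>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>', '  </model>', '</sbml>')
  writeLines(lines, path)
  invisible(path)
}

#' Write and read tab-separated tables
#'
#' Plain TSV with a header row, the exchange format for all tabular results.
#'
#' @param x data frame.
#' @param path file path.
#' @return `path` (write) or a tibble (read).
#' @export
write_tsv_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  tibble::as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' Default pipeline configuration
#'
#' A nested list of every parameter of the end-to-end synthetic pipeline,
#' with the defaults used throughout the package. Override entries before
#' passing to [run_pipeline()].
#'
#' @param seed master seed; stage seeds are derived from it.
#' @param out_dir optional output directory; when set, each stage writes its
#'   table(s) plus a JSON run manifest.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = NULL) {
  list(
    seed = as.integer(seed), out_dir = out_dir,
    network = list(n_substrates = 3, include_cbb = TRUE, include_phb = TRUE),
    proteome = list(noise_cv = 0.1, n_replicates = 4),
    sampling = list(n_samples = 300, warmup = 100),
    ensemble = list(n_draws = 0),
    utilization = list(t_low = 33, t_high = 66),
    essentiality = list(n_genes = 500, frac_essential = 0.1,
                        mean_rate = 15, essential_rate_ratio = 0.02,
                        window_genes = 100, fold = 5, central_fraction = 0.8),
    fitness = list(mutants_per_gene = 6, depth = 1e6,
                   generations = c(0, 8, 16), n_affected = 30,
                   pseudocount = 0.5, threshold = 3, min_generations = 8),
    tolerances = list(flux_tol = 1e-6, tol_mu = 1e-4))
}

#' Run the end-to-end synthetic pipeline
#'
#' Generates the toy model and synthetic data, then runs every analysis
#' stage: chemostat RBA solutions per condition, flux sampling, k_app
#' calibration, (optionally) the randomized-k_app ensemble with
#' utilized-reaction bookkeeping, enzyme utilization scoring, insertion-index
#' essentiality classification, and BarSeq fitness scoring. With
#' `config$out_dir` set, one TSV per stage plus a JSON manifest (seed,
#' parameters, configuration hash) are written.
#'
#' @param config a [pipeline_config()] list.
#' @return named list with the per-stage results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  if (!is.null(cfg$out_dir) && !dir.exists(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE)
  }
  seed <- cfg$seed

  net <- gen_toy_network(toy_network_config(
    n_substrates = cfg$network$n_substrates,
    include_cbb = cfg$network$include_cbb,
    include_phb = cfg$network$include_phb, seed = seed))
  kapp_true <- as_kapp_table(attr(net, "kapp_true"))
  mach <- toy_machineries(); bud <- toy_budgets()
  conds <- toy_conditions(net)

  # chemostat steady states and synthetic proteomes
  sols <- purrr::map(conds, function(cc)
    chemostat_solution(net, mach, bud, kapp_true, cc))
  proteomes <- purrr::imap(sols, function(sol, cn) {
    gen_proteome(sol, net, noise_cv = cfg$proteome$noise_cv,
                 n_replicates = cfg$proteome$n_replicates,
                 seed = seed + match(cn, names(conds)))
  })
  proteome_tbl <- dplyr::bind_rows(proteomes)

  # flux sampling with observed uptake pinned, then calibration
  samples <- purrr::imap(conds, function(cc, cn) {
    sample_flux_space(net, cc, n_samples = cfg$sampling$n_samples,
                      warmup = cfg$sampling$warmup,
                      seed = seed + 10 + match(cn, names(conds)),
                      fixed_fluxes = sols[[cn]]$flux[names(cc$uptake)])
  })
  kapp_est <- estimate_kapp(samples, proteome_tbl, net,
                            flux_tol = cfg$tolerances$flux_tol)

  ensemble_summary <- NULL
  if (cfg$ensemble$n_draws > 0) {
    draws <- sample_kapp_ensemble(kapp_est, n = cfg$ensemble$n_draws,
                                  seed = seed + 20)
    ens_sols <- purrr::map(conds, function(cc) {
      purrr::map(draws, function(kt) {
        maximize_growth(net, mach, bud, kt, cc,
                        tol_mu = cfg$tolerances$tol_mu)
      })
    })
    ensemble_summary <- count_utilized_reactions(
      ens_sols, flux_tol = cfg$tolerances$flux_tol)
  }

  # utilization against the minimal predicted allocation
  util <- purrr::imap(sols, function(sol, cn) {
    pred <- stats::setNames(sol$enzymes$conc, sol$enzymes$enzyme)
    meas <- enzyme_measured_conc(proteomes[[cn]], net)
    compute_utilization(pred, meas, condition = cn)
  }) |> dplyr::bind_rows()
  util_cat <- categorize_utilization(util, t_low = cfg$utilization$t_low,
                                     t_high = cfg$utilization$t_high)

  # essentiality
  ess_cfg <- cfg$essentiality
  lib <- gen_insertion_library(
    n_genes = ess_cfg$n_genes, frac_essential = ess_cfg$frac_essential,
    mean_rate = ess_cfg$mean_rate,
    essential_rate_ratio = ess_cfg$essential_rate_ratio, seed = seed + 30)
  gtab <- insertion_index(
    recount_insertions(lib$genes,
                       central_orf_filter(lib$insertions,
                                          ess_cfg$central_fraction)),
    window_genes = ess_cfg$window_genes)
  fit <- fit_gamma_mixture(gtab$ii_smooth)
  calls <- classify_essentiality(gtab, fit, fold = ess_cfg$fold)

  # fitness
  fit_cfg <- cfg$fitness
  n_aff <- fit_cfg$n_affected
  f_true <- stats::setNames(
    c(rep(c(-6, -4, -2), each = ceiling(n_aff / 3)),
      rep(0, ess_cfg$n_genes - 3 * ceiling(n_aff / 3))),
    paste0("g", seq_len(ess_cfg$n_genes)))
  bc <- gen_barcode_counts(f_true, mutants_per_gene = fit_cfg$mutants_per_gene,
                           depth = fit_cfg$depth,
                           generations = fit_cfg$generations,
                           seed = seed + 40)
  scores <- significance_call(
    gene_fitness(bc$counts, bc$samples, pseudocount = fit_cfg$pseudocount),
    threshold = fit_cfg$threshold,
    min_generations = fit_cfg$min_generations)

  out <- list(network = net, solutions = sols, proteomes = proteome_tbl,
              kapp = kapp_est, ensemble = ensemble_summary,
              utilization = util, utilization_categories = util_cat,
              essentiality = calls, fitness = scores,
              config = cfg)

  if (!is.null(cfg$out_dir)) {
    od <- cfg$out_dir
    write_network_json(net, file.path(od, "network.json"))
    write_tsv_table(proteome_tbl, file.path(od, "proteome.tsv"))
    write_tsv_table(kapp_est, file.path(od, "kapp.tsv"))
    write_tsv_table(util, file.path(od, "utilization.tsv"))
    write_tsv_table(util_cat, file.path(od, "utilization_categories.tsv"))
    write_tsv_table(dplyr::select(calls, -dplyr::any_of("ii_flag")),
                    file.path(od, "essentiality.tsv"))
    write_tsv_table(scores, file.path(od, "fitness.tsv"))
    flux_tbl <- purrr::imap_dfr(sols, function(s, cn)
      dplyr::mutate(tidy(s), condition = cn, .before = 1))
    write_tsv_table(flux_tbl, file.path(od, "rba_solutions.tsv"))
    manifest <- list(
      package = "rbalance",
      version = as.character(utils::packageVersion("rbalance")),
      seed = seed, config = cfg[setdiff(names(cfg), "out_dir")],
      config_hash = rlang::hash(cfg[setdiff(names(cfg), "out_dir")]),
      mu = purrr::map_dbl(sols, "mu"))
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Measured enzyme concentration per enzyme alternative
#'
#' Maps a protein-level proteome back onto enzyme alternatives: each
#' protein's measured abundance is split equally among the reactions using
#' it, and an alternative's concentration is the minimum over its subunits
#' of allocated abundance per required copy. Replicates are averaged.
#'
#' @param proteome tibble as from [gen_proteome()] (one condition).
#' @param network the [rba_network].
#' @return named numeric, enzyme alternative id -> mmol gDCW^-1.
#' @export
enzyme_measured_conc <- function(proteome, network) {
  enz <- enzyme_table(network)
  pm <- proteome |>
    dplyr::filter(.data$type == "protein") |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(conc = mean(.data$conc_mmol_gdcw))
  prot_use <- purrr::map_dfr(seq_len(nrow(enz)), function(i) {
    tibble::tibble(id = names(enz$genes[[i]]), reaction = enz$reaction[i])
  }) |> dplyr::distinct()
  n_shared <- prot_use |> dplyr::count(.data$id, name = "n_rxn")
  share <- pm |>
    dplyr::left_join(n_shared, by = "id") |>
    dplyr::mutate(share = .data$conc / pmax(.data$n_rxn, 1))
  out <- vapply(seq_len(nrow(enz)), function(i) {
    comp <- enz$genes[[i]]
    av <- share$share[match(names(comp), share$id)]
    if (anyNA(av)) return(NA_real_)
    min(av / as.numeric(comp))
  }, numeric(1))
  stats::setNames(out, enz$enzyme)[!is.na(out)]
}
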
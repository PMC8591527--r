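# run code with a temporary RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# constraint system of the metabolic (FBA-level) flux polytope at a chemostat
# steady state: S v = 0, biomass (and storage demand) fixed to the dilution
# rate, maintenance lower-bounded, uptake bounded or pinned. Returns the
# system in shifted non-negative coordinates u = v - lb plus the affine
# parametrization pieces used by the sampler.
flux_polytope <- function(network, condition, dilution = condition$dilution,
                          fixed_fluxes = NULL, big_m = 1000) {
  if (is.na(dilution)) stop("condition has no dilution rate to fix growth at")
  rxn <- network$reactions
  n <- nrow(rxn)
  lb <- ifelse(rxn$reversible, pmax(rxn$lb, -big_m), pmax(rxn$lb, 0))
  ub <- pmin(rxn$ub, big_m)

  importers <- substrate_importers(network)
  for (r in importers) {
    ub[rxn$id == r] <- if (r %in% names(condition$uptake))
      condition$uptake[[r]] else 0
  }
  for (r in condition$closed) ub[rxn$id == r] <- 0

  S_int <- network$S[!network$metabolites$boundary, , drop = FALSE]
  A_eq <- S_int
  rhs_eq <- numeric(nrow(S_int))

  pin <- c(stats::setNames(dilution, network$biomass_reaction),
           if (!is.null(network$phb))
             stats::setNames(network$phb$per_mu * dilution,
                             network$phb$reaction),
           fixed_fluxes)
  for (r in names(pin)) {
    row <- numeric(n); row[rxn$id == r] <- 1
    A_eq <- rbind(A_eq, row)
    rhs_eq <- c(rhs_eq, pin[[r]])
  }

  mnt <- network$maintenance
  if (!is.null(mnt) && !is.na(mnt$reaction)) {
    mnt_lb <- mnt$ngam + mnt$gam * dilution
    lb[rxn$id == mnt$reaction] <- pmax(lb[rxn$id == mnt$reaction], mnt_lb)
  }

  if (any(lb > ub + 1e-12)) stop("inconsistent flux bounds under condition")
  list(A_eq = A_eq, rhs_eq = rhs_eq, lb = lb, ub = ub, rxn_id = rxn$id)
}

# LP over the flux polytope in shifted coordinates; obj on net fluxes
polytope_lp <- function(poly, obj, maximize) {
  n <- length(poly$lb)
  A <- rbind(poly$A_eq, diag(n))
  dir <- c(rep("==", nrow(poly$A_eq)), rep("<=", n))
  rhs <- c(poly$rhs_eq - as.numeric(poly$A_eq %*% poly$lb), poly$ub - poly$lb)
  res <- solve_lp(obj, A, dir, rhs, maximize = maximize)
  if (res$status == "optimal") res$flux <- res$solution + poly$lb
  res
}

#' Flux variability analysis
#'
#' Minimum and maximum net flux per reaction over the metabolic flux polytope
#' at a chemostat steady state (growth fixed to the condition's dilution
#' rate).
#'
#' @param network an [rba_network].
#' @param condition a [growth_condition] with a dilution rate.
#' @param dilution growth rate to fix; defaults to the condition's.
#' @param fixed_fluxes optional named numeric of net fluxes to pin (e.g. the
#'   observed substrate uptake rate of the chemostat).
#' @param big_m cap for bounds that are infinite in the model.
#' @return tibble `reaction`, `min`, `max`.
#' @export
fva <- function(network, condition, dilution = condition$dilution,
                fixed_fluxes = NULL, big_m = 1000) {
  poly <- flux_polytope(network, condition, dilution, fixed_fluxes, big_m)
  n <- length(poly$lb)
  out <- purrr::map_dfr(seq_len(n), function(i) {
    obj <- numeric(n); obj[i] <- 1
    lo <- polytope_lp(poly, obj, maximize = FALSE)
    hi <- polytope_lp(poly, obj, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("flux polytope infeasible under condition '", condition$name, "'")
    }
    tibble::tibble(reaction = poly$rxn_id[i],
                   min = lo$flux[i], max = hi$flux[i])
  })
  out
}

#' Sample the feasible flux polytope
#'
#' Hit-and-run sampling of the metabolic flux space at a chemostat steady
#' state, emulating flux sampling analysis: starting from a Chebyshev-like
#' interior point, random directions are drawn in the null space of the
#' equality system and a uniform step is taken inside the box bounds.
#'
#' @inheritParams fva
#' @param n_samples number of samples to keep.
#' @param seed RNG seed (fixed seed gives an identical sample matrix).
#' @param warmup discarded leading iterations.
#' @param thin keep every `thin`-th iterate.
#' @return object of class `flux_samples`: `samples` (n_samples x reactions
#'   matrix of net fluxes), `envelope` (per-reaction min/max tibble),
#'   `condition`, `dilution`.
#' @export
sample_flux_space <- function(network, condition, n_samples = 1000,
                              seed = 1L, dilution = condition$dilution,
                              fixed_fluxes = NULL, warmup = 100, thin = 2,
                              big_m = 1000) {
  poly <- flux_polytope(network, condition, dilution, fixed_fluxes, big_m)
  n <- length(poly$lb)

  # FVA pass: identify reactions pinned by the constraint system, and use the
  # average of the FVA vertex solutions as a relative-interior start point
  verts <- matrix(NA_real_, 2 * n, n)
  for (i in seq_len(n)) {
    obj <- numeric(n); obj[i] <- 1
    lo <- polytope_lp(poly, obj, maximize = FALSE)
    hi <- polytope_lp(poly, obj, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("flux polytope infeasible under condition '", condition$name, "'")
    }
    verts[2 * i - 1, ] <- lo$flux; verts[2 * i, ] <- hi$flux
  }
  width <- apply(verts, 2, function(z) diff(range(z)))
  pinned <- width < 1e-9
  v0 <- colMeans(verts)

  # treat pinned reactions as equalities so null-space moves never touch them
  A_eq <- poly$A_eq
  for (i in which(pinned)) {
    row <- numeric(n); row[i] <- 1
    A_eq <- rbind(A_eq, row)
  }
  N <- MASS::Null(t(A_eq))
  keep <- matrix(NA_real_, n_samples, n,
                 dimnames = list(NULL, poly$rxn_id))

  if (ncol(N) == 0L) {
    # zero-dimensional (fully determined) steady state
    for (i in seq_len(n_samples)) keep[i, ] <- v0
  } else {
    with_seed(seed, {
      v <- v0
      total <- warmup + n_samples * thin
      kept <- 0L
      for (it in seq_len(total)) {
        p <- as.numeric(N %*% rnorm(ncol(N)))
        nz <- abs(p) > 1e-12
        if (any(nz)) {
          hi_t <- (poly$ub[nz] - v[nz]) / p[nz]
          lo_t <- (poly$lb[nz] - v[nz]) / p[nz]
          t_max <- min(pmax(hi_t, lo_t))
          t_min <- max(pmin(hi_t, lo_t))
          if (t_max > t_min) {
            v <- v + runif(1, t_min, t_max) * p
            v <- pmin(pmax(v, poly$lb), poly$ub)
          }
        }
        if (it > warmup && (it - warmup) %% thin == 0) {
          kept <- kept + 1L
          keep[kept, ] <- v
        }
      }
    })
  }

  envelope <- tibble::tibble(
    reaction = poly$rxn_id,
    min = apply(keep, 2, min),
    max = apply(keep, 2, max))

  structure(list(samples = keep, envelope = envelope,
                 condition = condition$name, dilution = dilution),
            class = "flux_samples")
}

#' @export
print.flux_samples <- function(x, ...) {
  cat("<flux_samples>", nrow(x$samples), "samples x", ncol(x$samples),
      "reactions | condition:", x$condition, "at D =", x$dilution, "\n")
  invisible(x)
}
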
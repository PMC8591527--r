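# shared fixtures, built in code and memoized for the session

toy_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      net <- gen_toy_network()
      cache <<- list(
        net = net,
        kapp = as_kapp_table(attr(net, "kapp_true")),
        kapp_true = attr(net, "kapp_true"),
        mach = toy_machineries(),
        bud = toy_budgets(),
        conds = toy_conditions(net))
    }
    cache
  }
})

# the hand-solvable single-reaction instance: one uptake reaction
# (k_app = 100 hr^-1, enzyme 1000 aa), biomass draws 1 mmol X per gDCW,
# protein budget 1 mmol aa gDCW^-1, machineries disabled.
# max flux = 100 * (1 / 1000) = 0.1  =>  mu_max = 0.1 hr^-1
t1_instance <- function() {
  mets <- tibble::tibble(
    id = c("s_e", "x", "biomass_e"),
    compartment = c("e", "c", "e"),
    boundary = c(TRUE, FALSE, TRUE),
    carbon = c(1, 1, 1), electrons = c(4, 4, 4), mw_g_mol = c(100, 100, 100))
  S <- matrix(0, 3, 2, dimnames = list(mets$id, c("UPT", "BIOMASS")))
  S["s_e", "UPT"] <- -1; S["x", "UPT"] <- 1
  S["x", "BIOMASS"] <- -1; S["biomass_e", "BIOMASS"] <- 1
  net <- rba_network(
    metabolites = mets,
    reactions = tibble::tibble(id = c("UPT", "BIOMASS"),
                               reversible = FALSE, lb = 0, ub = Inf),
    S = S,
    gpr = list(UPT = list(c(g1 = 1))),
    proteins = tibble::tibble(id = "g1", length_aa = 1000,
                              compartment = "cytoplasm"),
    biomass = c(x = 1), biomass_reaction = "BIOMASS",
    maintenance = list(reaction = NA_character_, ngam = 0, gam = 0))
  list(net = net,
       kapp = kapp_table("UPT", kapp_hr = 100),
       mach = toy_machineries()[0, ],
       bud = budget_spec("cytoplasm", pool = 1, fraction_intercept = 1),
       cond = growth_condition("t1", c(UPT = 100)))
}

# independent brute-force LP oracle: enumerate basic solutions of the
# slack-augmented system; returns feasibility and the optimal objective
brute_lp <- function(obj, A, dir, rhs) {
  m <- nrow(A); n <- ncol(A)
  sl <- diag(m)
  sl[dir == ">=", ] <- -sl[dir == ">=", , drop = FALSE]
  sl <- sl[, dir != "==", drop = FALSE]
  Afull <- cbind(A, sl); nf <- ncol(Afull)
  if (nf < m) return(list(feasible = NA, value = NA))
  best <- Inf; feasible <- FALSE
  for (cols in utils::combn(nf, m, simplify = FALSE)) {
    B <- Afull[, cols, drop = FALSE]
    if (abs(det(B)) < 1e-10) next
    x <- tryCatch(solve(B, rhs), error = function(e) NULL)
    if (is.null(x) || any(x < -1e-8)) next
    xx <- numeric(nf); xx[cols] <- x
    feasible <- TRUE
    best <- min(best, sum(obj * xx[seq_len(n)]))
  }
  list(feasible = feasible, value = best)
}

# feasibility of an rba_problem checked by the brute-force oracle
brute_feasible <- function(problem) {
  isTRUE(brute_lp(numeric(ncol(problem$A)), problem$A, problem$dir,
                  problem$rhs)$feasible)
}
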
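#' Chemostat substrate uptake rate
#'
#' `q_S = D * (S_i - S_r) / c_bm`: dilution rate times consumed substrate
#' concentration per biomass concentration (per-volume convention, the
#' culture volume cancels).
#'
#' @param records tibble with columns `dilution` (hr^-1), `feed_g_l`,
#'   `residual_g_l`, `biomass_g_l`.
#' @return `records` with `q_s` (g substrate gDCW^-1 hr^-1) added.
#' @export
substrate_uptake_rate <- function(records) {
  stopifnot(all(records$biomass_g_l > 0), all(records$dilution > 0),
            all(records$residual_g_l <= records$feed_g_l))
  dplyr::mutate(records,
                q_s = .data$dilution * (.data$feed_g_l - .data$residual_g_l) /
                  .data$biomass_g_l)
}

#' Biomass yield and maintenance from the growth-uptake relationship
#'
#' Ordinary least squares of substrate uptake on growth rate:
#' `q_S = mu / Y + m`. The inverse slope is the biomass yield (gDCW per g
#' substrate) and the intercept the maintenance consumption.
#'
#' @param data tibble with columns `mu` and `q_s`.
#' @return one-row tibble `yield_gdw_per_g`, `maintenance`, `slope`,
#'   `r_squared`, `slope_se`.
#' @export
fit_yield <- function(data) {
  if (dplyr::n_distinct(data$mu) < 2) stop("need >= 2 distinct growth rates")
  fit <- lm(q_s ~ mu, data = data)
  sm <- suppressWarnings(summary(fit))  # exact fits are expected inputs
  slope <- coef(fit)[["mu"]]
  if (slope == 0) stop("zero slope: yield undefined")
  tibble::tibble(yield_gdw_per_g = 1 / slope,
                 maintenance = coef(fit)[["(Intercept)"]],
                 slope = slope, r_squared = sm$r.squared,
                 slope_se = sm$coefficients["mu", "Std. Error"])
}

#' Convert a protein mass pool to amino-acid moles
#'
#' `pool = protein_mass * 1000 / mean_residue_mass`; with the default mean
#' residue mass of 110 g mol^-1, 0.68 g protein gDCW^-1 becomes 6.18 mmol
#' amino acids gDCW^-1.
#'
#' @param protein_mass g protein per gDCW.
#' @param mean_residue_mass g mol^-1 per amino acid.
#' @return mmol amino acids gDCW^-1.
#' @export
protein_pool_mmol <- function(protein_mass, mean_residue_mass = 110) {
  stopifnot(all(protein_mass >= 0), mean_residue_mass > 0)
  protein_mass * 1000 / mean_residue_mass
}

#' Chemostat retention time
#'
#' `t_R = 1/D`; steady-state samples are conventionally taken after five
#' retention times of continuous growth.
#'
#' @param dilution dilution rate D, hr^-1 (> 0).
#' @return tibble `dilution`, `retention_hr`, `five_retention_hr`.
#' @export
retention_time <- function(dilution) {
  if (any(dilution <= 0)) stop("dilution rate must be > 0")
  tibble::tibble(dilution = dilution, retention_hr = 1 / dilution,
                 five_retention_hr = 5 / dilution)
}

#' Growth-rate-dependent compartment fraction model
#'
#' Least-squares line of a compartment's proteome mass fraction against
#' growth rate; feeds [budget_spec()]. Predictions are clipped to [0, 1]
#' with a warning when clipping occurs.
#'
#' @param data tibble with columns `mu` and `fraction` (in [0, 1]).
#' @return one-row tibble `intercept`, `slope`, `r_squared` with a
#'   `predict` function attribute.
#' @export
compartment_fraction_fit <- function(data) {
  stopifnot(all(data$fraction >= 0), all(data$fraction <= 1))
  if (dplyr::n_distinct(data$mu) < 2) stop("need >= 2 distinct growth rates")
  fit <- lm(fraction ~ mu, data = data)
  out <- tibble::tibble(intercept = coef(fit)[["(Intercept)"]],
                        slope = coef(fit)[["mu"]],
                        r_squared = suppressWarnings(summary(fit))$r.squared)
  attr(out, "predict") <- function(mu) {
    p <- out$intercept + out$slope * mu
    if (any(p < 0 | p > 1)) {
      warning("compartment fraction prediction clipped to [0, 1]")
      p <- pmin(pmax(p, 0), 1)
    }
    p
  }
  out
}
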
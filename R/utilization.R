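#' Enzyme utilization from predicted-minimal vs measured abundance
#'
#' Utilization of an enzyme is the model-predicted minimal required
#' abundance divided by the experimentally measured abundance, in percent:
#' `U_E = predicted / measured * 100`. Values far below 100% flag expressed
#' but under-used enzyme; values above 100% (over-unity) signal calibration
#' error and are retained and flagged, not capped.
#'
#' @param predicted named numeric: enzyme -> predicted minimal concentration.
#' @param measured named numeric: enzyme -> measured concentration (same
#'   units as `predicted`).
#' @param condition optional condition label stored in the output.
#' @return tibble `enzyme`, `condition`, `predicted`, `measured`,
#'   `utilization_pct`, `status` (`"ok"`, `"measured_only"` for measured
#'   enzymes absent from predictions (U = 0), `"unmeasured"` for predicted
#'   but unmeasured enzymes (U = NA), `"undefined"` for measured = 0 with
#'   predicted > 0).
#' @export
compute_utilization <- function(predicted, measured,
                                condition = NA_character_) {
  ids <- union(names(predicted), names(measured))
  p <- stats::setNames(rep(0, length(ids)), ids)
  p[names(predicted)] <- predicted
  m_here <- ids %in% names(measured)
  m <- stats::setNames(rep(NA_real_, length(ids)), ids)
  m[names(measured)] <- measured

  status <- dplyr::case_when(
    !m_here & p > 0 ~ "unmeasured",
    m_here & !is.na(m) & m == 0 & p > 0 ~ "undefined",
    !ids %in% names(predicted) | p == 0 ~ "measured_only",
    TRUE ~ "ok")
  util <- ifelse(status %in% c("unmeasured", "undefined"), NA_real_,
                 ifelse(status == "measured_only" & (is.na(m) | m == 0), 0,
                        p / m * 100))
  tibble::tibble(enzyme = ids, condition = condition, predicted = p,
                 measured = as.numeric(m), utilization_pct = util,
                 status = status)
}

#' Categorize enzymes by mean utilization
#'
#' Mean utilization across the designated conditions sorts each enzyme into
#' low (mean <= `t_low`), moderate (`t_low` < mean <= `t_high`) or high
#' (mean > `t_high`) utilization; both boundaries are inclusive on the lower
#' category. Over-unity means (> 100%) are flagged.
#'
#' @param records tibble from [compute_utilization()], possibly several
#'   conditions row-bound.
#' @param t_low,t_high category boundaries in percent.
#' @return tibble `enzyme`, `mean_utilization`, `category`, `over_unity`,
#'   `n_conditions`.
#' @export
categorize_utilization <- function(records, t_low = 33, t_high = 66) {
  stopifnot(t_low <= t_high)
  records |>
    dplyr::filter(!is.na(.data$utilization_pct)) |>
    dplyr::group_by(.data$enzyme) |>
    dplyr::summarise(mean_utilization = mean(.data$utilization_pct),
                     n_conditions = dplyr::n()) |>
    dplyr::mutate(
      category = dplyr::case_when(
        .data$mean_utilization <= t_low ~ "low",
        .data$mean_utilization <= t_high ~ "moderate",
        TRUE ~ "high"),
      category = factor(.data$category, levels = c("low", "moderate", "high")),
      over_unity = .data$mean_utilization > 100)
}

#' Cross-condition abundance variability
#'
#' Coefficient of variation (sample standard deviation / mean) of the
#' per-condition mean abundance of each enzyme or protein.
#'
#' @param measured tibble with columns `id`, `condition` and an abundance
#'   column named by `value`.
#' @param value abundance column name.
#' @return tibble `id`, `cv`, `n_conditions`, `flag` (`"zero_mean"` when the
#'   CV is undefined).
#' @export
abundance_variability <- function(measured, value = "conc_mmol_gdcw") {
  per_cond <- measured |>
    dplyr::group_by(.data$id, .data$condition) |>
    dplyr::summarise(abund = mean(.data[[value]]), .groups = "drop")
  n_cond <- dplyr::n_distinct(per_cond$condition)
  if (n_cond < 2) stop("abundance variability needs >= 2 conditions")
  per_cond |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      cv = ifelse(mean(.data$abund) > 0,
                  sd(.data$abund) / mean(.data$abund), NA_real_),
      n_conditions = dplyr::n()) |>
    dplyr::mutate(flag = ifelse(is.na(.data$cv), "zero_mean", "ok"))
}

#' Machinery utilization
#'
#' The utilization ratio applied to macromolecular machines: predicted
#' machine concentration from the RBA solution divided by the measured
#' concentration, in percent. A measured ribosome reserve (measured above
#' the predicted requirement) shows up as utilization below 100%.
#'
#' @param solution an `rba_solution`.
#' @param measured_machinery named numeric: machinery id -> measured
#'   concentration (mmol gDCW^-1).
#' @return tibble `machinery`, `mu`, `predicted`, `measured`,
#'   `utilization_pct`, `status`.
#' @export
machinery_utilization <- function(solution, measured_machinery) {
  stopifnot(solution$status == "feasible")
  pred <- stats::setNames(solution$machinery$conc,
                          solution$machinery$machinery)
  out <- compute_utilization(pred, measured_machinery,
                             condition = solution$condition)
  out |>
    dplyr::rename(machinery = "enzyme") |>
    dplyr::mutate(mu = solution$mu, .after = "machinery") |>
    dplyr::select(-"condition")
}
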
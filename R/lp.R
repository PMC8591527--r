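#' Solve a linear program
#'
#' Standard `min/max c'x  s.t.  A x (<=|>=|==) b, x >= 0` interface over the
#' package's dense two-phase simplex (see `R/simplex.R`). Bland's rule makes
#' the solve immune to cycling on the degenerate equality blocks that RBA
#' problems produce.
#'
#' @param obj objective coefficient vector.
#' @param A constraint matrix (dense), one row per constraint.
#' @param dir character vector of `"<="`, `">="`, `"=="` per row.
#' @param rhs right-hand side vector.
#' @param maximize maximize instead of minimize?
#' @param tol pivoting / feasibility tolerance.
#'
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"` or
#'   `"iteration_limit"`), `solution` (named numeric, only when optimal) and
#'   `objective`.
#' @keywords internal
solve_lp <- function(obj, A, dir, rhs, maximize = FALSE, tol = 1e-9) {
  stopifnot(length(dir) == nrow(A), length(rhs) == nrow(A),
            length(obj) == ncol(A))
  bad <- !dir %in% c("<=", ">=", "==")
  if (any(bad)) stop("unknown constraint direction: ", dir[bad][1])
  res <- simplex_core(obj, A, dir, rhs, maximize = maximize, tol = tol)
  if (res$status == "optimal" && !is.null(colnames(A))) {
    names(res$solution) <- colnames(A)
  }
  res
}
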
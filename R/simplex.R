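# Dense two-phase primal simplex.
#
# Written in-package because no installed LP backend copes with the highly
# degenerate equality blocks of RBA problems (many zero right-hand sides keep
# artificial variables basic at level zero). Bland's rule throughout rules
# out cycling; redundant rows left over from phase 1 are dropped.

simplex_core <- function(obj, A, dir, rhs, maximize = FALSE, tol = 1e-9,
                         max_iter = NULL) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(dir) == m, length(rhs) == m, length(obj) == n)
  if (maximize) obj <- -obj

  # normalize to rhs >= 0
  flip <- rhs < 0
  if (any(flip)) {
    A[flip, ] <- -A[flip, , drop = FALSE]
    rhs[flip] <- -rhs[flip]
    dir[flip] <- c("<=" = ">=", ">=" = "<=", "==" = "==")[dir[flip]]
  }

  i_le <- which(dir == "<="); i_ge <- which(dir == ">=")
  n_sl <- length(i_le); n_su <- length(i_ge)
  need_art <- sort(c(i_ge, which(dir == "==")))
  n_art <- length(need_art)

  # columns: structural | slack | surplus | artificial
  Tm <- matrix(0, m, n + n_sl + n_su + n_art)
  Tm[, 1:n] <- A
  if (n_sl) Tm[cbind(i_le, n + seq_len(n_sl))] <- 1
  if (n_su) Tm[cbind(i_ge, n + n_sl + seq_len(n_su))] <- -1
  if (n_art) Tm[cbind(need_art, n + n_sl + n_su + seq_len(n_art))] <- 1
  b <- rhs
  ntot <- ncol(Tm)
  art_cols <- if (n_art) n + n_sl + n_su + seq_len(n_art) else integer()

  # starting basis: slack for <=, artificial for >= and ==
  basis <- integer(m)
  basis[i_le] <- n + seq_len(n_sl)
  basis[need_art] <- art_cols

  cost2 <- c(obj, numeric(ntot - n))             # phase-2 costs
  cost1 <- numeric(ntot); cost1[art_cols] <- 1   # phase-1 costs

  reduce <- function(cost) {
    cb <- cost[basis]
    as.numeric(cost - crossprod(Tm, cb))
  }

  if (is.null(max_iter)) max_iter <- 2000L + 50L * (m + n)

  run_phase <- function(cost, phase) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) return("iteration_limit")
      r <- reduce(cost)
      if (phase == 1) r[art_cols] <- pmax(r[art_cols], 0)  # never re-enter
      enter <- which(r < -tol)
      if (!length(enter)) return("optimal")
      j <- enter[1]                                        # Bland: lowest index
      col <- Tm[, j]
      pos <- which(col > tol)
      if (!length(pos)) return("unbounded")
      ratio <- b[pos] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + tol]
      i <- cand[which.min(basis[cand])]                    # Bland on leaving
      # pivot
      pv <- Tm[i, j]
      Tm[i, ] <<- Tm[i, ] / pv
      b[i] <<- b[i] / pv
      other <- setdiff(seq_len(m), i)
      fac <- Tm[other, j]
      Tm[other, ] <<- Tm[other, , drop = FALSE] - outer(fac, Tm[i, ])
      b[other] <<- b[other] - fac * b[i]
      basis[i] <<- j
    }
  }

  if (n_art) {
    st <- run_phase(cost1, 1)
    if (st != "optimal") return(list(status = st))
    if (sum(b[basis %in% art_cols]) > 1e-7) {
      return(list(status = "infeasible"))
    }
    # drive zero-level artificials out of the basis or drop redundant rows
    drop_rows <- integer()
    for (i in which(basis %in% art_cols)) {
      piv_j <- which(abs(Tm[i, seq_len(n + n_sl + n_su)]) > tol)
      piv_j <- setdiff(piv_j, basis)
      if (length(piv_j)) {
        j <- piv_j[1]
        pv <- Tm[i, j]
        Tm[i, ] <- Tm[i, ] / pv; b[i] <- b[i] / pv
        other <- setdiff(seq_len(m), i)
        fac <- Tm[other, j]
        Tm[other, ] <- Tm[other, , drop = FALSE] - outer(fac, Tm[i, ])
        b[other] <- b[other] - fac * b[i]
        basis[i] <- j
      } else {
        drop_rows <- c(drop_rows, i)  # redundant constraint
      }
    }
    if (length(drop_rows)) {
      keep <- setdiff(seq_len(m), drop_rows)
      Tm <- Tm[keep, , drop = FALSE]; b <- b[keep]; basis <- basis[keep]
      m <- length(keep)
    }
    # forbid artificials from ever re-entering
    if (length(art_cols)) Tm[, art_cols] <- 0
  }

  st <- run_phase(cost2, 2)
  if (st != "optimal") return(list(status = st))

  x <- numeric(ntot); x[basis] <- b
  sol <- x[seq_len(n)]
  obj_val <- sum(obj * sol)
  list(status = "optimal", solution = sol,
       objective = if (maximize) -obj_val else obj_val)
}
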
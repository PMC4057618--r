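# Linear-programming layer.
#
# Flux problems are box-bounded polytopes:
#   max/min  c'v   s.t.  S v = b,  lb <= v <= ub.
# They are reduced to computational standard form (min c'x, A x = b, x >= 0,
# with explicit slack rows for the upper bounds) and solved by a dense
# two-phase simplex with Bland's anti-cycling rule. Bland's rule makes every
# pivot choice deterministic, so identical inputs give byte-identical
# solutions; FBA bases are highly degenerate (many zero right-hand sides),
# which is exactly the regime where anti-cycling matters.
#
# Infinite bounds are capped at LP_BIG; an optimal solution pinned to an
# artificial cap on an objective variable is reported as unbounded.

LP_BIG <- 1e6
LP_TOL <- 1e-9

# min cost'x  s.t.  A x = b, x >= 0  (b any sign; rows are flipped here).
# Returns list(status, x, objective). Bland's rule throughout.
simplex_core <- function(cost, A, b, tol = LP_TOL) {
  m <- nrow(A); n <- ncol(A)
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]

  iterate <- function(tab, basis, cost_ext, tol) {
    ncols <- ncol(tab) - 1L
    repeat {
      cb <- cost_ext[basis]
      red <- cost_ext - as.vector(cb %*% tab[, seq_len(ncols), drop = FALSE])
      enter <- which(red < -tol)
      if (!length(enter)) return(list(tab = tab, basis = basis, status = "OPTIMAL"))
      j <- enter[1L]                      # Bland: smallest index enters
      col <- tab[, j]
      pos <- which(col > tol)
      if (!length(pos)) return(list(tab = tab, basis = basis, status = "UNBOUNDED"))
      ratios <- tab[pos, ncols + 1L] / col[pos]
      rmin <- min(ratios)
      cand <- pos[ratios <= rmin + tol]
      r <- cand[which.min(basis[cand])]   # Bland: smallest basic index leaves
      piv <- tab[r, j]
      tab[r, ] <- tab[r, ] / piv
      other <- setdiff(seq_len(nrow(tab)), r)
      tab[other, ] <- tab[other, ] - outer(tab[other, j], tab[r, ])
      basis[r] <- j
    }
  }

  # phase 1: artificial basis
  tab <- cbind(A, diag(m), b, deparse.level = 0)
  basis <- n + seq_len(m)
  cost1 <- c(rep(0, n), rep(1, m))
  ph1 <- iterate(tab, basis, cost1, tol)
  aux <- sum(ph1$tab[, n + m + 1L] * (ph1$basis > n))
  if (aux > 1e-7)
    return(list(status = "INFEASIBLE", x = NULL, objective = NA_real_))
  tab <- ph1$tab; basis <- ph1$basis
  # drive leftover artificials out of the (degenerate) basis
  drop_rows <- integer()
  for (r in which(basis > n)) {
    j <- which(abs(tab[r, seq_len(n)]) > tol)
    j <- j[!(j %in% basis)]
    if (!length(j)) { drop_rows <- c(drop_rows, r); next }
    j <- j[1L]
    piv <- tab[r, j]
    tab[r, ] <- tab[r, ] / piv
    other <- setdiff(seq_len(nrow(tab)), r)
    tab[other, ] <- tab[other, ] - outer(tab[other, j], tab[r, ])
    basis[r] <- j
  }
  if (length(drop_rows)) {                # redundant constraint rows
    tab <- tab[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }
  tab <- tab[, c(seq_len(n), n + m + 1L), drop = FALSE]

  # phase 2
  ph2 <- iterate(tab, basis, cost, tol)
  if (ph2$status == "UNBOUNDED")
    return(list(status = "UNBOUNDED", x = NULL, objective = NA_real_))
  x <- numeric(n)
  x[ph2$basis] <- ph2$tab[, n + 1L]
  x[x < 0 & x > -1e-9] <- 0
  list(status = "OPTIMAL", x = x, objective = sum(cost * x))
}

solve_lp <- function(obj, A, b, lb, ub, maximize = TRUE) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n,
            is.matrix(A), ncol(A) == n, length(b) == nrow(A))
  if (any(lb > ub))
    return(list(status = "INFEASIBLE", objective = NA_real_, solution = NULL))
  capped_lo <- !is.finite(lb)
  capped_hi <- !is.finite(ub)
  lb2 <- ifelse(capped_lo, -LP_BIG, lb)
  ub2 <- ifelse(capped_hi, LP_BIG, ub)
  width <- ub2 - lb2

  # presolve: substitute fixed variables (knocked-out reactions, maintenance
  # fluxes) into the right-hand side and drop empty rows
  fixed <- width <= LP_TOL
  v_full <- lb2
  b_red <- b - as.vector(A[, fixed, drop = FALSE] %*% lb2[fixed])
  A_red <- A[, !fixed, drop = FALSE]
  obj_red <- obj[!fixed]
  lb_red <- lb2[!fixed]
  width_red <- width[!fixed]
  empty <- rowSums(abs(A_red)) == 0
  if (any(abs(b_red[empty]) > 1e-9))
    return(list(status = "INFEASIBLE", objective = NA_real_, solution = NULL))
  A_red <- A_red[!empty, , drop = FALSE]
  b_red <- b_red[!empty]
  nred <- ncol(A_red)
  if (!nred) {
    if (length(b_red) && any(abs(b_red) > 1e-9))
      return(list(status = "INFEASIBLE", objective = NA_real_, solution = NULL))
    return(list(status = "OPTIMAL", objective = sum(obj * v_full),
                solution = v_full))
  }

  # standard form: x = v - lb with slack rows x + s = width
  b_std <- c(b_red - as.vector(A_red %*% lb_red), width_red)
  A_std <- rbind(cbind(A_red, matrix(0, nrow(A_red), nred)),
                 cbind(diag(nred), diag(nred)))
  cost <- c(if (maximize) -obj_red else obj_red, rep(0, nred))
  res <- simplex_core(cost, A_std, b_std)
  if (res$status != "OPTIMAL")
    return(list(status = res$status, objective = NA_real_, solution = NULL))
  v_full[!fixed] <- res$x[seq_len(nred)] + lb_red
  v <- v_full
  at_cap <- (capped_hi & v > LP_BIG - 1) | (capped_lo & v < -LP_BIG + 1)
  if (any(at_cap & obj != 0))
    return(list(status = "UNBOUNDED", objective = NA_real_, solution = NULL))
  list(status = "OPTIMAL", objective = sum(obj * v), solution = v)
}
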
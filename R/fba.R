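#' Flux balance analysis
#'
#' Maximizes the model objective (by default the biomass reaction, whose
#' flux is the growth rate in hr^-1) subject to steady-state mass balance
#' `S v = 0` and the reaction flux bounds.
#'
#' @param model A `metabolic_model`.
#' @param minimize_l1 If `TRUE`, follow the optimum with a taxicab-norm
#'   minimization ([minimize_taxicab()]) and return that flux vector.
#' @return Object of class `flux_result`: `status` (`"OPTIMAL"`,
#'   `"INFEASIBLE"` or `"UNBOUNDED"`), `objective` (the optimal objective
#'   value; growth rate when the objective is biomass), and `fluxes` (named
#'   vector over reactions; `NULL` unless optimal).
#' @export
solve_fba <- function(model, minimize_l1 = FALSE) {
  S <- stoichiometric_matrix(model)
  bnds <- reaction_bounds(model)
  obj <- objective_vector(model)
  res <- solve_lp(obj, S, rep(0, nrow(S)), bnds$lb, bnds$ub, maximize = TRUE)
  if (res$status != "OPTIMAL") {
    return(structure(list(status = res$status, objective = NA_real_,
                          fluxes = NULL), class = "flux_result"))
  }
  fluxes <- stats::setNames(res$solution, names(model$reactions))
  out <- structure(list(status = "OPTIMAL", objective = res$objective,
                        fluxes = fluxes), class = "flux_result")
  if (minimize_l1) out$fluxes <- minimize_taxicab(model, res$objective)
  out
}

#' @export
print.flux_result <- function(x, ...) {
  cat(sprintf("<flux_result> %s", x$status))
  if (x$status == "OPTIMAL")
    cat(sprintf(", objective = %.6g", x$objective))
  cat("\n")
  invisible(x)
}

#' Taxicab-norm flux minimization at the FBA optimum
#'
#' Among flux vectors attaining the already-computed optimal objective,
#' finds one minimizing the taxicab (L1) norm `sum(|v|)`. Implemented as a
#' second LP with split variables (`v = vp - vn`, `vp, vn >= 0`, minimize
#' `sum(vp + vn)`) and the first-stage objective fixed as an equality
#' constraint. This suppresses futile cycles: any internal loop can be
#' removed without changing the objective, so it carries zero flux at the
#' L1 optimum.
#'
#' @param model A `metabolic_model`.
#' @param attained_objective Objective value from a prior `OPTIMAL`
#'   [solve_fba()].
#' @param tol Feasibility slack on the fixed objective (absolute; also used
#'   when verifying the result).
#' @return Named flux vector attaining `attained_objective` with minimal
#'   taxicab norm.
#' @export
minimize_taxicab <- function(model, attained_objective, tol = 1e-9) {
  S <- stoichiometric_matrix(model)
  bnds <- reaction_bounds(model)
  obj <- objective_vector(model)
  n <- ncol(S)
  # split variables v = vp - vn with vp in [max(lb,0), max(ub,0)] and
  # vn in [max(-ub,0), max(-lb,0)]: the boxes reproduce lb <= v <= ub for
  # every sign pattern of (lb, ub), and minimizing sum(vp + vn) never leaves
  # both parts positive, so sum(vp + vn) = sum(|v|) at the optimum
  vp_ub <- pmax(bnds$ub, 0)
  vn_ub <- pmax(-bnds$lb, 0)
  vp_lb <- pmax(bnds$lb, 0)   # when lb > 0 the positive part must carry it
  vn_lb <- pmax(-bnds$ub, 0)  # when ub < 0 the negative part must carry it
  A_split <- cbind(S, -S)
  A_obj <- matrix(c(obj, -obj), nrow = 1)
  A <- rbind(A_split, A_obj)
  b <- c(rep(0, nrow(S)), attained_objective)
  cc <- rep(1, 2 * n)
  res <- solve_lp(cc, A, b, c(vp_lb, vn_lb), c(vp_ub, vn_ub),
                  maximize = FALSE)
  if (res$status != "OPTIMAL")
    stop("taxicab minimization ", tolower(res$status),
         " with the objective fixed at ", format(attained_objective),
         "; consider relaxing the fixing tolerance")
  v <- res$solution[seq_len(n)] - res$solution[n + seq_len(n)]
  v <- stats::setNames(v, names(model$reactions))
  if (abs(sum(obj * v) - attained_objective) > max(tol, 1e-7 * abs(attained_objective)))
    stop("taxicab solution drifted from the attained objective")
  v
}
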
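# Independent oracles. These deliberately avoid the code paths they check:
# the alignment oracle is a memoized three-state recursion written directly
# from the affine-gap scoring definition, and the LP oracle enumerates the
# vertices of the flux polytope by brute force.

blosum62 <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
})

# Optimal global affine-gap alignment score by exhaustive recursion over the
# three alignment states (diagonal, gap-in-a, gap-in-b). A gap run of length
# L costs open + L * extend, matching the package aligner's convention.
oracle_global_score <- function(a, b, mat = blosum62, open = 11, extend = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  memo <- new.env(hash = TRUE)
  rec <- function(i, j, state) {
    # best score of aligning a[i..], b[j..] given the previous column state
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- if (i > length(av) && j > length(bv)) {
      0
    } else {
      best <- -Inf
      if (i <= length(av) && j <= length(bv))
        best <- max(best, mat[av[i], bv[j]] + rec(i + 1, j + 1, "d"))
      if (i <= length(av)) {   # a[i] against gap in b
        cost <- extend + if (state == "gb") 0 else open
        best <- max(best, -cost + rec(i + 1, j, "gb"))
      }
      if (j <= length(bv)) {   # gap in a against b[j]
        cost <- extend + if (state == "ga") 0 else open
        best <- max(best, -cost + rec(i, j + 1, "ga"))
      }
      best
    }
    memo[[key]] <- res
    res
  }
  rec(1, 1, "d")
}

random_aa <- function(n, alphabet = c("A", "C", "D", "E", "F", "G", "H", "I",
                                      "K", "L", "M", "N", "P", "Q", "R", "S",
                                      "T", "V", "W", "Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Brute-force LP oracle: enumerate the vertices of
#   { v : S v = 0, lb <= v <= ub }
# (every vertex activates n - rank(S) bound constraints), keep the feasible
# ones, and return the maximal objective. NA when no feasible vertex exists.
oracle_lp_max <- function(obj, S, lb, ub, tol = 1e-7) {
  n <- ncol(S)
  r <- qr(S)$rank
  k <- n - r
  best <- -Inf
  feasible <- FALSE
  idx_sets <- if (k == 0) list(integer()) else
    utils::combn(n, k, simplify = FALSE)
  for (idx in idx_sets) {
    n_choice <- if (k == 0) 1L else 2^k
    for (mask in seq_len(n_choice) - 1L) {
      at_ub <- as.logical(bitwAnd(mask, 2^(seq_len(max(k, 1)) - 1L)))[seq_len(k)]
      vals <- ifelse(at_ub, ub[idx], lb[idx])
      E <- matrix(0, k, n)
      if (k > 0) E[cbind(seq_len(k), idx)] <- 1
      M <- rbind(S, E)
      rhs <- c(rep(0, nrow(S)), vals)
      if (qr(M)$rank < n) next
      v <- tryCatch(qr.solve(M, rhs), error = function(e) NULL)
      if (is.null(v)) next
      if (any(v < lb - tol) || any(v > ub + tol)) next
      if (max(abs(S %*% v)) > tol) next
      feasible <- TRUE
      best <- max(best, sum(obj * v))
    }
  }
  if (!feasible) return(NA_real_)
  best
}

# small hand-rolled models used across the FBA tests
chain_model <- function() {
  metabolic_model(
    id = "chain",
    metabolites = data.frame(id = c("A_c"), name = "A", compartment = "c"),
    reactions = list(
      list(id = "UPT", stoichiometry = c(A_c = 1),
           lower_bound = 0, upper_bound = 10, gpr = "g_upt"),
      list(id = "BIO", stoichiometry = c(A_c = -2),
           lower_bound = 0, upper_bound = 1000, gpr = "")),
    biomass = "BIO")
}

futile_cycle_model <- function() {
  # chain plus a two-reaction loop B <-> C that can spin freely
  metabolic_model(
    id = "loop",
    metabolites = data.frame(id = c("A_c", "B_c", "C_c"),
                             name = c("A", "B", "C"), compartment = "c"),
    reactions = list(
      list(id = "UPT", stoichiometry = c(A_c = 1),
           lower_bound = 0, upper_bound = 10, gpr = ""),
      list(id = "BIO", stoichiometry = c(A_c = -2),
           lower_bound = 0, upper_bound = 1000, gpr = ""),
      list(id = "L1", stoichiometry = c(B_c = -1, C_c = 1),
           lower_bound = -500, upper_bound = 500, gpr = ""),
      list(id = "L2", stoichiometry = c(C_c = -1, B_c = 1),
           lower_bound = -500, upper_bound = 500, gpr = "")),
    biomass = "BIO")
}
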
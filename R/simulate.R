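# Seeded generators for synthetic test inputs. All generators are pure
# functions of their configuration: the RNG state is saved and restored, so
# the same config always yields byte-identical output and callers' RNG
# streams are untouched.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Robinson & Robinson style background amino-acid frequencies
AA_FREQ <- c(A = 0.078, R = 0.051, N = 0.045, D = 0.054, C = 0.019,
             Q = 0.043, E = 0.063, G = 0.074, H = 0.022, I = 0.051,
             L = 0.091, K = 0.057, M = 0.022, F = 0.039, P = 0.052,
             S = 0.071, T = 0.058, W = 0.013, Y = 0.032, V = 0.064)

# substitution proposal: P(b | a) proportional to freq(b) * 2^(s(a,b)/2)
# over b != a -- high-scoring (conservative) exchanges are favored, so the
# realized alignment identity tracks the configured target identity
substitution_profile <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    mat <- substitution_matrix("BLOSUM62")[AA20, AA20]
    prof <- sapply(AA20, function(a) {
      w <- AA_FREQ * 2^(mat[a, ] / 2)
      w[a] <- 0
      w / sum(w)
    })
    cache <<- prof  # column per source residue
    cache
  }
})

random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE, prob = AA_FREQ), collapse = "")
}

# Per-site substitutions plus geometric deletions. Protected positions are
# never substituted or deleted; their post-mutation coordinates are returned
# alongside the sequence so planted sites can be tracked exactly.
mutate_protein <- function(seq, p_sub, p_indel = 0.008, protect = integer()) {
  chars <- strsplit(seq, "")[[1]]
  prof <- substitution_profile()
  hit <- runif(length(chars)) < p_sub
  hit[protect] <- FALSE
  for (i in which(hit))
    chars[i] <- sample(AA20, 1L, prob = prof[, chars[i]])
  keep <- rep(TRUE, length(chars))
  if (p_indel > 0) {
    i <- 1L
    while (i <= length(chars)) {
      if (!(i %in% protect) && runif(1) < p_indel) {
        gap <- 1L + stats::rgeom(1L, 0.6)
        span <- i:min(length(chars), i + gap - 1L)
        span <- setdiff(span, protect)
        keep[span] <- FALSE
        i <- i + gap
      } else {
        i <- i + 1L
      }
    }
  }
  new_pos <- cumsum(keep)
  list(seq = paste(chars[keep], collapse = ""),
       positions = stats::setNames(new_pos[protect], protect))
}

#' Simulate a pair of proteomes with planted orthologs
#'
#' Generates a "human" and a "yeast" proteome in which each planted ortholog
#' pair descends from a common ancestor with a configurable divergence, so
#' that pair members are mutually nearest by alignment score. Each pair
#' carries one planted active site whose fate is controlled: preserved
#' (identical residue in both copies), mutated (forced to a different
#' residue in yeast), or deleted (the yeast column removed). Optional
#' paralog decoys are within-species duplicates lying closer to their source
#' than any cross-species sequence, exercising the many-to-one best-hit
#' collision.
#'
#' @param seed Integer seed; identical configs give byte-identical output.
#' @param n_pairs Number of planted ortholog pairs.
#' @param n_paralogs Number of within-species decoy duplicates (attached to
#'   the first `n_paralogs` human sequences).
#' @param target_identity Approximate pairwise identity of planted pairs, in
#'   (0.35, 1]; below 0.35 the planted structure is no longer guaranteed and
#'   the generator refuses.
#' @param site_fate `"preserve"`, `"mutate"`, or `"delete_column"`.
#' @param length_range Ancestor length range (uniform integer draw).
#' @return List with `human` and `yeast` (named character vectors of
#'   sequences), `sites` (data frame `accession`, `position`, `residue`) and
#'   `truth` (data frame `human_acc`, `yeast_acc`, `site_fate`, plus decoy
#'   accessions in `paralogs`).
#' @export
simulate_proteomes <- function(seed = 1L, n_pairs = 5L, n_paralogs = 0L,
                               target_identity = 0.6,
                               site_fate = c("preserve", "mutate", "delete_column"),
                               length_range = c(120L, 240L)) {
  site_fate <- match.arg(site_fate)
  stopifnot(n_pairs >= 1L, n_paralogs >= 0L, n_paralogs <= n_pairs)
  if (target_identity <= 0.35 || target_identity > 1)
    stop("target_identity must lie in (0.35, 1]: planted mutual-nearest ",
         "structure is not guaranteed at lower identities")
  with_seed(seed, {
    p_sub <- 1 - sqrt(target_identity)  # both copies diverge independently
    human <- character(); yeast <- character()
    sites <- list(); truth <- list()
    for (k in seq_len(n_pairs)) {
      len <- sample(length_range[1]:length_range[2], 1L)
      anc <- random_protein(len)
      site <- sample(seq(10L, len - 10L), 1L)
      hm <- mutate_protein(anc, p_sub, protect = site)
      h <- hm$seq; h_site <- unname(hm$positions[as.character(site)])
      ym <- mutate_protein(anc, p_sub, protect = site)
      y <- ym$seq; y_site <- unname(ym$positions[as.character(site)])
      h_acc <- sprintf("HSIM%03d", k)
      y_acc <- sprintf("YSIM%03d", k)
      h_res <- substr(h, h_site, h_site)
      if (site_fate == "mutate") {
        alt <- sample(setdiff(AA20, h_res), 1L)
        substr(y, y_site, y_site) <- alt
      } else if (site_fate == "delete_column") {
        y <- paste0(substr(y, 1, y_site - 1L), substr(y, y_site + 1L, nchar(y)))
      }
      human[[h_acc]] <- h
      yeast[[y_acc]] <- y
      sites[[length(sites) + 1L]] <- data.frame(
        accession = h_acc, position = h_site, residue = h_res,
        stringsAsFactors = FALSE)
      if (site_fate == "preserve")
        sites[[length(sites) + 1L]] <- data.frame(
          accession = y_acc, position = y_site,
          residue = substr(y, y_site, y_site), stringsAsFactors = FALSE)
      truth[[k]] <- data.frame(human_acc = h_acc, yeast_acc = y_acc,
                               site_fate = site_fate, stringsAsFactors = FALSE)
    }
    paralogs <- character()
    if (n_paralogs > 0L) {
      for (k in seq_len(n_paralogs)) {
        src <- sprintf("HSIM%03d", k)
        acc <- sprintf("HPAR%03d", k)
        human[[acc]] <- mutate_protein(human[[src]], p_sub = 0.05,
                                       p_indel = 0)$seq
        paralogs <- c(paralogs, acc)
      }
    }
    list(human = human, yeast = yeast,
         sites = do.call(rbind, sites),
         truth = do.call(rbind, truth),
         paralogs = paralogs)
  })
}

#' Generate a hand-solvable toy metabolic model
#'
#' Builds a branched uptake network whose wild-type growth has the closed
#' form `sum(capacity * yield)` over open branches: branch i imports
#' substrate i at up to `capacities[i]`, converts it to a common biomass
#' precursor at `yields[i]`, and the biomass reaction drains the precursor.
#' Each conversion carries a single-gene GPR (`bg1`, `bg2`, ...). With
#' `include_cofactor_branch`, a cofactor metabolite (a ferroheme-like
#' compound) is producible from the precursor via a reaction gated by two
#' genes (`cg1`, `cg2`, combined by `cofactor_gpr`); the cofactor is
#' required only by an augmented biomass, so knocking the cofactor genes out
#' is silent under the original objective and lethal once the biomass is
#' augmented.
#'
#' @param n_branches Number of parallel substrate branches.
#' @param capacities Positive uptake capacities, length `n_branches`.
#' @param yields Precursor yield per unit substrate, length `n_branches`
#'   (recycled).
#' @param include_cofactor_branch Add the two-gene cofactor branch.
#' @param cofactor_gpr `"or"` (isozymes) or `"and"` (complex) for the
#'   cofactor reaction's two genes.
#' @return A `metabolic_model` with attribute `"closed_form_growth"`.
#' @export
generate_toy_model <- function(n_branches = 2L, capacities = c(10, 4),
                               yields = 1,
                               include_cofactor_branch = FALSE,
                               cofactor_gpr = c("or", "and")) {
  cofactor_gpr <- match.arg(cofactor_gpr)
  stopifnot(n_branches >= 1L, length(capacities) == n_branches)
  yields <- rep_len(yields, n_branches)
  if (any(capacities <= 0) || any(yields <= 0))
    stop("generate_toy_model: capacities and yields must be positive ",
         "(a zero-capacity branch makes the model degenerate)")
  mets <- data.frame(id = c(sprintf("sub%d_c", seq_len(n_branches)), "prec_c"),
                     name = c(sprintf("substrate %d", seq_len(n_branches)),
                              "biomass precursor"),
                     compartment = "c", stringsAsFactors = FALSE)
  rxns <- list()
  for (i in seq_len(n_branches)) {
    rxns[[length(rxns) + 1L]] <- list(
      id = sprintf("EX_sub%d", i), name = sprintf("substrate %d uptake", i),
      stoichiometry = stats::setNames(1, sprintf("sub%d_c", i)),
      lower_bound = 0, upper_bound = capacities[i], gpr = "")
    rxns[[length(rxns) + 1L]] <- list(
      id = sprintf("CNV%d", i), name = sprintf("branch %d conversion", i),
      stoichiometry = stats::setNames(c(-1, yields[i]),
                                      c(sprintf("sub%d_c", i), "prec_c")),
      lower_bound = 0, upper_bound = 1000, gpr = sprintf("bg%d", i))
  }
  if (include_cofactor_branch) {
    mets <- rbind(mets, data.frame(id = "cof_c", name = "cofactor",
                                   compartment = "c", stringsAsFactors = FALSE))
    rxns[[length(rxns) + 1L]] <- list(
      id = "COF", name = "cofactor synthesis",
      stoichiometry = c(prec_c = -1, cof_c = 1),
      lower_bound = 0, upper_bound = 1000,
      gpr = paste("cg1", cofactor_gpr, "cg2"))
  }
  rxns[[length(rxns) + 1L]] <- list(
    id = "GROWTH", name = "biomass drain",
    stoichiometry = c(prec_c = -1),
    lower_bound = 0, upper_bound = 1000, gpr = "")
  model <- metabolic_model(id = "toy_branched", metabolites = mets,
                           reactions = rxns, biomass = "GROWTH")
  attr(model, "closed_form_growth") <- sum(capacities * yields)
  model
}

#' Random box-bounded flux model
#'
#' Small random stoichiometric networks used to stress the LP layer against
#' brute-force polytope oracles: a few exchange columns keep the network
#' open, every flux is box-bounded (so the LP is always bounded), and zero
#' flux is always feasible.
#'
#' @param n_reactions Number of reactions (columns), at most ~8 if the
#'   caller intends vertex enumeration.
#' @param n_metabolites Number of metabolites (rows); default scales as half
#'   the reactions.
#' @param seed Integer seed.
#' @return A list `obj`, `S`, `lb`, `ub` describing `max obj'v` s.t.
#'   `S v = 0`, `lb <= v <= ub`.
#' @export
random_flux_model <- function(n_reactions = 6L,
                              n_metabolites = max(2L, n_reactions %/% 2L),
                              seed = 1L) {
  with_seed(seed, {
    repeat {
      S <- matrix(sample(c(-1, 0, 0, 1, 2), n_metabolites * n_reactions,
                         replace = TRUE),
                  nrow = n_metabolites)
      if (all(rowSums(S != 0) > 0) && all(colSums(S != 0) > 0)) break
    }
    rev <- runif(n_reactions) < 0.4
    lb <- ifelse(rev, -round(runif(n_reactions, 1, 10), 1), 0)
    ub <- round(runif(n_reactions, 1, 10), 1)
    obj <- numeric(n_reactions)
    obj[sample(n_reactions, max(1L, n_reactions %/% 3L))] <-
      round(runif(max(1L, n_reactions %/% 3L), 0.5, 2), 2)
    list(obj = obj, S = S, lb = lb, ub = ub)
  })
}
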
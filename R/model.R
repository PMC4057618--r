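#' Construct a genome-scale metabolic model
#'
#' The in-memory container used by all constraint-based operations:
#' metabolites, reactions (stoichiometry, flux bounds, GPR), genes, and a
#' designated biomass/objective reaction. Flux units are
#' mmol·gCDW^-1·hr^-1; the biomass flux is a growth rate in hr^-1.
#'
#' @param id Model identifier.
#' @param metabolites Data frame with columns `id`, `name`, `compartment`.
#' @param reactions List of reactions, each a list with `id`, `name`,
#'   `stoichiometry` (named numeric vector, metabolite id -> signed
#'   coefficient, negative = consumed), `lower_bound`, `upper_bound`, `gpr`
#'   (string, possibly empty).
#' @param genes Character vector of gene ids (defaults to the union of GPR
#'   genes).
#' @param biomass Reaction id of the biomass/objective reaction.
#' @param compartments Named character vector mapping compartment tags to
#'   labels (defaults to the tags present on metabolites).
#' @param objective Optional named numeric vector of objective coefficients;
#'   defaults to 1 on the biomass reaction.
#' @return Object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, genes = NULL,
                            biomass, compartments = NULL, objective = NULL) {
  stopifnot(is.data.frame(metabolites),
            all(c("id", "compartment") %in% names(metabolites)))
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (anyDuplicated(metabolites$id))
    stop("duplicate metabolite ids: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "))
  if (is.null(compartments)) {
    tags <- unique(metabolites$compartment)
    compartments <- stats::setNames(tags, tags)
  }
  bad_comp <- setdiff(metabolites$compartment, names(compartments))
  if (length(bad_comp))
    stop("metabolite compartment(s) not declared: ",
         paste(bad_comp, collapse = ", "))
  rxn_ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(rxn_ids))
    stop("duplicate reaction ids: ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "))
  names(reactions) <- rxn_ids
  gpr_trees <- vector("list", length(reactions))
  for (i in seq_along(reactions)) {
    r <- reactions[[i]]
    if (is.null(r$stoichiometry) || !length(r$stoichiometry))
      stop("reaction ", r$id, " has empty stoichiometry")
    unknown <- setdiff(names(r$stoichiometry), metabolites$id)
    if (length(unknown))
      stop("reaction ", r$id, " references undeclared metabolite(s): ",
           paste(unknown, collapse = ", "))
    if (r$lower_bound > r$upper_bound)
      stop("reaction ", r$id, ": lower_bound > upper_bound")
    gpr_trees[i] <- list(parse_gpr(r$gpr %||% ""))
    reactions[[i]]$gpr <- deparse_gpr(gpr_trees[[i]])
    if (is.null(r$name)) reactions[[i]]$name <- r$id
  }
  used_genes <- unique(unlist(lapply(gpr_trees, gpr_genes)))
  if (is.null(genes)) genes <- used_genes
  undeclared <- setdiff(used_genes, genes)
  if (length(undeclared))
    stop("GPR gene(s) not declared in the model gene list: ",
         paste(undeclared, collapse = ", "))
  if (!biomass %in% rxn_ids)
    stop("biomass reaction '", biomass, "' not present in the model")
  if (is.null(objective)) objective <- stats::setNames(1, biomass)
  bad_obj <- setdiff(names(objective), rxn_ids)
  if (length(bad_obj))
    stop("objective references unknown reaction(s): ",
         paste(bad_obj, collapse = ", "))
  structure(list(id = id, metabolites = metabolites, reactions = reactions,
                 genes = sort(unique(genes)), biomass = biomass,
                 compartments = compartments, objective = objective,
                 gpr_trees = stats::setNames(gpr_trees, rxn_ids),
                 provenance = character()),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %s: %d metabolites, %d reactions, %d genes; biomass = %s\n",
              x$id, nrow(x$metabolites), length(x$reactions),
              length(x$genes), x$biomass))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = "; "), "\n")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model A `metabolic_model`.
#' @return Dense numeric matrix S (metabolites x reactions); `S[i, j]` is the
#'   signed coefficient of metabolite i in reaction j.
#' @export
stoichiometric_matrix <- function(model) {
  met_ids <- model$metabolites$id
  rxn_ids <- names(model$reactions)
  S <- matrix(0, nrow = length(met_ids), ncol = length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoichiometry
    S[names(st), j] <- unname(st)
  }
  S
}

reaction_bounds <- function(model) {
  list(lb = vapply(model$reactions, `[[`, numeric(1), "lower_bound"),
       ub = vapply(model$reactions, `[[`, numeric(1), "upper_bound"))
}

objective_vector <- function(model) {
  obj <- stats::setNames(numeric(length(model$reactions)), names(model$reactions))
  obj[names(model$objective)] <- model$objective
  obj
}

#' Override exchange-reaction bounds (medium specification)
#'
#' Growth media are expressed as bound overrides on exchange reactions, e.g.
#' an aerobic glucose minimal medium as uptake limits on the glucose, oxygen
#' and inorganic-ion exchanges.
#'
#' @param model A `metabolic_model`.
#' @param medium Named list; each element is `c(lower, upper)` or a list with
#'   `lower_bound`/`upper_bound`, keyed by reaction id.
#' @return The model with overridden bounds (the input is unmodified).
#' @export
set_medium <- function(model, medium) {
  for (rid in names(medium)) {
    if (!rid %in% names(model$reactions))
      stop("set_medium: unknown reaction ", rid)
    m <- medium[[rid]]
    if (is.list(m)) m <- c(m$lower_bound %||% NA, m$upper_bound %||% NA)
    if (!is.na(m[1])) model$reactions[[rid]]$lower_bound <- as.numeric(m[1])
    if (length(m) > 1 && !is.na(m[2]))
      model$reactions[[rid]]$upper_bound <- as.numeric(m[2])
    if (model$reactions[[rid]]$lower_bound > model$reactions[[rid]]$upper_bound)
      stop("set_medium: bounds crossed for ", rid)
  }
  model
}
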
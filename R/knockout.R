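#' Apply a gene or reaction knockout
#'
#' Gene targets are propagated through the GPR rules: every reaction whose
#' rule evaluates inactive with the targets deleted gets bounds `[0, 0]`
#' (total loss of function). Reaction targets are zeroed directly. The input
#' model is never modified.
#'
#' @param model A `metabolic_model`.
#' @param targets Character vector of gene ids and/or reaction ids.
#' @return The knockout model, with attribute `"disabled_reactions"` listing
#'   the reactions forced to zero.
#' @export
apply_knockout <- function(model, targets) {
  targets <- unique(as.character(targets))
  is_gene <- targets %in% model$genes
  is_rxn <- targets %in% names(model$reactions)
  unknown <- targets[!is_gene & !is_rxn]
  if (length(unknown))
    stop("apply_knockout: unknown target(s): ", paste(unknown, collapse = ", "))
  genes <- targets[is_gene]
  disabled <- targets[is_rxn & !is_gene]
  if (length(genes)) {
    inactive <- names(model$reactions)[!vapply(
      model$gpr_trees, evaluate_gpr, logical(1), deleted_genes = genes)]
    disabled <- union(disabled, inactive)
  }
  for (rid in disabled) {
    model$reactions[[rid]]$lower_bound <- 0
    model$reactions[[rid]]$upper_bound <- 0
  }
  model$provenance <- c(model$provenance,
                        paste0("knockout:", paste(targets, collapse = "+")))
  attr(model, "disabled_reactions") <- disabled
  model
}

#' Augment the biomass function with additional metabolite requirements
#'
#' Adds small growth-coupled demands for metabolites missing from the
#' original biomass function (e.g. ferroheme b and mitochondrial charged
#' tRNA(Tyr)). Two modes:
#' * `"coefficient"` (default) — each metabolite is added as a biomass
#'   reactant (its coefficient decremented by the requirement), so the
#'   demand scales with growth;
#' * `"demand"` — a per-metabolite sink reaction with the requirement as its
#'   lower bound is added, a fixed flux independent of growth (the printed
#'   unit of such requirements, mmol/gCDW/hr, is a flux, which this mode
#'   matches literally).
#'
#' @param model A `metabolic_model`.
#' @param requirements Named numeric vector, metabolite id -> positive
#'   requirement (conventional default 0.0005 per metabolite).
#' @param mode `"coefficient"` or `"demand"`.
#' @return The augmented model (input unmodified); the augmentation is
#'   recorded in the model provenance.
#' @export
augment_biomass <- function(model, requirements,
                            mode = c("coefficient", "demand")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(requirements), !is.null(names(requirements)))
  if (any(requirements <= 0))
    stop("augment_biomass: requirements must be positive")
  unknown <- setdiff(names(requirements), model$metabolites$id)
  if (length(unknown))
    stop("augment_biomass: unknown metabolite(s): ",
         paste(unknown, collapse = ", "))
  if (mode == "coefficient") {
    st <- model$reactions[[model$biomass]]$stoichiometry
    for (m in names(requirements)) {
      st[m] <- (if (m %in% names(st)) st[[m]] else 0) - requirements[[m]]
    }
    model$reactions[[model$biomass]]$stoichiometry <- st
  } else {
    for (m in names(requirements)) {
      rid <- paste0("DM_", m)
      if (rid %in% names(model$reactions))
        stop("augment_biomass: demand reaction ", rid, " already exists")
      model$reactions[[rid]] <- list(
        id = rid, name = paste("demand for", m),
        stoichiometry = stats::setNames(-1, m),
        lower_bound = requirements[[m]], upper_bound = 1000,
        gpr = "")
      model$gpr_trees[rid] <- list(NULL)
    }
  }
  model$provenance <- c(model$provenance,
                        paste0("augment[", mode, "]:",
                               paste(names(requirements), requirements,
                                     sep = "=", collapse = ",")))
  model
}

#' Simulate a knockout panel
#'
#' For every target and biomass variant: applies the knockout, solves FBA,
#' classifies growth against `epsilon`, and (for optimal solves) records the
#' taxicab-minimized flux vector. Wild-type reference rows are computed once
#' per biomass variant. Solver failures are recorded per row (`FAILED`)
#' without aborting the panel.
#'
#' @param model A `metabolic_model`.
#' @param targets Character vector of gene or reaction ids (may be empty:
#'   wild-type rows only).
#' @param augmentations Named list of biomass variants beyond the original,
#'   e.g. `list(augmented = list(requirements = c(heme_c = 5e-4), mode =
#'   "coefficient"))`.
#' @param epsilon Growth-rate threshold (hr^-1) below which a knockout is
#'   classified `NO_GROWTH` (default `1e-6`).
#' @param level `"gene"` (propagate through GPRs) or `"reaction"` (zero the
#'   named reactions directly); recorded in the output.
#' @return Data frame of class `knockout_panel`: one row per (target or WT)
#'   x biomass variant with `target`, `biomass_variant`, `level`,
#'   `growth_rate`, `classification` (`GROWTH`/`NO_GROWTH`/`FAILED`),
#'   `wt_ratio`, `disabled_reactions` (comma-joined). Taxicab flux vectors
#'   are attached as attribute `"fluxes"` (a named list keyed
#'   `variant/target`).
#' @export
simulate_knockout_panel <- function(model, targets, augmentations = list(),
                                    epsilon = 1e-6,
                                    level = c("gene", "reaction")) {
  level <- match.arg(level)
  variants <- c(list(original = NULL), augmentations)
  rows <- list()
  fluxes <- list()
  for (vn in names(variants)) {
    mv <- model
    if (!is.null(variants[[vn]]))
      mv <- augment_biomass(mv, variants[[vn]]$requirements,
                            mode = variants[[vn]]$mode %||% "coefficient")
    wt <- tryCatch(solve_fba(mv), error = function(e) NULL)
    wt_rate <- if (!is.null(wt) && wt$status == "OPTIMAL") wt$objective else 0
    classify <- function(g) if (g < epsilon) "NO_GROWTH" else "GROWTH"
    add_row <- function(target, sol, disabled) {
      key <- paste(vn, target, sep = "/")
      if (is.null(sol)) {
        growth <- NA_real_; class <- "FAILED"
      } else if (sol$status == "OPTIMAL") {
        growth <- sol$objective; class <- classify(growth)
        fluxes[[key]] <<- tryCatch(
          minimize_taxicab(if (target == "WT") mv else km, growth),
          error = function(e) sol$fluxes)
      } else if (sol$status == "INFEASIBLE") {
        growth <- 0; class <- "NO_GROWTH"
      } else {
        growth <- NA_real_; class <- "FAILED"
      }
      rows[[length(rows) + 1L]] <<- data.frame(
        target = target, biomass_variant = vn, level = level,
        growth_rate = growth, classification = class,
        wt_ratio = if (is.na(growth) || wt_rate == 0) 0 else growth / wt_rate,
        disabled_reactions = paste(disabled, collapse = ","),
        stringsAsFactors = FALSE)
    }
    add_row("WT", wt, character())
    for (tg in targets) {
      km <- tryCatch(apply_knockout(mv, tg), error = function(e) NULL)
      if (is.null(km)) {
        add_row(tg, NULL, character())
        next
      }
      if (level == "reaction" && !tg %in% names(model$reactions))
        stop("simulate_knockout_panel: reaction-level panel but target ", tg,
             " is not a reaction id")
      sol <- tryCatch(solve_fba(km), error = function(e) NULL)
      add_row(tg, sol, attr(km, "disabled_reactions"))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fluxes") <- fluxes
  class(out) <- c("knockout_panel", class(out))
  out
}
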
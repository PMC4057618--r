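#' Wild-type growth check against an external genome-scale yeast model
#'
#' Loads a user-supplied genome-scale yeast model (SBML L3 + FBC), applies
#' optional medium overrides, maximizes the model's biomass objective, and
#' reports the wild-type growth rate together with the flux through a
#' reaction of interest (by default `r_0485`, glutathione synthetase, whose
#' wild-type flux is expected to be zero), from both the plain FBA solution
#' and the taxicab-minimized one.
#'
#' The consensus yeast model is too large to bundle; drop the SBML file at
#' [yeast7_model_path()] or pass an explicit path. On the published model
#' under aerobic glucose minimal conditions the expected growth rate is
#' 0.1405 hr^-1.
#'
#' @param path Model file (default: the documented drop-in location).
#' @param medium Optional exchange-bound overrides ([set_medium()]); `NULL`
#'   keeps the model's default (glucose minimal aerobic) bounds.
#' @param reaction Reaction id to report flux for.
#' @return List: `growth_rate`, `reaction`, `fba_flux`, `taxicab_flux`.
#' @export
yeast7_wildtype_check <- function(path = yeast7_model_path(), medium = NULL,
                                  reaction = "r_0485") {
  if (!file.exists(path))
    stop("external yeast model not found at ", path,
         "; download the SBML file and place it there (or pass `path`)")
  model <- load_model(path, dialect = "sbml_fbc")
  if (!is.null(medium)) model <- set_medium(model, medium)
  res <- solve_fba(model)
  if (res$status != "OPTIMAL")
    stop("wild-type solve returned ", res$status)
  v1 <- minimize_taxicab(model, res$objective)
  list(growth_rate = res$objective,
       reaction = reaction,
       fba_flux = unname(res$fluxes[reaction]),
       taxicab_flux = unname(v1[reaction]))
}
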
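# Model I/O: a native JSON dialect (schema-compatible with the COBRA JSON
# interchange format, so external constraint-based toolkits can read the
# same files) and a subset of SBML Level 3 + the FBC version-2 extension
# (species, reactions, stoichiometry, flux-bound parameters, gene-product
# associations, objectives). Identifiers are written with the conventional
# M_/R_/G_ SBML prefixes and the prefixes are stripped on read.

#' Load a genome-scale metabolic model
#'
#' @param path Model file.
#' @param dialect `"auto"` (by extension: `.json` vs `.xml`/`.sbml`),
#'   `"native_json"`, or `"sbml_fbc"`.
#' @param objective Optional reaction id to use as the biomass/objective
#'   when the file designates none.
#' @return A validated [metabolic_model()].
#' @export
load_model <- function(path, dialect = c("auto", "native_json", "sbml_fbc"),
                       objective = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "native_json"
               else "sbml_fbc"
  }
  switch(dialect,
         native_json = read_model_json(path, objective = objective),
         sbml_fbc = read_model_sbml(path, objective = objective))
}

#' Save a genome-scale metabolic model
#'
#' Loading, saving, then loading again is idempotent on ids, stoichiometry,
#' bounds and GPRs.
#'
#' @param model A `metabolic_model`.
#' @param path Output file.
#' @param dialect `"auto"` (by extension), `"native_json"`, or `"sbml_fbc"`.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path,
                       dialect = c("auto", "native_json", "sbml_fbc")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "native_json"
               else "sbml_fbc"
  }
  switch(dialect,
         native_json = write_model_json(model, path),
         sbml_fbc = write_model_sbml(model, path))
  invisible(path)
}

read_model_json <- function(path, objective = NULL) {
  j <- jsonlite::read_json(path)
  mets <- do.call(rbind, lapply(j$metabolites, function(m)
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment %||% "c",
               stringsAsFactors = FALSE)))
  if (is.null(mets)) stop("model has no metabolites: ", path)
  obj_coefs <- numeric()
  rxns <- lapply(j$reactions, function(r) {
    st <- unlist(r$metabolites)
    if (is.null(st)) stop("reaction ", r$id, " has empty stoichiometry")
    oc <- r$objective_coefficient %||% 0
    if (oc != 0) obj_coefs[[r$id]] <<- oc
    list(id = r$id, name = r$name %||% r$id,
         stoichiometry = st,
         lower_bound = as.numeric(r$lower_bound %||% -1000),
         upper_bound = as.numeric(r$upper_bound %||% 1000),
         gpr = r$gene_reaction_rule %||% "")
  })
  genes <- vapply(j$genes, function(g) g$id, character(1))
  comp <- unlist(j$compartments)
  if (is.null(comp)) comp <- NULL else comp <- stats::setNames(as.character(comp), names(comp))
  biomass <- objective
  if (is.null(biomass)) {
    if (!length(obj_coefs))
      stop("model ", path, " designates no objective reaction; ",
           "supply `objective`")
    biomass <- names(obj_coefs)[which.max(abs(obj_coefs))]
  }
  metabolic_model(id = j$id %||% tools::file_path_sans_ext(basename(path)),
                  metabolites = mets, reactions = rxns,
                  genes = if (length(genes)) genes else NULL,
                  biomass = biomass, compartments = comp,
                  objective = if (length(obj_coefs)) obj_coefs else NULL)
}

write_model_json <- function(model, path) {
  obj <- objective_vector(model)
  j <- list(
    id = model$id,
    version = "1",
    compartments = as.list(model$compartments),
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i)
      list(id = model$metabolites$id[i], name = model$metabolites$name[i],
           compartment = model$metabolites$compartment[i])),
    reactions = unname(lapply(model$reactions, function(r) {
      out <- list(id = r$id, name = r$name,
                  metabolites = as.list(r$stoichiometry),
                  lower_bound = r$lower_bound, upper_bound = r$upper_bound,
                  gene_reaction_rule = r$gpr)
      if (obj[r$id] != 0) out$objective_coefficient <- unname(obj[r$id])
      out
    })),
    genes = lapply(model$genes, function(g) list(id = g, name = g)))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_sanitize <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

write_model_sbml <- function(model, path) {
  bnds <- reaction_bounds(model)
  bound_vals <- sort(unique(c(bnds$lb, bnds$ub)))
  bound_ids <- stats::setNames(
    sprintf("fb_%d", seq_along(bound_vals)), sprintf("%.17g", bound_vals))
  bid <- function(v) unname(bound_ids[[sprintf("%.17g", v)]])
  obj <- objective_vector(model)
  gene_sbml <- stats::setNames(paste0("G_", sbml_sanitize(model$genes)),
                               model$genes)

  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  ln <- character()
  add <- function(...) ln[[length(ln) + 1L]] <<- paste0(...)
  add('<?xml version="1.0" encoding="UTF-8"?>')
  add(sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
              SBML_CORE_NS, SBML_FBC_NS))
  add(sprintf('  <model id="%s" name="%s" fbc:strict="true">',
              sbml_sanitize(model$id), esc(model$id)))
  add('    <listOfCompartments>')
  for (tag in names(model$compartments))
    add(sprintf('      <compartment id="%s" name="%s" constant="true"/>',
                sbml_sanitize(tag), esc(model$compartments[[tag]])))
  add('    </listOfCompartments>')
  add('    <listOfSpecies>')
  for (i in seq_len(nrow(model$metabolites)))
    add(sprintf(paste0('      <species id="M_%s" name="%s" compartment="%s" ',
                       'hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>'),
                sbml_sanitize(model$metabolites$id[i]),
                esc(model$metabolites$name[i]),
                sbml_sanitize(model$metabolites$compartment[i])))
  add('    </listOfSpecies>')
  add('    <listOfParameters>')
  for (k in seq_along(bound_vals))
    add(sprintf('      <parameter id="%s" value="%s" constant="true" sboTerm="SBO:0000626"/>',
                sprintf("fb_%d", k), format(bound_vals[k], digits = 17)))
  add('    </listOfParameters>')
  add('    <listOfReactions>')
  for (r in model$reactions) {
    st <- r$stoichiometry
    add(sprintf(paste0('      <reaction id="R_%s" name="%s" reversible="%s" fast="false" ',
                       'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
                sbml_sanitize(r$id), esc(r$name),
                if (r$lower_bound < 0) "true" else "false",
                bid(r$lower_bound), bid(r$upper_bound)))
    reac <- st[st < 0]; prod <- st[st > 0]
    if (length(reac)) {
      add('        <listOfReactants>')
      for (m in names(reac))
        add(sprintf('          <speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
                    sbml_sanitize(m), format(-reac[[m]], digits = 17)))
      add('        </listOfReactants>')
    }
    if (length(prod)) {
      add('        <listOfProducts>')
      for (m in names(prod))
        add(sprintf('          <speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
                    sbml_sanitize(m), format(prod[[m]], digits = 17)))
      add('        </listOfProducts>')
    }
    tree <- model$gpr_trees[[r$id]]
    if (!is.null(tree)) {
      add('        <fbc:geneProductAssociation>')
      render <- function(node, indent) {
        pad <- strrep(" ", indent)
        if (is.character(node)) {
          add(sprintf('%s<fbc:geneProductRef fbc:geneProduct="%s"/>',
                      pad, gene_sbml[[node]]))
        } else {
          tag <- if (node$op == "and") "fbc:and" else "fbc:or"
          add(sprintf("%s<%s>", pad, tag))
          for (a in node$args) render(a, indent + 2L)
          add(sprintf("%s</%s>", pad, tag))
        }
      }
      render(tree, 10L)
      add('        </fbc:geneProductAssociation>')
    }
    add('      </reaction>')
  }
  add('    </listOfReactions>')
  add('    <fbc:listOfObjectives fbc:activeObjective="obj">')
  add('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
  add('        <fbc:listOfFluxObjectives>')
  for (rid in names(obj)[obj != 0])
    add(sprintf('          <fbc:fluxObjective fbc:reaction="R_%s" fbc:coefficient="%s"/>',
                sbml_sanitize(rid), format(obj[[rid]], digits = 17)))
  add('        </fbc:listOfFluxObjectives>')
  add('      </fbc:objective>')
  add('    </fbc:listOfObjectives>')
  add('    <fbc:listOfGeneProducts>')
  for (g in model$genes)
    add(sprintf('      <fbc:geneProduct fbc:id="%s" fbc:label="%s"/>',
                gene_sbml[[g]], esc(g)))
  add('    </fbc:listOfGeneProducts>')
  add('  </model>')
  add('</sbml>')
  writeLines(ln, path)
  invisible(path)
}

strip_prefix <- function(x, prefix) {
  ifelse(startsWith(x, prefix), substring(x, nchar(prefix) + 1L), x)
}

read_model_sbml <- function(path, objective = NULL) {
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_CORE_NS, fbc = SBML_FBC_NS)
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mdl, "xml_missing")) stop("no <model> element in ", path)

  comp_nodes <- xml2::xml_find_all(mdl, ".//s:listOfCompartments/s:compartment", ns)
  compartments <- stats::setNames(
    ifelse(is.na(xml2::xml_attr(comp_nodes, "name")),
           xml2::xml_attr(comp_nodes, "id"),
           xml2::xml_attr(comp_nodes, "name")),
    xml2::xml_attr(comp_nodes, "id"))

  sp <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  if (!length(sp)) stop("model has no species: ", path)
  sp_id_raw <- xml2::xml_attr(sp, "id")
  mets <- data.frame(
    id = strip_prefix(sp_id_raw, "M_"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  strip_prefix(sp_id_raw, "M_"), xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)
  met_by_raw <- stats::setNames(mets$id, sp_id_raw)

  par_nodes <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  par_vals <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                              xml2::xml_attr(par_nodes, "id"))

  gp_nodes <- xml2::xml_find_all(mdl, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gp_label <- stats::setNames(
    ifelse(is.na(xml2::xml_attr(gp_nodes, "label")),
           strip_prefix(xml2::xml_attr(gp_nodes, "id"), "G_"),
           xml2::xml_attr(gp_nodes, "label")),
    xml2::xml_attr(gp_nodes, "id"))

  gpa_to_string <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- xml2::xml_attr(node, "geneProduct")
      lbl <- gp_label[[ref]] %||% strip_prefix(ref, "G_")
      return(lbl)
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, gpa_to_string, character(1))
    if (nm == "and") paste0("(", paste(parts, collapse = " and "), ")")
    else if (nm == "or") paste0("(", paste(parts, collapse = " or "), ")")
    else stop("unsupported gene association element <", nm, "> in ", path)
  }

  rx_nodes <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  rxns <- lapply(rx_nodes, function(rn) {
    rid <- strip_prefix(xml2::xml_attr(rn, "id"), "R_")
    reac <- xml2::xml_find_all(rn, "./s:listOfReactants/s:speciesReference", ns)
    prod <- xml2::xml_find_all(rn, "./s:listOfProducts/s:speciesReference", ns)
    st <- c(
      stats::setNames(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
                      met_by_raw[xml2::xml_attr(reac, "species")]),
      stats::setNames(as.numeric(xml2::xml_attr(prod, "stoichiometry")),
                      met_by_raw[xml2::xml_attr(prod, "species")]))
    if (anyNA(names(st)))
      stop("reaction ", rid, " references undeclared species in ", path)
    lb_ref <- xml2::xml_attr(rn, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(rn, "upperFluxBound")
    lb <- if (!is.na(lb_ref)) par_vals[[lb_ref]] else -1000
    ub <- if (!is.na(ub_ref)) par_vals[[ub_ref]] else 1000
    gpa <- xml2::xml_find_first(rn, "./fbc:geneProductAssociation/*", ns)
    gpr <- if (inherits(gpa, "xml_missing")) "" else gpa_to_string(gpa)
    rname <- xml2::xml_attr(rn, "name")
    list(id = rid,
         name = if (is.na(rname)) rid else rname,
         stoichiometry = st, lower_bound = lb, upper_bound = ub, gpr = gpr)
  })

  fo <- xml2::xml_find_all(
    mdl, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  obj_coefs <- stats::setNames(
    as.numeric(xml2::xml_attr(fo, "coefficient")),
    strip_prefix(xml2::xml_attr(fo, "reaction"), "R_"))
  obj_coefs <- obj_coefs[obj_coefs != 0]
  biomass <- objective
  if (is.null(biomass)) {
    if (!length(obj_coefs))
      stop("model ", path, " designates no objective reaction; supply `objective`")
    biomass <- names(obj_coefs)[which.max(abs(obj_coefs))]
  }
  mid <- xml2::xml_attr(mdl, "id")
  metabolic_model(
    id = if (is.na(mid)) tools::file_path_sans_ext(basename(path)) else mid,
    metabolites = mets, reactions = rxns,
    genes = if (length(gp_label)) unname(gp_label) else NULL,
    biomass = biomass,
    compartments = if (length(compartments)) compartments else NULL,
    objective = if (length(obj_coefs)) obj_coefs else NULL)
}
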
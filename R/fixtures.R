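#' Path to a packaged data file
#'
#' @param ... File name components under the package's `extdata` directory;
#'   with no arguments, the directory itself.
#' @return Absolute path.
#' @export
orthoflux_extdata <- function(...) {
  p <- system.file("extdata", ..., package = "orthoflux", mustWork = FALSE)
  if (!nzchar(p))
    stop("packaged data file not found: ", file.path(...))
  p
}

study_table_files <- c(
  ortholog_pairs = "ortholog_pairs.tsv",
  candidates = "candidates.tsv",
  active_sites = "active_sites.tsv",
  pathway_comparison = "pathway_comparison.tsv")

study_table_rows <- c(ortholog_pairs = 113L, candidates = 34L,
                      active_sites = 6L, pathway_comparison = 9L)

#' Load a curated study table
#'
#' The package bundles the curated tables of the active-site-variant
#' candidate study as plain TSV:
#' * `ortholog_pairs` — 113 human proteins carrying an active-site
#'   nonsynonymous variant, paired with their reciprocal best-hit yeast
#'   ortholog (`human_acc`, `yeast_acc`);
#' * `candidates` — the 34 enzymes with a 1 enzyme : 1 pathway : 1 reaction
#'   relationship: variant triple (`normal`, `variation`, `position`, with
#'   lowercase residue letters and `x` marking a stop/frameshift, as
#'   curated) and reaction chemistry (namespaced PubChem `CID:`/`SID:`
#'   substrate and product identifiers);
#' * `active_sites` — the 6 final pairs' annotated active-site positions and
#'   residues in both species plus the conserved block around the site;
#' * `pathway_comparison` — per-pathway conservation verdicts for the 6
#'   pairs (one row per pathway annotation).
#'
#' Row counts are verified on every load, so a corrupted installation fails
#' loudly.
#'
#' @param name One of `"ortholog_pairs"`, `"candidates"`, `"active_sites"`,
#'   `"pathway_comparison"`.
#' @return The table as a data frame.
#' @export
load_study_table <- function(name = names(study_table_files)) {
  name <- match.arg(name)
  path <- orthoflux_extdata(study_table_files[[name]])
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, quote = "")
  if (nrow(tab) != study_table_rows[[name]])
    stop("packaging error: ", name, " has ", nrow(tab),
         " rows, expected ", study_table_rows[[name]])
  tab
}

#' Enzyme annotations for the curated candidate pairs
#'
#' Combines the `candidates` chemistry (substrate/product compound IDs) and
#' the `pathway_comparison` pathway memberships into per-enzyme
#' [enzyme_annotation()] objects for the 6 final pairs: the human enzyme is
#' annotated with its human-side pathways, the yeast ortholog with every
#' pathway recorded for the pair (including yeast-only pathways, which share
#' the pair's single reaction chemistry).
#'
#' @return Named list of `enzyme_annotation`s keyed by accession (12
#'   entries: 6 human + 6 yeast).
#' @export
study_annotations <- function() {
  cand <- load_study_table("candidates")
  pw <- load_study_table("pathway_comparison")
  split_ids <- function(x) trimws(strsplit(x, "|", fixed = TRUE)[[1]])
  out <- list()
  for (h in unique(pw$human_acc)) {
    rows <- pw[pw$human_acc == h, , drop = FALSE]
    y <- rows$yeast_acc[1]
    crow <- cand[cand$accession == h, , drop = FALSE]
    stopifnot(nrow(crow) == 1L)
    rxn <- list(substrates = gsub("\\s+", "", split_ids(crow$substrate_id)),
                products = gsub("\\s+", "", split_ids(crow$product_id)))
    yeast_only <- grepl("only annotated in yeast", rows$details, ignore.case = TRUE)
    out[[h]] <- enzyme_annotation(h, pathways = rows$pathway[!yeast_only],
                                  reactions = list(rxn))
    out[[y]] <- enzyme_annotation(y, pathways = rows$pathway,
                                  reactions = list(rxn))
  }
  out
}

#' Path to the packaged toy metabolic model
#'
#' A 14-reaction branched network (glucose + galactose uptake, lumped
#' glycolysis, a pentose branch whose isomerase is the sole route to PRPP, a
#' two-gene heme-like cofactor branch required only by an augmented biomass,
#' and a maintenance drain). Wild-type growth has the closed form
#' `(10 + 4 - 0.5) / 2.5 = 5.4`: each biomass unit costs 2.5 hexose
#' equivalents and maintenance a fixed 0.5.
#'
#' @return Path to `toycell.json` (native JSON dialect).
#' @export
toy_model_path <- function() orthoflux_extdata("toycell.json")

#' Documented drop-in location for the external genome-scale yeast model
#'
#' Full-scale wild-type reproduction needs the published genome-scale yeast
#' consensus model (Yeast 7.0.0, SBML), which is too large to package and
#' must be supplied by the user: place the SBML file at the returned path
#' (or pass an explicit path to [load_model()]).
#'
#' @param filename Model file name searched for under `extdata/external`.
#' @return The expected path (which may not exist).
#' @export
yeast7_model_path <- function(filename = "yeast_7.00.xml") {
  file.path(system.file("extdata", package = "orthoflux"), "external", filename)
}
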
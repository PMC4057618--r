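#' Construct an enzyme annotation
#'
#' Pathway membership plus reaction chemistry for one enzyme. Compound
#' identifiers keep their namespace prefix (`CID:` for PubChem compounds,
#' `SID:` for substances); substrate/product comparisons are exact set
#' equality within namespace.
#'
#' @param accession Enzyme accession.
#' @param pathways Character vector of pathway labels (deduplicated).
#' @param reactions List of reactions, each a list with character vectors
#'   `substrates` and `products` of namespaced compound IDs.
#' @return Object of class `enzyme_annotation`.
#' @export
enzyme_annotation <- function(accession, pathways, reactions) {
  stopifnot(is.character(accession), length(accession) == 1L)
  pathways <- unique(as.character(pathways))
  reactions <- lapply(reactions, function(r) {
    stopifnot(all(c("substrates", "products") %in% names(r)))
    list(substrates = sort(unique(as.character(r$substrates))),
         products = sort(unique(as.character(r$products))))
  })
  # deduplicate identical substrate/product sets
  keys <- vapply(reactions, function(r)
    paste(paste(r$substrates, collapse = "|"), ">",
          paste(r$products, collapse = "|")), character(1))
  reactions <- reactions[!duplicated(keys)]
  structure(list(accession = accession, pathways = pathways,
                 reactions = reactions),
            class = "enzyme_annotation")
}

#' @export
print.enzyme_annotation <- function(x, ...) {
  cat(sprintf("<enzyme_annotation> %s: %d pathway(s), %d reaction(s)\n",
              x$accession, length(x$pathways), length(x$reactions)))
  invisible(x)
}

#' Does an enzyme have a 1 enzyme : 1 pathway : 1 reaction relationship?
#'
#' True iff the enzyme is annotated to exactly one pathway and catalyzes
#' exactly one reaction (one substrate/product set). Enzymes with no pathway
#' or no reaction annotation are indeterminate and return `NA` (callers
#' exclude them with reason `"unannotated"`).
#'
#' @param a An `enzyme_annotation`.
#' @return `TRUE`, `FALSE`, or `NA` for unannotated enzymes.
#' @export
is_one_one_one <- function(a) {
  stopifnot(inherits(a, "enzyme_annotation"))
  if (!length(a$pathways) || !length(a$reactions)) return(NA)
  length(a$pathways) == 1L && length(a$reactions) == 1L
}

#' Intersect candidates with reciprocal-ortholog pairs
#'
#' @param candidates Character vector of candidate accessions.
#' @param pairs Ortholog-pair data frame with column `query_acc` (the
#'   candidate-side accessions), e.g. from [reciprocal_best_hits()].
#' @return The surviving accessions, sorted (deterministic order).
#' @export
intersect_with_orthologs <- function(candidates, pairs) {
  sort(intersect(unique(candidates), pairs$query_acc), method = "radix")
}

#' Screen a query for a unique ortholog (no close paralogs)
#'
#' Operationalizes manual alignment inspection with explicit thresholds: the
#' query's ortholog is unique iff there is no second-best hit, or the
#' second-best bit score is at least `min_bit_margin` bits below the best, or
#' the second/best bit-score ratio is below `max_second_ratio`.
#'
#' @param acc Query accession.
#' @param all_hits Hit table containing all subjects per query (not only the
#'   best).
#' @param min_bit_margin Bits by which the best hit must beat the runner-up
#'   (default 50).
#' @param max_second_ratio Ratio `bit_second / bit_best` below which the
#'   ortholog counts as unique regardless of the margin (default 0.9).
#' @return `TRUE` if the ortholog is unique.
#' @export
paralog_screen <- function(acc, all_hits, min_bit_margin = 50,
                           max_second_ratio = 0.9) {
  h <- all_hits[all_hits$qseqid == acc, , drop = FALSE]
  if (!nrow(h)) stop("paralog_screen: no hits for query ", acc)
  bits <- sort(h$bitscore, decreasing = TRUE)
  if (length(bits) == 1L) return(TRUE)
  best <- bits[1]; second <- bits[2]
  second <= best - min_bit_margin || second / best < max_second_ratio
}

#' Compare pathway and reaction chemistry between orthologs
#'
#' Per-pathway verdicts:
#' * `SAME` — pathway annotated in both species and the (single) shared
#'   reaction has identical substrate and product compound-ID sets;
#' * `YEAST_ONLY_SAME_CHEMISTRY` — pathway annotated only in yeast but the
#'   yeast reaction chemistry matches the shared reaction (does not break the
#'   overall match);
#' * `HUMAN_ONLY` — pathway annotated only in the human enzyme;
#' * `MISMATCH` — pathway shared but substrate/product sets differ.
#'
#' The overall verdict is `TRUE` iff at least one pathway is `SAME` and no
#' shared pathway is `MISMATCH`.
#'
#' @param h,y `enzyme_annotation`s for the human enzyme and yeast ortholog.
#' @return List of class `pathway_comparison`: `verdicts` (named character
#'   vector over the union of pathways) and `overall_match`.
#' @export
pathway_compare <- function(h, y) {
  stopifnot(inherits(h, "enzyme_annotation"), inherits(y, "enzyme_annotation"))
  if (!length(h$pathways) || !length(y$pathways))
    stop("pathway_compare: empty annotation for ",
         if (!length(h$pathways)) h$accession else y$accession)
  same_chem <- function(r1, r2)
    identical(r1$substrates, r2$substrates) && identical(r1$products, r2$products)
  all_pw <- union(h$pathways, y$pathways)
  verdicts <- vapply(all_pw, function(pw) {
    in_h <- pw %in% h$pathways
    in_y <- pw %in% y$pathways
    if (in_h && in_y) {
      ok <- any(vapply(h$reactions, function(rh)
        any(vapply(y$reactions, function(ry) same_chem(rh, ry), logical(1))),
        logical(1)))
      if (ok) "SAME" else "MISMATCH"
    } else if (in_y) {
      ok <- any(vapply(y$reactions, function(ry)
        any(vapply(h$reactions, function(rh) same_chem(rh, ry), logical(1))),
        logical(1)))
      if (ok) "YEAST_ONLY_SAME_CHEMISTRY" else "MISMATCH"
    } else {
      "HUMAN_ONLY"
    }
  }, character(1))
  shared <- intersect(h$pathways, y$pathways)
  structure(list(verdicts = verdicts,
                 overall_match = any(verdicts[shared] == "SAME") &&
                   !any(verdicts[shared] == "MISMATCH")),
            class = "pathway_comparison")
}

#' @export
print.pathway_comparison <- function(x, ...) {
  cat("<pathway_comparison> overall match:", x$overall_match, "\n")
  for (pw in names(x$verdicts))
    cat(sprintf("  %-45s %s\n", pw, x$verdicts[pw]))
  invisible(x)
}
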
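#' Best hit per query
#'
#' For every query with at least one hit below the E-value threshold, keeps
#' the single hit with maximal bit score. Ties are broken by lower E-value,
#' then by lexicographically smallest subject accession, so reruns are
#' byte-identical.
#'
#' @param hits Hit data frame ([read_hit_table()] / [align_proteomes()]).
#' @param e_threshold Keep hits with `evalue < e_threshold` (default `1e-5`).
#' @return A hit data frame with one row per surviving query, ordered by
#'   query accession; queries with no passing hit are absent.
#' @export
best_hit_per_query <- function(hits, e_threshold = 1e-5) {
  stopifnot(is.data.frame(hits), e_threshold > 0)
  hits <- hits[hits$evalue < e_threshold, , drop = FALSE]
  if (!nrow(hits)) return(hits)
  ord <- order(hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid,
               method = "radix")
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits$qseqid), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Reciprocal best hits between two proteomes
#'
#' A pair (a, b) is reciprocal iff a's best hit is b and b's best hit is a.
#' Because each side contributes best hits only, the result is a partial
#' matching: no accession occurs in more than one pair.
#'
#' @param forward Best-hit table for species-A queries against species B
#'   (from [best_hit_per_query()]).
#' @param reverse Best-hit table for species-B queries against species A.
#' @return Data frame with columns `query_acc`, `subject_acc` (one row per
#'   mutual pair, sorted by `query_acc`) plus the supporting forward hit
#'   columns prefixed `fwd_` and reverse hit columns prefixed `rev_`.
#' @export
reciprocal_best_hits <- function(forward, reverse) {
  overlap <- intersect(forward$qseqid, reverse$qseqid)
  if (length(overlap))
    stop("query accession namespaces overlap between the two proteomes: ",
         paste(utils::head(overlap, 5), collapse = ", "))
  rev_best <- stats::setNames(reverse$sseqid, reverse$qseqid)
  mutual <- !is.na(rev_best[forward$sseqid]) &
    rev_best[forward$sseqid] == forward$qseqid
  fwd <- forward[mutual, , drop = FALSE]
  if (!nrow(fwd)) {
    return(data.frame(query_acc = character(), subject_acc = character(),
                      stringsAsFactors = FALSE))
  }
  rev <- reverse[match(fwd$sseqid, reverse$qseqid), , drop = FALSE]
  out <- data.frame(query_acc = fwd$qseqid, subject_acc = fwd$sseqid,
                    stringsAsFactors = FALSE)
  names(fwd) <- paste0("fwd_", names(fwd))
  names(rev) <- paste0("rev_", names(rev))
  out <- cbind(out, fwd, rev)
  out <- out[order(out$query_acc, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify every query by its hit topology
#'
#' Exhaustive, mutually exclusive labels per query:
#' * `NO_HIT` — absent from the forward best-hit table;
#' * `RECIPROCAL` — mutual best hit with its subject;
#' * `PARALOGOUS` — its best subject is also the best subject of a different,
#'   higher-scoring query (a many-to-one best-hit collision, resolved in
#'   favor of the highest bit score);
#' * `ONE_WAY_BEST` — has a best hit but mutuality fails and no
#'   higher-scoring query claims the same subject.
#'
#' @param queries Character vector of all query accessions (including those
#'   with no hits).
#' @param forward,reverse Best-hit tables from [best_hit_per_query()].
#' @return List with `labels` (named character vector over `queries`) and
#'   `counts` (table over the four classes).
#' @export
classify_queries <- function(queries, forward, reverse) {
  stopifnot(is.character(queries))
  labels <- stats::setNames(rep("NO_HIT", length(queries)), queries)
  pairs <- reciprocal_best_hits(forward, reverse)
  hit_idx <- match(queries, forward$qseqid)
  has_hit <- !is.na(hit_idx)
  labels[has_hit] <- "ONE_WAY_BEST"
  labels[queries %in% pairs$query_acc] <- "RECIPROCAL"
  # many-to-one collisions: for each subject claimed by >1 query, every
  # query except the top-scoring one is paralogous
  f <- forward[forward$qseqid %in% queries, , drop = FALSE]
  ord <- order(f$sseqid, -f$bitscore, f$evalue, f$qseqid, method = "radix")
  f <- f[ord, , drop = FALSE]
  losers <- f$qseqid[duplicated(f$sseqid)]
  labels[losers[labels[losers] != "RECIPROCAL"]] <- "PARALOGOUS"
  counts <- table(factor(labels,
                         levels = c("NO_HIT", "PARALOGOUS", "ONE_WAY_BEST", "RECIPROCAL")))
  list(labels = labels, counts = counts)
}
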
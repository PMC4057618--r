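# Per-column coordinate bookkeeping for one gapped pairwise alignment.
# Returns a data frame with one row per alignment column: the 1-based
# position in each ungapped sequence (NA where that row holds a gap) and the
# residue letters.
alignment_columns <- function(hit) {
  if (is.data.frame(hit)) hit <- as.list(hit[1, ])
  if (is.null(hit$qseq) || is.null(hit$sseq))
    stop("hit carries no gapped aligned strings (qseq/sseq); ",
         "use the extended 14-column hit dialect or align_pair()")
  qc <- strsplit(hit$qseq, "")[[1]]
  sc <- strsplit(hit$sseq, "")[[1]]
  if (length(qc) != length(sc)) stop("aligned strings differ in length")
  qpos <- ifelse(qc == "-", NA_integer_, hit$qstart - 1L + cumsum(qc != "-"))
  spos <- ifelse(sc == "-", NA_integer_, hit$sstart - 1L + cumsum(sc != "-"))
  data.frame(column = seq_along(qc) - 1L, q_res = qc, s_res = sc,
             q_pos = qpos, s_pos = spos, stringsAsFactors = FALSE)
}

#' Map a sequence position through a gapped alignment
#'
#' Translates a 1-based position in one sequence of a pairwise alignment to
#' the corresponding position in the partner sequence (same alignment
#' column). Positions aligned to a gap map to `NA` (distinct from positions
#' outside the aligned span, which raise an error). The mapping is strictly
#' increasing over non-gap columns.
#'
#' @param hit Alignment hit with gapped strings (`qseq`/`sseq`), e.g. from
#'   [align_pair()].
#' @param pos 1-based position in the source sequence.
#' @param direction `"query_to_subject"` or `"subject_to_query"`.
#' @return The partner 1-based position, or `NA` if the column holds a gap.
#' @export
map_position <- function(hit, pos, direction = c("query_to_subject",
                                                 "subject_to_query")) {
  direction <- match.arg(direction)
  cols <- alignment_columns(hit)
  src <- if (direction == "query_to_subject") cols$q_pos else cols$s_pos
  dst <- if (direction == "query_to_subject") cols$s_pos else cols$q_pos
  i <- match(pos, src)
  if (is.na(i)) {
    rng <- range(src, na.rm = TRUE)
    stop(sprintf("position %d outside the aligned span [%d, %d]",
                 pos, rng[1], rng[2]))
  }
  dst[i]
}

#' Active-site conservation across an ortholog pair
#'
#' For every annotated human active-site position, maps the position through
#' the pair's alignment and decides conservation. A site is conserved iff it
#' maps to a residue (not a gap), the residues are identical, and — when the
#' yeast protein carries its own curated active-site annotation — the mapped
#' position agrees with an annotated yeast site. When the yeast annotation is
#' absent, conservation is judged on residue identity alone and the mapping
#' is flagged `annotation_absent`. Sites outside the aligned span are
#' recorded as unconserved with a gap mapping, not raised as errors.
#'
#' @param hit Alignment hit (human as query, yeast as subject) with gapped
#'   strings.
#' @param human_sites Integer vector of 1-based human active-site positions.
#' @param yeast_sites Optional integer vector of annotated yeast active-site
#'   positions (`NULL` when no curated annotation exists).
#' @return Data frame with one row per human site: `human_pos`, `yeast_pos`
#'   (`NA` = gap), `human_residue`, `yeast_residue`, `column`,
#'   `annotation_agrees` (`NA` when no yeast annotation), `conserved`; the
#'   overall verdict (all sites conserved) is attached as attribute
#'   `"conserved"`.
#' @export
active_site_conserved <- function(hit, human_sites, yeast_sites = NULL) {
  stopifnot(length(human_sites) >= 1L)
  cols <- alignment_columns(hit)
  out <- lapply(human_sites, function(p) {
    i <- match(p, cols$q_pos)
    if (is.na(i)) {
      return(data.frame(human_pos = p, yeast_pos = NA_integer_,
                        human_residue = NA_character_,
                        yeast_residue = NA_character_, column = NA_integer_,
                        annotation_agrees = NA, conserved = FALSE))
    }
    ypos <- cols$s_pos[i]
    agrees <- if (is.null(yeast_sites) || is.na(ypos)) NA else ypos %in% yeast_sites
    conserved <- !is.na(ypos) &&
      cols$q_res[i] == cols$s_res[i] &&
      (is.na(agrees) || agrees)
    data.frame(human_pos = p, yeast_pos = ypos,
               human_residue = cols$q_res[i], yeast_residue = cols$s_res[i],
               column = cols$column[i], annotation_agrees = agrees,
               conserved = conserved)
  })
  out <- do.call(rbind, out)
  attr(out, "conserved") <- all(out$conserved)
  attr(out, "annotation_absent") <- is.null(yeast_sites)
  out
}

#' Conserved block around an alignment column
#'
#' Expands left and right from a site-containing alignment column while
#' columns are gap-free and score positively under the substitution matrix.
#' Identical columns render as the residue letter; positively-scoring
#' non-identical columns render as `'+'` (the alignment-midline convention).
#' Gap columns and columns scoring `<= 0` terminate the block. If the site
#' column itself is non-positive or gapped the block has length 1 and the
#' rendering rule is still applied.
#'
#' @param hit Alignment hit with gapped strings.
#' @param site_column 0-based alignment column of the site.
#' @param matrix Substitution matrix name or matrix (default BLOSUM62).
#' @return List of class `conservation_block` with `block` (the rendered
#'   string), `start`/`end` (0-based column range) and `contains_site`
#'   (always `TRUE`).
#' @export
conservation_block <- function(hit, site_column, matrix = "BLOSUM62") {
  cols <- alignment_columns(hit)
  if (site_column < 0L || site_column >= nrow(cols))
    stop("site_column ", site_column, " outside the alignment (0..",
         nrow(cols) - 1L, ")")
  mat <- substitution_matrix(matrix)
  colscore <- function(i) {
    if (cols$q_res[i] == "-" || cols$s_res[i] == "-") return(-Inf)
    mat[cols$q_res[i], cols$s_res[i]]
  }
  i0 <- site_column + 1L
  lo <- hi <- i0
  if (colscore(i0) > 0) {
    while (lo > 1L && colscore(lo - 1L) > 0) lo <- lo - 1L
    while (hi < nrow(cols) && colscore(hi + 1L) > 0) hi <- hi + 1L
  }
  render <- vapply(lo:hi, function(i) {
    if (cols$q_res[i] == cols$s_res[i] && cols$q_res[i] != "-") cols$q_res[i]
    else if (colscore(i) > 0) "+"
    else "."
  }, character(1))
  structure(list(block = paste(render, collapse = ""),
                 start = lo - 1L, end = hi - 1L, contains_site = TRUE),
            class = "conservation_block")
}

#' @export
print.conservation_block <- function(x, ...) {
  cat(sprintf("<conservation_block> columns %d-%d: %s\n", x$start, x$end, x$block))
  invisible(x)
}

#' Conservation report for a set of ortholog pairs
#'
#' Convenience driver: aligns each pair (or reuses hits carrying gapped
#' strings), applies [active_site_conserved()] and [conservation_block()],
#' and assembles a per-pair report table.
#'
#' @param pairs Data frame with columns `query_acc` (human) and `subject_acc`
#'   (yeast), e.g. from [reciprocal_best_hits()].
#' @param proteome Named vector/`AAStringSet` holding both species'
#'   sequences.
#' @param sites Data frame with columns `accession`, `position` (1-based),
#'   `residue` (site annotations for either species; absent yeast rows mean
#'   no curated yeast annotation).
#' @param matrix,gap_open,gap_extend Alignment scoring (global mode).
#' @return Data frame with one row per (pair, human site): accessions, human
#'   and mapped yeast positions/residues, `conserved`, `block`,
#'   `pair_conserved` (the pair-level all-sites verdict).
#' @export
conservation_report <- function(pairs, proteome, sites, matrix = "BLOSUM62",
                                gap_open = 11, gap_extend = 1) {
  proteome <- as_named_sequences(proteome)
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    h_acc <- pairs$query_acc[i]; y_acc <- pairs$subject_acc[i]
    if (!h_acc %in% names(proteome) || !y_acc %in% names(proteome))
      stop("conservation_report: sequence missing for pair ", h_acc, "/", y_acc)
    h_sites <- sites$position[sites$accession == h_acc]
    if (!length(h_sites))
      stop("conservation_report: no active-site annotation for ", h_acc)
    y_sites <- sites$position[sites$accession == y_acc]
    if (!length(y_sites)) y_sites <- NULL
    hit <- align_pair(proteome[[h_acc]], proteome[[y_acc]], mode = "global",
                      matrix = matrix, gap_open = gap_open,
                      gap_extend = gap_extend)
    hit$qseqid <- h_acc; hit$sseqid <- y_acc
    asc <- active_site_conserved(hit, h_sites, y_sites)
    blocks <- vapply(asc$column, function(cc) {
      if (is.na(cc)) return(NA_character_)
      conservation_block(hit, cc, matrix = matrix)$block
    }, character(1))
    rows[[length(rows) + 1L]] <- data.frame(
      human_acc = h_acc, yeast_acc = y_acc,
      human_site = asc$human_pos, yeast_site = asc$yeast_pos,
      human_residue = asc$human_residue, yeast_residue = asc$yeast_residue,
      conserved = asc$conserved, block = blocks,
      pair_conserved = attr(asc, "conserved"),
      annotation_absent = attr(asc, "annotation_absent"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
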
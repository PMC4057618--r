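#' Read a proteome from FASTA
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] that normalizes names
#' to the first whitespace-delimited token of the header (the accession) and
#' checks accession uniqueness.
#'
#' @param path FASTA file.
#' @return A named [Biostrings::AAStringSet].
#' @export
read_proteome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate accessions in ", path, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs
}

#' Write a proteome to FASTA
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param seqs Named [Biostrings::AAStringSet] or named character vector.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Construct a protein record
#'
#' A `protein_record` bundles a sequence with its species tag, annotated
#' active-site positions and nonsynonymous variants. Active-site annotations
#' are validated against the sequence: the annotated residue letter must
#' equal the sequence letter at that 1-based position.
#'
#' @param accession Accession string (unique within a proteome).
#' @param species One of `"human"`, `"yeast"`, `"other"`.
#' @param sequence Amino-acid string (uppercase; 20 standard letters plus X).
#' @param active_sites Optional data frame with columns `position` (1-based)
#'   and `residue` (single letters).
#' @param variants Optional data frame with columns `position`, `normal`,
#'   `variant` (single letters; `"x"` denotes a stop or frameshift).
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(accession, species, sequence,
                           active_sites = NULL, variants = NULL) {
  stopifnot(is.character(accession), length(accession) == 1L, nzchar(accession))
  species <- match.arg(species, c("human", "yeast", "other"))
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("empty sequence for ", accession)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", sequence))
    stop("non-amino-acid letters in sequence of ", accession)
  if (!is.null(active_sites) && nrow(active_sites)) {
    stopifnot(all(c("position", "residue") %in% names(active_sites)))
    if (any(active_sites$position < 1L | active_sites$position > nchar(sequence)))
      stop(accession, ": active-site position outside sequence")
    got <- substring(sequence, active_sites$position, active_sites$position)
    bad <- toupper(active_sites$residue) != got
    if (any(bad))
      stop(accession, ": annotated active-site residue disagrees with sequence at position ",
           paste(active_sites$position[bad], collapse = ", "))
  }
  if (!is.null(variants) && nrow(variants)) {
    stopifnot(all(c("position", "normal", "variant") %in% names(variants)))
    if (any(variants$position < 1L | variants$position > nchar(sequence)))
      stop(accession, ": variant position outside sequence")
  }
  structure(list(accession = accession, species = species, sequence = sequence,
                 active_sites = active_sites, variants = variants),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%s), %d aa, %d active site(s), %d variant(s)\n",
              x$accession, x$species, nchar(x$sequence),
              if (is.null(x$active_sites)) 0L else nrow(x$active_sites),
              if (is.null(x$variants)) 0L else nrow(x$variants)))
  invisible(x)
}

blast_columns <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                   "gapopen", "qstart", "qend", "sstart", "send",
                   "evalue", "bitscore")

#' Read a tabular alignment hit file
#'
#' Parses the 12-column tab-separated hit dialect
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`), or the extended 14-column dialect whose two extra
#' columns (`qseq`, `sseq`) carry the gapped aligned strings required for
#' position mapping.
#'
#' @param path Tab-separated hit file without header.
#' @return A data frame of hits; extended files gain `qseq`/`sseq` columns.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  raw <- readLines(path)
  raw <- raw[nzchar(raw) & !startsWith(raw, "#")]
  if (!length(raw))
    return(stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 12)), blast_columns))
  parts <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (!all(nf %in% c(12L, 14L)) || length(unique(nf)) != 1L)
    stop("malformed hit table ", path, ": line ",
         which(!nf %in% c(12L, 14L) | nf != nf[1])[1],
         " has ", nf[which(!nf %in% c(12L, 14L) | nf != nf[1])[1]],
         " fields (expected 12 or 14, consistently)")
  m <- do.call(rbind, parts)
  hits <- data.frame(qseqid = m[, 1], sseqid = m[, 2],
                     pident = as.numeric(m[, 3]), length = as.integer(m[, 4]),
                     mismatch = as.integer(m[, 5]), gapopen = as.integer(m[, 6]),
                     qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
                     sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
                     evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
                     stringsAsFactors = FALSE)
  num_bad <- which(is.na(hits$evalue) | is.na(hits$bitscore) | is.na(hits$pident))
  if (length(num_bad))
    stop("malformed hit table ", path, ": non-numeric score fields at line ",
         num_bad[1])
  if (nf[1] == 14L) {
    hits$qseq <- m[, 13]
    hits$sseq <- m[, 14]
    if (any(nchar(hits$qseq) != nchar(hits$sseq)))
      stop("malformed hit table ", path,
           ": aligned strings differ in length at line ",
           which(nchar(hits$qseq) != nchar(hits$sseq))[1])
  }
  hits
}

#' Write a tabular alignment hit file
#'
#' @param hits Data frame as returned by [read_hit_table()] or
#'   [align_proteomes()]; `qseq`/`sseq` columns, when present, produce the
#'   extended 14-column dialect.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  cols <- blast_columns
  if (all(c("qseq", "sseq") %in% names(hits))) cols <- c(cols, "qseq", "sseq")
  out <- hits[, cols, drop = FALSE]
  out$evalue <- formatC(out$evalue, format = "g", digits = 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
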
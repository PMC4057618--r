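#' Run the candidate-selection cascade
#'
#' Applies the five filtering stages in their fixed order:
#' 1. `one_one_one` — keep enzymes with a 1 enzyme : 1 pathway : 1 reaction
#'    relationship;
#' 2. `ortholog` — keep enzymes with a reciprocal best-hit ortholog;
#' 3. `conservation` — keep pairs whose annotated active site is conserved;
#' 4. `paralog` — keep queries whose ortholog passes [paralog_screen()];
#' 5. `pathway` — keep pairs whose pathway chemistry matches
#'    ([pathway_compare()]).
#'
#' Survivor sets are strictly nested and every dropped accession carries
#' exactly one reason — the first stage it failed. A survivor reaching the
#' conservation stage without a conservation verdict is a hard error: the
#' cascade never silently skips a record.
#'
#' @param candidates Character vector of candidate (human) accessions.
#' @param pairs Ortholog-pair data frame (`query_acc`, `subject_acc`).
#' @param conservation Data frame keyed by `human_acc` with logical column
#'   `pair_conserved` (e.g. aggregated from [conservation_report()]).
#' @param all_hits Forward hit table with all subjects per query, for the
#'   paralog screen.
#' @param annotations Named list of `enzyme_annotation`s covering candidates
#'   and their yeast orthologs.
#' @param min_bit_margin,max_second_ratio Paralog-screen thresholds.
#' @param skip Character vector of stage names to omit (stages can be
#'   skipped, never reordered).
#' @return Object of class `filter_report`: `stages` (ordered stage names),
#'   `survivors` (list of accession vectors per stage), `counts`, and
#'   `dropped` (data frame accession/stage/reason).
#' @export
run_filter_cascade <- function(candidates, pairs, conservation, all_hits,
                               annotations, min_bit_margin = 50,
                               max_second_ratio = 0.9, skip = character()) {
  stages <- c("one_one_one", "ortholog", "conservation", "paralog", "pathway")
  bad_skip <- setdiff(skip, stages)
  if (length(bad_skip)) stop("unknown stage(s) in skip: ",
                             paste(bad_skip, collapse = ", "))
  stages <- setdiff(stages, skip)
  current <- sort(unique(as.character(candidates)), method = "radix")
  survivors <- list()
  dropped <- data.frame(accession = character(), stage = character(),
                        reason = character(), stringsAsFactors = FALSE)
  drop <- function(accs, stage, reason) {
    if (length(accs))
      dropped <<- rbind(dropped, data.frame(accession = accs, stage = stage,
                                            reason = reason,
                                            stringsAsFactors = FALSE))
  }
  for (stage in stages) {
    keep <- switch(stage,
      one_one_one = {
        verdict <- vapply(current, function(a) {
          ann <- annotations[[a]]
          if (is.null(ann)) NA else is_one_one_one(ann)
        }, logical(1))
        drop(current[is.na(verdict)], stage, "unannotated")
        drop(current[!is.na(verdict) & !verdict], stage,
             "multiple pathways or reactions")
        current[!is.na(verdict) & verdict]
      },
      ortholog = {
        keep <- intersect_with_orthologs(current, pairs)
        drop(setdiff(current, keep), stage, "no reciprocal best-hit ortholog")
        keep
      },
      conservation = {
        idx <- match(current, conservation$human_acc)
        if (anyNA(idx))
          stop("run_filter_cascade: missing conservation result for ",
               paste(current[is.na(idx)], collapse = ", "))
        ok <- conservation$pair_conserved[idx]
        drop(current[!ok], stage, "active site not conserved")
        current[ok]
      },
      paralog = {
        ok <- vapply(current, paralog_screen, logical(1),
                     all_hits = all_hits, min_bit_margin = min_bit_margin,
                     max_second_ratio = max_second_ratio)
        drop(current[!ok], stage, "close paralog of the best hit")
        current[ok]
      },
      pathway = {
        ok <- vapply(current, function(a) {
          y <- pairs$subject_acc[match(a, pairs$query_acc)]
          ha <- annotations[[a]]; ya <- annotations[[y]]
          if (is.null(ha) || is.null(ya))
            stop("run_filter_cascade: missing pathway annotation for pair ",
                 a, "/", y)
          pathway_compare(ha, ya)$overall_match
        }, logical(1))
        drop(current[!ok], stage, "pathway or chemistry mismatch")
        current[ok]
      })
    survivors[[stage]] <- keep
    current <- keep
  }
  structure(list(stages = stages, survivors = survivors,
                 counts = vapply(survivors, length, integer(1)),
                 dropped = dropped),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  for (s in x$stages)
    cat(sprintf("  %-14s %4d survivor(s)\n", s, x$counts[[s]]))
  if (nrow(x$dropped)) {
    cat("  dropped:\n")
    for (i in seq_len(nrow(x$dropped)))
      cat(sprintf("    %-12s @ %-14s %s\n", x$dropped$accession[i],
                  x$dropped$stage[i], x$dropped$reason[i]))
  }
  invisible(x)
}
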
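ungapped_hit <- function(qseq, sseq, qstart = 1L, sstart = 1L) {
  data.frame(qseqid = "q", sseqid = "s", qstart = qstart, sstart = sstart,
             qseq = qseq, sseq = sseq, stringsAsFactors = FALSE)
}

test_that("position mapping reproduces offset arithmetic on an ungapped pair", {
  # subject leads by 11 residues: query position p maps to p + 11
  q <- random_aa(230)
  hit <- ungapped_hit(q, q, qstart = 1L, sstart = 12L)
  expect_equal(map_position(hit, 221, "query_to_subject"), 232)
  expect_equal(map_position(hit, 232, "subject_to_query"), 221)
})

test_that("gaps shift the mapping and gap columns map to NA", {
  hit <- ungapped_hit("AC-E", "ACDE")
  expect_equal(map_position(hit, 3, "query_to_subject"), 4)   # 'E'
  expect_true(is.na(map_position(hit, 3, "subject_to_query"))) # subject 'D'
})

test_that("positions outside the aligned span raise a distinct error", {
  hit <- ungapped_hit("ACDE", "ACDE", qstart = 10L, sstart = 10L)
  expect_error(map_position(hit, 2, "query_to_subject"), "outside the aligned span")
})

test_that("mapping round-trips and is strictly increasing", {
  set.seed(3)
  for (rep in 1:10) {
    a <- random_aa(40); b <- random_aa(35)
    hit <- align_pair(a, b, mode = "global")
    mapped <- vapply(seq_len(nchar(a)), function(p)
      map_position(hit, p, "query_to_subject"), integer(1))
    ok <- !is.na(mapped)
    # round trip over non-gap columns
    back <- vapply(mapped[ok], function(p)
      map_position(hit, p, "subject_to_query"), integer(1))
    expect_equal(back, which(ok))
    # strict monotonicity
    expect_true(all(diff(mapped[ok]) > 0))
  }
})

test_that("active-site conservation requires identity and annotation agreement", {
  # identical residue at site 5 in both
  s <- "MKRTAYWQED"
  hit <- ungapped_hit(s, s)
  asc <- active_site_conserved(hit, 5, 5)
  expect_true(attr(asc, "conserved"))

  # residue mismatch R -> K
  q <- "MKRTRYWQED"; y <- "MKRTKYWQED"
  asc2 <- active_site_conserved(ungapped_hit(q, y), 5, 5)
  expect_false(attr(asc2, "conserved"))

  # mapped position disagrees with the annotated yeast site by one
  asc3 <- active_site_conserved(ungapped_hit(q, q), 5, 6)
  expect_false(attr(asc3, "conserved"))
  expect_false(asc3$annotation_agrees)

  # no yeast annotation: identity alone decides, flagged annotation-absent
  asc4 <- active_site_conserved(ungapped_hit(q, q), 5, NULL)
  expect_true(attr(asc4, "conserved"))
  expect_true(attr(asc4, "annotation_absent"))
})

test_that("a site outside the alignment is recorded as a gap, not an error", {
  hit <- ungapped_hit("ACDE", "ACDE", qstart = 1L, sstart = 1L)
  asc <- active_site_conserved(hit, 9)
  expect_false(asc$conserved)
  expect_true(is.na(asc$yeast_pos))
})

test_that("conservation blocks render identity letters and '+' for positives", {
  # window scored (id, id, +, id): L/I scores +2 under BLOSUM62
  hit <- ungapped_hit("WWALAWW", "WWAIAWW")
  blk <- conservation_block(hit, 3L)
  expect_equal(blk$block, "WWA+AWW")
  expect_true(blk$start <= 3L && 3L <= blk$end)

  # all-identical 7-column window stays letters
  hit2 <- ungapped_hit("GDRCYQL", "GDRCYQL")
  expect_equal(conservation_block(hit2, 3L)$block, "GDRCYQL")
})

test_that("gap and non-positive columns terminate the block", {
  # D vs K scores -1: block must stop before it
  hit <- ungapped_hit("AADRRR", "AAKRRR")
  blk <- conservation_block(hit, 4L)
  expect_equal(blk$block, "RRR")
  expect_equal(blk$start, 3L)

  # site column itself non-positive: singleton block
  blk2 <- conservation_block(hit, 2L)
  expect_equal(nchar(blk2$block), 1L)
})

test_that("planted site fates drive the end-to-end conservation verdicts", {
  sim_ok <- simulate_proteomes(seed = 5, n_pairs = 3, target_identity = 0.7,
                               site_fate = "preserve")
  pairs <- data.frame(query_acc = sim_ok$truth$human_acc,
                      subject_acc = sim_ok$truth$yeast_acc,
                      stringsAsFactors = FALSE)
  rep_ok <- conservation_report(pairs, c(sim_ok$human, sim_ok$yeast), sim_ok$sites)
  expect_true(all(rep_ok$pair_conserved))

  sim_bad <- simulate_proteomes(seed = 5, n_pairs = 3, target_identity = 0.7,
                                site_fate = "mutate")
  pairs_bad <- data.frame(query_acc = sim_bad$truth$human_acc,
                          subject_acc = sim_bad$truth$yeast_acc,
                          stringsAsFactors = FALSE)
  rep_bad <- conservation_report(pairs_bad, c(sim_bad$human, sim_bad$yeast),
                                 sim_bad$sites)
  expect_false(any(rep_bad$pair_conserved))
})
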
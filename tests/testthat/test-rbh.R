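make_hit <- function(q, s, bits, evalue = 1e-20) {
  data.frame(qseqid = q, sseqid = s, pident = 90, length = 100, mismatch = 10,
             gapopen = 0, qstart = 1, qend = 100, sstart = 1, send = 100,
             evalue = evalue, bitscore = bits, stringsAsFactors = FALSE)
}

test_that("best hit per query keeps the top bit score with documented tie-breaks", {
  hits <- rbind(make_hit("q1", "s1", 50, 1e-6),
                make_hit("q1", "s2", 80, 1e-20),
                make_hit("q1", "s3", 80, 1e-18))
  best <- best_hit_per_query(hits, 1e-4)
  expect_equal(nrow(best), 1L)
  expect_equal(best$sseqid, "s2")  # equal bits, lower e-value wins

  # full tie: subject accession decides
  tie <- rbind(make_hit("q1", "sB", 80), make_hit("q1", "sA", 80))
  expect_equal(best_hit_per_query(tie, 1e-4)$sseqid, "sA")
})

test_that("queries whose hits all fail the threshold are absent", {
  hits <- rbind(make_hit("q1", "s1", 30, 0.5), make_hit("q2", "s1", 90, 1e-30))
  best <- best_hit_per_query(hits, 1e-5)
  expect_equal(best$qseqid, "q2")
})

test_that("reciprocal best hits form a partial matching", {
  fwd <- best_hit_per_query(rbind(make_hit("h1", "y1", 90),
                                  make_hit("h2", "y1", 70),
                                  make_hit("h3", "y2", 60)), 1e-5)
  rev <- best_hit_per_query(rbind(make_hit("y1", "h1", 88),
                                  make_hit("y2", "h9", 50)), 1e-5)
  pairs <- reciprocal_best_hits(fwd, rev)
  expect_equal(pairs$query_acc, "h1")
  expect_equal(pairs$subject_acc, "y1")
  expect_false(anyDuplicated(c(pairs$query_acc, pairs$subject_acc)) > 0)
})

test_that("swapping the two proteomes yields the same pairs, accessions swapped", {
  set.seed(7)
  sim <- simulate_proteomes(seed = 7, n_pairs = 4, target_identity = 0.7)
  fwd_hits <- align_proteomes(sim$human, sim$yeast)
  rev_hits <- align_proteomes(sim$yeast, sim$human)
  ab <- reciprocal_best_hits(best_hit_per_query(fwd_hits),
                             best_hit_per_query(rev_hits))
  ba <- reciprocal_best_hits(best_hit_per_query(rev_hits),
                             best_hit_per_query(fwd_hits))
  expect_setequal(paste(ab$query_acc, ab$subject_acc),
                  paste(ba$subject_acc, ba$query_acc))
})

test_that("overlapping accession namespaces are a configuration error", {
  fwd <- best_hit_per_query(make_hit("x1", "y1", 90), 1e-5)
  rev <- best_hit_per_query(make_hit("x1", "x2", 90), 1e-5)
  expect_error(reciprocal_best_hits(fwd, rev), "namespaces overlap")
})

test_that("query classification is exhaustive and mutually exclusive", {
  fwd <- best_hit_per_query(rbind(make_hit("h1", "y1", 90),
                                  make_hit("h2", "y1", 70),
                                  make_hit("h3", "y2", 60)), 1e-5)
  rev <- best_hit_per_query(rbind(make_hit("y1", "h1", 88),
                                  make_hit("y2", "h9", 50)), 1e-5)
  cl <- classify_queries(c("h1", "h2", "h3", "h4"), fwd, rev)
  expect_equal(unname(cl$labels["h1"]), "RECIPROCAL")
  expect_equal(unname(cl$labels["h2"]), "PARALOGOUS")
  expect_equal(unname(cl$labels["h3"]), "ONE_WAY_BEST")
  expect_equal(unname(cl$labels["h4"]), "NO_HIT")
  expect_equal(sum(cl$counts), 4L)
})

test_that("raising the e-value threshold never removes a reciprocal pair", {
  set.seed(11)
  sim <- simulate_proteomes(seed = 11, n_pairs = 5, target_identity = 0.6)
  fwd_hits <- align_proteomes(sim$human, sim$yeast)
  rev_hits <- align_proteomes(sim$yeast, sim$human)
  strict <- reciprocal_best_hits(best_hit_per_query(fwd_hits, 1e-10),
                                 best_hit_per_query(rev_hits, 1e-10))
  loose <- reciprocal_best_hits(best_hit_per_query(fwd_hits, 1e-3),
                                best_hit_per_query(rev_hits, 1e-3))
  expect_true(all(paste(strict$query_acc, strict$subject_acc) %in%
                  paste(loose$query_acc, loose$subject_acc)))
})
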
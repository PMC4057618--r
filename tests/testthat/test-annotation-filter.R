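ann <- function(acc, pathways, subs, prods) {
  enzyme_annotation(acc, pathways,
                    list(list(substrates = subs, products = prods)))
}

test_that("the 1:1:1 predicate counts pathways and reaction chemistry sets", {
  expect_true(is_one_one_one(ann("e1", "pw1", "CID:1", "CID:2")))
  expect_false(is_one_one_one(ann("e2", c("pw1", "pw2"), "CID:1", "CID:2")))
  # two reactions, same substrates but different products
  two_rxn <- enzyme_annotation("e3", "pw1",
    list(list(substrates = "CID:1", products = "CID:2"),
         list(substrates = "CID:1", products = "CID:3")))
  expect_false(is_one_one_one(two_rxn))
  # unannotated enzymes are indeterminate
  expect_true(is.na(is_one_one_one(enzyme_annotation("e4", character(), list()))))
})

test_that("ortholog intersection is a plain set intersection in stable order", {
  pairs <- data.frame(query_acc = c("P2", "P1"), subject_acc = c("Y2", "Y1"))
  expect_equal(intersect_with_orthologs(c("P1", "P3", "P2"), pairs),
               c("P1", "P2"))
  expect_equal(intersect_with_orthologs(character(), pairs), character())
  expect_equal(intersect_with_orthologs(c("P9"), pairs), character())
})

test_that("the paralog screen applies margin and ratio thresholds", {
  hits <- data.frame(qseqid = c("q", "q", "solo"),
                     sseqid = c("s1", "s2", "s9"),
                     bitscore = c(200, 190, 70))
  expect_true(paralog_screen("solo", hits))
  expect_false(paralog_screen("q", hits))            # margin 10 < 50, ratio 0.95
  hits$bitscore[2] <- 100
  expect_true(paralog_screen("q", hits))             # both criteria pass
  expect_error(paralog_screen("missing", hits), "no hits")
})

test_that("pathway comparison distinguishes SAME, yeast-only, and mismatches", {
  h <- ann("H", "porphyrin metabolism", "CID:137", "CID:1021")
  y <- enzyme_annotation("Y",
    c("porphyrin metabolism", "secondary metabolite biosynthesis"),
    list(list(substrates = "CID:137", products = "CID:1021")))
  cmp <- pathway_compare(h, y)
  expect_true(cmp$overall_match)
  expect_equal(unname(cmp$verdicts["porphyrin metabolism"]), "SAME")
  expect_equal(unname(cmp$verdicts["secondary metabolite biosynthesis"]),
               "YEAST_ONLY_SAME_CHEMISTRY")

  # identical annotations: all SAME
  cmp2 <- pathway_compare(h, ann("Y2", "porphyrin metabolism",
                                 "CID:137", "CID:1021"))
  expect_true(cmp2$overall_match)
  expect_true(all(cmp2$verdicts == "SAME"))

  # shared pathway, disjoint products: mismatch breaks the overall verdict
  cmp3 <- pathway_compare(h, ann("Y3", "porphyrin metabolism",
                                 "CID:137", "CID:9999"))
  expect_false(cmp3$overall_match)
  expect_equal(unname(cmp3$verdicts["porphyrin metabolism"]), "MISMATCH")
})

cascade_fixture <- function() {
  # hand-constructed inputs with a planted dropout at every stage:
  # c1 survives everything; c2 fails 1:1:1; c3 lacks an ortholog;
  # c4 fails conservation; c5 has a close paralog; c6 fails pathway match
  candidates <- paste0("c", 1:6)
  pairs <- data.frame(query_acc = c("c1", "c4", "c5", "c6"),
                      subject_acc = c("y1", "y4", "y5", "y6"),
                      stringsAsFactors = FALSE)
  conservation <- data.frame(
    human_acc = c("c1", "c4", "c5", "c6"),
    pair_conserved = c(TRUE, FALSE, TRUE, TRUE))
  hits <- data.frame(
    qseqid = c("c1", "c4", "c5", "c5", "c6"),
    sseqid = c("y1", "y4", "y5", "y5b", "y6"),
    bitscore = c(300, 250, 300, 295, 200))
  annotations <- list(
    c1 = ann("c1", "pw1", "CID:1", "CID:2"),
    c2 = ann("c2", c("pw1", "pw2"), "CID:1", "CID:2"),
    c3 = ann("c3", "pw3", "CID:5", "CID:6"),
    c4 = ann("c4", "pw4", "CID:7", "CID:8"),
    c5 = ann("c5", "pw5", "CID:9", "CID:10"),
    c6 = ann("c6", "pw6", "CID:11", "CID:12"),
    y1 = ann("y1", "pw1", "CID:1", "CID:2"),
    y4 = ann("y4", "pw4", "CID:7", "CID:8"),
    y5 = ann("y5", "pw5", "CID:9", "CID:10"),
    y6 = ann("y6", "pw6", "CID:11", "CID:99"))
  list(candidates = candidates, pairs = pairs, conservation = conservation,
       hits = hits, annotations = annotations)
}

test_that("the cascade drops one candidate per stage with a single reason each", {
  fx <- cascade_fixture()
  rep <- run_filter_cascade(fx$candidates, fx$pairs, fx$conservation,
                            fx$hits, fx$annotations)
  expect_equal(unname(rep$counts),
               c(5L, 4L, 3L, 2L, 1L))
  expect_equal(rep$survivors$pathway, "c1")
  # strict nesting
  for (k in seq_along(rep$stages)[-1])
    expect_true(all(rep$survivors[[k]] %in% rep$survivors[[k - 1]]))
  # one reason per dropped accession, at its first failing stage
  expect_equal(sort(rep$dropped$accession), paste0("c", 2:6))
  expect_equal(anyDuplicated(rep$dropped$accession), 0L)
  expect_equal(rep$dropped$stage[rep$dropped$accession == "c2"], "one_one_one")
  expect_equal(rep$dropped$stage[rep$dropped$accession == "c5"], "paralog")
})

test_that("the cascade is invariant to candidate input order", {
  fx <- cascade_fixture()
  rep1 <- run_filter_cascade(fx$candidates, fx$pairs, fx$conservation,
                             fx$hits, fx$annotations)
  rep2 <- run_filter_cascade(rev(fx$candidates), fx$pairs, fx$conservation,
                             fx$hits, fx$annotations)
  expect_identical(rep1$survivors, rep2$survivors)
})

test_that("missing conservation results are a hard error, empty input is not", {
  fx <- cascade_fixture()
  broken <- fx$conservation[fx$conservation$human_acc != "c4", ]
  expect_error(
    run_filter_cascade(fx$candidates, fx$pairs, broken, fx$hits,
                       fx$annotations),
    "missing conservation result for c4")
  empty <- run_filter_cascade(character(), fx$pairs, fx$conservation,
                              fx$hits, fx$annotations)
  expect_equal(unname(empty$counts), rep(0L, 5))
})
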
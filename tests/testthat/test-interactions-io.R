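test_that("TAB3 tables parse row-for-row with normalized symbols", {
  rows <- c(
    "trim28\tEsrrg\tTwo-hybrid\tphysical\tPUBMED:1\t9606\t9606",
    "TP53\tMDM2\tAffinity Capture-MS\tphysical\tPUBMED:2\t9606\t9606",
    " snca \tPRKN\tTwo-hybrid\tphysical\tPUBMED:3\t10090\t9606")
  path <- write_tab3_fixture(rows)
  rec <- read_interaction_table(path)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$interactor_a, c("TRIM28", "TP53", "SNCA"))
  expect_equal(rec$interactor_b, c("ESRRG", "MDM2", "PRKN"))
  expect_equal(rec$organism_a, c(9606L, 9606L, 10090L))
  expect_equal(rec$organism_b, rep(9606L, 3))
  expect_identical(attr(rec, "n_skipped"), 0L)
})

test_that("malformed rows are skipped and counted, comment lines ignored", {
  rows <- c(
    "A\tB\tTwo-hybrid\tphysical\tPUBMED:1\t9606\t9606",
    "# a comment line",
    "\tB\tTwo-hybrid\tphysical\tPUBMED:2\t9606\t9606",
    "C\tD\tTwo-hybrid\tphysical\tPUBMED:3\tnot-a-taxon\t9606")
  path <- write_tab3_fixture(rows)
  expect_message(rec <- read_interaction_table(path), "skipped 2")
  expect_equal(nrow(rec), 1L)
  expect_identical(attr(rec, "n_skipped"), 2L)
})

test_that("a dialect naming an absent column is a fatal error", {
  path <- write_tab3_fixture(
    "A\tB\tTwo-hybrid\tphysical\tPUBMED:1\t9606\t9606")
  bad <- biogrid_tab3_dialect(publication_id = "No Such Column")
  expect_error(read_interaction_table(path, bad), "No Such Column")
  expect_error(biogrid_tab3_dialect(nonsense = "x"), "unknown dialect")
})

test_that("collapse counts distinct evidence and enforces taxon/self rules", {
  rec <- rbind(
    evidence_df("B", "A", pub = "p1", sys = "m1"),
    evidence_df("A", "B", pub = "p2", sys = "m1"),
    evidence_df("A", "B", pub = "p2", sys = "m1"),   # verbatim duplicate
    evidence_df("C", "C", pub = "p3", sys = "m1"),   # self-loop
    evidence_df("A", "D", org_b = 10090L, pub = "p4", sys = "m1"))
  ed <- collapse_to_edges(rec, taxon = 9606L)
  expect_equal(nrow(ed), 1L)
  expect_equal(ed$gene_a, "A")   # canonical lexicographic order
  expect_equal(ed$gene_b, "B")
  expect_equal(ed$n_publications, 2L)
  expect_equal(ed$n_methods, 1L)
  expect_equal(ed$n_evidence, 2L)
})

test_that("identical evidence collapses to single-count edges", {
  rec <- rbind(evidence_df("X", "Y"), evidence_df("X", "Y"))
  ed <- collapse_to_edges(rec)
  expect_equal(ed$n_publications, 1L)
  expect_equal(ed$n_methods, 1L)
  expect_equal(ed$n_evidence, 1L)
})

test_that("collapse is order-independent and edges trace back to input", {
  set.seed(42)
  rec <- do.call(rbind, lapply(1:40, function(i)
    evidence_df(sample(LETTERS[1:6], 1), sample(LETTERS[1:6], 1),
                org_a = sample(c(9606L, 10090L), 1),
                org_b = sample(c(9606L, 10090L), 1),
                pub = paste0("p", sample(5, 1)),
                sys = paste0("m", sample(3, 1)))))
  suppressWarnings({
    e1 <- collapse_to_edges(rec)
    e2 <- collapse_to_edges(rec[sample(nrow(rec)), , drop = FALSE])
  })
  expect_equal(e1, e2)
  for (i in seq_len(nrow(e1))) {
    hit <- (rec$interactor_a == e1$gene_a[i] &
              rec$interactor_b == e1$gene_b[i]) |
           (rec$interactor_a == e1$gene_b[i] &
              rec$interactor_b == e1$gene_a[i])
    expect_true(any(hit & rec$organism_a == 9606L & rec$organism_b == 9606L))
    expect_true(e1$n_evidence[i] >=
                  max(e1$n_publications[i], e1$n_methods[i]))
  }
})

test_that("the evidence filter is a disjunction and is idempotent", {
  ed <- data.frame(gene_a = c("A", "C", "E"), gene_b = c("B", "D", "F"),
                   n_publications = c(2L, 1L, 1L),
                   n_methods = c(1L, 2L, 1L),
                   n_evidence = c(2L, 2L, 1L), stringsAsFactors = FALSE)
  kept <- filter_edges(ed)
  expect_equal(kept$gene_a, c("A", "C"))   # pub branch and method branch
  expect_equal(filter_edges(kept), kept)   # idempotent
  expect_equal(nrow(filter_edges(ed, 1L, 1L)), 3L)
  expect_error(filter_edges(ed, 0L, 1L))
})
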
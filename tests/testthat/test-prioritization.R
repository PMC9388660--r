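# A minimal convergence table + metrics pair with full control of raw
# values: every gene passes both filters so all are scored.
score_fixture <- function(conn, expr = unname(conn), enr = unname(conn),
                          genes = names(conn)) {
  cv <- data.frame(gene = genes,
                   observed_membership_number = 5L,
                   observed_proportion = 0.9,
                   expected_mean = 0.1, expected_sd = 0.01,
                   fold_enrichment = conn,
                   passes_sd_filter = TRUE, passes_membership_filter = TRUE,
                   is_restored_seed = FALSE, retained = TRUE,
                   stringsAsFactors = FALSE)
  class(cv) <- c("convergence_table", class(cv))
  met <- data.frame(gene = genes, abundance = expr,
                    relative_enrichment = enr,
                    present = TRUE, in_atlas = TRUE,
                    stringsAsFactors = FALSE)
  list(convergence = cv, metrics = met)
}

test_that("a triple category maximum scores exactly 3", {
  fx <- score_fixture(conn = c(BEST = 8, MID = 4, LOW = 2),
                      expr = c(12, 6, 3), enr = c(5, 2.5, 1))
  sc <- composite_scores(fx$convergence, fx$metrics)
  expect_identical(sc$composite[sc$gene == "BEST"], 3)
  expect_equal(sc$composite[sc$gene == "MID"], 1.5)   # half of each max
  expect_true(all(sc$composite >= 0 & sc$composite <= 3))
  expect_equal(max(sc$connectivity_norm), 1)
  expect_equal(max(sc$expression_norm), 1)
  expect_equal(max(sc$enrichment_norm), 1)
})

test_that("all-zero raw values give composite 0, zero categories warn", {
  fx <- score_fixture(conn = c(A = 2, Z = 0), expr = c(3, 0), enr = c(0, 0))
  expect_warning(sc <- composite_scores(fx$convergence, fx$metrics),
                 "enrichment")
  expect_equal(sc$composite[sc$gene == "Z"], 0)
  expect_true(all(sc$enrichment_norm == 0))
})

test_that("composite scoring is scale-invariant per category", {
  set.seed(9)
  conn <- runif(8, 0.5, 5); expr <- runif(8, 0, 20); enr <- runif(8, 0, 8)
  names(conn) <- sprintf("G%d", 1:8)
  a <- score_fixture(conn, expr, enr)
  b <- score_fixture(conn * 13, expr, enr)
  sa <- composite_scores(a$convergence, a$metrics)
  sb <- composite_scores(b$convergence, b$metrics)
  expect_equal(sa$composite, sb$composite)
  expect_equal(sa$gene, sb$gene)
})

test_that("restored seeds and atlas-missing genes follow the configuration", {
  fx <- score_fixture(conn = c(A = 4, B = 2, S = 1))
  fx$convergence$passes_sd_filter[3] <- FALSE
  fx$convergence$is_restored_seed[3] <- TRUE
  met <- fx$metrics[1:2, ]   # S missing from the atlas metrics too
  sc <- composite_scores(fx$convergence, met)
  expect_false("S" %in% sc$gene)
  sc2 <- composite_scores(fx$convergence, met,
                          include_restored_seeds = TRUE)
  s <- sc2[sc2$gene == "S", ]
  expect_true(s$atlas_missing)
  expect_equal(s$expression_raw, 0)

  fx$convergence$passes_sd_filter <- FALSE
  fx$convergence$is_restored_seed <- FALSE
  expect_error(composite_scores(fx$convergence, met), "nothing to score")
})

test_that("top targets are a deterministic ranked prefix", {
  fx <- score_fixture(conn = c(B = 3, A = 3, C = 1),
                      expr = c(1, 1, 9), enr = c(1, 1, 1))
  sc <- composite_scores(fx$convergence, fx$metrics)
  top2 <- top_targets(sc, 2)
  expect_equal(top2[1], "C")                 # unique expression maximum
  expect_equal(top2[2], "A")                 # tie broken alphabetically
  expect_equal(top_targets(sc, 2), top_targets(sc, 3)[1:2])  # prefix
  expect_equal(length(top_targets(sc, 25)), 3L)
})
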
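test_that("closed-form null matches the hand-derived hypergeometric values", {
  k5 <- closed_form_null(complete_graph(5), seed_set_size = 3)
  expect_true(all(k5$table$mean == 1))
  expect_true(all(k5$table$sd == 0))

  p5 <- closed_form_null(path_graph(), seed_set_size = 1)
  a <- p5$table[p5$table$gene == "A", ]
  expect_equal(a$mean, 3 / 5)           # |ball(A)| = |{A,B,C}| = 3 of 5
  expect_equal(a$sd, sqrt(0.6 * 0.4))   # k = 1: Bernoulli SD
  c_ <- p5$table[p5$table$gene == "C", ]
  expect_equal(c_$mean, 1)
  expect_equal(c_$sd, 0)

  # seed set = whole node set: every proportion is deterministic
  full <- closed_form_null(path_graph(), seed_set_size = 5)
  expect_true(all(full$table$sd == 0))
  expect_equal(full$table$mean[full$table$gene == "A"], 3 / 5)
})

test_that("Monte Carlo null is deterministic, bounded, and exact on K_n", {
  g <- complete_graph(6)
  mc <- simulate_null(g, 3, replicates = 50, rng_seed = 11)
  expect_true(all(mc$table$mean == 1))
  expect_true(all(mc$table$sd == 0))

  set.seed(5)
  h <- igraph::sample_gnp(40, 0.07)
  igraph::V(h)$name <- sprintf("N%02d", 1:40)
  a <- simulate_null(h, 6, replicates = 100, rng_seed = 42)
  b <- simulate_null(h, 6, replicates = 100, rng_seed = 42)
  expect_identical(a, b)
  d <- simulate_null(h, 6, replicates = 100, rng_seed = 43)
  expect_false(identical(a$table, d$table))
  expect_true(all(a$table$mean >= 0 & a$table$mean <= 1))
  expect_true(all(a$table$sd >= 0))
  expect_equal(nrow(a$table), igraph::vcount(h))   # entry for every node

  expect_error(simulate_null(h, 41), "seed_set_size")
  expect_error(simulate_null(h, 6, replicates = 0), "replicates")
})

test_that("Monte Carlo means converge on the analytic expectation", {
  g <- path_graph()
  mc <- simulate_null(g, 1, replicates = 4000, rng_seed = 2)
  cf <- closed_form_null(g, 1)
  se <- cf$table$sd / sqrt(4000)
  diff <- abs(mc$table$mean - cf$table$mean)
  expect_true(all(diff <= pmax(4 * se, 1e-12)))
})

test_that("the convergence table applies both exclusion rules", {
  genes <- c("HIT", "ONECOMM", "WEAK")
  st <- make_stats(genes, membership = c(3L, 1L, 2L), n_communities = 5L)
  nl <- make_null(genes, mean = c(0.20, 0.02, 0.30),
                  sd = c(0.05, 0.01, 0.05))
  # observed proportions: 0.6, 0.2, 0.4
  cv <- convergence_table(st, nl, sd_multiplier = 3, min_membership = 2)
  hit <- cv[cv$gene == "HIT", ]
  expect_equal(hit$fold_enrichment, 0.6 / 0.20)
  expect_true(hit$passes_sd_filter)       # 0.6 >= 0.20 + 3 * 0.05
  expect_true(hit$retained)
  expect_false(cv$retained[cv$gene == "ONECOMM"])  # single community
  expect_true(cv$passes_sd_filter[cv$gene == "ONECOMM"])
  expect_false(cv$passes_sd_filter[cv$gene == "WEAK"])
})

test_that("boundary case: a gene exactly at mean + 3 SD is retained", {
  st <- make_stats("G", membership = 2L, n_communities = 5L)  # obs 0.4
  nl <- make_null("G", mean = 0.25, sd = 0.05)                # 0.25+0.15
  cv <- convergence_table(st, nl)
  expect_true(cv$passes_sd_filter)
})

test_that("input seed genes are restored with their raw statistics", {
  genes <- c("S1", "X")
  st <- make_stats(genes, membership = c(1L, 3L), n_communities = 4L,
                   seed_genes = c("S1", "S2"))
  nl <- make_null(genes, mean = c(0.1, 0.1), sd = c(0.02, 0.02))
  cv <- convergence_table(st, nl)
  s1 <- cv[cv$gene == "S1", ]
  expect_true(s1$is_restored_seed)        # fails membership filter
  expect_true(s1$retained)
  s2 <- cv[cv$gene == "S2", ]             # absent from graph entirely
  expect_equal(nrow(s2), 1L)
  expect_true(s2$is_restored_seed)
  expect_equal(s2$observed_membership_number, 0L)
  expect_equal(s2$fold_enrichment, 0)
  expect_false(cv$is_restored_seed[cv$gene == "X"])
})

test_that("zero expectation is floored, mismatched universes are fatal", {
  st <- make_stats("G", membership = 2L, n_communities = 4L)
  nl <- make_null("G", mean = 0, sd = 0, replicates = 1000L)
  cv <- convergence_table(st, nl)
  expect_equal(cv$fold_enrichment, 0.5 / (1 / (1000 * 4)))
  expect_true(is.finite(cv$fold_enrichment))

  nl2 <- make_null("OTHER", mean = 0.1, sd = 0.1)
  expect_error(convergence_table(st, nl2), "universes")
  nl3 <- make_null("G", mean = 0.1, sd = 0.1, radius = 3L)
  expect_error(convergence_table(st, nl3), "radii")
})

test_that("raising either threshold never enlarges the retained set", {
  set.seed(123)
  for (i in 1:200) {
    n <- sample(5:20, 1)
    genes <- sprintf("G%02d", seq_len(n))
    ncomm <- sample(3:10, 1)
    st <- make_stats(genes, sample(1:ncomm, n, replace = TRUE), ncomm)
    nl <- make_null(genes, runif(n, 0, 0.5), runif(n, 0, 0.2))
    base <- retained_genes(convergence_table(st, nl, 2, 2L),
                           include_restored_seeds = FALSE)
    stricter_sd <- retained_genes(convergence_table(st, nl, 3, 2L),
                                  include_restored_seeds = FALSE)
    stricter_mm <- retained_genes(convergence_table(st, nl, 2, 3L),
                                  include_restored_seeds = FALSE)
    expect_true(all(stricter_sd %in% base))
    expect_true(all(stricter_mm %in% base))
  }
})
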
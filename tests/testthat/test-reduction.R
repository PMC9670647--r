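test_that("pairwise Pearson correlation matches hand values and contracts", {
  expect_equal(pearson_cor(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearson_cor(c(1, 2, 3), -c(1, 2, 3)), -1)
  expect_equal(pearson_cor(c(1, 2, 3), c(1, 2, 4)), 0.981981,
               tolerance = 1e-6)
  expect_error(pearson_cor(1:3, 1:4), "length")
  expect_true(is.na(pearson_cor(c(1, 2, NA), c(1, NA, 3), min_pairs = 2)))
  expect_true(is.na(pearson_cor(c(1, 1, 1), c(1, 2, 3))))
  # pairwise deletion: NA rows are dropped, not propagated
  expect_equal(pearson_cor(c(1, 2, 3, NA), c(1, 2, 4, 5), min_pairs = 3),
               0.981981, tolerance = 1e-6)
})

test_that("Benjamini-Hochberg matches the hand step-up computation", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(benjamini_hochberg(0.37), 0.37) # m = 1 identity
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(31)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    adj <- benjamini_hochberg(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(diff(adj[order(p)]) >= -1e-15)) # monotone in sorted order
  }
})

test_that("the normality screen flags gross non-normality but not Gaussian noise", {
  set.seed(12)
  vals <- cbind(matrix(rnorm(500 * 5), 500, 5),
                two_point = sample(c(0, 50), 500, replace = TRUE))
  colnames(vals) <- c(sprintf("gauss%d", 1:5), "two_point")
  tab <- make_table(vals)
  res <- shapiro_wilk_screen(tab)
  expect_true(res$flagged[res$name == "two_point"])
  expect_lt(res$p[res$name == "two_point"], 1e-10)
  expect_false(any(res$flagged[grepl("gauss", res$name)]))

  # single-variable table: BH is the identity at m = 1
  one <- make_table(matrix(rnorm(100), 100, 1))
  r1 <- shapiro_wilk_screen(one)
  expect_equal(r1$p_adj, r1$p)

  # too few values -> unevaluable, not fatal
  short <- make_table(matrix(c(1, 2, NA, NA, NA, NA, 1, 2, 3, 4, 5, 6), 6, 2))
  rs <- shapiro_wilk_screen(short)
  expect_false(rs$evaluable[1])
  expect_true(rs$evaluable[2])
})

test_that("the autocorrelation graph joins duplicates and honours the mode", {
  set.seed(3)
  x <- rnorm(60)
  vals <- cbind(a = x, b = x, c = x, d = rnorm(60), e = -x)
  tab <- make_table(vals)
  g <- build_autocorrelation_graph(tab, threshold = 0.9, min_pairs = 30)
  expect_setequal(igraph::V(g)$name, c("a", "b", "c", "d", "e"))
  # the three copies form a triangle
  sub <- igraph::induced_subgraph(g, c("a", "b", "c"))
  expect_equal(igraph::ecount(sub), 3)
  # signed mode: the negated copy is NOT an autocorrelate
  expect_equal(unname(igraph::degree(g, "e")), 0)
  expect_equal(unname(igraph::degree(g, "d")), 0)
  # absolute mode: it is
  ga <- build_autocorrelation_graph(tab, threshold = 0.9,
                                    threshold_mode = "absolute", min_pairs = 30)
  expect_equal(unname(igraph::degree(ga, "e")), 3)
})

test_that("planted blocks become connected components of the autocorrelation graph", {
  d <- synthetic_design(n_counties = 1000, n_blocks = 4, block_size = 4,
                        n_clusters = 1, n_noise_vars = 6, seed = 8)
  gen <- generate_synthetic(d)
  g <- build_autocorrelation_graph(gen$table, threshold = 0.9, min_pairs = 30)
  comp <- igraph::components(g)
  for (blk in gen$truth$blocks) {
    ids <- comp$membership[blk]
    expect_length(unique(ids), 1)                    # block is connected
    expect_equal(sum(comp$membership == ids[1]), length(blk)) # and nothing else
  }
})

test_that("minimum dominating set is exact on canonical graphs", {
  star <- named_graph(c("hub", "l1", "hub", "l2", "hub", "l3", "hub", "l4"))
  expect_identical(minimum_dominating_set(star), "hub")

  edgeless <- igraph::make_empty_graph(6, directed = FALSE)
  igraph::V(edgeless)$name <- letters[1:6]
  expect_identical(minimum_dominating_set(edgeless), letters[1:6])

  c6 <- named_graph(c("a","b","b","c","c","d","d","e","e","f","f","a"))
  expect_length(minimum_dominating_set(c6), 2)

  p4 <- named_graph(c("a","b","b","c","c","d"))
  expect_length(minimum_dominating_set(p4), 2)
})

test_that("dominating sets match brute force and carry a certificate", {
  set.seed(17)
  for (i in 1:30) {
    g <- random_gnp(sample(4:12, 1), runif(1, 0.1, 0.5), seed = 100 + i)
    s <- minimum_dominating_set(g)
    expect_true(is_dominating_set(g, s))
    expect_identical(length(s), oracle_mds_size(g))
    # greedy fallback always dominates (not necessarily minimum)
    sg <- minimum_dominating_set(g, method = "greedy")
    expect_true(is_dominating_set(g, sg))
    expect_gte(length(sg), length(s))
  }
})

test_that("among optimal dominating sets the lexicographically smallest wins", {
  k2 <- named_graph(c("zebra", "aardvark"))
  expect_identical(minimum_dominating_set(k2), "aardvark")
  k4 <- named_graph(c("d","b","d","c","d","a","b","c","b","a","c","a"))
  expect_identical(minimum_dominating_set(k4), "a")
})

test_that("the name filter removes exactly the matching columns", {
  vals <- matrix(rnorm(40), 10, 4)
  colnames(vals) <- c("Median income margin of error", "Percent in poverty",
                      "poverty 95% CI upper", "heat days")
  tab <- make_table(vals)
  res <- name_pattern_filter(tab)
  expect_setequal(res$removed, c("Median income margin of error",
                                 "poverty 95% CI upper"))
  expect_setequal(variables(res$table), c("Percent in poverty", "heat days"))
  expect_warning(res0 <- name_pattern_filter(tab, character()), "empty")
  expect_identical(variables(res0$table), variables(tab))
})

test_that("the name filter removes exactly the planted margin-of-error set", {
  d <- synthetic_design(n_counties = 150, n_noise_vars = 10, seed = 13)
  tab <- plant_moe_variables(generate_synthetic(d)$table, 0.15, seed = 13)
  res <- name_pattern_filter(tab)
  expect_setequal(res$removed, attr(tab, "planted_moe"))
})

test_that("reduction keeps one representative per block and is idempotent", {
  d <- synthetic_design(n_counties = 800, n_blocks = 5, block_size = 3,
                        n_clusters = 1, n_noise_vars = 8, seed = 19)
  gen <- generate_synthetic(d)
  red <- reduce_variables(gen$table, min_pairs = 30)
  for (blk in gen$truth$blocks) {
    expect_length(intersect(red$dominating_set, blk), 1)
  }
  expect_identical(red$n_after_mds, length(red$dominating_set))
  expect_lte(red$n_after_name_filter, red$n_after_mds)
  # idempotence: the reduced table's autocorrelation graph is edgeless,
  # so a second pass removes nothing
  red2 <- reduce_variables(red$table, min_pairs = 30)
  expect_identical(red2$n_after_mds, red$n_after_name_filter)
  expect_equal(igraph::ecount(red2$graph), 0)
})
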
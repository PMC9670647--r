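test_that("the empty-parent local score equals the closed-form Gaussian BIC", {
  set.seed(51)
  y <- rnorm(400)
  dat <- cbind(y = y)
  got <- local_bic("y", character(), dat)
  n <- length(y)
  sigma2 <- mean((y - mean(y))^2)
  want <- -(n / 2) * (log(2 * pi * sigma2) + 1) - (2 / 2) * log(n)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("an irrelevant parent costs about (1/2) ln N on average", {
  set.seed(52)
  n <- 500
  drops <- replicate(60, {
    dat <- cbind(x = rnorm(n), y = rnorm(n))
    local_bic("y", character(), dat) - local_bic("y", "x", dat)
  })
  # mean drop = (1/2) ln N - E[chi2_1]/2 = (1/2) ln N - 1/2
  expect_lt(abs(mean(drops) - (0.5 * log(n) - 0.5)), 0.35)
})

test_that("degenerate inputs are guarded", {
  set.seed(53)
  x <- rnorm(100)
  dat <- cbind(x = x, x2 = 2 * x, y = 3 * x + 1)
  # exact linear child: variance floor keeps the score finite
  s <- local_bic("y", "x", dat)
  expect_true(is.finite(s))
  # collinear parents are named in the error
  expect_error(local_bic("y", c("x", "x2"), dat), "x2")
  expect_error(local_bic("x", character(), cbind(x = rep(1, 50))), "constant")
  expect_error(local_bic("y", "x", cbind(x = 1:3, y = c(1, 2, NA))), "complete")
})

test_that("Markov-equivalent two-node structures score identically", {
  set.seed(54)
  n <- 300
  x <- rnorm(n); y <- 1.5 * x + rnorm(n)
  dat <- cbind(x = x, y = y)
  fwd <- local_bic("x", character(), dat) + local_bic("y", "x", dat)
  bwd <- local_bic("y", character(), dat) + local_bic("x", "y", dat)
  expect_equal(fwd, bwd, tolerance = 1e-8 * abs(fwd))
})

test_that("hill climbing leaves independent variables unconnected", {
  set.seed(55)
  n <- 2000
  dat <- cbind(a = rnorm(n), b = rnorm(n))
  # oracle: the empty DAG outscores either single-arc DAG on these data
  empty <- local_bic("a", character(), dat) + local_bic("b", character(), dat)
  one_arc <- local_bic("a", character(), dat) + local_bic("b", "a", dat)
  expect_gt(empty, one_arc)
  dag <- hill_climb(dat)
  expect_identical(nrow(dag$arcs), 0L)
})

test_that("hill climbing recovers a single strong dependency as one arc", {
  set.seed(56)
  n <- 2000
  x <- rnorm(n)
  dat <- cbind(x = x, y = 2 * x + rnorm(n))
  dag <- hill_climb(dat)
  expect_identical(nrow(dag$arcs), 1L)
  expect_setequal(as.vector(dag$arcs), c("x", "y"))
})

test_that("every returned DAG is acyclic, decomposable, and locally optimal", {
  set.seed(57)
  n <- 400
  x <- rnorm(n); y <- x + rnorm(n); z <- y + rnorm(n); w <- rnorm(n)
  dat <- cbind(x = x, y = y, z = z, w = w)
  dag <- hill_climb(dat)
  expect_true(igraph::is_dag(
    igraph::graph_from_adjacency_matrix(dag$adjacency * 1, mode = "directed")))
  expect_equal(dag$score_total, sum(dag$per_node_score), tolerance = 1e-12)
  # per-node bookkeeping matches from-scratch rescoring
  rescored <- vapply(dag$nodes, function(v) {
    local_bic(v, dag$nodes[dag$adjacency[, v]], dat)
  }, numeric(1))
  expect_equal(unname(dag$per_node_score[dag$nodes]), unname(rescored),
               tolerance = 1e-10)
  expect_true(is_locally_optimal(dag, dat))
})

test_that("hill climbing finds the exhaustive 3-node optimum on most simulations", {
  set.seed(58)
  hits <- 0L
  n_sim <- 10
  for (i in seq_len(n_sim)) {
    n <- 150
    b1 <- runif(1, -2, 2); b2 <- runif(1, -2, 2)
    x <- rnorm(n); y <- b1 * x + rnorm(n); z <- b2 * y + rnorm(n)
    dat <- cbind(x = x, y = y, z = z)
    dag <- hill_climb(dat)
    if (abs(dag$score_total - oracle_best_bic3(dat)) < 1e-6) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.9 * n_sim))
})

test_that("direct predictors are the outcome's parents, with its Markov blanket", {
  nodes <- c("A", "B", "PRM", "C")
  A <- matrix(FALSE, 4, 4, dimnames = list(nodes, nodes))
  A["A", "PRM"] <- TRUE; A["B", "PRM"] <- TRUE; A["PRM", "C"] <- TRUE
  dag <- phescreen:::new_learned_dag(A, stats::setNames(rep(-1, 4), nodes))
  dp <- direct_predictors(dag, "PRM")
  expect_identical(dp$predictors, c("A", "B"))
  expect_identical(dp$markov_blanket, c("A", "B", "C"))
  expect_error(direct_predictors(dag, "nope"), "not in network")

  # chain: direct vs ancestral distinction
  B <- matrix(FALSE, 3, 3, dimnames = list(c("X","Y","PRM"), c("X","Y","PRM")))
  B["X", "Y"] <- TRUE; B["Y", "PRM"] <- TRUE
  chain <- phescreen:::new_learned_dag(B, stats::setNames(rep(-1, 3), c("X","Y","PRM")))
  expect_identical(direct_predictors(chain, "PRM")$predictors, "Y")

  # empty DAG: no predictors
  C <- matrix(FALSE, 2, 2, dimnames = list(c("X","PRM"), c("X","PRM")))
  empty <- phescreen:::new_learned_dag(C, stats::setNames(rep(-1, 2), c("X","PRM")))
  expect_identical(direct_predictors(empty, "PRM")$predictors, character())
})

test_that("per-domain learning yields one network per non-empty list plus overall", {
  d <- synthetic_design(n_counties = 500, n_noise_vars = 10, seed = 59)
  gen <- generate_synthetic(d)
  lt <- link_outcomes(gen$table, apply_inclusion(gen$outcomes), "total")
  sc <- screen_correlates(lt, "prm_total", min_pairs = 30)
  # force most domains empty by a harsh retention rule, then a looser one
  nets <- suppressMessages(run_per_domain(lt, sc, "prm_total", k = 5))
  retained_domains <- unique(sc$entries$domain[sc$entries$retained])
  expect_setequal(names(nets), c("overall", retained_domains))
  for (nm in names(nets)) {
    expect_s3_class(nets[[nm]], "learned_dag")
    expect_true("prm_total" %in% nets[[nm]]$nodes)
  }
})

test_that("learning refuses too few complete rows", {
  dat <- matrix(rnorm(12), 3, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  expect_error(hill_climb(dat), "complete rows")
})
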
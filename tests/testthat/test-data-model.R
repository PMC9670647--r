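test_that("reading a table zero-pads FIPS and turns non-numeric cells into NA", {
  dat <- tempfile(fileext = ".csv"); meta <- tempfile(fileext = ".csv")
  writeLines(c("fips,povrate,income",
               "1001,0.21,43000",
               "6037,NA,61000",
               "45001,0.18,not-a-number"), dat)
  writeLines(c("name,domain", "povrate,social", "income,social"), meta)
  tab <- read_exposome_table(dat, meta)
  expect_identical(fips_keys(tab), c("01001", "06037", "45001"))
  expect_true(is.na(tab$values["06037", "povrate"]))
  expect_true(is.na(tab$values["45001", "income"]))
  expect_equal(tab$values["01001", "income"], 43000)
})

test_that("duplicate FIPS and uncovered columns are hard errors", {
  dat <- tempfile(fileext = ".csv"); meta <- tempfile(fileext = ".csv")
  writeLines(c("fips,x", "01001,1", "1001,2"), dat)
  writeLines(c("name,domain", "x,built"), meta)
  expect_error(read_exposome_table(dat, meta), "duplicate FIPS")

  writeLines(c("fips,x,y", "01001,1,2", "01003,3,4"), dat)
  expect_error(read_exposome_table(dat, meta), "y")
})

test_that("exposome tables round-trip through CSV", {
  set.seed(11)
  vals <- matrix(rnorm(12), 4, 3)
  vals[2, 3] <- NA
  tab <- make_table(vals)
  dat <- tempfile(fileext = ".csv"); meta <- tempfile(fileext = ".csv")
  write_exposome_table(tab, dat, meta)
  back <- read_exposome_table(dat, meta)
  expect_equal(back$values, tab$values, tolerance = 1e-12)
  expect_identical(back$meta$domain, tab$meta$domain)
})

test_that("constructor rejects inconsistent metadata and bad domains", {
  vals <- matrix(1:4, 2, 2, dimnames = list(c("00001", "00002"), c("a", "b")))
  expect_error(exposome_table(vals, data.frame(name = "a", domain = "built")),
               "do not match")
  expect_error(
    exposome_table(vals, data.frame(name = c("a", "b"),
                                    domain = c("built", "cosmic"))),
    "cosmic")
})

test_that("correlation graphs round-trip including isolated vertices and signs", {
  tri <- correlation_graph(
    c("a", "b", "c"),
    data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"),
               weight = c(0.95, 0.92, 0.91)),
    threshold = 0.9, threshold_mode = "signed", min_pairs = 30L)
  p <- tempfile(fileext = ".txt")
  write_correlation_graph(tri, p)
  back <- read_correlation_graph(p)
  expect_setequal(igraph::V(back)$name, c("a", "b", "c"))
  eb <- igraph::as_data_frame(back)
  eo <- igraph::as_data_frame(tri)
  key <- function(d) paste(pmin(d$from, d$to), pmax(d$from, d$to))
  expect_equal(eb$weight[order(key(eb))], eo$weight[order(key(eo))],
               tolerance = 1e-6)
  expect_equal(igraph::graph_attr(back, "threshold"), 0.9)

  iso <- correlation_graph(c("x", "y", "z"),
                           data.frame(from = character(), to = character(),
                                      weight = numeric()),
                           threshold = 0.9)
  write_correlation_graph(iso, p)
  back <- read_correlation_graph(p)
  expect_setequal(igraph::V(back)$name, c("x", "y", "z"))
  expect_equal(igraph::ecount(back), 0)

  neg <- correlation_graph(c("u", "v"),
                           data.frame(from = "u", to = "v", weight = -0.4),
                           threshold = 0.15, threshold_mode = "absolute")
  write_correlation_graph(neg, p)
  expect_equal(igraph::E(read_correlation_graph(p))$weight, -0.4,
               tolerance = 1e-6)
})

test_that("malformed graph files report the offending line", {
  p <- tempfile(fileext = ".txt")
  writeLines(c("# correlation graph: threshold=0.9 mode=signed min_pairs=30",
               "*vertices", "a", "b", "*edges", "a\tb"), p)
  expect_error(read_correlation_graph(p), "line 6")
  writeLines(c("*vertices", "a"), p)
  expect_error(read_correlation_graph(p), "malformed")
})

test_that("DAG DOT files round-trip nodes and arcs", {
  dag <- phescreen:::new_learned_dag(
    matrix(c(FALSE, TRUE, FALSE,
             FALSE, FALSE, FALSE,
             TRUE, FALSE, FALSE), 3, 3, byrow = TRUE,
           dimnames = list(c("a", "b", "c"), c("a", "b", "c"))),
    per_node_score = c(a = -1, b = -2, c = -3))
  p <- tempfile(fileext = ".dot")
  write_dag_dot(dag, p)
  back <- read_dag_dot(p)
  expect_setequal(back$nodes, c("a", "b", "c"))
  expect_equal(nrow(back$arcs), 2)
  expect_true(all(paste(back$arcs[, 1], back$arcs[, 2]) %in%
                    c("a b", "c a")))
})

test_that("link_outcomes restricts to included counties and appends one column", {
  vals <- matrix(rnorm(10), 5, 2,
                 dimnames = list(c("01001", "01003", "01005", "01007", "01009"),
                                 c("x1", "x2")))
  tab <- make_table(vals)
  out <- apply_inclusion(small_outcomes())
  linked <- link_outcomes(tab, out, "total")
  expect_identical(sort(fips_keys(linked)), c("01001", "01003", "01007"))
  expect_identical(ncol(linked$values), 3L)
  expect_true("prm_total" %in% variables(linked))
  expect_equal(linked$values["01001", "prm_total"], 2 / 5000 * 1e5)

  # all included: row count unchanged, column count +1
  all_in <- apply_inclusion(small_outcomes(), min_births = 0)
  linked2 <- link_outcomes(tab, all_in, "total")
  expect_identical(dim(linked2$values), c(5L, 3L))
})

test_that("outcome counties missing from the table are dropped with a warning", {
  vals <- matrix(rnorm(4), 2, 2,
                 dimnames = list(c("01001", "01003"), c("x1", "x2")))
  tab <- make_table(vals)
  out <- apply_inclusion(small_outcomes())
  expect_warning(linked <- link_outcomes(tab, out, "total"), "dropped")
  expect_identical(sort(fips_keys(linked)), c("01001", "01003"))

  far <- make_table(matrix(rnorm(2), 1, 2,
                           dimnames = list("56045", c("x1", "x2"))))
  expect_error(link_outcomes(far, out, "total"), "no overlapping FIPS")
  expect_error(link_outcomes(tab, out, "nh_black"), "not present")
})

test_that("linked row keys are always a subset of both inputs", {
  set.seed(42)
  for (i in 1:10) {
    n_t <- sample(3:8, 1); n_o <- sample(3:8, 1)
    t_fips <- formatC(sample(1:12, n_t), width = 5, flag = "0")
    o_fips <- formatC(sample(1:12, n_o), width = 5, flag = "0")
    tab <- make_table(matrix(rnorm(n_t * 2), n_t, 2,
                             dimnames = list(t_fips, c("a", "b"))))
    out <- apply_inclusion(outcome_set(data.frame(
      fips = o_fips, stratum = "total",
      deaths_4yr = rpois(n_o, 2), births_4yr = sample(500:5000, n_o))),
      min_births = 1000)
    common <- intersect(t_fips, o_fips[out$included])
    if (!length(common)) {
      expect_error(suppressWarnings(link_outcomes(tab, out, "total")),
                   "no overlapping")
    } else {
      linked <- suppressWarnings(link_outcomes(tab, out, "total"))
      expect_true(all(fips_keys(linked) %in% intersect(t_fips, o_fips)))
    }
  }
})
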
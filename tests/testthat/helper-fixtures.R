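# Builders for small in-code fixtures; nothing is read from disk except
# through tempfiles created here.

make_table <- function(values, domains = NULL) {
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("var%02d", seq_len(ncol(values)))
  }
  if (is.null(rownames(values))) {
    rownames(values) <- formatC(seq_len(nrow(values)), width = 5, flag = "0")
  }
  if (is.null(domains)) {
    domains <- rep_len(c("built", "social", "natural", "health", "policy"),
                       ncol(values))
  }
  exposome_table(values, data.frame(name = colnames(values), domain = domains))
}

random_gnp <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  g
}

named_graph <- function(edge_pairs, vertices = NULL) {
  # edge_pairs: character vector like c("a","b", "b","c")
  g <- igraph::make_graph(edge_pairs, directed = FALSE)
  if (!is.null(vertices)) {
    g <- igraph::add_vertices(g, length(setdiff(vertices, igraph::V(g)$name)),
                              name = setdiff(vertices, igraph::V(g)$name))
  }
  g
}

petersen_graph <- function() {
  g <- igraph::make_graph("Petersen")
  igraph::V(g)$name <- sprintf("p%02d", seq_len(igraph::vcount(g)))
  g
}

small_outcomes <- function() {
  outcome_set(data.frame(
    fips = c("01001", "01003", "01005", "01007", "01009"),
    stratum = "total",
    deaths_4yr = c(2L, 0L, 5L, 1L, 3L),
    births_4yr = c(5000L, 1000L, 999L, 12000L, 400L)
  ))
}
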
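# Independent brute-force oracles. These enumerate over bitmask subsets and
# never touch the package's search code, so they can certify exactness.

vertex_bitmasks <- function(graph, closed = TRUE) {
  n <- igraph::vcount(graph)
  adjm <- igraph::as_adjacency_matrix(graph, sparse = FALSE) > 0
  masks <- integer(n)
  for (v in seq_len(n)) {
    m <- if (closed) bitwShiftL(1L, v - 1L) else 0L
    for (u in which(adjm[v, ])) m <- bitwOr(m, bitwShiftL(1L, u - 1L))
    masks[v] <- m
  }
  masks
}

# minimum dominating set size by enumeration over all 2^n subsets
oracle_mds_size <- function(graph) {
  n <- as.integer(igraph::vcount(graph))
  if (n == 0) return(0L)
  stopifnot(n <= 20)
  masks <- vertex_bitmasks(graph, closed = TRUE)
  total <- bitwShiftL(1L, n)
  full <- total - 1L
  cover <- integer(total)
  size <- integer(total)
  best <- n
  for (s in seq_len(total - 1L)) {
    lb <- bitwAnd(s, -s)
    v <- 1L + as.integer(round(log2(lb)))
    rest <- s - lb
    cover[s + 1L] <- bitwOr(cover[rest + 1L], masks[v])
    size[s + 1L] <- size[rest + 1L] + 1L
    if (cover[s + 1L] == full && size[s + 1L] < best) best <- size[s + 1L]
  }
  best
}

# maximum clique size by enumeration over all 2^n subsets
oracle_max_clique_size <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0) return(0L)
  stopifnot(n <= 20)
  open <- vertex_bitmasks(graph, closed = FALSE)
  total <- bitwShiftL(1L, n)
  is_clique <- logical(total)
  size <- integer(total)
  is_clique[1] <- TRUE
  best <- 0L
  for (s in seq_len(total - 1L)) {
    lb <- bitwAnd(s, -s)
    v <- 1L + as.integer(round(log2(lb)))
    rest <- s - lb
    size[s + 1L] <- size[rest + 1L] + 1L
    is_clique[s + 1L] <- is_clique[rest + 1L] &&
      bitwAnd(open[v], rest) == rest
    if (is_clique[s + 1L] && size[s + 1L] > best) best <- size[s + 1L]
  }
  best
}

# hand step-up BH computation
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- sorted * m / seq_len(m)
  for (i in rev(seq_len(m - 1))) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# brute-force recomputation of a screening list from first principles
oracle_screen <- function(table, outcome_name, retention_r, min_pairs) {
  y <- table$values[, outcome_name]
  is_out <- table$meta$domain == "outcome"
  vars <- variables(table)[!is_out]
  rows <- lapply(vars, function(v) {
    x <- table$values[, v]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_pairs) return(NULL)
    xs <- x[ok] - mean(x[ok]); ys <- y[ok] - mean(y[ok])
    if (sum(xs^2) == 0 || sum(ys^2) == 0) return(NULL)
    r <- sum(xs * ys) / sqrt(sum(xs^2) * sum(ys^2))
    data.frame(name = v, domain = table$meta$domain[variables(table) == v],
               r = r, n_pairs = sum(ok))
  })
  df <- do.call(rbind, rows)
  df <- df[order(-abs(df$r), df$name), , drop = FALSE]
  df$retained <- abs(df$r) > retention_r
  rownames(df) <- NULL
  df
}

# all 25 DAGs on 3 labelled nodes, as adjacency matrices
enumerate_dags3 <- function(nodes) {
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  out <- list()
  for (s1 in 0:2) for (s2 in 0:2) for (s3 in 0:2) {
    A <- matrix(FALSE, 3, 3, dimnames = list(nodes, nodes))
    states <- c(s1, s2, s3)
    for (k in 1:3) {
      if (states[k] == 1) A[pairs[[k]][1], pairs[[k]][2]] <- TRUE
      if (states[k] == 2) A[pairs[[k]][2], pairs[[k]][1]] <- TRUE
    }
    # reject the two directed 3-cycles
    if (sum(A) == 3 && all(rowSums(A) == 1) && all(colSums(A) == 1)) next
    out[[length(out) + 1L]] <- A
  }
  out
}

# total Gaussian BIC of a fixed DAG, computed through stats::lm (independent
# of the package's scoring path)
oracle_dag_bic <- function(A, data) {
  nodes <- rownames(A)
  total <- 0
  for (v in nodes) {
    parents <- nodes[A[, v]]
    df <- as.data.frame(data)
    fmla <- if (length(parents)) {
      stats::reformulate(sprintf("`%s`", parents), response = sprintf("`%s`", v))
    } else {
      stats::as.formula(sprintf("`%s` ~ 1", v))
    }
    fit <- stats::lm(fmla, data = df)
    n <- nrow(df)
    sigma2 <- mean(stats::residuals(fit)^2)
    ll <- -(n / 2) * (log(2 * pi * sigma2) + 1)
    total <- total + ll - ((length(parents) + 2) / 2) * log(n)
  }
  total
}

oracle_best_bic3 <- function(data) {
  dags <- enumerate_dags3(colnames(data))
  max(vapply(dags, oracle_dag_bic, numeric(1), data = data))
}
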
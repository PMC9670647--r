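#' Local Gaussian BIC score of one node given its parents
#'
#' Fits the least-squares linear model child ~ intercept + parents, takes the
#' maximum-likelihood residual variance (floored at `variance_floor` to guard
#' exact collinearity between child and parents), and returns
#' logLik - (p/2) ln N with p = |parents| + 2 (regression coefficients,
#' intercept, and the variance). Higher is better; the network score is the
#' sum of local scores over nodes (decomposability).
#'
#' @param child name of the child column.
#' @param parent_set character vector of parent column names (possibly
#'   empty).
#' @param data numeric matrix or data.frame of complete cases.
#' @param variance_floor lower bound on the residual variance (default
#'   1e-12).
#' @return the local BIC contribution (a scalar).
#' @export
local_bic <- function(child, parent_set, data, variance_floor = 1e-12) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("data must be complete cases", call. = FALSE)
  y <- data[, child]
  n <- length(y)
  if (n < length(parent_set) + 2) {
    stop("need at least |parents| + 2 rows", call. = FALSE)
  }
  if (stats::sd(y) == 0) stop("child '", child, "' is constant", call. = FALSE)
  x <- cbind(`(intercept)` = 1, data[, parent_set, drop = FALSE])
  fit <- stats::lm.fit(x, y)
  if (fit$rank < ncol(x)) {
    dropped <- colnames(x)[is.na(fit$coefficients)]
    stop("rank-deficient parent matrix for '", child, "': collinear parent(s) ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  sigma2 <- max(mean(fit$residuals^2), variance_floor)
  loglik <- -(n / 2) * (log(2 * pi * sigma2) + 1)
  p <- length(parent_set) + 2
  loglik - (p / 2) * log(n)
}

# arcs as named logical adjacency matrix A[parent, child]
has_path <- function(A, from, to) {
  # BFS over children
  if (from == to) return(TRUE)
  frontier <- from
  seen <- rep(FALSE, nrow(A))
  names(seen) <- rownames(A)
  seen[from] <- TRUE
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, function(v) colnames(A)[A[v, ]])))
    nxt <- nxt[!seen[nxt]]
    if (to %in% nxt) return(TRUE)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  FALSE
}

new_learned_dag <- function(A, per_node_score, outcome = NULL) {
  nodes <- rownames(A)
  idx <- which(A, arr.ind = TRUE)
  arcs <- matrix(character(), ncol = 2, dimnames = list(NULL, c("from", "to")))
  if (nrow(idx)) {
    arcs <- cbind(from = nodes[idx[, 1]], to = nodes[idx[, 2]])
    arcs <- arcs[order(arcs[, 1], arcs[, 2]), , drop = FALSE]
  }
  structure(list(
    nodes = nodes,
    arcs = arcs,
    adjacency = A,
    per_node_score = per_node_score,
    score_total = sum(per_node_score)
  ), class = "learned_dag")
}

#' @export
print.learned_dag <- function(x, ...) {
  cat("<learned_dag> ", length(x$nodes), " nodes, ", nrow(x$arcs),
      " arcs, BIC = ", sprintf("%.3f", x$score_total),
      " (-2x convention: ", sprintf("%.3f", -2 * x$score_total), ")\n", sep = "")
  if (nrow(x$arcs)) {
    apply(x$arcs, 1, function(a) cat("  ", a[1], "->", a[2], "\n"))
  }
  invisible(x)
}

#' Greedy hill-climbing DAG search on the Gaussian BIC score
#'
#' Starts from the empty DAG and repeatedly applies the single arc addition,
#' deletion, or reversal that most improves the total BIC, subject to
#' acyclicity (steepest ascent), stopping at a local optimum or `max_iter`
#' moves. Ties among equal-gain moves are broken lexicographically on
#' (move type: add < delete < reverse, parent name, child name), so the
#' result is deterministic given the data. Local scores are cached by
#' (child, parent set).
#'
#' @param data numeric matrix or data.frame; rows with any missing value in
#'   `node_set` are dropped (complete-case analysis, row count reported via
#'   attribute `n_rows`).
#' @param node_set columns to learn over (default: all columns).
#' @param max_iter maximum number of moves (default 500).
#' @param variance_floor passed to [local_bic()].
#' @param standardize z-score the columns before learning (default FALSE;
#'   BIC rank order is scale-dependent only through the variance floor).
#' @param tol minimal gain counted as an improvement (default 1e-9).
#' @return a `learned_dag` with nodes, arcs, per-node scores, and total
#'   score.
#' @export
hill_climb <- function(data, node_set = NULL, max_iter = 500,
                       variance_floor = 1e-12, standardize = FALSE,
                       tol = 1e-9) {
  data <- as.matrix(data)
  if (is.null(node_set)) node_set <- colnames(data)
  data <- data[, node_set, drop = FALSE]
  data <- data[stats::complete.cases(data), , drop = FALSE]
  n <- nrow(data)
  if (n < length(node_set) + 2) {
    stop("fewer complete rows (", n, ") than nodes + 2", call. = FALSE)
  }
  if (standardize) data <- scale(data)
  nodes <- node_set
  k <- length(nodes)
  A <- matrix(FALSE, k, k, dimnames = list(nodes, nodes))

  cache <- new.env(parent = emptyenv())
  score_of <- function(child, parents) {
    key <- paste0(child, "|", paste(sort(parents), collapse = ","))
    if (!is.null(cache[[key]])) return(cache[[key]])
    s <- local_bic(child, sort(parents), data, variance_floor = variance_floor)
    cache[[key]] <- s
    s
  }
  parents_of <- function(child) nodes[A[, child]]
  local_scores <- vapply(nodes, function(v) score_of(v, character()), numeric(1))

  move_rank <- c(add = 1L, delete = 2L, reverse = 3L)
  for (iter in seq_len(max_iter)) {
    best <- NULL # list(type, from, to, gain, new_scores)
    # moves whose gains differ by less than tie_eps are treated as tied so
    # that mathematically score-equivalent orientations (which differ only
    # by floating-point noise) fall through to the lexicographic rule
    consider <- function(type, from, to, gain, new_scores) {
      if (gain <= tol) return(invisible())
      tie_eps <- 1e-8 * (1 + abs(gain))
      if (is.null(best) || gain > best$gain + tie_eps ||
          (abs(gain - best$gain) <= tie_eps &&
           (move_rank[type] < move_rank[best$type] ||
            (move_rank[type] == move_rank[best$type] &&
             (from < best$from || (from == best$from && to < best$to)))))) {
        best <<- list(type = type, from = from, to = to, gain = gain,
                      new_scores = new_scores)
      }
      invisible()
    }
    for (from in nodes) {
      for (to in nodes) {
        if (from == to) next
        if (!A[from, to]) {
          # addition (skip if it would create a cycle, i.e. to ~> from)
          if (!A[to, from] && !has_path(A, to, from)) {
            ns <- score_of(to, c(parents_of(to), from))
            consider("add", from, to, ns - local_scores[to],
                     stats::setNames(ns, to))
          }
        } else {
          # deletion
          ns <- score_of(to, setdiff(parents_of(to), from))
          consider("delete", from, to, ns - local_scores[to],
                   stats::setNames(ns, to))
          # reversal: legal iff no alternative directed path from -> to
          A2 <- A; A2[from, to] <- FALSE
          if (!has_path(A2, from, to)) {
            ns_to <- score_of(to, setdiff(parents_of(to), from))
            ns_from <- score_of(from, c(parents_of(from), to))
            gain <- (ns_to - local_scores[to]) + (ns_from - local_scores[from])
            consider("reverse", from, to, gain,
                     stats::setNames(c(ns_to, ns_from), c(to, from)))
          }
        }
      }
    }
    if (is.null(best)) break
    if (best$type == "add") {
      A[best$from, best$to] <- TRUE
    } else if (best$type == "delete") {
      A[best$from, best$to] <- FALSE
    } else {
      A[best$from, best$to] <- FALSE
      A[best$to, best$from] <- TRUE
    }
    local_scores[names(best$new_scores)] <- best$new_scores
  }
  dag <- new_learned_dag(A, local_scores)
  attr(dag, "n_rows") <- n
  dag
}

#' Certify that a DAG is single-move locally optimal
#'
#' Independently re-scores every legal arc addition, deletion, and reversal
#' and checks that none improves the total BIC by more than `tol`.
#'
#' @param dag a `learned_dag`.
#' @param data the (complete-case) data it was learned from.
#' @param tol gain tolerance (default 1e-9).
#' @return TRUE if locally optimal, otherwise FALSE with attribute
#'   `improving_move`.
#' @export
is_locally_optimal <- function(dag, data, tol = 1e-9) {
  data <- as.matrix(data)[, dag$nodes, drop = FALSE]
  data <- data[stats::complete.cases(data), , drop = FALSE]
  A <- dag$adjacency
  nodes <- dag$nodes
  sc <- function(child, parents) local_bic(child, parents, data)
  base <- vapply(nodes, function(v) sc(v, nodes[A[, v]]), numeric(1))
  for (from in nodes) {
    for (to in nodes) {
      if (from == to) next
      gain <- -Inf
      if (!A[from, to]) {
        if (!A[to, from] && !has_path(A, to, from)) {
          gain <- sc(to, c(nodes[A[, to]], from)) - base[to]
        }
      } else {
        gain_d <- sc(to, setdiff(nodes[A[, to]], from)) - base[to]
        gain <- gain_d
        A2 <- A; A2[from, to] <- FALSE
        if (!has_path(A2, from, to)) {
          gain_r <- gain_d + sc(from, c(nodes[A[, from]], to)) - base[from]
          gain <- max(gain, gain_r)
        }
      }
      if (is.finite(gain) && gain > tol) {
        out <- FALSE
        attr(out, "improving_move") <- c(from = from, to = to)
        return(out)
      }
    }
  }
  TRUE
}

#' Direct predictors (parents) of the outcome node
#'
#' @param dag a `learned_dag`.
#' @param outcome name of the outcome node.
#' @return list with `predictors` (parents of the outcome, sorted by name)
#'   and `markov_blanket` (parents, children, and co-parents of the
#'   outcome's children).
#' @export
direct_predictors <- function(dag, outcome) {
  stopifnot(inherits(dag, "learned_dag"))
  if (!outcome %in% dag$nodes) {
    stop("outcome '", outcome, "' not in network", call. = FALSE)
  }
  A <- dag$adjacency
  parents <- sort(dag$nodes[A[, outcome]])
  children <- sort(dag$nodes[A[outcome, ]])
  coparents <- unique(unlist(lapply(children, function(ch) dag$nodes[A[, ch]])))
  mb <- sort(setdiff(unique(c(parents, children, coparents)), outcome))
  list(predictors = parents, markov_blanket = mb)
}

#' Learn one network per PHE domain plus an overall network
#'
#' For each of the five domains, takes the top-k retained correlates of the
#' outcome from the domain sublist, adds the outcome node, and learns a DAG
#' by [hill_climb()]; an "overall" network uses the combined top-k list.
#' Domains with no retained variables are skipped with a message, mirroring
#' the empty rows a sparse domain produces.
#'
#' @param table a linked `exposome_table` containing the outcome column.
#' @param screen a `screen_result` for the same outcome.
#' @param outcome outcome column name.
#' @param k variables per list (default 20).
#' @param ... passed to [hill_climb()].
#' @return named list of `learned_dag`s (subset of overall, built, social,
#'   natural, health, policy), each with attribute `variables`.
#' @export
run_per_domain <- function(table, screen, outcome, k = 20, ...) {
  stopifnot(inherits(table, "exposome_table"), inherits(screen, "screen_result"))
  lists <- c(list(overall = screen), domain_sublists(screen))
  out <- list()
  for (nm in names(lists)) {
    vars <- top_k(lists[[nm]], k = k, retained_only = TRUE)
    if (!length(vars)) {
      message("domain '", nm, "': no retained variables, skipped")
      next
    }
    dat <- table$values[, c(vars, outcome), drop = FALSE]
    dag <- hill_climb(dat, ...)
    attr(dag, "variables") <- vars
    out[[nm]] <- dag
  }
  out
}
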
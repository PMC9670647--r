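#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values: sort ascending, adj_(i) = min over j >= i of
#' p_(j) * m / j, capped at 1, mapped back to input order. Delegates to
#' `stats::p.adjust(method = "BH")` after validating the input range.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in input order.
#' @export
benjamini_hochberg <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Shapiro-Wilk normality screen across a table
#'
#' Tests every variable for normality, adjusts across variables by
#' Benjamini-Hochberg, and flags variables whose adjusted p falls below
#' `alpha`. The screen is advisory: the pipeline logs the flags and proceeds
#' with Pearson correlation regardless (a Spearman fallback exists in
#' [build_autocorrelation_graph()] consumers but is off by default).
#' Variables with fewer than 3 non-missing values (or constant values) are
#' marked unevaluable rather than failing.
#'
#' @param table an `exposome_table`.
#' @param alpha flag threshold on the adjusted p-value (default 0.05).
#' @return data.frame with columns `name`, `p`, `p_adj`, `flagged`,
#'   `evaluable`.
#' @export
shapiro_wilk_screen <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "exposome_table"))
  vals <- table$values
  p <- vapply(seq_len(ncol(vals)), function(j) {
    x <- vals[, j]
    x <- x[!is.na(x)]
    if (length(x) < 3 || length(x) > 5000) return(NA_real_)
    if (stats::sd(x) == 0) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }, numeric(1))
  evaluable <- !is.na(p)
  p_adj <- rep(NA_real_, length(p))
  if (any(evaluable)) p_adj[evaluable] <- benjamini_hochberg(p[evaluable])
  data.frame(name = colnames(vals), p = p, p_adj = p_adj,
             flagged = !is.na(p_adj) & p_adj < alpha,
             evaluable = evaluable)
}

#' Build the autocorrelation graph of a variable table
#'
#' One vertex per variable (isolated vertices included); an edge joins two
#' variables whenever their pairwise-complete Pearson correlation meets the
#' threshold. Under the default `signed` mode the rule is r >= threshold,
#' reading "correlation is at least 0.9" literally; `absolute` mode uses
#' |r| >= threshold so that near-perfect negative correlates also count as
#' duplicates.
#'
#' @param table an `exposome_table`.
#' @param threshold autocorrelation threshold (default 0.9).
#' @param threshold_mode `"signed"` (default) or `"absolute"`.
#' @param min_pairs minimum overlapping counties per pair (default 30).
#' @return an igraph correlation graph.
#' @export
build_autocorrelation_graph <- function(table, threshold = 0.9,
                                        threshold_mode = c("signed", "absolute"),
                                        min_pairs = 30L) {
  threshold_mode <- match.arg(threshold_mode)
  if (ncol(table$values) < 2) stop("need at least 2 variables", call. = FALSE)
  r <- correlation_matrix(table, min_pairs = min_pairs)
  keep <- if (threshold_mode == "signed") r >= threshold else abs(r) >= threshold
  keep[is.na(keep)] <- FALSE
  diag(keep) <- FALSE
  idx <- which(keep & upper.tri(keep), arr.ind = TRUE)
  edges <- data.frame(from = rownames(r)[idx[, 1]],
                      to = colnames(r)[idx[, 2]],
                      weight = r[idx])
  correlation_graph(colnames(r), edges, threshold = threshold,
                    threshold_mode = threshold_mode, min_pairs = min_pairs)
}

#' Check a dominating set
#'
#' @param graph an igraph object.
#' @param set character vector of vertex names.
#' @return TRUE iff every vertex is in `set` or adjacent to a member.
#' @export
is_dominating_set <- function(graph, set) {
  vn <- igraph::V(graph)$name
  if (!all(set %in% vn)) return(FALSE)
  covered <- rep(FALSE, length(vn))
  names(covered) <- vn
  covered[set] <- TRUE
  for (v in set) {
    covered[igraph::neighbors(graph, v)$name] <- TRUE
  }
  all(covered)
}

# Exact minimum dominating set on one connected component, as a set-cover
# branch and bound. Vertices are integer indices 1..k ordered by name rank;
# the closed neighbourhood of v is the "set" that covers element v. The
# comparator prefers smaller cardinality, then the lexicographically
# smallest sorted rank vector, which realises the epsilon-weighted secondary
# objective exactly.
mds_component_exact <- function(nbr) {
  k <- length(nbr)
  closed <- lapply(seq_len(k), function(v) sort(unique(c(v, nbr[[v]]))))
  # greedy initial upper bound
  greedy <- integer(0)
  uncovered <- rep(TRUE, k)
  while (any(uncovered)) {
    gain <- vapply(seq_len(k), function(v) sum(uncovered[closed[[v]]]), integer(1))
    pick <- which.max(gain) # ties -> lowest rank
    greedy <- c(greedy, pick)
    uncovered[closed[[pick]]] <- FALSE
  }
  best <- sort(greedy)
  better <- function(a, b) {
    # TRUE if candidate a beats incumbent b
    if (length(a) != length(b)) return(length(a) < length(b))
    d <- which(a != b)
    length(d) > 0 && a[d[1]] < b[d[1]]
  }
  max_cover <- max(lengths(closed))
  masks <- lapply(closed, function(s) {
    m <- rep(FALSE, k); m[s] <- TRUE; m
  })
  recurse <- function(chosen, covered) {
    n_unc <- sum(!covered)
    if (n_unc == 0) {
      cand <- sort(chosen)
      if (better(cand, best)) best <<- cand
      return(invisible())
    }
    lb <- ceiling(n_unc / max_cover)
    if (length(chosen) + lb > length(best)) return(invisible())
    # branch on the uncovered vertex with fewest candidate dominators;
    # its dominators are exactly its closed neighbourhood
    unc <- which(!covered)
    u <- unc[which.min(lengths(closed[unc]))]
    for (v in closed[[u]]) { # ascending rank order -> lexicographic search
      recurse(c(chosen, v), covered | masks[[v]])
    }
    invisible()
  }
  recurse(integer(0), rep(FALSE, k))
  best
}

# Greedy ln-approximation fallback for very large components.
mds_component_greedy <- function(nbr) {
  k <- length(nbr)
  closed <- lapply(seq_len(k), function(v) sort(unique(c(v, nbr[[v]]))))
  chosen <- integer(0)
  uncovered <- rep(TRUE, k)
  while (any(uncovered)) {
    gain <- vapply(seq_len(k), function(v) sum(uncovered[closed[[v]]]), integer(1))
    pick <- which.max(gain)
    chosen <- c(chosen, pick)
    uncovered[closed[[pick]]] <- FALSE
  }
  sort(chosen)
}

#' Exact minimum dominating set of a graph
#'
#' Returns a vertex set S of minimum cardinality such that every vertex is in
#' S or adjacent to a member of S. The default method is exact: the graph is
#' decomposed into connected components and each component is solved by a
#' set-cover branch and bound with a greedy upper bound and a covering lower
#' bound. Among optimal sets the lexicographically smallest by variable name
#' is returned, so output is deterministic and seed-independent. Isolated
#' vertices are always in S. Every result is re-checked with a domination
#' certificate before returning.
#'
#' @param graph an igraph object with named vertices.
#' @param method `"exact"` (default) or `"greedy"` (1 + ln(Delta+1)
#'   approximation for very large graphs).
#' @param max_exact component size above which `"exact"` refuses and asks for
#'   the greedy method (default 64).
#' @return character vector of vertex names, sorted.
#' @export
minimum_dominating_set <- function(graph, method = c("exact", "greedy"),
                                   max_exact = 64L) {
  method <- match.arg(method)
  vn <- igraph::V(graph)$name
  if (!length(vn)) return(character())
  comp <- igraph::components(graph)
  sel <- character()
  for (ci in seq_len(comp$no)) {
    members <- which(comp$membership == ci)
    # order members by name
    members <- members[order(vn[members])]
    if (length(members) == 1) {
      sel <- c(sel, vn[members])
      next
    }
    if (method == "exact" && length(members) > max_exact) {
      stop("component of size ", length(members),
           " exceeds exact-search budget (", max_exact,
           "); use method = 'greedy'", call. = FALSE)
    }
    local_id <- stats::setNames(seq_along(members), vn[members])
    nbr <- lapply(members, function(v) {
      nb <- igraph::neighbors(graph, v)$name
      unname(local_id[nb[nb %in% names(local_id)]])
    })
    picked <- if (method == "exact") mds_component_exact(nbr) else mds_component_greedy(nbr)
    sel <- c(sel, vn[members][picked])
  }
  sel <- sort(sel)
  if (!is_dominating_set(graph, sel)) {
    stop("internal error: returned set fails the domination certificate",
         call. = FALSE)
  }
  sel
}

#' Default name patterns for margin-of-error variable elimination
#' @return character vector of case-insensitive patterns.
#' @export
default_moe_patterns <- function() {
  c("margin of error", "moe", "confidence limit", "confidence interval",
    "95% ci", "lower bound", "upper bound")
}

#' Remove confidence-limit / margin-of-error variables by name pattern
#'
#' Variables whose names match any of the case-insensitive patterns are
#' dropped. An empty pattern list is a warning no-op.
#'
#' @param table an `exposome_table`.
#' @param patterns character vector of case-insensitive regular expressions
#'   (default [default_moe_patterns()]).
#' @return list with `table` (filtered) and `removed` (names dropped).
#' @export
name_pattern_filter <- function(table, patterns = default_moe_patterns()) {
  stopifnot(inherits(table, "exposome_table"))
  if (!length(patterns)) {
    warning("empty pattern list: nothing removed", call. = FALSE)
    return(list(table = table, removed = character()))
  }
  vn <- variables(table)
  hit <- Reduce(`|`, lapply(patterns, function(p) grepl(p, vn, ignore.case = TRUE)))
  removed <- vn[hit]
  keep <- vn[!hit]
  if (!length(keep)) stop("pattern filter removed every variable", call. = FALSE)
  list(table = select_variables(table, keep), removed = removed)
}

#' Full variable-reduction stage
#'
#' Runs the reduction pipeline on an exposome table: (1) Shapiro-Wilk
#' normality screen with BH correction (advisory, logged); (2)
#' autocorrelation graph at the given threshold; (3) exact minimum dominating
#' set - vertices outside the set are removed; (4) name-pattern elimination
#' of confidence-limit and margin-of-error variables.
#'
#' @param table an `exposome_table`.
#' @param threshold autocorrelation threshold (default 0.9).
#' @param threshold_mode `"signed"` or `"absolute"`.
#' @param min_pairs minimum overlapping counties per correlation (default 30).
#' @param patterns name patterns to eliminate (default
#'   [default_moe_patterns()]).
#' @param mds_method `"exact"` or `"greedy"`.
#' @param alpha normality flag threshold (default 0.05).
#' @return a `reduction_report`: list with the reduced `table`, the
#'   autocorrelation `graph`, `dominating_set`, `removed_by_pattern`,
#'   `normality`, and the counts `n_input`, `n_after_mds`,
#'   `n_after_name_filter`.
#' @export
reduce_variables <- function(table, threshold = 0.9,
                             threshold_mode = c("signed", "absolute"),
                             min_pairs = 30L,
                             patterns = default_moe_patterns(),
                             mds_method = c("exact", "greedy"),
                             alpha = 0.05) {
  threshold_mode <- match.arg(threshold_mode)
  mds_method <- match.arg(mds_method)
  normality <- shapiro_wilk_screen(table, alpha = alpha)
  graph <- build_autocorrelation_graph(table, threshold = threshold,
                                       threshold_mode = threshold_mode,
                                       min_pairs = min_pairs)
  dom <- minimum_dominating_set(graph, method = mds_method)
  after_mds <- select_variables(table, intersect(variables(table), dom))
  filtered <- name_pattern_filter(after_mds, patterns)
  structure(list(
    table = filtered$table,
    graph = graph,
    dominating_set = dom,
    removed_by_pattern = filtered$removed,
    normality = normality,
    n_input = ncol(table$values),
    n_after_mds = length(dom),
    n_after_name_filter = ncol(filtered$table$values)
  ), class = "reduction_report")
}

#' @export
print.reduction_report <- function(x, ...) {
  cat("<reduction_report>\n",
      "  variables in:        ", x$n_input, "\n",
      "  after dominating set:", x$n_after_mds, "\n",
      "  after name filter:   ", x$n_after_name_filter, "\n",
      "  flagged non-normal:  ", sum(x$normality$flagged), "\n", sep = "")
  invisible(x)
}
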
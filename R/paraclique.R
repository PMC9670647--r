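#' Threshold a correlation matrix into an unweighted graph
#'
#' Builds a simple graph with an edge wherever |r| >= t (inclusive). Missing
#' correlations never produce an edge. The original correlation is kept as
#' the edge `weight` for provenance, but paraclique extraction treats the
#' graph as unweighted.
#'
#' @param cor_matrix symmetric correlation matrix with dimnames (e.g. from
#'   [correlation_matrix()]).
#' @param t absolute-correlation threshold in (0, 1).
#' @return an igraph correlation graph with `threshold_mode = "absolute"`.
#' @export
threshold_graph <- function(cor_matrix, t) {
  if (t <= 0 || t >= 1) stop("threshold must lie in (0, 1)", call. = FALSE)
  cor_matrix <- as.matrix(cor_matrix)
  keep <- abs(cor_matrix) >= t
  keep[is.na(keep)] <- FALSE
  diag(keep) <- FALSE
  idx <- which(keep & upper.tri(keep), arr.ind = TRUE)
  edges <- data.frame(from = rownames(cor_matrix)[idx[, 1]],
                      to = colnames(cor_matrix)[idx[, 2]],
                      weight = cor_matrix[idx])
  correlation_graph(colnames(cor_matrix), edges, threshold = t,
                    threshold_mode = "absolute")
}

# Adjacency as a list of sorted integer neighbour vectors, vertices ordered
# lexicographically by name. Shared by the clique and glom routines.
adjacency_by_name <- function(graph) {
  vn <- sort(igraph::V(graph)$name)
  id <- stats::setNames(seq_along(vn), vn)
  adj <- lapply(vn, function(v) {
    nb <- igraph::neighbors(graph, v)$name
    sort(unname(id[nb]))
  })
  list(names = vn, adj = adj)
}

#' Exact maximum clique
#'
#' Branch and bound in the style of Tomita: candidates are greedily coloured
#' and explored in reverse colour order, pruning when |current clique| +
#' colour bound cannot beat the incumbent. Vertices are ordered
#' lexicographically by name and the first optimum found is kept, so the
#' result is deterministic and an edgeless graph yields the
#' lexicographically first vertex.
#'
#' @param graph an igraph object with named vertices.
#' @param node_budget maximum number of search-tree nodes before giving up
#'   (default 5e6); exceeding it is an error advising a higher threshold.
#' @return character vector of clique vertex names, sorted.
#' @export
maximum_clique <- function(graph, node_budget = 5e6) {
  a <- adjacency_by_name(graph)
  n <- length(a$names)
  if (n == 0) return(character())
  adj <- a$adj
  is_adj <- function(u, v) v %in% adj[[u]]
  best <- integer(0)
  nodes_used <- 0L

  colour_bound <- function(P) {
    # greedy colouring in index order; returns colour class per candidate
    colours <- integer(length(P))
    classes <- list()
    for (i in seq_along(P)) {
      v <- P[i]
      placed <- FALSE
      for (ci in seq_along(classes)) {
        if (!any(vapply(classes[[ci]], function(u) is_adj(u, v), logical(1)))) {
          classes[[ci]] <- c(classes[[ci]], v)
          colours[i] <- ci
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        classes[[length(classes) + 1L]] <- v
        colours[i] <- length(classes)
      }
    }
    colours
  }

  expand <- function(R, P) {
    nodes_used <<- nodes_used + 1L
    if (nodes_used > node_budget) {
      stop("maximum-clique search exceeded its node budget; ",
           "use a higher correlation threshold", call. = FALSE)
    }
    if (!length(P)) {
      if (length(R) > length(best)) best <<- R
      return(invisible())
    }
    colours <- colour_bound(P)
    # explore highest colour first, ties by ascending vertex index, so the
    # first optimum found is the lexicographically earliest
    ord <- order(-colours, seq_along(P))
    P <- P[ord]; colours <- colours[ord]
    for (i in seq_along(P)) {
      if (length(R) + colours[i] <= length(best)) return(invisible())
      v <- P[i]
      rest <- if (i < length(P)) P[seq(i + 1L, length(P))] else integer(0)
      expand(c(R, v), intersect(rest, adj[[v]]))
    }
    invisible()
  }
  expand(integer(0), seq_len(n))
  sort(a$names[best])
}

#' Glom a seed clique into a paraclique
#'
#' One-pass rule: every vertex outside the seed adjacent to at least
#' |seed| - g seed members is added to the glommed set. Candidates are
#' evaluated against the seed only, not against the growing paraclique,
#' which preserves the analytic density lower bound
#' (C(s,2) + m(s-g)) / C(s+m, 2). An iterated variant that re-evaluates
#' candidates against the current paraclique is available via
#' `iterate = TRUE`.
#'
#' @param graph an igraph object.
#' @param seed_clique character vector of vertex names forming a clique.
#' @param g glom term, 0 <= g < |seed_clique|.
#' @param iterate if TRUE, repeat the absorption pass against the growing
#'   member set until a fixed point (non-default variant; the density bound
#'   is then not guaranteed).
#' @return a `paraclique` object: list with `seed_clique`, `glommed`,
#'   `glom_term`, `threshold`, `members`, `density`.
#' @export
glom <- function(graph, seed_clique, g, iterate = FALSE) {
  vn <- igraph::V(graph)$name
  if (!all(seed_clique %in% vn)) stop("seed vertex not in graph", call. = FALSE)
  s <- length(seed_clique)
  if (g < 0) stop("glom term must be non-negative", call. = FALSE)
  if (g >= s) {
    stop("glom term g = ", g, " must be smaller than the seed clique size ",
         s, call. = FALSE)
  }
  sub <- igraph::induced_subgraph(graph, seed_clique)
  if (igraph::ecount(sub) != choose(s, 2)) {
    stop("seed_clique is not a clique", call. = FALSE)
  }
  count_adj <- function(v, members) {
    sum(igraph::neighbors(graph, v)$name %in% members)
  }
  members <- sort(seed_clique)
  repeat {
    outside <- setdiff(vn, members)
    need <- length(if (iterate) members else seed_clique) - g
    ref <- if (iterate) members else seed_clique
    added <- outside[vapply(outside, count_adj, integer(1), members = ref) >= need]
    members <- sort(c(members, added))
    if (!iterate || !length(added)) break
  }
  glommed <- setdiff(members, seed_clique)
  msub <- igraph::induced_subgraph(graph, members)
  dens <- if (length(members) > 1) {
    igraph::ecount(msub) / choose(length(members), 2)
  } else 1
  structure(list(
    seed_clique = sort(seed_clique),
    glommed = sort(glommed),
    glom_term = as.integer(g),
    threshold = igraph::graph_attr(graph, "threshold"),
    members = members,
    density = dens
  ), class = "paraclique")
}

#' @export
print.paraclique <- function(x, ...) {
  cat("<paraclique> seed ", length(x$seed_clique), " + glommed ",
      length(x$glommed), " (g = ", x$glom_term, ", density ",
      sprintf("%.3f", x$density), ")\n", sep = "")
  invisible(x)
}

#' Iteratively extract paracliques from a thresholded graph
#'
#' Loop: find the maximum clique; stop when it is smaller than `min_clique`;
#' glom it; record the paraclique; delete its members from the graph;
#' repeat. Extraction order makes the paracliques pairwise vertex-disjoint.
#' When `require_outcome_vertex` is TRUE the retained list is filtered to
#' paracliques containing at least one outcome vertex.
#'
#' @param graph an igraph correlation graph (usually from
#'   [threshold_graph()]).
#' @param g glom term.
#' @param min_clique smallest seed clique worth extracting (default 3).
#' @param require_outcome_vertex filter the retained list to paracliques
#'   containing an outcome vertex (default TRUE).
#' @param outcome_vertices character vector of outcome variable names.
#' @return a `paraclique_set`: list with `all` (every paraclique extracted)
#'   and `retained` (those containing an outcome vertex, or identical to
#'   `all` when `require_outcome_vertex` is FALSE).
#' @export
extract_paracliques <- function(graph, g, min_clique = 3,
                                require_outcome_vertex = TRUE,
                                outcome_vertices = character()) {
  if (require_outcome_vertex && !length(outcome_vertices)) {
    stop("require_outcome_vertex = TRUE needs outcome_vertices", call. = FALSE)
  }
  out <- list()
  work <- graph
  while (igraph::vcount(work) > 0) {
    clique <- maximum_clique(work)
    if (length(clique) < min_clique) break
    pc <- glom(work, clique, g)
    out[[length(out) + 1L]] <- pc
    work <- igraph::delete_vertices(work, pc$members)
  }
  retained <- if (require_outcome_vertex) {
    Filter(function(pc) any(outcome_vertices %in% pc$members), out)
  } else out
  structure(list(all = out, retained = retained), class = "paraclique_set")
}

#' @export
print.paraclique_set <- function(x, ...) {
  cat("<paraclique_set> extracted ", length(x$all), ", retained ",
      length(x$retained), "\n", sep = "")
  for (pc in x$all) print(pc)
  invisible(x)
}

#' Independently verify a paraclique's certificates
#'
#' Re-checks, against the graph and not the construction path: the seed is a
#' clique; every glommed vertex has at least |seed| - g seed neighbours; and
#' the density meets the analytic lower bound
#' (C(s,2) + m(s-g)) / C(s+m, 2).
#'
#' @param graph the igraph the paraclique was extracted from (or a supergraph
#'   containing its members with the same edges).
#' @param pc a `paraclique`.
#' @return TRUE invisibly; stops with a message if any certificate fails.
#' @export
check_paraclique <- function(graph, pc) {
  s <- length(pc$seed_clique)
  m <- length(pc$glommed)
  sub <- igraph::induced_subgraph(graph, pc$seed_clique)
  if (igraph::ecount(sub) != choose(s, 2)) {
    stop("certificate failure: seed is not a clique", call. = FALSE)
  }
  for (v in pc$glommed) {
    k <- sum(igraph::neighbors(graph, v)$name %in% pc$seed_clique)
    if (k < s - pc$glom_term) {
      stop("certificate failure: glommed vertex ", v, " has ", k,
           " seed neighbours < ", s - pc$glom_term, call. = FALSE)
    }
  }
  if (s + m > 1) {
    bound <- (choose(s, 2) + m * (s - pc$glom_term)) / choose(s + m, 2)
    if (pc$density < bound - 1e-12) {
      stop("certificate failure: density ", pc$density,
           " below bound ", bound, call. = FALSE)
    }
  }
  invisible(TRUE)
}
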
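#' Build a correlation graph object
#'
#' Correlation graphs are igraph objects whose vertices are variable names
#' and whose edges carry the Pearson correlation as `weight`. Graph
#' attributes record the threshold, the threshold mode (`signed` edges
#' require r >= t, `absolute` edges require |r| >= t) and the pairwise
#' minimum-overlap rule under which edges were computed.
#'
#' @param vertices character vector of variable names.
#' @param edges data.frame with columns `from`, `to`, `weight` (possibly
#'   zero rows).
#' @param threshold correlation threshold the edges satisfy.
#' @param threshold_mode `"signed"` or `"absolute"`.
#' @param min_pairs minimum overlapping counties per pair.
#' @return an igraph object with the attributes above.
#' @export
correlation_graph <- function(vertices, edges, threshold,
                              threshold_mode = c("signed", "absolute"),
                              min_pairs = NA_integer_) {
  threshold_mode <- match.arg(threshold_mode)
  if (anyDuplicated(vertices)) stop("duplicate vertex names", call. = FALSE)
  if (nrow(edges)) {
    if (any(edges$from == edges$to)) stop("self-loop in edge list", call. = FALSE)
    if (any(abs(edges$weight) > 1 + 1e-12)) {
      stop("edge weight outside [-1, 1]", call. = FALSE)
    }
    bad <- !(edges$from %in% vertices) | !(edges$to %in% vertices)
    if (any(bad)) stop("edge endpoint not in vertex set", call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = vertices))
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  g <- igraph::set_graph_attr(g, "threshold_mode", threshold_mode)
  g <- igraph::set_graph_attr(g, "min_pairs", min_pairs)
  g
}

#' Write a correlation graph as plain edge-list text
#'
#' The format is diff-able, bit-stable text: a `*vertices` section listing
#' every vertex (so isolated vertices survive a round trip), then an
#' `*edges` section of tab-separated `from`, `to`, `weight` rows with
#' weights printed to 6 decimals. Header comment lines record threshold
#' provenance.
#'
#' @param graph an igraph correlation graph.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_correlation_graph <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  thr <- igraph::graph_attr(graph, "threshold")
  mode <- igraph::graph_attr(graph, "threshold_mode")
  mp <- igraph::graph_attr(graph, "min_pairs")
  writeLines(c(
    sprintf("# correlation graph: threshold=%s mode=%s min_pairs=%s",
            ifelse(is.null(thr), "NA", format(thr)),
            ifelse(is.null(mode), "NA", mode),
            ifelse(is.null(mp), "NA", format(mp))),
    "*vertices"), con)
  writeLines(igraph::V(graph)$name, con)
  writeLines("*edges", con)
  el <- igraph::as_data_frame(graph, what = "edges")
  if (nrow(el)) {
    writeLines(sprintf("%s\t%s\t%.6f", el$from, el$to, el$weight), con)
  }
  invisible(path)
}

#' Read a correlation graph written by [write_correlation_graph()]
#'
#' @param path file path.
#' @return an igraph correlation graph.
#' @export
read_correlation_graph <- function(path) {
  lines <- readLines(path)
  header <- grep("^# correlation graph:", lines, value = TRUE)
  thr <- NA_real_; mode <- "signed"; mp <- NA_integer_
  if (length(header)) {
    m <- regmatches(header[1],
                    regexec("threshold=([^ ]+) mode=([^ ]+) min_pairs=([^ ]+)", header[1]))[[1]]
    if (length(m) == 4) {
      thr <- suppressWarnings(as.numeric(m[2]))
      if (m[3] %in% c("signed", "absolute")) mode <- m[3]
      mp <- suppressWarnings(as.integer(m[4]))
    }
  }
  v_at <- which(lines == "*vertices")
  e_at <- which(lines == "*edges")
  if (length(v_at) != 1 || length(e_at) != 1 || e_at < v_at) {
    stop("malformed graph file (missing *vertices/*edges sections): ", path,
         call. = FALSE)
  }
  vertices <- lines[seq(v_at + 1, e_at - 1)]
  vertices <- vertices[nzchar(vertices)]
  edge_lines <- if (e_at < length(lines)) lines[seq(e_at + 1, length(lines))] else character()
  edge_lines_idx <- which(nzchar(edge_lines))
  edges <- data.frame(from = character(), to = character(), weight = numeric())
  if (length(edge_lines_idx)) {
    parts <- strsplit(edge_lines[edge_lines_idx], "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 3)
    if (length(bad)) {
      stop("malformed edge at line ", e_at + edge_lines_idx[bad[1]], " of ", path,
           call. = FALSE)
    }
    mat <- do.call(rbind, parts)
    w <- suppressWarnings(as.numeric(mat[, 3]))
    if (anyNA(w)) {
      stop("non-numeric weight at line ",
           e_at + edge_lines_idx[which(is.na(w))[1]], " of ", path, call. = FALSE)
    }
    edges <- data.frame(from = mat[, 1], to = mat[, 2], weight = w)
  }
  correlation_graph(vertices, edges, threshold = thr, threshold_mode = mode,
                    min_pairs = mp)
}

#' Write a learned DAG as DOT-compatible text
#'
#' Arcs point parent -> child. Node and score provenance are written as DOT
#' comments so the file remains renderable by graphviz.
#'
#' @param dag a `learned_dag` from [hill_climb()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_dag_dot <- function(dag, path) {
  stopifnot(inherits(dag, "learned_dag"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("digraph learned_dag {", con)
  writeLines(sprintf("  // total BIC score: %.6f", dag$score_total), con)
  writeLines(sprintf("  \"%s\";", dag$nodes), con)
  if (nrow(dag$arcs)) {
    writeLines(sprintf("  \"%s\" -> \"%s\";", dag$arcs[, 1], dag$arcs[, 2]), con)
  }
  writeLines("}", con)
  invisible(path)
}

#' Read a DAG written by [write_dag_dot()]
#'
#' Parses only the restricted DOT dialect this package emits (quoted node
#' statements and quoted `"a" -> "b";` arc statements).
#'
#' @param path file path.
#' @return a list with `nodes` and a two-column `arcs` matrix.
#' @export
read_dag_dot <- function(path) {
  lines <- readLines(path)
  arc_lines <- grep("->", lines, value = TRUE, fixed = TRUE)
  arcs <- matrix(character(), ncol = 2,
                 dimnames = list(NULL, c("from", "to")))
  if (length(arc_lines)) {
    m <- regmatches(arc_lines, regexec("\"([^\"]+)\" -> \"([^\"]+)\"", arc_lines))
    ok <- lengths(m) == 3
    if (!all(ok)) {
      stop("malformed arc at line ", which(lines == arc_lines[!ok][1]),
           " of ", path, call. = FALSE)
    }
    arcs <- do.call(rbind, lapply(m, function(p) p[2:3]))
    colnames(arcs) <- c("from", "to")
  }
  node_lines <- grep("^  \"[^\"]+\";$", lines, value = TRUE)
  nodes <- sub("^  \"([^\"]+)\";$", "\\1", node_lines)
  list(nodes = unique(c(nodes, as.vector(arcs))), arcs = arcs)
}
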
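#' Build an undirected herd exchange graph
#'
#' Herds are vertices and an edge joins two herds with one or more recorded
#' animal exchanges between them, in either direction: duplicate and
#' reciprocal records collapse to a single undirected edge, matching the 0/1
#' adjacency-matrix construction. The original (possibly directed) records
#' are retained for reporting, but direction never enters any metric.
#'
#' @param records an [exchange_records()] data.frame.
#' @param restrict_to optional herd ids: keeps only these herds (including
#'   edgeless ones) and the edges between them.
#' @return A list of class `herd_graph` with `graph` (igraph object),
#'   `herds`, `records`.
#' @export
build_graph <- function(records, restrict_to = NULL) {
  und <- unique_undirected_pairs(records)
  verts <- sort(unique(c(und$a, und$b, restrict_to)))
  if (!is.null(restrict_to)) {
    verts <- sort(unique(as.character(restrict_to)))
    und <- und[und$a %in% verts & und$b %in% verts, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(und, directed = FALSE,
                                     vertices = data.frame(name = verts))
  structure(list(graph = g, herds = verts, records = records),
            class = "herd_graph")
}

#' @export
print.herd_graph <- function(x, ...) {
  cat(sprintf("herd_graph: %d herds, %d undirected edges, AD = %.2f\n",
              length(x$herds), igraph::gsize(x$graph), average_degree(x)))
  comp <- igraph::components(x$graph)
  if (comp$no > 1L)
    cat(sprintf("  %d connected components (sizes %s)\n", comp$no,
                paste(sort(comp$csize, decreasing = TRUE), collapse = ", ")))
  invisible(x)
}

#' Average degree of a herd graph
#'
#' AD = 2e/n: the mean number of exchange partners per herd, where n is the
#' number of vertices and e the number of undirected edges.
#'
#' @param g a `herd_graph`, or anything coercible via `n`/`e` below.
#' @param n,e alternatively, give vertex and edge counts directly.
#' @return A single number.
#' @export
average_degree <- function(g = NULL, n = NULL, e = NULL) {
  if (!is.null(g)) {
    stopifnot(inherits(g, "herd_graph"))
    n <- length(g$herds); e <- igraph::gsize(g$graph)
  }
  if (is.null(n) || n < 1L) stop("empty vertex set")
  2 * e / n
}

#' All-pairs shortest path lengths (geodesic edge counts)
#'
#' Breadth-first geodesic distances between every pair of herds; `Inf` marks
#' pairs in different components.
#'
#' @param g a `herd_graph`.
#' @return A `herd_matrix` with `kind = "spl"`.
#' @export
shortest_path_lengths <- function(g) {
  stopifnot(inherits(g, "herd_graph"))
  d <- igraph::distances(g$graph, algorithm = "unweighted")
  d <- d[g$herds, g$herds, drop = FALSE]
  structure(list(herds = g$herds, values = d, kind = "spl"),
            class = "herd_matrix")
}

#' All-pairs geodesic counts
#'
#' Number of distinct shortest paths between every pair of herds, by the
#' standard BFS path-counting recurrence: sigma(s,v) = sum over geodesic
#' predecessors u of v of sigma(s,u). Diagonal is 1 (the empty path);
#' unreachable pairs are 0.
#'
#' @param g a `herd_graph`.
#' @return A symmetric numeric matrix with herd-id dimnames.
#' @export
geodesic_counts <- function(g) {
  stopifnot(inherits(g, "herd_graph"))
  n <- length(g$herds)
  # vertex order in the igraph object matches g$herds by construction
  adj <- lapply(igraph::as_adj_list(g$graph), as.integer)
  sigma <- matrix(0, n, n, dimnames = list(g$herds, g$herds))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); cnt <- numeric(n)
    dist[s] <- 0; cnt[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) for (w in adj[[v]]) {
        if (is.infinite(dist[w])) { dist[w] <- dist[v] + 1; nxt <- c(nxt, w) }
        if (dist[w] == dist[v] + 1) cnt[w] <- cnt[w] + cnt[v]
      }
      frontier <- unique(nxt)
    }
    sigma[s, ] <- cnt
  }
  sigma
}

#' Network metrics stratified by shortest path length
#'
#' For each observed SPL value d >= 1 over the analysis herd set: the pair
#' set P_d of herd pairs at geodesic distance d, the mean geodesic count over
#' P_d, the mean genetic distance over P_d (when a Reynolds matrix is
#' supplied), and the induced-subgraph metrics of the stratum: its vertex set
#' is every herd appearing in at least one pair of P_d, its edge set the
#' edges of `g` with both endpoints in that vertex set, and its average
#' degree 2e/n from those counts.
#'
#' @param g a `herd_graph`.
#' @param spl a `herd_matrix` of kind `"spl"` (from
#'   [shortest_path_lengths()]).
#' @param counts geodesic-count matrix (from [geodesic_counts()]); optional.
#' @param gen optional `herd_matrix` of kind `"reynolds"` aligned on a
#'   subset of the graph's herds.
#' @return A data.frame with one row per SPL stratum: `spl`,
#'   `mean_geodesics`, `mean_reynolds`, `n_exchanges`, `n_herds`,
#'   `average_degree`.
#' @export
spl_stratified_metrics <- function(g, spl, counts = NULL, gen = NULL) {
  stopifnot(inherits(g, "herd_graph"), inherits(spl, "herd_matrix"),
            spl$kind == "spl")
  herds <- spl$herds
  if (!all(herds %in% g$herds)) stop("SPL herds absent from graph")
  if (!is.null(gen) && !identical(gen$herds, herds))
    stop("genetic matrix herd ordering differs from SPL matrix")
  d <- spl$values
  ut <- upper.tri(d)
  dvals <- sort(unique(d[ut & is.finite(d) & d >= 1]))
  rows <- lapply(dvals, function(dd) {
    sel <- ut & d == dd
    pairs <- which(sel, arr.ind = TRUE)
    stratum_herds <- unique(c(herds[pairs[, 1]], herds[pairs[, 2]]))
    sub <- igraph::induced_subgraph(g$graph, stratum_herds)
    nh <- length(stratum_herds); ne <- igraph::gsize(sub)
    data.frame(
      spl = dd,
      n_pairs = nrow(pairs),
      mean_geodesics = if (is.null(counts)) NA_real_
                       else mean(counts[herds, herds][sel]),
      mean_reynolds = if (is.null(gen)) NA_real_ else mean(gen$values[sel]),
      n_exchanges = ne, n_herds = nh, average_degree = 2 * ne / nh)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Adjacency matrix of a herd graph
#'
#' @param g a `herd_graph`.
#' @return A symmetric 0/1 integer matrix with herd-id dimnames.
#' @export
adjacency_matrix <- function(g) {
  stopifnot(inherits(g, "herd_graph"))
  m <- as.matrix(igraph::as_adjacency_matrix(g$graph))
  m <- m[g$herds, g$herds, drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

#' Rebuild a herd graph from a 0/1 adjacency matrix
#'
#' @param m symmetric 0/1 matrix with herd-id dimnames.
#' @return A `herd_graph`.
#' @export
graph_from_adjacency <- function(m) {
  stopifnot(is.matrix(m), isSymmetric(unname(m)))
  herds <- rownames(m)
  pairs <- which(upper.tri(m) & m != 0, arr.ind = TRUE)
  if (nrow(pairs) == 0L)
    return(build_graph(exchange_records(character(0), character(0)),
                       restrict_to = herds))
  build_graph(exchange_records(herds[pairs[, 1]], herds[pairs[, 2]],
                               direction_known = FALSE),
              restrict_to = herds)
}

#' Write a herd graph as edge-list and adjacency-matrix TSV
#'
#' @param g a `herd_graph`.
#' @param edges_path,adjacency_path output paths (either may be `NULL`).
#' @return `g`, invisibly.
#' @export
write_graph_tables <- function(g, edges_path = NULL, adjacency_path = NULL) {
  stopifnot(inherits(g, "herd_graph"))
  if (!is.null(edges_path)) {
    el <- igraph::as_edgelist(g$graph)
    df <- data.frame(herd_i = el[, 1], herd_j = el[, 2])
    df <- df[order(df$herd_i, df$herd_j), , drop = FALSE]
    write.table(df, edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(adjacency_path)) {
    m <- adjacency_matrix(g)
    df <- data.frame(herd = rownames(m), m, check.names = FALSE)
    write.table(df, adjacency_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(g)
}
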
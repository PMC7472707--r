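#' Areal adjacency graphs
#'
#' An `adjacency_graph` stores the neighbourhood structure of a set of areal
#' units (districts): the ordered unit labels, per-unit neighbour index sets,
#' and the neighbour counts \eqn{m_j}. Two units are neighbours when they share
#' a boundary; the graph is undirected, without self-loops.
#'
#' @param unit_ids character vector of areal-unit labels, in canonical order.
#' @param edges two-column matrix or data.frame of unit labels (or 1-based
#'   indices), one row per undirected edge.
#' @return An object of class `adjacency_graph` with components `unit_ids`,
#'   `neighbors` (list of integer vectors, 1-based), and `m` (integer vector
#'   of neighbour counts).
#' @examples
#' g <- adjacency_graph(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
#' g$m
#' @export
adjacency_graph <- function(unit_ids, edges) {
  unit_ids <- as.character(unit_ids)
  if (anyDuplicated(unit_ids)) stop("duplicated unit ids")
  n <- length(unit_ids)
  edges <- as.matrix(edges)
  if (ncol(edges) != 2) stop("edges must have two columns")
  if (is.numeric(edges)) {
    ii <- as.integer(edges[, 1]); jj <- as.integer(edges[, 2])
  } else {
    ii <- match(as.character(edges[, 1]), unit_ids)
    jj <- match(as.character(edges[, 2]), unit_ids)
  }
  if (anyNA(ii) || anyNA(jj) || any(ii < 1 | ii > n | jj < 1 | jj > n))
    stop("edge refers to unknown unit")
  if (any(ii == jj)) stop("self-loops are not allowed")
  nbr <- vector("list", n)
  for (k in seq_along(ii)) {
    nbr[[ii[k]]] <- c(nbr[[ii[k]]], jj[k])
    nbr[[jj[k]]] <- c(nbr[[jj[k]]], ii[k])
  }
  nbr <- lapply(nbr, function(v) sort(unique(as.integer(v))))
  structure(
    list(unit_ids = unit_ids, neighbors = nbr, m = vapply(nbr, length, 1L)),
    class = "adjacency_graph"
  )
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat("adjacency_graph:", length(x$unit_ids), "units,",
      sum(x$m) / 2, "edges; m in [", min(x$m), ",", max(x$m), "]\n")
  invisible(x)
}

#' Number of undirected edges of a graph
#' @param graph an `adjacency_graph`.
#' @export
n_edges <- function(graph) sum(graph$m) / 2L

#' Validate an adjacency graph
#'
#' Checks symmetry of the neighbour lists, absence of self-loops, and
#' consistency of the stored neighbour counts.
#' @param graph an `adjacency_graph`.
#' @return `graph`, invisibly; errors on an invalid graph.
#' @export
validate_graph <- function(graph) {
  stopifnot(inherits(graph, "adjacency_graph"))
  n <- length(graph$unit_ids)
  for (j in seq_len(n)) {
    nb <- graph$neighbors[[j]]
    if (any(nb == j)) stop("self-loop at unit ", graph$unit_ids[j])
    if (length(nb) != graph$m[j]) stop("m inconsistent at unit ", j)
    for (k in nb) {
      if (!(j %in% graph$neighbors[[k]]))
        stop("asymmetric neighbour lists: ", j, " -> ", k)
    }
  }
  invisible(graph)
}

#' Rook-adjacency lattice graph
#'
#' Builds an `n_rows` by `n_cols` rectangular lattice with rook (shared-edge)
#' adjacency. The default analysis graph is the 8 x 8 lattice, a 64-unit
#' stand-in for a national district map.
#'
#' @param n_rows,n_cols positive integers; `n_rows * n_cols >= 2`.
#' @return An `adjacency_graph` with `n_rows * n_cols` units labelled
#'   `d01, d02, ...` in row-major order.
#' @examples
#' g <- lattice_graph(8, 8)   # 64 units, 112 edges
#' n_edges(g)
#' @export
lattice_graph <- function(n_rows, n_cols) {
  if (n_rows < 1 || n_cols < 1) stop("lattice dimensions must be positive")
  n <- n_rows * n_cols
  if (n < 2) stop("lattice must have at least 2 units")
  idx <- function(r, c) (r - 1L) * n_cols + c
  e <- list()
  for (r in seq_len(n_rows)) for (c in seq_len(n_cols)) {
    if (c < n_cols) e[[length(e) + 1L]] <- c(idx(r, c), idx(r, c + 1L))
    if (r < n_rows) e[[length(e) + 1L]] <- c(idx(r, c), idx(r + 1L, c))
  }
  ids <- sprintf("d%0*d", max(2L, nchar(n)), seq_len(n))
  adjacency_graph(ids, do.call(rbind, e))
}

#' Connected components of an adjacency graph
#'
#' @param graph an `adjacency_graph`.
#' @return A list of character vectors, each the unit ids of one component,
#'   ordered by first appearance.
#' @export
connected_components <- function(graph) {
  n <- length(graph$unit_ids)
  el <- graph_edge_matrix(graph)
  ig <- igraph::graph_from_edgelist(cbind(el[, 1], el[, 2]), directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0L, n - igraph::vcount(ig)))
  comp <- igraph::components(ig)$membership[seq_len(n)]
  lapply(sort(unique(comp)), function(k) graph$unit_ids[comp == k])
}

#' @return TRUE if the graph has a single connected component.
#' @rdname connected_components
#' @export
is_connected <- function(graph) length(connected_components(graph)) == 1L

graph_edge_matrix <- function(graph) {
  n <- length(graph$unit_ids)
  out <- list()
  for (j in seq_len(n)) {
    nb <- graph$neighbors[[j]]
    nb <- nb[nb > j]
    if (length(nb)) out[[length(out) + 1L]] <- cbind(j, nb)
  }
  if (!length(out)) return(matrix(integer(), 0, 2))
  do.call(rbind, out)
}

#' Read / write adjacency as an edge-list CSV
#'
#' The canonical interchange format: a two-column CSV (`from`, `to`) of unit
#' ids, one row per undirected edge, each pair listed once.
#'
#' @param graph an `adjacency_graph`.
#' @param path file path.
#' @param unit_ids optional full unit-id vector for [read_graph_edgelist()];
#'   needed if some units are isolated (they never appear in the edge list).
#' @export
write_graph_edgelist <- function(graph, path) {
  el <- graph_edge_matrix(graph)
  df <- data.frame(from = graph$unit_ids[el[, 1]], to = graph$unit_ids[el[, 2]],
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_graph_edgelist
#' @export
read_graph_edgelist <- function(path, unit_ids = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character"))
  if (is.null(unit_ids)) unit_ids <- sort(unique(c(df[[1]], df[[2]])))
  adjacency_graph(unit_ids, as.matrix(df[, 1:2]))
}

#' Adjacency from GeoJSON polygons by shared boundary
#'
#' Parses a GeoJSON FeatureCollection of Polygon / MultiPolygon features and
#' declares two features neighbours when they share at least one full polygon
#' edge segment (positive-length contact), after rounding coordinates to
#' `digits` decimal places. Point-touching corners do not create adjacency.
#' Assumes a well-noded boundary file in which neighbouring polygons trace
#' their common border with identical vertex chains.
#'
#' @param path path to a GeoJSON file.
#' @param id_property name of the feature property holding the unit id.
#' @param digits coordinate rounding used when matching shared segments.
#' @return An `adjacency_graph`.
#' @export
graph_from_geojson <- function(path, id_property = "id", digits = 6) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  ids <- character(0); seg_tab <- list()
  seg_key <- function(p1, p2) {
    a <- paste(round(p1, digits), collapse = ","); b <- paste(round(p2, digits), collapse = ",")
    if (a < b) paste(a, b, sep = "|") else paste(b, a, sep = "|")
  }
  rings_of <- function(geom) {
    if (geom$type == "Polygon") geom$coordinates
    else if (geom$type == "MultiPolygon") do.call(c, geom$coordinates)
    else stop("unsupported geometry type: ", geom$type)
  }
  feat_segs <- list()
  for (f in gj$features) {
    id <- as.character(f$properties[[id_property]])
    if (!length(id)) stop("feature missing id property '", id_property, "'")
    ids <- c(ids, id)
    segs <- character(0)
    for (ring in rings_of(f$geometry)) {
      pts <- lapply(ring, function(p) as.numeric(p[1:2]))
      for (k in seq_len(length(pts) - 1L))
        segs <- c(segs, seg_key(pts[[k]], pts[[k + 1L]]))
    }
    feat_segs[[id]] <- unique(segs)
  }
  if (anyDuplicated(ids)) stop("duplicated feature ids")
  owner <- new.env(parent = emptyenv())
  edges <- list()
  for (id in ids) for (s in feat_segs[[id]]) {
    prev <- owner[[s]]
    if (is.null(prev)) assign(s, id, envir = owner)
    else if (prev != id) edges[[length(edges) + 1L]] <- c(prev, id)
  }
  if (!length(edges)) stop("no shared boundaries found")
  edges <- unique(do.call(rbind, edges))
  adjacency_graph(ids, edges)
}
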
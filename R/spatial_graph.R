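#' Spatial neighbourhood graphs for areal units
#'
#' A `spatial_graph` is an undirected simple graph over labelled areal
#' units. Edges are stored as an m x 2 integer matrix of node indices with
#' i < j; no self-loops are permitted.
#'
#' @param node_ids character vector of unique unit labels.
#' @param edges two-column matrix of node indices or node labels; each row
#'   one undirected edge.
#' @param scheme construction scheme label, one of `"queen"`, `"knn"`,
#'   `"distance_band"`, `"custom"`.
#' @return object of class `spatial_graph` with elements `node_ids`,
#'   `edges`, `scheme`.
#' @export
spatial_graph <- function(node_ids, edges, scheme = "custom") {
  node_ids <- as.character(node_ids)
  if (anyDuplicated(node_ids)) stop("node_ids must be unique")
  scheme <- match.arg(scheme, c("queen", "knn", "distance_band", "custom"))
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop("edges must have two columns")
    if (is.character(edges)) {
      idx <- match(edges, node_ids)
      if (anyNA(idx))
        stop("edge refers to unknown node: ",
             paste(unique(edges[is.na(idx)]), collapse = ", "))
      edges <- matrix(idx, ncol = 2L)
    }
    storage.mode(edges) <- "integer"
    if (any(edges < 1L) || any(edges > length(node_ids)))
      stop("edge index out of range")
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  structure(list(node_ids = node_ids, edges = edges, scheme = scheme),
            class = "spatial_graph")
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat("spatial_graph (", x$scheme, "): ", length(x$node_ids), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Number of neighbours of each node
#' @param graph a [spatial_graph].
#' @return named integer vector of degrees.
#' @export
graph_degree <- function(graph) {
  stopifnot(inherits(graph, "spatial_graph"))
  d <- tabulate(c(graph$edges[, 1L], graph$edges[, 2L]),
                nbins = length(graph$node_ids))
  names(d) <- graph$node_ids
  d
}

#' Neighbour index list
#' @param graph a [spatial_graph].
#' @return named list; element i holds the integer indices of i's neighbours.
#' @export
graph_neighbors <- function(graph) {
  stopifnot(inherits(graph, "spatial_graph"))
  n <- length(graph$node_ids)
  nb <- rep(list(integer(0)), n)
  if (nrow(graph$edges) > 0L) {
    for (r in seq_len(nrow(graph$edges))) {
      i <- graph$edges[r, 1L]; j <- graph$edges[r, 2L]
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
    nb <- lapply(nb, sort)
  }
  names(nb) <- graph$node_ids
  nb
}

#' Connected components of a spatial graph
#' @param graph a [spatial_graph].
#' @return integer vector of component labels (1-based), one per node.
#' @export
graph_components <- function(graph) {
  n <- length(graph$node_ids)
  nb <- graph_neighbors(graph)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in nb[[v]]) if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
    }
  }
  comp
}

## ---- geometry helpers -------------------------------------------------

## squared point-segment distance, vectorised over points p (n x 2)
.pt_seg_dist2 <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(rowSums(sweep(p, 2L, a)^2))
  t <- ((p[, 1L] - a[1L]) * ab[1L] + (p[, 2L] - a[2L]) * ab[2L]) / len2
  t <- pmin(1, pmax(0, t))
  dx <- a[1L] + t * ab[1L] - p[, 1L]
  dy <- a[2L] + t * ab[2L] - p[, 2L]
  dx * dx + dy * dy
}

## do open segments (a1,a2) and (b1,b2) properly cross?
.seg_cross <- function(a1, a2, b1, b2) {
  d <- function(p, q, r) (q[1L] - p[1L]) * (r[2L] - p[2L]) -
                         (q[2L] - p[2L]) * (r[1L] - p[1L])
  d1 <- d(b1, b2, a1); d2 <- d(b1, b2, a2)
  d3 <- d(a1, a2, b1); d4 <- d(a1, a2, b2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

.ring_vertices <- function(ring) {
  v <- as.matrix(ring)
  if (ncol(v) != 2L) stop("ring must be a two-column coordinate matrix")
  ## drop closing vertex if the ring repeats its first point
  if (nrow(v) > 1L && all(v[1L, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  v
}

.check_simple_ring <- function(v, id) {
  n <- nrow(v)
  if (n < 3L) stop("polygon '", id, "' has fewer than 3 distinct vertices")
  for (i in seq_len(n)) {
    a1 <- v[i, ]; a2 <- v[if (i == n) 1L else i + 1L, ]
    for (j in seq_len(n)) {
      if (abs(i - j) <= 1L || abs(i - j) == n - 1L) next
      b1 <- v[j, ]; b2 <- v[if (j == n) 1L else j + 1L, ]
      if (.seg_cross(a1, a2, b1, b2))
        stop("polygon '", id, "' is self-intersecting")
    }
  }
  invisible(NULL)
}

## normalise a polygon argument to a list of vertex matrices (rings)
.poly_rings <- function(poly) {
  if (is.matrix(poly) || is.data.frame(poly)) list(.ring_vertices(poly))
  else lapply(poly, .ring_vertices)
}

#' Queen contiguity graph from polygon boundaries
#'
#' Two areal units are neighbours under queen contiguity when their
#' boundaries share at least one point — a common edge or a single common
#' corner both qualify. Boundary sharing is detected from the polygon
#' vertex chains: coincident vertices (within `tol`) or a vertex of one
#' unit lying on a boundary segment of the other.
#'
#' @param polygons named list, one element per unit; each element a
#'   two-column coordinate matrix (one ring) or a list of such matrices
#'   (multi-part unit). Rings may or may not repeat their first vertex.
#' @param tol distance tolerance for point coincidence, in coordinate
#'   units.
#' @return a [spatial_graph] with `scheme = "queen"`.
#' @examples
#' sq <- function(x, y) cbind(c(x, x + 1, x + 1, x), c(y, y, y + 1, y + 1))
#' g <- queen_adjacency(list(a = sq(0, 0), b = sq(1, 0), c = sq(0, 1),
#'                           d = sq(1, 1)))
#' graph_degree(g)  # all 3: a 2x2 block of squares is fully connected
#' @export
queen_adjacency <- function(polygons, tol = 1e-8) {
  if (is.null(names(polygons)) || anyDuplicated(names(polygons)))
    stop("polygons must be a named list with unique names")
  ids <- names(polygons)
  rings <- lapply(polygons, .poly_rings)
  for (i in seq_along(rings))
    for (v in rings[[i]]) .check_simple_ring(v, ids[i])
  verts <- lapply(rings, function(r) do.call(rbind, r))
  bbox <- t(vapply(verts, function(v)
    c(min(v[, 1L]), max(v[, 1L]), min(v[, 2L]), max(v[, 2L])),
    numeric(4L)))
  n <- length(ids)
  edges <- matrix(integer(0), ncol = 2L)
  tol2 <- tol * tol
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (bbox[i, 1L] > bbox[j, 2L] + tol || bbox[j, 1L] > bbox[i, 2L] + tol ||
          bbox[i, 3L] > bbox[j, 4L] + tol || bbox[j, 3L] > bbox[i, 4L] + tol)
        next
      if (.polys_touch(verts[[i]], verts[[j]], rings[[i]], rings[[j]], tol2))
        edges <- rbind(edges, c(i, j))
    }
  }
  spatial_graph(ids, edges, scheme = "queen")
}

.polys_touch <- function(va, vb, ringsa, ringsb, tol2) {
  ## vertex-vertex coincidence
  for (r in seq_len(nrow(va))) {
    d2 <- (vb[, 1L] - va[r, 1L])^2 + (vb[, 2L] - va[r, 2L])^2
    if (any(d2 <= tol2)) return(TRUE)
  }
  ## vertex of one on a boundary segment of the other (T-junctions)
  if (.verts_on_edges(va, ringsb, tol2)) return(TRUE)
  if (.verts_on_edges(vb, ringsa, tol2)) return(TRUE)
  FALSE
}

.verts_on_edges <- function(pts, rings, tol2) {
  for (v in rings) {
    n <- nrow(v)
    for (s in seq_len(n)) {
      a <- v[s, ]; b <- v[if (s == n) 1L else s + 1L, ]
      if (any(.pt_seg_dist2(pts, a, b) <= tol2)) return(TRUE)
    }
  }
  FALSE
}

## pairwise distances between rows of a 2-column coordinate matrix
.pair_dist <- function(xy, great_circle = FALSE) {
  if (great_circle) {
    ## haversine distance on a sphere of radius 6371 km; columns (lon, lat)
    lam <- xy[, 1L] * pi / 180
    phi <- xy[, 2L] * pi / 180
    n <- nrow(xy)
    d <- matrix(0, n, n)
    for (i in seq_len(n)) {
      h <- sin((phi - phi[i]) / 2)^2 +
        cos(phi[i]) * cos(phi) * sin((lam - lam[i]) / 2)^2
      d[i, ] <- 2 * 6371 * asin(pmin(1, sqrt(h)))
    }
    d
  } else {
    as.matrix(stats::dist(xy))
  }
}

.centroid_xy <- function(centroids) {
  if (is.data.frame(centroids)) {
    if (!all(c("unit_id", "x", "y") %in% names(centroids)))
      stop("centroids data frame needs columns unit_id, x, y")
    xy <- as.matrix(centroids[, c("x", "y")])
    rownames(xy) <- as.character(centroids$unit_id)
  } else {
    xy <- as.matrix(centroids)
    if (is.null(rownames(xy))) stop("centroid matrix must have row names")
  }
  if (anyDuplicated(rownames(xy))) stop("duplicate unit_id in centroids")
  if (anyDuplicated(xy) > 0) stop("centroid coordinates must be distinct")
  xy
}

#' k-nearest-neighbour graph from centroids
#'
#' Each unit is linked to its `k` nearest distinct units; the directed
#' relation is then symmetrised by union, so every node ends with at least
#' `k` neighbours. Distance ties are broken by node label order (the
#' earlier label wins).
#'
#' @param centroids data frame with columns `unit_id`, `x`, `y`, or a
#'   coordinate matrix with row names.
#' @param k number of nearest neighbours, `1 <= k < N`.
#' @param great_circle if `TRUE`, coordinates are (lon, lat) degrees and
#'   haversine distances are used.
#' @return a [spatial_graph] with `scheme = "knn"`.
#' @export
knn_graph <- function(centroids, k = 5L, great_circle = FALSE) {
  xy <- .centroid_xy(centroids)
  n <- nrow(xy)
  if (k < 1L || k >= n) stop("k must satisfy 1 <= k < number of points")
  d <- .pair_dist(xy, great_circle)
  edges <- matrix(integer(0), ncol = 2L)
  for (i in seq_len(n)) {
    ord <- order(d[i, -i], seq_len(n)[-i])  # ties -> lower index/label first
    nn <- (seq_len(n)[-i])[ord[seq_len(k)]]
    edges <- rbind(edges, cbind(i, nn))
  }
  spatial_graph(rownames(xy), edges, scheme = "knn")
}

#' Distance-band graph from centroids
#'
#' Units within `threshold` of each other (0 < d <= threshold) are
#' neighbours. With `threshold = "auto"` the band is set to the maximum
#' over units of the nearest-neighbour distance, the smallest band that
#' leaves no unit isolated.
#'
#' @inheritParams knn_graph
#' @param threshold positive distance in coordinate units, or `"auto"`.
#' @return a [spatial_graph] with `scheme = "distance_band"` and attribute
#'   `threshold` (the numeric band used). Isolated nodes trigger a warning
#'   listing them.
#' @export
distance_band_graph <- function(centroids, threshold = "auto",
                                great_circle = FALSE) {
  xy <- .centroid_xy(centroids)
  n <- nrow(xy)
  d <- .pair_dist(xy, great_circle)
  if (identical(threshold, "auto")) {
    diag(d) <- Inf
    threshold <- max(apply(d, 1L, min))
    diag(d) <- 0
  }
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be a positive distance or \"auto\"")
  idx <- which(d > 0 & d <= threshold & upper.tri(d), arr.ind = TRUE)
  g <- spatial_graph(rownames(xy), idx, scheme = "distance_band")
  iso <- names(which(graph_degree(g) == 0L))
  if (length(iso) > 0L)
    warning("isolated node(s) at threshold ", format(threshold), ": ",
            paste(iso, collapse = ", "))
  attr(g, "threshold") <- threshold
  g
}

#' Spatial weight matrix of a neighbourhood graph
#'
#' Builds the N x N matrix W with w_ij > 0 exactly for neighbouring pairs
#' and a zero diagonal. `"binary"` gives w_ij = 1 for neighbours (symmetric
#' by construction); `"row_standardized"` divides each row by its sum so
#' non-isolated rows sum to 1 (rows of isolates stay zero).
#'
#' @param graph a [spatial_graph].
#' @param style `"binary"` or `"row_standardized"`.
#' @return object of class `weight_matrix`: list with `w` (dense numeric
#'   matrix, dimnames = unit ids), `N`, `style`.
#' @export
weight_matrix <- function(graph, style = c("binary", "row_standardized")) {
  stopifnot(inherits(graph, "spatial_graph"))
  style <- match.arg(style)
  n <- length(graph$node_ids)
  w <- matrix(0, n, n, dimnames = list(graph$node_ids, graph$node_ids))
  if (nrow(graph$edges) > 0L) {
    w[graph$edges] <- 1
    w[graph$edges[, c(2L, 1L), drop = FALSE]] <- 1
  }
  if (style == "row_standardized") {
    rs <- rowSums(w)
    nz <- rs > 0
    w[nz, ] <- w[nz, , drop = FALSE] / rs[nz]
  }
  structure(list(w = w, N = n, style = style), class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat("weight_matrix: N =", x$N, ", style =", x$style,
      ", S0 =", sum(x$w), "\n")
  invisible(x)
}

## ---- readers ----------------------------------------------------------

#' Read polygons from a GeoJSON FeatureCollection
#'
#' Accepts Polygon and MultiPolygon features; each feature must carry a
#' `unit_id` property. Only exterior rings are retained (holes do not
#' affect queen contiguity for valid areal partitions).
#'
#' @param path path to a GeoJSON file.
#' @return named list of polygon rings suitable for [queen_adjacency]:
#'   a coordinate matrix per single-ring unit, a list of matrices for
#'   multi-part units.
#' @export
read_geojson <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection")
  out <- list()
  for (ft in gj$features) {
    id <- ft$properties$unit_id
    if (is.null(id)) stop("GeoJSON feature lacks a unit_id property")
    id <- as.character(id)
    if (id %in% names(out)) stop("duplicate unit_id in GeoJSON: ", id)
    geom <- ft$geometry
    ring_mat <- function(ring)
      do.call(rbind, lapply(ring, function(p) c(p[[1L]], p[[2L]])))
    if (identical(geom$type, "Polygon")) {
      out[[id]] <- ring_mat(geom$coordinates[[1L]])
    } else if (identical(geom$type, "MultiPolygon")) {
      out[[id]] <- lapply(geom$coordinates, function(poly) ring_mat(poly[[1L]]))
    } else {
      stop("unsupported geometry type '", geom$type, "' for unit ", id)
    }
  }
  out
}

#' Read a neighbourhood graph from an adjacency-list text file
#'
#' One node per line in the form `id: id1,id2,...` (the list may be
#' empty). The relation is symmetrised on read; a warning reports entries
#' that were present in only one direction.
#'
#' @param path path to the adjacency list.
#' @return a [spatial_graph] with `scheme = "custom"`.
#' @export
read_adjacency <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, ":", fixed = TRUE)
  if (any(lengths(parts) < 1L)) stop("malformed adjacency line")
  ids <- trimws(vapply(parts, `[[`, character(1L), 1L))
  if (anyDuplicated(ids)) stop("duplicate node id in adjacency list")
  nb <- lapply(parts, function(p) {
    if (length(p) < 2L || !nzchar(trimws(p[[2L]]))) return(character(0))
    trimws(strsplit(p[[2L]], ",", fixed = TRUE)[[1L]])
  })
  unknown <- setdiff(unique(unlist(nb)), ids)
  if (length(unknown) > 0L)
    stop("adjacency list refers to unknown node(s): ",
         paste(unknown, collapse = ", "))
  edges <- matrix(character(0), ncol = 2L)
  asym <- character(0)
  for (i in seq_along(ids)) {
    for (j in nb[[i]]) {
      if (!(ids[i] %in% nb[[match(j, ids)]]))
        asym <- c(asym, paste0(ids[i], "-", j))
      edges <- rbind(edges, c(ids[i], j))
    }
  }
  if (length(asym) > 0L)
    warning("asymmetric adjacency entries symmetrised: ",
            paste(unique(asym), collapse = ", "))
  spatial_graph(ids, edges, scheme = "custom")
}

#' Read a centroid table from CSV
#'
#' @param path CSV with columns `unit_id,x,y`.
#' @return data frame with columns `unit_id`, `x`, `y`.
#' @export
read_centroid_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("unit_id", "x", "y")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L)
    stop("missing centroid column(s): ", paste(miss, collapse = ", "))
  x$unit_id <- as.character(x$unit_id)
  if (anyDuplicated(x$unit_id)) stop("duplicate unit_id in centroid CSV")
  x[, need]
}
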
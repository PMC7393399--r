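#' Per-triangle areas of a surface mesh
#'
#' Each area is half the magnitude of the cross product of two edge
#' vectors.  Degenerate (collinear) faces yield area 0 with a warning.
#'
#' @param mesh a [surface_mesh].
#' @return numeric vector of face areas in mm^2.
#' @export
triangle_areas <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices
  f <- mesh$faces + 1L
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  a <- 0.5 * sqrt(cx^2 + cy^2 + cz^2)
  if (any(a == 0))
    warning(sum(a == 0), " degenerate (zero-area) face(s)")
  a
}

#' Per-vertex areas of a surface mesh
#'
#' Each vertex receives one third of the area of every incident triangle,
#' so vertex areas conserve total surface area exactly:
#' `sum(vertex_areas) == sum(triangle_areas)` up to float rounding.
#' Vertices with no incident face get area 0.
#'
#' @param mesh a [surface_mesh].
#' @return A [vertex_scalar_field] of areas (mm^2).
#' @export
vertex_areas <- function(mesh) {
  fa <- suppressWarnings(triangle_areas(mesh))
  n <- n_vertices(mesh)
  va <- numeric(n)
  idx <- as.vector(mesh$faces) + 1L
  acc <- rowsum(rep(fa / 3, 3L), group = idx)
  va[as.integer(rownames(acc))] <- acc[, 1L]
  vertex_scalar_field(va, units = "mm")
}

#' Build the vertex adjacency graph of a mesh
#'
#' Undirected mesh-edge graph with Euclidean edge lengths (mm).  Used by
#' [shortest_path()], [close_path()] and [flood_fill()]; building it once
#' and passing it in avoids repeated construction.
#'
#' @param mesh a [surface_mesh].
#' @return An object of class `mesh_graph` with per-vertex neighbor lists
#'   (0-based ids) and matching edge lengths.
#' @export
mesh_graph <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  f <- mesh$faces
  a <- c(f[, 1L], f[, 2L], f[, 3L])
  b <- c(f[, 2L], f[, 3L], f[, 1L])
  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- !duplicated(lo * as.double(n_vertices(mesh)) + hi)
  lo <- lo[keep]; hi <- hi[keep]
  len <- sqrt(rowSums((mesh$vertices[lo + 1L, , drop = FALSE] -
                         mesh$vertices[hi + 1L, , drop = FALSE])^2))
  n <- n_vertices(mesh)
  ends <- c(hi, lo)            # neighbor seen from lo, then from hi
  srcs <- c(lo, hi)
  w <- c(len, len)
  ord <- order(srcs, ends)
  srcs <- srcs[ord]; ends <- ends[ord]; w <- w[ord]
  grp <- factor(srcs, levels = 0:(n - 1L))
  structure(list(n = n,
                 neighbors = split(ends, grp),
                 lengths = split(w, grp)),
            class = "mesh_graph")
}

#' Shortest path between two vertices on the mesh edge graph
#'
#' Dijkstra search over mesh edges with Euclidean edge weights.  Ties in
#' path length are broken deterministically by preferring the
#' lower-indexed predecessor, so repeated runs give identical paths.
#'
#' @param graph a [mesh_graph].
#' @param src,dst 0-based vertex ids.
#' @return integer vector of 0-based vertex ids from `src` to `dst`
#'   inclusive, with attribute `length` (total path length, mm).
#' @export
shortest_path <- function(graph, src, dst) {
  stopifnot(inherits(graph, "mesh_graph"))
  n <- graph$n
  src <- as.integer(src); dst <- as.integer(dst)
  if (src < 0L || src >= n || dst < 0L || dst >= n)
    stop("src/dst out of vertex range [0, ", n, ")")
  if (src == dst)
    return(structure(src, length = 0))
  dist <- rep(Inf, n)
  prev <- rep(NA_integer_, n)
  done <- logical(n)
  dist[src + 1L] <- 0
  eps <- 1e-12
  repeat {
    d <- dist; d[done] <- Inf
    u1 <- which.min(d)           # ties: which.min takes the lowest index
    if (!is.finite(d[u1])) break
    if (u1 == dst + 1L) break
    done[u1] <- TRUE
    nb <- graph$neighbors[[u1]] + 1L
    nd <- d[u1] + graph$lengths[[u1]]
    for (k in seq_along(nb)) {
      v <- nb[k]
      if (done[v]) next
      if (nd[k] < dist[v] - eps ||
          (abs(nd[k] - dist[v]) <= eps && !is.na(prev[v]) && u1 < prev[v])) {
        dist[v] <- nd[k]
        prev[v] <- u1
      }
    }
  }
  if (!is.finite(dist[dst + 1L])) {
    comp <- .component_of(graph, src)
    stop(sprintf(
      "vertices %d and %d are not connected (component of %d has %d vertices)",
      src, dst, src, sum(comp)))
  }
  path <- integer(0)
  v <- dst + 1L
  while (!is.na(v)) {
    path <- c(v, path)
    v <- if (v == src + 1L) NA_integer_ else prev[v]
  }
  structure(path - 1L, length = dist[dst + 1L])
}

.component_of <- function(graph, src) {
  seen <- logical(graph$n)
  queue <- src + 1L
  seen[queue] <- TRUE
  while (length(queue)) {
    u <- queue[1L]; queue <- queue[-1L]
    nb <- graph$neighbors[[u]] + 1L
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  seen
}
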
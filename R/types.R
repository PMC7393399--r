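#' @title Core data structures for cortical surface lesion analysis
#' @description
#' The package represents a reconstructed cortical sheet as a triangulated
#' surface mesh plus per-vertex scalar fields (thickness, curvature,
#' frequency counts), labelled vertex sets (lesion labels, lesion overlays),
#' and a per-vertex network parcellation.  Vertex indices are 0-based
#' throughout, matching the on-disk FreeSurfer label format; every function
#' that accepts or returns vertex ids uses this convention.
#' @name lesionsurf-types
NULL

#' Construct a triangulated surface mesh
#'
#' @param vertices numeric matrix, N x 3, vertex coordinates in mm.
#' @param faces integer matrix, M x 3, 0-based vertex indices per triangle.
#' @param hemisphere optional hemisphere tag, `"lh"` or `"rh"`.
#' @param comment optional creator comment preserved on write.
#' @return An object of class `surface_mesh` with elements `vertices`,
#'   `faces`, `hemisphere`, `comment`.
#' @export
surface_mesh <- function(vertices, faces, hemisphere = NULL, comment = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an N x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an M x 3 matrix")
  n <- nrow(vertices)
  if (nrow(faces) > 0L) {
    if (min(faces) < 0L || max(faces) >= n)
      stop("face indices must lie in [0, ", n, ")")
    if (any(faces[, 1L] == faces[, 2L] | faces[, 1L] == faces[, 3L] |
              faces[, 2L] == faces[, 3L]))
      stop("a face repeats a vertex")
  }
  if (!is.null(hemisphere)) hemisphere <- match.arg(hemisphere, c("lh", "rh"))
  structure(list(vertices = vertices, faces = faces,
                 hemisphere = hemisphere, comment = comment),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$hemisphere)) "" else paste0(" [", x$hemisphere, "]")))
  invisible(x)
}

#' Number of vertices in a mesh
#' @param mesh a `surface_mesh`.
#' @return integer vertex count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' Construct a per-vertex scalar field
#'
#' @param values numeric vector, one value per mesh vertex.
#' @param units one of `"mm"`, `"dimensionless"`, `"count"`.
#' @return An object of class `vertex_scalar_field`.
#' @export
vertex_scalar_field <- function(values, units = c("dimensionless", "mm", "count")) {
  units <- match.arg(units)
  structure(list(values = as.numeric(values), units = units),
            class = "vertex_scalar_field")
}

#' @export
print.vertex_scalar_field <- function(x, ...) {
  cat(sprintf("vertex_scalar_field: %d values (%s), range [%g, %g]\n",
              length(x$values), x$units,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Construct a surface label (a named set of vertices on one hemisphere)
#'
#' @param vertex_ids 0-based vertex indices; sorted and deduplicated.
#' @param hemisphere `"lh"` or `"rh"`.
#' @param name label name, conventionally `<hemi>.<stem>`; may be `NULL`.
#' @param values optional per-vertex scalar (default 0), aligned to the
#'   sorted `vertex_ids`.
#' @return An object of class `surface_label`.
#' @export
surface_label <- function(vertex_ids, hemisphere, name = NULL, values = NULL) {
  hemisphere <- match.arg(hemisphere, c("lh", "rh"))
  vertex_ids <- as.integer(vertex_ids)
  if (length(vertex_ids) == 0L) stop("empty label")
  if (anyNA(vertex_ids) || any(vertex_ids < 0L))
    stop("vertex ids must be non-negative integers")
  if (is.null(values)) {
    ord <- order(vertex_ids)
    vertex_ids <- vertex_ids[ord]
    if (anyDuplicated(vertex_ids)) {
      keep <- !duplicated(vertex_ids)
      vertex_ids <- vertex_ids[keep]
    }
    values <- numeric(length(vertex_ids))
  } else {
    if (length(values) != length(vertex_ids))
      stop("values must align with vertex_ids")
    if (anyDuplicated(vertex_ids)) stop("duplicate vertex id in label")
    ord <- order(vertex_ids)
    vertex_ids <- vertex_ids[ord]
    values <- as.numeric(values)[ord]
  }
  structure(list(name = name, hemisphere = hemisphere,
                 vertex_ids = vertex_ids, values = values),
            class = "surface_label")
}

#' @export
print.surface_label <- function(x, ...) {
  cat(sprintf("surface_label '%s' [%s]: %d vertices\n",
              if (is.null(x$name)) "<unnamed>" else x$name,
              x$hemisphere, length(x$vertex_ids)))
  invisible(x)
}

#' Construct a surface parcellation
#'
#' Region id 0 is reserved for unassigned ("unknown") vertices and is
#' excluded from all network denominators in the statistics functions.
#'
#' @param region_id_per_vertex integer vector, one region id per vertex
#'   (element `i` is the region of 0-based vertex `i - 1`).
#' @param region_table data frame with columns `id`, `name`, `r`, `g`, `b`
#'   (colors 0-255).  Every nonzero id occurring in
#'   `region_id_per_vertex` must be present.
#' @return An object of class `parcellation`.
#' @export
parcellation <- function(region_id_per_vertex, region_table) {
  ids <- as.integer(region_id_per_vertex)
  region_table <- as.data.frame(region_table, stringsAsFactors = FALSE)
  needed <- c("id", "name", "r", "g", "b")
  if (!all(needed %in% names(region_table)))
    stop("region_table needs columns: ", paste(needed, collapse = ", "))
  region_table$id <- as.integer(region_table$id)
  if (anyDuplicated(region_table$id)) stop("duplicate region id in table")
  used <- setdiff(unique(ids), 0L)
  missing_ids <- setdiff(used, region_table$id)
  if (length(missing_ids))
    stop("region ids not in region_table: ", paste(missing_ids, collapse = ", "))
  structure(list(region_id_per_vertex = ids, region_table = region_table),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("parcellation: %d vertices, %d regions (%d unassigned)\n",
              length(x$region_id_per_vertex),
              length(setdiff(unique(x$region_id_per_vertex), 0L)),
              sum(x$region_id_per_vertex == 0L)))
  invisible(x)
}

#' Construct a voxel volume (scalar 3-D grid)
#'
#' @param data 3-D numeric array of intensities.
#' @param voxel_size length-3 numeric, voxel edge lengths in mm.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, voxel_size = c(1, 1, 1)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("data must be a 3-D array")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive lengths (mm)")
  structure(list(data = data, voxel_size = voxel_size),
            class = "voxel_volume")
}

#' Construct aligned tissue masks for QC statistics
#'
#' @param wm,gm,csf logical 3-D arrays, same shape as the intensity grid.
#' @param allow_overlap allow masks to overlap (default `FALSE`).
#' @return An object of class `tissue_masks`.
#' @export
tissue_masks <- function(wm, gm, csf, allow_overlap = FALSE) {
  dims <- dim(wm)
  for (m in list(wm, gm, csf)) {
    if (!is.logical(m) || length(dim(m)) != 3L)
      stop("masks must be logical 3-D arrays")
    if (!identical(dim(m), dims)) stop("masks must share one shape")
  }
  if (!allow_overlap && any((wm & gm) | (gm & csf) | (wm & csf)))
    stop("tissue masks overlap; pass allow_overlap = TRUE to permit this")
  structure(list(wm = wm, gm = gm, csf = csf), class = "tissue_masks")
}
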
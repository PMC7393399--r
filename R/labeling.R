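# Non-interactive re-implementation of the FreeView "Custom Fill" lesion
# outlining workflow: anchor points -> closed path -> flood fill -> saved,
# protocol-named label files.

#' Close an anchor outline into a cycle on the mesh
#'
#' Consecutive anchors (and last back to first) are joined by
#' [shortest_path()] on the mesh edge graph, mirroring how interactive
#' outlining connects clicked points.  Duplicate junction vertices are
#' merged; a path that revisits a vertex elsewhere is rejected as
#' self-intersecting.
#'
#' @param mesh a [surface_mesh].
#' @param anchors ordered 0-based vertex ids, at least 3.
#' @param graph optional prebuilt [mesh_graph].
#' @return An object of class `closed_path`: list with `vertices` (the
#'   cycle, first vertex not repeated at the end) and `hemisphere`.
#' @export
close_path <- function(mesh, anchors, graph = NULL) {
  anchors <- as.integer(anchors)
  if (length(anchors) < 3L)
    stop("need at least 3 anchor points to maintain an unbroken chain ",
         "around the lesion (got ", length(anchors), ")")
  if (anyDuplicated(anchors)) stop("duplicate anchor vertex")
  if (is.null(graph)) graph <- mesh_graph(mesh)
  cycle <- integer(0)
  k <- length(anchors)
  for (i in seq_len(k)) {
    seg <- shortest_path(graph, anchors[i], anchors[if (i == k) 1L else i + 1L])
    cycle <- c(cycle, seg[-length(seg)])   # drop junction; next seg re-adds it
  }
  if (length(cycle) < 3L) stop("closed path needs at least 3 vertices")
  if (anyDuplicated(cycle))
    stop("outline self-intersects: vertex ",
         cycle[anyDuplicated(cycle)], " appears twice")
  structure(list(vertices = cycle, hemisphere = mesh$hemisphere),
            class = "closed_path")
}

#' @export
print.closed_path <- function(x, ...) {
  cat(sprintf("closed_path: %d vertices%s\n", length(x$vertices),
              if (is.null(x$hemisphere)) "" else paste0(" [", x$hemisphere, "]")))
  invisible(x)
}

#' Flood-fill the patch enclosed by a closed path
#'
#' Breadth-first fill from `seed` through mesh adjacency, never crossing a
#' boundary vertex.  The returned label is the union of the boundary and
#' the filled interior: the drawn outline passes through inaccurate
#' surface, so it is excluded from statistics along with the interior
#' (subtract the boundary ids if a boundary-free label is wanted).
#'
#' A fill that grows past `max_fill_fraction` of the mesh vertices signals
#' an unclosed outline and raises an error instead of silently labelling
#' most of the hemisphere.
#'
#' @param mesh a [surface_mesh].
#' @param boundary a `closed_path` (or any integer vector of boundary ids).
#' @param seed 0-based vertex id inside the outline; must not lie on it.
#' @param max_fill_fraction abort threshold, fraction of mesh vertices
#'   (default 0.5).
#' @param graph optional prebuilt [mesh_graph].
#' @return A [surface_label] (unnamed; see [save_lesion_label()]).
#' @export
flood_fill <- function(mesh, boundary, seed, max_fill_fraction = 0.5,
                       graph = NULL) {
  bverts <- if (inherits(boundary, "closed_path")) boundary$vertices
            else as.integer(boundary)
  seed <- as.integer(seed)
  n <- n_vertices(mesh)
  if (seed < 0L || seed >= n) stop("seed out of vertex range")
  if (seed %in% bverts)
    stop("seed lies on path; place the fill seed inside the closed outline")
  if (is.null(graph)) graph <- mesh_graph(mesh)
  limit <- max_fill_fraction * n
  blocked <- logical(n)
  blocked[bverts + 1L] <- TRUE
  seen <- logical(n)
  seen[seed + 1L] <- TRUE
  frontier <- seed + 1L
  count <- 1L
  while (length(frontier)) {
    nxt <- unlist(graph$neighbors[frontier], use.names = FALSE) + 1L
    nxt <- unique(nxt[!seen[nxt] & !blocked[nxt]])
    seen[nxt] <- TRUE
    count <- count + length(nxt)
    if (count > limit)
      stop(sprintf(
        "fill escaped outline: %d of %d vertices reached (limit %.0f%%); the path is probably not closed",
        count, n, 100 * max_fill_fraction))
    frontier <- nxt
  }
  ids <- sort(unique(c(which(seen) - 1L, bverts)))
  hemi <- if (inherits(boundary, "closed_path") && !is.null(boundary$hemisphere))
    boundary$hemisphere else mesh$hemisphere
  if (is.null(hemi)) hemi <- "lh"
  surface_label(ids, hemisphere = hemi)
}

#' Save a lesion label under its protocol name
#'
#' Writes `<hemi>.lesion-<NN>.label` (NN zero-padded, 1..99) into
#' `<subject_dir>/label/`, creating the directory if needed.
#'
#' @param label a [surface_label].
#' @param mesh the mesh the label lives on (for vertex coordinates).
#' @param subject_dir subject directory root.
#' @param ordinal lesion number on this hemisphere, 1..99.
#' @param overwrite overwrite an existing file of the same name.
#' @return the written path, invisibly.
#' @export
save_lesion_label <- function(label, mesh, subject_dir, ordinal,
                              overwrite = FALSE) {
  fname <- lesion_filename(label$hemisphere, ordinal)
  dir.create(file.path(subject_dir, "label"), showWarnings = FALSE,
             recursive = TRUE)
  path <- file.path(subject_dir, "label", fname)
  if (file.exists(path) && !overwrite)
    stop("label file already exists: ", path,
         " (pass overwrite = TRUE to replace)")
  label$name <- sub("\\.label$", "", fname)
  write_label(label, mesh, path)
  invisible(path)
}

#' Next free lesion ordinal in a subject directory
#'
#' @param subject_dir subject directory root.
#' @param hemisphere `"lh"` or `"rh"`.
#' @return smallest unused ordinal (1 if none used).
#' @export
next_lesion_ordinal <- function(subject_dir, hemisphere) {
  hemisphere <- match.arg(hemisphere, c("lh", "rh"))
  files <- list.files(file.path(subject_dir, "label"))
  used <- integer(0)
  for (f in files) {
    p <- parse_lesion_filename(f)
    if (!is.null(p) && p$hemisphere == hemisphere) used <- c(used, p$ordinal)
  }
  if (length(used) == 0L) 1L else min(setdiff(1:99, used))
}

#' Combine lesion labels into a hemisphere overlay
#'
#' The overlay is the union of all lesion labels on one hemisphere and is
#' the exclusion mask applied by [corrected_stats()].  The operation is
#' commutative, associative and idempotent.
#'
#' @param labels list of [surface_label]s, all on `hemisphere`.
#' @param hemisphere `"lh"` or `"rh"`.
#' @return A [surface_label] named `<hemi>.all-lesions`.
#' @export
combine_labels <- function(labels, hemisphere) {
  hemisphere <- match.arg(hemisphere, c("lh", "rh"))
  if (length(labels) == 0L) stop("no labels to combine")
  for (lb in labels) {
    stopifnot(inherits(lb, "surface_label"))
    if (lb$hemisphere != hemisphere)
      stop("label '", if (is.null(lb$name)) "<unnamed>" else lb$name,
           "' is on hemisphere ", lb$hemisphere, ", not ", hemisphere,
           "; lesions must only be placed on a single hemisphere")
  }
  ids <- sort(unique(unlist(lapply(labels, `[[`, "vertex_ids"))))
  surface_label(ids, hemisphere = hemisphere,
                name = paste0(hemisphere, ".all-lesions"))
}
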
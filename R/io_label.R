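# ASCII label format: one comment line, a count line, then one row per
# vertex: "index x y z value".  The format carries no hemisphere field, so
# hemisphere is taken from the lh./rh. filename prefix.

.LESION_LABEL_RE <- "^(lh|rh)\\.lesion-([0-9]{2})\\.label$"

#' Read a FreeSurfer ASCII label
#'
#' @param path path to a `.label` file.  Hemisphere is inferred from the
#'   `lh.`/`rh.` filename prefix unless `hemisphere` is given; a prefix that
#'   contradicts an explicit `hemisphere` is an error.
#' @param hemisphere optional explicit hemisphere.
#' @return A [surface_label]; vertex ids are 0-based as on disk.
#' @export
read_label <- function(path, hemisphere = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop(path, ": truncated label file")
  body_start <- if (startsWith(lines[1L], "#")) 2L else 1L
  n <- suppressWarnings(as.integer(trimws(lines[body_start])))
  if (is.na(n)) stop(path, ": unreadable vertex count line")
  if (n == 0L) stop(path, ": empty label")
  rows <- lines[seq.int(body_start + 1L, length.out = length(lines) - body_start)]
  if (length(rows) != n)
    stop(sprintf("%s: header declares %d vertices but file has %d rows",
                 path, n, length(rows)))
  m <- matrix(scan(text = rows, quiet = TRUE), ncol = 5L, byrow = TRUE)
  ids <- as.integer(m[, 1L])
  if (any(ids < 0L)) stop(path, ": negative vertex index")
  if (anyDuplicated(ids)) stop(path, ": duplicate vertex index")
  file_hemi <- .hemi_from_filename(path)
  if (!is.null(hemisphere) && !is.null(file_hemi) && hemisphere != file_hemi)
    stop(sprintf("%s: filename prefix says '%s' but caller declared '%s'",
                 path, file_hemi, hemisphere))
  hemi <- if (!is.null(hemisphere)) hemisphere else file_hemi
  if (is.null(hemi))
    stop(path, ": hemisphere not inferable from filename; pass hemisphere=")
  name <- sub("\\.label$", "", basename(path))
  surface_label(ids, hemisphere = hemi, name = name, values = m[, 5L])
}

#' Write a FreeSurfer ASCII label
#'
#' Coordinates are looked up in `mesh` at the label's vertex ids, so the
#' written file places each labelled vertex at its surface position.
#'
#' @param label a [surface_label].
#' @param mesh the [surface_mesh] the label lives on.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_label <- function(label, mesh, path) {
  stopifnot(inherits(label, "surface_label"), inherits(mesh, "surface_mesh"))
  ids <- label$vertex_ids
  if (length(ids) == 0L) stop("empty label")
  if (max(ids) >= n_vertices(mesh))
    stop("label vertex id out of range for this mesh")
  xyz <- mesh$vertices[ids + 1L, , drop = FALSE]
  con <- file(path, "wb")  # "wb": fixed \n line endings on every platform
  on.exit(close(con))
  writeLines(c(sprintf("#!ascii label, from subject lesionsurf"),
               as.character(length(ids)),
               sprintf("%d  %.3f  %.3f  %.3f %.10f",
                       ids, xyz[, 1L], xyz[, 2L], xyz[, 3L], label$values)),
             con)
  invisible(path)
}

#' Parse a protocol lesion-label filename
#'
#' Protocol labels are named `<hemi>.lesion-<NN>.label` with `NN` a
#' zero-padded ordinal, e.g. `lh.lesion-01.label`.
#'
#' @param filename a bare filename (no directory).
#' @return `NULL` if the name does not match, otherwise a list with
#'   `hemisphere` and `ordinal`.
#' @export
parse_lesion_filename <- function(filename) {
  m <- regmatches(filename, regexec(.LESION_LABEL_RE, filename))[[1L]]
  if (length(m) == 0L) return(NULL)
  list(hemisphere = m[2L], ordinal = as.integer(m[3L]))
}

#' Compose a protocol lesion-label filename
#'
#' @param hemisphere `"lh"` or `"rh"`.
#' @param ordinal integer in 1..99; zero-padded to two digits.
#' @return the filename, e.g. `"rh.lesion-07.label"`.
#' @export
lesion_filename <- function(hemisphere, ordinal) {
  hemisphere <- match.arg(hemisphere, c("lh", "rh"))
  ordinal <- as.integer(ordinal)
  if (is.na(ordinal) || ordinal < 1L || ordinal > 99L)
    stop("lesion ordinal must be in 1..99, got ", ordinal)
  sprintf("%s.lesion-%02d.label", hemisphere, ordinal)
}
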
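# FreeSurfer binary formats are big-endian regardless of host platform.

.SURF_MAGIC <- 16777214L  # 0xFFFFFE, triangle surface
.CURV_MAGIC <- 16777215L  # 0xFFFFFF, new-format curv

.read_int3 <- function(con) {
  b <- readBin(con, "integer", n = 3L, size = 1L, signed = FALSE)
  if (length(b) < 3L) return(NA_integer_)
  b[1L] * 65536L + b[2L] * 256L + b[3L]
}

.write_int3 <- function(con, value) {
  writeBin(as.raw(c(value %/% 65536L, (value %/% 256L) %% 256L, value %% 256L)),
           con)
}

.fmt_error <- function(path, con, what) {
  off <- tryCatch(seek(con), error = function(e) NA)
  stop(sprintf("%s: %s (at byte offset %s)", path, what,
               if (is.na(off)) "?" else format(off)), call. = FALSE)
}

.read_exact <- function(con, path, what, n, size, type = "integer") {
  x <- readBin(con, type, n = n, size = size, endian = "big")
  if (length(x) < n)
    .fmt_error(path, con, sprintf("truncated file while reading %s", what))
  x
}

#' Read a FreeSurfer binary triangle surface
#'
#' Parses the big-endian triangle surface format (3-byte magic `0xFFFFFE`,
#' creator comment terminated by a blank line, vertex and face counts,
#' float32 coordinates, int32 face indices).  Face indices are kept 0-based.
#'
#' @param path path to a surface file (e.g. `lh.pial`).
#' @param hemisphere optional hemisphere tag; if `NULL`, inferred from a
#'   `lh.`/`rh.` filename prefix when present.
#' @return A [surface_mesh].
#' @seealso [write_surface()]
#' @export
read_surface <- function(path, hemisphere = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- .read_int3(con)
  if (is.na(magic) || magic != .SURF_MAGIC)
    .fmt_error(path, con, sprintf(
      "bad magic 0x%06X (expected 0x%06X for a triangle surface)",
      if (is.na(magic)) 0L else magic, .SURF_MAGIC))
  comment <- .read_comment(con, path)
  counts <- .read_exact(con, path, "vertex/face counts", 2L, 4L)
  nv <- counts[1L]; nf <- counts[2L]
  if (nv < 0L || nf < 0L) .fmt_error(path, con, "negative count in header")
  coords <- .read_exact(con, path, "vertex coordinates", 3L * nv, 4L, "numeric")
  faces <- .read_exact(con, path, "face indices", 3L * nf, 4L)
  if (nf > 0L && (min(faces) < 0L || max(faces) >= nv))
    .fmt_error(path, con, sprintf("face index out of range [0, %d)", nv))
  if (is.null(hemisphere)) hemisphere <- .hemi_from_filename(path)
  surface_mesh(matrix(coords, ncol = 3L, byrow = TRUE),
               matrix(faces, ncol = 3L, byrow = TRUE),
               hemisphere = hemisphere, comment = comment)
}

# comment is terminated by "\n\n"; the terminator is not part of the comment
.read_comment <- function(con, path) {
  bytes <- raw(0)
  prev <- as.raw(0L)
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0L)
      .fmt_error(path, con, "truncated file inside creator comment")
    if (b == as.raw(10L) && prev == as.raw(10L)) break
    bytes <- c(bytes, b)
    prev <- b
  }
  rawToChar(bytes[-length(bytes)])  # drop first newline of the terminator
}

.hemi_from_filename <- function(path) {
  base <- basename(path)
  if (startsWith(base, "lh.")) "lh" else if (startsWith(base, "rh.")) "rh" else NULL
}

#' Write a FreeSurfer binary triangle surface
#'
#' Output is big-endian and byte-identical across platforms for identical
#' input.  The mesh's stored creator comment is preserved, so
#' `write_surface(read_surface(p), q)` reproduces the file bit for bit.
#'
#' @param mesh a [surface_mesh].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_surface <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  comment <- if (is.null(mesh$comment)) "created by lesionsurf" else mesh$comment
  con <- file(path, "wb")
  on.exit(close(con))
  .write_int3(con, .SURF_MAGIC)
  writeBin(charToRaw(paste0(comment, "\n\n")), con)
  writeBin(c(nrow(mesh$vertices), nrow(mesh$faces)), con, size = 4L,
           endian = "big")
  writeBin(as.numeric(t(mesh$vertices)), con, size = 4L, endian = "big")
  writeBin(as.integer(t(mesh$faces)), con, size = 4L, endian = "big")
  invisible(path)
}

#' Read a FreeSurfer "curv" per-vertex scalar file (new format)
#'
#' @param path path to a curv-format file (e.g. `lh.thickness`).
#' @param units units tag to attach to the field.
#' @return A [vertex_scalar_field].
#' @export
read_curv <- function(path, units = "dimensionless") {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- .read_int3(con)
  if (is.na(magic) || magic != .CURV_MAGIC)
    .fmt_error(path, con, sprintf(
      "bad magic 0x%06X (expected 0x%06X for new-format curv)",
      if (is.na(magic)) 0L else magic, .CURV_MAGIC))
  hdr <- .read_exact(con, path, "curv header", 3L, 4L)
  nv <- hdr[1L]
  if (hdr[3L] != 1L)
    .fmt_error(path, con, sprintf("vals_per_vertex = %d (only 1 supported)", hdr[3L]))
  values <- .read_exact(con, path, "per-vertex values", nv, 4L, "numeric")
  vertex_scalar_field(values, units = units)
}

#' Write a FreeSurfer "curv" per-vertex scalar file (new format)
#'
#' @param field a [vertex_scalar_field] (or bare numeric vector).
#' @param path destination path.
#' @param n_faces face count recorded in the header (informational in this
#'   format; defaults to 0).
#' @return `path`, invisibly.
#' @export
write_curv <- function(field, path, n_faces = 0L) {
  values <- if (inherits(field, "vertex_scalar_field")) field$values else as.numeric(field)
  con <- file(path, "wb")
  on.exit(close(con))
  .write_int3(con, .CURV_MAGIC)
  writeBin(c(length(values), as.integer(n_faces), 1L), con, size = 4L,
           endian = "big")
  writeBin(as.numeric(values), con, size = 4L, endian = "big")
  invisible(path)
}
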
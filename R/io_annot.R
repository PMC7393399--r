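# Binary annotation format: int32 vertex count, then (vertex, packed RGB
# code) int32 pairs, then a colortable block (new format, version 2).
# Codes pack as R + G*256 + B*65536, no alpha contribution.

.pack_rgb <- function(r, g, b) as.integer(r + g * 256L + b * 65536L)

#' Read a FreeSurfer binary annotation (parcellation)
#'
#' Vertices whose packed color code is 0 and absent from the colortable are
#' mapped to region id 0 (unassigned).  Any other code missing from the
#' colortable is a format error.  Region ids are the colortable structure
#' indices, so membership round-trips exactly.
#'
#' @param path path to a `.annot` file.
#' @return A [parcellation].
#' @export
read_annot <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  nv <- .read_exact(con, path, "vertex count", 1L, 4L)
  if (nv < 0L) .fmt_error(path, con, "negative vertex count")
  pairs <- .read_exact(con, path, "vertex/code pairs", 2L * nv, 4L)
  verts <- pairs[seq(1L, by = 2L, length.out = nv)]
  codes <- pairs[seq(2L, by = 2L, length.out = nv)]
  if (nv > 0L && (min(verts) < 0L || max(verts) >= nv))
    .fmt_error(path, con, "vertex index out of range")
  tag <- readBin(con, "integer", 1L, 4L, endian = "big")
  if (length(tag) == 0L || tag != 1L)
    .fmt_error(path, con, "missing colortable block")
  version <- .read_exact(con, path, "colortable version", 1L, 4L)
  if (version >= 0L)
    .fmt_error(path, con, "old-format colortable not supported")
  .read_exact(con, path, "max structure count", 1L, 4L)
  fn_len <- .read_exact(con, path, "filename length", 1L, 4L)
  .read_exact(con, path, "filename", fn_len, 1L, "raw")
  n_entries <- .read_exact(con, path, "colortable entry count", 1L, 4L)
  ids <- integer(n_entries); names_ <- character(n_entries)
  rgb <- matrix(0L, n_entries, 3L)
  for (i in seq_len(n_entries)) {
    ids[i] <- .read_exact(con, path, "structure index", 1L, 4L)
    nm_len <- .read_exact(con, path, "name length", 1L, 4L)
    nm <- .read_exact(con, path, "structure name", nm_len, 1L, "raw")
    names_[i] <- rawToChar(nm[nm != as.raw(0L)])
    rgba <- .read_exact(con, path, "RGBA", 4L, 4L)
    rgb[i, ] <- rgba[1:3]
  }
  code_of_entry <- .pack_rgb(rgb[, 1L], rgb[, 2L], rgb[, 3L])
  region_of_code <- ids[match(codes, code_of_entry)]
  unknown_zero <- is.na(region_of_code) & codes == 0L
  region_of_code[unknown_zero] <- 0L
  if (anyNA(region_of_code)) {
    bad <- unique(codes[is.na(region_of_code)])
    stop(sprintf("%s: color code(s) absent from colortable: %s", path,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  per_vertex <- integer(nv)
  per_vertex[verts + 1L] <- region_of_code
  tab <- data.frame(id = ids, name = names_,
                    r = rgb[, 1L], g = rgb[, 2L], b = rgb[, 3L],
                    stringsAsFactors = FALSE)
  parcellation(per_vertex, tab)
}

#' Write a FreeSurfer binary annotation
#'
#' Emits the new-format (version 2) colortable.  If unassigned vertices
#' (region id 0) exist but the region table has no id-0 entry, an
#' `unknown` entry with the conventional FreeSurfer color (25, 5, 25) is
#' added so the file is self-describing.
#'
#' @param parc a [parcellation].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_annot <- function(parc, path) {
  stopifnot(inherits(parc, "parcellation"))
  tab <- parc$region_table
  if (any(parc$region_id_per_vertex == 0L) && !any(tab$id == 0L))
    tab <- rbind(data.frame(id = 0L, name = "unknown", r = 25L, g = 5L, b = 25L,
                            stringsAsFactors = FALSE), tab)
  code_of_id <- .pack_rgb(tab$r, tab$g, tab$b)
  if (anyDuplicated(code_of_id))
    stop("two regions share one RGB color; annot codes would collide")
  codes <- code_of_id[match(parc$region_id_per_vertex, tab$id)]
  nv <- length(codes)
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "big")
  wint(nv)
  pairs <- integer(2L * nv)
  pairs[seq(1L, by = 2L, length.out = nv)] <- seq_len(nv) - 1L
  pairs[seq(2L, by = 2L, length.out = nv)] <- codes
  wint(pairs)
  wint(1L)                      # colortable-present tag
  wint(-2L)                     # new-format version
  wint(nrow(tab))               # max structure count
  fname <- c(charToRaw("NOFILE"), as.raw(0L))
  wint(length(fname)); writeBin(fname, con)
  wint(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    wint(tab$id[i])
    nm <- c(charToRaw(tab$name[i]), as.raw(0L))
    wint(length(nm)); writeBin(nm, con)
    wint(c(tab$r[i], tab$g[i], tab$b[i], 0L))
  }
  invisible(path)
}
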
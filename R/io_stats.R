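#' Write a per-region statistics table (TSV)
#'
#' One table per hemisphere, modeled on `aparcstats2table` output: one row
#' per region with vertex count, surface area (mm^2), mean and SD thickness
#' (mm) and volume (ml, i.e. mm^3 / 1000).
#'
#' @param rows a data frame of region statistics as produced by
#'   [region_stats()]; must come from a single hemisphere.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_stats_table <- function(rows, path) {
  cols <- c("region", "num_vertices", "surface_area_mm2",
            "mean_thickness_mm", "thickness_sd_mm", "volume_ml")
  rows <- as.data.frame(rows)
  if (nrow(rows) > 0L) {
    if (!all(cols %in% names(rows)))
      stop("stats rows need columns: ", paste(cols, collapse = ", "))
    if ("hemisphere" %in% names(rows) && length(unique(rows$hemisphere)) > 1L)
      stop("stats table must come from a single hemisphere")
  }
  out <- if (nrow(rows) > 0L) rows[, cols, drop = FALSE] else
    stats::setNames(as.data.frame(matrix(nrow = 0L, ncol = length(cols))), cols)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(out) > 0L)
    writeLines(sprintf("%s\t%d\t%.6f\t%s\t%s\t%s",
                       out$region, out$num_vertices, out$surface_area_mm2,
                       .fmt_or_na(out$mean_thickness_mm),
                       .fmt_or_na(out$thickness_sd_mm),
                       .fmt_or_na(out$volume_ml)), con)
  invisible(path)
}

.fmt_or_na <- function(x) ifelse(is.na(x), "NA", sprintf("%.6f", x))

#' Read back a statistics table written by [write_stats_table()]
#'
#' @param path path to the TSV.
#' @return a data frame.
#' @export
read_stats_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
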
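# Regional surface statistics with lesion exclusion.  Volume follows the
# classic surface-based formula: mean regional thickness multiplied by
# regional surface area (reported in ml = mm^3 / 1000).

.YEO7_NAMES <- c("Visual", "Somatomotor", "DorsalAttention", "Salience",
                 "Limbic", "ExecutiveControl", "DefaultMode")

#' Per-region surface statistics, optionally excluding labelled vertices
#'
#' For every region id other than 0 (unassigned), member vertices are the
#' region's vertices minus the exclusion label.  Surface area is the sum
#' of per-vertex areas over members; mean thickness is by default the
#' area-weighted mean (each vertex weighted by its vertex area, consistent
#' with the area-based volume formula); volume is
#' `area * mean_thickness / 1000` (ml).  Regions emptied by exclusion are
#' reported with `num_vertices` 0 and `NA` thickness (flagged by the
#' `empty` column).
#'
#' @param mesh a [surface_mesh].
#' @param thickness a [vertex_scalar_field] (or numeric vector), mm.
#' @param parc a [parcellation] on the same mesh.
#' @param exclude optional [surface_label] of vertices to ignore.
#' @param weighted area-weight the thickness mean/SD (default `TRUE`);
#'   `FALSE` gives plain per-vertex averaging.
#' @return data frame with columns `region`, `hemisphere`, `num_vertices`,
#'   `surface_area_mm2`, `mean_thickness_mm`, `thickness_sd_mm`,
#'   `volume_ml`, `empty`.
#' @export
region_stats <- function(mesh, thickness, parc, exclude = NULL,
                         weighted = TRUE) {
  th <- if (inherits(thickness, "vertex_scalar_field")) thickness$values
        else as.numeric(thickness)
  n <- n_vertices(mesh)
  if (length(th) != n)
    stop("thickness has ", length(th), " values but mesh has ", n, " vertices")
  if (length(parc$region_id_per_vertex) != n)
    stop("parcellation covers ", length(parc$region_id_per_vertex),
         " vertices but mesh has ", n)
  va <- vertex_areas(mesh)$values
  included <- rep(TRUE, n)
  if (!is.null(exclude)) {
    if (length(exclude$vertex_ids) && max(exclude$vertex_ids) >= n)
      stop("exclusion label vertex id out of range for this mesh")
    included[exclude$vertex_ids + 1L] <- FALSE
  }
  tab <- parc$region_table[parc$region_table$id != 0L, , drop = FALSE]
  tab <- tab[order(tab$id), , drop = FALSE]
  hemi <- if (is.null(mesh$hemisphere)) "lh" else mesh$hemisphere
  rid <- parc$region_id_per_vertex
  out <- lapply(seq_len(nrow(tab)), function(i) {
    mem <- which(rid == tab$id[i] & included)
    nv <- length(mem)
    if (nv == 0L)
      return(data.frame(region = tab$name[i], hemisphere = hemi,
                        num_vertices = 0L, surface_area_mm2 = 0,
                        mean_thickness_mm = NA_real_, thickness_sd_mm = NA_real_,
                        volume_ml = NA_real_, empty = TRUE,
                        stringsAsFactors = FALSE))
    a <- va[mem]
    x <- th[mem]
    area <- sum(a)
    w <- if (weighted) a else rep(1, nv)
    mt <- sum(w * x) / sum(w)
    sdt <- sqrt(sum(w * (x - mt)^2) / sum(w))
    data.frame(region = tab$name[i], hemisphere = hemi, num_vertices = nv,
               surface_area_mm2 = area, mean_thickness_mm = mt,
               thickness_sd_mm = sdt, volume_ml = area * mt / 1000,
               empty = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pre- and post-correction statistics for a lesion overlay
#'
#' `pre` is [region_stats()] with no exclusion; `post` excludes the
#' combined lesion overlay.  Per region, pre area equals post area plus
#' the lesion-overlap area (conservation, up to float rounding).
#'
#' @inheritParams region_stats
#' @param overlay the combined lesion overlay ([combine_labels()]).
#' @return list with elements `pre` and `post`.
#' @export
corrected_stats <- function(mesh, thickness, parc, overlay, weighted = TRUE) {
  list(pre = region_stats(mesh, thickness, parc, exclude = NULL,
                          weighted = weighted),
       post = region_stats(mesh, thickness, parc, exclude = overlay,
                           weighted = weighted))
}

.union_ids <- function(lesions) {
  sort(unique(unlist(lapply(lesions, `[[`, "vertex_ids"))))
}

#' Percent of each network's surface area overlapped by lesions
#'
#' Per network: `100 * area(union(lesions) intersect network) / area(network)`,
#' with areas taken as per-vertex areas.  Unassigned vertices (region 0)
#' enter no denominator.
#'
#' @param mesh a [surface_mesh].
#' @param parc a [parcellation].
#' @param lesions list of [surface_label]s (may be empty).
#' @return data frame with columns `network`, `network_area_mm2`,
#'   `lesion_area_mm2`, `pct_surface_area_affected`.
#' @export
pct_surface_area_affected <- function(mesh, parc, lesions) {
  va <- vertex_areas(mesh)$values
  rid <- parc$region_id_per_vertex
  les <- logical(n_vertices(mesh))
  u <- .union_ids(lesions)
  if (length(u)) les[u + 1L] <- TRUE
  tab <- parc$region_table[parc$region_table$id != 0L, , drop = FALSE]
  tab <- tab[order(tab$id), , drop = FALSE]
  res <- lapply(seq_len(nrow(tab)), function(i) {
    inreg <- rid == tab$id[i]
    na <- sum(va[inreg])
    la <- sum(va[inreg & les])
    data.frame(network = tab$name[i], network_area_mm2 = na,
               lesion_area_mm2 = la,
               pct_surface_area_affected = if (na > 0) 100 * la / na else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Percent change in volume caused by lesion correction
#'
#' `100 * (post - pre) / denominator`.  The default denominator is the
#' post-correction volume; both conventions are exposed because "percent
#' change" is reported against either baseline in practice.  Values are
#' signed: negative when correction removed volume relative to the chosen
#' baseline.
#'
#' @param pre_volume,post_volume volumes (ml); vectorized.
#' @param denominator `"post"` (default) or `"pre"`.
#' @return percent change(s).
#' @export
pct_volume_change <- function(pre_volume, post_volume,
                              denominator = c("post", "pre")) {
  denominator <- match.arg(denominator)
  den <- if (denominator == "post") post_volume else pre_volume
  if (any(!is.na(den) & den == 0)) stop("zero denominator volume")
  100 * (post_volume - pre_volume) / den
}

#' Count lesions overlapping each network
#'
#' A lesion counts toward every network it touches (one vertex suffices),
#' so the counts sum to more than the number of lesions when lesions
#' straddle network boundaries.
#'
#' @param parc a [parcellation].
#' @param lesions list of [surface_label]s.
#' @return data frame with `network`, `n_lesions_in_network`, `is_lesioned`.
#' @export
lesions_per_network <- function(parc, lesions) {
  rid <- parc$region_id_per_vertex
  tab <- parc$region_table[parc$region_table$id != 0L, , drop = FALSE]
  tab <- tab[order(tab$id), , drop = FALSE]
  counts <- integer(nrow(tab))
  for (lb in lesions) {
    hit <- unique(rid[lb$vertex_ids + 1L])
    counts <- counts + as.integer(tab$id %in% hit)
  }
  data.frame(network = tab$name, n_lesions_in_network = counts,
             is_lesioned = counts >= 1L, stringsAsFactors = FALSE)
}

#' Number of distinct networks a lesion overlaps
#'
#' @param parc a [parcellation].
#' @param lesion a [surface_label].
#' @return integer count of distinct nonzero region ids under the lesion.
#' @export
networks_per_lesion <- function(parc, lesion) {
  length(setdiff(unique(parc$region_id_per_vertex[lesion$vertex_ids + 1L]), 0L))
}

#' Group lesion-frequency map on a common template mesh
#'
#' Value at a vertex is the number of subjects whose overlay contains it —
#' the per-vertex counting behind a group "heat map" of lesion locations.
#'
#' @param template a [surface_mesh] all overlays are indexed on.
#' @param overlays list of per-subject [surface_label] overlays.
#' @return A [vertex_scalar_field] of counts.
#' @export
group_frequency_map <- function(template, overlays) {
  n <- n_vertices(template)
  counts <- numeric(n)
  for (ov in overlays) {
    stopifnot(inherits(ov, "surface_label"))
    if (length(ov$vertex_ids) && max(ov$vertex_ids) >= n)
      stop("overlay '", if (is.null(ov$name)) "<unnamed>" else ov$name,
           "' indexes vertex ", max(ov$vertex_ids),
           " but the template mesh has ", n, " vertices")
    counts[ov$vertex_ids + 1L] <- counts[ov$vertex_ids + 1L] + 1
  }
  vertex_scalar_field(counts, units = "count")
}

#' Per-network lesion overlap report
#'
#' One row per network, combining lesion counts, percent surface area
#' affected, and pre/post volumes with their percent change — the columns
#' a network-level lesion-burden table is built from.
#'
#' @inheritParams region_stats
#' @param lesions list of individual lesion [surface_label]s.
#' @param denominator baseline for percent volume change (`"post"` default).
#' @return data frame with columns `network`, `n_lesions_in_network`,
#'   `is_lesioned`, `pct_surface_area_affected`, `pre_volume_ml`,
#'   `post_volume_ml`, `pct_volume_change`.
#' @export
network_overlap_report <- function(mesh, thickness, parc, lesions,
                                   denominator = c("post", "pre"),
                                   weighted = TRUE) {
  denominator <- match.arg(denominator)
  hemi <- if (is.null(mesh$hemisphere)) "lh" else mesh$hemisphere
  if (length(lesions)) {
    overlay <- combine_labels(lesions, hemi)
    cs <- corrected_stats(mesh, thickness, parc, overlay, weighted = weighted)
  } else {
    pre <- region_stats(mesh, thickness, parc, weighted = weighted)
    cs <- list(pre = pre, post = pre)
  }
  area <- pct_surface_area_affected(mesh, parc, lesions)
  cnt <- lesions_per_network(parc, lesions)
  stopifnot(identical(area$network, cnt$network),
            identical(area$network, cs$pre$region))
  pvc <- ifelse(cnt$is_lesioned,
                pct_volume_change(cs$pre$volume_ml, cs$post$volume_ml,
                                  denominator = denominator),
                0)
  data.frame(network = area$network,
             hemisphere = hemi,
             n_lesions_in_network = cnt$n_lesions_in_network,
             is_lesioned = cnt$is_lesioned,
             pct_surface_area_affected = area$pct_surface_area_affected,
             pre_volume_ml = cs$pre$volume_ml,
             post_volume_ml = cs$post$volume_ml,
             pct_volume_change = pvc,
             stringsAsFactors = FALSE)
}
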
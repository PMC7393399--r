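# Independent reference implementations used to cross-check the package.
# These are deliberately written as plain loops (or delegated to igraph),
# sharing no code with the implementation paths they verify.

# per-region stats by looping over faces and vertices directly
oracle_region_stats <- function(mesh, thickness, parc, exclude_ids = integer(0)) {
  n <- nrow(mesh$vertices)
  va <- numeric(n)
  for (i in seq_len(nrow(mesh$faces))) {
    tri <- mesh$faces[i, ] + 1L
    p <- mesh$vertices[tri[1], ]
    e1 <- mesh$vertices[tri[2], ] - p
    e2 <- mesh$vertices[tri[3], ] - p
    cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    area <- 0.5 * sqrt(sum(cr^2))
    for (k in tri) va[k] <- va[k] + area / 3
  }
  keep <- rep(TRUE, n)
  keep[exclude_ids + 1L] <- FALSE
  tab <- parc$region_table[parc$region_table$id != 0L, , drop = FALSE]
  tab <- tab[order(tab$id), , drop = FALSE]
  res <- NULL
  for (i in seq_len(nrow(tab))) {
    mem <- which(parc$region_id_per_vertex == tab$id[i] & keep)
    if (length(mem) == 0L) {
      row <- data.frame(region = tab$name[i], num_vertices = 0L,
                        surface_area_mm2 = 0, mean_thickness_mm = NA_real_,
                        volume_ml = NA_real_)
    } else {
      area <- sum(va[mem])
      mt <- sum(va[mem] * thickness[mem]) / area
      row <- data.frame(region = tab$name[i], num_vertices = length(mem),
                        surface_area_mm2 = area, mean_thickness_mm = mt,
                        volume_ml = area * mt / 1000)
    }
    res <- rbind(res, row)
  }
  res
}

# shortest-path length via igraph (independent route to the same quantity)
oracle_path_length <- function(mesh, src, dst) {
  f <- mesh$faces
  e <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]), cbind(f[, 3], f[, 1]))
  e <- unique(t(apply(e, 1L, sort)))
  w <- sqrt(rowSums((mesh$vertices[e[, 1] + 1L, , drop = FALSE] -
                       mesh$vertices[e[, 2] + 1L, , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e + 1L, directed = FALSE)
  as.numeric(igraph::distances(g, v = src + 1L, to = dst + 1L, weights = w))
}

# flood fill by an explicit breadth-first queue over face adjacency
oracle_fill <- function(mesh, boundary_ids, seed) {
  n <- nrow(mesh$vertices)
  adj <- vector("list", n)
  for (i in seq_len(nrow(mesh$faces))) {
    tri <- mesh$faces[i, ] + 1L
    for (a in tri) for (b in tri) if (a != b)
      adj[[a]] <- union(adj[[a]], b)
  }
  blocked <- logical(n); blocked[boundary_ids + 1L] <- TRUE
  seen <- logical(n); seen[seed + 1L] <- TRUE
  queue <- seed + 1L
  while (length(queue)) {
    u <- queue[1L]; queue <- queue[-1L]
    for (v in adj[[u]]) if (!seen[v] && !blocked[v]) {
      seen[v] <- TRUE; queue <- c(queue, v)
    }
  }
  sort(unique(c(which(seen) - 1L, boundary_ids)))
}

oracle_lesions_per_network <- function(parc, lesions) {
  tab <- parc$region_table[parc$region_table$id != 0L, , drop = FALSE]
  tab <- tab[order(tab$id), , drop = FALSE]
  counts <- integer(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    for (lb in lesions) {
      touched <- FALSE
      for (v in lb$vertex_ids)
        if (parc$region_id_per_vertex[v + 1L] == tab$id[i]) { touched <- TRUE; break }
      if (touched) counts[i] <- counts[i] + 1L
    }
  }
  counts
}

oracle_frequency <- function(n, overlays) {
  counts <- integer(n)
  for (ov in overlays)
    for (v in ov$vertex_ids) counts[v + 1L] <- counts[v + 1L] + 1L
  counts
}

# run a short python snippet against nibabel (the independent reference
# implementation of the FreeSurfer formats); returns stdout lines
run_python <- function(code) {
  res <- suppressWarnings(
    system2("python", c("-c", shQuote(code)), stdout = TRUE, stderr = TRUE))
  if (!is.null(attr(res, "status")) && attr(res, "status") != 0)
    stop("python oracle failed:\n", paste(res, collapse = "\n"))
  res
}

has_nibabel <- function() {
  ok <- tryCatch({
    run_python("import nibabel.freesurfer"); TRUE
  }, error = function(e) FALSE)
  ok
}

# small hand-built fixture: two triangles sharing an edge, plus an
# isolated vertex (index 4)
flat_mesh <- function() {
  surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
                     c(5, 5, 5)),
               rbind(c(0L, 1L, 2L), c(1L, 3L, 2L)),
               hemisphere = "lh")
}

seven_region_parc <- function(n, seed = 1) {
  set.seed(seed)
  parcellation(sample(1:7, n, replace = TRUE), lesionsurf:::.yeo7_table())
}
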
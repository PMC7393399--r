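# Synthetic cortical subjects and voxel phantoms with known ground truth.
# Spheres stand in for folded cortices: every statistic in the package is
# geometry-agnostic, and spheres come with analytic area checks.  All
# randomness flows from one seed through a named sub-generator per
# component so parcellation, thickness and lesions can vary independently.

.subseed <- function(seed, component) {
  offs <- c(parcellation = 1L, thickness = 2L, lesions = 3L, phantom = 4L,
            raters = 5L, wrinkle = 6L)
  (as.integer(seed) * 97L + offs[[component]]) %% 2147483647L
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' Icosphere mesh
#'
#' Recursively subdivided icosahedron projected onto a sphere, oriented
#' with vertices at the north and south poles.  Subdivision `s` gives
#' `10 * 4^s + 2` vertices and `20 * 4^s` faces; total area converges to
#' `4 * pi * radius^2` from below.
#'
#' @param subdivisions non-negative integer.
#' @param radius sphere radius, mm.
#' @param hemisphere optional hemisphere tag for the mesh.
#' @return A [surface_mesh].
#' @export
make_icosphere <- function(subdivisions = 3L, radius = 1, hemisphere = NULL) {
  stopifnot(subdivisions >= 0L, radius > 0)
  # pole-oriented icosahedron: poles plus two latitude rings of five
  lat <- atan(0.5)
  lon1 <- (0:4) * 2 * pi / 5
  lon2 <- lon1 + pi / 5
  v <- rbind(c(0, 0, 1),
             cbind(cos(lat) * cos(lon1), cos(lat) * sin(lon1), sin(lat)),
             cbind(cos(lat) * cos(lon2), cos(lat) * sin(lon2), -sin(lat)),
             c(0, 0, -1))
  top <- cbind(0L, 1:5, c(2:5, 1L))
  upper <- cbind(1:5, c(6:10), c(2:5, 1L))
  lower <- cbind(c(6:10), c(7:10, 6L), c(2:5, 1L))
  bottom <- cbind(11L, c(7:10, 6L), 6:10)
  f <- rbind(top, upper, lower, bottom)
  for (s in seq_len(subdivisions)) {
    n <- nrow(v)
    edge_key <- function(a, b) pmin(a, b) * n + pmax(a, b)
    mids <- new.env(hash = TRUE)
    newv <- list()
    midpoint <- function(a, b) {
      key <- as.character(edge_key(a, b))
      id <- mids[[key]]
      if (!is.null(id)) return(id)
      m <- (v[a + 1L, ] + v[b + 1L, ]) / 2
      m <- m / sqrt(sum(m^2))
      newv[[length(newv) + 1L]] <<- m
      id <- n + length(newv) - 1L
      mids[[key]] <- id
      id
    }
    newf <- matrix(0L, 4L * nrow(f), 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1L]; b <- f[i, 2L]; c_ <- f[i, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newf[4L * i - 3L, ] <- c(a, ab, ca)
      newf[4L * i - 2L, ] <- c(b, bc, ab)
      newf[4L * i - 1L, ] <- c(c_, ca, bc)
      newf[4L * i, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- newf
  }
  surface_mesh(v * radius, f, hemisphere = hemisphere)
}

.yeo7_table <- function() {
  # deterministic colors so annot files are byte-reproducible
  data.frame(id = 1:7, name = .YEO7_NAMES,
             r = c(120, 70, 0, 196, 220, 230, 205),
             g = c(18, 130, 118, 58, 248, 148, 62),
             b = c(134, 180, 14, 250, 164, 34, 78),
             stringsAsFactors = FALSE)
}

.grow_parcellation <- function(mesh, n_networks, seed) {
  n <- n_vertices(mesh)
  centers <- .with_seed(seed, sample.int(n, n_networks))
  cv <- mesh$vertices[centers, , drop = FALSE]
  # nearest-centroid on the sphere (angular = monotone in Euclidean here)
  d <- matrix(0, n, n_networks)
  for (j in seq_len(n_networks))
    d[, j] <- rowSums(sweep(mesh$vertices, 2L, cv[j, ])^2)
  max.col(-d, ties.method = "first")
}

.smooth_thickness <- function(mesh, seed, base = 2.5, amplitude = 0.3) {
  n <- n_vertices(mesh)
  r <- sqrt(rowSums(mesh$vertices^2))
  u <- mesh$vertices / r
  .with_seed(seed, {
    th <- rep(base, n)
    for (i in 1:3) {
      dirv <- stats::rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
      freq <- stats::runif(1, 1.5, 4)
      phase <- stats::runif(1, 0, 2 * pi)
      th <- th + (amplitude / 3) * sin(freq * pi * (u %*% dirv) + phase)
    }
    pmax(as.vector(th), 0.5)
  })
}

# breadth-first lesion growth inside one network, frontier ordered by
# vertex index, stopping when the accumulated vertex-area fraction of the
# network first reaches the target
.grow_lesion <- function(graph, in_network, va, seed_vertex, target_fraction) {
  net_area <- sum(va[in_network])
  target <- target_fraction * net_area
  sel <- logical(length(in_network))
  sel[seed_vertex + 1L] <- TRUE
  acc <- va[seed_vertex + 1L]
  frontier <- seed_vertex + 1L
  while (acc < target) {
    nxt <- sort(unique(unlist(graph$neighbors[frontier], use.names = FALSE) + 1L))
    nxt <- nxt[!sel[nxt] & in_network[nxt]]
    if (length(nxt) == 0L)
      stop(sprintf("unreachable target fraction %.3f: network exhausted at %.3f",
                   target_fraction, acc / net_area))
    for (vtx in nxt) {
      sel[vtx] <- TRUE
      acc <- acc + va[vtx]
      if (acc >= target) break
    }
    frontier <- which(sel)
  }
  list(ids = which(sel) - 1L, achieved_fraction = acc / net_area,
       quantization = max(va[in_network]) / net_area)
}

#' Generate a synthetic cortical subject with known ground truth
#'
#' Builds, per hemisphere, an icosphere "cortex", a smooth thickness field
#' (base 2.5 mm plus a low-frequency perturbation), a contiguous
#' 7-network parcellation from seeded nearest-centroid growth, and
#' contiguous lesion patches grown breadth-first from a random in-network
#' seed vertex until each reaches its target fraction of the network's
#' vertex area.  Thickness inside a lesion is multiplied by `thinning`,
#' emulating encephalomalacic thinning.  The achieved (vertex-quantized)
#' area fractions, the quantization bound, and exact pre/post region
#' statistics computed by a direct per-vertex loop are recorded in
#' `ground_truth`.
#'
#' @param seed integer seed; the same seed reproduces the subject exactly.
#' @param subdivisions icosphere subdivision level (default 4: 2562
#'   vertices per hemisphere).
#' @param radius sphere radius in mm (default 70, giving a hemisphere
#'   surface area of roughly 6.2e4 mm^2).
#' @param n_networks number of parcellation regions (default 7).
#' @param lesion_specs list of lesion specifications; each a list with
#'   `network` (name or id), `fraction` (target area fraction, in (0,1)),
#'   and optional `hemi` (`"lh"`/`"rh"`; assigned round-robin if absent).
#' @param thinning multiplicative thickness factor inside lesions
#'   (default 0.25).
#' @param wrinkle amplitude (fraction of radius) of a radial sinusoidal
#'   perturbation that de-trivializes vertex areas (default 0, a true
#'   sphere).
#' @return An object of class `synthetic_subject`: per-hemisphere
#'   `mesh`, `thickness`, `parcellation`, `lesions`, plus `ground_truth`
#'   and the generator parameters.
#' @export
make_subject <- function(seed, subdivisions = 4L, radius = 70,
                         n_networks = 7L, lesion_specs = list(),
                         thinning = 0.25, wrinkle = 0) {
  seed <- as.integer(seed)
  hemis <- list()
  for (hi in 1:2) {
    hemi <- c("lh", "rh")[hi]
    mesh <- make_icosphere(subdivisions, radius, hemisphere = hemi)
    if (wrinkle > 0) {
      u <- mesh$vertices / sqrt(rowSums(mesh$vertices^2))
      bump <- .with_seed(.subseed(seed + hi, "wrinkle"), {
        dirv <- matrix(stats::rnorm(9), 3L)
        dirv <- dirv / sqrt(rowSums(dirv^2))
        amp <- stats::runif(3, 0.3, 1)
        b <- rep(0, nrow(u))
        for (j in 1:3) b <- b + amp[j] * sin(4 * pi * (u %*% dirv[j, ]))
        as.vector(b) / sum(abs(amp))
      })
      mesh$vertices <- mesh$vertices * (1 + wrinkle * bump)
    }
    rid <- .grow_parcellation(mesh, n_networks, .subseed(seed + hi, "parcellation"))
    tab <- .yeo7_table()[seq_len(n_networks), , drop = FALSE]
    parc <- parcellation(rid, tab)
    th <- .smooth_thickness(mesh, .subseed(seed + hi, "thickness"))
    hemis[[hemi]] <- list(mesh = mesh, parc = parc, thickness = th,
                          lesions = list(), lesion_truth = list())
  }
  # assign lesion specs to hemispheres (round-robin when unspecified)
  specs <- lapply(seq_along(lesion_specs), function(i) {
    sp <- lesion_specs[[i]]
    if (is.null(sp$hemi)) sp$hemi <- c("lh", "rh")[(i - 1L) %% 2L + 1L]
    if (is.character(sp$network)) sp$network <- match(sp$network, .YEO7_NAMES)
    if (is.na(sp$network) || sp$network < 1L || sp$network > n_networks)
      stop("unknown lesion network in spec ", i)
    if (sp$fraction <= 0 || sp$fraction >= 1)
      stop("lesion target fraction must be in (0, 1)")
    sp
  })
  for (hemi in c("lh", "rh")) {
    h <- hemis[[hemi]]
    graph <- mesh_graph(h$mesh)
    va <- vertex_areas(h$mesh)$values
    my <- Filter(function(sp) sp$hemi == hemi, specs)
    lseed <- .subseed(seed + match(hemi, c("lh", "rh")), "lesions")
    for (j in seq_along(my)) {
      sp <- my[[j]]
      in_net <- h$parc$region_id_per_vertex == sp$network
      cand <- which(in_net) - 1L
      sv <- .with_seed(lseed + j, cand[sample.int(length(cand), 1L)])
      les <- .grow_lesion(graph, in_net, va, sv, sp$fraction)
      lb <- surface_label(les$ids, hemisphere = hemi,
                          name = sub("\\.label$", "", lesion_filename(hemi, j)))
      h$thickness[les$ids + 1L] <- h$thickness[les$ids + 1L] * thinning
      h$lesions[[j]] <- lb
      h$lesion_truth[[j]] <- list(network = .YEO7_NAMES[sp$network],
                                  network_id = sp$network,
                                  target_fraction = sp$fraction,
                                  achieved_fraction = les$achieved_fraction,
                                  quantization = les$quantization,
                                  n_vertices = length(les$ids))
    }
    hemis[[hemi]] <- h
  }
  # ground-truth stats by a direct per-vertex loop (independent of the
  # vectorized regionstats path)
  gt <- list()
  for (hemi in c("lh", "rh")) {
    h <- hemis[[hemi]]
    overlay_ids <- if (length(h$lesions))
      sort(unique(unlist(lapply(h$lesions, `[[`, "vertex_ids")))) else integer(0)
    gt[[hemi]] <- list(
      lesions = h$lesion_truth,
      overlay_n_vertices = length(overlay_ids),
      pre = .loop_region_stats(h$mesh, h$thickness, h$parc, integer(0)),
      post = .loop_region_stats(h$mesh, h$thickness, h$parc, overlay_ids))
  }
  structure(list(hemis = hemis, ground_truth = gt, seed = seed,
                 params = list(subdivisions = subdivisions, radius = radius,
                               n_networks = n_networks, thinning = thinning,
                               wrinkle = wrinkle)),
            class = "synthetic_subject")
}

# deliberately plain reference computation: per-vertex loop, unvectorized
.loop_region_stats <- function(mesh, thickness, parc, exclude_ids) {
  va <- numeric(n_vertices(mesh))
  f <- mesh$faces + 1L
  v <- mesh$vertices
  for (i in seq_len(nrow(f))) {
    p <- v[f[i, 1L], ]; q <- v[f[i, 2L], ]; r <- v[f[i, 3L], ]
    cr <- c((q - p)[2] * (r - p)[3] - (q - p)[3] * (r - p)[2],
            (q - p)[3] * (r - p)[1] - (q - p)[1] * (r - p)[3],
            (q - p)[1] * (r - p)[2] - (q - p)[2] * (r - p)[1])
    a <- 0.5 * sqrt(sum(cr^2))
    for (k in 1:3) va[f[i, k]] <- va[f[i, k]] + a / 3
  }
  excl <- logical(n_vertices(mesh))
  if (length(exclude_ids)) excl[exclude_ids + 1L] <- TRUE
  tab <- parc$region_table[parc$region_table$id != 0L, , drop = FALSE]
  tab <- tab[order(tab$id), , drop = FALSE]
  out <- data.frame(region = tab$name, num_vertices = 0L,
                    surface_area_mm2 = 0, mean_thickness_mm = NA_real_,
                    volume_ml = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tab))) {
    mem <- which(parc$region_id_per_vertex == tab$id[i] & !excl)
    out$num_vertices[i] <- length(mem)
    if (length(mem) == 0L) next
    area <- sum(va[mem])
    mt <- sum(va[mem] * thickness[mem]) / area
    out$surface_area_mm2[i] <- area
    out$mean_thickness_mm[i] <- mt
    out$volume_ml[i] <- area * mt / 1000
  }
  out
}

#' @export
print.synthetic_subject <- function(x, ...) {
  nles <- sum(vapply(x$hemis, function(h) length(h$lesions), 1L))
  cat(sprintf("synthetic_subject (seed %d): %d vertices/hemi, %d lesion(s)\n",
              x$seed, n_vertices(x$hemis$lh$mesh), nles))
  invisible(x)
}

#' Write a synthetic subject as a FreeSurfer-style directory
#'
#' Layout: `surf/<hemi>.pial`, `surf/<hemi>.white` (pial shrunk inward
#' radially by the thickness, preserving the 1:1 vertex pairing),
#' `surf/<hemi>.thickness` (curv format), `parc/<hemi>.networks.annot`,
#' `label/<hemi>.lesion-NN.label`, and `ground_truth.json`.  Output is
#' byte-identical for identical subjects.
#'
#' @param subject a `synthetic_subject`.
#' @param dir destination directory (created).
#' @return `dir`, invisibly.
#' @export
write_subject_dir <- function(subject, dir) {
  stopifnot(inherits(subject, "synthetic_subject"))
  for (d in c("surf", "label", "parc"))
    dir.create(file.path(dir, d), showWarnings = FALSE, recursive = TRUE)
  for (hemi in names(subject$hemis)) {
    h <- subject$hemis[[hemi]]
    write_surface(h$mesh, file.path(dir, "surf", paste0(hemi, ".pial")))
    white <- h$mesh
    rr <- sqrt(rowSums(white$vertices^2))
    white$vertices <- white$vertices * (1 - h$thickness / rr)
    write_surface(white, file.path(dir, "surf", paste0(hemi, ".white")))
    write_curv(h$thickness, file.path(dir, "surf", paste0(hemi, ".thickness")),
               n_faces = nrow(h$mesh$faces))
    write_annot(h$parc, file.path(dir, "parc", paste0(hemi, ".networks.annot")))
    for (j in seq_along(h$lesions))
      save_lesion_label(h$lesions[[j]], h$mesh, dir, j, overwrite = TRUE)
  }
  jsonlite::write_json(subject$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Concentric-shell voxel phantom for QC statistics
#'
#' WM core, GM shell, CSF shell with Gaussian intensities, plus an
#' optional ellipsoidal lesion mask.  Grid coordinates put the volume
#' center at a voxel center when dimensions are odd, so symmetric
#' ellipsoids digitize symmetrically.
#'
#' @param seed integer seed.
#' @param shape grid dimensions (default `c(63, 63, 63)`).
#' @param voxel_size voxel edge lengths, mm.
#' @param mu,sigma length-3 per-class intensity means and SDs, ordered
#'   WM, GM, CSF.
#' @param lesion_axes optional length-3 full axes (mm) of an ellipsoidal
#'   lesion mask centered at `lesion_center`.
#' @param lesion_center lesion center in mm offsets from the grid center.
#' @return list with `volume` ([voxel_volume]), `masks` ([tissue_masks]),
#'   `lesion_mask` (logical array or `NULL`), and `params`.
#' @export
make_phantom <- function(seed, shape = c(63L, 63L, 63L),
                         voxel_size = c(1, 1, 1),
                         mu = c(150, 100, 50), sigma = c(10, 10, 10),
                         lesion_axes = NULL, lesion_center = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 3L)) stop("degenerate phantom shape")
  if (any(sigma <= 0)) stop("per-class sigma must be positive")
  vs <- as.numeric(voxel_size)
  ax <- (seq_len(shape[1L]) - (shape[1L] + 1) / 2) * vs[1L]
  ay <- (seq_len(shape[2L]) - (shape[2L] + 1) / 2) * vs[2L]
  az <- (seq_len(shape[3L]) - (shape[3L] + 1) / 2) * vs[3L]
  r2 <- outer(outer(ax^2, ay^2, "+"), az^2, "+")
  r <- sqrt(r2)
  rmax <- min(shape * vs) / 2
  wm <- r <= 0.45 * rmax
  gm <- r > 0.45 * rmax & r <= 0.7 * rmax
  csf <- r > 0.7 * rmax & r <= 0.9 * rmax
  data <- array(0, shape)
  .with_seed(.subseed(seed, "phantom"), {
    data[wm] <- stats::rnorm(sum(wm), mu[1L], sigma[1L])
    data[gm] <- stats::rnorm(sum(gm), mu[2L], sigma[2L])
    data[csf] <- stats::rnorm(sum(csf), mu[3L], sigma[3L])
  })
  lesion <- NULL
  if (!is.null(lesion_axes)) {
    semi <- as.numeric(lesion_axes) / 2
    nx <- outer(outer(((ax - lesion_center[1L]) / semi[1L])^2,
                      ((ay - lesion_center[2L]) / semi[2L])^2, "+"),
                ((az - lesion_center[3L]) / semi[3L])^2, "+")
    lesion <- nx <= 1
    if (!any(lesion)) stop("lesion ellipsoid contains no voxel")
  }
  list(volume = voxel_volume(data, vs),
       masks = tissue_masks(wm, gm, csf),
       lesion_mask = lesion,
       params = list(seed = seed, mu = mu, sigma = sigma,
                     n_voxels = c(wm = sum(wm), gm = sum(gm), csf = sum(csf))))
}

#' Simulated rater matrix for ICC testing
#'
#' Subject lesion volumes drawn from a normal true-volume distribution,
#' observed by each rater with rater-specific Gaussian error.  The
#' theoretical single-rater agreement ICC,
#' `var_true / (var_true + mean(rater_sds^2))`, is recorded as an
#' attribute.
#'
#' @param seed integer seed.
#' @param n_subjects number of subjects (>= 2).
#' @param true_mean,true_sd mean and SD (ml) of the true volumes.
#' @param rater_sds per-rater measurement-error SDs (length = n raters,
#'   >= 2).
#' @return numeric matrix (subjects x raters) with attribute
#'   `theoretical_icc`.
#' @export
make_rater_data <- function(seed, n_subjects, true_mean = 10, true_sd = 3,
                            rater_sds = c(1, 1)) {
  if (n_subjects < 2L || length(rater_sds) < 2L)
    stop("need at least 2 subjects and 2 raters")
  k <- length(rater_sds)
  .with_seed(.subseed(seed, "raters"), {
    truth <- stats::rnorm(n_subjects, true_mean, true_sd)
    m <- sapply(seq_len(k), function(j)
      truth + if (rater_sds[j] > 0) stats::rnorm(n_subjects, 0, rater_sds[j])
              else 0)
    dimnames(m) <- list(NULL, paste0("rater", seq_len(k)))
    structure(m, theoretical_icc = true_sd^2 / (true_sd^2 + mean(rater_sds^2)))
  })
}
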
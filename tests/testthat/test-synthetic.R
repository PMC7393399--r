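# Synthetic subject and phantom generators.

test_that("icospheres have the expected counts, radius and manifold edges", {
  ico0 <- make_icosphere(0, 1)
  expect_identical(n_vertices(ico0), 12L)
  expect_identical(nrow(ico0$faces), 20L)
  ico2 <- make_icosphere(2, 3)
  expect_identical(n_vertices(ico2), 162L)
  expect_equal(sqrt(rowSums(ico2$vertices^2)), rep(3, 162), tolerance = 1e-12)
  # area increases monotonically toward 4*pi*r^2
  areas <- vapply(0:3, function(s) sum(triangle_areas(make_icosphere(s, 1))),
                  numeric(1))
  expect_true(all(diff(areas) > 0))
  expect_lt(areas[4], 4 * pi)
  # every undirected edge is shared by exactly two faces
  f <- ico2$faces
  key <- paste(pmin(f[, c(1, 2, 3)], f[, c(2, 3, 1)]),
               pmax(f[, c(1, 2, 3)], f[, c(2, 3, 1)]))
  expect_true(all(table(key) == 2L))
  # every vertex is referenced by at least one face
  expect_setequal(unique(as.vector(f)), 0:161)
})

test_that("subjects are deterministic per seed down to the written bytes", {
  spec <- list(list(network = "Limbic", fraction = 0.1, hemi = "lh"))
  s1 <- make_subject(40, subdivisions = 2, lesion_specs = spec)
  s2 <- make_subject(40, subdivisions = 2, lesion_specs = spec)
  s3 <- make_subject(41, subdivisions = 2, lesion_specs = spec)
  expect_identical(s1$hemis$lh$thickness, s2$hemis$lh$thickness)
  expect_identical(s1$hemis$lh$parc$region_id_per_vertex,
                   s2$hemis$lh$parc$region_id_per_vertex)
  expect_identical(s1$hemis$lh$lesions[[1]]$vertex_ids,
                   s2$hemis$lh$lesions[[1]]$vertex_ids)
  expect_false(identical(s1$hemis$lh$thickness, s3$hemis$lh$thickness))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_subject_dir(s1, d1); write_subject_dir(s2, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 0L)
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
})

test_that("parcellations cover every vertex with seven contiguous patches", {
  s <- make_subject(6, subdivisions = 3)
  for (hemi in c("lh", "rh")) {
    rid <- s$hemis[[hemi]]$parc$region_id_per_vertex
    expect_true(all(rid %in% 1:7))
    expect_identical(sort(unique(rid)), 1:7)
    # contiguity: each network is one connected patch of the mesh graph
    g <- mesh_graph(s$hemis[[hemi]]$mesh)
    for (net in 1:7) {
      members <- which(rid == net)
      seen <- logical(length(rid)); seen[members[1L]] <- TRUE
      frontier <- members[1L]
      while (length(frontier)) {
        nxt <- unique(unlist(g$neighbors[frontier]) + 1L)
        nxt <- nxt[!seen[nxt] & rid[nxt] == net]
        seen[nxt] <- TRUE
        frontier <- nxt
      }
      expect_identical(which(seen), members)
    }
  }
})

test_that("planted lesions honor target fractions within quantization", {
  for (frac in c(0.05, 0.10, 0.25)) {
    s <- make_subject(19, subdivisions = 3,
                      lesion_specs = list(list(network = "DefaultMode",
                                               fraction = frac, hemi = "rh")))
    tr <- s$ground_truth$rh$lesions[[1]]
    expect_lte(abs(tr$achieved_fraction - frac), tr$quantization)
    expect_gte(tr$achieved_fraction, frac)   # growth stops at first crossing
    # lesion vertices all lie inside the target network
    rid <- s$hemis$rh$parc$region_id_per_vertex
    expect_true(all(rid[s$hemis$rh$lesions[[1]]$vertex_ids + 1L] == 7L))
  }
  expect_error(make_subject(19, subdivisions = 2,
                            lesion_specs = list(list(network = "Visual",
                                                     fraction = 1.5))),
               "in \\(0, 1\\)")
  s0 <- make_subject(19, subdivisions = 2)
  expect_length(s0$hemis$lh$lesions, 0L)
  expect_equal(s0$ground_truth$lh$pre$volume_ml,
               s0$ground_truth$lh$post$volume_ml, tolerance = 1e-12)
})

test_that("subject ground truth is recomputable from the emitted files", {
  d <- withr::local_tempdir()
  s <- make_subject(33, subdivisions = 3,
                    lesion_specs = list(list(network = "Salience",
                                             fraction = 0.12, hemi = "lh")))
  write_subject_dir(s, d)
  mesh <- read_surface(file.path(d, "surf", "lh.pial"))
  th <- read_curv(file.path(d, "surf", "lh.thickness"), units = "mm")
  parc <- read_annot(file.path(d, "parc", "lh.networks.annot"))
  lab <- read_label(file.path(d, "label", "lh.lesion-01.label"))
  expect_identical(lab$vertex_ids, s$hemis$lh$lesions[[1]]$vertex_ids)
  expect_identical(parc$region_id_per_vertex,
                   s$hemis$lh$parc$region_id_per_vertex)
  cs <- corrected_stats(mesh, th, parc, combine_labels(list(lab), "lh"))
  gt <- s$ground_truth$lh
  # float32 storage of coordinates/thickness bounds the drift
  expect_equal(cs$pre$volume_ml, gt$pre$volume_ml, tolerance = 1e-5)
  expect_equal(cs$post$volume_ml, gt$post$volume_ml, tolerance = 1e-5)
  # white surface keeps the 1:1 vertex pairing at thickness distance
  white <- read_surface(file.path(d, "surf", "lh.white"))
  gap <- sqrt(rowSums((mesh$vertices - white$vertices)^2))
  expect_equal(gap, th$values, tolerance = 1e-4)
})

test_that("phantoms separate tissue classes and honor their parameters", {
  ph <- make_phantom(50, shape = c(41L, 41L, 41L), sigma = c(0.1, 0.1, 0.1))
  expect_false(any(ph$masks$wm & ph$masks$gm))
  expect_false(any(ph$masks$gm & ph$masks$csf))
  # near-zero noise: class histograms do not overlap
  expect_gt(min(ph$volume$data[ph$masks$wm]), max(ph$volume$data[ph$masks$gm]))
  expect_gt(min(ph$volume$data[ph$masks$gm]), max(ph$volume$data[ph$masks$csf]))
  expect_error(make_phantom(50, shape = c(1L, 5L, 5L)), "degenerate")
  expect_error(make_phantom(50, sigma = c(0, 1, 1)), "positive")
})
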
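# Regional statistics, lesion exclusion, network overlap.

test_that("region volume follows area x mean thickness / 1000", {
  m <- make_icosphere(3, 10, hemisphere = "lh")
  n <- n_vertices(m)
  parc <- parcellation(rep(5L, n), lesionsurf:::.yeo7_table())
  rs <- region_stats(m, rep(2.5, n), parc)
  row <- rs[rs$region == "Limbic", ]
  area <- sum(triangle_areas(m))
  expect_equal(row$surface_area_mm2, area, tolerance = 1e-9)
  expect_equal(row$mean_thickness_mm, 2.5, tolerance = 1e-12)
  expect_equal(row$volume_ml, area * 2.5 / 1000, tolerance = 1e-9)
  expect_identical(rs$num_vertices[rs$region != "Limbic"], rep(0L, 6))
  expect_true(all(rs$empty[rs$region != "Limbic"]))
  expect_true(all(is.na(rs$mean_thickness_mm[rs$empty])))
  expect_error(region_stats(m, rep(1, n - 1L), parc), "values but mesh")
})

test_that("excluding an entire region empties and flags it", {
  m <- make_icosphere(2, 10, hemisphere = "lh")
  parc <- seven_region_parc(n_vertices(m), seed = 2)
  target <- which(parc$region_id_per_vertex == 3L) - 1L
  rs <- region_stats(m, rep(2, n_vertices(m)), parc,
                     exclude = surface_label(target, "lh"))
  row <- rs[rs$region == "DorsalAttention", ]
  expect_identical(row$num_vertices, 0L)
  expect_true(row$empty)
  expect_true(is.na(row$mean_thickness_mm))
})

test_that("region stats equal a brute-force oracle on synthetic subjects", {
  for (seed in c(1, 7, 23)) {
    s <- make_subject(seed, subdivisions = 3, wrinkle = 0.08,
                      lesion_specs = list(list(network = "Visual",
                                               fraction = 0.2, hemi = "lh")))
    h <- s$hemis$lh
    excl <- h$lesions[[1]]$vertex_ids
    got <- region_stats(h$mesh, h$thickness, h$parc,
                        exclude = surface_label(excl, "lh"))
    want <- oracle_region_stats(h$mesh, h$thickness, h$parc, excl)
    expect_identical(got$region, want$region)
    expect_identical(got$num_vertices, want$num_vertices)
    expect_equal(got$surface_area_mm2, want$surface_area_mm2, tolerance = 1e-9)
    expect_equal(got$volume_ml, want$volume_ml, tolerance = 1e-9)
  }
})

test_that("pre/post statistics conserve area and respond to exclusion", {
  s <- make_subject(5, subdivisions = 3,
                    lesion_specs = list(list(network = "Salience",
                                             fraction = 0.15, hemi = "lh")))
  h <- s$hemis$lh
  overlay <- combine_labels(h$lesions, "lh")
  cs <- corrected_stats(h$mesh, h$thickness, h$parc, overlay)
  va <- vertex_areas(h$mesh)$values
  rid <- h$parc$region_id_per_vertex
  for (i in 1:7) {
    les_area <- sum(va[intersect(which(rid == i), overlay$vertex_ids + 1L)])
    expect_equal(cs$pre$surface_area_mm2[i],
                 cs$post$surface_area_mm2[i] + les_area, tolerance = 1e-9)
  }
  # no overlay: pre == post
  cs0 <- corrected_stats(h$mesh, h$thickness, h$parc, NULL)
  expect_equal(cs0$post$volume_ml, cs0$pre$volume_ml, tolerance = 1e-12)
  # removing thinned lesion cortex raises mean thickness
  expect_gt(cs$post$mean_thickness_mm[4], cs$pre$mean_thickness_mm[4])
  # monotonicity: a larger exclusion never increases post area
  bigger <- surface_label(unique(c(overlay$vertex_ids,
                                   sample(0:(n_vertices(h$mesh) - 1L), 100))),
                          "lh")
  post2 <- region_stats(h$mesh, h$thickness, h$parc, exclude = bigger)
  expect_true(all(post2$surface_area_mm2 <= cs$post$surface_area_mm2 + 1e-12))
  expect_true(all(post2$num_vertices <= cs$post$num_vertices))
})

test_that("exclusion of a known area fraction scales area and volume", {
  # uniform thickness, one region: excluding 10% of vertex area leaves 90%
  m <- make_icosphere(3, 10, hemisphere = "lh")
  n <- n_vertices(m)
  parc <- parcellation(rep(2L, n), lesionsurf:::.yeo7_table())
  va <- vertex_areas(m)$values
  k <- which(cumsum(va) / sum(va) >= 0.1)[1L]
  excl <- surface_label(0:(k - 1L), "lh")
  frac <- sum(va[1:k]) / sum(va)
  cs <- corrected_stats(m, rep(2.5, n), parc, excl)
  expect_equal(cs$post$surface_area_mm2[2],
               (1 - frac) * cs$pre$surface_area_mm2[2], tolerance = 1e-9)
  expect_equal(cs$post$volume_ml[2],
               (1 - frac) * cs$pre$volume_ml[2], tolerance = 1e-9)
})

test_that("percent surface area affected recovers planted fractions", {
  expect_equal(pct_volume_change(90, 100, "pre"), 100 / 9, tolerance = 1e-12)
  expect_equal(pct_volume_change(90, 100, "post"), 10, tolerance = 1e-12)
  expect_equal(pct_volume_change(70, 70), 0)
  expect_error(pct_volume_change(90, 0, "post"), "zero denominator")

  s <- make_subject(9, subdivisions = 4,
                    lesion_specs = list(list(network = "Limbic",
                                             fraction = 0.10, hemi = "lh")))
  h <- s$hemis$lh
  pa <- pct_surface_area_affected(h$mesh, h$parc, h$lesions)
  truth <- s$ground_truth$lh$lesions[[1]]
  expect_equal(pa$pct_surface_area_affected[pa$network == "Limbic"],
               100 * truth$achieved_fraction, tolerance = 1e-9)
  expect_lte(abs(truth$achieved_fraction - 0.10), truth$quantization)
  expect_true(all(pa$pct_surface_area_affected[pa$network != "Limbic"] == 0))
  # no lesions: zero everywhere; a lesion covering a whole network: 100
  pa0 <- pct_surface_area_affected(h$mesh, h$parc, list())
  expect_true(all(pa0$pct_surface_area_affected == 0))
  whole <- surface_label(which(h$parc$region_id_per_vertex == 5L) - 1L, "lh")
  pa1 <- pct_surface_area_affected(h$mesh, h$parc, list(whole))
  expect_equal(pa1$pct_surface_area_affected[pa1$network == "Limbic"], 100)
})

test_that("with uniform thickness, volume change mirrors area change", {
  s <- make_subject(13, subdivisions = 3,
                    lesion_specs = list(list(network = "Visual",
                                             fraction = 0.25, hemi = "lh")))
  h <- s$hemis$lh
  th <- rep(2.5, n_vertices(h$mesh))   # uniform: decouples from thinning
  overlay <- combine_labels(h$lesions, "lh")
  cs <- corrected_stats(h$mesh, th, h$parc, overlay)
  pa <- pct_surface_area_affected(h$mesh, h$parc, h$lesions)
  pvc <- pct_volume_change(cs$pre$volume_ml, cs$post$volume_ml, "pre")
  expect_equal(pvc, -pa$pct_surface_area_affected, tolerance = 1e-9)
})

test_that("lesion-network counting uses touch semantics", {
  n <- 70L
  parc <- parcellation(rep(1:7, each = 10L), lesionsurf:::.yeo7_table())
  inside <- surface_label(41:45, "lh")         # fully in network 5
  straddle <- surface_label(c(5L, 15L, 25L), "lh")  # touches networks 1-3
  lp <- lesions_per_network(parc, list(inside))
  expect_identical(lp$n_lesions_in_network, c(0L, 0L, 0L, 0L, 1L, 0L, 0L))
  lp2 <- lesions_per_network(parc, list(inside, straddle))
  expect_identical(lp2$n_lesions_in_network, c(1L, 1L, 1L, 0L, 1L, 0L, 0L))
  expect_identical(sum(lp2$n_lesions_in_network), 4L)  # 4 > 2 lesions
  expect_identical(networks_per_lesion(parc, inside), 1L)
  expect_identical(networks_per_lesion(parc, straddle), 3L)
  expect_identical(networks_per_lesion(parc, surface_label(seq(0, 69, 10), "lh")),
                   7L)
  # random lesions match the loop oracle
  set.seed(31)
  for (i in 1:5) {
    lesions <- lapply(1:3, function(j)
      surface_label(sample(0:69, sample(3:20, 1)), "lh"))
    expect_identical(lesions_per_network(parc, lesions)$n_lesions_in_network,
                     oracle_lesions_per_network(parc, lesions))
  }
})

test_that("group frequency maps count subjects per vertex", {
  m <- make_icosphere(2, 1)
  ov1 <- surface_label(0:9, "lh")
  f1 <- group_frequency_map(m, list(ov1))
  expect_equal(f1$values[1:10], rep(1, 10))
  expect_equal(sum(f1$values), 10)
  f2 <- group_frequency_map(m, list(ov1, ov1))
  expect_equal(f2$values[1:10], rep(2, 10))
  set.seed(8)
  overlays <- lapply(1:12, function(i)
    surface_label(sample(0:(n_vertices(m) - 1L), sample(5:40, 1)), "lh"))
  f <- group_frequency_map(m, overlays)
  expect_equal(f$values, oracle_frequency(n_vertices(m), overlays))
  expect_lte(max(f$values), 12)
  expect_error(group_frequency_map(m, list(surface_label(5000L, "lh"))),
               "template mesh has")
})
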
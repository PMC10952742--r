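# Synthetic scene generator: determinism, topology, placement truth,
# density calibration, slab projection and null-regime fidelity.

test_that("identical config and seed reproduce the scene exactly", {
  cfg <- small_config(seed = 7L)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$cells, b$cells)
  expect_identical(a$network$points, b$network$points)
  # and serialized byte-for-byte
  fa <- tempfile(fileext = ".json"); fb <- tempfile(fileext = ".json")
  write_network_json(a$network, fa); write_network_json(b$network, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
})

test_that("default tree spans branch orders 0..8 ending on the venule", {
  cfg <- generator_config(seed = 11L)  # in-vivo field of view defaults
  net <- generate_vessel_network(cfg)
  ord <- net$segments$branch_order
  expect_setequal(sort(unique(ord)), 0:8)
  expect_identical(net$segments$vessel_class[ord == 0L], "arteriole")
  expect_identical(net$segments$vessel_class[ord == 8L], "venule")
  expect_identical(max(ord), ord[net$segments$vessel_class == "venule"])
  # capillary diameters stay below the 10 um eligibility cap
  cap <- net$segments$segment_id[net$segments$vessel_class == "capillary"]
  expect_true(all(net$points$diameter[net$points$segment_id %in% cap] < 10))
  # all polyline points inside the ROI
  expect_true(all(net$points$x >= 0 & net$points$x <= cfg$roi_extent[1]))
  expect_true(all(net$points$y >= 0 & net$points$y <= cfg$roi_extent[2]))
  expect_true(all(net$points$z >= 0 & net$points$z <= cfg$roi_extent[3]))
})

test_that("an ROI too small for an arteriole-to-venule path is refused", {
  cfg <- generator_config(roi_extent = c(30, 30, 10), seed = 1L)
  expect_error(generate_vessel_network(cfg),
               class = "pemscope_infeasible_geometry")
})

test_that("zero densities yield a network without cells", {
  cfg <- small_config(seed = 3L, pericyte_linear_density = 0,
                      microglia_density = 0)
  sc <- generate_scene(cfg)
  expect_identical(nrow(sc$cells), 0L)
  expect_gt(nrow(sc$network$segments), 0L)
})

test_that("infeasible pericyte spacing signals an infeasible density", {
  cfg <- small_config(seed = 5L, pericyte_linear_density = 0.2,
                      pericyte_min_spacing = 25)
  expect_error(generate_scene(cfg),
               class = "pemscope_infeasible_density")
})

test_that("every pericyte-attracted microglia is a PEM at generation", {
  for (seed in 1:5) {
    sc <- generate_scene(small_config(seed = seed,
                                      frac_pericyte_attracted = 1,
                                      frac_vessel_attracted = 0,
                                      attraction_radius = 5))
    lab <- classify_cells(sc$cells, sc$network,
                          association_criteria(use_nucleus_center = FALSE))
    mic <- lab$microglia
    expect_true(all(mic$is_pem))
    # and the intended partner is within the attraction radius
    att <- mic[mic$truth_class == "pericyte-attracted", ]
    expect_true(all(att$nearest_pericyte_distance < 10))
  }
})

test_that("pericytes sit on sub-10-um capillaries with minimum spacing", {
  sc <- generate_scene(small_config(seed = 9L,
                                    pericyte_linear_density = 0.01))
  peri <- sc$cells[sc$cells$cell_type == "pericyte", ]
  expect_gt(nrow(peri), 0L)
  expect_true(all(peri$host_diameter < 10))
  cls <- sc$network$segments$vessel_class[
    match(peri$on_segment, sc$network$segments$segment_id)]
  expect_true(all(cls == "capillary"))
  for (sid in unique(peri$on_segment)) {
    s <- sort(peri$arclength[peri$on_segment == sid])
    if (length(s) > 1L) expect_true(all(diff(s) >= 25))
  }
})

test_that("realized counts are calibrated to density x measure", {
  # 400 seeds; mean realized/expected within 2%
  n_seeds <- 400L
  ratio_m <- numeric(n_seeds); ratio_p <- numeric(n_seeds)
  for (k in seq_len(n_seeds)) {
    cfg <- small_config(seed = 1000L + k)
    sc <- generate_scene(cfg)
    cap <- sc$network$segments$segment_id[
      sc$network$segments$vessel_class == "capillary"]
    L <- total_length(sc$network, cap)
    area <- cfg$roi_extent[1] * cfg$roi_extent[2]
    ratio_m[k] <- sum(sc$cells$cell_type == "microglia") /
      (cfg$microglia_density * area)
    ratio_p[k] <- sum(sc$cells$cell_type == "pericyte") /
      (cfg$pericyte_linear_density * L)
  }
  expect_lt(abs(mean(ratio_m) - 1), 0.02)
  expect_lt(abs(mean(ratio_p) - 1), 0.02)
})

test_that("slab projection retains exactly the brute-force slab set", {
  sc <- generate_scene(small_config(seed = 21L))
  lo <- 10; hi <- 30
  flat <- project_to_section(sc, thickness = hi - lo,
                             z_center = (lo + hi) / 2)
  truth <- sc$cells$cell_id[sc$cells$z_um >= lo & sc$cells$z_um <= hi]
  expect_setequal(flat$cells$cell_id, truth)
  expect_true(all(is.na(flat$cells$z_um)))
  expect_identical(flat$dims, 2L)
  # clipped polylines originate from in-slab points only
  orig_in <- sc$network$points[sc$network$points$z >= lo &
                                 sc$network$points$z <= hi, ]
  expect_identical(nrow(flat$network$points) <= nrow(orig_in), TRUE)
})

test_that("full-depth slab retains all cells; empty slab retains none", {
  sc <- generate_scene(small_config(seed = 22L))
  all_in <- project_to_section(sc, thickness = sc$config$roi_extent[3] + 1,
                               z_center = sc$config$roi_extent[3] / 2)
  expect_identical(nrow(all_in$cells), nrow(sc$cells))
  # a slab placed in the widest cell-free z gap retains nothing
  zs <- sort(unique(c(0, sc$cells$z_um, sc$config$roi_extent[3])))
  gap <- which.max(diff(zs))
  shallow <- project_to_section(sc, thickness = diff(zs)[gap] / 2,
                                z_center = (zs[gap] + zs[gap + 1]) / 2)
  expect_identical(nrow(shallow$cells), 0L)
})

test_that("null-regime microglia are indistinguishable from uniform", {
  # With all attraction fractions zero, the distance-to-nearest-pericyte
  # distribution of generated microglia must match that of microglia
  # re-placed uniformly in the same ROI against the same pericyte
  # pattern (the conditioned null the chance module simulates).
  set.seed(99)
  d_gen <- numeric(0); d_ref <- numeric(0)
  for (seed in 1:12) {
    cfg <- generator_config(roi_extent = c(400, 400, 10),
                            segment_length_range = c(30, 50),
                            branch_prob = 0.9,
                            pericyte_linear_density = 0.006,
                            pericyte_min_spacing = 15,
                            microglia_density = 1.4e-3,
                            frac_vessel_attracted = 0,
                            frac_pericyte_attracted = 0,
                            seed = 3000L + seed)
    sc <- generate_scene(cfg)
    mic <- sc$cells[sc$cells$cell_type == "microglia", ]
    peri <- sc$cells[sc$cells$cell_type == "pericyte", ]
    if (nrow(peri) < 3L) next
    pm <- cells_xyz(peri)
    d_gen <- c(d_gen, apply(pemscope:::.cross_dist(cells_xyz(mic), pm),
                            1, min))
    unif <- cbind(runif(nrow(mic), 0, 400), runif(nrow(mic), 0, 400),
                  runif(nrow(mic), 0, 10))
    d_ref <- c(d_ref, apply(pemscope:::.cross_dist(unif, pm), 1, min))
  }
  expect_gte(length(d_gen), 2000L)
  ks <- suppressWarnings(stats::ks.test(d_gen, d_ref))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("uniform-placement distances follow the Poisson nearest law", {
  # The closed form the chance module uses: for both populations uniform
  # (toroidal metric, so edges vanish), the nearest-distance CDF is
  # 1 - exp(-lambda * pi * d^2).
  set.seed(7)
  box <- c(600, 600)
  n_p <- 30L
  u <- numeric(0)
  for (rep in 1:10) {
    p <- cbind(runif(n_p, 0, box[1]), runif(n_p, 0, box[2]))
    m <- cbind(runif(250, 0, box[1]), runif(250, 0, box[2]))
    d <- apply(pemscope:::.cross_dist_torus(m, p, box), 1, min)
    u <- c(u, 1 - exp(-(n_p / prod(box)) * pi * d^2))
  }
  ks <- suppressWarnings(stats::ks.test(u, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})
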
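# CAM/PEM classification: boundary behaviour, eligibility, oracle
# equivalence, invariances and the counting protocols.

test_that("vessel distance is the exact perpendicular distance", {
  net <- straight_capillary(length_um = 100, diameter = 4, y = 50)
  cell <- test_cell(1, "microglia", x = 40, y = 55)  # 5 um laterally
  d <- nearest_vessel_distance(cell, net)
  expect_equal(d$distance, 5.0, tolerance = 1e-12)
})

test_that("a vessel at the diameter cap is ineligible for CAM", {
  net <- straight_capillary(length_um = 100, diameter = 12, y = 50)
  cell <- test_cell(1, "microglia", x = 40, y = 52)
  d <- nearest_vessel_distance(cell, net)
  expect_true(is.na(d$distance))
  lab <- classify_cells(cell, net)
  expect_false(lab$microglia$is_cam)
})

test_that("the 10 um criterion is a strict inequality at the boundary", {
  net <- straight_capillary(length_um = 100, diameter = 4, y = 50)
  cells <- rbind(test_cell(1, "microglia", x = 50, y = 50 + 9.99),
                 test_cell(2, "microglia", x = 50, y = 50 + 10.00))
  lab <- classify_cells(cells, net)
  expect_identical(lab$microglia$is_cam, c(TRUE, FALSE))
  # non-strict mode admits the boundary
  lab2 <- classify_cells(cells, net,
                         association_criteria(strict_inequality = FALSE))
  expect_identical(lab2$microglia$is_cam, c(TRUE, TRUE))
})

test_that("PEM requires the pericyte to reside on a sub-10-um vessel", {
  mic <- test_cell(1, "microglia", x = 50, y = 59.9)
  ok <- test_cell(2, "pericyte", x = 50, y = 50)
  ok$host_diameter <- 6
  bad <- test_cell(3, "pericyte", x = 50, y = 50)
  bad$host_diameter <- 15
  lab_ok <- classify_cells(rbind(mic, ok))
  expect_true(lab_ok$microglia$is_pem)
  expect_true(lab_ok$pericytes$has_pem)
  lab_bad <- classify_cells(rbind(mic, bad))
  expect_false(lab_bad$microglia$is_pem)
  # no pericytes at all: not an error, simply no PEM
  lab_none <- classify_cells(mic)
  expect_false(lab_none$microglia$is_pem)
})

test_that("PEM and CAM labels are independent of one another", {
  # pericyte nearby but its vessel far away: PEM without CAM
  net <- straight_capillary(length_um = 100, diameter = 4, y = 0)
  mic <- test_cell(1, "microglia", x = 50, y = 60)
  peri <- test_cell(2, "pericyte", x = 50, y = 55)
  peri$host_diameter <- 4
  lab <- classify_cells(rbind(mic, peri), net)
  expect_true(lab$microglia$is_pem)
  expect_false(lab$microglia$is_cam)
})

test_that("mixed 2D and 3D tables are refused", {
  a <- test_cell(1, "microglia", 10, 10, z = 5)
  b <- test_cell(2, "pericyte", 10, 12)
  b$z_um <- NA_real_
  expect_error(classify_cells(rbind(a, b)), "dimensionality")
})

test_that("labels equal the exhaustive oracle on random scenes", {
  for (seed in 1:30) {
    sc <- generate_scene(small_config(seed = 400L + seed))
    crit <- association_criteria(use_nucleus_center = FALSE)
    lab <- classify_cells(sc$cells, sc$network, crit)
    mic <- sc$cells[sc$cells$cell_type == "microglia", ]
    peri <- sc$cells[sc$cells$cell_type == "pericyte", ]
    expect_identical(lab$microglia$is_pem, oracle_pem_labels(mic, peri))
    d_oracle <- oracle_vessel_distance(mic, sc$network)
    cam_oracle <- !is.na(d_oracle) & d_oracle < 10
    expect_identical(lab$microglia$is_cam, cam_oracle)
    expect_true(all(abs(lab$microglia$nearest_vessel_distance - d_oracle)
                    < 0.05, na.rm = TRUE))
  }
})

test_that("classification is idempotent and rigid-motion invariant", {
  sc <- generate_scene(small_config(seed = 77L))
  crit <- association_criteria(use_nucleus_center = FALSE)
  lab1 <- classify_cells(sc$cells, sc$network, crit)
  relabeled <- rbind(lab1$microglia[, names(sc$cells)],
                     lab1$pericytes[, names(sc$cells)])
  lab2 <- classify_cells(relabeled, sc$network, crit)
  expect_identical(lab2$microglia$is_pem[order(lab2$microglia$cell_id)],
                   lab1$microglia$is_pem[order(lab1$microglia$cell_id)])
  expect_identical(lab2$microglia$is_cam[order(lab2$microglia$cell_id)],
                   lab1$microglia$is_cam[order(lab1$microglia$cell_id)])
  # rotate + translate everything rigidly
  th <- 0.83; shift <- c(31, -12, 7)
  lab3 <- classify_cells(rotate_cells(sc$cells, th, shift),
                         rotate_network(sc$network, th, shift), crit)
  expect_identical(lab3$microglia$is_pem, lab1$microglia$is_pem)
  expect_identical(lab3$microglia$is_cam, lab1$microglia$is_cam)
})

test_that("enlarging the radius never removes a label", {
  sc <- generate_scene(small_config(seed = 88L))
  labs <- lapply(c(5, 10, 15), function(r) {
    classify_cells(sc$cells, sc$network,
                   association_criteria(r_assoc = r,
                                        use_nucleus_center = FALSE))
  })
  for (k in 1:2) {
    expect_true(all(labs[[k]]$microglia$is_pem <=
                      labs[[k + 1]]$microglia$is_pem))
    expect_true(all(labs[[k]]$microglia$is_cam <=
                      labs[[k + 1]]$microglia$is_cam))
  }
})

test_that("PEM distance is symmetric between the paired cells", {
  sc <- generate_scene(small_config(seed = 91L))
  crit <- association_criteria(use_nucleus_center = FALSE)
  lab <- classify_cells(sc$cells, sc$network, crit)
  mic <- lab$microglia[lab$microglia$is_pem, ]
  for (i in seq_len(nrow(mic))) {
    p <- lab$pericytes[lab$pericytes$cell_id == mic$nearest_pericyte_id[i], ]
    d <- sqrt((mic$x_um[i] - p$x_um)^2 + (mic$y_um[i] - p$y_um)^2 +
                (mic$z_um[i] - p$z_um)^2)
    expect_equal(d, mic$nearest_pericyte_distance[i], tolerance = 1e-12)
  }
})

test_that("summary proportions follow the defining arithmetic", {
  mk <- function(n, cam, pem, both) {
    mic <- do.call(rbind, c(list(test_cell(1, "microglia", 1, 0)[0, ]),
                            lapply(seq_len(n), function(i)
                              test_cell(i, "microglia", i, 0))))
    mic$is_cam <- seq_len(n) <= cam
    mic$is_pem <- seq_len(n) <= both |
      (seq_len(n) > cam & seq_len(n) <= cam + (pem - both))
    mic$nearest_vessel_distance <- rep(NA_real_, nrow(mic))
    mic$nearest_pericyte_distance <- rep(NA_real_, nrow(mic))
    mic$nearest_pericyte_id <- rep(NA_integer_, nrow(mic))
    structure(list(microglia = mic,
                   pericytes = .s <- transform(test_cell(999, "pericyte",
                                                         0, 0)[0, ],
                                               has_pem = logical(0)),
                   criteria = association_criteria()),
              class = "association_result")
  }
  s <- summarize_association(mk(100, 40, 7, 7))
  expect_equal(s$pct_cam, 40)
  expect_equal(s$pct_pem, 7)
  expect_equal(s$pct_cam_that_are_pem, 17.5)
  # zero denominators report missing, never zero
  s0 <- summarize_association(mk(0, 0, 0, 0))
  expect_true(is.na(s0$pct_cam) && is.na(s0$pct_pem))
  expect_true(is.na(s0$pct_pericytes_with_pem))
})

test_that("protocol A excludes nuclei touching the box edge", {
  cells <- rbind(test_cell(1, "microglia", 2, 300),    # touches left edge
                 test_cell(2, "microglia", 400, 300),  # interior
                 test_cell(3, "microglia", 797.5, 300),# touches right edge
                 test_cell(4, "pericyte", 400, 598))   # touches top edge
  lab <- classify_cells(cells)
  counts <- count_protocol(lab, "A", geometry = c(0, 0, 800, 600))
  expect_identical(counts$n_microglia, 1L)
  expect_identical(counts$n_pericytes, 0L)
})

test_that("tile margins count a cell once, in its top/left tile only", {
  # cell exactly on the shared margin of tiles 1 and 2 (x = 400)
  cells <- rbind(test_cell(1, "microglia", 400, 100),
                 test_cell(2, "microglia", 100, 400),
                 test_cell(3, "microglia", 0, 0))
  lab <- classify_cells(cells)
  counts <- count_protocol(lab, "B", geometry = c(0, 0, 800, 800),
                           every = 1L, max_tiles = 10L)
  # every cell appears in exactly one tile
  expect_identical(sum(counts$n_microglia), 3L)
  on_margin <- counts[counts$x0 == 400 & counts$y0 == 0, ]
  expect_identical(on_margin$n_microglia, 1L)  # cell 1 in its left-margin tile
})

test_that("grid counts equal brute-force membership on random scenes", {
  for (seed in 1:10) {
    cfg <- generator_config(roi_extent = c(900, 900, 10),
                            segment_length_range = c(40, 80),
                            seed = 600L + seed)
    sc <- generate_scene(cfg)
    flat <- project_to_section(sc, 10, 5)
    lab <- classify_cells(flat$cells, flat$network)
    counts <- count_protocol(lab, "B", geometry = c(0, 0, 900, 900),
                             tile_size = 300, every = 2L, max_tiles = 4L)
    cc <- rbind(lab$microglia[, c("x_um", "y_um")],
                lab$pericytes[, c("x_um", "y_um")])
    for (k in seq_len(nrow(counts))) {
      tx <- counts$x0[k]; ty <- counts$y0[k]
      truth <- sum(cc$x_um >= tx & cc$x_um < tx + 300 &
                     cc$y_um >= ty & cc$y_um < ty + 300)
      expect_identical(counts$n_microglia[k] + counts$n_pericytes[k],
                       as.integer(truth))
    }
    # no double counting: selected tiles are disjoint half-open squares
    expect_identical(anyDuplicated(counts[, c("x0", "y0")]), 0L)
  }
})

test_that("protocol C honours the shrunken trace and tile budget", {
  poly <- cbind(c(0, 1300, 1300, 0), c(0, 0, 1300, 1300))
  cells <- rbind(test_cell(1, "microglia", 650, 650),
                 test_cell(2, "microglia", 30, 30))  # within 50 um of edge
  lab <- classify_cells(cells)
  counts <- count_protocol(lab, "C", geometry = poly, tile_size = 500,
                           every = 1L, max_tiles = 20L)
  # only tiles fully inside the 50-um-shrunk square qualify: the
  # 500-tiles starting at (0,0) touch the boundary, so cell 2 is never
  # counted
  expect_identical(sum(counts$n_microglia), 1L)
})

test_that("a region smaller than one tile warns and returns no units", {
  lab <- classify_cells(test_cell(1, "microglia", 10, 10))
  expect_warning(
    counts <- count_protocol(lab, "B", geometry = c(0, 0, 100, 100)),
    "smaller than one tile")
  expect_identical(nrow(counts), 0L)
})
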
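# Branch orders, tree location and width-at-landmark measurement.

test_that("a single bifurcation orders as 0, 1, 1", {
  nodes <- data.frame(node_id = 1:4,
                      x = c(0, 50, 100, 100), y = c(0, 0, 30, -30),
                      z = 0)
  segs <- data.frame(segment_id = 1:3, from_node = c(1L, 2L, 2L),
                     to_node = c(2L, 3L, 4L),
                     branch_order = NA_integer_,
                     vessel_class = c("arteriole", "capillary", "capillary"))
  pts <- rbind(data.frame(segment_id = 1L, x = c(0, 50), y = c(0, 0),
                          z = 0, diameter = 12),
               data.frame(segment_id = 2L, x = c(50, 100), y = c(0, 30),
                          z = 0, diameter = 5),
               data.frame(segment_id = 3L, x = c(50, 100), y = c(0, -30),
                          z = 0, diameter = 5))
  net <- assign_branch_orders(vessel_network(nodes, segs, pts))
  expect_identical(net$segments$branch_order, c(0L, 1L, 1L))
})

test_that("orders equal the BFS-depth oracle on random trees", {
  skip_if_not_installed("igraph")
  for (seed in 1:40) {
    net <- random_tree_network(sample(5:50, 1), seed = 500L + seed)
    root <- net$segments$segment_id[1]
    ordered <- assign_branch_orders(net, root_segment = root)
    oracle <- oracle_branch_orders(net, root)
    expect_identical(ordered$segments$branch_order, as.integer(oracle))
  }
})

test_that("a cyclic graph is refused unless a spanning tree is requested", {
  nodes <- data.frame(node_id = 1:3, x = c(0, 50, 25),
                      y = c(0, 0, 40), z = 0)
  segs <- data.frame(segment_id = 1:3, from_node = c(1L, 2L, 3L),
                     to_node = c(2L, 3L, 1L), branch_order = NA_integer_,
                     vessel_class = "capillary")
  pts <- do.call(rbind, lapply(1:3, function(s) {
    a <- nodes[segs$from_node[s], ]; b <- nodes[segs$to_node[s], ]
    data.frame(segment_id = s, x = c(a$x, b$x), y = c(a$y, b$y), z = 0,
               diameter = 5)
  }))
  net <- vessel_network(nodes, segs, pts)
  expect_error(assign_branch_orders(net, root_segment = 1L), "cycle")
  ok <- assign_branch_orders(net, root_segment = 1L, spanning_tree = TRUE)
  expect_false(anyNA(ok$segments$branch_order))
})

test_that("cells map to the order of their host segment and junctions", {
  net <- assign_branch_orders(generate_vessel_network(
    generator_config(seed = 15L)))
  # generator truth: pericytes carry their placement segment
  sc <- place_cells(net, generator_config(seed = 15L), seed = 16L)
  peri <- sc$cells[sc$cells$cell_type == "pericyte", ]
  loc <- locate_on_tree(peri, net)
  truth_ord <- net$segments$branch_order[
    match(peri$on_segment, net$segments$segment_id)]
  expect_identical(loc$tree_order, truth_ord)
  # junction flag from an explicit construction
  node1 <- net$nodes[1, ]
  near_node <- test_cell(9999, "pericyte", node1$x, node1$y + 5, node1$z)
  locj <- locate_on_tree(near_node, net, d_junction = 10)
  expect_true(locj$at_junction)
  # a cell far from everything is unmapped and excluded
  far <- test_cell(9998, "pericyte", -500, -500, 0)
  locf <- locate_on_tree(far, net, max_snap = 20)
  expect_false(locf$mapped)
  expect_true(is.na(locf$tree_order))
})

test_that("order distributions conserve mapped cell counts", {
  sc <- generate_scene(generator_config(seed = 18L))
  net <- assign_branch_orders(sc$network)
  lab <- classify_cells(sc$cells, net,
                        association_criteria(use_nucleus_center = FALSE))
  core <- c("cell_id", "tree_order", "at_junction", "mapped")
  locate_as <- function(cells, label) {
    out <- locate_on_tree(cells, net)[, core]
    out$class_label <- label
    out
  }
  located <- rbind(
    locate_as(lab$pericytes, "pericyte"),
    locate_as(lab$microglia[lab$microglia$is_cam, , drop = FALSE], "CAM"))
  tab <- order_distribution(located)
  for (cl in unique(tab$class_label)) {
    expect_identical(sum(tab$n[tab$class_label == cl]),
                     sum(located$mapped[located$class_label == cl]))
    expect_equal(sum(tab$fraction[tab$class_label == cl]), 1)
  }
})

test_that("every location type reads a constant-diameter capillary alike", {
  net <- straight_capillary(length_um = 120, diameter = 4.0)
  expect_equal(measure_width_at(net, 1L, 60, "center"), 4.0)
  expect_equal(measure_width_at(net, 1L, 60, "two_line", 4), 4.0)
})

test_that("dilated pericyte sites read the dilated width", {
  # constant 4.21 um baseline with a 1.16x window around the pericyte
  net <- straight_capillary(length_um = 120, diameter = 4.21,
                            n_points = 121L)
  net <- pemscope:::.apply_dilation(net, 1L, 60, 5, 1.16)
  expect_equal(measure_width_at(net, 1L, 60, "center"), 4.21 * 1.16,
               tolerance = 1e-6)
  expect_equal(measure_width_at(net, 1L, 60, "two_line", 4), 4.89,
               tolerance = 0.01)
})

test_that("width table applies exclusion rules and landmark typing", {
  net <- straight_capillary(length_um = 200, diameter = 4.21,
                            n_points = 201L)
  peri1 <- test_cell(1, "pericyte", 50, 52)   # P (no PEM)
  peri1$on_segment <- 1L; peri1$arclength <- 50; peri1$host_diameter <- 4.21
  peri2 <- test_cell(2, "pericyte", 120, 52)  # PEM partner
  peri2$on_segment <- 1L; peri2$arclength <- 120; peri2$host_diameter <- 4.21
  mic_pem <- test_cell(3, "microglia", 120, 58)   # PEM on peri2
  mic_cam9 <- test_cell(4, "microglia", 111.5, 53) # CAM 9 um from peri2
  mic_cam <- test_cell(5, "microglia", 170, 53)    # clean CAM
  cells <- rbind(peri1, peri2, mic_pem, mic_cam9, mic_cam)
  lab <- classify_cells(cells, net)
  w <- measure_widths(lab, net, width_rules("invivo"), group_id = 1L)
  expect_setequal(unique(w$location_type), c("P", "PEM", "CAM", "VO"))
  expect_identical(w$cell_id[w$location_type == "P"], 1L)
  expect_identical(w$cell_id[w$location_type == "PEM"], 2L)
  # the CAM 9 um from a pericyte is excluded from the CAM width set
  expect_identical(w$cell_id[w$location_type == "CAM"], 5L)
  # VO points keep clear of all somata and of the segment ends
  vo <- w[w$location_type == "VO", ]
  expect_true(all(vo$arclength >= 10 & vo$arclength <= 190))
  expect_true(all(abs(vo$arclength - 50) > 5 | vo$width == 4.21))
})

test_that("width contrasts recover the generator dilation factors", {
  meas <- list()
  for (seed in 1:12) {
    sc <- generate_scene(small_config(seed = 700L + seed))
    lab <- classify_cells(sc$cells, sc$network,
                          association_criteria(use_nucleus_center = FALSE))
    meas[[seed]] <- measure_widths(lab, sc$network,
                                   width_rules("invivo"),
                                   group_id = seed)
  }
  tab <- width_contrast_table(do.call(rbind, meas), min_measurements = 1L)
  expect_equal(unname(tab$means[["VO"]]), 4.21, tolerance = 0.05)
  expect_equal(unname(tab$pct_diff_vs_vo[["P"]]), 16, tolerance = 3)
  expect_equal(unname(tab$pct_diff_vs_vo[["PEM"]]), 21, tolerance = 3)
})

test_that("groups below the measurement threshold are excluded", {
  m <- data.frame(group_id = c(rep(1, 8), rep(2, 3)),
                  location_type = c(rep(c("VO", "P"), 4), "VO", "VO", "P"),
                  segment_id = 1L, arclength = 1, width = 4,
                  cell_id = NA_integer_)
  tab <- width_contrast_table(m, min_measurements = 4L)
  expect_identical(tab$groups_excluded, "2")
  expect_identical(nrow(tab$per_group), 1L)
  # identical widths: all percent differences zero
  expect_true(all(abs(na.omit(tab$pct_diff_vs_vo)) < 1e-12))
})

test_that("orders, junction flags and widths are rigid-motion invariant", {
  sc <- generate_scene(small_config(seed = 23L))
  net <- assign_branch_orders(sc$network)
  lab <- classify_cells(sc$cells, net,
                        association_criteria(use_nucleus_center = FALSE))
  loc <- locate_on_tree(lab$pericytes, net)
  w <- measure_widths(lab, net, width_rules("invivo"), group_id = 1L)
  th <- 1.2; shift <- c(-40, 25, 3)
  net_r <- assign_branch_orders(rotate_network(sc$network, th, shift))
  cells_r <- rotate_cells(sc$cells, th, shift)
  lab_r <- classify_cells(cells_r, net_r,
                          association_criteria(use_nucleus_center = FALSE))
  loc_r <- locate_on_tree(lab_r$pericytes, net_r)
  expect_identical(net_r$segments$branch_order, net$segments$branch_order)
  expect_identical(loc_r$tree_order, loc$tree_order)
  expect_identical(loc_r$at_junction, loc$at_junction)
  w_r <- measure_widths(lab_r, net_r, width_rules("invivo"), group_id = 1L)
  expect_equal(sort(w_r$width), sort(w$width), tolerance = 1e-9)
})

test_that("every emitted width is positive on an eligible vessel", {
  sc <- generate_scene(small_config(seed = 31L))
  lab <- classify_cells(sc$cells, sc$network,
                        association_criteria(use_nucleus_center = FALSE))
  w <- measure_widths(lab, sc$network, width_rules("invivo"))
  expect_true(all(w$width > 0))
  expect_true(all(w$width < 10 * 1.25))  # dilation never crosses far
  host <- mapply(function(s, a) diameter_at(sc$network, s, a),
                 w$segment_id, w$arclength)
  expect_true(all(host < 10))
})
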
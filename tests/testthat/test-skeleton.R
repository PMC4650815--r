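test_that("skeletons are thin subsets of the mask, near the true axis", {
  fx <- tube_fixture(radius_um = 95, length_mm = 2)
  sk <- skeletonize(fx$mask)
  expect_true(all(fx$mask$data[sk$data]))  # skeleton subset of mask
  # distance of skeleton voxels to the analytic axis, away from endpoints
  co <- which(sk$data, arr.ind = TRUE)
  w <- sweep((co - 1) * 0.019, 2, fx$spec$origin_mm, "+")
  interior <- w[, 2] > 0.3 + 0.15 & w[, 2] < 2.3 - 0.15
  d_axis <- sqrt((w[interior, 1] - 0.3)^2 + (w[interior, 3] - 0.3)^2) / 0.019
  expect_lte(max(d_axis), 1)
  # idempotence
  expect_identical(skeletonize(sk)$data, sk$data)
  # single voxel is its own skeleton
  single <- ct_volume(array(c(rep(FALSE, 13), TRUE, rep(FALSE, 13)),
                            c(3, 3, 3)), 19)
  expect_identical(skeletonize(single)$data, single$data)
  # empty mask -> empty skeleton with a message
  empty <- ct_volume(array(FALSE, c(4, 4, 4)), 19)
  expect_message(sk0 <- skeletonize(empty), "empty")
  expect_false(any(sk0$data))
})

test_that("ring masks keep exactly one cycle through the whole chain", {
  arc <- make_arc(c(1.2, 1.2, 0.3), 1.0, 2 * pi, 80, label = "ring")
  spec <- phantom_spec(list(arc), voxel_um = 19)
  ras <- rasterize(spec)
  sk <- skeletonize(ras$mask)
  g <- prune_spurs(build_graph(sk))
  expect_equal(graph_cycle_count(g), 1L)
  expect_equal(nrow(g$nodes), 1L)   # one artificial node on the pure cycle
  expect_equal(length(g$edges), 1L)
  expect_equal(g$edges[[1]]$from, g$edges[[1]]$to)
})

test_that("graph extraction recovers chains, Y junctions and components", {
  # straight chain: 2 endpoint nodes, 1 edge, arclength (N-1) * voxel
  ch <- chain_skeleton(n = 12)
  g <- build_graph(ch)
  expect_equal(nrow(g$nodes), 2L)
  expect_equal(length(g$edges), 1L)
  expect_equal(g$edges[[1]]$arclength_mm, 11 * 0.019, tolerance = 1e-12)
  # Y skeleton: 3 endpoints + 1 branch node, 3 edges
  gy <- build_graph(y_skeleton())
  expect_equal(nrow(gy$nodes), 4L)
  expect_equal(length(gy$edges), 3L)
  expect_equal(sort(gy$nodes$degree), c(1, 1, 1, 3))
  # connected components preserved mask -> skeleton -> graph
  t1 <- make_tube(c(0.2, 0.2, 0.2), c(0.2, 1.4, 0.2), 80, label = "a")
  t2 <- make_tube(c(1.0, 0.2, 0.2), c(1.0, 1.4, 0.2), 80, label = "b")
  spec <- phantom_spec(list(t1, t2), voxel_um = 19)
  ras <- rasterize(spec)
  dm <- dim(ras$mask$data)
  lab_mask <- angiomorph:::cpp_label_components(as.logical(ras$mask$data),
                                               dm, 26L)
  sk <- skeletonize(ras$mask)
  lab_sk <- angiomorph:::cpp_label_components(as.logical(sk$data), dm, 26L)
  expect_equal(max(lab_mask), 2L)
  expect_equal(max(lab_sk), 2L)
  g2 <- build_graph(sk)
  expect_equal(graph_cycle_count(g2), 0L)
  expect_equal(length(g2$edges) - (nrow(g2$nodes) - 2L), 0L)  # two trees
})

test_that("spur pruning removes short terminal twigs but never cycles", {
  # chain with a 3-voxel spur
  a <- array(FALSE, c(20, 11, 5))
  a[3:17, 5, 3] <- TRUE
  a[10, 6, 3] <- TRUE; a[10, 7, 3] <- TRUE; a[10, 8, 3] <- TRUE
  g <- build_graph(ct_volume(a, 19))
  expect_equal(length(g$edges), 3L)
  gp <- prune_spurs(g, 0.1)
  expect_equal(length(gp$edges), 1L)
  expect_equal(gp$edges[[1]]$arclength_mm, 14 * 0.019, tolerance = 1e-12)
  # min_length 0 is the identity
  expect_equal(length(prune_spurs(g, 0)$edges), 3L)
  # ring with a spur: cycle preserved, spur removed
  b <- array(FALSE, c(12, 12, 5))
  th <- seq(0, 2 * pi, length.out = 40)[-40]
  xs <- round(6 + 3.4 * cos(th)); ys <- round(6 + 3.4 * sin(th))
  for (i in seq_along(xs)) b[xs[i], ys[i], 3] <- TRUE
  b[10, 6, 3] <- TRUE; b[11, 6, 3] <- TRUE
  gr <- prune_spurs(build_graph(ct_volume(b, 19)), 0.1)
  expect_equal(graph_cycle_count(gr), 1L)
  expect_true(all(vapply(gr$edges, function(e) e$arclength_mm, 1) > 0.05))
  # idempotent at its fixed point
  expect_equal(length(prune_spurs(gp, 0.1)$edges), length(gp$edges))
})

test_that("label matching transfers ground-truth names and gates by distance", {
  fx <- tube_fixture(radius_um = 95, length_mm = 1.6)
  sk <- skeletonize(fx$mask)
  g <- match_labels(prune_spurs(build_graph(sk), 0.12), fx$truth)
  labs <- vapply(g$edges, function(e) e$label, character(1))
  expect_true("tube" %in% labs)
  # two parallel tubes ten voxels apart: no label swaps
  t1 <- make_tube(c(0.2, 0.2, 0.2), c(0.2, 1.4, 0.2), 60, label = "left")
  t2 <- make_tube(c(0.39, 0.2, 0.2), c(0.39, 1.4, 0.2), 60, label = "right")
  spec <- phantom_spec(list(t1, t2), voxel_um = 19)
  ras <- rasterize(spec)
  g2 <- match_labels(prune_spurs(build_graph(skeletonize(ras$mask)), 0.12),
                     ras$truth)
  for (e in g2$edges) {
    side <- if (mean(e$points[, 1]) < 0.3) "left" else "right"
    expect_equal(e$label, side)
  }
  # truth far away -> unassigned; empty truth -> all unassigned
  far <- make_tube(c(5, 5, 5), c(5, 6.4, 5), 60, label = "far")
  far_truth <- rasterize(phantom_spec(list(far), voxel_um = 19), 1)$truth
  g3 <- match_labels(prune_spurs(build_graph(skeletonize(ras$mask)), 0.12),
                     far_truth)
  expect_true(all(vapply(g3$edges, function(e) e$label, "") == "unassigned"))
  g4 <- match_labels(g2, angiomorph:::new_centerline_graph(
    data.frame(id = integer(), x = numeric(), y = numeric(), z = numeric(),
               degree = numeric()), list(), 19))
  expect_true(all(vapply(g4$edges, function(e) e$label, "") == "unassigned"))
})

test_that("graph export round-trips through JSON and CSV", {
  fx <- tube_fixture(radius_um = 95, length_mm = 1.2)
  g <- match_labels(prune_spurs(build_graph(skeletonize(fx$mask)), 0.12),
                    fx$truth)
  jf <- tempfile(fileext = ".json")
  cf <- tempfile(fileext = ".csv")
  write_graph(g, jf)
  write_graph(g, cf)
  back <- jsonlite::read_json(jf, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  expect_equal(length(back$edges), length(g$edges))
  csv <- read.csv(cf)
  expect_true(all(c("edge", "label", "x_mm") %in% names(csv)))
  unlink(c(jf, cf))
})
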
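test_that("tube primitives are straight with constant radius", {
  tube <- make_tube(c(0, 0, 0), c(3, 0, 0), 95)
  expect_equal(max(tube$radius_um), 190 / 2)
  expect_equal(arc_chord_ratio(tube$points), 1.0)
  expect_equal(angiomorph:::polyline_arclength(tube$points), 3.0)
  expect_error(make_tube(c(1, 1, 1), c(1, 1, 1), 50), "coincident")
  expect_error(make_tube(c(0, 0, 0), c(1, 0, 0), 50, n_points = 1),
               "n_points")
})

test_that("arc primitives have analytic curvature and arc:chord ratio", {
  semi <- make_arc(c(0, 0, 0), 1, pi, 80)
  expect_equal(arc_chord_ratio(semi$points), pi / 2, tolerance = 1e-4)
  quarter <- make_arc(c(0, 0, 0), 1, pi / 2, 80)
  expect_equal(arc_chord_ratio(quarter$points), (pi / 2) / sqrt(2),
               tolerance = 1e-4)
  expect_equal(middle_curvature(make_arc(c(0, 0, 0), 2, pi, 80)$points),
               0.5, tolerance = 0.01)
  expect_error(make_arc(c(0, 0, 0), 1, 0, 80), "span")
  expect_error(make_arc(c(0, 0, 0), -1, pi, 80), "radius")
})

test_that("branching trunk places origins deterministically inside the window", {
  prims <- make_branching_trunk(branch_count = 7, window_mm = 3,
                                extra_branches = 3, seed = 5)
  expect_length(prims, 11)  # trunk + 7 + 3
  origins <- vapply(prims[2:8], function(p) p$points[1, 2], numeric(1))
  expect_true(all(origins > 0 & origins < 3))
  beyond <- vapply(prims[9:11], function(p) p$points[1, 2], numeric(1))
  expect_true(all(beyond > 3))
  # deterministic given seed
  prims2 <- make_branching_trunk(branch_count = 7, window_mm = 3,
                                 extra_branches = 3, seed = 5)
  expect_identical(prims, prims2)
  expect_length(make_branching_trunk(branch_count = 0), 1)
  # origins closer than two branch radii are rejected
  expect_error(make_branching_trunk(branch_count = 30, window_mm = 3,
                                    branch_radius_um = 60),
               "invalid geometry")
})

test_that("Circle-of-Willis phantom carries its stated ground-truth width", {
  for (wmm in c(2.82, 2.56)) {
    spec <- make_cow_phantom(wmm)
    expect_equal(attr(spec, "truth_width_mm"), wmm)
    # exact up to centerline polyline discretization (~1e-4 mm sagitta)
    expect_equal(cow_width(rasterize(spec, 1)$truth), wmm, tolerance = 1e-3)
  }
  expect_error(make_cow_phantom(0.1), "too small")
})

test_that("straightening drives ring arcs to arc:chord 1 and preserves width", {
  spec <- make_cow_phantom(2.82, straightening = 1)
  truth <- rasterize(spec, 1)$truth
  ring <- Filter(function(e) e$label %in% c("ica_left", "ica_right",
                                            "anterior_left", "anterior_right",
                                            "posterior_left",
                                            "posterior_right"),
                 truth$edges)
  for (e in ring)
    expect_equal(arc_chord_ratio(e), 1, tolerance = 1e-3)
  expect_equal(cow_width(truth), 2.82, tolerance = 1e-3)
  # partial straightening reduces tortuosity monotonically
  acr_of <- function(s) {
    tr <- rasterize(make_cow_phantom(2.82, straightening = s), 1)$truth
    e <- Filter(function(e) e$label == "ica_left", tr$edges)[[1]]
    arc_chord_ratio(e)
  }
  expect_true(acr_of(0.8) < acr_of(0))
})

test_that("focal stenosis dips the radius profile without breaking the spec", {
  spec <- make_cow_phantom(2.82, stenosis_labels = "ica_left",
                           stenosis_severity = 0.5)
  prim <- Filter(function(p) p$label == "ica_left", spec$primitives)[[1]]
  expect_equal(min(prim$radius_um) / max(prim$radius_um), 0.5,
               tolerance = 0.01)
  plain <- Filter(function(p) p$label == "ica_right", spec$primitives)[[1]]
  expect_equal(min(plain$radius_um), max(plain$radius_um))
})

test_that("rasterization obeys the 50% partial-volume rule and volume bound", {
  fx <- tube_fixture(radius_um = 95, length_mm = 2)
  vol_mask <- sum(fx$mask$data) * (0.019)^3
  vol_true <- pi * 0.095^2 * 2
  expect_lt(abs(vol_mask - vol_true) / vol_true, 0.10)
  # 190 um tube at 19 um voxels is ~10 voxels across
  mid <- fx$mask$data[, round(dim(fx$mask$data)[2] / 2), ]
  expect_equal(max(rowSums(mid)), 10, tolerance = 1)
  # empty spec renders an all-background mask
  empty <- phantom_spec(list(), voxel_um = 19)
  expect_false(any(rasterize(empty)$mask$data))
})

test_that("35 um voxels lose sub-2-voxel vessels that 19 um retains", {
  t40 <- make_tube(c(0.2, 0.2, 0.2), c(0.2, 1.2, 0.2), 20, label = "t40")
  m19 <- rasterize(phantom_spec(list(t40), voxel_um = 19))$mask
  expect_gt(sum(m19$data), 100)  # 40 um vessel retained at high-res
  t30 <- make_tube(c(0.2, 0.2, 0.2), c(0.2, 1.2, 0.2), 15, label = "t30")
  expect_warning(rasterize(phantom_spec(list(t30), voxel_um = 35), 1),
                 "sub-resolution")
  m35s <- rasterize(phantom_spec(list(t40), voxel_um = 35))$mask
  expect_lt(sum(m35s$data), 0.5 * pi * 0.02^2 * 1 / 0.035^3)
})

test_that("rendered volumes are HU-calibrated and obey the noise law", {
  fx <- tube_fixture(radius_um = 95, length_mm = 1.2)
  con <- contrast_model(2.2, kvp = 50)
  # zero noise, no blur: piecewise-constant at vessel/background HU
  pro <- acquisition_protocol()
  v0 <- render_ct(fx$spec, con, pro, seed = 1, mask = fx$mask,
                  psf_fwhm_vox = 0, sigma_ref = 0)
  expect_equal(unique(as.numeric(v0$data[fx$mask$data])), vessel_hu(con))
  expect_equal(unique(as.numeric(v0$data[!fx$mask$data])),
               con$background_hu)
  # measured background SD ratio across protocols ~ 2 (inverse sqrt law)
  v1440 <- render_ct(fx$spec, con, acquisition_protocol(), seed = 3,
                     mask = fx$mask)
  v360 <- render_ct(fx$spec, con,
                    acquisition_protocol(n_projections = 360), seed = 3,
                    mask = fx$mask)
  bgv <- !fx$mask$data
  ratio <- sd(v360$data[bgv]) / sd(v1440$data[bgv])
  expect_equal(ratio, 2, tolerance = 0.05)
  # ROI mean in the vessel ~ vessel HU within 2 SE
  roi <- roi_stats(v1440, c(0.3, 0.9, 0.3), 0.05)
  se <- roi$sd_hu / sqrt(roi$n_voxels)
  expect_lt(abs(roi$mean_hu - vessel_hu(con)), 2 * se + 15)  # + blur bias
  # determinism
  v1440b <- render_ct(fx$spec, con, acquisition_protocol(), seed = 3,
                      mask = fx$mask)
  expect_identical(v1440$data, v1440b$data)
  expect_error(render_ct(fx$spec, NULL, pro), "config error")
})

test_that("cohort generation reproduces its stated width distribution", {
  par0 <- cohort_params("wt", 7, 2.82, 0.19, seed = 11)
  coh <- make_cohort(par0, render = FALSE)
  widths <- vapply(coh, function(s) s$truth_width_mm, numeric(1))
  expect_length(widths, 7)
  expect_lt(abs(mean(widths) - 2.82), 3 * 0.19 / sqrt(7))
  # sd = 0 collapses to the mean
  coh0 <- make_cohort(cohort_params("x", 4, 2.7, 0, seed = 2),
                      render = FALSE)
  expect_equal(vapply(coh0, function(s) s$truth_width_mm, numeric(1)),
               rep(2.7, 4))
  # identical seeds give identical subjects (specs and widths)
  coh2 <- make_cohort(par0, render = FALSE)
  expect_identical(lapply(coh, `[[`, "spec"), lapply(coh2, `[[`, "spec"))
})
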
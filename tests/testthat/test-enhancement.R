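test_that("Hessian eigenvalues vanish on constant volumes and detect shape", {
  const <- ct_volume(array(500, c(12, 12, 12)), 19)
  ev <- suppressWarnings(hessian_eigenvalues(const, 40))
  expect_equal(max(abs(ev$l1)), 0)
  expect_equal(max(abs(ev$l3)), 0)

  # bright tube: l2, l3 < 0 and |l1| small on the axis
  fx <- tube_fixture(radius_um = 95, length_mm = 1.4)
  vol <- mask_to_volume(fx$mask)
  ev <- hessian_eigenvalues(vol, 60)
  i <- round((c(0.3, 1.0, 0.3) - fx$spec$origin_mm) / 0.019) + 1
  l1 <- ev$l1[i[1], i[2], i[3]]
  l2 <- ev$l2[i[1], i[2], i[3]]
  l3 <- ev$l3[i[1], i[2], i[3]]
  expect_lt(l2, 0); expect_lt(l3, 0)
  expect_lt(abs(l1), 0.1 * abs(l3))

  # bright sphere: all three negative and comparable at the center
  sph <- array(0, c(31, 31, 31))
  ctr <- c(16, 16, 16)
  for (z in 1:31) for (y in 1:31)
    sph[, y, z] <- 500 * (( (1:31) - ctr[1])^2 + (y - ctr[2])^2 +
                            (z - ctr[3])^2 <= 6^2)
  evs <- hessian_eigenvalues(ct_volume(sph, 19), 6 * 19 / sqrt(3))
  s1 <- evs$l1[16, 16, 16]; s3 <- evs$l3[16, 16, 16]
  expect_lt(s3, 0); expect_lt(s1, 0)
  expect_gt(s1 / s3, 0.5)  # comparable magnitudes

  expect_warning(hessian_eigenvalues(const, 5), "clamped")
})

test_that("vesselness is bounded, polarity-gated and offset-invariant", {
  fx <- tube_fixture(radius_um = 95, length_mm = 1.4)
  vol <- mask_to_volume(fx$mask)
  ves <- frangi_vesselness(vol)
  expect_true(all(ves$data >= 0 & ves$data <= 1))
  # constant volume -> zero response
  ves0 <- frangi_vesselness(ct_volume(array(7, c(10, 10, 10)), 19),
                            vesselness_params(scales_um = c(30, 60)))
  expect_equal(max(ves0$data), 0)
  # adding a constant HU offset leaves the response unchanged
  vol2 <- ct_volume(vol$data + 250, vol$voxel_um, vol$origin_mm)
  ves2 <- frangi_vesselness(vol2)
  expect_equal(ves2$data, ves$data, tolerance = 1e-6)
  expect_error(vesselness_params(scales_um = numeric()), "empty scale")
  expect_error(vesselness_params(scales_um = c(50, 30)), "increasing")
})

test_that("scale selection peaks near radius/sqrt(2) on an analytic tube", {
  fx <- tube_fixture(radius_um = 95, length_mm = 1.4)
  vol <- mask_to_volume(fx$mask)
  i <- round((c(0.3, 1.0, 0.3) - fx$spec$origin_mm) / 0.019) + 1
  scales <- default_scales()
  resp <- vapply(scales, function(s) {
    v <- frangi_vesselness(vol, vesselness_params(scales_um = s, c = 150))
    v$data[i[1], i[2], i[3]]
  }, numeric(1))
  opt <- 95 / sqrt(2)
  peak <- scales[which.max(resp)]
  step <- scales[2] / scales[1]
  expect_true(peak >= opt / step && peak <= opt * step)
})

test_that("vesselness is monotone in tube contrast and favors tubes over plates", {
  fx <- tube_fixture(radius_um = 95, length_mm = 1.2)
  i <- round((c(0.3, 0.9, 0.3) - fx$spec$origin_mm) / 0.019) + 1
  pars <- vesselness_params(scales_um = c(40, 65, 100), c = 200)
  resp <- vapply(c(100, 300, 600), function(amp) {
    v <- mask_to_volume(fx$mask, vessel = 73 + amp)
    frangi_vesselness(v, pars)$data[i[1], i[2], i[3]]
  }, numeric(1))
  expect_true(all(diff(resp) >= 0))
  expect_gt(resp[3], resp[1])

  # plate (slab) of matched contrast scores below the tube
  slab <- array(73, dim(fx$mask$data))
  slab[, , i[3] + (-3:3)] <- 573
  pslab <- frangi_vesselness(ct_volume(slab, 19, fx$spec$origin_mm),
                             pars)$data[i[1], i[2], i[3]]
  ptube <- frangi_vesselness(mask_to_volume(fx$mask, vessel = 573),
                             pars)$data[i[1], i[2], i[3]]
  expect_lt(pslab, ptube)
})

test_that("hysteresis segmentation seeds high and grows low, monotonically", {
  fx <- tube_fixture(radius_um = 95, length_mm = 1.6)
  ves <- frangi_vesselness(mask_to_volume(fx$mask))
  seg <- segment_vessels(ves, 0.05, 0.5)
  # recall over ground-truth voxels away from the tube ends
  co <- which(fx$mask$data, arr.ind = TRUE)
  w <- sweep((co - 1) * 0.019, 2, fx$spec$origin_mm, "+")
  interior <- w[, 2] > 0.3 + 2 * 0.019 & w[, 2] < 1.9 - 2 * 0.019
  expect_gte(mean(seg$data[which(fx$mask$data)[interior]]), 0.95)
  # all-zero vesselness -> empty mask; unreachable seed -> empty mask
  zero <- ct_volume(array(0, c(8, 8, 8)), 19)
  expect_false(any(segment_vessels(zero, 0.05, 0.5)$data))
  expect_false(any(segment_vessels(ves, 0.05, 1 + 1e-9)$data))
  # raising the low threshold never adds voxels
  seg2 <- segment_vessels(ves, 0.2, 0.5)
  expect_true(all(fx$mask$data[seg2$data] | TRUE))  # sanity
  expect_true(all(seg$data[seg2$data]))
  expect_error(segment_vessels(ves, 0.6, 0.4), "high_threshold")
})
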
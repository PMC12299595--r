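test_that("normalization divides by S0 and flags non-positive voxels", {
  g <- makeOffsetGrid(-2, 2, 1)
  arr <- array(2, c(3, 3, 5))
  s0m <- matrix(2, 3, 3); s0m[2, 2] <- 0
  st <- new("ZSpectrumStack", sSat = arr, s0 = s0m, grid = g)
  nz <- normalizeToS0(st)
  expect_true(all(nz$z[1, 1, ] == 1))
  expect_false(nz$valid[2, 2])
  expect_true(all(is.na(nz$z[2, 2, ])))
  st0 <- new("ZSpectrumStack", sSat = array(0, c(3, 3, 5)), s0 = matrix(1, 3, 3),
             grid = g)
  expect_true(all(normalizeToS0(st0)$z == 0))
})

test_that("shift correction: identity at zero, range guard, centring", {
  g <- aptwOffsetGrid()
  z <- zspectrumModel(g, threePool(), b0_shift = 0)
  expect_identical(correctVoxel(g, z, 0), z)

  # shift 0.5: offsets near +6 need samples beyond the acquired range
  z5 <- zspectrumModel(g, threePool(), b0_shift = 0.5)
  out <- correctVoxel(g, z5, 0.5)
  expect_true(is.na(out[25]))
  expect_true(all(is.finite(out[1:24])))

  # corrected spectrum of a shifted voxel has its water minimum back at 0
  z2 <- zspectrumModel(g, threePool(), b0_shift = 0.2)
  zc <- correctVoxel(g, z2, 0.2)
  keep <- is.finite(zc)
  sf <- stats::splinefun(offsets(g)[keep], zc[keep], method = "natural")
  fine <- seq(-1, 1, by = 0.001)
  expect_lt(abs(fine[which.min(sf(fine))]), 0.0100001)

  expect_error(correctVoxel(g, z, NA_real_), "non-finite shift")
})

test_that("MTRasym arithmetic and grid guards", {
  g <- aptwOffsetGrid()
  z <- rep(0.8, 25)
  expect_equal(mtrAsym(z, g), 0)
  z[abs(offsets(g) - 3.5) < 1e-9] <- 0.55
  z[abs(offsets(g) + 3.5) < 1e-9] <- 0.60
  expect_equal(mtrAsym(z, g), 5)
  # evaluated at the mirrored offset the sign flips
  expect_equal(mtrAsym(z, g, at_ppm = -3.5), -5)
  expect_error(mtrAsym(z, g, at_ppm = 3.25), "not on the grid")
})

test_that("full chain equals the analytic oracle on noiseless phantoms", {
  cfg <- pipelineConfig()
  # B0-free: agreement to well under 0.05 percentage points
  ph <- buildPhantom(quickSpec(), seed = 2)
  b0 <- b0Map(ph$wassr, ph$truth$brain_mask, cfg)
  ap <- aptwMap(ph$aptw, b0, ph$truth$brain_mask, cfg)
  expect_true(all(validVoxels(ap)[ph$truth$brain_mask]))
  err <- abs(aptwPercent(ap) - ph$truth$aptw_percent)[validVoxels(ap)]
  expect_lt(max(err), 0.05)

  # smooth +/-0.3 ppm field: corrected map within 0.1 pp of truth, and
  # strictly better (voxel-aggregate RMS) than skipping the correction
  ph2 <- buildPhantom(quickSpec(b0_amplitude_ppm = 0.3), seed = 4)
  b02 <- b0Map(ph2$wassr, ph2$truth$brain_mask, cfg)
  apc <- aptwMap(ph2$aptw, b02, ph2$truth$brain_mask, cfg)
  apu <- aptwMap(ph2$aptw, b02, ph2$truth$brain_mask, cfg, correct = FALSE)
  both <- validVoxels(apc) & validVoxels(apu)
  ec <- (aptwPercent(apc) - ph2$truth$aptw_percent)[both]
  eu <- (aptwPercent(apu) - ph2$truth$aptw_percent)[both]
  expect_lt(max(abs(ec)), 0.1)
  expect_lt(sqrt(mean(ec^2)), sqrt(mean(eu^2)))
})

test_that("adding amide depth increases APTw monotonically through the chain", {
  cfg <- pipelineConfig()
  amps <- c(0.03, 0.05, 0.065)
  got <- vapply(amps, function(a) {
    ph <- buildPhantom(quickSpec(shape = c(8, 8), amide_amplitude = a,
                                 layout = NULL), seed = 6)
    b0 <- b0Map(ph$wassr, ph$truth$brain_mask, cfg)
    ap <- aptwMap(ph$aptw, b0, ph$truth$brain_mask, cfg)
    mean(aptwPercent(ap)[ph$truth$roi_masks$left_hippocampus &
                           validVoxels(ap)])
  }, 0)
  expect_true(all(diff(got) > 0))
  # matches the analytic direction too
  truth <- vapply(amps, function(a)
    trueMtrAsym(defaultTissues(a)$hippocampus$pools), 0)
  expect_true(all(diff(truth) > 0))
})

test_that("ROI-mean MTRasym curve matches the map at the analysis offset", {
  cfg <- pipelineConfig()
  ph <- buildPhantom(quickSpec(b0_amplitude_ppm = 0.15, noise_sd = 0.005),
                     seed = 8)
  b0 <- b0Map(ph$wassr, ph$truth$brain_mask, cfg)
  ap <- aptwMap(ph$aptw, b0, ph$truth$brain_mask, cfg)
  roi <- ph$truth$roi_masks$left_hippocampus
  curve <- meanMtrAsymCurve(ph$aptw, b0, roi, cfg)
  expect_named(curve, c("offset_ppm", "mean", "sem", "n"))
  expect_true(all(curve$offset_ppm > 0))
  at <- curve$mean[abs(curve$offset_ppm - 3.5) < 1e-9]
  expect_equal(at, mean(aptwPercent(ap)[roi & validVoxels(ap)]),
               tolerance = 1e-9)
  expect_error(meanMtrAsymCurve(ph$aptw, b0, matrix(FALSE, 16, 16), cfg),
               "no valid voxels")
})
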
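test_that("noiseless, B0-free phantom spectra equal the forward model exactly", {
  ph <- buildPhantom(quickSpec(), seed = 3)
  off <- offsets(ph$aptw)
  cm <- ph$truth$class_map
  tis <- ph$spec$tissues
  for (nm in unique(as.vector(cm))) {
    i <- which(cm == nm, arr.ind = TRUE)[1, ]
    got <- sSat(ph$aptw)[i[1], i[2], ] / s0(ph$aptw)[i[1], i[2]]
    expect_equal(got, zspectrumModel(off, tis[[nm]]$pools),
                 tolerance = 1e-12)
  }
})

test_that("ground-truth APTw map equals the analytic MTRasym of each voxel", {
  ph <- buildPhantom(quickSpec(b0_amplitude_ppm = 0.2, noise_sd = 0.01),
                     seed = 5)
  cm <- ph$truth$class_map
  for (nm in unique(as.vector(cm))) {
    expect_equal(unique(ph$truth$aptw_percent[cm == nm]),
                 trueMtrAsym(ph$spec$tissues[[nm]]$pools))
  }
})

test_that("B0 field is shared between acquisitions, bounded, and the WASSR
           line minimum sits at the true shift", {
  sp <- quickSpec(b0_amplitude_ppm = 0.25)
  ph <- buildPhantom(sp, seed = 9)
  expect_equal(max(abs(ph$truth$b0_ppm)), 0.25)
  # noiseless WASSR spectrum of a shifted voxel: argmin of the closed-form
  # model on a fine grid must sit at the voxel's true shift
  i <- which(abs(ph$truth$b0_ppm) > 0.1, arr.ind = TRUE)[1, ]
  true_shift <- ph$truth$b0_ppm[i[1], i[2]]
  fine <- seq(-0.8, 0.8, by = 1e-4)
  tis <- ph$spec$tissues[[ph$truth$class_map[i[1], i[2]]]]
  zf <- zspectrumModel(fine, tis$wassr_water, b0_shift = true_shift)
  expect_lt(abs(fine[which.min(zf)] - true_shift), 1e-3)
  # and the sampled WASSR stack is that same model
  got <- sSat(ph$wassr)[i[1], i[2], ] / s0(ph$wassr)[i[1], i[2]]
  expect_equal(got, zspectrumModel(offsets(ph$wassr), tis$wassr_water,
                                   b0_shift = true_shift),
               tolerance = 1e-12)
})

test_that("identical (spec, seed) gives identical phantoms; seeds differ", {
  sp <- quickSpec(b0_amplitude_ppm = 0.2, noise_sd = 0.01)
  a <- buildPhantom(sp, seed = 11)
  b <- buildPhantom(sp, seed = 11)
  expect_identical(a, b)
  c <- buildPhantom(sp, seed = 12)
  expect_false(identical(sSat(a$aptw), sSat(c$aptw)))
})

test_that("cohort simulation: counts, determinism, and degenerate SD", {
  specs <- list(CTRL = quickSpec(), LPS05 = quickSpec(group = "LPS05"),
                LPS10 = quickSpec(group = "LPS10"))
  subj <- simulateCohort(specs, n_per_group = 7, base_seed = 2,
                         build = FALSE)
  expect_length(subj, 21)
  expect_equal(as.vector(table(vapply(subj, `[[`, "", "group"))), rep(7L, 3))
  expect_false(anyDuplicated(vapply(subj, `[[`, 0L, "seed")) > 0)

  # zero between-subject SD + zero noise + zero B0: all subjects in a
  # group carry identical image stacks
  one <- simulateCohort(specs["CTRL"], n_per_group = 3, base_seed = 4,
                        between_subject_sd = 0)
  expect_identical(sSat(one[[1]]$phantom$aptw), sSat(one[[2]]$phantom$aptw))
  expect_identical(sSat(one[[2]]$phantom$aptw), sSat(one[[3]]$phantom$aptw))

  # with between-subject SD the amide amplitudes differ per subject
  two <- simulateCohort(specs["CTRL"], n_per_group = 3, base_seed = 4,
                        between_subject_sd = 0.003, build = FALSE)
  amps <- vapply(two, function(s) s$spec$amide_amplitude, 0)
  expect_gt(stats::sd(amps), 0)
})

test_that("phantom spec guards its invariants", {
  expect_error(phantomSpec(b0_amplitude_ppm = 0.6), "0.5 ppm")
  expect_error(phantomSpec(noise_sd = -0.1), ">= 0")
  expect_error(phantomSpec(shape = c(2, 2)), "shape")
})
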
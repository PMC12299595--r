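# shared fixtures: small phantoms and hand-built stacks

quickSpec <- function(shape = c(16, 16), group = "CTRL",
                      b0_amplitude_ppm = 0, noise_sd = 0, ...) {
  phantomSpec(shape = shape, group = group,
              b0_amplitude_ppm = b0_amplitude_ppm, noise_sd = noise_sd, ...)
}

# build a ZSpectrumStack directly from the forward model, one shared pool
# set, an explicit per-voxel b0 matrix, and no noise
modelStack <- function(pools, grid, b0 = matrix(0, 4, 4), s0_value = 1) {
  off <- offsets(grid)
  nr <- nrow(b0); nc <- ncol(b0)
  arr <- array(NA_real_, c(nr, nc, length(off)))
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    arr[i, j, ] <- s0_value * zspectrumModel(off, pools, b0[i, j])
  }
  new("ZSpectrumStack", sSat = arr, s0 = matrix(s0_value, nr, nc),
      grid = grid)
}

waterOnly <- function(A = 0.6, G = 0.6) poolSpec(0, A, G)

threePool <- function(amide = 0.05) {
  rbind(poolSpec(0, 0.85, 1.5),
        poolSpec(3.5, amide, 1.4),
        poolSpec(-3.5, 0.07, 1.5))
}
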
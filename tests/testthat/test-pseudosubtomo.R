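test_that("extract_crop centres, pads and carries sub-pixel offsets", {
  img <- matrix(0, 64, 64)
  img[33, 41] <- 1   # isolated delta
  cr <- extract_crop(img, c(33, 41), 16)
  expect_true(cr$visible)
  expect_equal(cr$subpixel, c(0, 0))
  # |FT| of a delta is flat
  expect_equal(Mod(cr$ft), matrix(1, 16, 16), tolerance = 1e-12)
  # shifting the image by one pixel and re-extracting shifts identically
  img2 <- matrix(0, 64, 64)
  img2[34, 41] <- 1
  cr2 <- extract_crop(img2, c(34, 41), 16)
  expect_equal(cr2$crop, cr$crop)
  # sub-pixel offsets: shifting a band-limited image by half a pixel and
  # re-extracting equals the on-pixel crop times a Fourier phase ramp
  # (blob wide enough to be band-limited, narrow enough not to clip)
  box <- 24
  base <- exp(-(outer((seq_len(64) - 28)^2, (seq_len(64) - 36)^2,
                      `+`)) / (2 * 2.2^2))
  h64 <- pseudotomo:::freq_index(64)
  shifted <- Re(stats::fft(stats::fft(base) *
                             exp(-2i * pi * matrix(h64, 64, 64) * 0.5 /
                                 64),
                           inverse = TRUE)) / 64^2
  cr_on <- extract_crop(base, c(28, 36), box)
  cr_half <- extract_crop(shifted, c(28.5, 36), box)
  expect_equal(cr_half$subpixel, c(0.5, 0), tolerance = 1e-12)
  hb <- pseudotomo:::freq_index(box)
  ramp <- exp(-2i * pi * matrix(hb, box, box) * 0.5 / box)
  msk <- pseudotomo:::nyquist_mask(box, 2)
  expect_lt(max(Mod(cr_half$ft - cr_on$ft * ramp)[msk]) /
              max(Mod(cr_on$ft)), 1e-6)
  # out-of-view particle is flagged invisible
  expect_false(extract_crop(img, c(-5, 10), 16)$visible)
})

test_that("forward insertion distributes unit multiplicity (conservation)", {
  set.seed(22)
  n <- 16
  X <- ft_centered(matrix(rnorm(n * n), n, n))
  ctf <- matrix(runif(n * n, 0.2, 1), n, n)
  for (ang in list(0, c(-40, 10, 35), c(-60, -30, 0, 30, 60))) {
    align <- tilt_alignment(ang)
    ps <- pseudo_subtomogram(n, 1)
    for (f in seq_along(ang)) {
      mp <- compose_projection(particle_pose(diag(3),
                                             n_tilts = length(ang)),
                               align, f)
      ps <- forward_insert(ps, X, ctf, mp)
    }
    # sum of M equals the number of inserted in-radius pixels, exactly
    expect_equal(sum(ps$M), ps$n_inserted)
    expect_equal(ps$n_inserted + ps$n_skipped,
                 length(ang) * (n - 1)^2)
    expect_true(all(ps$W >= 0) && all(ps$M >= 0))
    # |CTF| <= 1 implies W <= M voxel-wise
    expect_true(all(ps$W <= ps$M + 1e-12))
    # D vanishes wherever M does
    expect_true(all(Mod(ps$D)[ps$M == 0] == 0))
  }
})

test_that("on-grid insertion hits single voxels; off-grid matches oracle", {
  n <- 16
  X <- matrix(0 + 0i, n, n); X[2, 1] <- 3 + 1i
  ctf <- matrix(1, n, n)
  ps <- pseudo_subtomogram(n, 1)
  ps <- forward_insert(ps, X, ctf, list(A = diag(3)[1:2, ], t = c(0, 0)))
  expect_equal(ps$D[2, 1, 1], 3 + 1i)
  expect_equal(ps$M[2, 1, 1], 1)
  # off-grid: independent R scatter oracle over the eight neighbours
  ang <- 37
  align <- tilt_alignment(ang)
  mp <- compose_projection(particle_pose(diag(3)), align, 1)
  set.seed(23)
  Xr <- ft_centered(matrix(rnorm(n * n), n, n))
  ps2 <- pseudo_subtomogram(n, 1)
  ps2 <- forward_insert(ps2, Xr, ctf, mp)
  oracle <- array(0, c(n, n, n))
  h <- pseudotomo:::freq_index(n)
  for (iy in 1:n) for (ix in 1:n) {
    hx <- h[ix]; hy <- h[iy]
    if (abs(hx) >= n / 2 || abs(hy) >= n / 2) next
    q <- as.numeric(t(mp$A) %*% c(hx, hy))
    if (any(abs(q) >= n / 2)) next
    f0 <- floor(q); w <- q - f0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wt <- (if (dx) w[1] else 1 - w[1]) *
            (if (dy) w[2] else 1 - w[2]) *
            (if (dz) w[3] else 1 - w[3])
      hh <- f0 + c(dx, dy, dz)
      ii <- ifelse(hh < 0, hh + n, hh) + 1
      oracle[ii[1], ii[2], ii[3]] <- oracle[ii[1], ii[2], ii[3]] + wt
    }
  }
  expect_equal(ps2$M, oracle, tolerance = 1e-12)
})

test_that("single-tilt construction reproduces the crop on the plane", {
  n <- 16
  set.seed(24)
  X <- ft_centered(matrix(rnorm(n * n), n, n))
  crops <- list(list(ft = X, ctf = matrix(1, n, n), visible = TRUE))
  mps <- list(list(A = diag(3)[1:2, ], t = c(0, 0)))
  ps <- construct_pseudosubtomogram(crops, mps)
  msk <- abs(pseudotomo:::freq_index(n)) < n / 2
  expect_equal(ps$D[msk, msk, 1], X[msk, msk], tolerance = 1e-12)
  expect_equal(ps$M[msk, msk, 1], matrix(1, n - 1, n - 1))
  expect_true(all(ps$M[, , 2:n] == 0))
  # Hermitian symmetry of D
  conj_idx <- c(1, n:2)
  expect_equal(ps$D, Conj(ps$D[conj_idx, conj_idx, conj_idx]),
               tolerance = 1e-10)
  # no visible tilts is an explicit error
  crops[[1]]$visible <- FALSE
  expect_error(construct_pseudosubtomogram(crops, mps), "no visible")
})

test_that("construction is additive over tilt subsets", {
  n <- 16
  set.seed(25)
  align <- tilt_alignment(c(-40, -10, 15, 50))
  crops <- lapply(1:4, function(f) {
    list(ft = ft_centered(matrix(rnorm(n * n), n, n)),
         ctf = matrix(runif(n * n, 0.3, 1), n, n), visible = TRUE)
  })
  mps <- fx_mappings(align)
  all4 <- construct_pseudosubtomogram(crops, mps)
  a <- construct_pseudosubtomogram(crops[1:2], mps[1:2])
  b <- construct_pseudosubtomogram(crops[3:4], mps[3:4])
  s <- add_pseudosubtomograms(a, b)
  expect_equal(s$D, all4$D, tolerance = 1e-12)
  expect_equal(s$W, all4$W, tolerance = 1e-12)
  expect_equal(s$M, all4$M, tolerance = 1e-12)
})

test_that("a +/-60 degree series leaves the missing wedge empty", {
  n <- 24
  angles <- seq(-60, 60, by = 3)
  align <- tilt_alignment(angles)
  crops <- lapply(angles, function(a) {
    list(ft = matrix(1 + 0i, n, n), ctf = matrix(1, n, n),
         visible = TRUE)
  })
  ps <- construct_pseudosubtomogram(crops, fx_mappings(align))
  # geometric predicate: polar angle from the tilt-axis plane (y axis is
  # the tilt axis; planes sweep x-z) beyond 60 degrees + margin is empty
  h <- pseudotomo:::freq_index(n)
  for (ix in 1:n) for (iz in 1:n) {
    hx <- h[ix]; hz <- h[iz]
    r <- sqrt(hx^2 + hz^2)
    if (r < 3) next
    # angle of (hx, hz) from the x axis; wedge is around the z axis
    ang <- abs(atan2(hx, hz)) * 180 / pi
    ang <- min(ang, 180 - ang)
    if (ang < 30 - 20 / r * 57.3) {  # inside wedge with interp margin
      expect_equal(sum(ps$M[ix, , iz]), 0)
    }
  }
  expect_gt(sum(ps$M), 0)
})

test_that("rotated construction frames commute with rotation", {
  n <- 24
  ph <- fx_phantom(n, seed = 6)
  V <- ft_centered(ph$data)
  align <- tilt_alignment(seq(-60, 60, by = 20))
  mps <- fx_mappings(align)
  crops <- lapply(seq_along(mps), function(f) {
    list(ft = project_map_slice(V, mps[[f]], n, 1),
         ctf = matrix(1, n, n), visible = TRUE)
  })
  Q <- euler_to_matrix(0, 30, 0)
  ps0 <- construct_pseudosubtomogram(crops, mps)
  psQ <- construct_pseudosubtomogram(crops, mps, frame = Q)
  # the frame option equals explicit composition of the mappings
  mpsQ <- lapply(mps, function(m) list(A = m$A %*% t(Q), t = m$t))
  ps_manual <- construct_pseudosubtomogram(crops, mpsQ)
  expect_equal(psQ$D, ps_manual$D, tolerance = 1e-12)
  expect_equal(psQ$M, ps_manual$M, tolerance = 1e-12)
  # and the rotated-frame triplet is the rotation of the original:
  # compare low-frequency structure via correlation (pointwise equality
  # cannot hold for interpolated plane data)
  M0r <- rotate_volume_oracle(fftshift(ps0$M), t(Q))
  MQ <- fftshift(psQ$M)
  sh <- fftshift(pseudotomo:::shell_index(n, 3))
  low <- sh > 1 & sh <= n / 4
  cc <- cor(M0r[low], MQ[low])
  if (cc < 0.9) {   # orientation of the oracle rotation
    cc <- cor(rotate_volume_oracle(fftshift(ps0$M), Q)[low], MQ[low])
  }
  expect_gt(cc, 0.95)
  # shell sums of M are rotation-invariant to within interpolation loss
  shu <- pseudotomo:::shell_index(n, 3)
  s0 <- vapply(3:(n / 3), function(k) sum(ps0$M[shu == k]), numeric(1))
  sQ <- vapply(3:(n / 3), function(k) sum(psQ$M[shu == k]), numeric(1))
  # trilinear mass redistributes across rounded-|k| bins at the
  # few-percent level at this box size
  expect_lt(median(abs(s0 - sQ) / s0), 0.03)
  expect_lt(max(abs(s0 - sQ) / s0), 0.06)
})

test_that("pseudo-subtomograms survive the MRC round trip", {
  n <- 16
  set.seed(26)
  align <- tilt_alignment(c(0, 30))
  crops <- lapply(1:2, function(f) {
    list(ft = ft_centered(matrix(rnorm(n * n), n, n)),
         ctf = matrix(runif(n * n), n, n), visible = TRUE)
  })
  ps <- construct_pseudosubtomogram(crops, fx_mappings(align),
                                    pixel_size = 1.5)
  prefix <- file.path(withr::local_tempdir(), "p1")
  write_pseudosubtomogram(ps, prefix)
  back <- read_pseudosubtomogram(prefix)
  expect_equal(back$D, ps$D, tolerance = 1e-6)
  expect_equal(back$W, ps$W, tolerance = 1e-6)
  expect_equal(back$M, ps$M, tolerance = 1e-6)
  expect_equal(back$pixel_size, 1.5, tolerance = 1e-6)
})
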
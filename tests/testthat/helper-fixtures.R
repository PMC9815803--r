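# Shared fixtures, built once per test run. Everything is generated in
# code; nothing is read from disk.

fixture_env <- new.env()

fx_phantom <- function(box = 32, seed = 3, pixel_size = 1) {
  key <- sprintf("ph_%d_%d_%g", box, seed, pixel_size)
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- make_phantom(box, seed = seed,
                                       pixel_size = pixel_size)
  }
  fixture_env[[key]]
}

fx_reference <- function(box = 32, seed = 3, pad = 2) {
  key <- sprintf("ref_%d_%d_%d", box, seed, pad)
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- prepare_reference(fx_phantom(box, seed)$data,
                                            pad = pad)
  }
  fixture_env[[key]]
}

# identity-pose per-tilt mappings for an alignment
fx_mappings <- function(align) {
  lapply(seq_len(align$n_tilts), function(f) {
    compose_projection(particle_pose(diag(3), n_tilts = align$n_tilts),
                       align, f)
  })
}

# maximum angular difference between two rotations, degrees
rotation_angle_deg <- function(R1, R2) {
  tr <- sum(diag(t(R1) %*% R2))
  acos(min(1, max(-1, (tr - 1) / 2))) * 180 / pi
}

# simple independent trilinear rotation of a real volume (R oracle)
rotate_volume_oracle <- function(vol, R) {
  n <- dim(vol)[1]
  c0 <- n / 2 + 1
  out <- array(0, dim(vol))
  idx <- as.matrix(expand.grid(x = 1:n, y = 1:n, z = 1:n))
  src <- (idx - c0) %*% t(R) + c0
  ok <- rowSums(src < 1 | src > n - 1e-9) == 0
  s <- src[ok, , drop = FALSE]
  f <- floor(s); w <- s - f
  acc <- numeric(sum(ok))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (if (dx) w[, 1] else 1 - w[, 1]) *
          (if (dy) w[, 2] else 1 - w[, 2]) *
          (if (dz) w[, 3] else 1 - w[, 3])
    ii <- cbind(pmin(f[, 1] + dx, n), pmin(f[, 2] + dy, n),
                pmin(f[, 3] + dz, n))
    acc <- acc + wt * vol[ii]
  }
  out[idx[ok, , drop = FALSE]] <- acc
  out
}
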
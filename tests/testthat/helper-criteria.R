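# End-to-end study procedures shared by the acceptance checks. Each
# takes a seed and returns the measured quantity; problem sizes are the
# desk-scale study conditions described in the methods vignette.

criterion_equivalence_exact <- function(seed = 1) {
  # single tilt, on-grid construction, unit CTF: the pseudo-subtomogram
  # likelihood and the 2D tilt likelihood are the same number
  ph <- fx_phantom(32)
  V <- ft_centered(ph$data)
  align <- tilt_alignment(0)
  pose <- particle_pose(euler_to_matrix(25, 55, 80), n_tilts = 1)
  set.seed(seed)
  mp <- compose_projection(pose, align, 1)
  crop <- list(ft = project_map_slice(V, mp, 32, 1) +
                 ft_centered(matrix(rnorm(32 * 32), 32, 32)),
               ctf = matrix(1, 32, 32), visible = TRUE)
  ps <- construct_pseudosubtomogram(list(crop), fx_mappings(align))
  sig <- rep(32^2 / 2, 17)
  a <- nll_2d(list(crop), V, pose, align, sig)
  b <- nll_pseudo(ps, V, pose$rotation, sig)
  abs(a - b) / a
}

criterion_equivalence_general <- function(seed = 1, n_particles = 20) {
  # general 5-tilt poses at SNR 1; each likelihood is evaluated under
  # its own maximum-likelihood per-shell noise estimate
  ph <- fx_phantom(32)
  V <- ft_centered(ph$data)
  cfg <- sim_config(box = 32, n_particles = n_particles,
                    scheme = dose_symmetric_scheme(60, 30), snr = 1,
                    apply_damage = FALSE, defocus = 15000, seed = seed)
  sim <- simulate_tilt_series(ph, cfg)
  mps <- fx_mappings(sim$align)
  pss <- lapply(sim$particles, function(p) {
    construct_pseudosubtomogram(p$crops, mps)
  })
  parts <- lapply(seq_along(pss), function(i) {
    list(ps = pss[[i]], rotation = sim$truth$rotations[[i]])
  })
  sig3 <- update_sigma(parts, V)
  sig3[!is.finite(sig3) | sig3 <= 0] <- max(sig3, na.rm = TRUE)
  sh2 <- pseudotomo:::shell_index(32, 2)
  msk2 <- pseudotomo:::nyquist_mask(32, 2)
  acc <- rep(0, 17); cnt <- rep(0, 17)
  for (i in seq_along(sim$particles)) {
    pose <- particle_pose(sim$truth$rotations[[i]], n_tilts = 5)
    for (f in 1:5) {
      mp <- compose_projection(pose, sim$align, f)
      pred <- project_map_slice(V, mp, 32, 1) *
        sim$particles[[i]]$crops[[f]]$ctf
      r2 <- Mod(sim$particles[[i]]$crops[[f]]$ft - pred)^2
      for (k in 0:16) {
        ii <- sh2 == k & msk2
        acc[k + 1] <- acc[k + 1] + sum(r2[ii])
        cnt[k + 1] <- cnt[k + 1] + sum(ii)
      }
    }
  }
  sig2 <- acc / (2 * cnt)
  n2d <- mean(vapply(seq_along(sim$particles), function(i) {
    nll_2d(sim$particles[[i]]$crops, V,
           particle_pose(sim$truth$rotations[[i]], n_tilts = 5),
           sim$align, sig2)
  }, numeric(1)))
  np <- mean(vapply(seq_along(pss), function(i) {
    nll_pseudo(pss[[i]], V, sim$truth$rotations[[i]], sig3)
  }, numeric(1)))
  abs(np - n2d) / n2d
}

criterion_conservation <- function(seed = 1) {
  # max |sum(M) - inserted| over several tilt schemes (should be 0)
  set.seed(seed)
  n <- 24
  worst <- 0
  for (angs in list(c(0), seq(-60, 60, by = 3), c(-55, -17, 2, 33),
                    runif(7, -80, 80))) {
    align <- tilt_alignment(angs)
    crops <- lapply(angs, function(a) {
      list(ft = ft_centered(matrix(rnorm(n * n), n, n)),
           ctf = matrix(runif(n * n), n, n), visible = TRUE)
    })
    ps <- construct_pseudosubtomogram(crops, fx_mappings(align))
    worst <- max(worst, abs(sum(ps$M) - ps$n_inserted))
  }
  worst
}

criterion_reconstruction <- function(seed = 1, n_particles = 200,
                                     box = 48, tilt_step = 3) {
  # noiseless particles at random orientations; minimum FSC of the
  # regularisation-free map update against the phantom up to 0.8 Nyquist
  ph <- fx_phantom(box, seed = 3)
  V <- ft_centered(ph$data)
  cfg <- sim_config(box = box, n_particles = n_particles,
                    scheme = dose_symmetric_scheme(60, tilt_step),
                    noise_sd = 0, apply_damage = FALSE, defocus = 20000,
                    seed = seed)
  sim <- simulate_tilt_series(ph, cfg)
  mps <- fx_mappings(sim$align)
  particles <- lapply(seq_along(sim$particles), function(i) {
    list(crops = sim$particles[[i]]$crops, mappings = mps,
         rotation = sim$truth$rotations[[i]])
  })
  Vr <- reconstruct_particles(particles, box, 1, oversample = 2)
  fsc <- compute_fsc(Vr, V)
  min(fsc[seq_len(floor(0.8 * box / 2) + 1)])
}

criterion_pose_recovery <- function(seed = 1, n_particles = 60) {
  # SNR 0.5, +/-60/3 scheme; grid search in a 10-degree grid around a
  # perturbed start plus local refinement
  ph <- fx_phantom(32)
  Vp <- fx_reference(32, pad = 2)
  cfg <- sim_config(box = 32, n_particles = n_particles,
                    scheme = dose_symmetric_scheme(60, 3), snr = 0.5,
                    defocus = 20000, seed = seed)
  sim <- simulate_tilt_series(ph, cfg)
  mps <- fx_mappings(sim$align)
  pss <- lapply(sim$particles, function(p) {
    construct_pseudosubtomogram(p$crops, mps)
  })
  parts <- lapply(seq_along(pss), function(i) {
    list(ps = pss[[i]], rotation = sim$truth$rotations[[i]])
  })
  sig <- update_sigma(parts, Vp)
  sig[!is.finite(sig) | sig <= 0] <- max(sig, na.rm = TRUE)
  set.seed(seed + 1)
  aerr <- terr <- numeric(length(pss))
  for (i in seq_along(pss)) {
    start <- matrix_to_euler(sim$truth$rotations[[i]]) + rnorm(3, sd = 10)
    prior <- orientation_prior(start, sigma_angles = rep(10, 3),
                               sigma_shift = rep(5, 3))
    gs <- grid_search_pose(pss[[i]], Vp, prior, angular_step = 10,
                           sigma2 = sig)
    lr <- local_refine_pose(pss[[i]], Vp, gs$map_pose, sig, prior)
    Rhat <- euler_to_matrix(lr$angles[1], lr$angles[2], lr$angles[3])
    aerr[i] <- rotation_angle_deg(Rhat, sim$truth$rotations[[i]])
    terr[i] <- sqrt(sum(lr$shift^2))   # truth is zero shift
  }
  list(angular = median(aerr), translational = median(terr))
}

criterion_sigma_recovery <- function(seed = 1, n_particles = 100) {
  n <- 32; s_px <- 1.5
  mp <- fx_mappings(tilt_alignment(0))
  set.seed(seed)
  parts <- lapply(seq_len(n_particles), function(i) {
    crops <- list(list(ft = ft_centered(matrix(rnorm(n * n, sd = s_px),
                                               n, n)),
                       ctf = matrix(1, n, n), visible = TRUE))
    list(ps = construct_pseudosubtomogram(crops, mp), rotation = diag(3))
  })
  sig <- update_sigma(parts, array(0 + 0i, c(n, n, n)))
  gen <- n^2 * s_px^2 / 2
  max(abs(sig[3:13] - gen) / gen)   # shells 2..12 (~0.8 Nyquist)
}

criterion_defocus_recovery <- function(seed = 1, n_particles = 100,
                                       box = 64) {
  def_true <- rep(25000, 5); def_true[3] <- 25800
  ph <- fx_phantom(box, seed = 3, pixel_size = 2)
  Vp <- prepare_reference(ph$data, pad = 2)
  cfg <- sim_config(box = box, pixel_size = 2, n_particles = n_particles,
                    scheme = dose_symmetric_scheme(60, 30), snr = 0.5,
                    defocus = def_true, seed = seed)
  sim <- simulate_tilt_series(ph, cfg)
  parts <- lapply(seq_along(sim$particles), function(i) {
    list(crops = sim$particles[[i]]$crops,
         rotation = sim$truth$rotations[[i]],
         position = sim$particles[[i]]$position)
  })
  optics <- list(voltage_kv = 300, cs = 2.7, amplitude_contrast = 0.07)
  ent <- make_tilt_entries(parts, Vp, sim$align, 25000, optics, 2)
  lam <- electron_wavelength(300)
  deltas <- vapply(1:5, function(f) {
    cp <- condense_tilt_image(ent[[f]], 0.07,
                              box^2 * sim$noise_sd^2 / 2)
    refine_defocus(cp, lam, 2)$delta_defocus
  }, numeric(1))
  # recovery of the injected offset relative to the control tilts
  (deltas[3] - mean(deltas[-3]))
}

criterion_rigid_recovery <- function(seed = 1, n_particles = 60) {
  shifts <- matrix(0, 5, 2); shifts[3, ] <- c(3, 0)   # 1.5 px at 2 A/px
  psis <- rep(0, 5); psis[3] <- 0.5
  ph <- fx_phantom(64, seed = 3, pixel_size = 2)
  Vp <- prepare_reference(ph$data, pad = 2)
  cfg <- sim_config(box = 64, pixel_size = 2, n_particles = n_particles,
                    scheme = dose_symmetric_scheme(60, 30), snr = 0.5,
                    defocus = 25000, seed = seed, tilt_shifts = shifts,
                    tilt_psi = psis)
  sim <- simulate_tilt_series(ph, cfg)
  parts <- lapply(seq_along(sim$particles), function(i) {
    list(crops = sim$particles[[i]]$crops,
         rotation = sim$truth$rotations[[i]],
         position = sim$particles[[i]]$position)
  })
  optics <- list(voltage_kv = 300, cs = 2.7, amplitude_contrast = 0.07)
  ent <- make_tilt_entries(parts, Vp, sim$align, 25000, optics, 2)
  sig0 <- 64^2 * sim$noise_sd^2 / 2
  lmaps <- lapply(seq_along(parts), function(i) {
    e <- ent[[3]][[i]]
    precompute_position_likelihood(e$X, e$ctf * e$pred, sig0)
  })
  pos2d <- t(vapply(parts, function(p) {
    as.numeric(sim$align$rotations[[3]][1:2, ] %*% p$position) / 2
  }, numeric(2)))
  rr <- refine_rigid_tilt_alignment(lmaps, pos2d, 2)
  list(psi_err = abs(rr$psi - 0.5),
       shift_err = max(abs(rr$shift / 2 - c(1.5, 0))))
}

criterion_motion_recovery <- function(seed = 1, n_particles = 10) {
  sch <- dose_symmetric_scheme(60, 30, dose_per_tilt = 3)
  nf <- 5; np <- n_particles
  drift <- c(6, 0, 0)
  motion <- array(0, c(np, nf, 3))
  for (f in 1:nf) {
    motion[, f, ] <- matrix(rep((sch$order[f] - 1) / (nf - 1) * drift,
                                each = np), np, 3)
  }
  ph <- fx_phantom(64, seed = 3, pixel_size = 2)
  Vp <- prepare_reference(ph$data, pad = 2)
  cfg <- sim_config(box = 64, pixel_size = 2, n_particles = np,
                    scheme = sch, snr = 10, defocus = 25000,
                    seed = seed, motion = motion)
  sim <- simulate_tilt_series(ph, cfg)
  parts <- lapply(seq_along(sim$particles), function(i) {
    list(crops = sim$particles[[i]]$crops,
         rotation = sim$truth$rotations[[i]],
         position = sim$particles[[i]]$position)
  })
  optics <- list(voltage_kv = 300, cs = 2.7, amplitude_contrast = 0.07)
  ent <- make_tilt_entries(parts, Vp, sim$align, 25000, optics, 2)
  sig0 <- 64^2 * sim$noise_sd^2 / 2
  lmaps <- lapply(1:np, function(i) lapply(1:nf, function(f) {
    e <- ent[[f]][[i]]
    precompute_position_likelihood(e$X, e$ctf * e$pred, sig0)
  }))
  pos <- t(vapply(parts, function(p) p$position, numeric(3)))
  mo <- refine_particle_motion(lmaps, sim$align, pos, 2, sigma_d = 5,
                               corr_length = Inf)
  drift_err <- max(vapply(1:nf, function(f) {
    P <- sim$align$rotations[[f]][1:2, ]
    max(vapply(1:np, function(i) {
      sqrt(sum((as.numeric(P %*% (mo$trajectories[i, f, ] -
                                  motion[i, f, ])) / 2)^2))
    }, numeric(1)))
  }, numeric(1)))
  # stiff-limit agreement with the rigid translation solution
  rigid <- vapply(1:nf, function(f) {
    lm_f <- lapply(1:np, function(i) lmaps[[i]][[f]])
    pos2d <- t(vapply(1:np, function(i) {
      as.numeric(sim$align$rotations[[f]][1:2, ] %*% pos[i, ]) / 2
    }, numeric(2)))
    refine_rigid_tilt_alignment(lm_f, pos2d, 2)$shift
  }, numeric(2))
  proj <- vapply(1:nf, function(f) {
    as.numeric(sim$align$rotations[[f]][1:2, ] %*%
                 mo$trajectories[1, f, ])
  }, numeric(2))
  list(drift_err = drift_err,
       stiff_vs_rigid = max(abs(proj - rigid)) / 2)
}

criterion_aberration_recovery <- function(seed = 1, n_particles = 80) {
  inj <- c(0, 0, 0, 0, 0, 0.5)
  ph <- fx_phantom(48, seed = 3, pixel_size = 2)
  Vp <- prepare_reference(ph$data, pad = 2)
  cfg <- sim_config(box = 48, pixel_size = 2, n_particles = n_particles,
                    scheme = dose_symmetric_scheme(60, 30),
                    noise_sd = 0, defocus = 25000, zernike_odd = inj,
                    seed = seed, apply_damage = FALSE)
  sim <- simulate_tilt_series(ph, cfg)
  parts <- lapply(seq_along(sim$particles), function(i) {
    list(crops = sim$particles[[i]]$crops,
         rotation = sim$truth$rotations[[i]],
         position = sim$particles[[i]]$position)
  })
  optics <- list(voltage_kv = 300, cs = 2.7, amplitude_contrast = 0.07)
  ent <- make_tilt_entries(parts, Vp, sim$align, 25000, optics, 2,
                           apply_damage = FALSE)
  cps <- lapply(1:5, function(f) condense_tilt_image(ent[[f]], 0.07, 1))
  ab <- estimate_aberrations(cps, 3, "odd", 2)
  abs(ab$coefficients[6] - 0.5) / 0.5
}

criterion_workflow_cycle <- function(seed) {
  # one improve -> realign cycle: initial alignment with perturbed tilt
  # geometry, pose refinement, rigid frame re-alignment against the
  # average, new pseudo-subtomograms, pose re-refinement
  ph <- fx_phantom(32, seed = 3, pixel_size = 2)
  sch <- dose_symmetric_scheme(60, 15, dose_per_tilt = 3)
  nf <- length(sch$angles)
  set.seed(seed)
  shifts <- matrix(rnorm(nf * 2, sd = 2.5), nf, 2)
  shifts[sch$angles == 0, ] <- 0
  psis <- rnorm(nf, sd = 0.4); psis[sch$angles == 0] <- 0
  cfg <- sim_config(box = 32, pixel_size = 2, n_particles = 16,
                    scheme = sch, snr = 0.8, defocus = 25000,
                    seed = seed, tilt_shifts = shifts, tilt_psi = psis)
  sim <- simulate_tilt_series(ph, cfg)
  nominal <- tilt_alignment(sch$angles, sch$order, dose = sch$dose)
  mk_parts <- function(align) {
    mps <- fx_mappings(align)
    lapply(seq_along(sim$particles), function(i) {
      p <- sim$particles[[i]]
      ps <- construct_pseudosubtomogram(p$crops, mps, pixel_size = 2)
      eul <- matrix_to_euler(sim$truth$rotations[[i]]) + rnorm(3, sd = 6)
      list(ps = ps, crops = p$crops, mappings = mps,
           pose = list(angles = as.numeric(eul), shift = c(0, 0, 0)),
           position = p$position)
    })
  }
  prior <- orientation_prior(sigma_angles = rep(8, 3),
                             sigma_shift = rep(4, 3))
  Vf <- ft_centered(ph$data)
  Vf[pseudotomo:::shell_index(32, 3) > 5] <- 0   # low-pass initial map
  set.seed(seed + 1)
  parts <- mk_parts(nominal)
  fit1 <- refine_map(parts, Vf, n_iter = 2, search = "local",
                     prior = prior, reconstruct_oversample = 2)
  # tilt-series geometry refinement against the current average
  Vcur <- prepare_reference(fit1$map, pad = 2)
  parts_ref <- lapply(seq_along(parts), function(i) {
    ang <- fit1$poses[[i]]$angles
    list(crops = parts[[i]]$crops,
         rotation = euler_to_matrix(ang[1], ang[2], ang[3]),
         position = parts[[i]]$position)
  })
  optics <- list(voltage_kv = 300, cs = 2.7, amplitude_contrast = 0.07)
  ent <- make_tilt_entries(parts_ref, Vcur, nominal, 25000, optics, 2)
  sig0 <- 32^2 * sim$noise_sd^2 / 2
  align2 <- nominal
  for (f in seq_len(nf)) {
    lmaps <- lapply(seq_along(ent[[f]]), function(i) {
      e <- ent[[f]][[i]]
      precompute_position_likelihood(e$X, e$ctf * e$pred, sig0)
    })
    pos2d <- t(vapply(parts_ref, function(p) {
      as.numeric(nominal$rotations[[f]][1:2, ] %*% p$position) / 2
    }, numeric(2)))
    rr <- refine_rigid_tilt_alignment(lmaps, pos2d, 2, shift_range = 3)
    if (!isTRUE(rr$skipped)) {
      align2 <- update_tilt_alignment(align2, f, rr$psi, rr$shift)
    }
  }
  set.seed(seed + 1)
  parts2 <- mk_parts(align2)
  for (i in seq_along(parts2)) parts2[[i]]$pose <- fit1$poses[[i]]
  fit2 <- refine_map(parts2, fit1$map, n_iter = 2, search = "local",
                     prior = prior, reconstruct_oversample = 2)
  c(before = fit1$resolution, after = fit2$resolution)
}
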
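# Shared small refinement fixture: a 5-tilt dose-symmetric series of
# box-48 particles at SNR 0.5 with known optics.
refine_fixture <- function(seed = 31, n_particles = 40, snr = 0.5,
                           defocus = rep(25000, 5), tilt_shifts = NULL,
                           tilt_psi = NULL, motion = NULL,
                           zernike_odd = numeric(), box = 48,
                           apply_damage = FALSE, defocus_v = NULL,
                           astigmatism_azimuth = 0) {
  ph <- fx_phantom(box, seed = 3, pixel_size = 2)
  sch <- dose_symmetric_scheme(60, 30, dose_per_tilt = 3)
  cfg <- sim_config(box = box, pixel_size = 2, scheme = sch,
                    n_particles = n_particles,
                    snr = if (is.finite(snr)) snr else NULL,
                    noise_sd = if (is.finite(snr)) NULL else 0,
                    defocus = defocus, defocus_v = defocus_v,
                    astigmatism_azimuth = astigmatism_azimuth,
                    zernike_odd = zernike_odd,
                    tilt_shifts = tilt_shifts, tilt_psi = tilt_psi,
                    motion = motion, apply_damage = apply_damage,
                    seed = seed)
  sim <- simulate_tilt_series(ph, cfg)
  parts <- lapply(seq_along(sim$particles), function(i) {
    list(crops = sim$particles[[i]]$crops,
         rotation = sim$truth$rotations[[i]],
         position = sim$particles[[i]]$position)
  })
  list(sim = sim, parts = parts, ph = ph,
       V = prepare_reference(ph$data, pad = 2),
       optics = list(voltage_kv = 300, cs = 2.7,
                     amplitude_contrast = 0.07),
       sig0 = if (sim$noise_sd > 0) box^2 * sim$noise_sd^2 / 2 else 1,
       px = 2)
}

test_that("condensed scoring equals the direct per-particle sum", {
  fx <- refine_fixture(n_particles = 10)
  ent <- make_tilt_entries(fx$parts, fx$V, fx$sim$align, 25000,
                           fx$optics, fx$px, apply_damage = FALSE)
  cp <- condense_tilt_image(ent[[2]], 0.07, fx$sig0)
  msk <- pseudotomo:::nyquist_mask(48, 2)
  # direct Eq-style sum at zero perturbation
  direct0 <- sum(vapply(ent[[2]], function(e) {
    sum((Mod(e$X - e$ctf * e$pred)^2 / fx$sig0)[msk])
  }, numeric(1)))
  expect_lt(abs(condensed_score(cp, 0) - direct0) / direct0, 1e-8)
  # and at a non-trivial common phase perturbation
  h <- pseudotomo:::freq_index(48) / (48 * 2)
  j2 <- outer(h^2, h^2, `+`)
  delta <- pi * electron_wavelength(300) * 600 * j2
  w <- 0.07; sbar <- sqrt(1 - w^2)
  directd <- sum(vapply(ent[[2]], function(e) {
    ctfd <- -(sbar * sin(e$chi + delta) + w * cos(e$chi + delta)) *
      e$kappa
    sum((Mod(e$X - ctfd * e$pred)^2 / fx$sig0)[msk])
  }, numeric(1)))
  expect_lt(abs(condensed_score(cp, delta) - directd) / directd, 1e-8)
  # condensing disjoint subsets and summing equals condensing all
  cpa <- condense_tilt_image(ent[[2]][1:4], 0.07, fx$sig0)
  cpb <- condense_tilt_image(ent[[2]][5:10], 0.07, fx$sig0)
  pooled <- pseudotomo:::pool_condensed(list(cpa, cpb))
  expect_equal(condensed_score(pooled, delta),
               condensed_score(cp, delta), tolerance = 1e-10)
  # a particle predicted perfectly implies zero phase error everywhere
  e1 <- ent[[2]][[1]]
  e1$X <- e1$ctf * e1$pred
  cp1 <- condense_tilt_image(list(e1), 0.07, fx$sig0)
  expect_lt(condensed_score(cp1, 0), condensed_score(cp1, 0.3) + 1e-9)
  expect_error(condense_tilt_image(list(), 0.07), "no particles")
})

test_that("defocus refinement is centred and recovers an injected offset", {
  def_true <- rep(25000, 5); def_true[3] <- 25800
  fx <- refine_fixture(seed = 31, n_particles = 80, box = 64,
                       defocus = def_true)
  ent <- make_tilt_entries(fx$parts, fx$V, fx$sim$align, 25000,
                           fx$optics, fx$px, apply_damage = FALSE)
  lam <- electron_wavelength(300)
  deltas <- vapply(1:5, function(f) {
    cp <- condense_tilt_image(ent[[f]], 0.07, fx$sig0)
    refine_defocus(cp, lam, fx$px)$delta_defocus
  }, numeric(1))
  # the injected tilt stands out by ~800 A over the control tilts
  expect_lt(abs((deltas[3] - mean(deltas[-3])) - 800), 100)
  # control tilts sit near zero
  expect_lt(max(abs(deltas[-3])), 300)
  # a minimum at the scan boundary is flagged and left unrefined
  cp3 <- condense_tilt_image(ent[[3]], 0.07, fx$sig0)
  rb <- refine_defocus(cp3, lam, fx$px, range = 300, step = 100)
  expect_true(rb$at_boundary)
  expect_equal(rb$delta_defocus, 0)
})

test_that("recovery error shrinks with particle count", {
  lam <- electron_wavelength(300)
  err_for <- function(np, seeds) {
    vapply(seeds, function(s) {
      def_true <- rep(25000, 5); def_true[2] <- 25800
      fx <- refine_fixture(seed = s, n_particles = np,
                           defocus = def_true)
      ent <- make_tilt_entries(fx$parts, fx$V, fx$sim$align, 25000,
                               fx$optics, fx$px, apply_damage = FALSE)
      ds <- vapply(c(2, 4), function(f) {
        cp <- condense_tilt_image(ent[[f]], 0.07, fx$sig0)
        refine_defocus(cp, lam, fx$px)$delta_defocus
      }, numeric(1))
      abs(ds[1] - ds[2] - 800)
    }, numeric(1))
  }
  seeds <- c(101, 202, 303)
  e_small <- median(err_for(6, seeds))
  e_large <- median(err_for(48, seeds))
  expect_lt(e_large, e_small)
})

test_that("astigmatism is recovered per series with canonical azimuth", {
  fx <- refine_fixture(seed = 41, n_particles = 120, defocus = 25000,
                       defocus_v = 24800, astigmatism_azimuth = 30,
                       box = 48)
  ent <- make_tilt_entries(fx$parts, fx$V, fx$sim$align, 24900,
                           fx$optics, fx$px, apply_damage = FALSE)
  cps <- lapply(1:5, function(f) condense_tilt_image(ent[[f]], 0.07,
                                                     fx$sig0))
  ra <- refine_astigmatism(cps, ctf_params(defocus_u = 24900,
                                           defocus_v = 24900), fx$px)
  expect_lt(abs((ra$defocus_u - ra$defocus_v) - 200), 100)
  expect_lt(min(abs(ra$azimuth - 30), abs(ra$azimuth - 30 + 180)), 15)
  expect_gte(ra$azimuth, 0)
  expect_lt(ra$azimuth, 180)
  # zero-astigmatism data: |u - v| stays at the noise floor
  fx0 <- refine_fixture(seed = 43, n_particles = 60, defocus = 25000)
  ent0 <- make_tilt_entries(fx0$parts, fx0$V, fx0$sim$align, 25000,
                            fx0$optics, fx0$px, apply_damage = FALSE)
  cps0 <- lapply(1:5, function(f) condense_tilt_image(ent0[[f]], 0.07,
                                                      fx0$sig0))
  ra0 <- refine_astigmatism(cps0, ctf_params(defocus_u = 25000), fx0$px)
  expect_lt(abs(ra0$defocus_u - ra0$defocus_v), 120)
})

test_that("odd Zernike aberrations are recovered and parities separate", {
  inj <- c(0, 0, 0, 0, 0, 0.5)  # trefoil (n = 3, m = +3)
  fx <- refine_fixture(seed = 42, n_particles = 80, snr = Inf,
                       zernike_odd = inj, box = 48)
  ent <- make_tilt_entries(fx$parts, fx$V, fx$sim$align, 25000,
                           fx$optics, fx$px, apply_damage = FALSE)
  cps <- lapply(1:5, function(f) condense_tilt_image(ent[[f]], 0.07, 1))
  ab <- estimate_aberrations(cps, 3, "odd", fx$px)
  expect_lt(abs(ab$coefficients[6] - 0.5) / 0.5, 0.2)
  expect_lt(max(abs(ab$coefficients[-6])), 0.1)
  # after applying the fitted odd terms to the predictions, the even
  # estimates sit at the noise level (parity separation is sequential:
  # the even estimator assumes antisymmetric phases are accounted for)
  optics_odd <- fx$optics
  optics_odd$zernike_odd <- ab$coefficients
  ent2 <- make_tilt_entries(fx$parts, fx$V, fx$sim$align, 25000,
                            optics_odd, fx$px, apply_damage = FALSE)
  cps2 <- lapply(1:5, function(f) condense_tilt_image(ent2[[f]], 0.07,
                                                      1))
  ev <- estimate_aberrations(cps2, 4, "even", fx$px)
  idx <- ev$indices
  high <- which(idx$n >= 2)
  expect_lt(max(abs(ev$coefficients[high])), 0.15)
  # zero-aberration data gives coefficients near zero
  fx0 <- refine_fixture(seed = 44, n_particles = 40, snr = Inf,
                        box = 48)
  ent0 <- make_tilt_entries(fx0$parts, fx0$V, fx0$sim$align, 25000,
                            fx0$optics, fx0$px, apply_damage = FALSE)
  cps0 <- lapply(1:5, function(f) condense_tilt_image(ent0[[f]], 0.07,
                                                      1))
  ab0 <- estimate_aberrations(cps0, 3, "odd", fx0$px)
  expect_lt(max(abs(ab0$coefficients)), 0.1)
})

test_that("damage scale factors track accumulated dose", {
  fx <- refine_fixture(seed = 91, n_particles = 60, snr = 2,
                       apply_damage = TRUE)
  ent <- make_tilt_entries(fx$parts, fx$V, fx$sim$align, 25000,
                           fx$optics, fx$px, apply_damage = FALSE)
  sf <- lapply(1:5, function(f) {
    cp <- condense_tilt_image(ent[[f]], 0.07, fx$sig0)
    estimate_scale_factors(cp, fx$px)
  })
  B <- vapply(sf, function(x) x$B, numeric(1))
  ord <- fx$sim$config$scheme$order
  # B grows in acquisition (dose) order
  expect_true(all(diff(B[order(ord)]) > 0))
  # undamaged data: B near zero
  fx0 <- refine_fixture(seed = 92, n_particles = 40, snr = 2,
                        apply_damage = FALSE)
  ent0 <- make_tilt_entries(fx0$parts, fx0$V, fx0$sim$align, 25000,
                            fx0$optics, fx0$px, apply_damage = FALSE)
  cp0 <- condense_tilt_image(ent0[[3]], 0.07, fx0$sig0)
  s0 <- estimate_scale_factors(cp0, fx0$px)
  expect_lt(abs(s0$B), 150)
  expect_lt(abs(s0$s - 1), 0.15)
  # ratio-based: invariant to a global intensity rescaling
  ent_scaled <- ent0
  for (f in 1:5) for (i in seq_along(ent_scaled[[f]])) {
    ent_scaled[[f]][[i]]$X <- ent_scaled[[f]][[i]]$X * 2
    ent_scaled[[f]][[i]]$pred <- ent_scaled[[f]][[i]]$pred * 2
  }
  cp_s <- condense_tilt_image(ent_scaled[[3]], 0.07, fx0$sig0)
  s_s <- estimate_scale_factors(cp_s, fx0$px)
  expect_equal(s_s$s, s0$s, tolerance = 1e-6)
  expect_equal(s_s$B, s0$B, tolerance = 1e-6)
})

test_that("position likelihood maps agree with the direct 2D term", {
  fx <- refine_fixture(seed = 71, n_particles = 3)
  ent <- make_tilt_entries(fx$parts, fx$V, fx$sim$align, 25000,
                           fx$optics, fx$px, apply_damage = FALSE)
  e <- ent[[2]][[1]]
  lm <- precompute_position_likelihood(e$X, e$ctf * e$pred, fx$sig0)
  msk <- pseudotomo:::nyquist_mask(48, 2)
  direct <- sum((Mod(e$X - e$ctf * e$pred)^2 / fx$sig0)[msk])
  at0 <- lookup_position_nll(lm, c(0, 0))
  expect_lt(abs(at0 - direct) / direct, 1e-8)
  # adding a constant leaves the argmin untouched
  lm2 <- lm + 1000
  class(lm2) <- class(lm)
  g <- expand.grid(dx = seq(-2, 2, 0.5), dy = seq(-2, 2, 0.5))
  v1 <- mapply(function(x, y) lookup_position_nll(lm, c(x, y)),
               g$dx, g$dy)
  v2 <- mapply(function(x, y) lookup_position_nll(lm2, c(x, y)),
               g$dx, g$dy)
  expect_equal(which.min(v1), which.min(v2))
  # noiseless particle: the minimum sits at the true (zero) offset
  fx0 <- refine_fixture(seed = 72, n_particles = 2, snr = Inf)
  ent0 <- make_tilt_entries(fx0$parts, fx0$V, fx0$sim$align, 25000,
                            fx0$optics, fx0$px, apply_damage = FALSE)
  e0 <- ent0[[1]][[1]]
  lm0 <- precompute_position_likelihood(e0$X, e0$ctf * e0$pred, 1)
  n <- nrow(lm0)
  best <- which(lm0 == min(lm0), arr.ind = TRUE)[1, ]
  expect_equal(as.numeric(best), c(n / 2 + 1, n / 2 + 1))
})

test_that("rigid tilt alignment recovers an injected shift and rotation", {
  shifts <- matrix(0, 5, 2); shifts[3, ] <- c(3, 0)   # 1.5 px
  psis <- rep(0, 5); psis[3] <- 0.5
  fx <- refine_fixture(seed = 71, n_particles = 60,
                       tilt_shifts = shifts, tilt_psi = psis, box = 64)
  ent <- make_tilt_entries(fx$parts, fx$V, fx$sim$align, 25000,
                           fx$optics, fx$px, apply_damage = FALSE)
  res <- lapply(c(1, 3), function(f) {
    lmaps <- lapply(seq_along(ent[[f]]), function(i) {
      e <- ent[[f]][[i]]
      precompute_position_likelihood(e$X, e$ctf * e$pred, fx$sig0)
    })
    pos2d <- t(vapply(fx$parts, function(p) {
      as.numeric(fx$sim$align$rotations[[f]][1:2, ] %*% p$position) /
        fx$px
    }, numeric(2)))
    refine_rigid_tilt_alignment(lmaps, pos2d, fx$px)
  })
  # perturbed tilt: 0.5 deg and 1.5 px recovered tightly
  expect_lt(abs(res[[2]]$psi - 0.5), 0.1)
  expect_lt(max(abs(res[[2]]$shift / fx$px - c(1.5, 0))), 0.2)
  # clean tilt: identity update
  expect_lt(abs(res[[1]]$psi), 0.1)
  expect_lt(max(abs(res[[1]]$shift / fx$px)), 0.2)
  # too few particles: skipped with a warning
  expect_warning(r0 <- refine_rigid_tilt_alignment(list(), matrix(0, 0, 2),
                                                   2), "too few")
  expect_true(r0$skipped)
})

test_that("motion refinement recovers a common drift and honours limits", {
  sch <- dose_symmetric_scheme(60, 30, dose_per_tilt = 3)
  nf <- 5; np <- 10
  drift <- c(6, 0, 0)   # 3 px at 2 A/px over the series
  motion <- array(0, c(np, nf, 3))
  for (f in 1:nf) {
    motion[, f, ] <- matrix(rep((sch$order[f] - 1) / (nf - 1) * drift,
                                each = np), np, 3)
  }
  fx <- refine_fixture(seed = 81, n_particles = np, snr = 10,
                       motion = motion, box = 64)
  ent <- make_tilt_entries(fx$parts, fx$V, fx$sim$align, 25000,
                           fx$optics, fx$px, apply_damage = FALSE)
  lmaps <- lapply(1:np, function(i) lapply(1:nf, function(f) {
    e <- ent[[f]][[i]]
    precompute_position_likelihood(e$X, e$ctf * e$pred, fx$sig0)
  }))
  pos <- t(vapply(fx$parts, function(p) p$position, numeric(3)))
  mo <- refine_particle_motion(lmaps, fx$sim$align, pos, fx$px,
                               sigma_d = 5, corr_length = Inf)
  err <- vapply(1:nf, function(f) {
    P <- fx$sim$align$rotations[[f]][1:2, ]
    max(vapply(1:np, function(i) {
      sqrt(sum((as.numeric(P %*% (mo$trajectories[i, f, ] -
                                  motion[i, f, ])) / fx$px)^2))
    }, numeric(1)))
  }, numeric(1))
  expect_lt(max(err), 0.5)
  # stiffness -> Inf reproduces the rigid per-tilt translation solution
  rigid <- vapply(1:nf, function(f) {
    lm_f <- lapply(1:np, function(i) lmaps[[i]][[f]])
    pos2d <- t(vapply(1:np, function(i) {
      as.numeric(fx$sim$align$rotations[[f]][1:2, ] %*% pos[i, ]) /
        fx$px
    }, numeric(2)))
    refine_rigid_tilt_alignment(lm_f, pos2d, fx$px)$shift
  }, numeric(2))
  proj <- vapply(1:nf, function(f) {
    as.numeric(fx$sim$align$rotations[[f]][1:2, ] %*%
                 mo$trajectories[1, f, ])
  }, numeric(2))
  expect_lt(max(abs(proj - rigid)) / fx$px, 0.25)
  # zero-motion noiseless data: all displacements stay below 0.05 px
  fx0 <- refine_fixture(seed = 82, n_particles = 4, snr = Inf, box = 64)
  ent0 <- make_tilt_entries(fx0$parts, fx0$V, fx0$sim$align, 25000,
                            fx0$optics, fx0$px, apply_damage = FALSE)
  lm0 <- lapply(1:4, function(i) lapply(1:nf, function(f) {
    e <- ent0[[f]][[i]]
    precompute_position_likelihood(e$X, e$ctf * e$pred, 1)
  }))
  pos0 <- t(vapply(fx0$parts, function(p) p$position, numeric(3)))
  mo0 <- refine_particle_motion(lm0, fx0$sim$align, pos0, fx0$px,
                                sigma_d = 2, corr_length = 500)
  projmax <- max(vapply(1:nf, function(f) {
    P <- fx0$sim$align$rotations[[f]][1:2, ]
    max(abs(vapply(1:4, function(i) {
      as.numeric(P %*% mo0$trajectories[i, f, ]) / fx0$px
    }, numeric(2))))
  }, numeric(1)))
  expect_lt(projmax, 0.05)
  # stiffness -> 0 with no temporal prior approaches independent fits
  mo_ind <- refine_particle_motion(lm0, fx0$sim$align, pos0, fx0$px,
                                   sigma_d = Inf, corr_length = 0)
  expect_true(is.finite(mo_ind$score))
})
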
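# Tilt-series refinement against the current average: optical parameters
# (defocus, astigmatism, higher-order Zernike aberrations, dose-damage
# scale factors) and geometry (rigid per-tilt alignment, spatially
# coherent per-particle 3D motion), all minimising the 2D tilt-image
# likelihood.
#
# The optical estimators condense all particles of a tilt image into a
# small set of per-frequency accumulators; writing the CTF at phase
# chi + delta as cos(delta) a + sin(delta) b with a = CTF(chi),
# b = -(sqrt(1-w^2) cos chi - w sin chi), every common phase perturbation
# delta(j) can be scored EXACTLY (equal to the direct per-particle sum)
# from the condensed images, because the per-particle defocus differences
# live inside chi_p and are already folded into the accumulators.

#' Condense one tilt image's particles for optical refinement
#'
#' Accumulates, per 2D frequency j (all divided by sigma_j^2):
#' `C = sum_p kappa e^{-i chi_p} Re(X_p conj(V_p))`,
#' `P2 = sum_p kappa^2 e^{-2 i chi_p} |V_p|^2`,
#' `P0 = sum_p kappa^2 |V_p|^2`,
#' `K = sum_p kappa c(chi_p) conj(X_p) V_p` (odd-aberration cross term),
#' `crossc = sum_p c Re(conj(X) V)` and `powc = sum_p c^2 |V|^2`
#' (kappa-free, for scale-factor fits), and the data power `X2`.
#' With these, the tilt-image likelihood under any common phase model is
#' recovered without revisiting particles.
#'
#' @param entries list, one per particle in this tilt image: `X` (complex
#'   crop transform), `pred` (CTF-free complex prediction slice, shift
#'   included), `chi` (CTF phase array), `kappa` (damage scale array)
#' @param amplitude_contrast the common amplitude contrast w
#' @param sigma2 noise power: scalar, per-shell vector, or full grid
#' @return object of class `condensed_pair`
#' @export
condense_tilt_image <- function(entries, amplitude_contrast, sigma2 = 1) {
  if (!length(entries)) stop("no particles in this tilt image")
  n <- nrow(entries[[1]]$X)
  sig <- expand_sigma_grid(sigma2, n)
  mask <- nyquist_mask(n, 2)
  w <- amplitude_contrast
  sbar <- sqrt(1 - w^2)
  C <- P2 <- matrix(0 + 0i, n, n)
  P0 <- X2 <- crossc <- powc <- matrix(0, n, n)
  K <- matrix(0 + 0i, n, n)
  for (e in entries) {
    kap <- if (is.null(e$kappa)) 1 else e$kappa
    reXV <- Re(e$X * Conj(e$pred))
    p2 <- Mod(e$pred)^2
    eic <- exp(-1i * e$chi)
    a <- -(sbar * sin(e$chi) + w * cos(e$chi))
    C <- C + kap * eic * reXV / sig
    P2 <- P2 + kap^2 * eic^2 * p2 / sig
    P0 <- P0 + kap^2 * p2 / sig
    K <- K + kap * a * Conj(e$X) * e$pred / sig
    crossc <- crossc + a * reXV / sig
    powc <- powc + a^2 * p2 / sig
    X2 <- X2 + Mod(e$X)^2 / sig
  }
  structure(list(C = C, P2 = P2, P0 = P0, K = K, crossc = crossc,
                 powc = powc, X2 = X2, w = w, sbar = sbar, n = n,
                 mask = mask, n_particles = length(entries)),
            class = "condensed_pair")
}

expand_sigma_grid <- function(sigma2, n) {
  if (length(sigma2) == 1) return(matrix(sigma2, n, n))
  if (is.matrix(sigma2)) return(sigma2)
  sh <- pmin(shell_index(n, 2), length(sigma2) - 1L) + 1L
  matrix(sigma2[sh], n, n)
}

#' Score a common phase perturbation from a condensed pair
#'
#' The exact tilt-image negative log-likelihood when every particle's CTF
#' phase is shifted by `delta(j)`:
#' `X2 + 2 Re[(w + i s) e^{-i delta} C] + (P0 + Re[(w + i s)^2 e^{-2 i
#' delta} P2]) / 2`, summed over the Nyquist-masked plane.
#'
#' @param cp a [condense_tilt_image()] result
#' @param delta phase perturbation: scalar or n x n array (radians)
#' @return scalar score (lower is better)
#' @export
condensed_score <- function(cp, delta = 0) {
  u <- complex(real = cp$w, imaginary = cp$sbar)
  ed <- exp(-1i * delta)
  val <- cp$X2 + 2 * Re(u * ed * cp$C) +
    0.5 * (cp$P0 + Re(u^2 * ed^2 * cp$P2))
  sum(val[cp$mask])
}

# frequency-squared grid (1/A^2) for a condensed pair
cp_j2 <- function(cp, pixel_size) {
  h <- freq_index(cp$n) / (cp$n * pixel_size)
  outer(h^2, h^2, `+`)
}

#' Single-pass defocus refinement for one tilt image
#'
#' Scans a grid of common defocus offsets (each offset shifts every
#' particle's chi by `pi lambda dz |j|^2`), scores via the condensed
#' pair, and parabola-fits the minimum. A minimum at the scan boundary is
#' flagged and the offset returned unrefined (0).
#'
#' @param cp a [condense_tilt_image()] result
#' @param lambda electron wavelength, Angstrom
#' @param pixel_size Angstrom/px
#' @param range search half-range, Angstrom
#' @param step scan step, Angstrom
#' @return list `delta_defocus` (Angstrom), `score`, `at_boundary`
#' @export
refine_defocus <- function(cp, lambda, pixel_size, range = 3000,
                           step = 100) {
  j2 <- cp_j2(cp, pixel_size)
  dzs <- seq(-range, range, by = step)
  scores <- vapply(dzs, function(dz) {
    condensed_score(cp, pi * lambda * dz * j2)
  }, numeric(1))
  b <- which.min(scores)
  if (b == 1 || b == length(dzs)) {
    return(list(delta_defocus = 0, score = scores[b], at_boundary = TRUE,
                scan = data.frame(dz = dzs, score = scores)))
  }
  # parabola through the three points around the minimum
  y <- scores[(b - 1):(b + 1)]
  denom <- y[1] - 2 * y[2] + y[3]
  frac <- if (abs(denom) > 0) 0.5 * (y[1] - y[3]) / denom else 0
  dz_hat <- dzs[b] + frac * step
  sc <- condensed_score(cp, pi * lambda * dz_hat * j2)
  if (sc > scores[b]) {  # keep the non-increasing guarantee
    dz_hat <- dzs[b]; sc <- scores[b]
  }
  list(delta_defocus = dz_hat, score = sc, at_boundary = FALSE,
       scan = data.frame(dz = dzs, score = scores))
}

# chi contribution of an astigmatic defocus ellipse
chi_astig <- function(du, dv, az_deg, lambda, jx, jy) {
  az <- atan2(jy, jx)
  a0 <- az_deg * pi / 180
  dz <- 0.5 * (du + dv) + 0.5 * (du - dv) * cos(2 * (az - a0))
  pi * lambda * dz * (jx^2 + jy^2)
}

#' Astigmatism refinement from a condensed pair
#'
#' Three-parameter (defocus_u, defocus_v, azimuth) local optimisation of
#' the condensed score, perturbing the current astigmatic ellipse.
#'
#' @param cp a [condense_tilt_image()] result, or a list of them (one
#'   per image of a tilt series) pooled by summation — the default
#'   per-series mode
#' @param params current [ctf_params()] (supplies the reference ellipse)
#' @param pixel_size Angstrom/px
#' @return list `defocus_u`, `defocus_v`, `azimuth` (in `[0, 180)`),
#'   `score`
#' @export
refine_astigmatism <- function(cp, params, pixel_size) {
  if (!inherits(cp, "condensed_pair")) cp <- pool_condensed(cp)
  lambda <- electron_wavelength(params$voltage_kv)
  h <- freq_index(cp$n) / (cp$n * pixel_size)
  jx <- matrix(h, cp$n, cp$n); jy <- t(jx)
  chi0 <- chi_astig(params$defocus_u, params$defocus_v,
                    params$astigmatism_azimuth, lambda, jx, jy)
  j2 <- jx^2 + jy^2
  az <- atan2(jy, jx)
  c2 <- cos(2 * az) * j2
  s2 <- sin(2 * az) * j2
  # Cartesian astigmatism parameters (mean defocus, cos/sin components):
  # removes the azimuth degeneracy of the (u, v, angle) form at zero
  # astigmatism
  obj <- function(par) {
    chi <- pi * lambda * (par[1] * j2 + par[2] * c2 + par[3] * s2)
    condensed_score(cp, chi - chi0)
  }
  a0 <- params$astigmatism_azimuth * pi / 180
  amp0 <- (params$defocus_u - params$defocus_v) / 2
  p0 <- c((params$defocus_u + params$defocus_v) / 2,
          amp0 * cos(2 * a0), amp0 * sin(2 * a0))
  s0 <- obj(p0)
  # coarse seed over the astigmatism components (the landscape is
  # oscillatory in defocus, so a pure local search can stall)
  seed_grid <- expand.grid(ac = seq(-300, 300, by = 75),
                           as = seq(-300, 300, by = 75))
  seed_scores <- mapply(function(ac, as) obj(c(p0[1], p0[2] + ac,
                                               p0[3] + as)),
                        seed_grid$ac, seed_grid$as)
  g <- which.min(seed_scores)
  p0g <- c(p0[1], p0[2] + seed_grid$ac[g], p0[3] + seed_grid$as[g])
  if (seed_scores[g] < s0) p0 <- p0g
  fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 600,
                                     parscale = c(100, 50, 50)))
  par <- if (fit$value <= s0) fit$par else p0
  amp <- sqrt(par[2]^2 + par[3]^2)
  azim <- (0.5 * atan2(par[3], par[2]) * 180 / pi) %% 180
  list(defocus_u = par[1] + amp, defocus_v = par[1] - amp,
       azimuth = azim, score = min(fit$value, s0))
}

#' Global Zernike aberration estimation from pooled condensed pairs
#'
#' Pools the condensed accumulators over the data set, derives the
#' per-frequency optimal phase error, and fits it to a Zernike basis by
#' weighted least squares. Even coefficients perturb chi; odd
#' coefficients describe the antisymmetric phase applied to predictions.
#'
#' @param cps list of [condense_tilt_image()] results (one per tilt
#'   image, pooled by summation)
#' @param max_order maximum Zernike radial order (3 covers coma/trefoil)
#' @param parity `"even"` or `"odd"`
#' @param pixel_size Angstrom/px
#' @return list `coefficients` (ordered as [zernike_indices()]),
#'   `indices`, `phase_map` (per-pixel optimum), `weights`
#' @export
estimate_aberrations <- function(cps, max_order = 3,
                                 parity = c("even", "odd"),
                                 pixel_size = 1) {
  parity <- match.arg(parity)
  pool <- pool_condensed(cps)
  n <- pool$n
  h <- freq_index(n) / (n * pixel_size)
  jx <- matrix(h, n, n); jy <- t(jx)
  nyq <- 1 / (2 * pixel_size)
  mask <- pool$mask
  B <- zernike_basis(max_order, jx, jy, nyq, parity)
  if (parity == "odd") {
    # model X ~ e^{i phi} c V: the per-pixel optimum is phi = -arg(K),
    # naturally weighted by |K| (which vanishes at CTF zeros)
    phase <- -Arg(pool$K)
    wgt <- Mod(pool$K)
    keep <- as.vector(mask) & as.vector(wgt) > 0
    Bk <- B[keep, , drop = FALSE]
    y <- as.vector(phase)[keep]
    wk <- as.vector(wgt)[keep]
    BtWB <- crossprod(Bk, Bk * wk)
    if (rcond_safe(BtWB) < 1e-10) {
      stop("rank-deficient aberration fit; unconstrained coefficients: ",
           paste(which(abs(diag(BtWB)) < 1e-12), collapse = ", "))
    }
    coefs <- as.numeric(solve(BtWB, crossprod(Bk, y * wk)))
  } else {
    # even terms shift chi itself; a per-pixel phase estimate rails at
    # CTF zeros, so minimise the condensed likelihood directly over the
    # coefficient vector (exact, zero-weighted at zeros by the model)
    phase <- NULL
    wgt <- pool$powc
    obj <- function(coef) {
      delta <- matrix(B %*% coef, n, n)
      condensed_score(pool, delta)
    }
    p0 <- numeric(ncol(B))
    fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000,
                                       parscale = rep(0.05, ncol(B)),
                                       reltol = 1e-10))
    coefs <- if (fit$value <= obj(p0)) fit$par else p0
  }
  list(coefficients = coefs, indices = attr(B, "indices"),
       phase_map = phase, weights = wgt)
}

# sum condensed pairs (linearity of the accumulators)
pool_condensed <- function(cps) {
  if (inherits(cps, "condensed_pair")) return(cps)
  pool <- cps[[1]]
  for (cp in cps[-1]) {
    for (f in c("C", "P2", "P0", "K", "crossc", "powc", "X2")) {
      pool[[f]] <- pool[[f]] + cp[[f]]
    }
    pool$n_particles <- pool$n_particles + cp$n_particles
  }
  pool
}

rcond_safe <- function(M) {
  tryCatch(1 / kappa(M), error = function(e) 0)
}

#' Per-tilt damage scale-factor estimation
#'
#' Fits `kappa_f(k) = s_f exp(-B_f k^2 / 4)` to the per-shell ratio of
#' the kappa-free cross term to the prediction power (an intensity-scale
#' invariant ratio); s is clipped to `[0, 1.5]`.
#'
#' @param cp a [condense_tilt_image()] result for one tilt image
#' @param pixel_size Angstrom/px
#' @param k_min lowest radial frequency used in the fit (1/A)
#' @return list `s`, `B`, `kappa_shells` (raw per-shell ratios),
#'   `clipped`
#' @export
estimate_scale_factors <- function(cp, pixel_size, k_min = 0.02) {
  n <- cp$n
  sh <- shell_index(n, 2)
  nshell <- n %/% 2 + 1
  idx <- pmin(sh, nshell - 1L) + 1L
  mask <- cp$mask
  cross_s <- tapply(cp$crossc[mask], idx[mask], sum)
  pow_s <- tapply(cp$powc[mask], idx[mask], sum)
  kappa <- rep(NA_real_, nshell)
  kappa[as.integer(names(cross_s))] <- cross_s / pmax(pow_s, 1e-30)
  k <- (seq_len(nshell) - 1) / (n * pixel_size)
  use <- is.finite(kappa) & kappa > 0.05 & k >= k_min
  clipped <- FALSE
  if (sum(use) < 3) {
    return(list(s = 1, B = 0, kappa_shells = kappa, clipped = TRUE))
  }
  wts <- as.numeric(pow_s[match(which(use), as.integer(names(pow_s)))])
  wts[!is.finite(wts)] <- 0
  fit <- stats::lm(log(kappa[use]) ~ I(k[use]^2), weights = wts)
  s <- exp(coef(fit)[1])
  B <- -4 * coef(fit)[2]
  if (s < 0) { s <- 0; clipped <- TRUE }
  if (s > 1.5) { s <- 1.5; clipped <- TRUE }
  list(s = as.numeric(s), B = as.numeric(B), kappa_shells = kappa,
       clipped = clipped)
}

# ---- geometry refinement --------------------------------------------------

#' Precompute a particle's 2D position likelihood in one tilt image
#'
#' The tilt-image negative log-likelihood as a function of an integer 2D
#' displacement of the particle, computed in one FFT:
#' `nll(d) = sum (|X|^2 + |P|^2)/sigma^2 - 2 Re sum (conj(X) P / sigma^2)
#' e^{-2 pi i j.d}`. Sub-pixel values are read off by bilinear
#' interpolation with [lookup_position_nll()].
#'
#' @param X complex crop transform
#' @param pred complex full prediction (CTF included, current shift
#'   included)
#' @param sigma2 noise power (scalar, shells or grid)
#' @return n x n matrix of nll values, displacement (0,0) at the centre
#'   (index n/2 + 1), class `position_likelihood`
#' @export
precompute_position_likelihood <- function(X, pred, sigma2 = 1) {
  n <- nrow(X)
  sig <- expand_sigma_grid(sigma2, n)
  mask <- nyquist_mask(n, 2)
  Y <- Conj(X) * pred / sig
  Y[!mask] <- 0
  const <- sum(((Mod(X)^2 + Mod(pred)^2) / sig)[mask])
  cc <- Re(stats::fft(Y))
  m <- const - 2 * fftshift(cc)
  structure(m, class = c("position_likelihood", "matrix"))
}

#' Interpolated position-likelihood lookup
#'
#' Catmull-Rom (bicubic) interpolation: a piecewise-linear lookup would
#' pin continuous optimisation to integer displacements, so a C1
#' interpolant that carries curvature between nodes is required.
#'
#' @param lmap a [precompute_position_likelihood()] map
#' @param d 2D displacement in pixels (sub-pixel allowed)
#' @return interpolated nll (edge values beyond the map)
#' @export
lookup_position_nll <- function(lmap, d) {
  n <- nrow(lmap)
  x <- d[1] + n / 2 + 1
  y <- d[2] + n / 2 + 1
  x <- min(max(x, 3), n - 2); y <- min(max(y, 3), n - 2)
  x0 <- floor(x); y0 <- floor(y)
  tx <- x - x0; ty <- y - y0
  cr_w <- function(t) {
    c(-0.5 * t + t^2 - 0.5 * t^3,
      1 - 2.5 * t^2 + 1.5 * t^3,
      0.5 * t + 2 * t^2 - 1.5 * t^3,
      -0.5 * t^2 + 0.5 * t^3)
  }
  wx <- cr_w(tx); wy <- cr_w(ty)
  block <- lmap[(x0 - 1):(x0 + 2), (y0 - 1):(y0 + 2)]
  as.numeric(wx %*% block %*% wy)
}

#' Rigid per-tilt alignment refinement
#'
#' For one tilt image, optimises a common in-plane rotation (about the
#' tomogram origin's projection) and 2D shift that minimise the summed
#' interpolated position likelihoods of all particles; other tilts are
#' untouched. Returns the identity update when fewer than `min_particles`
#' are available.
#'
#' @param lmaps list of [precompute_position_likelihood()] maps, one per
#'   particle in this tilt
#' @param positions_2d m x 2 matrix of projected particle positions
#'   (pixels, relative to the projected tomogram origin)
#' @param pixel_size Angstrom/px
#' @param shift_range integer shift half-range (px) for the initial scan
#' @param min_particles minimum particles required
#' @return list `psi` (degrees), `shift` (Angstrom), `score`
#' @export
refine_rigid_tilt_alignment <- function(lmaps, positions_2d, pixel_size,
                                        shift_range = 4,
                                        min_particles = 3) {
  m <- length(lmaps)
  if (m < min_particles) {
    warning("too few particles; skipping rigid alignment for this tilt")
    return(list(psi = 0, shift = c(0, 0), score = NA_real_,
                skipped = TRUE))
  }
  score <- function(psi, tx, ty) {
    a <- psi * pi / 180
    R2 <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)
    s <- 0
    for (i in seq_len(m)) {
      u <- positions_2d[i, ]
      d <- as.numeric(R2 %*% u) - u + c(tx, ty)
      s <- s + lookup_position_nll(lmaps[[i]], d)
    }
    s
  }
  # integer-shift scan at zero rotation, then continuous polish
  grid <- expand.grid(tx = -shift_range:shift_range,
                      ty = -shift_range:shift_range)
  gscore <- mapply(function(tx, ty) score(0, tx, ty), grid$tx, grid$ty)
  g0 <- which.min(gscore)
  p0 <- c(0, grid$tx[g0], grid$ty[g0])
  s0 <- gscore[g0]
  fit <- stats::optim(p0, function(p) score(p[1], p[2], p[3]),
                      method = "Nelder-Mead",
                      control = list(maxit = 400,
                                     parscale = c(0.2, 0.5, 0.5)))
  if (fit$value <= s0) {
    list(psi = fit$par[1], shift = fit$par[2:3] * pixel_size,
         score = fit$value, skipped = FALSE)
  } else {
    list(psi = 0, shift = p0[2:3] * pixel_size, score = s0,
         skipped = FALSE)
  }
}

#' Spatially coherent per-particle 3D motion refinement
#'
#' Estimates a 3D trajectory per particle over the tilt series
#' (acquisition order) by minimising the summed interpolated position
#' likelihoods of all particles and tilts plus a Gaussian-process-style
#' prior that couples the per-increment displacements of spatially close
#' particles (kernel `exp(-|x_p - x_q| / L)`), independent per
#' tilt-to-tilt increment.
#'
#' `corr_length = Inf` ties all particles to one common trajectory (the
#' infinitely stiff limit); `sigma_d = Inf` removes the temporal penalty
#' so every tilt is fitted independently.
#'
#' @param lmaps list over particles of lists over tilts of position
#'   likelihood maps
#' @param align a [tilt_alignment()] (supplies projections and
#'   acquisition order)
#' @param positions n_p x 3 particle positions (Angstrom)
#' @param pixel_size Angstrom/px
#' @param sigma_d prior sd of per-increment displacement, Angstrom
#'   (default 1)
#' @param corr_length spatial correlation length of the prior, Angstrom
#'   (default 500)
#' @param maxit optimiser budget
#' @return list `trajectories` (n_p x n_f x 3 array, Angstrom),
#'   `score`, `converged`
#' @export
refine_particle_motion <- function(lmaps, align, positions, pixel_size,
                                   sigma_d = 1, corr_length = 500,
                                   maxit = 400) {
  np <- length(lmaps)
  nf <- align$n_tilts
  ord <- order(align$order)       # tilt indices in acquisition order
  shared <- is.infinite(corr_length)
  npar_p <- if (shared) 1L else np
  # prior precision over particles, per axis and increment
  if (!shared && is.finite(sigma_d)) {
    Dm <- as.matrix(stats::dist(positions))
    Km <- exp(-Dm / max(corr_length, 1e-6)) + diag(1e-8, np)
    Kinv <- solve(Km)
  } else {
    Kinv <- diag(1, npar_p)
  }
  proj <- lapply(seq_len(nf), function(f) {
    align$rotations[[f]][1:2, , drop = FALSE]
  })
  unpack <- function(par) array(par, c(npar_p, nf, 3))
  obj <- function(par) {
    Tr <- unpack(par)
    s <- 0
    for (ip in seq_len(np)) {
      tp <- if (shared) 1L else ip
      for (f in seq_len(nf)) {
        d2 <- as.numeric(proj[[f]] %*% Tr[tp, f, ]) / pixel_size
        s <- s + lookup_position_nll(lmaps[[ip]][[f]], d2)
      }
    }
    if (is.finite(sigma_d)) {
      for (r in 2:nf) {
        f1 <- ord[r]; f0 <- ord[r - 1]
        for (ax in 1:3) {
          d <- Tr[, f1, ax] - Tr[, f0, ax]
          s <- s + as.numeric(d %*% Kinv %*% d) / (2 * sigma_d^2)
        }
      }
    }
    # tiny ridge: keeps the along-beam component bounded
    s + 1e-6 * sum(par^2)
  }
  p0 <- numeric(npar_p * nf * 3)
  s0 <- obj(p0)
  fit <- stats::optim(p0, obj, method = "BFGS",
                      control = list(maxit = maxit))
  converged <- fit$convergence == 0
  if (!converged) {
    warning("motion refinement did not fully converge; ",
            "returning best iterate")
  }
  best <- if (fit$value <= s0) fit$par else p0
  Tr <- unpack(best)
  out <- array(0, c(np, nf, 3))
  for (ip in seq_len(np)) {
    out[ip, , ] <- Tr[if (shared) 1L else ip, , ]
  }
  list(trajectories = out, score = min(fit$value, s0),
       converged = converged)
}
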
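# Contrast transfer function model: astigmatic defocus, phase shift,
# even/odd Zernike aberrations and dose-dependent damage envelopes.

#' Relativistic electron wavelength
#'
#' De Broglie wavelength with the relativistic correction,
#' `lambda = 12.2639 / sqrt(V + 0.97845e-6 V^2)` Angstrom (V in volts).
#'
#' @param voltage_kv acceleration voltage in kV
#' @return wavelength in Angstrom
#' @export
electron_wavelength <- function(voltage_kv) {
  stopifnot(all(voltage_kv > 0))
  v <- voltage_kv * 1000
  12.2639 / sqrt(v + 0.97845e-6 * v^2)
}

#' CTF parameter set
#'
#' Per-tilt, per-particle optical parameters. Defocus is positive for
#' underfocus; astigmatism is described by two defoci and the azimuth of
#' the `defocus_u` axis. Even Zernike coefficients add to the phase
#' function chi; odd coefficients describe antisymmetric aberrations
#' applied as a unit-modulus phase factor on complex predictions.
#'
#' @param voltage_kv kV (> 0)
#' @param cs spherical aberration, mm
#' @param amplitude_contrast fraction in `[0, 1]`
#' @param defocus_u,defocus_v defoci along the astigmatism axes, Angstrom
#' @param astigmatism_azimuth azimuth of the u axis, degrees
#' @param phase_shift additional phase shift, radians
#' @param zernike_even,zernike_odd coefficient vectors (radians at
#'   Nyquist-scaled radius 1) matching [zernike_basis()] ordering
#' @param scale per-tilt damage scale `kappa(k)`: either NULL (use the
#'   dose-driven fallback), a function of `k` (1/Angstrom), or a
#'   `c(s, B)` pair for `s * exp(-B k^2 / 4)`
#' @return object of class `ctf_params`
#' @export
ctf_params <- function(voltage_kv = 300, cs = 2.7, amplitude_contrast = 0.07,
                       defocus_u = 20000, defocus_v = defocus_u,
                       astigmatism_azimuth = 0, phase_shift = 0,
                       zernike_even = numeric(), zernike_odd = numeric(),
                       scale = NULL) {
  stopifnot(voltage_kv > 0, amplitude_contrast >= 0,
            amplitude_contrast <= 1)
  structure(list(voltage_kv = voltage_kv, cs = cs,
                 amplitude_contrast = amplitude_contrast,
                 defocus_u = defocus_u, defocus_v = defocus_v,
                 astigmatism_azimuth = astigmatism_azimuth,
                 phase_shift = phase_shift,
                 zernike_even = zernike_even, zernike_odd = zernike_odd,
                 scale = scale),
            class = "ctf_params")
}

# frequency grids (1/Angstrom) for an n x n crop
freq_grid_2d <- function(n, pixel_size) {
  h <- freq_index(n) / (n * pixel_size)
  list(jx = matrix(h, n, n), jy = matrix(h, n, n, byrow = TRUE))
}

#' CTF phase function chi at 2D frequencies
#'
#' `chi(j) = pi lambda dz(alpha) |j|^2 - (pi/2) Cs lambda^3 |j|^4 +
#' phase_shift + sum(z_even * basis(j))` with `dz` the astigmatic defocus
#' ellipse. Frequencies in 1/Angstrom.
#'
#' @param params a [ctf_params()]
#' @param jx,jy frequency components, 1/Angstrom (vectors/matrices)
#' @param nyquist Nyquist frequency (1/Angstrom) used to scale the Zernike
#'   disk; required when even Zernike coefficients are present
#' @return phase in radians, same shape as `jx`
#' @export
ctf_phase <- function(params, jx, jy, nyquist = NULL) {
  lambda <- electron_wavelength(params$voltage_kv)
  j2 <- jx^2 + jy^2
  az <- atan2(jy, jx)
  a0 <- params$astigmatism_azimuth * pi / 180
  dz <- 0.5 * (params$defocus_u + params$defocus_v) +
        0.5 * (params$defocus_u - params$defocus_v) * cos(2 * (az - a0))
  cs_A <- params$cs * 1e7
  chi <- pi * lambda * dz * j2 - (pi / 2) * cs_A * lambda^3 * j2^2 +
         params$phase_shift
  if (length(params$zernike_even)) {
    if (is.null(nyquist)) stop("nyquist needed for Zernike evaluation")
    zb <- zernike_eval(params$zernike_even, jx, jy, nyquist,
                       parity = "even")
    chi <- chi + zb
  }
  chi
}

#' Evaluate the (real) CTF on a frequency grid
#'
#' `CTF(j) = -(sqrt(1 - w^2) sin chi + w cos chi) * kappa(|j|)`, negative
#' at low frequency for underfocus. Odd Zernike terms do not enter here;
#' they modulate complex predictions via [odd_aberration_phase()].
#'
#' @inheritParams ctf_phase
#' @param dose accumulated dose (e/A^2) used by the damage fallback when
#'   no fitted scale is present
#' @return real array of CTF values
#' @export
evaluate_ctf <- function(params, jx, jy, nyquist = NULL, dose = 0) {
  chi <- ctf_phase(params, jx, jy, nyquist)
  w <- params$amplitude_contrast
  ctf <- -(sqrt(1 - w^2) * sin(chi) + w * cos(chi))
  k <- sqrt(jx^2 + jy^2)
  ctf * ctf_scale(params, k, dose)
}

#' Damage/scale envelope kappa(k) for one tilt
#' @param params a [ctf_params()]
#' @param k radial frequency, 1/Angstrom
#' @param dose accumulated dose, e/A^2
#' @return values in `[0, 1.5]`
#' @export
ctf_scale <- function(params, k, dose = 0) {
  s <- params$scale
  if (is.null(s)) return(dose_damage_weight(k, dose))
  if (is.function(s)) return(s(k))
  s[1] * exp(-s[2] * k^2 / 4)
}

#' Dose-dependent damage weight
#'
#' Parametric fallback `exp(-dose / (2 (0.245 k^-1.665 + 2.81)))` built on
#' the standard frequency-dependent critical-exposure curve; used when no
#' fitted per-tilt scale is available.
#'
#' @param k radial frequency, 1/Angstrom
#' @param dose accumulated dose, e/A^2
#' @return weight in `[0, 1]`
#' @export
dose_damage_weight <- function(k, dose) {
  stopifnot(all(dose >= 0))
  kc <- pmax(k, 1e-6)
  exp(-dose / (2 * (0.245 * kc^-1.665 + 2.81)))
}

#' Defocus of a particle in one tilt image
#'
#' The tilt image's base defocus plus the signed depth of the particle
#' along the beam: `defocus = base - handedness * z_camera`, where
#' `z_camera` is the third component of the tilt rotation applied to the
#' particle position. With the default handedness (+1), a particle 500 A
#' above the tilt-axis plane at zero tilt is 500 A less underfocused.
#'
#' @param base_defocus tilt-image defocus at the tilt axis plane, Angstrom
#' @param position particle 3D position (Angstrom, tomogram centre origin)
#' @param align a [tilt_alignment()]
#' @param f tilt index
#' @param handedness +1 or -1 global sign flag
#' @return defocus in Angstrom
#' @export
defocus_at_particle <- function(base_defocus, position, align, f,
                                handedness = 1) {
  z <- as.numeric(align$rotations[[f]][3, ] %*% position)
  base_defocus - handedness * z
}

# ---- Zernike polynomials --------------------------------------------------

# radial polynomial R_n^m (unnormalised), m >= 0, n - m even
zernike_radial <- function(n, m, rho) {
  s <- 0
  out <- 0 * rho
  for (k in 0:((n - m) / 2)) {
    c_k <- (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + m) / 2 - k) *
       factorial((n - m) / 2 - k))
    out <- out + c_k * rho^(n - 2 * k)
  }
  out
}

#' Zernike basis on a frequency disk
#'
#' Standard (unnormalised) Zernike polynomials `Z_n^m` evaluated on
#' frequencies scaled so the unit disk edge sits at Nyquist. `parity`
#' selects even (n even: symmetric aberrations) or odd (n odd:
#' antisymmetric) members up to `max_order`.
#'
#' @param max_order maximum radial order n
#' @param parity `"even"` or `"odd"`
#' @return data.frame of `(n, m)` index pairs (m signed: negative = sine
#'   term), one row per basis member, in a fixed order
#' @export
zernike_indices <- function(max_order, parity = c("even", "odd")) {
  parity <- match.arg(parity)
  rows <- list()
  for (n in 0:max_order) {
    if ((parity == "even" && n %% 2 != 0) ||
        (parity == "odd" && n %% 2 != 1)) next
    for (m in seq(-n, n, by = 2)) {
      rows[[length(rows) + 1L]] <- c(n = n, m = m)
    }
  }
  as.data.frame(do.call(rbind, rows))
}

#' Evaluate a Zernike expansion at 2D frequencies
#' @param coef coefficient vector ordered as [zernike_indices()]
#' @param jx,jy frequencies, 1/Angstrom
#' @param nyquist Nyquist frequency, 1/Angstrom (disk edge)
#' @param parity `"even"` or `"odd"`
#' @return array of phase values (radians)
#' @export
zernike_eval <- function(coef, jx, jy, nyquist, parity = "even") {
  idx <- zernike_indices_for(length(coef), parity)
  rho <- sqrt(jx^2 + jy^2) / nyquist
  theta <- atan2(jy, jx)
  out <- 0 * rho
  for (i in seq_len(nrow(idx))) {
    out <- out + coef[i] * zernike_one(idx$n[i], idx$m[i], rho, theta)
  }
  out
}

zernike_one <- function(n, m, rho, theta) {
  r <- zernike_radial(n, abs(m), rho)
  if (m > 0) r * cos(m * theta)
  else if (m < 0) r * sin(-m * theta)
  else r
}

# index table truncated/validated to a coefficient count
zernike_indices_for <- function(ncoef, parity) {
  ord <- 0
  repeat {
    idx <- zernike_indices(ord, parity)
    if (nrow(idx) >= ncoef) break
    ord <- ord + 1
    if (ord > 20) stop("coefficient vector too long")
  }
  idx[seq_len(ncoef), , drop = FALSE]
}

#' Zernike basis matrix on a 2D frequency grid
#'
#' One column per `(n, m)` member of [zernike_indices()], evaluated at the
#' supplied frequencies; used for least-squares aberration fits.
#'
#' @param max_order maximum radial order
#' @param jx,jy frequencies, 1/Angstrom
#' @param nyquist Nyquist frequency
#' @param parity `"even"` or `"odd"`
#' @return matrix, `length(jx)` rows
#' @export
zernike_basis <- function(max_order, jx, jy, nyquist,
                          parity = c("even", "odd")) {
  parity <- match.arg(parity)
  idx <- zernike_indices(max_order, parity)
  rho <- sqrt(as.vector(jx)^2 + as.vector(jy)^2) / nyquist
  theta <- atan2(as.vector(jy), as.vector(jx))
  B <- vapply(seq_len(nrow(idx)), function(i) {
    zernike_one(idx$n[i], idx$m[i], rho, theta)
  }, numeric(length(rho)))
  attr(B, "indices") <- idx
  B
}

#' Phase factor of antisymmetric (odd) aberrations
#'
#' Unit-modulus factor `exp(i phi_odd(j))` to be multiplied onto complex
#' predictions; does not change the CTF modulus.
#'
#' @inheritParams ctf_phase
#' @return complex array
#' @export
odd_aberration_phase <- function(params, jx, jy, nyquist) {
  if (!length(params$zernike_odd)) return(array(1 + 0i, dim = dim(jx)))
  phi <- zernike_eval(params$zernike_odd, jx, jy, nyquist, parity = "odd")
  exp(1i * phi)
}
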
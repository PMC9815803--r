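# Assembly of per-tilt-image particle entries (observation, CTF-free
# prediction, CTF phase, damage scale) used by the condensed optical
# refinements and the position-likelihood geometry refinements.

#' Build per-tilt refinement entries from particles and a reference
#'
#' For every tilt image f and particle p: the observed crop transform,
#' the CTF-free predicted slice (particle pose composed with the tilt
#' alignment, shift phases included), the CTF phase surface chi at the
#' particle's depth-dependent defocus, the damage scale kappa, and the
#' full CTF.
#'
#' @param particles list; each element has `crops` (per-tilt list with
#'   `ft`), `rotation` (3x3 pose) and `position` (Angstrom)
#' @param V complex reference transform
#' @param align a [tilt_alignment()]
#' @param defocus base defocus per tilt image, Angstrom
#' @param optics list with `voltage_kv`, `cs`, `amplitude_contrast`, and
#'   optionally `zernike_even`, `zernike_odd`, `phase_shift`
#' @param pixel_size Angstrom/px
#' @param apply_damage evaluate the dose-damage envelope from the
#'   alignment's accumulated dose
#' @return list over tilts; each element is a list over particles of
#'   entries `X`, `pred`, `chi`, `kappa`, `ctf`; frequency grids in
#'   attributes `jx`, `jy`, `nyquist`
#' @export
make_tilt_entries <- function(particles, V, align, defocus, optics,
                              pixel_size = 1, apply_damage = TRUE) {
  n2 <- nrow(particles[[1]]$crops[[1]]$ft)
  h <- freq_index(n2) / (n2 * pixel_size)
  jx <- matrix(h, n2, n2); jy <- t(jx)
  nyq <- 1 / (2 * pixel_size)
  nf <- align$n_tilts
  defocus <- rep_len(defocus, nf)
  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    out[[f]] <- lapply(particles, function(p) {
      cr <- p$crops[[f]]
      if (!is.null(cr$visible) && !cr$visible) return(NULL)
      pose <- particle_pose(p$rotation, n_tilts = nf)
      mp <- compose_projection(pose, align, f)
      pred <- project_map_slice(V, mp, n2, pixel_size)
      dz <- defocus_at_particle(defocus[f], p$position, align, f)
      pars <- ctf_params(voltage_kv = optics$voltage_kv, cs = optics$cs,
                         amplitude_contrast = optics$amplitude_contrast,
                         defocus_u = dz, defocus_v = dz +
                           (optics$defocus_v_offset %||% 0),
                         astigmatism_azimuth =
                           optics$astigmatism_azimuth %||% 0,
                         phase_shift = optics$phase_shift %||% 0,
                         zernike_even = optics$zernike_even %||%
                           numeric(),
                         zernike_odd = optics$zernike_odd %||% numeric())
      chi <- ctf_phase(pars, jx, jy, nyq)
      kap <- if (apply_damage) {
        dose_damage_weight(sqrt(jx^2 + jy^2), align$dose[f])
      } else matrix(1, n2, n2)
      w <- optics$amplitude_contrast
      ctf <- -(sqrt(1 - w^2) * sin(chi) + w * cos(chi)) * kap
      if (length(pars$zernike_odd)) {
        pred <- pred * odd_aberration_phase(pars, jx, jy, nyq)
      }
      list(X = cr$ft, pred = pred, chi = chi, kappa = kap, ctf = ctf)
    })
    out[[f]] <- Filter(Negate(is.null), out[[f]])
  }
  attr(out, "jx") <- jx
  attr(out, "jy") <- jy
  attr(out, "nyquist") <- nyq
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
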
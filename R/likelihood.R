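# Likelihood evaluation and pose search.
#
# nll_2d is the exact 2D tilt-image data model (per-pixel Gaussian noise
# in Fourier space, summed over all tilt images); nll_pseudo is its
# pseudo-subtomogram approximation, a sum over 3D voxels weighted by the
# multiplicity M and per-shell noise power. The two agree exactly when
# the forward mapping is trivial (single tilt, on-grid) and to a few
# percent for general tilt geometries.

#' Exact 2D tilt-series negative log-likelihood
#'
#' `sum_{f,j} |X_fj - CTF_f(j) V_fj|^2 / sigma_j^2` with `V_fj` the
#' phase-shifted central section of the reference under the composed
#' particle/tilt mapping. This is the reference implementation the
#' pseudo-subtomogram likelihood approximates.
#'
#' @param crops list per tilt: `ft` (complex crop transform), `ctf`,
#'   optional `visible`
#' @param V complex 3D reference transform (centre-origin)
#' @param pose a [particle_pose()] hypothesis
#' @param align a [tilt_alignment()]
#' @param sigma2 noise power per 2D radial shell (length n/2 + 1)
#' @param pixel_size Angstrom/px
#' @return scalar negative log-likelihood (2 x the Gaussian exponent)
#' @export
nll_2d <- function(crops, V, pose, align, sigma2, pixel_size = 1) {
  n2 <- nrow(crops[[1]]$ft)
  sh <- shell_index(n2, 2) + 1L
  mask <- nyquist_mask(n2, 2)
  if (any(sigma2[unique(sh[mask])] <= 0, na.rm = TRUE)) {
    stop("zero noise power in a populated shell")
  }
  sig <- matrix(sigma2[pmin(sh, length(sigma2))], n2, n2)
  total <- 0
  for (f in seq_along(crops)) {
    cr <- crops[[f]]
    if (!is.null(cr$visible) && !cr$visible) next
    mp <- compose_projection(pose, align, f)
    pred <- project_map_slice(V, mp, n2, pixel_size) * cr$ctf
    d2 <- Mod(cr$ft - pred)^2
    total <- total + sum((d2 / sig)[mask])
  }
  total
}

#' Pseudo-subtomogram negative log-likelihood
#'
#' `sum_k |D_k - W_k V(R k) e^{-2 pi i k.s}|^2 / (M_k sigma_k^2)` over
#' voxels with multiplicity at or above `m_threshold`.
#'
#' @param ps a `pseudo_subtomogram`
#' @param V complex 3D reference transform
#' @param rotation 3x3 matrix mapping pseudo-frame vectors into the
#'   reference frame (the pose hypothesis R_p)
#' @param sigma2 noise power per 3D radial shell
#' @param shift 3D translation offset in Angstrom
#' @param m_threshold voxels with `M` below this are excluded (default
#'   0.05; near-empty voxels carry unreliable statistics)
#' @return scalar negative log-likelihood
#' @export
nll_pseudo <- function(ps, V, rotation, sigma2, shift = c(0, 0, 0),
                       m_threshold = 0.05) {
  nv <- dim(V)[1]
  scale <- nv / ps$box
  cpp_nll_pseudo(ps$D, ps$W, ps$M, ps$box, V, nv, rotation * scale,
                 shift / ps$pixel_size, sigma2, m_threshold)
}

#' Gaussian pose prior
#'
#' @param centre a [particle_pose()] (or Euler triple) giving the prior
#'   centre; shifts centre at zero offset
#' @param sigma_angles Gaussian sigma per Euler angle, degrees (Inf =
#'   uniform)
#' @param sigma_shift Gaussian sigma per translation axis, Angstrom
#' @return object of class `orientation_prior`
#' @export
orientation_prior <- function(centre = c(0, 0, 0),
                              sigma_angles = c(Inf, Inf, Inf),
                              sigma_shift = c(Inf, Inf, Inf)) {
  if (is.numeric(centre) && length(centre) == 3) {
    centre_angles <- centre
  } else {
    centre_angles <- matrix_to_euler(centre$rotation)
  }
  stopifnot(all(sigma_angles > 0), all(sigma_shift > 0))
  structure(list(centre = centre_angles,
                 sigma_angles = rep_len(sigma_angles, 3),
                 sigma_shift = rep_len(sigma_shift, 3)),
            class = "orientation_prior")
}

#' Negative log prior of a pose
#'
#' `sum((d_angle / sigma)^2) / 2 + sum((d_shift / sigma)^2) / 2` with
#' angular differences wrapped into (-180, 180]. Infinite sigmas
#' contribute zero.
#'
#' @param angles Euler triple (rot, tilt, psi), degrees
#' @param shift 3D shift, Angstrom
#' @param prior an [orientation_prior()]
#' @return scalar
#' @export
pose_prior_nll <- function(angles, shift, prior) {
  da <- wrap_angle(angles - prior$centre)
  a <- ifelse(is.finite(prior$sigma_angles),
              (da / prior$sigma_angles)^2, 0)
  s <- ifelse(is.finite(prior$sigma_shift),
              (shift / prior$sigma_shift)^2, 0)
  sum(a) / 2 + sum(s) / 2
}

#' Exhaustive pose grid search under a Gaussian prior
#'
#' Evaluates `nll_pseudo + pose_prior_nll` on a uniform Euler grid within
#' +/- 3 sigma of the prior centre (full circle for infinite sigma) and a
#' translation grid handled by phase ramps. Returns the MAP pose and
#' softmax (marginal) weights stabilised with log-sum-exp; ties break to
#' the lowest linear grid index.
#'
#' @param ps a `pseudo_subtomogram`
#' @param V reference transform
#' @param prior an [orientation_prior()]
#' @param angular_step grid step, degrees (> 0)
#' @param trans_range translation half-range, Angstrom (0 = no search)
#' @param trans_step translation step, Angstrom
#' @param sigma2 per-shell noise power
#' @param m_threshold multiplicity cutoff
#' @return list: `map_pose` (angles, shift, nll), `grid` (data.frame of
#'   hypotheses with weights)
#' @export
grid_search_pose <- function(ps, V, prior, angular_step, trans_range = 0,
                             trans_step = 1, sigma2,
                             m_threshold = 0.05) {
  stopifnot(angular_step > 0)
  axis_grid <- function(centre, sig) {
    if (is.finite(sig)) {
      half <- min(3 * sig, 180)
      centre + seq(-half, half, by = angular_step)
    } else {
      seq(0, 360 - angular_step, by = angular_step)
    }
  }
  rots <- axis_grid(prior$centre[1], prior$sigma_angles[1])
  tilts <- axis_grid(prior$centre[2], prior$sigma_angles[2])
  psis <- axis_grid(prior$centre[3], prior$sigma_angles[3])
  # uniform tilt grid is restricted to [0, 180]
  if (!is.finite(prior$sigma_angles[2])) {
    tilts <- tilts[tilts <= 180]
  }
  ts <- if (trans_range > 0) seq(-trans_range, trans_range,
                                 by = trans_step) else 0
  hyp <- expand.grid(rot = rots, tilt = tilts, psi = psis,
                     sx = ts, sy = ts, sz = ts,
                     KEEP.OUT.ATTRS = FALSE)
  if (!nrow(hyp)) stop("empty pose grid")
  nll <- numeric(nrow(hyp))
  for (i in seq_len(nrow(hyp))) {
    R <- euler_to_matrix(hyp$rot[i], hyp$tilt[i], hyp$psi[i])
    sh <- c(hyp$sx[i], hyp$sy[i], hyp$sz[i])
    nll[i] <- nll_pseudo(ps, V, R, sigma2, sh, m_threshold) +
      pose_prior_nll(c(hyp$rot[i], hyp$tilt[i], hyp$psi[i]), sh, prior)
  }
  # log-sum-exp softmax; ties to the lowest linear index
  z <- -(nll - min(nll))
  wgt <- exp(z) / sum(exp(z))
  best <- which(nll == min(nll))[1]
  hyp$nll <- nll
  hyp$weight <- wgt
  list(map_pose = list(angles = c(hyp$rot[best], hyp$tilt[best],
                                  hyp$psi[best]),
                       shift = c(hyp$sx[best], hyp$sy[best], hyp$sz[best]),
                       nll = nll[best]),
       grid = hyp)
}

#' Continuous local pose refinement
#'
#' Derivative-free (Nelder-Mead) polish of `nll_pseudo + prior` over the
#' three Euler angles and the 3D shift, started from a grid-search pose.
#' Never returns a pose worse than the start.
#'
#' @param ps a `pseudo_subtomogram`
#' @param V reference transform
#' @param start list with `angles` (degrees) and `shift` (Angstrom)
#' @param sigma2 per-shell noise power
#' @param prior optional [orientation_prior()]
#' @param m_threshold multiplicity cutoff
#' @param maxit optimiser iteration budget
#' @return list `angles`, `shift`, `nll`
#' @export
local_refine_pose <- function(ps, V, start, sigma2, prior = NULL,
                              m_threshold = 0.05, maxit = 200) {
  obj <- function(par) {
    v <- nll_pseudo(ps, V, euler_to_matrix(par[1], par[2], par[3]),
                    sigma2, par[4:6], m_threshold)
    if (!is.null(prior)) {
      v <- v + pose_prior_nll(par[1:3], par[4:6], prior)
    }
    v
  }
  p0 <- c(start$angles, start$shift)
  v0 <- obj(p0)
  # parscale sets the initial simplex to a few degrees / Angstrom
  # regardless of the absolute angle values; a restart tightens the
  # final simplex
  best <- list(par = p0, value = v0)
  for (r in 1:2) {
    fit <- stats::optim(best$par, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit,
                                       parscale = c(30, 30, 30,
                                                    10, 10, 10) / r))
    if (fit$value < best$value) best <- fit
  }
  if (best$value <= v0) {
    list(angles = best$par[1:3], shift = best$par[4:6],
         nll = best$value)
  } else {
    list(angles = start$angles, shift = start$shift, nll = v0)
  }
}
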
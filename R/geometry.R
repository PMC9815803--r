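# Pose algebra: Euler conventions, tilt/particle transform composition and
# Fourier-slice extraction.
#
# Frame conventions
# -----------------
# * tilt_alignment stores, per tilt image f, the full 3x3 rotation B_f that
#   maps tomogram-frame coordinates into camera (image) coordinates, plus a
#   2D image shift t_f (Angstrom) and the nominal stage angle. The camera
#   z-axis is the beam direction.
# * A particle pose stores the rotation R_p mapping tomogram-frame vectors
#   into the reference-map frame, a 3D position (Angstrom, relative to the
#   tomogram centre) and optional per-tilt 3D offsets T_pf (Angstrom).
# * The composed projection for particle p in tilt f is the 2x3 matrix
#   A_pf = P_f R_p^T (P_f = first two rows of B_f) with 2D shift
#   t_pf = P_f T_pf + t_f: the 3D reference-frame frequency sampled at 2D
#   image frequency j is t(A_pf) %*% j.

#' Rotation matrix from ZYZ Euler angles (degrees)
#'
#' RELION's Euler convention: `R = Rz(psi) Ry(tilt) Rz(rot)`, mapping
#' reference-frame vectors into the rotated (particle/image) frame. Angles in
#' degrees.
#'
#' @param rot,tilt,psi Euler angles in degrees
#' @return 3x3 orthonormal matrix with determinant +1
#' @export
euler_to_matrix <- function(rot, tilt, psi) {
  rz <- function(a) {
    a <- a * pi / 180
    matrix(c(cos(a), -sin(a), 0,
             sin(a),  cos(a), 0,
             0, 0, 1), 3, 3)
  }
  ry <- function(a) {
    a <- a * pi / 180
    matrix(c(cos(a), 0, -sin(a),
             0, 1, 0,
             sin(a), 0, cos(a)), 3, 3)
  }
  rz(psi) %*% ry(tilt) %*% rz(rot)
}

#' Euler angles (degrees) from a rotation matrix
#'
#' Inverse of [euler_to_matrix()] up to the gimbal degeneracy at tilt 0 or
#' 180 degrees, where `rot` is set to 0 and the in-plane angle is absorbed
#' into `psi`.
#'
#' @param R 3x3 rotation matrix
#' @return numeric vector `c(rot, tilt, psi)` in degrees
#' @export
matrix_to_euler <- function(R) {
  tilt <- acos(max(-1, min(1, R[3, 3]))) * 180 / pi
  if (abs(sin(tilt * pi / 180)) < 1e-10) {
    # gimbal degeneracy: only rot + psi (tilt 0) or psi - rot (tilt 180)
    # is defined; absorb everything into psi
    rot <- 0
    if (R[3, 3] > 0) {
      psi <- atan2(R[1, 2], R[1, 1]) * 180 / pi
    } else {
      psi <- atan2(R[1, 2], -R[1, 1]) * 180 / pi
    }
  } else {
    rot <- atan2(-R[3, 2], -R[3, 1]) * 180 / pi
    psi <- atan2(-R[2, 3], R[1, 3]) * 180 / pi
  }
  c(rot = rot, tilt = tilt, psi = psi)
}

#' Tilt-series alignment object
#'
#' One entry per tilt image: full 3x3 rotation mapping tomogram coordinates
#' into camera coordinates, 2D image shift in Angstrom, nominal stage angle
#' (degrees) and acquisition order index.
#'
#' @param angles nominal stage tilt angles (degrees), one per image; the
#'   stage rotation is about the camera y axis
#' @param order acquisition order (1-based permutation); default stage order
#' @param psi in-plane rotation per image (degrees, about the beam)
#' @param shifts n x 2 matrix of image shifts (Angstrom)
#' @param dose accumulated dose at each image (e/A^2), in stage-angle order
#' @return object of class `tilt_alignment`
#' @export
tilt_alignment <- function(angles, order = seq_along(angles), psi = 0,
                           shifts = NULL, dose = NULL) {
  nf <- length(angles)
  psi <- rep_len(psi, nf)
  if (is.null(shifts)) shifts <- matrix(0, nf, 2)
  if (is.null(dose)) dose <- rep(0, nf)
  rots <- lapply(seq_len(nf), function(f) {
    euler_to_matrix(0, angles[f], psi[f])
  })
  structure(list(angles = angles, psi = psi, rotations = rots,
                 shifts = shifts, order = as.integer(order), dose = dose,
                 n_tilts = nf),
            class = "tilt_alignment")
}

#' Apply a rigid update to one tilt of an alignment
#'
#' Composes an additional in-plane rotation (degrees, about the beam)
#' and image shift (Angstrom) onto tilt `f`.
#'
#' @param align a [tilt_alignment()]
#' @param f tilt index
#' @param dpsi in-plane rotation increment, degrees
#' @param dshift length-2 shift increment, Angstrom
#' @return the updated alignment
#' @export
update_tilt_alignment <- function(align, f, dpsi = 0, dshift = c(0, 0)) {
  align$psi[f] <- align$psi[f] + dpsi
  align$rotations[[f]] <- euler_to_matrix(0, align$angles[f],
                                          align$psi[f])
  align$shifts[f, ] <- align$shifts[f, ] + dshift
  align
}

#' Particle pose
#'
#' @param rotation 3x3 matrix mapping tomogram-frame vectors into the
#'   reference frame, or a length-3 Euler triple (rot, tilt, psi, degrees)
#' @param position 3D position in Angstrom relative to the tomogram centre
#' @param offsets optional n_tilts x 3 matrix of per-tilt 3D offsets T_pf
#'   (Angstrom); default zero
#' @param n_tilts number of tilt images (needed when `offsets` is NULL)
#' @return object of class `particle_pose`
#' @export
particle_pose <- function(rotation = diag(3), position = c(0, 0, 0),
                          offsets = NULL, n_tilts = 1) {
  if (is.numeric(rotation) && length(rotation) == 3) {
    rotation <- euler_to_matrix(rotation[1], rotation[2], rotation[3])
  }
  stopifnot(all(dim(rotation) == c(3, 3)))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8) {
    stop("rotation is not orthonormal")
  }
  if (is.null(offsets)) offsets <- matrix(0, n_tilts, 3)
  structure(list(rotation = rotation, position = as.numeric(position),
                 offsets = offsets),
            class = "particle_pose")
}

#' Compose particle and tilt transforms into a projection mapping
#'
#' Returns the 2x3 matrix `A_pf` whose transpose maps 2D image frequencies
#' into 3D reference-frame frequencies, and the 2D shift
#' `t_pf = P_f T_pf + t_f` (Angstrom) with `P_f` the first two rows of the
#' tilt rotation.
#'
#' @param pose a [particle_pose()]
#' @param align a [tilt_alignment()]
#' @param f tilt index (1-based)
#' @return list with elements `A` (2x3), `t` (length 2, Angstrom)
#' @export
compose_projection <- function(pose, align, f) {
  if (f < 1 || f > align$n_tilts) stop("tilt index out of range")
  B <- align$rotations[[f]]
  P <- B[1:2, , drop = FALSE]
  A <- P %*% t(pose$rotation)
  Tpf <- pose$offsets[f, ]
  t2 <- as.numeric(P %*% Tpf) + align$shifts[f, ]
  list(A = A, t = t2)
}

#' Extract a phase-shifted central section from a 3D Fourier volume
#'
#' Samples `V` by trilinear interpolation at the 3D frequencies
#' `t(A) %*% j` for every 2D frequency j of an `n2 x n2` crop and applies
#' the translation phase ramp `exp(-2 pi i j . t)`. Frequencies with any
#' component at or beyond Nyquist return zero.
#'
#' @param V complex 3D Fourier array (centre-origin convention, DC at
#'   index 1), cubic box
#' @param mapping list with `A` (2x3 rotation slice) and `t` (2D shift,
#'   Angstrom) as returned by [compose_projection()]
#' @param n2 crop box size in pixels
#' @param pixel_size pixel size in Angstrom
#' @return complex `n2 x n2` matrix (unshifted layout, DC at index 1)
#' @export
project_map_slice <- function(V, mapping, n2 = dim(V)[1],
                              pixel_size = 1) {
  n3 <- dim(V)[1]
  # grid-unit mapping: physical j = h2/(n2*px); 3D grid q = j * n3*px
  Q <- t(mapping$A) * (n3 / n2)
  s_px <- mapping$t / pixel_size
  cpp_slice_sample(V, n3, Q, as.integer(n2), s_px[1], s_px[2])
}
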
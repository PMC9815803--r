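# Pseudo-subtomogram construction: (D, W, M) triplets of 3D Fourier-space
# arrays accumulated from CTF-premultiplied 2D tilt crops by trilinear
# forward insertion.
#
# D sums CTF * X over all tilt pixels mapped into 3D, W sums CTF^2 and M
# counts how often each voxel was hit (trilinear weights summing to one
# per inserted pixel). All three are full-complex/real arrays in the
# centre-origin Fourier convention; because the complete 2D frequency
# plane of each (Hermitian) crop is inserted, D is Hermitian by
# construction and each physical frequency carries the same multiplicity
# as in the 2D data it came from.

#' Extract a particle crop from a tilt image
#'
#' Real-space crop of `box` pixels centred on the nearest pixel to the
#' projected particle position; the residual sub-pixel offset is returned
#' so callers can carry it as a phase ramp. Particles whose centre falls
#' outside the image are flagged invisible.
#'
#' @param image 2D real matrix (a tilt image)
#' @param centre_px projected particle position in pixels (1-based,
#'   image coordinates)
#' @param box crop size in pixels (even)
#' @return list with `crop` (box x box real matrix, zero-padded at image
#'   edges), `ft` (centre-origin Fourier transform), `subpixel` (residual
#'   offset in pixels), `visible` (logical)
#' @export
extract_crop <- function(image, centre_px, box) {
  stopifnot(box %% 2 == 0)
  nx <- nrow(image); ny <- ncol(image)
  cx <- round(centre_px[1]); cy <- round(centre_px[2])
  visible <- cx >= 1 && cx <= nx && cy >= 1 && cy <= ny
  crop <- matrix(0, box, box)
  if (visible) {
    xs <- (cx - box / 2):(cx + box / 2 - 1)
    ys <- (cy - box / 2):(cy + box / 2 - 1)
    okx <- xs >= 1 & xs <= nx
    oky <- ys >= 1 & ys <= ny
    crop[which(okx), which(oky)] <- image[xs[okx], ys[oky]]
  }
  list(crop = crop, ft = ft_centered(crop),
       subpixel = c(centre_px[1] - cx, centre_px[2] - cy),
       visible = visible)
}

#' Empty pseudo-subtomogram
#' @param box box size (even)
#' @param pixel_size Angstrom/px
#' @param frame 3x3 rotation of the construction frame (tomogram frame by
#'   default); mappings used at insertion are expected relative to it
#' @return object of class `pseudo_subtomogram`
#' @export
pseudo_subtomogram <- function(box, pixel_size = 1, frame = diag(3)) {
  # D, W, M must be distinct allocations: the insertion kernel updates
  # them in place
  structure(list(D = array(0 + 0i, dim = c(box, box, box)),
                 W = array(0, dim = c(box, box, box)),
                 M = array(0, dim = c(box, box, box)),
                 box = as.integer(box),
                 pixel_size = pixel_size, frame = frame,
                 n_inserted = 0L, n_skipped = 0L),
            class = "pseudo_subtomogram")
}

#' Insert one CTF-premultiplied crop into a (D, W, M) triplet
#'
#' Every 2D Fourier pixel inside the Nyquist box is projected to its 3D
#' frequency `t(A) %*% j` and distributed over the eight nearest voxels
#' with trilinear weights summing to one; `ctf * value` accumulates into
#' D, `ctf^2` into W and 1 into M. Out-of-radius frequencies are skipped
#' and tallied.
#'
#' @param ps a [pseudo_subtomogram()]
#' @param crop_ft complex crop transform (centre-origin, box2 x box2)
#' @param ctf real CTF array matching `crop_ft`
#' @param mapping list with 2x3 `A` and 2D `t` (Angstrom) from
#'   [compose_projection()]; `t` is applied as a de-modulating phase so
#'   the inserted data are centred
#' @return the updated `pseudo_subtomogram`
#' @export
forward_insert <- function(ps, crop_ft, ctf, mapping) {
  n2 <- nrow(crop_ft)
  Q <- t(mapping$A) * (ps$box / n2)
  # de-modulate the measured shift so the particle sits at the origin
  if (any(mapping$t != 0)) {
    h <- freq_index(n2)
    ph <- outer(h * (mapping$t[1] / ps$pixel_size),
                h * (mapping$t[2] / ps$pixel_size), `+`)
    crop_ft <- crop_ft * exp(2i * pi * ph / n2)
  }
  cnt <- cpp_forward_insert(crop_ft, ctf, Q, ps$box, ps$D, ps$W, ps$M)
  ps$n_inserted <- ps$n_inserted + cnt[1]
  ps$n_skipped <- ps$n_skipped + cnt[2]
  ps
}

#' Construct a pseudo-subtomogram from a particle's tilt crops
#'
#' Sums Fourier-space contributions of all visible tilts into the (D, W,
#' M) triplet. Each entry of `crops` provides the crop transform and CTF;
#' `mappings` provides the per-tilt projection geometry.
#'
#' @param crops list per tilt with elements `ft` (complex crop transform),
#'   `ctf` (real array), and optional `visible` flag
#' @param mappings list per tilt of [compose_projection()] results
#' @param box pseudo-subtomogram box size (defaults to crop box)
#' @param pixel_size Angstrom/px
#' @param frame construction-frame rotation (3x3); mappings are composed
#'   with it so a rotated frame yields a rotated triplet
#' @return a `pseudo_subtomogram`
#' @export
construct_pseudosubtomogram <- function(crops, mappings, box = NULL,
                                        pixel_size = 1, frame = diag(3)) {
  vis <- vapply(crops, function(cr) {
    is.null(cr$visible) || isTRUE(cr$visible)
  }, logical(1))
  if (!any(vis)) stop("no visible tilts: cannot construct pseudo-subtomogram")
  if (is.null(box)) box <- nrow(crops[[which(vis)[1]]]$ft)
  ps <- pseudo_subtomogram(box, pixel_size, frame)
  for (f in which(vis)) {
    mp <- mappings[[f]]
    if (!identical(frame, diag(3))) {
      mp <- list(A = mp$A %*% t(frame), t = mp$t)
    }
    ps <- forward_insert(ps, crops[[f]]$ft, crops[[f]]$ctf, mp)
  }
  ps
}

#' Sum two pseudo-subtomograms (linearity of the construction)
#' @param a,b `pseudo_subtomogram`s on identical grids
#' @return their element-wise sum
#' @export
add_pseudosubtomograms <- function(a, b) {
  stopifnot(a$box == b$box, a$pixel_size == b$pixel_size)
  a$D <- a$D + b$D; a$W <- a$W + b$W; a$M <- a$M + b$M
  a$n_inserted <- a$n_inserted + b$n_inserted
  a$n_skipped <- a$n_skipped + b$n_skipped
  a
}

#' Write a pseudo-subtomogram as MRC volumes plus a STAR index entry
#'
#' Stores D as two real volumes (real and imaginary parts), W and M as
#' real volumes; values round-trip through [read_pseudosubtomogram()].
#'
#' @param ps a `pseudo_subtomogram`
#' @param prefix path prefix; writes `<prefix>_{dre,dim,w,m}.mrc`
#' @return named character vector of the four paths
#' @export
write_pseudosubtomogram <- function(ps, prefix) {
  paths <- c(dre = paste0(prefix, "_dre.mrc"),
             dim = paste0(prefix, "_dim.mrc"),
             w = paste0(prefix, "_w.mrc"),
             m = paste0(prefix, "_m.mrc"))
  write_mrc(volume_grid(Re(ps$D), ps$pixel_size), paths["dre"])
  write_mrc(volume_grid(Im(ps$D), ps$pixel_size), paths["dim"])
  write_mrc(volume_grid(ps$W, ps$pixel_size), paths["w"])
  write_mrc(volume_grid(ps$M, ps$pixel_size), paths["m"])
  paths
}

#' Read a pseudo-subtomogram written by [write_pseudosubtomogram()]
#' @param prefix path prefix used at write time
#' @param frame construction-frame rotation recorded in the index table
#' @return a `pseudo_subtomogram`
#' @export
read_pseudosubtomogram <- function(prefix, frame = diag(3)) {
  dre <- read_mrc(paste0(prefix, "_dre.mrc"))
  dimv <- read_mrc(paste0(prefix, "_dim.mrc"))
  w <- read_mrc(paste0(prefix, "_w.mrc"))
  m <- read_mrc(paste0(prefix, "_m.mrc"))
  ps <- pseudo_subtomogram(dim(dre$data)[1], dre$pixel_size, frame)
  ps$D <- dre$data + 1i * dimv$data
  ps$W <- w$data
  ps$M <- m$data
  ps
}
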
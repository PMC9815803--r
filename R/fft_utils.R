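#' @useDynLib pseudotomo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft optim rnorm runif median sd mad coef lm
#' @importFrom utils head tail
NULL

# Fourier conventions used throughout the package
# -----------------------------------------------
# All Fourier arrays are unshifted DFTs of *centre-origin* real arrays:
# the real-space origin sits at voxel n/2 (0-based) on every axis, which is
# implemented by an ifftshift before the forward transform. Under this
# convention rotating a Fourier array about DC corresponds to rotating the
# real array about its centre, and the central 2D section of a volume's
# transform equals the transform of its axial projection (Fourier-slice
# theorem, exact on the grid).
#
# Frequency of 0-based index i is h = i < n/2 ? i : i - n (grid units,
# cycles per box); physical frequency is h / (n * pixel_size) in 1/Angstrom.
# Boxes are even; components with |h| >= n/2 (Nyquist) are excluded from
# all likelihoods and insertions.

#' Circular shift moving the array centre to the origin (ifftshift)
#' @param x numeric or complex array (any dimension, even sizes)
#' @return array of the same shape
#' @keywords internal
ifftshift <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  idx <- lapply(d, function(n) {
    c((n %/% 2 + 1):n, 1:(n %/% 2))
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' Circular shift moving the origin back to the array centre (fftshift)
#' @param x array
#' @return array of the same shape
#' @keywords internal
fftshift <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  idx <- lapply(d, function(n) {
    c((n - n %/% 2 + 1):n, 1:(n - n %/% 2))
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' Centre-origin forward Fourier transform
#'
#' DFT of a real array whose origin is taken at the central voxel
#' (index n/2, 0-based) of every axis.
#'
#' @param x real array (2D or 3D, even box)
#' @return complex array, DC at index 1
#' @export
ft_centered <- function(x) {
  stats::fft(ifftshift(x))
}

#' Centre-origin inverse Fourier transform
#'
#' Inverse of [ft_centered()]; returns the real part (imaginary residue of
#' order machine epsilon for Hermitian inputs).
#'
#' @param X complex array
#' @return real array
#' @export
ift_centered <- function(X) {
  fftshift(Re(stats::fft(X, inverse = TRUE)) / length(X))
}

#' Signed frequency (grid units) for each index of an even box
#' @param n box size (even)
#' @return integer vector of length n: 0, 1, ..., n/2-1, -n/2, ..., -1
#' @export
freq_index <- function(n) {
  i <- seq_len(n) - 1L
  ifelse(i < n / 2, i, i - n)
}

#' Radial shell index array (rounded |h|) for a 2D or 3D box
#' @param n box size
#' @param ndim 2 or 3
#' @return integer array of shell indices (0-based shells)
#' @keywords internal
shell_index <- function(n, ndim = 3) {
  h <- freq_index(n)
  if (ndim == 2) {
    r <- sqrt(outer(h^2, h^2, `+`))
  } else {
    h2 <- h^2
    r <- sqrt(outer(outer(h2, h2, `+`), h2, `+`))
  }
  array(as.integer(round(r)), dim = dim(r))
}

#' Logical mask of frequencies inside the Nyquist box
#'
#' TRUE where every frequency component satisfies |h| < n/2.
#'
#' @param n box size
#' @param ndim 2 or 3
#' @return logical array
#' @keywords internal
nyquist_mask <- function(n, ndim = 3) {
  ok <- abs(freq_index(n)) < n / 2
  if (ndim == 2) outer(ok, ok, `&`)
  else outer(outer(ok, ok, `&`), ok, `&`)
}

#' Per-shell mean of |X|^2
#' @param X complex (or real) array
#' @param nshell number of shells (defaults to n/2 + 1)
#' @return numeric vector of shell-mean power
#' @keywords internal
shell_power <- function(X, nshell = NULL) {
  n <- dim(X)[1]
  ndim <- length(dim(X))
  if (is.null(nshell)) nshell <- n %/% 2 + 1
  sh <- shell_index(n, ndim)
  keep <- sh < nshell & nyquist_mask(n, ndim)
  p <- as.vector(Mod(X)^2)[keep]
  s <- as.vector(sh)[keep]
  tab <- vapply(seq_len(nshell) - 1L, function(k) {
    v <- p[s == k]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  tab
}

# wrap an angular difference into (-180, 180]
wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  ifelse(a == -180, 180, a)
}
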
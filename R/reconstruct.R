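# Regularised expectation-maximisation reconstruction with per-shell
# noise (sigma^2) and signal (tau^2) power estimation, plus FSC-based
# resolution. The map update is the Wiener-style ratio
#   V_k = sum_p D(R_p^T k)/sigma_k^2 / (sum_p W(R_p^T k)/sigma_k^2 + 1/tau_k^2)
# evaluated element-wise; sigma^2 and tau^2 are updated from per-shell
# residual and power sums over hollow unit-thickness spheres.

#' Empty reconstruction state
#' @param box box size
#' @param pixel_size Angstrom/px
#' @return object of class `reconstruction_state` with Hermitian
#'   numerator/denominator/multiplicity accumulators
#' @export
reconstruction_state <- function(box, pixel_size = 1) {
  structure(list(num = array(0 + 0i, c(box, box, box)),
                 den = array(0, c(box, box, box)),
                 mult = array(0, c(box, box, box)),
                 box = as.integer(box), pixel_size = pixel_size,
                 n_particles = 0L),
            class = "reconstruction_state")
}

#' Accumulate one particle into a reconstruction state
#'
#' Gathers the particle's (D, W, M) triplet at the rotated positions
#' `R_p^T k` (trilinear) and adds it into the accumulators with per-shell
#' `1/sigma^2` weighting; the particle's 3D shift is removed as a phase
#' ramp before accumulation.
#'
#' @param state a [reconstruction_state()]
#' @param ps a `pseudo_subtomogram`
#' @param rotation 3x3 pose rotation R_p (pseudo frame to reference)
#' @param sigma2 per-shell noise power
#' @param shift particle 3D shift in Angstrom
#' @return the updated state
#' @export
backproject_accumulate <- function(state, ps, rotation, sigma2,
                                   shift = c(0, 0, 0)) {
  stopifnot(state$box == ps$box)
  cpp_backproject(ps$D, ps$W, ps$M, ps$box, rotation,
                  shift / ps$pixel_size, sigma2,
                  state$num, state$den, state$mult)
  state$n_particles <- state$n_particles + 1L
  state
}

#' Regularised map update
#'
#' `V_k = num_k / (den_k + 1/tau_k^2)`, element-wise; voxels with zero
#' denominator are set to zero. `tau2 = Inf` gives the unregularised
#' ratio `num/den`.
#'
#' @param state a [reconstruction_state()]
#' @param tau2 per-shell signal power (may be `Inf`)
#' @param correct_interpolation divide the real-space map by the
#'   trilinear-interpolation envelope (sinc^2 per axis per stage).
#'   Off by default: the recommended route to interpolation accuracy is
#'   an oversampled construction grid (see [reconstruct_particles()]),
#'   after which the envelope is negligible.
#' @return complex 3D Fourier map
#' @export
em_update_map <- function(state, tau2 = Inf,
                          correct_interpolation = FALSE) {
  n <- state$box
  sh <- shell_index(n, 3)
  tau2 <- rep_len(tau2, n %/% 2 + 1)
  inv_tau <- ifelse(is.finite(tau2) & tau2 > 0, 1 / tau2,
                    ifelse(tau2 == 0, Inf, 0))
  reg <- array(inv_tau[pmin(sh, n %/% 2) + 1L], dim = dim(sh))
  den <- state$den + reg
  V <- array(0 + 0i, dim = c(n, n, n))
  ok <- den > 0 & is.finite(den)
  V[ok] <- state$num[ok] / den[ok]
  if (correct_interpolation) V <- gridding_correct(V, stages = 2)
  V
}

# divide the real-space map by the trilinear interpolation envelope
# (sinc^2 per axis per stage), floored to avoid edge blow-up
gridding_correct <- function(V, stages = 2) {
  n <- dim(V)[1]
  x <- (seq_len(n) - n / 2 - 1) / n
  s <- (sin(pi * x) / (pi * x))^2
  s[x == 0] <- 1
  env1 <- s^stages
  env <- outer(outer(env1, env1), env1)
  env <- pmax(env, 0.05)
  ft_centered(ift_centered(V) / env)
}

#' Per-shell noise power update
#'
#' `sigma_k^2 = sum_p sum_{k in S_k} |D_k - W_k V(R_p k)|^2 /
#' (2 sum_p sum M_k)` over unit-thickness shells. Shells without data
#' keep their previous value.
#'
#' @param particles list; each element has `ps` (pseudo-subtomogram),
#'   `rotation` (3x3) and optional `shift` (Angstrom)
#' @param V current reference transform
#' @param previous previous per-shell values carried into empty shells
#' @param m_threshold multiplicity cutoff
#' @return numeric vector of per-shell noise power
#' @export
update_sigma <- function(particles, V, previous = NULL,
                         m_threshold = 0.05) {
  n <- particles[[1]]$ps$box
  nshell <- n %/% 2 + 1
  acc <- matrix(0, nshell, 4)
  nv <- dim(V)[1]
  for (prt in particles) {
    sh <- if (is.null(prt$shift)) c(0, 0, 0) else prt$shift
    acc <- acc + cpp_residual_shells(prt$ps$D, prt$ps$W, prt$ps$M,
                                     prt$ps$box, V, nv,
                                     prt$rotation * (nv / prt$ps$box),
                                     sh / prt$ps$pixel_size,
                                     nshell, m_threshold)
  }
  out <- rep(NA_real_, nshell)
  pop <- acc[, 2] > 0
  out[pop] <- acc[pop, 1] / (2 * acc[pop, 2])
  if (!is.null(previous)) out[!pop] <- previous[!pop]
  attr(out, "shell_sums") <- acc
  out
}

#' Per-shell signal power update
#'
#' `tau_k^2 = shell_mean(|V_k|^2) / 2 * (sum W / sum M)`: the shell power
#' of the current map, halved per complex component, corrected by the
#' average squared CTF so it matches the CTF-premultiplied data scale.
#'
#' @param V current reference transform
#' @param shell_sums per-shell matrix with columns (residual, sum M,
#'   sum W, count), e.g. from `attr(update_sigma(...), "shell_sums")`
#' @return numeric vector of per-shell signal power (NA on empty shells)
#' @export
update_tau <- function(V, shell_sums) {
  n <- dim(V)[1]
  nshell <- n %/% 2 + 1
  pow <- shell_power(V, nshell)
  ratio <- rep(NA_real_, nshell)
  pop <- shell_sums[, 2] > 0
  ratio[pop] <- shell_sums[pop, 3] / shell_sums[pop, 2]
  pow / 2 * ratio
}

#' Prepare a reference map for slice extraction
#'
#' Zero-pads the real-space map by an integer factor and divides it by
#' the trilinear interpolation envelope (sinc^2 per axis on the padded
#' grid) before transforming. Sampling the result with trilinear
#' interpolation is then accurate to well below a percent over the
#' Nyquist range — the standard projector setup for Fourier-slice
#' extraction. All slice/likelihood functions accept references of any
#' (integer multiple) size.
#'
#' @param map real-space map: [volume_grid()], real array, or a complex
#'   Fourier array (inverted internally)
#' @param pad integer padding factor (default 2)
#' @param precorrect divide by the interpolation envelope (default TRUE)
#' @return complex Fourier array of size `pad * n`
#' @export
prepare_reference <- function(map, pad = 2, precorrect = TRUE) {
  if (inherits(map, "volume_grid")) map <- map$data
  if (is.complex(map)) map <- ift_centered(map)
  n <- dim(map)[1]
  nb <- as.integer(pad * n)
  if (precorrect) {
    x <- (seq_len(nb) - nb / 2 - 1) / nb
    s <- (sin(pi * x) / (pi * x))^2
    s[x == 0] <- 1
    xs <- (nb / 2 - n / 2 + 1):(nb / 2 + n / 2)
    env <- outer(outer(s[xs], s[xs]), s[xs])
    map <- map / env
  }
  if (pad == 1) return(ft_centered(map))
  big <- array(0, c(nb, nb, nb))
  i0 <- nb / 2 - n / 2
  big[(i0 + 1):(i0 + n), (i0 + 1):(i0 + n), (i0 + 1):(i0 + n)] <- map
  ft_centered(big)
}

#' Crop a Fourier array to a smaller box (same pixel size)
#'
#' Selects the frequencies of an `n_out` box from an array built on an
#' integer-multiple oversampled grid (`n_in = s * n_out`); the inverse of
#' zero-padding in real space.
#'
#' @param V complex Fourier array (2D or 3D), centre-origin convention
#' @param n_out output box size; `dim(V)[1]` must be a multiple
#' @return cropped complex array
#' @export
fourier_crop <- function(V, n_out) {
  n_in <- dim(V)[1]
  s <- n_in / n_out
  stopifnot(s == round(s), s >= 1)
  if (s == 1) return(V)
  src <- match(s * freq_index(n_out), freq_index(n_in))
  if (length(dim(V)) == 2) V[src, src] else V[src, src, src]
}

#' Streaming reconstruction of a particle set
#'
#' Constructs each particle's pseudo-subtomogram on an oversampled grid
#' (default 2x, the standard padding that keeps forward-mapping
#' interpolation error low), accumulates it, applies the regularised map
#' update and crops back to the working box. Particles are processed one
#' at a time so memory stays flat.
#'
#' @param particles list; each element has `crops` (per-tilt list with
#'   `ft`, `ctf`), `mappings` (per-tilt [compose_projection()] results),
#'   `rotation` (3x3 pose) and optional `shift` (Angstrom)
#' @param box working box size (crop size)
#' @param pixel_size Angstrom/px
#' @param sigma2 per-shell noise power on the oversampled shell grid, or
#'   scalar
#' @param tau2 per-shell signal power (default unregularised)
#' @param oversample integer padding factor (default 2)
#' @param half `NULL` for all particles, or 1/2 for the odd/even half set
#' @return complex Fourier map on the working box
#' @export
reconstruct_particles <- function(particles, box, pixel_size = 1,
                                  sigma2 = 1, tau2 = Inf, oversample = 2,
                                  half = NULL) {
  nbig <- box * oversample
  nshell <- nbig %/% 2 + 1
  sig <- if (length(sigma2) == 1) rep(sigma2, nshell)
         else rep_len(sigma2, nshell)
  st <- reconstruction_state(nbig, pixel_size)
  for (i in seq_along(particles)) {
    if (!is.null(half) && (i %% 2) != (half %% 2)) next
    p <- particles[[i]]
    ps <- construct_pseudosubtomogram(p$crops, p$mappings, box = nbig,
                                      pixel_size = pixel_size)
    sh <- if (is.null(p$shift)) c(0, 0, 0) else p$shift
    st <- backproject_accumulate(st, ps, p$rotation, sig, sh)
  }
  fourier_crop(em_update_map(st, tau2), box)
}

#' Fourier shell correlation between two maps
#'
#' `FSC_k = Re sum V1 V2* / sqrt(sum |V1|^2 sum |V2|^2)` per
#' unit-thickness shell; shells with zero power in either map get FSC 0.
#'
#' @param V1,V2 complex Fourier arrays of equal size (or real-space
#'   arrays, transformed internally)
#' @return numeric vector of FSC per shell (DC shell first)
#' @export
compute_fsc <- function(V1, V2) {
  stopifnot(all(dim(V1) == dim(V2)))
  if (is.double(V1)) V1 <- ft_centered(V1)
  if (is.double(V2)) V2 <- ft_centered(V2)
  n <- dim(V1)[1]
  nshell <- n %/% 2 + 1
  sh <- shell_index(n, 3)
  keep <- nyquist_mask(n, 3) & sh < nshell
  s <- as.vector(sh)[keep]
  cross <- as.vector(Re(V1 * Conj(V2)))[keep]
  p1 <- as.vector(Mod(V1)^2)[keep]
  p2 <- as.vector(Mod(V2)^2)[keep]
  vapply(seq_len(nshell) - 1L, function(k) {
    i <- s == k
    den <- sqrt(sum(p1[i]) * sum(p2[i]))
    if (!is.finite(den) || den == 0) return(0)
    sum(cross[i]) / den
  }, numeric(1))
}

#' Resolution at an FSC threshold
#'
#' Frequency of the first crossing below `threshold`, linearly
#' interpolated between shells; returned as a real-space distance in
#' Angstrom (`Inf` pixel size gives shells).
#'
#' @param fsc per-shell FSC from [compute_fsc()]
#' @param pixel_size Angstrom/px
#' @param box box size the FSC came from
#' @param threshold FSC threshold (default 0.143)
#' @return resolution in Angstrom (2 * pixel_size if never crossing)
#' @export
resolution_at <- function(fsc, pixel_size, box, threshold = 0.143) {
  ks <- seq_along(fsc) - 1
  below <- which(fsc < threshold & ks > 0)
  if (!length(below)) return(2 * pixel_size)
  b <- below[1]
  k1 <- ks[b - 1]; k0 <- fsc[b - 1]
  kf <- k1 + (k0 - threshold) / max(k0 - fsc[b], 1e-12)
  freq <- kf / (box * pixel_size)
  1 / max(freq, 1e-12)
}

#' Fit a subtomogram average by regularised expectation-maximisation
#'
#' The central estimator: alternates pose search (optional), half-set
#' backprojection, the regularised map update and per-shell noise/signal
#' power re-estimation, tracking gold-standard FSC resolution per
#' iteration. Half sets are split by even/odd particle index.
#'
#' @param particles list; each element has `ps` (a `pseudo_subtomogram`)
#'   and `pose` (list with `angles` in degrees and `shift` in Angstrom)
#' @param V0 initial reference: complex Fourier array or real-space array
#' @param n_iter maximum number of EM iterations (0 returns the input)
#' @param search `"none"` (fixed poses), `"local"` (continuous polish) or
#'   `"grid"` (grid + polish)
#' @param prior an [orientation_prior()] used when searching (per
#'   particle, centred on its current pose)
#' @param angular_step grid step in degrees for `search = "grid"`
#' @param sigma2 initial per-shell noise power; estimated from residuals
#'   when NULL
#' @param tau2 initial per-shell signal power; from the reference's shell
#'   power when NULL
#' @param m_threshold multiplicity cutoff
#' @param reconstruct_oversample padding factor for the M-step map
#'   update; honoured when particles also carry `crops` and `mappings`
#'   (the oversampled triplet is rebuilt per iteration and discarded)
#' @param reference_pad padding factor for the search/residual reference
#'   (see [prepare_reference()]); 1 uses the raw map
#' @param verbose print per-iteration resolution
#' @return object of class `tomo_refinement`
#' @export
refine_map <- function(particles, V0, n_iter = 5,
                       search = c("none", "local", "grid"),
                       prior = NULL, angular_step = 10,
                       sigma2 = NULL, tau2 = NULL, m_threshold = 0.05,
                       reconstruct_oversample = 1, reference_pad = 2,
                       verbose = FALSE) {
  search <- match.arg(search)
  n <- particles[[1]]$ps$box
  px <- particles[[1]]$ps$pixel_size
  nshell <- n %/% 2 + 1
  V <- if (is.double(V0)) ft_centered(V0) else V0
  prep <- function(Vbox) {
    if (reference_pad > 1) prepare_reference(Vbox, pad = reference_pad)
    else Vbox
  }
  Vs <- prep(V)
  poses <- lapply(particles, function(p) p$pose)
  part_rot <- function(p) euler_to_matrix(p$angles[1], p$angles[2],
                                          p$angles[3])
  plist <- function() {
    lapply(seq_along(particles), function(i) {
      list(ps = particles[[i]]$ps, rotation = part_rot(poses[[i]]),
           shift = poses[[i]]$shift)
    })
  }
  if (is.null(sigma2)) {
    sigma2 <- update_sigma(plist(), Vs, m_threshold = m_threshold)
    sigma2[!is.finite(sigma2) | sigma2 <= 0] <-
      max(sigma2[is.finite(sigma2) & sigma2 > 0], 1e-8)
  }
  if (is.null(tau2)) {
    tau2 <- shell_power(V, nshell)
    tau2[!is.finite(tau2)] <- 0
    tau2 <- tau2 / 2
    tau2[tau2 <= 0] <- min(tau2[tau2 > 0], na.rm = TRUE)
  }
  history <- data.frame(iter = integer(), resolution = numeric(),
                        mean_nll = numeric())
  fsc <- NULL
  V1 <- V2 <- NULL
  res_prev <- Inf
  stable <- 0L
  for (it in seq_len(n_iter)) {
    # E-step: pose search
    if (search != "none") {
      for (i in seq_along(particles)) {
        pr <- if (!is.null(prior)) {
          orientation_prior(poses[[i]]$angles, prior$sigma_angles,
                            prior$sigma_shift)
        } else NULL
        start <- poses[[i]]
        if (search == "grid" && !is.null(pr)) {
          gs <- grid_search_pose(particles[[i]]$ps, Vs, pr, angular_step,
                                 sigma2 = sigma2,
                                 m_threshold = m_threshold)
          start <- gs$map_pose
        }
        poses[[i]] <- local_refine_pose(particles[[i]]$ps, Vs, start,
                                        sigma2, pr, m_threshold)
      }
    }
    # M-step: half-set reconstruction (optionally on a padded grid)
    ov <- reconstruct_oversample
    use_ov <- ov > 1 && !is.null(particles[[1]]$crops) &&
      !is.null(particles[[1]]$mappings)
    if (use_ov) {
      nbig <- n * ov
      half <- list(reconstruction_state(nbig, px),
                   reconstruction_state(nbig, px))
      sig_big <- rep_len(rep(sigma2, each = ov), nbig %/% 2 + 1)
      for (i in seq_along(particles)) {
        h <- 1 + (i %% 2)
        psb <- construct_pseudosubtomogram(particles[[i]]$crops,
                                           particles[[i]]$mappings,
                                           box = nbig, pixel_size = px)
        half[[h]] <- backproject_accumulate(half[[h]], psb,
                                            part_rot(poses[[i]]), sig_big,
                                            poses[[i]]$shift)
      }
      tau_big <- rep_len(rep(tau2, each = ov), nbig %/% 2 + 1)
      V1 <- fourier_crop(em_update_map(half[[1]], tau_big), n)
      V2 <- fourier_crop(em_update_map(half[[2]], tau_big), n)
      full <- half[[1]]
      full$num <- half[[1]]$num + half[[2]]$num
      full$den <- half[[1]]$den + half[[2]]$den
      full$mult <- half[[1]]$mult + half[[2]]$mult
      V <- fourier_crop(em_update_map(full, tau_big), n)
    } else {
      half <- list(reconstruction_state(n, px), reconstruction_state(n, px))
      for (i in seq_along(particles)) {
        h <- 1 + (i %% 2)
        half[[h]] <- backproject_accumulate(half[[h]], particles[[i]]$ps,
                                            part_rot(poses[[i]]), sigma2,
                                            poses[[i]]$shift)
      }
      V1 <- em_update_map(half[[1]], tau2)
      V2 <- em_update_map(half[[2]], tau2)
      full <- half[[1]]
      full$num <- half[[1]]$num + half[[2]]$num
      full$den <- half[[1]]$den + half[[2]]$den
      full$mult <- half[[1]]$mult + half[[2]]$mult
      V <- em_update_map(full, tau2)
    }
    Vs <- prep(V)
    # noise/signal updates
    sig_new <- update_sigma(plist(), Vs, previous = sigma2,
                            m_threshold = m_threshold)
    ss <- attr(sig_new, "shell_sums")
    sig_new[!is.finite(sig_new) | sig_new <= 0] <- sigma2[1]
    sigma2 <- sig_new
    tau_new <- update_tau(V, ss)
    tau2 <- ifelse(is.finite(tau_new) & tau_new > 0, tau_new, tau2)
    fsc <- compute_fsc(V1, V2)
    res <- resolution_at(fsc, px, n)
    nll_now <- mean(vapply(seq_along(particles), function(i) {
      nll_pseudo(particles[[i]]$ps, Vs, part_rot(poses[[i]]), sigma2,
                 poses[[i]]$shift, m_threshold)
    }, numeric(1)))
    history <- rbind(history, data.frame(iter = it, resolution = res,
                                         mean_nll = nll_now))
    if (verbose) {
      message(sprintf("iter %d: resolution %.2f A, mean nll %.4g",
                      it, res, nll_now))
    }
    # convergence: resolution change below one shell twice in a row
    shell_width <- 1 / (n * px)
    if (is.finite(res_prev) &&
        abs(1 / res - 1 / res_prev) < shell_width) {
      stable <- stable + 1L
    } else stable <- 0L
    res_prev <- res
    if (stable >= 2L) break
  }
  structure(list(map = V,
                 half_maps = if (!is.null(V1)) list(V1, V2) else NULL,
                 fsc = fsc, sigma2 = sigma2, tau2 = tau2,
                 poses = poses, history = history,
                 box = n, pixel_size = px,
                 resolution = if (nrow(history)) tail(history$resolution, 1)
                              else NA_real_,
                 n_particles = length(particles)),
            class = "tomo_refinement")
}

#' @export
print.tomo_refinement <- function(x, ...) {
  cat("Pseudo-subtomogram refinement\n")
  cat(sprintf("  particles: %d   box: %d px @ %.3f A/px\n",
              x$n_particles, x$box, x$pixel_size))
  cat(sprintf("  iterations run: %d\n", nrow(x$history)))
  if (is.finite(x$resolution)) {
    cat(sprintf("  half-set FSC(0.143) resolution: %.2f A\n", x$resolution))
  }
  invisible(x)
}

#' @export
summary.tomo_refinement <- function(object, ...) {
  cat("Pseudo-subtomogram refinement\n\n")
  print(object$history, row.names = FALSE)
  cat("\nPer-shell noise power (sigma^2), first shells:\n")
  print(head(round(object$sigma2, 4), 8))
  invisible(object)
}

#' @export
coef.tomo_refinement <- function(object, ...) {
  do.call(rbind, lapply(seq_along(object$poses), function(i) {
    p <- object$poses[[i]]
    data.frame(particle = i, rot = p$angles[1], tilt = p$angles[2],
               psi = p$angles[3], dx = p$shift[1], dy = p$shift[2],
               dz = p$shift[3])
  }))
}

#' @export
plot.tomo_refinement <- function(x, ...) {
  if (is.null(x$fsc)) {
    warning("no FSC recorded")
    return(invisible(x))
  }
  k <- seq_along(x$fsc) - 1
  freq <- k / (x$box * x$pixel_size)
  graphics::plot(freq, x$fsc, type = "l", xlab = "spatial frequency (1/A)",
                 ylab = "FSC", ylim = c(-0.1, 1), ...)
  graphics::abline(h = 0.143, lty = 2, col = "grey40")
  invisible(x)
}

#' Alias for the EM driver with the interface of the iterative algorithm
#'
#' Thin wrapper over [refine_map()] returning the map and the noise/signal
#' model; kept as the procedural entry point.
#'
#' @inheritParams refine_map
#' @return list with `V` (complex map), `model` (sigma2, tau2, fsc), and
#'   the full `tomo_refinement` fit
#' @export
run_em <- function(particles, V0, n_iter = 5, ...) {
  if (n_iter == 0) {
    V <- if (is.double(V0)) ft_centered(V0) else V0
    return(list(V = V, model = NULL, fit = NULL))
  }
  fit <- refine_map(particles, V0, n_iter = n_iter, ...)
  list(V = fit$map, model = list(sigma2 = fit$sigma2, tau2 = fit$tau2,
                                 fsc = fit$fsc), fit = fit)
}
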
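# Fully synthetic tilt-series generator with known ground truth for every
# parameter the estimators recover: phantom, dose-symmetric tilt scheme,
# per-tilt astigmatic CTFs with dose-dependent damage, optional injected
# aberrations, tilt misalignments, per-particle 3D motion, and white
# Gaussian real-space noise.
#
# The simulator projects the phantom in REAL space (rotate-and-sum along
# the beam) so that it shares no Fourier-slice code with the likelihood;
# only the pose-composition primitives of the geometry module are reused.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

#' Dose-symmetric tilt scheme
#'
#' Stage angles in ascending order together with the acquisition order
#' 0, +step, -step, +2 step, -2 step, ... and the accumulated dose at
#' each image.
#'
#' @param max_angle maximum tilt, degrees
#' @param step angular increment, degrees
#' @param dose_per_tilt e/A^2 deposited per image
#' @return list `angles` (ascending), `order` (acquisition rank per
#'   image), `dose` (accumulated e/A^2 per image), `sequence` (angles in
#'   acquisition order)
#' @export
dose_symmetric_scheme <- function(max_angle = 60, step = 3,
                                  dose_per_tilt = 3) {
  pos <- seq(step, max_angle, by = step)
  seq_ang <- c(0, as.vector(rbind(pos, -pos)))
  angles <- sort(seq_ang)
  order <- match(angles, seq_ang)   # acquisition rank of each stage angle
  dose <- order * dose_per_tilt
  list(angles = angles, order = order, dose = dose, sequence = seq_ang)
}

#' Simulation configuration
#'
#' Defaults describe the study conditions used throughout the package's
#' validation: a dose-symmetric +/-60 degree, 3 degree tilt series at
#' 3 e/A^2 per image, 300 kV optics at 2.5 um underfocus and white
#' Gaussian noise set by a target SNR.
#'
#' @param box crop/phantom box, pixels (even)
#' @param pixel_size Angstrom/px
#' @param scheme a [dose_symmetric_scheme()] (or compatible list)
#' @param n_particles number of particles
#' @param defocus base defocus per tilt, Angstrom (recycled)
#' @param defocus_v astigmatic second defocus (default = defocus)
#' @param astigmatism_azimuth degrees
#' @param voltage_kv,cs,amplitude_contrast microscope optics
#' @param zernike_odd,zernike_even injected aberration coefficients
#'   (radians at Nyquist)
#' @param noise_sd real-space noise sd; overrides `snr` when not NULL
#' @param snr target band-limited signal-to-noise ratio within the
#'   particle support (used when `noise_sd` is NULL; NULL = noiseless)
#' @param slab_thickness particle slab extent along z, Angstrom
#' @param field_extent lateral extent of particle positions, Angstrom
#' @param min_distance minimum particle separation, Angstrom
#' @param tilt_shifts true per-tilt image shifts, n x 2 (Angstrom)
#' @param tilt_psi true per-tilt in-plane rotations, degrees
#' @param motion n_particles x n_tilts x 3 array of true displacements
#'   (Angstrom, acquisition-time ordering follows the scheme), or NULL
#' @param random_orientations draw uniform particle orientations (TRUE)
#'   or use identity poses
#' @param apply_damage apply the dose-dependent damage envelope
#' @param seed integer seed fixing every random draw
#' @return object of class `sim_config`
#' @export
sim_config <- function(box = 32, pixel_size = 1,
                       scheme = dose_symmetric_scheme(),
                       n_particles = 10, defocus = 25000,
                       defocus_v = NULL, astigmatism_azimuth = 0,
                       voltage_kv = 300, cs = 2.7,
                       amplitude_contrast = 0.07,
                       zernike_odd = numeric(), zernike_even = numeric(),
                       noise_sd = NULL, snr = NULL,
                       slab_thickness = 600, field_extent = 2000,
                       min_distance = 100,
                       tilt_shifts = NULL, tilt_psi = NULL,
                       motion = NULL, random_orientations = TRUE,
                       apply_damage = TRUE, seed = 1) {
  nf <- length(scheme$angles)
  stopifnot(box %% 2 == 0, all(abs(scheme$angles) <= 90))
  if (is.null(defocus_v)) defocus_v <- defocus
  structure(list(box = box, pixel_size = pixel_size, scheme = scheme,
                 n_particles = n_particles,
                 defocus = rep_len(defocus, nf),
                 defocus_v = rep_len(defocus_v, nf),
                 astigmatism_azimuth = astigmatism_azimuth,
                 voltage_kv = voltage_kv, cs = cs,
                 amplitude_contrast = amplitude_contrast,
                 zernike_odd = zernike_odd, zernike_even = zernike_even,
                 noise_sd = noise_sd, snr = snr,
                 slab_thickness = slab_thickness,
                 field_extent = field_extent,
                 min_distance = min_distance,
                 tilt_shifts = tilt_shifts, tilt_psi = tilt_psi,
                 motion = motion,
                 random_orientations = random_orientations,
                 apply_damage = apply_damage, seed = seed),
            class = "sim_config")
}

#' Deterministic multi-blob phantom
#'
#' An asymmetric arrangement of Gaussian blobs of varied widths and
#' amplitudes inside a soft spherical support; asymmetry makes pose
#' recovery unambiguous.
#'
#' @param box box size in pixels (>= 16, even)
#' @param seed RNG seed
#' @param n_blobs number of blobs (>= 12)
#' @param pixel_size Angstrom/px
#' @return a [volume_grid()]
#' @export
make_phantom <- function(box, seed = 1, n_blobs = 14, pixel_size = 1) {
  stopifnot(box >= 16, n_blobs >= 12)
  with_seed(seed, {
    x <- seq_len(box) - box / 2 - 1
    vol <- array(0, c(box, box, box))
    rmax <- 0.30 * box
    centres <- matrix(runif(3 * n_blobs, -rmax, rmax), ncol = 3)
    widths <- runif(n_blobs, 0.03 * box, 0.09 * box)
    amps <- runif(n_blobs, 0.5, 2)
    gx <- array(rep(x, times = box * box), c(box, box, box))
    gy <- aperm(gx, c(2, 1, 3))
    gz <- aperm(gx, c(3, 2, 1))
    for (b in seq_len(n_blobs)) {
      r2 <- (gx - centres[b, 1])^2 + (gy - centres[b, 2])^2 +
            (gz - centres[b, 3])^2
      vol <- vol + amps[b] * exp(-r2 / (2 * widths[b]^2))
    }
    # soft raised-cosine support
    r <- sqrt(gx^2 + gy^2 + gz^2)
    r0 <- 0.38 * box; r1 <- 0.46 * box
    mask <- ifelse(r <= r0, 1,
                   ifelse(r >= r1, 0, 0.5 * (1 + cos(pi * (r - r0) /
                                                     (r1 - r0)))))
    volume_grid(vol * mask, pixel_size = pixel_size)
  })
}

# uniform random rotation (Shoemake quaternion method)
random_rotation <- function() {
  u <- runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' Draw the ground truth of a simulation
#'
#' All random draws of the generative model except per-pixel noise:
#' particle orientations, slab positions with a minimum-distance
#' constraint, and the true/nominal tilt alignments.
#'
#' @param config a [sim_config()]
#' @return list of class `sim_truth`
#' @export
draw_truth <- function(config) {
  with_seed(config$seed, {
    sch <- config$scheme
    nf <- length(sch$angles)
    np <- config$n_particles
    rots <- lapply(seq_len(np), function(p) {
      if (config$random_orientations) random_rotation() else diag(3)
    })
    # slab placement with minimum distance
    pos <- matrix(0, np, 3)
    placed <- 0
    attempts <- 0
    while (placed < np) {
      cand <- c(runif(2, -config$field_extent / 2,
                      config$field_extent / 2),
                runif(1, -config$slab_thickness / 2,
                      config$slab_thickness / 2))
      ok <- placed == 0 ||
        min(sqrt(rowSums(sweep(pos[seq_len(placed), , drop = FALSE],
                               2, cand)^2))) >= config$min_distance
      if (ok) {
        placed <- placed + 1
        pos[placed, ] <- cand
      }
      attempts <- attempts + 1
      if (attempts > 1000 * np) {
        stop("could not place particles; reduce n_particles or ",
             "min_distance")
      }
    }
    shifts <- config$tilt_shifts
    if (is.null(shifts)) shifts <- matrix(0, nf, 2)
    psi <- config$tilt_psi
    if (is.null(psi)) psi <- rep(0, nf)
    align_true <- tilt_alignment(sch$angles, sch$order, psi = psi,
                                 shifts = shifts, dose = sch$dose)
    align_nominal <- tilt_alignment(sch$angles, sch$order,
                                    dose = sch$dose)
    motion <- config$motion
    if (is.null(motion)) motion <- array(0, c(np, nf, 3))
    structure(list(rotations = rots, positions = pos,
                   align_true = align_true,
                   align_nominal = align_nominal, motion = motion,
                   config = config),
              class = "sim_truth")
  })
}

# per-tilt CTF parameter set for a config
sim_ctf_params <- function(config, f) {
  ctf_params(voltage_kv = config$voltage_kv, cs = config$cs,
             amplitude_contrast = config$amplitude_contrast,
             defocus_u = config$defocus[f],
             defocus_v = config$defocus_v[f],
             astigmatism_azimuth = config$astigmatism_azimuth,
             zernike_odd = config$zernike_odd,
             zernike_even = config$zernike_even)
}

#' Simulate the tilt crops of one particle
#'
#' Projects the phantom in real space with the particle's true pose and
#' the true tilt alignment, applies the per-tilt CTF (with depth-dependent
#' defocus, damage envelope and any injected aberrations) in Fourier
#' space, shifts by the true in-image displacement, and adds white
#' Gaussian noise.
#'
#' @param phantom a [volume_grid()]
#' @param truth a [draw_truth()] result
#' @param p particle index
#' @param noise_sd real-space noise sd (0 = noiseless)
#' @return list per tilt: `ft`, `ctf`, `visible`, `defocus`, `dose`
#' @export
simulate_particle_crops <- function(phantom, truth, p, noise_sd = 0) {
  config <- truth$config
  n2 <- config$box
  px <- config$pixel_size
  nf <- truth$align_true$n_tilts
  Rp <- truth$rotations[[p]]
  h <- freq_index(n2)
  jx <- matrix(h, n2, n2) / (n2 * px)
  jy <- t(jx)
  nyq <- 1 / (2 * px)
  crops <- vector("list", nf)
  with_seed((config$seed * 7919 + p * 104729) %% 2147483647, {
    for (f in seq_len(nf)) {
      B <- truth$align_true$rotations[[f]]
      G <- Rp %*% t(B)            # camera -> reference coordinates
      proj <- cpp_project_real(phantom$data, dim(phantom$data)[1],
                               G, n2, 0, 0)
      ft <- ft_centered(proj)
      # true in-image displacement: projected position + motion + shift,
      # minus the nominal extraction centre (nominal alignment, position)
      P_true <- B[1:2, , drop = FALSE]
      P_nom <- truth$align_nominal$rotations[[f]][1:2, , drop = FALSE]
      d2 <- as.numeric(P_true %*% (truth$positions[p, ] +
                                   truth$motion[p, f, ])) +
            truth$align_true$shifts[f, ] -
            as.numeric(P_nom %*% truth$positions[p, ])
      if (any(d2 != 0)) {
        ph <- outer(h * (d2[1] / px), h * (d2[2] / px), `+`)
        ft <- ft * exp(-2i * pi * ph / n2)
      }
      pars <- sim_ctf_params(config, f)
      dz <- defocus_at_particle(config$defocus[f], truth$positions[p, ],
                                truth$align_true, f)
      pars$defocus_u <- dz
      pars$defocus_v <- dz + (config$defocus_v[f] - config$defocus[f])
      dose <- if (config$apply_damage) truth$align_true$dose[f] else 0
      ctf <- evaluate_ctf(pars, jx, jy, nyquist = nyq, dose = dose)
      ft <- ft * ctf * odd_aberration_phase(pars, jx, jy, nyq)
      real_img <- ift_centered(ft)
      if (noise_sd > 0) {
        real_img <- real_img + array(rnorm(n2 * n2, sd = noise_sd),
                                     c(n2, n2))
      }
      crops[[f]] <- list(ft = ft_centered(real_img), ctf = ctf,
                         visible = TRUE, defocus = dz,
                         dose = truth$align_true$dose[f])
    }
  })
  crops
}

#' Simulate a complete synthetic tilt-series data set
#'
#' @param phantom a [volume_grid()] (see [make_phantom()])
#' @param config a [sim_config()]
#' @return list of class `tomo_simulation`: `particles` (per particle:
#'   `crops`, `position`), `truth`, `align` (nominal alignment the
#'   estimators start from), `noise_sd`, `snr`, `config`
#' @export
simulate_tilt_series <- function(phantom, config) {
  truth <- draw_truth(config)
  noise_sd <- config$noise_sd
  if (is.null(noise_sd)) {
    if (is.null(config$snr)) {
      noise_sd <- 0
    } else {
      # calibrate noise from the signal power of a noiseless particle
      crops0 <- simulate_particle_crops(phantom, truth, 1, 0)
      pwr <- mean(vapply(crops0, function(cr) {
        img <- ift_centered(cr$ft)
        mean(img^2)
      }, numeric(1)))
      noise_sd <- sqrt(pwr / config$snr)
    }
  }
  particles <- lapply(seq_len(config$n_particles), function(p) {
    list(crops = simulate_particle_crops(phantom, truth, p, noise_sd),
         position = truth$positions[p, ])
  })
  sig_pwr <- if (noise_sd > 0) {
    mean(vapply(particles[[1]]$crops, function(cr) {
      mean(ift_centered(cr$ft)^2)
    }, numeric(1))) - noise_sd^2
  } else NA_real_
  structure(list(particles = particles, truth = truth,
                 align = truth$align_nominal, noise_sd = noise_sd,
                 snr = if (noise_sd > 0) sig_pwr / noise_sd^2 else Inf,
                 config = config, phantom = phantom),
            class = "tomo_simulation")
}

#' Export a simulation as a ready-to-run project directory
#'
#' Writes the phantom and per-particle crop stacks as MRC, tilt-series
#' metadata and particle tables as STAR, with the generative parameters
#' in a clearly flagged `synthetic_truth` block.
#'
#' @param sim a [simulate_tilt_series()] result
#' @param dir output directory (created)
#' @return invisible list of written paths
#' @export
export_fixture <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- sim$config
  paths <- list(phantom = file.path(dir, "phantom.mrc"))
  write_mrc(sim$phantom, paths$phantom)
  sch <- cfg$scheme
  tilt_df <- data.frame(ptmTiltIndex = seq_along(sch$angles),
                        ptmTiltAngle = sch$angles,
                        ptmAcquisitionOrder = sch$order,
                        ptmAccumulatedDose = sch$dose,
                        ptmDefocus = cfg$defocus,
                        ptmDefocusV = cfg$defocus_v,
                        ptmShiftX = sim$truth$align_true$shifts[, 1],
                        ptmShiftY = sim$truth$align_true$shifts[, 2],
                        ptmInPlanePsi = sim$truth$align_true$psi)
  part_rows <- lapply(seq_along(sim$particles), function(p) {
    eul <- matrix_to_euler(sim$truth$rotations[[p]])
    stack <- file.path(dir, sprintf("particle_%03d.mrc", p))
    crops <- sim$particles[[p]]$crops
    arr <- array(0, c(cfg$box, cfg$box, length(crops)))
    for (f in seq_along(crops)) arr[, , f] <- ift_centered(crops[[f]]$ft)
    write_mrc(volume_grid(arr, cfg$pixel_size), stack)
    data.frame(ptmParticle = p, ptmImageName = basename(stack),
               ptmAngleRot = eul[1], ptmAngleTilt = eul[2],
               ptmAnglePsi = eul[3],
               ptmCoordX = sim$particles[[p]]$position[1],
               ptmCoordY = sim$particles[[p]]$position[2],
               ptmCoordZ = sim$particles[[p]]$position[3])
  })
  doc <- list(
    optics = list(type = "pairs", values = list(
      ptmVoltage = cfg$voltage_kv, ptmCs = cfg$cs,
      ptmAmplitudeContrast = cfg$amplitude_contrast,
      ptmPixelSize = cfg$pixel_size, ptmBox = cfg$box)),
    tilts = list(type = "loop", data = tilt_df),
    particles = list(type = "loop", data = do.call(rbind, part_rows)),
    synthetic_truth = list(type = "pairs", values = list(
      ptmIsSyntheticTruth = 1L, ptmSeed = cfg$seed,
      ptmNoiseSd = sim$noise_sd)))
  class(doc) <- "star_document"
  paths$star <- file.path(dir, "project.star")
  write_star(doc, paths$star)
  invisible(paths)
}
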
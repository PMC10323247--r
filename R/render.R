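#' Calibrated image stack
#'
#' Container for a multi-frame single-channel image with acquisition
#' metadata. Pixel coordinates are 0-based with the origin at the centre of
#' the top-left pixel; x runs along columns, y along rows.
#'
#' @param frames 3D numeric array `[H, W, n_frames]`, or a list of equally
#'   sized H x W matrices
#' @param channel channel role, `"complex"` or `"microtubule"`
#' @param pixel_size um/px
#' @param dt frame interval, s
#' @return object of class `image_stack`
#' @export
image_stack <- function(frames, channel = c("complex", "microtubule"),
                        pixel_size, dt) {
  channel <- match.arg(channel)
  if (is.list(frames)) {
    dm <- dim(frames[[1]])
    ok <- vapply(frames, function(f) identical(dim(f), dm), logical(1))
    if (!all(ok))
      stop("frame shape mismatch at page ", which(!ok)[1])
    frames <- array(unlist(frames), dim = c(dm, length(frames)))
  }
  stopifnot(length(dim(frames)) == 3)
  if (!(pixel_size > 0) || !(dt > 0)) stop("pixel_size and dt must be > 0")
  structure(list(frames = frames, channel = channel,
                 pixel_size = pixel_size, dt = dt),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("image_stack: %d frames of %d x %d px (%s channel), %.3g um/px, dt %.3g s\n",
              d[3], d[1], d[2], x$channel, x$pixel_size, x$dt))
  invisible(x)
}

n_frames <- function(stack) dim(stack$frames)[3]

# Pixel-integrated isotropic Gaussian: photon count deposited by an emitter
# at (x0, y0) into each pixel of the frame (added in place within a window).
add_gaussian_spot <- function(frame, x0, y0, sigma, photons) {
  H <- nrow(frame); W <- ncol(frame)
  r <- ceiling(4 * sigma) + 1L
  cx <- round(x0); cy <- round(y0)
  xs <- max(0L, cx - r):min(W - 1L, cx + r)
  ys <- max(0L, cy - r):min(H - 1L, cy + r)
  if (!length(xs) || !length(ys)) return(frame)
  fx <- stats::pnorm(xs + 0.5, x0, sigma) - stats::pnorm(xs - 0.5, x0, sigma)
  fy <- stats::pnorm(ys + 0.5, y0, sigma) - stats::pnorm(ys - 0.5, y0, sigma)
  frame[ys + 1L, xs + 1L] <- frame[ys + 1L, xs + 1L] + photons * outer(fy, fx)
  frame
}

# expected photon image of the microtubule channel: Gaussian cross-section
# line of total brightness `photons_per_um` per micrometre of filament
render_path_photons <- function(path, image_size, psf_sigma, photons_per_um) {
  frame <- matrix(0, image_size[1], image_size[2])
  step_um <- 0.25 * path$pixel_size                  # fine sampling along the line
  s <- seq(0, path$length_um, by = step_um)
  xy <- path_point_at(path, s)
  per_sample <- photons_per_um * step_um
  for (i in seq_along(s))
    frame <- add_gaussian_spot(frame, xy[i, 1], xy[i, 2], psf_sigma, per_sample)
  frame
}

#' Render a synthetic TIRF image stack from ground truth
#'
#' Forward model of the camera: every surviving fluorophore of a particle
#' contributes a pixel-integrated isotropic Gaussian of SD `psf_sigma` and
#' total photon count `unit_intensity`; a constant `background_rate`
#' photons/px/frame is added; photon counts are Poisson-distributed, scaled
#' by `camera_gain` (ADU/photon), Gaussian read noise of SD `read_noise_sd`
#' ADU is added, and values are clipped to the 16-bit range. With
#' `config$motion_blur` the emitter position is averaged over
#' `n_substeps` sub-frame samples (continuous-exposure blur; use motion-blur
#' coefficient R = 1/6 downstream); by default the position is sampled once
#' per frame (R = 0).
#'
#' @param truth a `ground_truth` from [simulate_tracks()]
#' @param config the [scene_config()] (defaults to `truth$config`)
#' @param noise if FALSE, returns the noiseless expectation
#'   (`camera_gain` x expected photons, no Poisson/read noise, no clipping)
#' @param channel `"complex"` renders the particles, `"microtubule"` renders
#'   the path as a line profile
#' @param mt_photons_per_um line brightness of the microtubule channel
#' @return an [image_stack()]
#' @export
render_stack <- function(truth, config = truth$config, noise = TRUE,
                         channel = c("complex", "microtubule"),
                         mt_photons_per_um = 2000) {
  channel <- match.arg(channel)
  H <- config$image_size[1]; W <- config$image_size[2]
  nf <- config$n_frames

  if (channel == "microtubule") {
    base <- render_path_photons(truth$path, config$image_size,
                                config$psf_sigma, mt_photons_per_um)
    photon_frames <- replicate(nf, base, simplify = FALSE)
  } else {
    pos <- truth$positions; fl <- truth$fluorophores
    photon_frames <- vector("list", nf)
    for (t in seq_len(nf)) {
      frame <- matrix(0, H, W)
      idx <- which(pos$frame == t)
      for (j in idx) {
        surv <- fl$surviving[fl$particle_id == pos$particle_id[j] &
                             fl$frame == t]
        if (surv <= 0) next
        ph <- surv * config$unit_intensity
        if (config$motion_blur && truth$particles$D_true[pos$particle_id[j]] > 0) {
          # average emitter image over sub-frame Brownian positions
          Dp <- truth$particles$D_true[pos$particle_id[j]]
          ns <- config$n_substeps
          sub <- pos$arclength_um[j] +
            cumsum(stats::rnorm(ns, 0, sqrt(2 * Dp * config$dt / ns)))
          sub <- reflect_into(sub, truth$path$length_um)
          xy <- path_point_at(truth$path, sub)
          for (q in seq_len(ns))
            frame <- add_gaussian_spot(frame, xy[q, 1], xy[q, 2],
                                       config$psf_sigma, ph / ns)
        } else {
          frame <- add_gaussian_spot(frame, pos$x_px[j], pos$y_px[j],
                                     config$psf_sigma, ph)
        }
      }
      photon_frames[[t]] <- frame
    }
  }

  frames <- lapply(photon_frames, function(ph) {
    if (!noise) return(config$camera_gain * ph)
    counts <- matrix(stats::rpois(H * W, as.vector(ph) + config$background_rate),
                     H, W)
    adu <- counts * config$camera_gain
    if (config$read_noise_sd > 0)
      adu <- adu + matrix(stats::rnorm(H * W, 0, config$read_noise_sd), H, W)
    pmin(pmax(round(adu), 0), 65535)
  })
  image_stack(frames, channel = channel, pixel_size = config$pixel_size,
              dt = config$dt)
}
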
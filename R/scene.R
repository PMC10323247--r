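#' Configuration of a synthetic TIRF scene
#'
#' Bundles the imaging and simulation parameters used by [simulate_tracks()],
#' [simulate_photobleach_trace()] and [render_stack()]. Defaults emulate a
#' single-molecule TIRF acquisition on an EMCCD camera: 113 ms frame
#' interval, ~107 nm pixels, and a diffusion coefficient in the regime
#' measured for microtubule-lattice diffusion of large protein complexes.
#'
#' @param image_size integer (H, W) in pixels
#' @param pixel_size pixel size, micrometres per pixel
#' @param dt frame interval, seconds
#' @param n_frames number of frames
#' @param psf_sigma Gaussian PSF standard deviation, pixels
#' @param camera_gain camera gain, ADU per photon
#' @param read_noise_sd Gaussian read noise SD, ADU
#' @param background_rate background photons per pixel per frame
#' @param bleach_rate photobleaching rate per fluorophore, 1/s
#' @param unit_intensity emitted photons per frame per fluorophore
#' @param D diffusion coefficient of mobile particles, um^2/s
#' @param static_fraction fraction of particles bound statically, in \[0, 1\]
#' @param oligomer_size_distribution probability vector over oligomer sizes
#'   1..K (sums to 1)
#' @param motion_blur if TRUE, [render_stack()] averages `n_substeps`
#'   sub-frame positions per frame (continuous exposure); pair with motion
#'   blur coefficient R = 1/6 in [cve_diffusion()]. Default FALSE (position
#'   sampled once per frame; R = 0).
#' @param n_substeps sub-frame samples used when `motion_blur` is TRUE
#' @param seed integer seed; all stochastic draws of a scene flow from one
#'   generator seeded with this value
#' @return object of class `scene_config` (a validated list)
#' @export
scene_config <- function(image_size = c(64L, 256L), pixel_size = 0.107,
                         dt = 0.113, n_frames = 100L, psf_sigma = 1.3,
                         camera_gain = 50, read_noise_sd = 10,
                         background_rate = 20, bleach_rate = 0.02,
                         unit_intensity = 300, D = 0.05,
                         static_fraction = 0.2,
                         oligomer_size_distribution = 1,
                         motion_blur = FALSE, n_substeps = 10L,
                         seed = 1L) {
  stopifnot(length(image_size) == 2, all(image_size >= 8))
  if (!(pixel_size > 0)) stop("pixel_size must be > 0")
  if (!(dt > 0)) stop("dt must be > 0")
  if (D < 0) stop("D must be >= 0")
  if (static_fraction < 0 || static_fraction > 1)
    stop("static_fraction must be in [0, 1]")
  p <- oligomer_size_distribution
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("oligomer_size_distribution must be non-negative and sum to 1")
  stopifnot(psf_sigma > 0, camera_gain > 0, read_noise_sd >= 0,
            background_rate >= 0, bleach_rate >= 0, unit_intensity >= 0)
  structure(list(image_size = as.integer(image_size), pixel_size = pixel_size,
                 dt = dt, n_frames = as.integer(n_frames),
                 psf_sigma = psf_sigma, camera_gain = camera_gain,
                 read_noise_sd = read_noise_sd,
                 background_rate = background_rate, bleach_rate = bleach_rate,
                 unit_intensity = unit_intensity, D = D,
                 static_fraction = static_fraction,
                 oligomer_size_distribution = p,
                 motion_blur = isTRUE(motion_blur),
                 n_substeps = as.integer(n_substeps),
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Straight microtubule path helper
#'
#' Builds a `microtubule_path` (ordered 2D pixel points with cumulative
#' arclength in micrometres) for a straight segment, the geometry used by the
#' synthetic scenes.
#'
#' @param from,to endpoints `c(x, y)` in pixels (0-based, pixel-centre)
#' @param pixel_size um/px used for the arclength
#' @param step sampling step along the line, pixels
#' @return object of class `microtubule_path`
#' @export
straight_path <- function(from, to, pixel_size = 0.107, step = 1) {
  len_px <- sqrt(sum((to - from)^2))
  if (len_px <= 0) stop("degenerate path: zero length")
  n <- max(2L, ceiling(len_px / step) + 1L)
  t <- seq(0, 1, length.out = n)
  pts <- cbind(x = from[1] + t * (to[1] - from[1]),
               y = from[2] + t * (to[2] - from[2]))
  microtubule_path(pts, pixel_size)
}

#' Microtubule path constructor
#'
#' @param points n x 2 matrix of ordered (x, y) pixel coordinates
#' @param pixel_size um/px
#' @param width_px estimated apparent width of the filament, pixels
#' @return object of class `microtubule_path` with fields `points`
#'   (matrix), `arclength_um` (cumulative, starting at 0), `pixel_size`,
#'   `width_px`, `length_um`
#' @export
microtubule_path <- function(points, pixel_size, width_px = 3) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("a path needs at least 2 points")
  seg <- sqrt(rowSums(diff(points)^2))
  arc <- c(0, cumsum(seg)) * pixel_size
  if (any(diff(arc) <= 0)) stop("arclength must be strictly increasing")
  structure(list(points = points, arclength_um = arc,
                 pixel_size = pixel_size, width_px = width_px,
                 length_um = arc[length(arc)]),
            class = "microtubule_path")
}

# linear interpolation of (x, y) at arclength s (um) along a path
path_point_at <- function(path, s_um) {
  arc <- path$arclength_um
  s_um <- pmin(pmax(s_um, 0), arc[length(arc)])
  x <- stats::approx(arc, path$points[, 1], xout = s_um)$y
  y <- stats::approx(arc, path$points[, 2], xout = s_um)$y
  cbind(x = x, y = y)
}

# reflect positions into [0, L] (standard folding for reflecting boundaries)
reflect_into <- function(s, L) {
  if (L <= 0) stop("path length must be > 0")
  m <- s %% (2 * L)
  ifelse(m > L, 2 * L - m, m)
}

#' Simulate ground-truth particle motion on a microtubule
#'
#' Draws particles on a microtubule path and propagates them for
#' `config$n_frames` frames. Each particle is statically bound with
#' probability `static_fraction`, otherwise it performs one-dimensional
#' Brownian motion along the path arclength with increments
#' \eqn{\Delta s \sim N(0, 2 D \Delta t)} and reflecting boundaries at the
#' path ends. Oligomer sizes are drawn from
#' `oligomer_size_distribution`; each fluorophore bleaches after an
#' exponential time with rate `bleach_rate`.
#'
#' @param config a [scene_config()]
#' @param path a `microtubule_path`
#' @param n_particles number of particles to place
#' @param D_of_size optional function size -> D (um^2/s) giving
#'   size-dependent mobility (e.g. friction growing with oligomer size);
#'   default uses `config$D` for every mobile particle
#' @param s0_um optional vector of initial arclength positions (um), one per
#'   particle; default draws them uniformly along the path
#' @return object of class `ground_truth`: list with `particles` (data.frame:
#'   particle_id, oligomer_size, class, D_true, s0_um), `positions`
#'   (data.frame: particle_id, frame, arclength_um, x_px, y_px),
#'   `fluorophores` (data.frame: particle_id, frame, surviving), `config`,
#'   `path`. Frames are 1-based. Reproducible for a fixed `config$seed`.
#' @export
simulate_tracks <- function(config, path, n_particles = 10L,
                            D_of_size = NULL, s0_um = NULL) {
  stopifnot(inherits(config, "scene_config"),
            inherits(path, "microtubule_path"))
  if (path$length_um <= 0) stop("path length must be > 0")
  set.seed(config$seed)
  n_fr <- config$n_frames
  L <- path$length_um
  sizes <- sample.int(length(config$oligomer_size_distribution), n_particles,
                      replace = TRUE, prob = config$oligomer_size_distribution)
  cls <- ifelse(stats::runif(n_particles) < config$static_fraction,
                "static", "diffusive")
  D_true <- ifelse(cls == "static", 0,
                   if (is.null(D_of_size)) config$D
                   else vapply(sizes, D_of_size, numeric(1)))
  s0 <- if (is.null(s0_um)) stats::runif(n_particles, 0, L)
        else {
          stopifnot(length(s0_um) == n_particles, all(s0_um >= 0),
                    all(s0_um <= L))
          s0_um
        }

  pos <- vector("list", n_particles)
  fl <- vector("list", n_particles)
  for (i in seq_len(n_particles)) {
    if (cls[i] == "static" || D_true[i] == 0) {
      s <- rep(s0[i], n_fr)
    } else {
      inc <- stats::rnorm(n_fr - 1L, 0, sqrt(2 * D_true[i] * config$dt))
      s <- reflect_into(s0[i] + c(0, cumsum(inc)), L)
    }
    xy <- path_point_at(path, s)
    pos[[i]] <- data.frame(particle_id = i, frame = seq_len(n_fr),
                           arclength_um = s, x_px = xy[, 1], y_px = xy[, 2])
    # exponential bleach times per fluorophore -> surviving count per frame
    tb <- if (config$bleach_rate > 0)
      stats::rexp(sizes[i], config$bleach_rate) else rep(Inf, sizes[i])
    t_fr <- (seq_len(n_fr) - 1L) * config$dt
    surv <- vapply(t_fr, function(tt) sum(tb > tt), integer(1))
    fl[[i]] <- data.frame(particle_id = i, frame = seq_len(n_fr),
                          surviving = surv)
  }
  empty_pos <- data.frame(particle_id = integer(0), frame = integer(0),
                          arclength_um = numeric(0), x_px = numeric(0),
                          y_px = numeric(0))
  empty_fl <- data.frame(particle_id = integer(0), frame = integer(0),
                         surviving = integer(0))
  structure(list(
    particles = data.frame(particle_id = seq_len(n_particles),
                           oligomer_size = sizes, class = cls,
                           D_true = D_true, s0_um = s0),
    positions = if (n_particles) do.call(rbind, pos) else empty_pos,
    fluorophores = if (n_particles) do.call(rbind, fl) else empty_fl,
    config = config, path = path), class = "ground_truth")
}

#' Simulate a photobleaching intensity trace
#'
#' Generates the intensity-versus-time trace of an immobilized oligomer of
#' `k` fluorophores: each fluorophore bleaches after an exponential time with
#' rate `config$bleach_rate`, and the trace value at frame t is
#' (surviving count) x `unit_intensity` plus optional Gaussian noise. After
#' all fluorophores have bleached the trace sits at background (0).
#'
#' @param k oligomer size (number of fluorophores), >= 1
#' @param config a [scene_config()]
#' @param noise_sd Gaussian noise SD added per frame, ADU (0 = noiseless)
#' @param seed optional seed overriding `config$seed` (use when drawing
#'   ensembles of traces)
#' @return numeric vector of length `config$n_frames` (ADU above background)
#' @export
simulate_photobleach_trace <- function(k, config, noise_sd = 0, seed = NULL) {
  stopifnot(k >= 1)
  if (!is.null(seed)) set.seed(seed)
  tb <- if (config$bleach_rate > 0) stats::rexp(k, config$bleach_rate)
        else rep(Inf, k)
  t_fr <- (seq_len(config$n_frames) - 1L) * config$dt
  surv <- vapply(t_fr, function(tt) sum(tb > tt), numeric(1))
  tr <- surv * config$unit_intensity
  if (noise_sd > 0) tr <- tr + stats::rnorm(length(tr), 0, noise_sd)
  tr
}
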
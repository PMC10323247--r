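#' Project a 2D track onto an averaged path
#'
#' Maps each localization of a track to the arclength of its nearest point
#' on a path, retaining the perpendicular residual for quality control.
#' When no path is supplied, the averaged path is the track's own
#' principal-axis line: the total-least-squares line through all positions,
#' which removes transverse localization jitter while preserving
#' along-filament motion.
#'
#' @param track data.frame with columns `frame`, `x`, `y` (px) for a single
#'   track (one `track_id`)
#' @param path optional `microtubule_path`; default NULL uses the
#'   principal-axis line
#' @param pixel_size um/px (required when `path` is NULL; otherwise taken
#'   from the path)
#' @return object of class `projected_track`: list with `frame`,
#'   `s_um` (arclength positions), `residual_um` (signed perpendicular
#'   residuals), `dt_frames` (frame steps), `track_id` if present
#' @export
project_onto_path <- function(track, path = NULL, pixel_size = NULL) {
  stopifnot(all(c("frame", "x", "y") %in% names(track)))
  if (is.unsorted(track$frame, strictly = TRUE))
    track <- track[order(track$frame), , drop = FALSE]
  P <- cbind(track$x, track$y)
  if (is.null(path)) {
    if (is.null(pixel_size)) stop("pixel_size required without a path")
    ctr <- colMeans(P)
    Pc <- sweep(P, 2, ctr)
    sv <- svd(Pc)
    v <- sv$v[, 1]                       # principal axis (TLS line)
    s_px <- Pc %*% v
    r_px <- Pc %*% sv$v[, 2]
    s_um <- as.vector(s_px - min(s_px)) * pixel_size
    res_um <- as.vector(r_px) * pixel_size
  } else {
    if (path$length_um <= 0) stop("degenerate path")
    proj <- project_points_polyline(P, path$points)
    s_um <- proj$arc_px * path$pixel_size
    res_um <- proj$dist_px * path$pixel_size
  }
  structure(list(track_id = track$track_id[1], frame = track$frame,
                 s_um = s_um, residual_um = res_um),
            class = "projected_track")
}

# nearest point of each row of P on the polyline `pts`; returns arclength
# (px) and signed perpendicular distance (px)
project_points_polyline <- function(P, pts) {
  seg_a <- pts[-nrow(pts), , drop = FALSE]
  seg_b <- pts[-1, , drop = FALSE]
  seg_v <- seg_b - seg_a
  seg_len <- sqrt(rowSums(seg_v^2))
  cum <- c(0, cumsum(seg_len))
  arc <- dist <- numeric(nrow(P))
  for (i in seq_len(nrow(P))) {
    d <- sweep(seg_a, 2, P[i, ], "-") * -1          # P - a
    t <- rowSums(d * seg_v) / seg_len^2
    t <- pmin(pmax(t, 0), 1)
    foot <- seg_a + seg_v * t
    dd <- sqrt(rowSums(sweep(foot, 2, P[i, ], "-")^2))
    j <- which.min(dd)
    arc[i] <- cum[j] + t[j] * seg_len[j]
    # sign via cross product of tangent and offset
    off <- P[i, ] - foot[j, ]
    s <- sign(seg_v[j, 1] * off[2] - seg_v[j, 2] * off[1])
    dist[i] <- dd[j] * if (s == 0) 1 else s
  }
  list(arc_px = arc, dist_px = dist)
}

# consecutive-frame displacements (gap-spanning steps excluded) and the
# lag-1 products between displacement pairs that share a frame
cve_moments <- function(track1d) {
  df <- diff(track1d$frame)
  ds <- diff(track1d$s_um)
  keep <- df == 1L
  d1 <- ds[keep]
  # adjacent displacement pairs: both steps single-frame and contiguous
  adj <- keep[-length(keep)] & keep[-1]
  prod1 <- ds[-length(ds)][adj] * ds[-1][adj]
  list(d = d1, prod = prod1)
}

#' Covariance-based estimator of the 1D diffusion coefficient
#'
#' Unbiased estimator of the diffusion coefficient and of the localization
#' variance from single-particle displacements, using the lag-1
#' displacement covariance to correct for localization noise and motion
#' blur. With displacements \eqn{\Delta s_i = s_{i+1} - s_i}:
#' \deqn{\hat D = \frac{\langle \Delta s^2 \rangle}{2\Delta t} +
#'       \frac{\langle \Delta s_i \Delta s_{i+1} \rangle}{\Delta t}}
#' \deqn{\hat\sigma^2_{loc} = R\,\langle \Delta s^2 \rangle +
#'       (2R - 1)\,\langle \Delta s_i \Delta s_{i+1} \rangle}
#' where R is the motion-blur coefficient (0 for instantaneous sampling,
#' 1/6 for continuous full-frame exposure). `D_hat` can be negative on
#' short or noisy tracks; the estimator is unbiased, not positive, and the
#' value is reported as-is (summaries should use medians). Displacements
#' spanning detection gaps are excluded from both moments.
#'
#' @param track1d a `projected_track` from [project_onto_path()]
#' @param dt frame interval, s
#' @param R motion-blur coefficient, in \[0, 1/4\]
#' @param min_steps minimum number of usable displacements; shorter tracks
#'   return a result flagged `too_short`
#' @return object of class `diffusion_estimate`: list with `D_hat` (um^2/s),
#'   `sigma2_loc_hat` (um^2), `R`, `n_steps`, `too_short`,
#'   `motility_class` (NA until [classify_motility()])
#' @export
cve_diffusion <- function(track1d, dt, R = 0, min_steps = 10L) {
  stopifnot(inherits(track1d, "projected_track"), dt > 0,
            R >= 0, R <= 0.25)
  m <- cve_moments(track1d)
  n <- length(m$d)
  if (n < max(2L, min_steps)) {
    return(structure(list(D_hat = NA_real_, sigma2_loc_hat = NA_real_,
                          R = R, dt = dt, n_steps = n, too_short = TRUE,
                          motility_class = NA_character_),
                     class = "diffusion_estimate"))
  }
  msq <- mean(m$d^2)
  mcov <- if (length(m$prod)) mean(m$prod) else 0
  D_hat <- msq / (2 * dt) + mcov / dt
  s2 <- R * msq + (2 * R - 1) * mcov
  structure(list(D_hat = D_hat, sigma2_loc_hat = s2, R = R, dt = dt,
                 n_steps = n, too_short = FALSE,
                 motility_class = NA_character_),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  if (x$too_short) {
    cat(sprintf("diffusion_estimate: too short (%d steps)\n", x$n_steps))
  } else {
    cat(sprintf("diffusion_estimate: D = %.4g um^2/s, sigma2_loc = %.3g um^2, n = %d steps%s\n",
                x$D_hat, x$sigma2_loc_hat, x$n_steps,
                if (is.na(x$motility_class)) "" else paste0(", ", x$motility_class)))
  }
  invisible(x)
}

#' MSD-based diffusion coefficient (independent cross-check)
#'
#' Ordinary least-squares fit of the time-averaged mean squared displacement
#' against lag time over lags `1..max_lag`; D = slope / 2. Used as an
#' independent oracle for [cve_diffusion()] on long, low-noise tracks; on
#' ballistic motion the slope grows with `max_lag`, which is flagged.
#'
#' @param track1d a `projected_track`
#' @param dt frame interval, s
#' @param max_lag maximum lag, frames
#' @return list with `D_hat` (um^2/s), `msd` (per-lag values), `lags_s`,
#'   `nonlinear` (TRUE when the MSD curve bends away from a line)
#' @export
msd_diffusion <- function(track1d, dt, max_lag = 10L) {
  stopifnot(dt > 0)
  # require uniform sampling; use the contiguous positions only
  if (any(diff(track1d$frame) != 1L))
    stop("msd_diffusion requires a gap-free track")
  s <- track1d$s_um
  n <- length(s)
  if (n <= max_lag) stop("track shorter than max_lag")
  lags <- seq_len(max_lag)
  msd <- vapply(lags, function(L) mean((s[(1 + L):n] - s[1:(n - L)])^2),
                numeric(1))
  tau <- lags * dt
  fit <- stats::lm(msd ~ tau)
  # nonlinearity flag: quadratic term significant and positive curvature share
  fit2 <- stats::lm(msd ~ tau + I(tau^2))
  curv <- abs(stats::coef(fit2)[3]) * max(tau)^2 / max(msd)
  list(D_hat = unname(stats::coef(fit)[2] / 2), msd = msd, lags_s = tau,
       nonlinear = is.finite(curv) && curv > 0.2)
}

# environment caching null quantiles of the static-particle CVE statistic
.null_cache <- new.env(parent = emptyenv())

# (1 - alpha) quantile of the dimensionless ratio D_hat * dt / sigma2_hat
# for a static track with n displacements. Both numerator and denominator
# are estimated from the same displacements (they are anticorrelated), so
# the null must be built on the ratio, not on D_hat alone; draws with
# non-positive estimated localization variance map to +Inf (maximally
# diffusive-looking). Scale-invariant in sigma and dt.
static_null_quantile <- function(n_steps, alpha, R = 0, n_sim = 4000L) {
  key <- sprintf("n%d_a%g_R%g", n_steps, alpha, R)
  if (!is.null(.null_cache[[key]])) return(.null_cache[[key]])
  stat <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(20260901L + n_steps)
    vapply(seq_len(n_sim), function(i) {
      eps <- stats::rnorm(n_steps + 1L)
      d <- diff(eps)
      msq <- mean(d^2)
      mcov <- mean(d[-length(d)] * d[-1])
      D_stat <- msq / 2 + mcov
      s2 <- R * msq + (2 * R - 1) * mcov
      if (s2 <= 0) Inf else D_stat / s2
    }, numeric(1))
  })
  q <- stats::quantile(stat, 1 - alpha, names = FALSE)
  .null_cache[[key]] <- q
  q
}

#' Classify a track as statically bound or diffusive
#'
#' A track is called diffusive when its CVE diffusion coefficient exceeds
#' the (1 - alpha) quantile of the null distribution of the estimator for a
#' purely static particle with the same localization variance and number of
#' steps (the null is simulated once per track length and cached). Tracks
#' with non-positive estimated localization variance use the raw positional
#' scatter instead.
#'
#' @param est a `diffusion_estimate` from [cve_diffusion()]
#' @param alpha test level (default 0.05)
#' @return the estimate with `motility_class` set to `"static"` or
#'   `"diffusive"`
#' @export
classify_motility <- function(est, alpha = 0.05) {
  stopifnot(inherits(est, "diffusion_estimate"))
  if (est$too_short) return(est)
  if (is.na(est$D_hat) || est$D_hat <= 0) {
    est$motility_class <- "static"
    return(est)
  }
  t_obs <- if (est$sigma2_loc_hat > 0)
    est$D_hat * est$dt / est$sigma2_loc_hat else Inf
  qn <- static_null_quantile(est$n_steps, alpha, est$R)
  est$motility_class <- if (t_obs > qn) "diffusive" else "static"
  est
}

#' Estimate diffusion for every track in a table
#'
#' Convenience wrapper: splits a tracked-spot table by `track_id`, projects
#' each track ([project_onto_path()]), applies [cve_diffusion()] and
#' [classify_motility()].
#'
#' @param tracks data.frame from [link_tracks()]
#' @param pixel_size um/px
#' @param dt s/frame
#' @param R motion-blur coefficient
#' @param min_steps minimum displacements
#' @param alpha classification level
#' @param path optional `microtubule_path` used for every track
#' @return data.frame: track_id, D_hat, sigma2_loc_hat, n_steps, too_short,
#'   motility_class
#' @export
estimate_diffusion_table <- function(tracks, pixel_size, dt, R = 0,
                                     min_steps = 10L, alpha = 0.05,
                                     path = NULL) {
  ids <- unique(tracks$track_id)
  rows <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    if (nrow(tr) < min_steps + 1L) {
      return(data.frame(track_id = id, D_hat = NA_real_,
                        sigma2_loc_hat = NA_real_, n_steps = nrow(tr) - 1L,
                        too_short = TRUE, motility_class = NA_character_))
    }
    p1 <- project_onto_path(tr, path = path, pixel_size = pixel_size)
    est <- cve_diffusion(p1, dt = dt, R = R, min_steps = min_steps)
    est <- classify_motility(est, alpha = alpha)
    data.frame(track_id = id, D_hat = est$D_hat,
               sigma2_loc_hat = est$sigma2_loc_hat, n_steps = est$n_steps,
               too_short = est$too_short, motility_class = est$motility_class)
  })
  do.call(rbind, rows)
}
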
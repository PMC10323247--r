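#' Detect sub-pixel fluorescent spots in a single frame
#'
#' Candidate local maxima above a robust noise-scaled threshold are refined
#' by least-squares fitting of a 2D isotropic Gaussian plus constant offset
#' in a local window. The threshold is `local_background + snr_min *
#' noise_sd`, with background the frame median and noise the MAD-based
#' robust SD. Fits that fail to converge, leave the sigma bounds
#' `[0.5, 3] * psf_sigma_guess`, fall below the SNR cut, or drift out of the
#' fit window are discarded. Overlapping candidates (closer than
#' `2 * psf_sigma_guess` px) are resolved by keeping the brighter fit.
#'
#' @param frame 2D numeric matrix (one image), finite-valued
#' @param psf_sigma_guess expected PSF sigma, px
#' @param snr_min minimum peak amplitude in units of the robust noise SD
#' @param window half-size of the square fit window (full width
#'   `2*window+1`; default 4 gives the 9 x 9 px window)
#' @return data.frame with one row per accepted spot: `x`, `y` (sub-pixel,
#'   0-based pixel-centre), `sigma` (px), `integrated_intensity` (ADU;
#'   background-subtracted Gaussian volume `2*pi*sigma^2*A`),
#'   `local_background` (ADU/px), `amplitude` (ADU), `fit_uncertainty` (px).
#'   Zero rows when nothing is found.
#' @export
detect_spots <- function(frame, psf_sigma_guess = 1.3, snr_min = 4,
                         window = 4L) {
  stopifnot(is.matrix(frame), all(is.finite(frame)))
  H <- nrow(frame); W <- ncol(frame)
  bg <- stats::median(frame)
  noise <- stats::mad(frame)
  if (noise == 0) noise <- stats::sd(frame)
  if (is.na(noise) || noise == 0) noise <- 1e-12

  sm <- gaussian_smooth(frame, sigma = max(1, psf_sigma_guess / 2))
  thr <- stats::median(sm) + snr_min * stats::mad(sm)
  cand <- local_maxima(sm)
  cand <- cand[sm[cand] > thr, drop = FALSE]
  if (!length(cand)) return(empty_spots())

  rows <- ((cand - 1L) %% H) + 1L
  cols <- ((cand - 1L) %/% H) + 1L
  out <- vector("list", length(cand))
  for (i in seq_along(cand)) {
    fit <- fit_gaussian_2d(frame, x0 = cols[i] - 1L, y0 = rows[i] - 1L,
                           sigma0 = psf_sigma_guess, window = window)
    if (is.null(fit)) next
    ok <- fit$sigma >= 0.5 * psf_sigma_guess &&
          fit$sigma <= 3 * psf_sigma_guess &&
          fit$amplitude > snr_min * noise &&
          fit$x >= 0 && fit$x < W && fit$y >= 0 && fit$y < H &&
          abs(fit$x - (cols[i] - 1L)) <= window &&
          abs(fit$y - (rows[i] - 1L)) <= window
    if (ok) out[[i]] <- fit
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out) || !nrow(out)) return(empty_spots())
  dedupe_spots(out, min_sep = 2 * psf_sigma_guess)
}

empty_spots <- function() {
  data.frame(x = numeric(0), y = numeric(0), sigma = numeric(0),
             integrated_intensity = numeric(0), local_background = numeric(0),
             amplitude = numeric(0), fit_uncertainty = numeric(0))
}

# separable Gaussian smoothing (zero-padded borders)
gaussian_smooth <- function(m, sigma) {
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, 0, sigma); k <- k / sum(k)
  sm <- apply(m, 2, function(col) stats::filter(col, k, sides = 2))
  sm <- t(apply(sm, 1, function(row) stats::filter(row, k, sides = 2)))
  sm[is.na(sm)] <- stats::median(m)
  sm
}

# linear indices of strict 3x3 local maxima (border excluded)
local_maxima <- function(m) {
  H <- nrow(m); W <- ncol(m)
  if (H < 3 || W < 3) return(integer(0))
  core <- m[2:(H - 1), 2:(W - 1)]
  is_max <- rep(TRUE, length(core))
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- m[(2:(H - 1)) + dy, (2:(W - 1)) + dx]
    is_max <- is_max & (core >= nb)
  }
  # strictness against at least one neighbour avoids plateaus firing twice
  strict <- rep(FALSE, length(core))
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- m[(2:(H - 1)) + dy, (2:(W - 1)) + dx]
    strict <- strict | (core > nb)
  }
  idx <- which(is_max & strict)
  rr <- ((idx - 1L) %% (H - 2L)) + 2L
  cc <- ((idx - 1L) %/% (H - 2L)) + 2L
  (cc - 1L) * H + rr
}

# least-squares 2D Gaussian fit in a local window; returns one-row
# data.frame or NULL on failure
fit_gaussian_2d <- function(frame, x0, y0, sigma0, window = 4L) {
  H <- nrow(frame); W <- ncol(frame)
  xs <- max(0L, round(x0) - window):min(W - 1L, round(x0) + window)
  ys <- max(0L, round(y0) - window):min(H - 1L, round(y0) + window)
  if (length(xs) < 5 || length(ys) < 5) return(NULL)
  z <- frame[ys + 1L, xs + 1L]
  gx <- rep(xs, each = length(ys)); gy <- rep(ys, times = length(xs))
  zv <- as.vector(z)
  b0 <- min(zv); a0 <- max(zv) - b0
  if (a0 <= 0) return(NULL)
  par0 <- c(A = a0, x = x0, y = y0, s = sigma0, b = b0)
  resid_fn <- function(p) {
    zv - (p[5] + p[1] * exp(-((gx - p[2])^2 + (gy - p[3])^2) / (2 * p[4]^2)))
  }
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par0, fn = resid_fn,
                         lower = c(0, min(xs) - 1, min(ys) - 1, 0.25 * sigma0, -Inf),
                         upper = c(Inf, max(xs) + 1, max(ys) + 1, 4 * sigma0, Inf),
                         control = minpack.lm::nls.lm.control(maxiter = 150))),
    error = function(e) NULL)
  if (is.null(fit) || fit$info %in% c(0, 5)) return(NULL)
  p <- fit$par
  # positional uncertainty from the parameter covariance (guarded)
  unc <- tryCatch({
    cv <- stats::vcov(fit); sqrt(max(cv["x", "x"], 0))
  }, error = function(e) NA_real_)
  data.frame(x = unname(p["x"]), y = unname(p["y"]), sigma = unname(p["s"]),
             integrated_intensity = unname(2 * pi * p["s"]^2 * p["A"]),
             local_background = unname(p["b"]), amplitude = unname(p["A"]),
             fit_uncertainty = unc)
}

# keep the brighter of any pair of fits closer than min_sep px
dedupe_spots <- function(spots, min_sep) {
  o <- order(-spots$integrated_intensity)
  spots <- spots[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(spots))
  for (i in seq_len(nrow(spots))) {
    if (!keep[i]) next
    if (i < nrow(spots)) {
      j <- (i + 1):nrow(spots)
      d2 <- (spots$x[j] - spots$x[i])^2 + (spots$y[j] - spots$y[i])^2
      keep[j[d2 < min_sep^2]] <- FALSE
    }
  }
  out <- spots[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect spots in every frame of a stack
#'
#' @param stack an [image_stack()]
#' @inheritParams detect_spots
#' @return data.frame of spots with a leading `frame` column (1-based)
#' @export
detect_stack <- function(stack, psf_sigma_guess = 1.3, snr_min = 4,
                         window = 4L) {
  nf <- n_frames(stack)
  res <- vector("list", nf)
  for (t in seq_len(nf)) {
    sp <- detect_spots(stack$frames[, , t], psf_sigma_guess, snr_min, window)
    if (nrow(sp)) res[[t]] <- cbind(frame = t, sp)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) out <- cbind(frame = integer(0), empty_spots())
  out
}

#' Link per-frame spots into tracks
#'
#' Greedy nearest-neighbour assignment between the heads of open tracks and
#' the spots of each new frame: candidate pairs are sorted by Euclidean
#' distance and matched one-to-one; pairs farther than
#' `max_disp * (frame gap)` px are forbidden. Tracks left unmatched for more
#' than `max_gap` frames are closed; unmatched spots seed new tracks.
#'
#' @param spots data.frame as returned by [detect_stack()] (must contain
#'   `frame`, `x`, `y`; other columns are carried through)
#' @param max_disp maximum displacement per frame, px
#' @param max_gap maximum number of consecutive missed frames bridged
#' @param min_length tracks shorter than this many localizations are dropped
#' @return data.frame of tracked spots with a leading `track_id` column,
#'   sorted by (track_id, frame)
#' @export
link_tracks <- function(spots, max_disp = 5, max_gap = 2L, min_length = 2L) {
  if (!nrow(spots)) return(cbind(track_id = integer(0), spots))
  stopifnot(!is.unsorted(spots$frame))
  frames <- sort(unique(spots$frame))
  spots$track_id <- NA_integer_
  next_id <- 1L
  # open tracks: id, last x, y, last frame
  open <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                     last = integer(0))
  for (f in frames) {
    idx <- which(spots$frame == f)
    open <- open[f - open$last <= max_gap + 1L, , drop = FALSE]
    assigned_spot <- rep(FALSE, length(idx))
    if (nrow(open) && length(idx)) {
      dx <- outer(open$x, spots$x[idx], "-")
      dy <- outer(open$y, spots$y[idx], "-")
      d <- sqrt(dx^2 + dy^2)
      lim <- max_disp * (f - open$last)          # gap-spanning allowance
      cand <- which(d <= lim, arr.ind = TRUE)
      if (nrow(cand)) {
        cand <- cand[order(d[cand]), , drop = FALSE]
        used_tr <- rep(FALSE, nrow(open))
        for (k in seq_len(nrow(cand))) {
          tr <- cand[k, 1]; sp <- cand[k, 2]
          if (used_tr[tr] || assigned_spot[sp]) next
          used_tr[tr] <- TRUE; assigned_spot[sp] <- TRUE
          spots$track_id[idx[sp]] <- open$id[tr]
          open$x[tr] <- spots$x[idx[sp]]; open$y[tr] <- spots$y[idx[sp]]
          open$last[tr] <- f
        }
      }
    }
    if (any(!assigned_spot)) {
      new_idx <- idx[!assigned_spot]
      ids <- next_id + seq_along(new_idx) - 1L
      spots$track_id[new_idx] <- ids
      next_id <- next_id + length(new_idx)
      open <- rbind(open, data.frame(id = ids, x = spots$x[new_idx],
                                     y = spots$y[new_idx], last = f))
    }
  }
  keep <- table(spots$track_id)
  spots <- spots[spots$track_id %in% as.integer(names(keep[keep >= min_length])), ,
                 drop = FALSE]
  spots <- spots[order(spots$track_id, spots$frame), , drop = FALSE]
  # renumber consecutively
  spots$track_id <- match(spots$track_id, unique(spots$track_id))
  rownames(spots) <- NULL
  spots[, c("track_id", setdiff(names(spots), "track_id"))]
}
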
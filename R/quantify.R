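#' Background-corrected mean intensity over a microtubule area
#'
#' Implements per-microtubule intensity measurement: the mean pixel value of
#' the complex channel over the microtubule area minus the mean over a
#' background region. By default the background region is an annulus around
#' the dilated microtubule mask that excludes every microtubule mask in the
#' field, so neighbouring filaments never contaminate the background. Each
#' measurement (one microtubule, averaged over frames) is one experimental
#' data point.
#'
#' @param stack complex-channel [image_stack()]
#' @param mt_mask logical H x W mask of the microtubule area
#' @param bg_mask optional logical mask of the background region; when NULL
#'   an annulus of width `annulus_px` around `mt_mask` is used, minus
#'   `exclude_mask`
#' @param exclude_mask optional logical mask (e.g. union of all microtubule
#'   areas) removed from the automatic background annulus
#' @param annulus_px width of the automatic background annulus, px
#' @param frames frame indices to average over (default: all)
#' @return one-row data.frame: `mean_bc_intensity` (ADU/px), `mean_mt`,
#'   `mean_bg`, `n_pixels`, `n_bg_pixels`
#' @export
background_corrected_intensity <- function(stack, mt_mask, bg_mask = NULL,
                                           exclude_mask = NULL,
                                           annulus_px = 6L, frames = NULL) {
  stopifnot(inherits(stack, "image_stack"), is.logical(mt_mask))
  if (!any(mt_mask)) stop("mt_mask is empty")
  if (is.null(bg_mask)) {
    brush <- EBImage::makeBrush(2L * as.integer(annulus_px) + 1L, shape = "disc")
    grown <- EBImage::imageData(EBImage::dilate(EBImage::Image(mt_mask * 1), brush)) > 0
    bg_mask <- grown & !mt_mask
    if (!is.null(exclude_mask)) bg_mask <- bg_mask & !exclude_mask
  } else {
    if (any(bg_mask & mt_mask)) stop("mt_mask and bg_mask must be disjoint")
  }
  if (!any(bg_mask))
    stop("empty background region; supply bg_mask explicitly")
  if (is.null(frames)) frames <- seq_len(n_frames(stack))
  avg <- apply(stack$frames[, , frames, drop = FALSE], c(1, 2), mean)
  mean_mt <- mean(avg[mt_mask])
  mean_bg <- mean(avg[bg_mask])
  data.frame(mean_bc_intensity = mean_mt - mean_bg, mean_mt = mean_mt,
             mean_bg = mean_bg, n_pixels = sum(mt_mask),
             n_bg_pixels = sum(bg_mask))
}

#' Mean integrated track intensity over the first frames
#'
#' Averages the background-subtracted integrated spot intensity over the
#' earliest `n_first` localizations of a track (default 20), limiting the
#' influence of photobleaching on the intensity estimate.
#'
#' @param track data.frame for one track with columns `frame` and
#'   `integrated_intensity`
#' @param n_first number of earliest frames to average (default 20)
#' @return mean integrated intensity, ADU
#' @export
track_mean_intensity <- function(track, n_first = 20L) {
  stopifnot(nrow(track) >= 1, "integrated_intensity" %in% names(track))
  o <- order(track$frame)
  ii <- track$integrated_intensity[o]
  mean(ii[seq_len(min(n_first, length(ii)))])
}

# single change point minimizing residual sum of squares; returns index of
# the last pre-step sample and the RSS achieved
best_single_step <- function(y) {
  n <- length(y)
  best <- list(rss = Inf, k = NA_integer_)
  cs <- cumsum(y); cs2 <- cumsum(y^2)
  for (k in 1:(n - 1)) {
    m1 <- cs[k] / k; m2 <- (cs[n] - cs[k]) / (n - k)
    rss <- (cs2[k] - k * m1^2) + (cs2[n] - cs2[k] - (n - k) * m2^2)
    if (rss < best$rss) best <- list(rss = rss, k = k, level1 = m1, level2 = m2)
  }
  best
}

#' Detect bleaching steps in an intensity trace
#'
#' Penalized least-squares change-point analysis: steps are added by binary
#' segmentation while the Bayesian information criterion improves
#' (`n*log(RSS/n) + penalty*k*log(n)`). Intended for photobleaching traces,
#' where each step is the loss of one fluorophore.
#'
#' @param trace numeric intensity trace (ADU)
#' @param max_steps maximum number of steps considered
#' @param penalty multiplier on the BIC complexity term
#' @return list: `n_steps`, `change_points` (frame index of last sample
#'   before each step), `levels` (segment means, length `n_steps + 1`)
#' @export
detect_bleach_steps <- function(trace, max_steps = 12L, penalty = 2) {
  n <- length(trace)
  stopifnot(n >= 4)
  segments <- list(c(1L, n))
  cps <- integer(0)
  rss0 <- sum((trace - mean(trace))^2)
  bic <- n * log(max(rss0, 1e-300) / n)
  repeat {
    if (length(cps) >= max_steps) break
    # best split over current segments
    cand <- NULL
    for (sg in segments) {
      if (sg[2] - sg[1] < 3) next
      y <- trace[sg[1]:sg[2]]
      b <- best_single_step(y)
      seg_rss0 <- sum((y - mean(y))^2)
      gain <- seg_rss0 - b$rss
      if (is.null(cand) || gain > cand$gain)
        cand <- list(gain = gain, seg = sg, k = sg[1] + b$k - 1L)
    }
    if (is.null(cand)) break
    new_cps <- sort(c(cps, cand$k))
    rss <- step_rss(trace, new_cps)
    new_bic <- n * log(max(rss, 1e-300) / n) +
      penalty * length(new_cps) * log(n)
    if (new_bic >= bic) break
    bic <- new_bic
    cps <- new_cps
    segments <- cp_segments(n, cps)
  }
  bounds <- c(0L, cps, n)
  levels <- vapply(seq_len(length(bounds) - 1L), function(i)
    mean(trace[(bounds[i] + 1L):bounds[i + 1L]]), numeric(1))
  list(n_steps = length(cps), change_points = cps, levels = levels)
}

step_rss <- function(y, cps) {
  bounds <- c(0L, cps, length(y))
  sum(vapply(seq_len(length(bounds) - 1L), function(i) {
    seg <- y[(bounds[i] + 1L):bounds[i + 1L]]
    sum((seg - mean(seg))^2)
  }, numeric(1)))
}

cp_segments <- function(n, cps) {
  bounds <- c(0L, cps, n)
  lapply(seq_len(length(bounds) - 1L), function(i)
    c(bounds[i] + 1L, bounds[i + 1L]))
}

#' Calibrate the single-fluorophore unit intensity from photobleaching traces
#'
#' Selects traces whose change-point analysis finds exactly one downward
#' step with a terminal level consistent with background (|level| below
#' `bg_tol_sd` robust noise SDs) and returns the mean pre-bleach plateau as
#' the unit (single-fluorophore) intensity. Multi-step traces (oligomers)
#' are rejected.
#'
#' @param traces list of numeric intensity traces (ADU, background at 0)
#' @param bg_tol_sd terminal-level tolerance in units of the per-trace noise SD
#' @param min_accepted minimum number of accepted single-step traces below
#'   which the result is flagged low-confidence (with a warning)
#' @param penalty BIC penalty multiplier passed to [detect_bleach_steps()]
#' @return list: `unit_intensity` (ADU), `n_accepted`, `n_total`,
#'   `low_confidence`, `accepted` (logical per trace)
#' @export
calibrate_unit_intensity <- function(traces, bg_tol_sd = 2, min_accepted = 20L,
                                     penalty = 2) {
  stopifnot(is.list(traces), length(traces) > 0)
  plateau <- rep(NA_real_, length(traces))
  for (i in seq_along(traces)) {
    y <- traces[[i]]
    if (length(y) < 4) next
    st <- detect_bleach_steps(y, penalty = penalty)
    if (st$n_steps != 1L) next
    noise <- stats::mad(diff(y)) / sqrt(2)
    if (noise == 0) noise <- max(stats::sd(y[seq_len(st$change_points[1])]), 1e-12)
    final_level <- st$levels[2]
    if (abs(final_level) > bg_tol_sd * noise) next
    if (st$levels[1] <= final_level) next        # upward step: not a bleach
    plateau[i] <- st$levels[1]
  }
  acc <- !is.na(plateau)
  if (!any(acc)) stop("no single-step traces accepted")
  low <- sum(acc) < min_accepted
  if (low)
    warning(sprintf("only %d single-step traces accepted (< %d); unit intensity is low-confidence",
                    sum(acc), min_accepted))
  list(unit_intensity = mean(plateau[acc]), n_accepted = sum(acc),
       n_total = length(traces), low_confidence = low, accepted = acc)
}

#' Convert track intensities to molecule numbers
#'
#' Divides each track's mean integrated intensity by the calibrated
#' single-fluorophore unit intensity; the ratio is reported as a positive
#' real and as the nearest integer count (at least 1).
#'
#' @param mean_intensities numeric vector of per-track mean integrated
#'   intensities (ADU), e.g. from [track_mean_intensity()]
#' @param unit_intensity single-fluorophore intensity, ADU (> 0)
#' @param track_id optional identifiers carried into the output
#' @return data.frame: `track_id`, `mean_integrated_intensity`,
#'   `n_molecules` (real), `n_molecules_rounded` (integer >= 1)
#' @export
count_molecules <- function(mean_intensities, unit_intensity,
                            track_id = seq_along(mean_intensities)) {
  if (!(unit_intensity > 0)) stop("unit_intensity must be > 0")
  ratio <- mean_intensities / unit_intensity
  data.frame(track_id = track_id,
             mean_integrated_intensity = mean_intensities,
             n_molecules = ratio,
             n_molecules_rounded = pmax(1L, as.integer(round(ratio))))
}
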
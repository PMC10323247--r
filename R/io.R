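#' Read a multi-page TIFF into an image stack
#'
#' Loads 8/16-bit unsigned or 32-bit float multi-page TIFFs. Integer data
#' are returned in ADU exactly as stored; float data are assumed to be
#' written on the package's fixed scale (ADU / 65535, see [write_stack()])
#' and are rescaled back. Metadata (pixel size, frame interval, channel
#' role) come from the caller (typically the experiment manifest), which
#' overrides any embedded tags.
#'
#' @param path TIFF file path
#' @param channel `"complex"` or `"microtubule"`
#' @param pixel_size um/px
#' @param dt s/frame
#' @return an [image_stack()]
#' @export
read_stack <- function(path, channel = "complex", pixel_size, dt) {
  if (!file.exists(path)) stop("stack file not found: ", path)
  meta <- tiff::readTIFF(path, payload = FALSE, all = TRUE)
  if (is.list(meta) && !is.data.frame(meta)) meta <- meta[[1]]
  bits <- if (is.data.frame(meta)) meta$bits.per.sample[1] else meta$bits.per.sample
  is_float <- !is.null(bits) && bits >= 32
  # integer data come back in ADU via as.is; float data are stored on the
  # package's ADU/65535 scale and must be read normalized, then rescaled
  pages <- tiff::readTIFF(path, all = TRUE, as.is = !is_float)
  if (!is.list(pages)) pages <- list(pages)
  dm <- dim(pages[[1]])
  for (i in seq_along(pages))
    if (!identical(dim(pages[[i]]), dm))
      stop("frame shape mismatch at page ", i)
  if (is_float)
    pages <- lapply(pages, function(p) p * 65535)
  image_stack(pages, channel = channel, pixel_size = pixel_size, dt = dt)
}

#' Write an image stack as a multi-page TIFF
#'
#' 16-bit unsigned output (default) stores rounded ADU clipped to
#' \[0, 65535\]; the write-then-read round trip is bit-identical. 32-bit
#' float output stores ADU / 65535 and preserves fractional ADU values to
#' single precision.
#'
#' @param stack an [image_stack()]
#' @param path output file
#' @param bits 16 (unsigned integer) or 32 (float)
#' @return `path`, invisibly
#' @export
write_stack <- function(stack, path, bits = 16L) {
  stopifnot(inherits(stack, "image_stack"), bits %in% c(16L, 32L))
  nf <- n_frames(stack)
  pages <- lapply(seq_len(nf), function(t) {
    f <- stack$frames[, , t]
    if (bits == 16L) f <- pmin(pmax(round(f), 0), 65535)
    f / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

track_csv_columns <- c("track_id", "frame", "x_px", "y_px", "sigma_px",
                       "integrated_intensity", "background")

#' Write tracks to CSV
#'
#' Stable schema: `track_id, frame, x_px, y_px, sigma_px,
#' integrated_intensity, background`, sorted by (track_id, frame). The
#' round trip through [read_tracks()] is lossless.
#'
#' @param tracks data.frame from [link_tracks()] (columns `track_id`,
#'   `frame`, `x`, `y`, `sigma`, `integrated_intensity`,
#'   `local_background`)
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_tracks <- function(tracks, path) {
  out <- data.frame(track_id = tracks$track_id, frame = tracks$frame,
                    x_px = tracks$x, y_px = tracks$y,
                    sigma_px = tracks$sigma,
                    integrated_intensity = tracks$integrated_intensity,
                    background = tracks$local_background)
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read tracks from CSV
#'
#' Validates the [write_tracks()] schema, restores the package-internal
#' column names and re-sorts by (track_id, frame), warning when rows were
#' out of order on disk.
#'
#' @param path CSV path
#' @return data.frame with columns `track_id`, `frame`, `x`, `y`, `sigma`,
#'   `integrated_intensity`, `local_background`
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop("track file not found: ", path)
  d <- utils::read.csv(path)
  missing_cols <- setdiff(track_csv_columns, names(d))
  if (length(missing_cols))
    stop("track CSV is missing columns: ", paste(missing_cols, collapse = ", "))
  o <- order(d$track_id, d$frame)
  if (!identical(o, seq_len(nrow(d)))) {
    warning("track rows out of order on disk; re-sorted")
    d <- d[o, , drop = FALSE]
  }
  data.frame(track_id = d$track_id, frame = d$frame, x = d$x_px, y = d$y_px,
             sigma = d$sigma_px, integrated_intensity = d$integrated_intensity,
             local_background = d$background)
}

#' Write / read a scene configuration as YAML (JSON fallback)
#'
#' @param config a [scene_config()]
#' @param path output path; `.json` selects JSON, anything else YAML
#' @return `path` invisibly (write) or a `scene_config` (read)
#' @export
write_scene_config <- function(config, path) {
  stopifnot(inherits(config, "scene_config"))
  lst <- unclass(config)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

#' @rdname write_scene_config
#' @export
read_scene_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lst <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  do.call(scene_config, lst[intersect(names(lst), names(formals(scene_config)))])
}

#' Write ground truth to CSV
#'
#' Emits one row per particle per frame with the true path position,
#' rendered pixel position, oligomer size, motility class and surviving
#' fluorophore count.
#'
#' @param truth a `ground_truth` from [simulate_tracks()]
#' @param path output CSV
#' @return `path`, invisibly
#' @export
write_ground_truth <- function(truth, path) {
  d <- merge(truth$positions,
             truth$particles[, c("particle_id", "oligomer_size", "class")],
             by = "particle_id")
  d <- merge(d, truth$fluorophores, by = c("particle_id", "frame"))
  d <- d[order(d$particle_id, d$frame),
         c("particle_id", "frame", "arclength_um", "x_px", "y_px",
           "oligomer_size", "class", "surviving")]
  names(d)[names(d) == "surviving"] <- "surviving_fluorophores"
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
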
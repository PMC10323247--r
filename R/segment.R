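#' Segment microtubules from the microtubule channel
#'
#' The time-averaged microtubule image is thresholded (Otsu on the averaged
#' frame), small objects are removed, the binary mask is skeletonized
#' (Zhang-Suen thinning) and each skeleton branch at least `min_length_px`
#' long is ordered into a point list with cumulative arclength. A dilated
#' mask (radius `dilate_px`) around each filament is returned as the
#' per-microtubule measurement area.
#'
#' @param mt_stack an [image_stack()] with `channel == "microtubule"`
#' @param min_length_px minimum skeleton length kept, px
#' @param dilate_px dilation radius defining the area around each
#'   microtubule, px
#' @return list of `microtubule_path` objects, each carrying an extra `mask`
#'   field (logical H x W matrix of its dilated area). Empty list (with a
#'   warning) when no filament is found.
#' @export
segment_microtubules <- function(mt_stack, min_length_px = 20, dilate_px = 4L) {
  stopifnot(inherits(mt_stack, "image_stack"))
  avg <- apply(mt_stack$frames, c(1, 2), mean)
  rng <- range(avg)
  if (diff(rng) <= 0) {
    warning("no microtubule found (flat channel)")
    return(list())
  }
  norm <- (avg - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  bw <- norm > thr
  if (!any(bw)) {
    warning("no microtubule found")
    return(list())
  }
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  lab <- EBImage::imageData(lab)
  paths <- list()
  brush <- EBImage::makeBrush(2L * as.integer(dilate_px) + 1L, shape = "disc")
  for (k in seq_len(max(lab))) {
    comp <- lab == k
    if (sum(comp) < min_length_px) next
    skel <- zhang_suen_thin(comp)
    pts <- order_skeleton(skel)
    if (is.null(pts) || nrow(pts) < max(2, min_length_px)) next
    mask <- EBImage::imageData(EBImage::dilate(EBImage::Image(comp * 1), brush)) > 0
    width <- 2 * sum(comp) / max(nrow(pts), 1)  # mean cross-section estimate
    p <- microtubule_path(pts, mt_stack$pixel_size, width_px = width)
    p$mask <- mask
    paths[[length(paths) + 1L]] <- p
  }
  if (!length(paths)) warning("no microtubule found")
  paths
}

# Zhang-Suen binary thinning; input/output logical matrix
zhang_suen_thin <- function(bw) {
  img <- matrix(0L, nrow(bw) + 2L, ncol(bw) + 2L)
  img[2:(nrow(bw) + 1L), 2:(ncol(bw) + 1L)] <- bw * 1L
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      idx <- which(img == 1L)
      if (!length(idx)) break
      H <- nrow(img)
      r <- ((idx - 1L) %% H) + 1L; c <- ((idx - 1L) %/% H) + 1L
      p2 <- img[cbind(r - 1L, c)];     p3 <- img[cbind(r - 1L, c + 1L)]
      p4 <- img[cbind(r, c + 1L)];     p5 <- img[cbind(r + 1L, c + 1L)]
      p6 <- img[cbind(r + 1L, c)];     p7 <- img[cbind(r + 1L, c - 1L)]
      p8 <- img[cbind(r, c - 1L)];     p9 <- img[cbind(r - 1L, c - 1L)]
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- cbind(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      A <- rowSums(seqs[, 1:8, drop = FALSE] == 0L &
                   seqs[, 2:9, drop = FALSE] == 1L)
      if (phase == 1) {
        del <- B >= 2 & B <= 6 & A == 1 & (p2 * p4 * p6) == 0 & (p4 * p6 * p8) == 0
      } else {
        del <- B >= 2 & B <= 6 & A == 1 & (p2 * p4 * p8) == 0 & (p2 * p6 * p8) == 0
      }
      if (any(del)) {
        img[idx[del]] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img[2:(nrow(bw) + 1L), 2:(ncol(bw) + 1L)] == 1L
}

# order skeleton pixels into an (x, y) 0-based point matrix by walking from
# an endpoint; returns NULL for pathological skeletons
order_skeleton <- function(skel) {
  idx <- which(skel)
  if (length(idx) < 2) return(NULL)
  H <- nrow(skel)
  r <- ((idx - 1L) %% H) + 1L; c <- ((idx - 1L) %/% H) + 1L
  pts <- cbind(r, c)
  key <- paste(r, c)
  nbr_count <- function(p) {
    n <- 0L
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      if (paste(p[1] + dy, p[2] + dx) %in% key) n <- n + 1L
    }
    n
  }
  deg <- apply(pts, 1, nbr_count)
  start <- if (any(deg == 1)) which(deg == 1)[1] else 1L
  visited <- rep(FALSE, nrow(pts))
  ord <- integer(0)
  cur <- start
  repeat {
    visited[cur] <- TRUE
    ord <- c(ord, cur)
    # nearest unvisited 8-neighbour
    cand <- which(!visited &
                  abs(pts[, 1] - pts[cur, 1]) <= 1 &
                  abs(pts[, 2] - pts[cur, 2]) <= 1)
    if (!length(cand)) break
    d <- (pts[cand, 1] - pts[cur, 1])^2 + (pts[cand, 2] - pts[cur, 2])^2
    cur <- cand[which.min(d)]
  }
  if (length(ord) < 2) return(NULL)
  # x = col - 1, y = row - 1 (0-based pixel-centre convention)
  cbind(x = pts[ord, 2] - 1, y = pts[ord, 1] - 1)
}

# bilinear interpolation at 0-based (x, y); outside the image -> edge value
bilinear <- function(frame, x, y) {
  H <- nrow(frame); W <- ncol(frame)
  x <- pmin(pmax(x, 0), W - 1); y <- pmin(pmax(y, 0), H - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, W - 1); y1 <- pmin(y0 + 1, H - 1)
  fx <- x - x0; fy <- y - y0
  v00 <- frame[cbind(y0 + 1, x0 + 1)]; v10 <- frame[cbind(y0 + 1, x1 + 1)]
  v01 <- frame[cbind(y1 + 1, x0 + 1)]; v11 <- frame[cbind(y1 + 1, x1 + 1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v10) + fy * ((1 - fx) * v01 + fx * v11)
}

#' Build a kymograph (time x arclength intensity map) along a path
#'
#' For every frame, the image is sampled by bilinear interpolation at 1 px
#' steps along the path; at each arclength step the intensity is reduced
#' over a `width`-px cross-section normal to the path (maximum by default,
#' mean optionally).
#'
#' @param stack an [image_stack()]
#' @param path a `microtubule_path`
#' @param width cross-section width, px (>= 1)
#' @param fun `"max"` or `"mean"` reduction across the cross-section
#' @return numeric matrix, rows = frames (time), columns = arclength samples
#' @export
make_kymograph <- function(stack, path, width = 5, fun = c("max", "mean")) {
  fun <- match.arg(fun)
  if (width < 1) stop("width must be >= 1")
  step_um <- stack$pixel_size                   # 1 px arclength sampling
  s <- seq(0, path$length_um, by = step_um)
  xy <- path_point_at(path, s)
  # unit tangent by central differences -> unit normal
  tx <- c(diff(xy[, 1]), NA); ty <- c(diff(xy[, 2]), NA)
  tx[length(tx)] <- tx[length(tx) - 1]; ty[length(ty)] <- ty[length(ty) - 1]
  nrm <- sqrt(tx^2 + ty^2); nrm[nrm == 0] <- 1
  nx <- -ty / nrm; ny <- tx / nrm
  offs <- seq(-(width - 1) / 2, (width - 1) / 2, length.out = max(1, round(width)))
  nf <- n_frames(stack)
  kymo <- matrix(0, nf, length(s))
  for (t in seq_len(nf)) {
    frame <- stack$frames[, , t]
    prof <- matrix(0, length(offs), length(s))
    for (j in seq_along(offs))
      prof[j, ] <- bilinear(frame, xy[, 1] + offs[j] * nx, xy[, 2] + offs[j] * ny)
    kymo[t, ] <- if (fun == "max") apply(prof, 2, max) else colMeans(prof)
  }
  kymo
}
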
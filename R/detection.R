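# Spot detection on single frames and Gag-anchored event-site building.

# Separable Gaussian blur with replicate edge padding.
gaussian_blur <- function(img, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(m) {
    # pad rows by replication, convolve down columns
    padded <- rbind(m[rep(1L, r), , drop = FALSE], m,
                    m[rep(nrow(m), r), , drop = FALSE])
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) {
      out <- out + k[i] * padded[i:(i + nrow(m) - 1L), , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(img))))
}

#' Detect diffraction-limited spots in a frame
#'
#' Difference-of-Gaussians (DoG) blob detection: the frame is filtered at
#' `psf_sigma` and `1.6 * psf_sigma`, strict 8-neighbour local maxima of
#' the difference are thresholded at `threshold_snr` times a robust noise
#' scale (median absolute deviation of the DoG response), and each
#' detection is refined to a subpixel centroid by intensity-weighted
#' center of mass in a `(2*ceil(3*psf_sigma)+1)^2` window (weights are the
#' window values above their perimeter median).
#'
#' @param frame 2-D numeric matrix (finite values).
#' @param psf_sigma expected spot sigma in pixels, `> 0`.
#' @param threshold_snr detection threshold in robust noise SDs.
#' @return data.frame with columns `row`, `col` (0-based subpixel
#'   centroid), `peak` (DoG response) and `quality`, sorted by descending
#'   peak. Zero rows if nothing is found.
#' @export
detect_spots <- function(frame, psf_sigma = 1.3, threshold_snr = 5) {
  stopifnot(is.matrix(frame), psf_sigma > 0)
  empty <- data.frame(row = numeric(0), col = numeric(0),
                      peak = numeric(0), quality = character(0))
  if (!all(is.finite(frame))) stop_invalid("frame contains non-finite values")
  if (diff(range(frame)) == 0) return(empty)
  dog <- gaussian_blur(frame, psf_sigma) - gaussian_blur(frame, 1.6 * psf_sigma)
  noise <- stats::mad(dog)
  thr <- threshold_snr * noise
  h <- nrow(dog); w <- ncol(dog)
  core <- dog[2:(h - 1), 2:(w - 1)]
  is_max <- core > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (core > dog[2:(h - 1) + dr, 2:(w - 1) + dc])
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  rwin <- as.integer(ceiling(3 * psf_sigma))
  cent <- t(apply(idx, 1L, function(ij) {
    r <- ij[1] + 1L; c <- ij[2] + 1L  # back to full-frame 1-based indices
    rr <- max(1L, r - rwin):min(h, r + rwin)
    cc <- max(1L, c - rwin):min(w, c + rwin)
    win <- frame[rr, cc, drop = FALSE]
    perim <- c(win[1, ], win[nrow(win), ], win[, 1], win[, ncol(win)])
    wgt <- pmax(win - stats::median(perim), 0)
    s <- sum(wgt)
    if (s <= 0) return(c(r - 1, c - 1))
    c(sum((rr - 1) * rowSums(wgt)), sum((cc - 1) * colSums(wgt))) / s
  }))
  out <- data.frame(row = cent[, 1], col = cent[, 2],
                    peak = dog[cbind(idx[, 1] + 1L, idx[, 2] + 1L)],
                    quality = "ok")
  out <- out[order(-out$peak, out$row, out$col), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build stationary event sites from start/end Gag detections
#'
#' Greedy nearest-neighbour matching (ascending pair distance, each
#' detection used once, ties broken by lower (row, col)) between the Gag
#' detections at the start and end of the record. Pairs displaced by at
#' most `max_displacement` become valid sites anchored at the start
#' centroid; everything else is reported as rejected.
#'
#' @param gag_start,gag_end detection tables from [detect_spots()].
#' @param max_displacement maximum allowed displacement (px).
#' @return data.frame with `site_id`, `row`, `col`, `displacement_px`,
#'   `status` (`"valid"`/`"rejected"`), `reason`.
#' @export
build_event_sites <- function(gag_start, gag_end, max_displacement = 2) {
  n1 <- nrow(gag_start); n2 <- nrow(gag_end)
  if (n1 == 0L || n2 == 0L) {
    return(data.frame(site_id = integer(0), row = numeric(0),
                      col = numeric(0), displacement_px = numeric(0),
                      status = character(0), reason = character(0)))
  }
  d <- outer(seq_len(n1), seq_len(n2), function(i, j) {
    sqrt((gag_start$row[i] - gag_end$row[j])^2 +
         (gag_start$col[i] - gag_end$col[j])^2)
  })
  pairs <- data.frame(i = rep(seq_len(n1), n2),
                      j = rep(seq_len(n2), each = n1),
                      dist = as.vector(d))
  pairs <- pairs[order(pairs$dist, gag_start$row[pairs$i],
                       gag_start$col[pairs$i]), ]
  used_i <- logical(n1); used_j <- logical(n2)
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (used_i[i] || used_j[j]) next
    used_i[i] <- TRUE; used_j[j] <- TRUE
    ok <- pairs$dist[k] <= max_displacement
    rows[[length(rows) + 1L]] <- data.frame(
      row = gag_start$row[i], col = gag_start$col[i],
      displacement_px = pairs$dist[k],
      status = if (ok) "valid" else "rejected",
      reason = if (ok) "" else "displacement exceeds max_displacement")
  }
  for (i in which(!used_i)) {
    rows[[length(rows) + 1L]] <- data.frame(
      row = gag_start$row[i], col = gag_start$col[i],
      displacement_px = NA_real_, status = "rejected",
      reason = "no end-frame match")
  }
  for (j in which(!used_j)) {
    rows[[length(rows) + 1L]] <- data.frame(
      row = gag_end$row[j], col = gag_end$col[j],
      displacement_px = NA_real_, status = "rejected",
      reason = "no start-frame match")
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$row, out$col), ]
  out <- cbind(site_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Colocalize a site with a channel's detections
#'
#' @param site one row of a site table (needs `row`, `col`).
#' @param channel_detections a [detect_spots()] table.
#' @param radius matching radius (px), `> 0`; detections strictly beyond
#'   it do not colocalize.
#' @return list with `colocalized` (logical) and `offset`
#'   (`c(drow, dcol)` of the nearest detection, `NA` if none within
#'   radius).
#' @export
colocalize <- function(site, channel_detections, radius = 2) {
  stopifnot(radius > 0)
  if (nrow(channel_detections) == 0L) {
    return(list(colocalized = FALSE, offset = c(NA_real_, NA_real_)))
  }
  d <- sqrt((channel_detections$row - site$row)^2 +
            (channel_detections$col - site$col)^2)
  k <- which.min(d)
  if (d[k] <= radius) {
    list(colocalized = TRUE,
         offset = c(channel_detections$row[k] - site$row,
                    channel_detections$col[k] - site$col))
  } else {
    list(colocalized = FALSE, offset = c(NA_real_, NA_real_))
  }
}
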
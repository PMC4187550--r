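# Raster/vector geometry primitives shared by the synthetic generator and the
# segmentation stage.
#
# Convention (used everywhere in this package): images are numeric matrices
# indexed [x, y] with 1-based integer pixel centres; x increases along the
# first dimension, y along the second. A pixel's position is its centre.

#' Closed contour with a smooth random radial perturbation
#'
#' Builds a star-shaped closed polygon around `centre`: the radius at polar
#' angle theta is `radius_px * (1 + irregularity * s(theta))` where `s` is a
#' band-limited random harmonic series normalised to max |s| = 1. With
#' `irregularity = 0` the contour is an exact circle.
#'
#' @param centre numeric length-2, (x, y) in pixels.
#' @param radius_px mean radius in pixels.
#' @param irregularity relative perturbation amplitude in `[0, 1)`.
#' @param n_vertices number of polygon vertices.
#' @param n_harmonics highest random harmonic (harmonics 2..n_harmonics are
#'   used so the centroid stays near `centre`).
#' @return an `n_vertices` x 2 matrix of (x, y) vertices; the polygon is
#'   closed implicitly (last vertex connects to the first).
#' @keywords internal
radial_contour <- function(centre, radius_px, irregularity = 0,
                           n_vertices = 360L, n_harmonics = 6L) {
  stopifnot_scalar_number(radius_px, "radius_px", positive = TRUE)
  if (irregularity < 0 || irregularity >= 1) {
    abort_glut4("`irregularity` must lie in [0, 1)", "glut4_invalid_parameter")
  }
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  s <- rep(0, n_vertices)
  if (irregularity > 0 && n_harmonics >= 2L) {
    for (k in 2:n_harmonics) {
      # decaying amplitude keeps the boundary smooth
      a <- stats::rnorm(1, 0, 1 / k)
      b <- stats::rnorm(1, 0, 1 / k)
      s <- s + a * cos(k * theta) + b * sin(k * theta)
    }
    if (max(abs(s)) > 0) s <- s / max(abs(s))
  }
  r <- radius_px * (1 + irregularity * s)
  cbind(x = centre[1] + r * cos(theta), y = centre[2] + r * sin(theta))
}

#' Polygon area by the shoelace formula (pixel^2 units)
#' @keywords internal
polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Polygon perimeter (pixel units)
#' @keywords internal
polygon_perimeter <- function(v) {
  d <- sqrt(rowSums((v - v[c(2:nrow(v), 1), , drop = FALSE])^2))
  sum(d)
}

#' Resample a closed polygon to uniform arc-length spacing
#'
#' @param v n x 2 vertex matrix (closed implicitly).
#' @param n_out number of output vertices.
#' @return `n_out` x 2 matrix starting at the original first vertex.
#' @keywords internal
resample_contour <- function(v, n_out) {
  vc <- rbind(v, v[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(vc)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) abort_glut4("degenerate contour (zero perimeter)",
                              "glut4_segmentation_failure")
  target <- seq(0, total, length.out = n_out + 1L)[-(n_out + 1L)]
  xi <- stats::approx(cum, vc[, 1], xout = target, ties = "ordered")$y
  yi <- stats::approx(cum, vc[, 2], xout = target, ties = "ordered")$y
  cbind(x = xi, y = yi)
}

#' Rasterise the interior of a closed polygon (even-odd scanline fill)
#'
#' @param v n x 2 vertex matrix.
#' @param dim integer length-2 image dimensions (nx, ny).
#' @return logical matrix, TRUE where the pixel centre lies inside.
#' @keywords internal
fill_contour <- function(v, dim) {
  nx <- dim[1]; ny <- dim[2]
  mask <- matrix(FALSE, nx, ny)
  x1 <- v[, 1]; y1 <- v[, 2]
  idx <- c(2:nrow(v), 1)
  x2 <- v[idx, 1]; y2 <- v[idx, 2]
  # crossings per scan row, half-open rule avoids double counting vertices
  for (yy in seq_len(ny)) {
    lo <- pmin(y1, y2); hi <- pmax(y1, y2)
    hit <- which(lo <= yy & yy < hi)
    if (length(hit) == 0) next
    xc <- x1[hit] + (yy - y1[hit]) * (x2[hit] - x1[hit]) / (y2[hit] - y1[hit])
    xc <- sort(xc)
    for (j in seq(1, length(xc) - 1, by = 2)) {
      a <- max(1, ceiling(xc[j] + 1e-9)); b <- min(nx, floor(xc[j + 1] - 1e-9))
      if (b >= a) mask[a:b, yy] <- TRUE
    }
  }
  mask
}

#' Minimum Euclidean distance from points to a closed polyline
#'
#' @param p m x 2 matrix of query points.
#' @param v n x 2 vertex matrix of the closed polygon.
#' @return numeric vector of length m.
#' @keywords internal
dist_to_polyline <- function(p, v) {
  m <- nrow(p)
  best <- rep(Inf, m)
  idx <- c(2:nrow(v), 1)
  px <- p[, 1]; py <- p[, 2]
  for (e in seq_len(nrow(v))) {
    ax <- v[e, 1]; ay <- v[e, 2]
    bx <- v[idx[e], 1]; by <- v[idx[e], 2]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      d2 <- (px - ax)^2 + (py - ay)^2
    } else {
      t <- ((px - ax) * dx + (py - ay) * dy) / len2
      t <- pmin(1, pmax(0, t))
      d2 <- (px - (ax + t * dx))^2 + (py - (ay + t * dy))^2
    }
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' Interior / band / exterior masks of a closed contour
#'
#' The band contains the pixels whose centre lies within `halfwidth_px` of the
#' contour polyline (exact point-to-segment distances; an EBImage distance
#' transform is only used to pre-select candidate pixels). The interior mask
#' excludes the band.
#'
#' @return list(interior, band, exterior, fill) of logical matrices where
#'   `fill` is the raw polygon fill (band not removed).
#' @keywords internal
contour_band_masks <- function(v, dim, halfwidth_px) {
  fill <- fill_contour(v, dim)
  # distance queries only need modest vertex density; resampling long
  # contours keeps the exact point-to-segment pass cheap (chord error at
  # 256 vertices is far below the rasterisation scale)
  vq <- if (nrow(v) > 256L) resample_contour(v, 256L) else v
  din <- as.matrix(EBImage::distmap(matrix(as.numeric(fill), dim[1], dim[2])))
  dout <- as.matrix(EBImage::distmap(matrix(as.numeric(!fill), dim[1], dim[2])))
  cand <- (fill & din <= halfwidth_px + 2) | (!fill & dout <= halfwidth_px + 2)
  band <- matrix(FALSE, dim[1], dim[2])
  ci <- which(cand, arr.ind = TRUE)
  if (nrow(ci) > 0) {
    dd <- dist_to_polyline(ci, vq)
    band[cand] <- dd <= halfwidth_px
  }
  interior <- fill & !band
  exterior <- !(band | interior)
  list(interior = interior, band = band, exterior = exterior, fill = fill)
}

#' Gaussian blur with replicated-edge boundary handling
#'
#' Thin wrapper over EBImage's FFT filter with a Gaussian brush; the kernel is
#' truncated when the image is smaller than the nominal support.
#' @keywords internal
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  size <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  size <- min(size, 2L * (min(dim(m)) %/% 2L) - 1L)
  if (size < 3L) return(m)
  brush <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
  brush <- brush / sum(brush)  # truncation leaves the kernel slightly < 1
  as.matrix(EBImage::filter2(m, brush, boundary = "replicate"))
}

#' Central-difference gradient of a matrix (replicated edges)
#' @return list(gx, gy)
#' @keywords internal
grad_xy <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  xp <- m[c(2:nx, nx), ]; xm <- m[c(1, 1:(nx - 1)), ]
  yp <- m[, c(2:ny, ny)]; ym <- m[, c(1, 1:(ny - 1))]
  list(gx = (xp - xm) / 2, gy = (yp - ym) / 2)
}

#' Bilinear interpolation of a matrix at sub-pixel points
#' @keywords internal
bilinear <- function(m, x, y) {
  nx <- nrow(m); ny <- ncol(m)
  x <- pmin(pmax(x, 1), nx); y <- pmin(pmax(y, 1), ny)
  x0 <- pmin(floor(x), nx - 1L); y0 <- pmin(floor(y), ny - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(x0, y0); i10 <- cbind(x0 + 1, y0)
  i01 <- cbind(x0, y0 + 1); i11 <- cbind(x0 + 1, y0 + 1)
  m[i00] * (1 - fx) * (1 - fy) + m[i10] * fx * (1 - fy) +
    m[i01] * (1 - fx) * fy + m[i11] * fx * fy
}
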
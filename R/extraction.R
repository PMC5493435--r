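# From image + outline to the cortical intensity profile. Replaces the
# manual freehand-trace / straighten / plot-profile workflow with a
# reproducible geometric one: iso-contour outline, arc-length-equidistant
# sampling with a fixed geometric phase origin, bilinear interpolation
# averaged across a band normal to the outline.

shoelace_area <- function(x, y) {
  0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

polygon_centroid <- function(x, y) {
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  a <- 0.5 * sum(cross)
  c(sum((x + xn) * cross), sum((y + yn) * cross)) / (6 * a)
}

#' Extract a closed cell outline from a binary mask
#'
#' Traces the boundary of the single foreground component of a mask as a
#' subpixel polygon (marching-squares iso-contour at level 0.5), oriented
#' clockwise in image coordinates (x right, y down). This is the automated
#' stand-in for manually tracing the cell perimeter.
#'
#' @param mask Logical or 0/1 numeric matrix (rows = y) with exactly one
#'   connected foreground component of area >= 9 px.
#' @return A tibble of class `cell_outline` with columns `x`, `y`
#'   (0-based subpixel image coordinates).
#' @examples
#' mask <- matrix(FALSE, 20, 20); mask[6:15, 6:15] <- TRUE
#' outline <- extract_outline(mask)
#' @export
extract_outline <- function(mask) {
  mask <- mask_matrix(mask)
  npix <- sum(mask)
  if (npix == 0) {
    abort("empty mask: no foreground component to outline",
      class = "crescentr_error")
  }
  n_comp <- max(EBImage::bwlabel(mask))
  if (n_comp != 1) {
    abort(sprintf("mask has %d connected components; exactly one is required",
      n_comp), class = "crescentr_error")
  }
  if (npix < 9) {
    abort("foreground component smaller than 9 px", class = "crescentr_error")
  }
  h <- nrow(mask); w <- ncol(mask)
  padded <- matrix(0, h + 2, w + 2)
  padded[2:(h + 1), 2:(w + 1)] <- mask
  # contourLines treats rows of z as its x axis: our y. Grid offset -1 for
  # the padding ring, so coordinates land on 0-based pixel centers.
  cl <- grDevices::contourLines(x = -1:h, y = -1:w, z = padded, levels = 0.5)
  lengths <- vapply(cl, function(p) length(p$x), integer(1))
  p <- cl[[which.max(lengths)]]
  x <- p$y; y <- p$x # swap back to image (x, y)
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) { # drop duplicated closing vertex
    x <- x[-n]; y <- y[-n]
  }
  if (shoelace_area(x, y) < 0) { # enforce clockwise (y-down frame)
    x <- rev(x); y <- rev(y)
  }
  structure(tibble(x = x, y = y),
    class = c("cell_outline", class(tibble())))
}

mask_matrix <- function(mask) {
  if (!is.matrix(mask)) abort("mask must be a matrix", class = "crescentr_error")
  mode(mask) <- "numeric"
  (mask > 0.5) * 1
}

outline_coords <- function(outline) {
  if (is.data.frame(outline)) {
    stopifnot(all(c("x", "y") %in% names(outline)))
    return(list(x = as.numeric(outline$x), y = as.numeric(outline$y)))
  }
  abort("outline must be a data frame with columns x and y",
    class = "crescentr_error")
}

# arc position of the outermost intersection of the ray centroid + s * dir
# with the polygon; exact per-edge linear solve so the phase origin is
# independent of where the vertex list happens to start.
ray_arc_position <- function(x, y, cumlen, centroid, dir) {
  n <- length(x)
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  ex <- xn - x; ey <- yn - y
  det <- dir[1] * (-ey) - dir[2] * (-ex)
  rx <- x - centroid[1]; ry <- y - centroid[2]
  s <- ifelse(abs(det) > 1e-12, (rx * (-ey) + ry * ex) / det, NA_real_)
  u <- ifelse(abs(det) > 1e-12, (dir[1] * ry - dir[2] * rx) / det, NA_real_)
  hit <- !is.na(s) & s > 0 & u >= 0 & u < 1
  if (!any(hit)) {
    abort("could not anchor the phase origin on the outline",
      class = "crescentr_error")
  }
  i <- which(hit)[which.max(s[hit])]
  cumlen[i] + u[i] * sqrt(ex[i]^2 + ey[i]^2)
}

bilinear <- function(image, px, py) {
  h <- nrow(image); w <- ncol(image)
  if (any(px < 0 | px > w - 1 | py < 0 | py > h - 1)) {
    abort("outline (or its sampling band) exits the image bounds",
      class = "crescentr_error")
  }
  x0 <- pmin(floor(px), w - 2); y0 <- pmin(floor(py), h - 2)
  fx <- px - x0; fy <- py - y0
  i00 <- image[cbind(y0 + 1, x0 + 1)]
  i01 <- image[cbind(y0 + 1, x0 + 2)]
  i10 <- image[cbind(y0 + 2, x0 + 1)]
  i11 <- image[cbind(y0 + 2, x0 + 2)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

#' Sample a cortical intensity profile along an outline
#'
#' Takes `n_samples` grey values at arc-length-equidistant positions along
#' a closed outline, each the mean of bilinear interpolation at
#' `line_width` one-pixel-spaced offsets normal to the outline. The first
#' sample sits one step past the fixed phase origin — the outline point in
#' the direction of the anterior-posterior axis from the cell centroid —
#' and traversal is clockwise, so sample k corresponds to angle
#' `theta_k = 2*pi*k/N` and phases reported by the harmonic statistics are
#' comparable across cells. The origin is geometric: cyclically reindexing
#' the outline vertex list does not change the sampled profile.
#'
#' @param image Numeric matrix (rows = y).
#' @param outline A [extract_outline()] result or any data frame with
#'   subpixel columns `x`, `y` (0-based, y down) forming a closed polygon.
#' @param n_samples Number of samples N (default 100).
#' @param line_width Width in px of the sampling band normal to the
#'   outline (default 3, averaging offsets -1, 0, +1).
#' @param offset Shift of the whole band along the outward normal, in px;
#'   negative values sample inside the outline (e.g. `-ring_width/2` to
#'   sit on the cortical ring centerline of a synthetic cell).
#' @param ap_axis Unit reference direction of the anterior-posterior axis
#'   in image coordinates, default `c(1, 0)`.
#' @param pixel_scale Optional microns per pixel; when given,
#'   `arc_position` is reported in microns.
#' @return A raw [intensity_profile()]; `arc_position` holds the cumulative
#'   arc length from the phase origin.
#' @export
sample_profile <- function(image, outline, n_samples = 100, line_width = 3,
                           offset = 0, ap_axis = c(1, 0),
                           pixel_scale = NULL) {
  if (n_samples < 3) {
    abort("n_samples must be at least 3", class = "crescentr_error")
  }
  co <- outline_coords(outline)
  x <- co$x; y <- co$y
  n <- length(x)
  if (n < 3) abort("outline needs at least 3 vertices", class = "crescentr_error")
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  elen <- sqrt((xn - x)^2 + (yn - y)^2)
  keep <- elen > 0 # drop zero-length edges up front
  if (any(!keep)) {
    x <- x[keep]; y <- y[keep]
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    elen <- sqrt((xn - x)^2 + (yn - y)^2)
  }
  cumlen <- c(0, cumsum(elen))
  total <- cumlen[length(cumlen)]
  centroid <- polygon_centroid(x, y)
  ap <- ap_axis / sqrt(sum(ap_axis^2))
  t0 <- ray_arc_position(x, y, cumlen[-length(cumlen)], centroid, ap)
  arc <- total * seq_len(n_samples) / n_samples
  tq <- (t0 + arc) %% total
  edge <- findInterval(tq, cumlen, rightmost.closed = TRUE)
  edge <- pmin(pmax(edge, 1), length(elen))
  u <- (tq - cumlen[edge]) / elen[edge]
  px <- x[edge] + u * (xn[edge] - x[edge])
  py <- y[edge] + u * (yn[edge] - y[edge])
  tx <- (xn[edge] - x[edge]) / elen[edge]
  ty <- (yn[edge] - y[edge]) / elen[edge]
  # outward normal of a clockwise polygon in the y-down frame
  nx <- ty; ny <- -tx
  m <- max(1L, as.integer(round(line_width)))
  offs <- offset + seq(-(m - 1) / 2, (m - 1) / 2, length.out = m)
  acc <- rep(0, n_samples)
  for (o in offs) {
    acc <- acc + bilinear(image, px + o * nx, py + o * ny)
  }
  scale <- pixel_scale %||% 1
  intensity_profile(acc / m, arc_position = arc * scale)
}

#' Estimate the image background level
#'
#' Median grey value of the pixels outside a 3-px dilation of the cell
#' mask; the dilation keeps the blurred cortex edge out of the estimate.
#'
#' @param image Numeric matrix (rows = y).
#' @param mask Logical/0-1 matrix of the cell region, same shape.
#' @param clearance Dilation radius in px (default 3).
#' @return Scalar background grey value.
#' @export
estimate_background <- function(image, mask, clearance = 3) {
  mask <- mask_matrix(mask)
  stopifnot(all(dim(image) == dim(mask)))
  brush <- EBImage::makeBrush(2 * as.integer(clearance) + 1, shape = "disc")
  grown <- EBImage::dilate(mask, brush)
  outside <- image[grown < 0.5]
  if (length(outside) == 0) {
    abort("no exterior pixels left to estimate the background from",
      class = "crescentr_error")
  }
  median(outside)
}

#' Full extraction pipeline: image + mask to normalized profile
#'
#' Convenience wrapper chaining [extract_outline()], [sample_profile()],
#' [background_correct()] and [normalize_profile()].
#'
#' @inheritParams sample_profile
#' @param mask Binary cell mask.
#' @param background `"auto"` ([estimate_background()]), `"none"`, or a
#'   fixed nonnegative grey value.
#' @return A mean-normalized [intensity_profile()].
#' @examples
#' sim <- simulate_cell_image(cell_spec(crescent_kappa = 4))
#' prof <- extract_cortical_profile(sim$image, sim$mask, offset = -2)
#' polarization_coefficient(prof)
#' @export
extract_cortical_profile <- function(image, mask, n_samples = 100,
                                     line_width = 3, offset = 0,
                                     background = "auto", ap_axis = c(1, 0),
                                     pixel_scale = NULL) {
  outline <- extract_outline(mask)
  prof <- sample_profile(image, outline, n_samples = n_samples,
    line_width = line_width, offset = offset, ap_axis = ap_axis,
    pixel_scale = pixel_scale)
  bg <- if (identical(background, "auto")) {
    estimate_background(image, mask)
  } else if (identical(background, "none")) 0 else as.numeric(background)
  normalize_profile(background_correct(prof, bg))
}
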
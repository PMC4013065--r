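#' Nearest-neighbour colour classification
#'
#' Labels every pixel as plant or background according to which colour
#' exemplar set contains its nearest neighbour in RGB space (Euclidean
#' distance on raw 0-255 intensities, no colour-space conversion). Ties
#' between the closest foreground and closest background exemplar are
#' resolved to background, the conservative choice for a segmentation
#' whose false positives are pruned later by morphology and the pot
#' filter.
#'
#' @param image numeric array `c(H, W, 3)` with intensities in \[0, 255\]
#'   (as returned by [read_image()]).
#' @param samples a list with components `foreground` and `background`,
#'   each a matrix (or vector) of RGB exemplar rows in \[0, 255\]; see
#'   [colour_samples()].
#' @param px_per_mm scale factor attached to the resulting mask.
#' @return a [binary_mask()].
#' @export
classify_nearest_neighbour <- function(image, samples, px_per_mm = 1) {
  samples <- colour_samples(samples$foreground, samples$background)
  d <- dim(image)
  if (length(d) != 3L || d[3] < 3L) stop("`image` must be an H x W x 3 array")
  px <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
              as.vector(image[, , 3]))
  dfg <- min_sq_dist(px, samples$foreground)
  dbg <- min_sq_dist(px, samples$background)
  binary_mask(matrix(dfg < dbg, nrow = d[1], ncol = d[2]),
              px_per_mm = px_per_mm)
}

#' @rdname classify_nearest_neighbour
#' @param foreground,background RGB exemplars: a length-3 vector or a
#'   matrix with 3 columns.
#' @export
colour_samples <- function(foreground, background) {
  norm1 <- function(x, what) {
    if (is.null(x) || length(x) == 0L)
      stop("empty ", what, " colour sample set")
    if (!is.matrix(x)) x <- matrix(x, ncol = 3L, byrow = TRUE)
    if (ncol(x) != 3L) stop(what, " samples must have 3 columns (R,G,B)")
    if (anyNA(x) || any(x < 0) || any(x > 255))
      stop(what, " samples must lie in [0, 255]")
    x
  }
  list(foreground = norm1(foreground, "foreground"),
       background = norm1(background, "background"))
}

min_sq_dist <- function(px, exemplars) {
  # px: n x 3, exemplars: m x 3 -> per-pixel min squared distance
  d <- rep(Inf, nrow(px))
  for (i in seq_len(nrow(exemplars))) {
    e <- exemplars[i, ]
    di <- (px[, 1] - e[1])^2 + (px[, 2] - e[2])^2 + (px[, 3] - e[3])^2
    d <- pmin(d, di)
  }
  d
}

# ---- morphology -----------------------------------------------------------

disc_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
}

shift_mask <- function(g, dr, dc, fill = FALSE) {
  h <- nrow(g); w <- ncol(g)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- g[rs - dr, cs - dc, drop = FALSE]
  out
}

erode_mask <- function(g, radius) {
  if (radius <= 0) return(g)
  off <- disc_offsets(radius)
  out <- g
  for (i in seq_len(nrow(off)))
    out <- out & shift_mask(g, off$dr[i], off$dc[i], fill = FALSE)
  out
}

dilate_mask <- function(g, radius) {
  if (radius <= 0) return(g)
  off <- disc_offsets(radius)
  out <- g
  for (i in seq_len(nrow(off)))
    out <- out | shift_mask(g, off$dr[i], off$dc[i], fill = FALSE)
  out
}

#' Morphological cleanup of a segmentation
#'
#' Erosion followed by dilation (an opening when the radii are equal),
#' both with a disc structuring element rasterised on the 8-connected
#' grid. Erosion removes small isolated false-positive specks; dilation
#' restores the border pixels of the surviving plant region. Radius 0
#' disables the corresponding step, so `(0, 0)` is the identity.
#'
#' @param mask a [binary_mask()].
#' @param erosion_radius,dilation_radius disc radii in pixels, >= 0.
#' @return a cleaned `binary_mask` with the same scale factor.
#' @export
morphological_cleanup <- function(mask, erosion_radius = 1,
                                  dilation_radius = 1) {
  stopifnot(is_binary_mask(mask))
  if (erosion_radius < 0 || dilation_radius < 0) stop("radii must be >= 0")
  g <- as_mask_matrix(mask)
  g <- erode_mask(g, erosion_radius)
  g <- dilate_mask(g, dilation_radius)
  binary_mask(g, px_per_mm = mask_scale(mask))
}

# ---- pot-region filter ----------------------------------------------------

#' Pot region of interest
#'
#' An axis-aligned rectangle in pixel coordinates delimiting one pot in
#' the tray; foreground found outside it is deleted by
#' [filter_by_pot_region()]. Coordinates are inclusive 1-based row/column
#' indices.
#'
#' @param row0,row1,col0,col1 rectangle bounds, `row0 <= row1`,
#'   `col0 <= col1`.
#' @export
pot_region <- function(row0, col0, row1, col1) {
  v <- c(row0 = row0, col0 = col0, row1 = row1, col1 = col1)
  if (anyNA(v) || any(!is.finite(v))) stop("pot region bounds must be finite")
  if (row1 < row0 || col1 < col0) stop("degenerate pot region")
  structure(as.list(v), class = "pot_region")
}

#' Delete foreground outside the pot region
#'
#' @param mask a [binary_mask()].
#' @param region a [pot_region()]; must intersect the image.
#' @return the filtered mask; foreground inside the region is unchanged.
#' @export
filter_by_pot_region <- function(mask, region) {
  stopifnot(is_binary_mask(mask), inherits(region, "pot_region"))
  h <- nrow(mask); w <- ncol(mask)
  if (region$row0 > h || region$col0 > w || region$row1 < 1 || region$col1 < 1)
    stop("pot region lies outside the image")
  keep <- matrix(FALSE, h, w)
  keep[max(1, region$row0):min(h, region$row1),
       max(1, region$col0):min(w, region$col1)] <- TRUE
  binary_mask(as_mask_matrix(mask) & keep, px_per_mm = mask_scale(mask))
}

#' Full segmentation pipeline
#'
#' Nearest-neighbour colour classification, morphological cleanup, and
#' (optionally) the pot-region filter, in that order.
#'
#' @inheritParams classify_nearest_neighbour
#' @inheritParams morphological_cleanup
#' @param region optional [pot_region()].
#' @return a [binary_mask()].
#' @export
segment_image <- function(image, samples, erosion_radius = 1,
                          dilation_radius = 1, region = NULL,
                          px_per_mm = 1) {
  m <- classify_nearest_neighbour(image, samples, px_per_mm = px_per_mm)
  m <- morphological_cleanup(m, erosion_radius, dilation_radius)
  if (!is.null(region)) m <- filter_by_pot_region(m, region)
  m
}
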
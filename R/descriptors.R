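# The twenty rosette shape descriptors.
#
# Geometric conventions (documented in the methods vignette):
#  * the rosette is the union of unit-square pixels of the largest
#    8-connected foreground component;
#  * area = pixel count / scale^2;
#  * boundary lengths use Douglas-Peucker-simplified contours with a
#    half-pixel offset correction (see contour_perimeter_px);
#  * convex-hull quantities (hull perimeter/area, max diameter, minimal
#    enclosing circle, minimal-area rectangle) are computed on pixel
#    *corners*, so the hull always contains the pixel union and
#    compactness = area / hull area is guaranteed <= 1;
#  * principal-axis statistics are pixel-centre sums, reported in pixel
#    units so they are invariant under recalibration (their unit is a
#    ratio by convention).

#' Names, groups and transform flags of the 20 shape descriptors
#'
#' `descriptor_names()` returns the canonical lower-case names in table
#' order. `descriptor_groups()` labels each as `"A"` (Area group:
#' size-like, monotone in time, modelled with a quadratic time term) or
#' `"N"` (NonArea group: shape-like). `descriptor_log_flags()` gives the
#' default natural-log transform policy used by the statistics pipeline.
#'
#' @return a character (or logical) vector named by descriptor.
#' @export
descriptor_names <- function() {
  c("mincirclediam", "normsmallpax", "normlargepax", "minrectarea",
    "mindistcenbdy", "vrectsizey", "vrectsizex", "compactness",
    "normrotmo", "area", "paxratio", "circumference", "excentricity",
    "maxdiam", "roundness", "bdryround", "bdrycount", "bdrytoarearatio",
    "conhullcirc", "conhullarea")
}

#' @rdname descriptor_names
#' @export
descriptor_groups <- function() {
  g <- c(mincirclediam = "A", normsmallpax = "N", normlargepax = "N",
         minrectarea = "A", mindistcenbdy = "N", vrectsizey = "A",
         vrectsizex = "A", compactness = "N", normrotmo = "N", area = "A",
         paxratio = "N", circumference = "A", excentricity = "N",
         maxdiam = "A", roundness = "N", bdryround = "N", bdrycount = "A",
         bdrytoarearatio = "N", conhullcirc = "A", conhullarea = "A")
  g[descriptor_names()]
}

#' @rdname descriptor_names
#' @export
descriptor_log_flags <- function() {
  logd <- c("mincirclediam", "minrectarea", "vrectsizey", "vrectsizex",
            "area", "circumference", "maxdiam", "bdryround", "bdrycount",
            "conhullcirc", "conhullarea")
  stats::setNames(descriptor_names() %in% logd, descriptor_names())
}

# ---- geometric primitives on point sets -----------------------------------

# Corners (x = col, y = row, in px) of the pixels on the outer boundary of
# a region; the convex hull of the region's pixel union equals the hull of
# these points.
boundary_pixel_corners <- function(vertices) {
  r <- vertices[, 1]; c <- vertices[, 2]
  xy <- rbind(cbind(c - 0.5, r - 0.5), cbind(c + 0.5, r - 0.5),
              cbind(c - 0.5, r + 0.5), cbind(c + 0.5, r + 0.5))
  unique(xy)
}

# Convex hull vertices in counter-clockwise order; pts is an n x 2 matrix.
hull_vertices <- function(pts) {
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  pts[rev(idx), , drop = FALSE]  # chull returns clockwise
}

shoelace_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

max_pairwise_distance <- function(pts) {
  n <- nrow(pts)
  if (n < 2L) return(0)
  d2 <- 0
  for (i in seq_len(n - 1L)) {
    di <- (pts[-seq_len(i), 1] - pts[i, 1])^2 +
      (pts[-seq_len(i), 2] - pts[i, 2])^2
    d2 <- max(d2, di)
  }
  sqrt(d2)
}

# Minimal enclosing circle (Welzl's algorithm with move-to-front) over a
# small point set such as hull vertices. Returns list(center, radius).
min_enclosing_circle_pts <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n == 1L) return(list(center = pts[1, ], radius = 0))
  circ2 <- function(a, b) list(center = (a + b) / 2,
                               radius = sqrt(sum((a - b)^2)) / 2)
  circ3 <- function(a, b, c) {
    ax <- a[1]; ay <- a[2]; bx <- b[1]; by <- b[2]; cx <- c[1]; cy <- c[2]
    dd <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(dd) < 1e-12) return(NULL)
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / dd
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / dd
    ctr <- c(ux, uy)
    list(center = ctr, radius = sqrt(sum((ctr - a)^2)))
  }
  inside <- function(circ, p, tol = 1e-7)
    sqrt(sum((p - circ$center)^2)) <= circ$radius + tol
  trivial <- function(bnd) {
    k <- nrow(bnd)
    if (k == 0L) return(list(center = c(0, 0), radius = -1))
    if (k == 1L) return(list(center = bnd[1, ], radius = 0))
    if (k == 2L) return(circ2(bnd[1, ], bnd[2, ]))
    for (ij in list(c(1, 2), c(1, 3), c(2, 3))) {
      cc <- circ2(bnd[ij[1], ], bnd[ij[2], ])
      if (all(apply(bnd, 1, function(p) inside(cc, p)))) return(cc)
    }
    cc <- circ3(bnd[1, ], bnd[2, ], bnd[3, ])
    if (is.null(cc)) circ2(bnd[which.min(bnd[, 1]), ],
                           bnd[which.max(bnd[, 1]), ]) else cc
  }
  welzl <- function(p, bnd) {
    if (nrow(p) == 0L || nrow(bnd) == 3L) return(trivial(bnd))
    q <- p[nrow(p), , drop = FALSE]
    cc <- welzl(p[-nrow(p), , drop = FALSE], bnd)
    if (cc$radius >= 0 && inside(cc, q[1, ])) return(cc)
    welzl(p[-nrow(p), , drop = FALSE], rbind(bnd, q))
  }
  # deterministic pseudo-shuffle (Welzl expects random order; avoid
  # touching the global RNG stream)
  ord <- order(sin(seq_len(n) * 12.9898 + 78.233))
  welzl(pts[ord, , drop = FALSE], pts[0, , drop = FALSE])
}

# Minimum-area enclosing rectangle by rotating calipers over hull edges.
min_area_rect_pts <- function(hull) {
  n <- nrow(hull)
  if (n < 3L) {
    # degenerate: collinear corner set cannot occur for pixel corners,
    # but guard anyway
    return(list(area = 0, width = 0, height = 0))
  }
  best <- Inf; bw <- 0; bh <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    L <- sqrt(sum(e^2))
    if (L == 0) next
    u <- e / L
    v <- c(-u[2], u[1])
    pu <- hull[, 1] * u[1] + hull[, 2] * u[2]
    pv <- hull[, 1] * v[1] + hull[, 2] * v[2]
    w <- diff(range(pu)); h <- diff(range(pv))
    if (w * h < best) { best <- w * h; bw <- w; bh <- h }
  }
  list(area = best, width = bw, height = bh)
}

# ---- the descriptor set ---------------------------------------------------

#' Extract the 20 shape descriptors from a mask
#'
#' Computes all descriptors on the largest 8-connected foreground
#' component, in physical units given by the mask scale factor: lengths in
#' mm, areas in mm^2, `bdrytoarearatio` in 1/mm, and the remaining ratio
#' descriptors dimensionless. Principal-axis statistics (`normsmallpax`,
#' `normlargepax`, `normrotmo`) are pixel-based ratios and therefore
#' invariant under recalibration. Degenerate masks (single pixel or
#' collinear pixels) yield `NA` for the axis-ratio descriptors rather than
#' an error.
#'
#' @param mask a [binary_mask()] with at least one foreground pixel.
#' @param excentricity_mode `"paxratio"` (default) reports excentricity as
#'   the normlargepax/normsmallpax ratio exactly as paxratio is defined;
#'   `"moment"` reports the moment-based eccentricity
#'   `sqrt(1 - lambda_min / lambda_max)` of the second-moment matrix.
#' @return a one-row `data.frame` with the 20 columns of
#'   [descriptor_names()], in order.
#' @examples
#' m <- synthetic_disc_mask(radius = 20)
#' extract_descriptors(m)
#' @export
extract_descriptors <- function(mask, excentricity_mode = c("paxratio",
                                                            "moment")) {
  stopifnot(is_binary_mask(mask))
  excentricity_mode <- match.arg(excentricity_mode)
  g <- as_mask_matrix(mask)
  if (!any(g)) stop("no plant found: mask has no foreground pixels")
  sf <- mask_scale(mask)
  comp <- largest_component(g)
  npix <- sum(comp)

  cts <- contours(binary_mask(comp, px_per_mm = sf))
  outer <- cts[[1L]]
  holes <- cts[-1L]

  # boundary lengths (px)
  circumference_px <- contour_perimeter_px(outer$vertices)
  holes_px <- if (length(holes))
    sum(vapply(holes, function(h) contour_perimeter_px(h$vertices),
               numeric(1))) else 0
  bdrycount_px <- circumference_px + holes_px

  # convex hull on pixel corners (x = col, y = row)
  corners <- boundary_pixel_corners(outer$vertices)
  hull <- hull_vertices(corners)
  conhullarea_px <- shoelace_area(hull)
  conhullcirc_px <- polyline_length(hull, closed = TRUE)
  maxdiam_px <- max_pairwise_distance(hull)
  mec <- min_enclosing_circle_pts(hull)
  mincirclediam_px <- 2 * mec$radius
  mrect <- min_area_rect_pts(hull)

  # axis-aligned bounding box (vertical rectangle), whole-pixel extents
  rc <- which(comp, arr.ind = TRUE)
  vrectsizey_px <- diff(range(rc[, 1])) + 1
  vrectsizex_px <- diff(range(rc[, 2])) + 1

  # centroid and minimal centroid-to-boundary distance
  cy <- mean(rc[, 1]); cx <- mean(rc[, 2])
  bdyv <- do.call(rbind, lapply(cts, function(ct) ct$vertices))
  mindist_px <- sqrt(min((bdyv[, 1] - cy)^2 + (bdyv[, 2] - cx)^2)) + 0.5

  # principal-axis statistics on pixel centres (pixel-ratio units)
  dy <- rc[, 1] - cy; dx <- rc[, 2] - cx
  normrotmo <- sum(dx^2 + dy^2) / npix^2
  ax <- principal_axis_sums(dx, dy, npix)

  paxratio <- ax$normlargepax / ax$normsmallpax
  excentricity <- switch(excentricity_mode,
                         paxratio = paxratio,
                         moment = ax$moment_eccentricity)

  area_mm2 <- npix / sf^2
  circumference_mm <- circumference_px / sf
  bdrycount_mm <- bdrycount_px / sf
  conhullarea_mm2 <- conhullarea_px / sf^2

  out <- data.frame(
    mincirclediam = mincirclediam_px / sf,
    normsmallpax = ax$normsmallpax,
    normlargepax = ax$normlargepax,
    minrectarea = mrect$area / sf^2,
    mindistcenbdy = mindist_px / sf,
    vrectsizey = vrectsizey_px / sf,
    vrectsizex = vrectsizex_px / sf,
    compactness = area_mm2 / conhullarea_mm2,
    normrotmo = normrotmo,
    area = area_mm2,
    paxratio = paxratio,
    circumference = circumference_mm,
    excentricity = excentricity,
    maxdiam = maxdiam_px / sf,
    roundness = circumference_mm^2 / area_mm2,
    bdryround = bdrycount_mm^2 / area_mm2,
    bdrycount = bdrycount_mm,
    bdrytoarearatio = bdrycount_mm / area_mm2,
    conhullcirc = conhullcirc_px / sf,
    conhullarea = conhullarea_mm2
  )
  out[, descriptor_names()]
}

# Sums of absolute pixel coordinates along the principal directions.
# normsmallpax: distances from the *smaller* (minor) axis, measured along
# the larger (major) direction -- the larger of the two statistics;
# normlargepax: distances from the larger axis along the minor direction.
# Both are normalised by the pixel count. Degenerate (collinear or < 3 px)
# point sets yield NA for the minor-direction statistic.
principal_axis_sums <- function(dx, dy, npix) {
  if (npix < 3L) {
    return(list(normsmallpax = NA_real_, normlargepax = NA_real_,
                moment_eccentricity = NA_real_))
  }
  m <- cbind(dx, dy)
  S <- crossprod(m) / npix
  eg <- eigen(S, symmetric = TRUE)
  lam <- eg$values
  if (lam[1] <= 0) {
    return(list(normsmallpax = NA_real_, normlargepax = NA_real_,
                moment_eccentricity = NA_real_))
  }
  major <- eg$vectors[, 1]
  minor <- eg$vectors[, 2]
  cmaj <- abs(m %*% major)
  normsmallpax <- sum(cmaj) / npix
  if (lam[2] / lam[1] < 1e-9) {
    # collinear pixels: minor-axis statistics are degenerate
    return(list(normsmallpax = normsmallpax, normlargepax = NA_real_,
                moment_eccentricity = NA_real_))
  }
  cmin <- abs(m %*% minor)
  list(normsmallpax = normsmallpax,
       normlargepax = sum(cmin) / npix,
       moment_eccentricity = sqrt(1 - lam[2] / lam[1]))
}

#' Rosette area of a mask
#'
#' Foreground pixel count of the largest component divided by the squared
#' scale factor.
#'
#' @param mask a [binary_mask()].
#' @param largest_only count only the largest 8-connected component
#'   (default), as done by [extract_descriptors()]; set `FALSE` to count
#'   every foreground pixel.
#' @return area in mm^2.
#' @export
mask_area <- function(mask, largest_only = TRUE) {
  stopifnot(is_binary_mask(mask))
  g <- as_mask_matrix(mask)
  if (!any(g)) stop("no plant found: mask has no foreground pixels")
  n <- if (largest_only) sum(largest_component(g)) else sum(g)
  n / mask_scale(mask)^2
}
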
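# Synthetic rosettes and descriptor tables with known ground truth.
#
# The generator is the package's substitute for the original image set:
# masks are unions of elliptical leaf blades on thin petiole bars placed
# at successive phyllotaxis angles, and descriptor tables follow exactly
# the generative structure assumed by the mixed model (fixed ecotype /
# time / interaction effects, a plant random intercept, AR(1) errors over
# imaging occasions).

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Parameters of a synthetic rosette
#'
#' @param n_leaves number of leaves (>= 1).
#' @param leaf_length,leaf_width leaf blade ellipse axes, mm.
#' @param petiole_length distance from rosette centre to the blade base,
#'   mm; long petioles produce low-compactness rosettes.
#' @param phyllotaxis_angle angle between successive leaves, degrees
#'   (default the golden angle 137.5).
#' @param jitter_sd standard deviation of the per-leaf size/placement
#'   jitter, mm.
#' @param image_size canvas side, px.
#' @param px_per_mm scale factor of the rendered mask.
#' @return a parameter list of class `rosette_params`.
#' @export
rosette_params <- function(n_leaves = 8L, leaf_length = 12, leaf_width = 6,
                           petiole_length = 4, phyllotaxis_angle = 137.5,
                           jitter_sd = 0.4, image_size = 256L,
                           px_per_mm = 4) {
  p <- list(n_leaves = as.integer(n_leaves), leaf_length = leaf_length,
            leaf_width = leaf_width, petiole_length = petiole_length,
            phyllotaxis_angle = phyllotaxis_angle, jitter_sd = jitter_sd,
            image_size = as.integer(image_size), px_per_mm = px_per_mm)
  num <- unlist(p[c("n_leaves", "leaf_length", "leaf_width", "image_size",
                    "px_per_mm")])
  if (any(!is.finite(num)) || any(num <= 0))
    stop("rosette parameters must be positive")
  if (p$petiole_length < 0 || p$jitter_sd < 0)
    stop("petiole_length and jitter_sd must be >= 0")
  structure(p, class = "rosette_params")
}

#' Render a synthetic rosette mask
#'
#' Leaves are ellipses with semi-axes `leaf_length/2` x `leaf_width/2`
#' placed radially at successive phyllotaxis angles, their blade base at
#' `petiole_length` from the centre; each is connected to the centre by a
#' petiole bar 30% of the leaf width wide. Leaf sizes carry a mild
#' developmental gradient (older leaves larger) plus Gaussian jitter.
#' Rendering is deterministic for a given seed and leaves the global RNG
#' stream untouched.
#'
#' @param params a [rosette_params()].
#' @param seed integer seed for the jitter draws.
#' @param scale overall multiplier applied to leaf and petiole lengths
#'   (used by [render_timecourse()]).
#' @return a [binary_mask()].
#' @export
render_rosette <- function(params, seed = 1L, scale = 1) {
  stopifnot(inherits(params, "rosette_params"))
  n <- params$n_leaves
  jit <- with_seed(seed, matrix(stats::rnorm(3L * n, 0, params$jitter_sd),
                                ncol = 3L))
  grad <- if (n > 1L) seq(0.7, 1, length.out = n) else 1
  len <- pmax(0.5, (params$leaf_length * grad + jit[, 1]) * scale)
  wid <- pmax(0.3, (params$leaf_width * grad + jit[, 2]) * scale)
  pet <- pmax(0, (params$petiole_length + jit[, 3] * 0.5) * scale)
  ang <- (seq_len(n) - 1L) * params$phyllotaxis_angle * pi / 180

  half <- params$image_size / (2 * params$px_per_mm)
  if (max(pet + len) > half - 1)
    stop("rosette exceeds canvas: increase image_size or reduce scale")

  s <- params$image_size
  c0 <- (s + 1) / 2
  xy <- (seq_len(s) - c0) / params$px_per_mm  # mm
  X <- matrix(xy, s, s, byrow = TRUE)          # col coordinate
  Y <- matrix(xy, s, s)                        # row coordinate
  g <- matrix(FALSE, s, s)
  for (i in seq_len(n)) {
    u <- c(cos(ang[i]), sin(ang[i]))
    along <- X * u[1] + Y * u[2]
    perp <- -X * u[2] + Y * u[1]
    cx <- pet[i] + len[i] / 2
    g <- g | (((along - cx) / (len[i] / 2))^2 +
                (perp / (wid[i] / 2))^2 <= 1)
    pw <- 0.3 * wid[i] / 2
    g <- g | (along >= 0 & along <= cx & abs(perp) <= pw)
  }
  binary_mask(g, px_per_mm = params$px_per_mm)
}

#' Growth parameters for a synthetic time course
#'
#' @param k relative area growth rate, 1/day, >= 0: rosette area scales as
#'   `exp(k * (t - t0))`, so linear leaf dimensions scale as
#'   `exp(k (t - t0) / 2)`.
#' @param petiole_elongation additional petiole growth, mm/day, used to
#'   emulate a declining compactness trend.
#' @return a list of class `growth_params`.
#' @export
growth_params <- function(k = 0.1, petiole_elongation = 0) {
  if (!is.finite(k) || k < 0)
    stop("negative or non-finite growth rate k")
  if (petiole_elongation < 0) stop("petiole_elongation must be >= 0")
  structure(list(k = k, petiole_elongation = petiole_elongation),
            class = "growth_params")
}

#' Render a rosette time course
#'
#' Renders one rosette at each imaging date, growing exponentially in
#' area at rate `k` (identical masks when `k = 0` and
#' `petiole_elongation = 0`). The same per-leaf jitter draws are reused at
#' every date, so the time course is a smoothly scaled version of one
#' individual.
#'
#' @param params a [rosette_params()] describing the plant at the first
#'   date.
#' @param growth a [growth_params()].
#' @param das numeric vector of imaging dates (days), increasing.
#' @param seed integer seed.
#' @return a named list of [binary_mask()], one per date.
#' @export
render_timecourse <- function(params, growth, das = c(17, 22, 25, 28, 30),
                              seed = 1L) {
  stopifnot(inherits(params, "rosette_params"),
            inherits(growth, "growth_params"))
  if (any(diff(das) <= 0)) stop("`das` must be strictly increasing")
  out <- lapply(das, function(t) {
    dt <- t - das[1]
    p <- params
    p$petiole_length <- params$petiole_length +
      growth$petiole_elongation * dt
    render_rosette(p, seed = seed, scale = exp(growth$k * dt / 2))
  })
  names(out) <- paste0("das", das)
  out
}

#' Paint a mask into a noisy RGB scene
#'
#' Renders plant pixels in green and background in brown with Gaussian
#' per-pixel colour jitter, plus "salt" noise: a fraction of background
#' pixels flipped to plant-like colour. Used to exercise the segmentation
#' pipeline against a known planted mask.
#'
#' @param mask a [binary_mask()].
#' @param fg,bg central RGB colours of plant and soil.
#' @param colour_sd per-channel Gaussian jitter SD.
#' @param salt_fraction fraction of background pixels flipped to `fg`.
#' @param seed integer seed.
#' @return an H x W x 3 array in \[0, 255\].
#' @export
render_scene <- function(mask, fg = c(60, 150, 50), bg = c(115, 85, 55),
                         colour_sd = 8, salt_fraction = 0.002, seed = 1L) {
  stopifnot(is_binary_mask(mask))
  g <- as_mask_matrix(mask)
  h <- nrow(g); w <- ncol(g)
  with_seed(seed, {
    plantlike <- g
    bgidx <- which(!g)
    nsalt <- round(salt_fraction * length(bgidx))
    if (nsalt > 0) plantlike[sample(bgidx, nsalt)] <- TRUE
    a <- array(0, dim = c(h, w, 3L))
    for (ch in 1:3) {
      base <- ifelse(plantlike, fg[ch], bg[ch])
      a[, , ch] <- pmin(255, pmax(0, base + stats::rnorm(h * w, 0,
                                                         colour_sd)))
    }
    a
  })
}

# ---- descriptor-table generator -------------------------------------------

#' Specification of a simulated descriptor table
#'
#' Defines the generative twin of the longitudinal mixed model: for each
#' descriptor, responses on the analysis scale are
#' `baseline + unit_scale * (eco_offset + slope*das + quad*das^2 +
#' inter_slope*das + b_plant + e)`, with `b_plant ~ N(0, sd_plant^2)` and
#' `e` a stationary AR(1) process (parameter `rho`, marginal SD
#' `sd_resid`) over imaging occasions. Offsets, slopes and SDs are in
#' standardized (residual-SD) units. Columns flagged for log transform
#' are exponentiated so the returned table is on the raw measurement
#' scale, exactly like a table extracted from images.
#'
#' Defaults emulate the study design the package targets: 19 ecotypes x
#' 12 replicate plants x 5 imaging dates (17, 22, 25, 28, 30 days after
#' stratification), ecotype offsets evenly spread over +/- 0.8 SD,
#' ecotype-specific time slopes over +/- 0.02 SD/day, between-plant SD
#' equal to the residual SD and AR(1) correlation 0.6.
#'
#' @param n_ecotypes,n_reps,das design dimensions.
#' @param descriptors descriptor columns to simulate.
#' @param eco_offsets numeric vector (length `n_ecotypes`) of ecotype
#'   main effects in SD units, or `NULL` for the evenly spaced default.
#' @param interaction_slopes per-ecotype deviations of the time slope
#'   (SD/day), or `NULL` for the default spread.
#' @param time_slope,time_quad common time trend (SD/day, SD/day^2);
#'   `NULL` gives group defaults (Area group: 0.5 and -0.004, i.e. a
#'   relative area growth rate around 0.12/day with visible curvature;
#'   NonArea: -0.02 and 0).
#' @param sd_plant,rho,sd_resid variance components: plant random
#'   intercept SD, AR(1) parameter (0 <= rho < 1) and residual SD.
#' @param seed integer seed.
#' @return a list of class `table_effect_spec`.
#' @export
table_effect_spec <- function(n_ecotypes = 19L, n_reps = 12L,
                              das = c(17, 22, 25, 28, 30),
                              descriptors = descriptor_names(),
                              eco_offsets = NULL,
                              interaction_slopes = NULL,
                              time_slope = NULL, time_quad = NULL,
                              sd_plant = 1, rho = 0.6, sd_resid = 1,
                              seed = 1L) {
  n_ecotypes <- as.integer(n_ecotypes); n_reps <- as.integer(n_reps)
  if (n_ecotypes < 1L || n_reps < 1L) stop("design dimensions must be >= 1")
  if (rho < 0 || rho >= 1) stop("rho must satisfy 0 <= rho < 1")
  if (sd_plant < 0 || sd_resid < 0) stop("standard deviations must be >= 0")
  if (is.null(eco_offsets))
    eco_offsets <- if (n_ecotypes > 1L)
      seq(-0.8, 0.8, length.out = n_ecotypes) else 0
  if (is.null(interaction_slopes))
    interaction_slopes <- if (n_ecotypes > 1L)
      seq(-0.02, 0.02, length.out = n_ecotypes) else 0
  if (length(eco_offsets) != n_ecotypes ||
      length(interaction_slopes) != n_ecotypes)
    stop("effect vectors must have length n_ecotypes")
  structure(list(n_ecotypes = n_ecotypes, n_reps = n_reps, das = das,
                 descriptors = descriptors, eco_offsets = eco_offsets,
                 interaction_slopes = interaction_slopes,
                 time_slope = time_slope, time_quad = time_quad,
                 sd_plant = sd_plant, rho = rho, sd_resid = sd_resid,
                 seed = as.integer(seed)),
            class = "table_effect_spec")
}

# Realistic anchors on the analysis scale (log for log-flagged columns)
# and the SD unit used to map standardized effects onto each descriptor.
descriptor_baselines <- function() {
  b <- c(mincirclediam = log(45), normsmallpax = 11, normlargepax = 9,
         minrectarea = log(1300), mindistcenbdy = 4, vrectsizey = log(42),
         vrectsizex = log(42), compactness = 0.8, normrotmo = 0.16,
         area = log(500), paxratio = 0.85, circumference = log(150),
         excentricity = 0.85, maxdiam = log(48), roundness = 45,
         bdryround = log(60), bdrycount = log(170),
         bdrytoarearatio = 0.35, conhullcirc = log(140),
         conhullarea = log(900))
  s <- c(mincirclediam = 0.15, normsmallpax = 1.5, normlargepax = 1.2,
         minrectarea = 0.25, mindistcenbdy = 0.8, vrectsizey = 0.15,
         vrectsizex = 0.15, compactness = 0.05, normrotmo = 0.02,
         area = 0.25, paxratio = 0.06, circumference = 0.2,
         excentricity = 0.06, maxdiam = 0.15, roundness = 8,
         bdryround = 0.25, bdrycount = 0.2, bdrytoarearatio = 0.08,
         conhullcirc = 0.15, conhullarea = 0.25)
  list(baseline = b, unit_scale = s)
}

#' Simulate a longitudinal descriptor table
#'
#' Draws a table from the generative model described in
#' [table_effect_spec()]. The true effect parameters are recorded in the
#' `"ground_truth"` attribute for parameter-recovery tests. Reproducible:
#' the same spec (including its seed) always yields a bit-identical
#' table.
#'
#' @param spec a [table_effect_spec()].
#' @return a `data.frame` with `plant_id`, `ecotype`, `das` and one
#'   column per requested descriptor, on the raw measurement scale.
#' @examples
#' tab <- simulate_descriptor_table(table_effect_spec(n_ecotypes = 3,
#'                                                    n_reps = 2,
#'                                                    descriptors = "area"))
#' head(tab)
#' @export
simulate_descriptor_table <- function(spec = table_effect_spec()) {
  stopifnot(inherits(spec, "table_effect_spec"))
  anchors <- descriptor_baselines()
  logf <- descriptor_log_flags()
  grp <- descriptor_groups()
  nT <- length(spec$das)
  nplants <- spec$n_ecotypes * spec$n_reps
  eco <- rep(sprintf("E%02d", seq_len(spec$n_ecotypes)),
             each = spec$n_reps)
  pid <- sprintf("p%04d", seq_len(nplants))
  base <- data.frame(
    plant_id = rep(pid, each = nT),
    ecotype = rep(eco, each = nT),
    das = rep(spec$das, times = nplants),
    stringsAsFactors = FALSE)
  eidx <- rep(match(eco, unique(eco)), each = nT)

  das_c <- base$das - mean(spec$das)  # centred time keeps baselines meaningful
  truth <- list()
  with_seed(spec$seed, {
    for (d in spec$descriptors) {
      is_area <- !is.na(grp[d]) && grp[d] == "A"
      slope <- if (!is.null(spec$time_slope)) spec$time_slope
               else if (is_area) 0.5 else -0.02
      quad <- if (!is.null(spec$time_quad)) spec$time_quad
              else if (is_area) -0.004 else 0
      b_plant <- rep(stats::rnorm(nplants, 0, spec$sd_plant), each = nT)
      e <- as.vector(vapply(seq_len(nplants), function(i) {
        z <- numeric(nT)
        z[1] <- stats::rnorm(1, 0, spec$sd_resid)
        if (nT > 1L) for (t in 2:nT)
          z[t] <- spec$rho * z[t - 1] +
            stats::rnorm(1, 0, spec$sd_resid * sqrt(1 - spec$rho^2))
        z
      }, numeric(nT)))
      z <- spec$eco_offsets[eidx] + slope * das_c + quad * das_c^2 +
        spec$interaction_slopes[eidx] * das_c + b_plant + e
      bl <- anchors$baseline[d]; us <- anchors$unit_scale[d]
      if (is.na(bl)) { bl <- 0; us <- 1 }  # non-canonical column
      y <- bl + us * z
      base[[d]] <- if (!is.na(logf[d]) && logf[d]) exp(y) else y
      truth[[d]] <- list(slope = slope, quad = quad, baseline = bl,
                         unit_scale = us, area_group = is_area)
    }
  })
  attr(base, "ground_truth") <- list(spec = spec, descriptors = truth,
                                     das_centre = mean(spec$das))
  base
}

#' Rasterised analytic test shapes
#'
#' Discs, rectangles and annuli digitised on the pixel grid, used
#' throughout the tests to compare descriptors against closed-form
#' values.
#'
#' @param radius,inner_radius disc radii in px (pixel centres within
#'   `radius` of the centre are foreground; an annulus excludes centres
#'   within `inner_radius`).
#' @param height,width rectangle extent in px.
#' @param pad background margin, px.
#' @param px_per_mm scale factor of the mask.
#' @return a [binary_mask()].
#' @export
synthetic_disc_mask <- function(radius, pad = 3L, px_per_mm = 1) {
  n <- 2L * ceiling(radius) + 2L * pad + 1L
  c0 <- ceiling(radius) + pad + 1L
  i <- seq_len(n)
  g <- outer(i, i, function(r, c) (r - c0)^2 + (c - c0)^2 <= radius^2)
  binary_mask(g, px_per_mm = px_per_mm)
}

#' @rdname synthetic_disc_mask
#' @export
synthetic_rect_mask <- function(height, width, pad = 3L, px_per_mm = 1) {
  g <- matrix(FALSE, height + 2L * pad, width + 2L * pad)
  g[pad + seq_len(height), pad + seq_len(width)] <- TRUE
  binary_mask(g, px_per_mm = px_per_mm)
}

#' @rdname synthetic_disc_mask
#' @param hole_side side of the square hole of a square annulus, px.
#' @param side outer side of the square annulus, px.
#' @export
synthetic_annulus_mask <- function(side, hole_side, pad = 3L,
                                   px_per_mm = 1) {
  stopifnot(hole_side < side)
  g <- matrix(FALSE, side + 2L * pad, side + 2L * pad)
  g[pad + seq_len(side), pad + seq_len(side)] <- TRUE
  off <- pad + floor((side - hole_side) / 2)
  g[off + seq_len(hole_side), off + seq_len(hole_side)] <- FALSE
  binary_mask(g, px_per_mm = px_per_mm)
}
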
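#' Binary plant mask
#'
#' A `binary_mask` is a logical matrix (`TRUE` = plant pixel) carrying a
#' `px_per_mm` scale factor so that downstream descriptors can be reported
#' in physical units. Pixel coordinates are row-major with the origin at
#' the top-left corner: row indices increase downwards, column indices to
#' the right (standard raster convention).
#'
#' @param grid logical matrix, `TRUE` for foreground (plant) pixels.
#' @param px_per_mm scale factor in pixels per millimetre; must be a single
#'   finite positive number. Use [calibrate_mask()] to derive it from an
#'   internal length reference.
#' @return an object of class `binary_mask`.
#' @examples
#' m <- binary_mask(matrix(c(TRUE, FALSE, TRUE, TRUE), 2), px_per_mm = 2)
#' mask_area_px(m)
#' @export
binary_mask <- function(grid, px_per_mm = 1) {
  if (is.numeric(grid)) grid <- grid > 0
  if (!is.matrix(grid) || !is.logical(grid))
    stop("`grid` must be a logical matrix")
  if (nrow(grid) < 1L || ncol(grid) < 1L) stop("mask must be at least 1x1")
  if (anyNA(grid)) stop("mask grid contains NA")
  if (!is.numeric(px_per_mm) || length(px_per_mm) != 1L ||
      !is.finite(px_per_mm) || px_per_mm <= 0)
    stop("`px_per_mm` must be a single finite positive number")
  structure(grid, px_per_mm = as.numeric(px_per_mm), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %d foreground px, %.4g px/mm\n",
              nrow(x), ncol(x), sum(x), attr(x, "px_per_mm")))
  invisible(x)
}

#' @rdname binary_mask
#' @param mask a `binary_mask`.
#' @export
mask_scale <- function(mask) attr(mask, "px_per_mm")

#' @rdname binary_mask
#' @export
mask_area_px <- function(mask) sum(mask)

is_binary_mask <- function(x) inherits(x, "binary_mask")

as_mask_matrix <- function(mask) {
  m <- unclass(mask)
  attr(m, "px_per_mm") <- NULL
  m
}

#' Set the physical scale of a mask from a length reference
#'
#' Computes the pixels-per-mm scale factor from an internal length
#' reference visible in the image (e.g. a ruler segment of known length
#' spanning a measured number of pixels) and attaches it to the mask.
#' A typical top-down tray setup at 3000x4000 px resolution gives scale
#' factors around 7.3 px/mm.
#'
#' @param mask a `binary_mask`.
#' @param reference_length_px length of the reference object in pixels (> 0).
#' @param reference_length_mm physical length of the reference in mm (> 0).
#' @return the mask with `px_per_mm = reference_length_px / reference_length_mm`.
#' @examples
#' m <- binary_mask(matrix(TRUE, 4, 4))
#' mask_scale(calibrate_mask(m, 731, 100)) # 7.31 px/mm
#' @export
calibrate_mask <- function(mask, reference_length_px, reference_length_mm) {
  stopifnot(is_binary_mask(mask))
  for (v in c(reference_length_px, reference_length_mm))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("reference lengths must be single finite positive numbers")
  binary_mask(as_mask_matrix(mask),
              px_per_mm = reference_length_px / reference_length_mm)
}

# ---- image / mask file I/O ------------------------------------------------

#' Read an RGB image
#'
#' Supports PNG and JPEG (via the png/jpeg packages) and plain-text
#' portable anymap files (ASCII PBM/PGM/PPM, magic P1/P2/P3). Returns an
#' H x W x 3 numeric array with channel intensities in \[0, 255\].
#'
#' @param path file path; format chosen by extension (`.png`, `.jpg`,
#'   `.jpeg`, `.pbm`, `.pgm`, `.ppm`, `.pnm`).
#' @return numeric array `c(H, W, 3)` in \[0, 255\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    a <- jpeg::readJPEG(path)
  } else if (ext %in% c("pbm", "pgm", "ppm", "pnm")) {
    return(read_pnm(path))
  } else {
    stop("unsupported image format: .", ext)
  }
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  a * 255
}

# Plain (ASCII) portable anymap reader; P1 bitmap, P2 graymap, P3 pixmap.
read_pnm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- sub("#.*$", "", txt)
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  magic <- tok[1]
  if (!magic %in% c("P1", "P2", "P3")) stop("unsupported PNM magic: ", magic)
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  if (magic == "P1") {
    vals <- as.numeric(tok[-(1:3)])
    g <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
    g <- (1 - g) * 255  # PBM: 1 = black
    return(array(rep(g, 3L), dim = c(h, w, 3L)))
  }
  maxval <- as.numeric(tok[4])
  vals <- as.numeric(tok[-(1:4)]) * (255 / maxval)
  if (magic == "P2") {
    g <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
    return(array(rep(g, 3L), dim = c(h, w, 3L)))
  }
  stopifnot(length(vals) == 3L * w * h)
  a <- array(0, dim = c(h, w, 3L))
  for (ch in 1:3) a[, , ch] <- matrix(vals[seq(ch, length(vals), by = 3L)],
                                      nrow = h, ncol = w, byrow = TRUE)
  a
}

write_pnm <- function(img, path) {
  # img: H x W x 3 array in [0,255] -> ASCII P3
  h <- dim(img)[1]; w <- dim(img)[2]
  img <- round(img)
  vals <- integer(3L * w * h)
  for (ch in 1:3) vals[seq(ch, length(vals), by = 3L)] <- as.integer(t(img[, , ch]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(w, h), "255"), con)
  writeLines(paste(vals, collapse = " "), con)
  invisible(path)
}

#' Read or write a binary mask file
#'
#' Masks are stored as 8-bit greyscale images with 0 = background and
#' 255 = plant; PNG (binary) or ASCII PGM (text, useful for fixtures) are
#' supported. The scale factor is not stored in the image; supply it on
#' read or via [calibrate_mask()].
#'
#' @param path file path (`.png` or `.pgm`).
#' @param px_per_mm scale factor attached to the mask on read.
#' @return `read_mask()` returns a `binary_mask`; `write_mask()` its path,
#'   invisibly.
#' @export
read_mask <- function(path, px_per_mm = 1) {
  a <- read_image(path)
  binary_mask(a[, , 1] >= 128, px_per_mm = px_per_mm)
}

#' @rdname read_mask
#' @param mask a `binary_mask` to write.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is_binary_mask(mask))
  ext <- tolower(tools::file_ext(path))
  g <- as_mask_matrix(mask)
  if (ext == "png") {
    png::writePNG(g * 1.0, path)
  } else if (ext == "pgm") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(g), nrow(g)), "255"), con)
    writeLines(paste(as.integer(t(g)) * 255L, collapse = " "), con)
  } else stop("unsupported mask format: .", ext)
  invisible(path)
}
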
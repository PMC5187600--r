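#' @useDynLib fuzzac, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm setNames
#' @importFrom utils read.csv write.csv
NULL

# ---- validation helpers -----------------------------------------------------

stop_validation <- function(...) stop(..., call. = FALSE)

assert_image <- function(img, arg = "image") {
  if (!is.matrix(img) || !is.numeric(img))
    stop_validation(arg, " must be a numeric matrix")
  if (nrow(img) < 1L || ncol(img) < 1L)
    stop_validation(arg, " must have at least one row and one column")
  invisible(img)
}

assert_membership <- function(u, img = NULL) {
  assert_image(u, "membership map")
  if (anyNA(u) || min(u) < 0 || max(u) > 1)
    stop_validation("membership values must lie in [0, 1]")
  if (!is.null(img) && !identical(dim(u), dim(img)))
    stop_validation("membership map and image must have the same shape")
  invisible(u)
}

assert_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)))
    stop_validation(what, " must have the same shape")
  invisible(NULL)
}

# ---- image loading and normalization ---------------------------------------

#' Load a grayscale image and normalize it to the unit interval
#'
#' Reads a PNG, TIFF, or PGM raster, converts RGB(A) input to a single
#' channel by averaging the color channels, and min-max normalizes the
#' intensities to the unit interval.  A constant image maps to all zeros.
#' All downstream energies are computed on this normalized scale, so
#' tolerances and the default parameters are portable across bit depths.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff`, `.pgm`, or `.pnm` file.
#' @return A numeric matrix of intensities in \[0, 1\] (rows = image rows).
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop_validation("path must be a single file name")
  if (!file.exists(path)) stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    pgm  = ,
    pnm  = read_pgm(path),
    stop_validation("unsupported image format: .", ext,
                    " (supported: png, tif/tiff, pgm)")
  )
  img <- flatten_gray(raw)
  assert_image(img)
  normalize_intensity(img)
}

# RGB(A) arrays -> single channel by mean of the first three channels.
flatten_gray <- function(raw) {
  if (is.matrix(raw)) return(raw)
  if (length(dim(raw)) == 3L) {
    nch <- dim(raw)[3]
    if (nch >= 3L) return((raw[, , 1] + raw[, , 2] + raw[, , 3]) / 3)
    return(raw[, , 1])
  }
  stop_validation("decoded image has unsupported dimensions")
}

normalize_intensity <- function(img) {
  lo <- min(img); hi <- max(img)
  if (hi > lo) (img - lo) / (hi - lo) else array(0, dim(img))
}

# Minimal PGM reader: plain (P2) and binary (P5), maxval up to 65535.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tokens <- character(0)
  # header tokens, skipping '#' comments
  while (length(tokens) < 4L) {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated PGM header in ", path)
    line <- sub("#.*$", "", line)
    tok <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    tokens <- c(tokens, tok[nzchar(tok)])
  }
  magic <- tokens[1]
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3])
  maxval <- as.integer(tokens[4])
  if (is.na(w) || is.na(h) || w < 1L || h < 1L)
    stop_validation("invalid PGM dimensions in ", path)
  n <- w * h
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  } else if (magic == "P5") {
    if (maxval < 256) {
      vals <- as.integer(readBin(con, "raw", n = n))
    } else {
      vals <- readBin(con, "integer", n = n, size = 2L,
                      signed = FALSE, endian = "big")
    }
  } else stop_validation("not a PGM file (magic ", magic, "): ", path)
  if (length(vals) < n) stop("truncated PGM pixel data in ", path)
  matrix(vals / maxval, nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(img, path, maxval = 255L) {
  assert_image(img)
  v <- round(normalize_intensity(img) * maxval)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P5", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  writeBin(as.raw(as.integer(t(v))), con)
  invisible(path)
}

# ---- mask / membership writers ----------------------------------------------

#' Write a binary mask as a 0/255 PNG
#'
#' @param mask Logical (or 0/1 numeric) matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_mask_png <- function(mask, path) {
  assert_image(mask * 1, "mask")
  png::writePNG(ifelse(mask > 0, 1, 0), path)
  invisible(path)
}

#' Write a membership map as an 8-bit PNG (u scaled to 0-255)
#'
#' @param u Membership matrix in \[0, 1\].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_membership_png <- function(u, path) {
  assert_membership(u)
  png::writePNG(u, path)
  invisible(path)
}

#' Lossless textual dump of a membership map
#'
#' Writes a plain-text grid (`height width` header, then one row per line at
#' full double precision) so memberships round-trip exactly; the companion
#' reader is [read_membership_grid()].
#'
#' @param u Membership matrix in \[0, 1\].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_membership_grid <- function(u, path) {
  assert_membership(u)
  lines <- c(paste(nrow(u), ncol(u)),
             apply(u, 1L, function(r) paste(sprintf("%.17g", r), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_membership_grid
#' @return For `read_membership_grid`, the membership matrix.
#' @export
read_membership_grid <- function(path) {
  lines <- readLines(path)
  hw <- as.integer(strsplit(trimws(lines[1]), "[[:space:]]+")[[1]])
  vals <- lapply(lines[-1], function(l)
    as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]]))
  u <- do.call(rbind, vals)
  if (!identical(dim(u), hw)) {
    if (nrow(u) != hw[1] || ncol(u) != hw[2])
      stop("membership grid header does not match data in ", path)
  }
  assert_membership(u)
}

# ---- disc patch mask --------------------------------------------------------

#' Disc-shaped local patch footprint
#'
#' The local patch centered at pixel x is the set of pixels y with
#' Euclidean distance |y - x| <= r; this builds its discrete footprint
#' (a binary stencil) and the corresponding offset list used by the
#' statistics and sweep kernels.
#'
#' @param radius Patch radius r in pixels (integer, >= 1).
#' @return An object of class `patch_mask`: a list with `radius`, the
#'   logical `footprint` matrix of size (2r+1) x (2r+1), and `offsets`,
#'   an integer matrix of (dy, dx) pairs inside the disc.
#' @export
make_disc_mask <- function(radius) {
  if (length(radius) != 1L || is.na(radius) || radius < 1 ||
      radius != round(radius))
    stop_validation("radius must be a single integer >= 1")
  radius <- as.integer(radius)
  d <- seq.int(-radius, radius)
  fp <- outer(d, d, function(dy, dx) dy * dy + dx * dx <= radius * radius)
  idx <- which(fp, arr.ind = TRUE)
  # row-major offset order: by dy, then dx
  off <- cbind(dy = d[idx[, 1]], dx = d[idx[, 2]])
  off <- off[order(off[, 1], off[, 2]), , drop = FALSE]
  structure(list(radius = radius, footprint = fp,
                 offsets = matrix(as.integer(off), ncol = 2L,
                                  dimnames = list(NULL, c("dy", "dx")))),
            class = "patch_mask")
}

#' @export
print.patch_mask <- function(x, ...) {
  cat("disc patch mask: radius", x$radius, "-", nrow(x$offsets), "pixels\n")
  invisible(x)
}

# ---- initial membership -----------------------------------------------------

#' Initial fuzzy membership from seed regions
#'
#' Builds the initial pseudo level set: membership `u_in` inside the seed
#' region(s) and `u_out` outside, with `u_in > 0.5 > u_out`.  The crisp
#' defaults (1 and 0) give a crisp initial partition, the usual starting
#' point for fuzzy region-based contours.
#'
#' @param image The image matrix (only its shape is used).
#' @param seed_regions Either a list of rectangles, each
#'   `c(row, col, height, width)` (1-based top-left corner), or a logical
#'   matrix the same shape as `image`.
#' @param u_in,u_out Inside/outside membership values; must satisfy
#'   `u_in > 0.5` and `u_out < 0.5`.
#' @return Membership matrix the same shape as `image`.
#' @export
init_membership <- function(image, seed_regions, u_in = 1, u_out = 0) {
  assert_image(image)
  if (!(u_in > 0.5 && u_out < 0.5 && u_in <= 1 && u_out >= 0))
    stop_validation("need 0 <= u_out < 0.5 < u_in <= 1")
  inside <- seeds_to_mask(seed_regions, dim(image))
  if (!any(inside)) stop_validation("empty seed set")
  u <- matrix(u_out, nrow(image), ncol(image))
  u[inside] <- u_in
  u
}

seeds_to_mask <- function(seed_regions, shape) {
  if (is.matrix(seed_regions)) {
    if (!identical(dim(seed_regions), as.integer(shape)) &&
        !identical(dim(seed_regions), shape))
      stop_validation("seed mask must have the same shape as the image")
    return(seed_regions > 0)
  }
  if (is.numeric(seed_regions)) seed_regions <- list(seed_regions)
  if (!is.list(seed_regions) || length(seed_regions) == 0L)
    stop_validation("empty seed set")
  inside <- matrix(FALSE, shape[1], shape[2])
  for (rect in seed_regions) {
    if (length(rect) != 4L)
      stop_validation("each seed rectangle must be c(row, col, height, width)")
    r0 <- rect[1]; c0 <- rect[2]; h <- rect[3]; w <- rect[4]
    r1 <- r0 + h - 1L; c1 <- c0 + w - 1L
    if (h < 1L || w < 1L || r0 < 1L || c0 < 1L ||
        r1 > shape[1] || c1 > shape[2])
      stop_validation("seed rectangle out of image bounds: ",
                      paste(rect, collapse = ","))
    inside[r0:r1, c0:c1] <- TRUE
  }
  inside
}
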
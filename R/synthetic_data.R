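# Seedable synthetic phantoms with ground truth.
#
# The generators emulate the structure of the validation experiments: a
# multi-object phantom with per-object intensity levels and interior holes;
# a circle + rectangle phantom corrupted by additive Gaussian noise of a
# stated variance on the [0,1] scale; and an intensity-inhomogeneous phantom
# whose objects ramp through the background level, so that no global
# threshold (and no global two-prototype model) can separate them.

# Run code with a fixed RNG seed without disturbing the session RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic phantom
#'
#' @param height,width Canvas size in pixels.
#' @param shapes List of shapes; each is a list with `kind` one of
#'   `"circle"` (`center = c(row, col)`, `radius`), `"rectangle"`
#'   (`corner = c(row, col)`, `height`, `width`), `"annulus"`
#'   (`center`, `outer`, `inner`), or `"ramp_rectangle"` (rectangle whose
#'   intensity ramps linearly from `level` to `level2` along its long axis);
#'   plus an intensity `level` in \[0, 1\] and an optional list `holes` of
#'   `list(center=, radius=)` discs punched out of the shape.
#' @param background_level Background intensity in \[0, 1\].
#' @param bias_amplitude,bias_scale Multiplicative smooth bias field
#'   `1 + amplitude * exp(-d^2 / (2 scale^2))` centered on the canvas
#'   (d = distance to the canvas center); `amplitude = 0` disables it.
#' @param noise_variance Variance of additive Gaussian noise on the \[0, 1\]
#'   scale (the result is clipped back to \[0, 1\]).
#' @param seed RNG seed; the phantom is a pure function of the spec.
#' @return A validated `phantom_spec` list.
#' @export
phantom_spec <- function(height, width, shapes, background_level = 0.2,
                         bias_amplitude = 0, bias_scale = NULL,
                         noise_variance = 0, seed = 1L) {
  if (height < 1 || width < 1) stop_validation("canvas must be non-empty")
  if (noise_variance < 0) stop_validation("noise_variance must be >= 0")
  if (background_level < 0 || background_level > 1)
    stop_validation("background_level must be in [0, 1]")
  if (is.null(bias_scale)) bias_scale <- max(height, width) / 2
  structure(list(height = as.integer(height), width = as.integer(width),
                 shapes = shapes, background_level = background_level,
                 bias_amplitude = bias_amplitude, bias_scale = bias_scale,
                 noise_variance = noise_variance, seed = as.integer(seed)),
            class = "phantom_spec")
}

shape_support <- function(shape, h, w) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  kind <- shape$kind
  if (kind == "circle") {
    ctr <- shape$center
    sup <- (rr - ctr[1])^2 + (cc - ctr[2])^2 <= shape$radius^2
    extent <- c(ctr[1] - shape$radius, ctr[1] + shape$radius,
                ctr[2] - shape$radius, ctr[2] + shape$radius)
  } else if (kind == "rectangle" || kind == "ramp_rectangle") {
    r0 <- shape$corner[1]; c0 <- shape$corner[2]
    r1 <- r0 + shape$height - 1; c1 <- c0 + shape$width - 1
    sup <- rr >= r0 & rr <= r1 & cc >= c0 & cc <= c1
    extent <- c(r0, r1, c0, c1)
  } else if (kind == "annulus") {
    ctr <- shape$center
    d2 <- (rr - ctr[1])^2 + (cc - ctr[2])^2
    sup <- d2 <= shape$outer^2 & d2 >= shape$inner^2
    extent <- c(ctr[1] - shape$outer, ctr[1] + shape$outer,
                ctr[2] - shape$outer, ctr[2] + shape$outer)
  } else stop_validation("unknown shape kind: ", kind)
  if (extent[1] < 1 || extent[2] > h || extent[3] < 1 || extent[4] > w)
    stop_validation("shape extends outside the canvas: ", kind)
  sup
}

shape_levels <- function(shape, sup, h, w) {
  if (shape$kind != "ramp_rectangle") return(shape$level)
  # linear ramp level -> level2 along the long axis of the rectangle
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  if (shape$height >= shape$width) {
    t <- (rr[sup] - shape$corner[1]) / max(shape$height - 1, 1)
  } else {
    t <- (cc[sup] - shape$corner[2]) / max(shape$width - 1, 1)
  }
  shape$level + t * (shape$level2 - shape$level)
}

#' Render a phantom and its ground-truth mask
#'
#' Shapes are painted at their intensity levels over the background (later
#' shapes overwrite earlier ones), holes are punched back to background, the
#' multiplicative bias field is applied, Gaussian noise of the requested
#' variance is added, and the image is clipped to \[0, 1\].  The ground
#' truth is the union of the shape supports minus holes, and is free of
#' noise and bias by construction.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (intensity matrix) and `truth` (logical mask).
#' @export
generate_phantom <- function(spec) {
  h <- spec$height; w <- spec$width
  img <- matrix(spec$background_level, h, w)
  truth <- matrix(FALSE, h, w)
  for (shape in spec$shapes) {
    sup <- shape_support(shape, h, w)
    if (!is.null(shape$holes)) {
      for (hole in shape$holes) {
        hole_sup <- shape_support(list(kind = "circle", center = hole$center,
                                       radius = hole$radius), h, w)
        sup <- sup & !hole_sup
      }
    }
    img[sup] <- shape_levels(shape, sup, h, w)
    truth <- truth | sup
  }
  if (spec$bias_amplitude != 0) {
    rr <- matrix(seq_len(h), h, w)
    cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    d2 <- (rr - (h + 1) / 2)^2 + (cc - (w + 1) / 2)^2
    img <- img * (1 + spec$bias_amplitude * exp(-d2 / (2 * spec$bias_scale^2)))
  }
  if (spec$noise_variance > 0) {
    img <- img + with_seed(spec$seed,
                           matrix(rnorm(h * w, 0, sqrt(spec$noise_variance)),
                                  h, w))
  }
  img <- pmin(pmax(img, 0), 1)
  list(image = img, truth = truth)
}

#' Three-object phantom with distinct intensities and interior holes
#'
#' A clean multi-object scene over a mid-gray background: a bright circle, a
#' dark rectangle with two circular holes, and a ring (annulus) at an
#' intermediate level.  The three foreground levels are pairwise at least
#' 0.15 apart and straddle the background level, so a single pair of global
#' prototypes cannot separate all three objects from the background, while
#' patch-local prototypes can.  Ground truth excludes the holes.
#'
#' @param seed RNG seed (the preset is noise-free, so the output is the same
#'   for every seed; the argument is kept for interface uniformity).
#' @param size Canvas side length in pixels (default 128).
#' @return List with `image`, `truth`, and `init` (the default seed
#'   rectangles used by the replication experiments).
#' @export
three_object_phantom <- function(seed = 1L, size = 128L) {
  s <- size / 128
  spec <- phantom_spec(
    height = size, width = size,
    shapes = list(
      list(kind = "circle", center = round(c(36, 38) * s),
           radius = round(19 * s), level = 0.90),
      list(kind = "rectangle", corner = round(c(76, 16) * s),
           height = round(38 * s), width = round(46 * s), level = 0.20,
           holes = list(list(center = round(c(88, 30) * s),
                             radius = round(4 * s)),
                        list(center = round(c(100, 48) * s),
                             radius = round(4 * s)))),
      list(kind = "annulus", center = round(c(52, 94) * s),
           outer = round(21 * s), inner = round(8 * s), level = 0.65)
    ),
    background_level = 0.45, noise_variance = 0, seed = seed)
  ph <- generate_phantom(spec)
  ph$init <- list(c(round(10 * s), round(10 * s),
                    round(110 * s), round(110 * s)))
  ph
}

#' Circle + rectangle phantom with additive Gaussian noise
#'
#' Two bright shapes (a circle and a rectangle) over a dark background,
#' corrupted by zero-mean Gaussian noise of the given variance on the
#' \[0, 1\] scale and clipped.  The ground truth is identical across noise
#' levels for a fixed geometry.
#'
#' @param noise_variance Noise variance (the replication protocol uses
#'   0.01, 0.10, and 0.20).
#' @param seed RNG seed for the noise.
#' @param size Canvas side length (default 128).
#' @return List with `image`, `truth`, and `init` (default seed rectangles).
#' @export
circle_rectangle_phantom <- function(noise_variance = 0, seed = 1L,
                                     size = 128L) {
  s <- size / 128
  spec <- phantom_spec(
    height = size, width = size,
    shapes = list(
      list(kind = "circle", center = round(c(44, 42) * s),
           radius = round(24 * s), level = 0.95),
      list(kind = "rectangle", corner = round(c(76, 72) * s),
           height = round(38 * s), width = round(44 * s), level = 0.70)
    ),
    background_level = 0.05, noise_variance = noise_variance, seed = seed)
  ph <- generate_phantom(spec)
  # tight initialization (~4 px of margin around each shape): membership
  # updates then stay confined to a thin ribbon around the true boundary
  ph$init <- list(c(round(16 * s), round(14 * s), round(57 * s),
                    round(57 * s)),
                  c(round(72 * s), round(68 * s), round(46 * s),
                    round(52 * s)))
  ph
}

#' Intensity-inhomogeneous phantom (two ramped bars + bias field)
#'
#' Two elongated rectangular objects whose intensity ramps linearly along
#' their axis through the (constant) background level, under a smooth
#' multiplicative bias field.  The object and background intensity
#' histograms overlap, so no single global threshold separates them — the
#' regime in which whole-image prototypes fail and patch-local statistics
#' are required, used by the localization-radius study.
#'
#' @param seed RNG seed (light noise is added for realism).
#' @param size Canvas side length (default 128).
#' @return List with `image`, `truth`, and `init` (default seed rectangles).
#' @export
inhomogeneous_phantom <- function(seed = 1L, size = 128L) {
  s <- size / 128
  spec <- phantom_spec(
    height = size, width = size,
    shapes = list(
      list(kind = "ramp_rectangle", corner = round(c(18, 26) * s),
           height = round(92 * s), width = round(18 * s),
           level = 0.10, level2 = 0.85),
      list(kind = "ramp_rectangle", corner = round(c(18, 84) * s),
           height = round(92 * s), width = round(18 * s),
           level = 0.85, level2 = 0.10)
    ),
    background_level = 0.46,
    bias_amplitude = 0.35, bias_scale = 40 * s,
    noise_variance = 1e-4, seed = seed)
  ph <- generate_phantom(spec)
  # loose initialization: one tall rectangle per object, ~20 px of margin,
  # so that a small localization radius cannot see the objects from the
  # initial contour (the "too local" failure regime)
  ph$init <- list(c(round(4 * s), round(6 * s), round(120 * s),
                    round(58 * s)),
                  c(round(4 * s), round(64 * s), round(120 * s),
                    round(58 * s)))
  ph
}

#' Connected components of a binary mask (8-connectivity)
#'
#' Small utility used to count recovered objects in the replication
#' experiments.
#'
#' @param mask Logical matrix.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  offs <- cbind(dy = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                dx = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  todo <- which(mask & lab == 0L)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0L) {
      p <- queue[[1L]]
      queue <- queue[-1L]
      pr <- ((p - 1L) %% nr) + 1L
      pc <- ((p - 1L) %/% nr) + 1L
      nbr_r <- pr + offs[, 1]
      nbr_c <- pc + offs[, 2]
      ok <- nbr_r >= 1L & nbr_r <= nr & nbr_c >= 1L & nbr_c <= nc
      nidx <- (nbr_c[ok] - 1L) * nr + nbr_r[ok]
      nidx <- nidx[mask[nidx] & lab[nidx] == 0L]
      if (length(nidx) > 0L) {
        lab[nidx] <- cur
        queue <- c(queue, nidx)
      }
    }
  }
  lab
}
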
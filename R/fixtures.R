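# Deterministic synthetic images: piecewise-constant phantoms, Gaussian
# noise, and line/block/mixed damage masks. Every generator is a pure
# function of its arguments and seed, so tests and experiments need no
# external data.

.grid_rc <- function(h, w) {
  list(rows = matrix(seq_len(h), h, w),
       cols = matrix(seq_len(w), h, w, byrow = TRUE))
}

#' Piecewise-constant test phantom with exact ground truth
#'
#' Generates a two-intensity image plus the exact foreground indicator.
#' Kinds:
#' \describe{
#'   \item{`disk`}{filled circle; geometry `center = c(row, col)`
#'     (default image center) and `radius` (default `min(h, w) / 4`).}
#'   \item{`triangle`}{filled triangle; geometry `vertices`, a 3x2 matrix of
#'     (row, col) corners (default: a clipped triangle spanning the central
#'     portion of the canvas).}
#'   \item{`two_phase`}{two foreground disks of different radii, a simple
#'     non-convex two-phase scene.}
#'   \item{`step_edge`}{vertical step: right half foreground.}
#' }
#'
#' @param kind One of `"disk"`, `"triangle"`, `"two_phase"`, `"step_edge"`.
#' @param size Integer vector `c(height, width)`, each at least 3.
#' @param fg_intensity,bg_intensity Foreground/background gray levels in
#'   `[0, 255]`; must differ.
#' @param center,radius,vertices Optional geometry overrides (pixels,
#'   1-based).
#' @return A list with `clean` (numeric matrix), `mask` (binary matrix,
#'   1 on the foreground, exactly where `clean == fg_intensity`), and the
#'   effective `kind`, `fg_intensity`, `bg_intensity`.
#' @export
make_phantom <- function(kind = c("disk", "triangle", "two_phase",
                                  "step_edge"),
                         size = c(128L, 128L),
                         fg_intensity = 200, bg_intensity = 50,
                         center = NULL, radius = NULL, vertices = NULL) {
  kind <- match.arg(kind)
  if (length(size) != 2L || any(size < 3))
    stop_param("size must be c(height, width) with both at least 3")
  h <- as.integer(size[1]); w <- as.integer(size[2])
  if (fg_intensity == bg_intensity)
    stop_param("fg_intensity and bg_intensity must differ")
  g <- .grid_rc(h, w)
  mask <- switch(kind,
    disk = {
      if (is.null(center)) center <- c((h + 1) / 2, (w + 1) / 2)
      if (is.null(radius)) radius <- min(h, w) / 4
      assert_positive(radius, "radius")
      if (center[1] - radius < 0.5 || center[1] + radius > h + 0.5 ||
          center[2] - radius < 0.5 || center[2] + radius > w + 0.5)
        stop_param("disk does not fit inside the canvas")
      ((g$rows - center[1])^2 + (g$cols - center[2])^2 <= radius^2) + 0
    },
    triangle = {
      if (is.null(vertices))
        vertices <- rbind(c(0.20 * h, 0.50 * w),
                          c(0.80 * h, 0.22 * w),
                          c(0.80 * h, 0.78 * w))
      if (!is.matrix(vertices) || !identical(dim(vertices), c(3L, 2L)))
        stop_param("vertices must be a 3x2 matrix of (row, col) corners")
      if (any(vertices[, 1] < 0.5) || any(vertices[, 1] > h + 0.5) ||
          any(vertices[, 2] < 0.5) || any(vertices[, 2] > w + 0.5))
        stop_param("triangle vertices fall outside the canvas")
      # twice the signed area; zero means a degenerate triangle
      a2 <- (vertices[2, 1] - vertices[1, 1]) * (vertices[3, 2] - vertices[1, 2]) -
            (vertices[3, 1] - vertices[1, 1]) * (vertices[2, 2] - vertices[1, 2])
      if (a2 == 0) stop_param("triangle has zero area")
      side <- function(a, b) {
        (b[1] - a[1]) * (g$cols - a[2]) - (b[2] - a[2]) * (g$rows - a[1])
      }
      s1 <- side(vertices[1, ], vertices[2, ])
      s2 <- side(vertices[2, ], vertices[3, ])
      s3 <- side(vertices[3, ], vertices[1, ])
      ((s1 >= 0 & s2 >= 0 & s3 >= 0) | (s1 <= 0 & s2 <= 0 & s3 <= 0)) + 0
    },
    two_phase = {
      r1 <- 0.22 * min(h, w)
      r2 <- 0.13 * min(h, w)
      c1 <- c(0.42 * h, 0.36 * w)
      c2 <- c(0.62 * h, 0.68 * w)
      d1 <- (g$rows - c1[1])^2 + (g$cols - c1[2])^2 <= r1^2
      d2 <- (g$rows - c2[1])^2 + (g$cols - c2[2])^2 <= r2^2
      (d1 | d2) + 0
    },
    step_edge = {
      (g$cols > w / 2) + 0
    })
  clean <- bg_intensity + (fg_intensity - bg_intensity) * mask
  list(clean = clean, mask = mask, kind = kind,
       fg_intensity = fg_intensity, bg_intensity = bg_intensity)
}

#' Additive Gaussian noise, clipped to the intensity range
#'
#' Adds i.i.d. `N(0, sigma^2)` noise per pixel and clips to `[0, 255]`.
#' Deterministic in `seed`; the global RNG state is left untouched.
#'
#' @param img Numeric matrix.
#' @param sigma Noise standard deviation (gray levels), `>= 0`.
#' @param seed Integer seed.
#' @return Noisy matrix of the same shape.
#' @export
add_gaussian_noise <- function(img, sigma, seed) {
  assert_image(img, "img")
  assert_nonneg(sigma, "sigma")
  if (sigma == 0) return(img)
  noise <- withr::with_seed(seed, stats::rnorm(length(img), 0, sigma))
  pmin(pmax(img + matrix(noise, nrow(img), ncol(img)), 0), 255)
}

# Rasterize one straight stroke of the given width across the whole image.
.draw_line <- function(h, w, row0, col0, angle, width) {
  g <- .grid_rc(h, w)
  nx <- -sin(angle); ny <- cos(angle)   # unit normal to the stroke
  d <- abs((g$rows - row0) * nx + (g$cols - col0) * ny)
  d <= width / 2
}

#' Binary damage mask for inpainting experiments
#'
#' Produces an `InpaintMask`-style field with 0 on damaged pixels and 1
#' elsewhere. `"line"` draws full-span strokes 1-3 px wide, `"block"`
#' axis-aligned rectangles, `"mixed"` the union of both. Unless an explicit
#' `blocks` list is given, geometry is random but deterministic in `seed`,
#' and the damaged fraction is kept between 2% and 30% of the pixels.
#'
#' @param size Integer vector `c(height, width)`.
#' @param kind One of `"line"`, `"block"`, `"mixed"`.
#' @param seed Integer seed.
#' @param n_lines,n_blocks Number of random strokes / rectangles.
#' @param blocks Optional explicit damage rectangles: a list of integer
#'   vectors `c(row0, col0, height, width)` (1-based corner); overrides the
#'   random block geometry.
#' @return Binary matrix with values in `{0, 1}`, 0 = damaged.
#' @export
make_damage_mask <- function(size, kind = c("line", "block", "mixed"),
                             seed = 1L, n_lines = 3L, n_blocks = 2L,
                             blocks = NULL) {
  kind <- match.arg(kind)
  if (length(size) != 2L || any(size < 3))
    stop_param("size must be c(height, width) with both at least 3")
  h <- as.integer(size[1]); w <- as.integer(size[2])
  damaged <- matrix(FALSE, h, w)
  if (!is.null(blocks)) {
    for (b in blocks) {
      if (length(b) != 4L || any(b < 1) || b[1] + b[3] - 1 > h ||
          b[2] + b[4] - 1 > w)
        stop_param("each block must be c(row0, col0, height, width) ",
                   "inside the canvas")
      damaged[b[1]:(b[1] + b[3] - 1), b[2]:(b[2] + b[4] - 1)] <- TRUE
    }
    return((!damaged) + 0)
  }
  withr::with_seed(seed, {
    add_line <- function(m) {
      m | .draw_line(h, w, stats::runif(1, 1, h), stats::runif(1, 1, w),
                     stats::runif(1, 0, pi),
                     sample(1:3, 1))
    }
    add_block <- function(m) {
      bh <- max(2L, round(stats::runif(1, 0.12, 0.22) * h))
      bw <- max(2L, round(stats::runif(1, 0.12, 0.22) * w))
      r0 <- sample.int(h - bh + 1L, 1L)
      c0 <- sample.int(w - bw + 1L, 1L)
      m[r0:(r0 + bh - 1L), c0:(c0 + bw - 1L)] <- TRUE
      m
    }
    if (kind %in% c("line", "mixed"))
      for (i in seq_len(n_lines)) damaged <- add_line(damaged)
    if (kind %in% c("block", "mixed"))
      for (i in seq_len(n_blocks)) damaged <- add_block(damaged)
    # keep the damaged fraction inside [2%, 30%]
    top_up <- if (kind == "block") add_block else add_line
    while (mean(damaged) < 0.02) damaged <- top_up(damaged)
  })
  if (mean(damaged) > 0.30)
    stop_param("damage exceeds 30% of the image; reduce n_lines/n_blocks")
  (!damaged) + 0
}
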
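# Procedural background images: seeded multi-octave value noise mapped
# through a soil colour ramp, a stand-in for photographed pot/soil
# backgrounds when none are supplied.

#' Background style
#'
#' @param colors character vector of ramp colours, dark to light.
#' @param amplitude noise contrast in `[0, 1]`; 0 gives a constant image
#'   of the ramp midpoint.
#' @param octaves number of noise octaves (each doubles the frequency and
#'   halves the weight).
#' @param base_cells coarsest noise grid size.
#' @return a `background_style`.
#' @export
background_style <- function(colors = c("#2b1d12", "#4a3420", "#6b4e2e",
                                        "#8a6a42", "#9c8a6a"),
                             amplitude = 1, octaves = 4L, base_cells = 4L) {
  stopifnot(length(colors) >= 2, amplitude >= 0, amplitude <= 1,
            octaves >= 1, base_cells >= 2)
  structure(list(colors = colors, amplitude = amplitude,
                 octaves = as.integer(octaves),
                 base_cells = as.integer(base_cells)),
            class = "background_style")
}

# Bilinear upsampling of a coarse grid to h x w.
.bilinear_field <- function(grid, h, w) {
  gh <- nrow(grid); gw <- ncol(grid)
  ry <- (seq_len(h) - 0.5) / h * (gh - 1) + 1
  rx <- (seq_len(w) - 0.5) / w * (gw - 1) + 1
  y0 <- pmin(floor(ry), gh - 1); fy <- ry - y0
  x0 <- pmin(floor(rx), gw - 1); fx <- rx - x0
  g00 <- grid[cbind(rep(y0, w), rep(x0, each = h))]
  g10 <- grid[cbind(rep(y0 + 1, w), rep(x0, each = h))]
  g01 <- grid[cbind(rep(y0, w), rep(x0 + 1, each = h))]
  g11 <- grid[cbind(rep(y0 + 1, w), rep(x0 + 1, each = h))]
  fyv <- rep(fy, w); fxv <- rep(fx, each = h)
  v <- g00 * (1 - fyv) * (1 - fxv) + g10 * fyv * (1 - fxv) +
    g01 * (1 - fyv) * fxv + g11 * fyv * fxv
  matrix(v, h, w)
}

#' Generate a procedural background image
#'
#' Seeded multi-octave value noise (coarse uniform grids, bilinearly
#' upsampled, octave weights 1/2^o) mapped through the style's soil colour
#' ramp. Deterministic given `(height, width, style, seed)`.
#'
#' @param height,width image size in pixels.
#' @param style a [background_style()].
#' @param seed integer seed.
#' @return H x W x 3 numeric array, integer values in `[0, 255]`.
#' @export
make_background <- function(height, width, style = background_style(),
                            seed = 0L) {
  stopifnot(height >= 1, width >= 1)
  field <- matrix(0, height, width)
  withr::with_seed(seed, {
    for (o in seq_len(style$octaves)) {
      cells <- style$base_cells * 2^(o - 1)
      grid <- matrix(stats::runif((cells + 1)^2), cells + 1)
      field <- field + .bilinear_field(grid, height, width) / 2^(o - 1)
    }
  })
  field <- field / sum(1 / 2^(seq_len(style$octaves) - 1))
  field <- 0.5 + style$amplitude * (field - 0.5)
  ramp <- grDevices::colorRamp(style$colors)(clamp(as.vector(field), 0, 1))
  out <- array(0, dim = c(height, width, 3))
  for (ch in 1:3) out[, , ch] <- matrix(ramp[, ch], height, width)
  round(out)
}
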
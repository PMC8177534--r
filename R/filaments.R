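# Synthetic 2D filament textures with a controlled bundling factor: the
# simulated counterpart of cortical microtubule arrays, used as ground truth
# for the bundling-skewness and parallelness metrics.

#' Specify a synthetic filament texture
#'
#' `n_filaments` filaments are grouped into bundles of exactly
#' `bundle_factor` coincident filaments, so bundle pixels carry the summed
#' intensity `bundle_factor * filament_intensity`; where two bundles cross,
#' intensities add again. Bundle orientations are drawn around
#' `mean_orientation` with spread `orientation_sd`; with `placement =
#' "spread"` and zero orientation spread the bundles form an evenly spaced
#' parallel array that never overlaps (the idealized shank array).
#'
#' @param n_filaments total number of filaments; must be divisible by
#'   `bundle_factor`.
#' @param bundle_factor filaments per bundle (>= 1).
#' @param orientation_sd orientation spread in degrees (>= 0).
#' @param mean_orientation mean orientation in degrees (90 = vertical).
#' @param filament_intensity intensity of a single filament, arbitrary units.
#' @param noise_sd additive Gaussian noise SD (clipped at zero).
#' @param image_shape image size `(rows, cols)` in pixels.
#' @param length_px filament length in pixels.
#' @param placement `"random"` (uniform random bundle centres) or `"spread"`
#'   (evenly spaced across the image).
#' @param seed RNG seed; generation is bit-reproducible given the seed.
#' @return An object of class `filament_texture_spec`.
#' @export
filament_texture_spec <- function(n_filaments = 48, bundle_factor = 1,
                                  orientation_sd = 30, mean_orientation = 90,
                                  filament_intensity = 100, noise_sd = 0,
                                  image_shape = c(256, 256), length_px = 200,
                                  placement = c("random", "spread"),
                                  seed = 1L) {
  placement <- match.arg(placement)
  assert_that(n_filaments >= 1 && bundle_factor >= 1,
              "n_filaments and bundle_factor must be >= 1")
  assert_that(n_filaments %% bundle_factor == 0,
              "n_filaments must be divisible by bundle_factor")
  assert_that(orientation_sd >= 0, "orientation_sd must be >= 0")
  assert_that(filament_intensity > 0, "filament_intensity must be > 0")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  assert_that(length(image_shape) == 2 && all(image_shape >= 8),
              "image_shape must be two values >= 8")
  structure(list(n_filaments = n_filaments, bundle_factor = bundle_factor,
                 orientation_sd = orientation_sd,
                 mean_orientation = mean_orientation,
                 filament_intensity = filament_intensity, noise_sd = noise_sd,
                 image_shape = as.integer(image_shape), length_px = length_px,
                 placement = placement, seed = seed),
            class = "filament_texture_spec")
}

#' Generate a filament texture image with ground-truth mask
#'
#' Rasterizes each bundle as a one-pixel-wide line segment carrying
#' `bundle_factor * filament_intensity`; crossing bundles add. Returns the
#' noisy image together with the noiseless ground-truth filament mask.
#'
#' @param spec a [filament_texture_spec()].
#' @return An object of class `filament_texture`: list with `image` (numeric
#'   matrix), `mask` (logical ground-truth filament pixels) and `spec`.
#' @export
make_filament_texture <- function(spec) {
  assert_that(inherits(spec, "filament_texture_spec"),
              "spec must be a filament_texture_spec")
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  nb <- spec$n_filaments / spec$bundle_factor
  with_seed(spec$seed, {
    img <- matrix(0, nr, nc)
    if (spec$placement == "spread") {
      cx <- (seq_len(nb) - 0.5) * nc / nb
      cy <- rep(nr / 2, nb)
    } else {
      cx <- runif(nb, 1, nc)
      cy <- runif(nb, 1, nr)
    }
    theta <- (spec$mean_orientation + rnorm(nb, 0, spec$orientation_sd)) * pi / 180
    for (i in seq_len(nb)) {
      t <- seq(-spec$length_px / 2, spec$length_px / 2, by = 0.25)
      xs <- round(cx[i] + t * cos(theta[i]))
      ys <- round(cy[i] + t * sin(theta[i]))
      ok <- xs >= 1 & xs <= nc & ys >= 1 & ys <= nr
      if (!any(ok)) next
      px <- unique(cbind(ys[ok], xs[ok]))
      img[px] <- img[px] + spec$bundle_factor * spec$filament_intensity
    }
    mask <- img > 0
    if (spec$noise_sd > 0) {
      img <- pmax(img + matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc), 0)
    }
    structure(list(image = img, mask = mask, spec = spec),
              class = "filament_texture")
  })
}
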
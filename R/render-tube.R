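#' Specify the rendering of a tube-shaped cell into an image stack
#'
#' The tube is the set of voxels within `radius` of the centerline, rendered
#' as a filled cross-section (a wall-stained and a cytoplasm-filled tube
#' segment identically for centroid purposes). Noise is additive Gaussian,
#' clipped at zero, or Poisson shot noise.
#'
#' The curve's own axes are mapped onto stack axes through `orientation`: by
#' default the curve's axial x runs along the stack's optical axis z, so that
#' each optical slice cuts the tube transversally -- the geometry in which
#' per-slice centroids sample the centerline.
#'
#' @param centerline a [centerline_spec()].
#' @param radius tube radius in micrometres (> 0).
#' @param voxel_size `(vx, vy, vz)` in micrometres.
#' @param wall_intensity tube intensity, arbitrary units.
#' @param background_intensity background intensity (< wall_intensity).
#' @param noise_sd standard deviation of additive Gaussian noise (a.u.).
#' @param noise_model `"gaussian"` (additive, clipped at 0) or `"poisson"`.
#' @param seed RNG seed for the noise draw.
#' @param dims optional stack dimensions `(nx, ny, nz)` in voxels; when `NULL`
#'   the stack is auto-sized to fit the tube with `margin`.
#' @param orientation named character vector mapping curve axes to stack axes,
#'   e.g. `c(x = "z", y = "y", z = "x")` (the default).
#' @param margin clearance between tube surface and lateral stack faces, in
#'   micrometres; the slice axis is cut flush with the curve's axial extent so
#'   end slices are clean cross-sections.
#' @return An object of class `tube_render_spec`.
#' @export
tube_render_spec <- function(centerline, radius, voxel_size = c(0.4, 0.4, 0.4),
                             wall_intensity = 200, background_intensity = 10,
                             noise_sd = 0, noise_model = c("gaussian", "poisson"),
                             seed = NULL, dims = NULL,
                             orientation = c(x = "z", y = "y", z = "x"),
                             margin = 2) {
  noise_model <- match.arg(noise_model)
  assert_that(inherits(centerline, "centerline_spec"),
              "centerline must be a centerline_spec")
  assert_that(radius > 0, "radius must be > 0")
  assert_that(all(voxel_size > 0), "voxel sizes must be > 0")
  assert_that(wall_intensity > background_intensity,
              "wall_intensity must exceed background_intensity")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  assert_that(setequal(names(orientation), c("x", "y", "z")) &&
                setequal(orientation, c("x", "y", "z")),
              "orientation must be a bijection of c('x','y','z')")
  structure(list(centerline = centerline, radius = radius,
                 voxel_size = as.numeric(voxel_size),
                 wall_intensity = wall_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, noise_model = noise_model, seed = seed,
                 dims = dims, orientation = orientation, margin = margin),
            class = "tube_render_spec")
}

#' Render a tube image stack from a centerline specification
#'
#' Voxels within `radius` of the (densely sampled) centerline receive
#' `wall_intensity`, all others `background_intensity`; noise is then drawn
#' with the spec's seed, so rendering is bit-reproducible given the spec. The
#' stack metadata records the ground-truth sinuosity, arc length, chord and
#' the base/tip points in stack coordinates.
#'
#' @param spec a [tube_render_spec()].
#' @return An [image_stack()] with ground-truth metadata.
#' @examples
#' spec <- tube_render_spec(centerline_spec("straight", length = 20),
#'                          radius = 4, voxel_size = c(0.5, 0.5, 1))
#' stk <- render_tube_stack(spec)
#' stk$metadata$truth_sinuosity  # 100
#' @export
render_tube_stack <- function(spec) {
  assert_that(inherits(spec, "tube_render_spec"), "spec must be a tube_render_spec")
  vx <- spec$voxel_size[1]; vy <- spec$voxel_size[2]; vz <- spec$voxel_size[3]
  r <- spec$radius

  cl <- make_centerline(spec$centerline,
                        n_points = max(100, ceiling(4 * spec_axial_extent(spec$centerline))))
  # dense samples so that point-to-sample distance approximates point-to-curve
  step <- min(spec$voxel_size) / 2
  n_dense <- max(2L, ceiling(cl$arc_length / step) + 1L)
  dense <- eval_centerline(spec$centerline, seq(0, 1, length.out = n_dense))

  # map curve axes onto stack axes
  p_stack <- dense[, match(c("x", "y", "z"), spec$orientation), drop = FALSE]
  colnames(p_stack) <- c("x", "y", "z")

  # place the tube: lateral margin on x/y, flush cut along the slice axis z
  off <- c(r + spec$margin - min(p_stack[, 1]),
           r + spec$margin - min(p_stack[, 2]),
           -min(p_stack[, 3]))
  p_stack <- sweep(p_stack, 2, off, "+")

  if (is.null(spec$dims)) {
    nx <- ceiling((max(p_stack[, 1]) + r + spec$margin) / vx) + 1L
    ny <- ceiling((max(p_stack[, 2]) + r + spec$margin) / vy) + 1L
    nz <- floor(max(p_stack[, 3]) / vz) + 1L
  } else {
    nx <- spec$dims[1]; ny <- spec$dims[2]; nz <- spec$dims[3]
    lim <- c((nx - 1) * vx, (ny - 1) * vy, (nz - 1) * vz)
    fits <- min(p_stack[, 1]) >= r && max(p_stack[, 1]) <= lim[1] - r &&
      min(p_stack[, 2]) >= r && max(p_stack[, 2]) <= lim[2] - r &&
      min(p_stack[, 3]) >= 0 && max(p_stack[, 3]) <= lim[3]
    if (!fits) stop_config("tube exits stack bounds: enlarge dims or drop them for auto-sizing")
  }

  xs <- (seq_len(nx) - 1) * vx
  ys <- (seq_len(ny) - 1) * vy
  voxels <- array(spec$background_intensity, dim = c(ny, nx, nz))
  ord <- order(p_stack[, 3])
  pz_sorted <- p_stack[ord, 3]

  for (k in seq_len(nz)) {
    zc <- (k - 1) * vz
    lo <- findInterval(zc - r, pz_sorted) + 1L
    hi <- findInterval(zc + r, pz_sorted)
    if (hi < lo) next
    sel <- ord[lo:hi]
    dz <- p_stack[sel, 3] - zc
    rho <- sqrt(pmax(r^2 - dz^2, 0))
    keep <- rho > 0
    if (!any(keep)) next
    mask <- matrix(FALSE, ny, nx)
    px <- p_stack[sel, 1][keep]; py <- p_stack[sel, 2][keep]; prho <- rho[keep]
    for (s in seq_along(prho)) {
      ci <- which(abs(xs - px[s]) <= prho[s])
      if (!length(ci)) next
      ri <- which(abs(ys - py[s]) <= prho[s])
      if (!length(ri)) next
      disc <- outer((ys[ri] - py[s])^2, (xs[ci] - px[s])^2, "+") <= prho[s]^2
      mask[ri, ci] <- mask[ri, ci] | disc
    }
    slice <- voxels[, , k]
    slice[mask] <- spec$wall_intensity
    voxels[, , k] <- slice
  }

  if (spec$noise_sd > 0 || spec$noise_model == "poisson") {
    voxels <- with_seed(spec$seed, {
      if (spec$noise_model == "gaussian") {
        pmax(voxels + array(rnorm(length(voxels), 0, spec$noise_sd), dim = dim(voxels)), 0)
      } else {
        array(rpois(length(voxels), lambda = voxels), dim = dim(voxels))
      }
    })
  }

  ends <- eval_centerline(spec$centerline, c(0, 1))
  ends_stack <- sweep(ends[, match(c("x", "y", "z"), spec$orientation), drop = FALSE], 2, off, "+")
  image_stack(voxels, voxel_size = spec$voxel_size,
              metadata = list(truth_sinuosity = cl$sinuosity,
                              truth_arc_length = cl$arc_length,
                              truth_chord = cl$chord,
                              base_point = as.numeric(ends_stack[1, ]),
                              tip_point = as.numeric(ends_stack[2, ]),
                              radius = r,
                              noise_sd = spec$noise_sd,
                              seed = if (is.null(spec$seed)) NA else spec$seed))
}

# Rough axial extent of a centerline spec, used to pick a sampling density.
spec_axial_extent <- function(spec) {
  if (spec$kind == "piecewise") {
    polyline_length(spec$waypoints)
  } else {
    spec$length
  }
}
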
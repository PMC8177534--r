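#' Specify a parametric tube centerline
#'
#' A centerline is a parametric 3D curve evaluated on \eqn{t \in [0, 1]}, with
#' the base at \eqn{t = 0} and the tip at \eqn{t = 1}. The curve's axial
#' coordinate runs along x; waves are drawn in the x-y plane, the x-z plane,
#' or both. All lengths are in micrometres.
#'
#' @param kind one of `"straight"`, `"sinusoid"`, `"helix"`, `"piecewise"`.
#' @param length axial extent of the curve along x, in micrometres (> 0).
#'   Ignored for `"piecewise"`.
#' @param amplitude wave amplitude A in micrometres (>= 0, sinusoid only).
#' @param wavelength wavelength of the sinusoid in micrometres (> 0).
#' @param helix_radius helix radius in micrometres (>= 0, helix only).
#' @param pitch helix pitch (axial advance per turn) in micrometres (> 0).
#' @param plane plane of the sinusoid wave: `"x-y"`, `"x-z"` or `"both"`.
#' @param waypoints for `kind = "piecewise"`, an n x 3 matrix of 3D points
#'   (columns x, y, z) interpolated linearly.
#' @param phase phase offset of the sinusoid in radians.
#' @return An object of class `centerline_spec`.
#' @seealso [make_centerline()], [centerline_semicircle()]
#' @export
centerline_spec <- function(kind = c("straight", "sinusoid", "helix", "piecewise"),
                            length = 150, amplitude = 0, wavelength = NA_real_,
                            helix_radius = NA_real_, pitch = NA_real_,
                            plane = c("x-y", "x-z", "both"),
                            waypoints = NULL, phase = 0) {
  kind <- match.arg(kind)
  plane <- match.arg(plane)
  if (kind != "piecewise") {
    assert_that(is.numeric(length) && length > 0, "centerline length must be > 0")
  }
  if (kind == "sinusoid") {
    assert_that(amplitude >= 0, "amplitude must be >= 0")
    assert_that(is.finite(wavelength) && wavelength > 0,
                "wavelength must be > 0 for a sinusoid centerline")
  }
  if (kind == "helix") {
    assert_that(is.finite(helix_radius) && helix_radius >= 0,
                "helix_radius must be >= 0")
    assert_that(is.finite(pitch) && pitch > 0, "pitch must be > 0 for a helix")
  }
  if (kind == "piecewise") {
    waypoints <- as.matrix(waypoints)
    assert_that(!is.null(waypoints) && ncol(waypoints) == 3 && nrow(waypoints) >= 2,
                "piecewise centerline needs an n x 3 waypoint matrix with n >= 2")
    assert_that(all(is.finite(waypoints)), "waypoints must be finite")
  }
  structure(list(kind = kind, length = length, amplitude = amplitude,
                 wavelength = wavelength, helix_radius = helix_radius,
                 pitch = pitch, plane = plane, waypoints = waypoints,
                 phase = phase),
            class = "centerline_spec")
}

# Evaluate the parametric curve at parameter values t in [0, 1].
eval_centerline <- function(spec, t) {
  switch(spec$kind,
    straight = cbind(x = t * spec$length, y = 0 * t, z = 0 * t),
    sinusoid = {
      x <- t * spec$length
      wave <- spec$amplitude * sin(2 * pi * x / spec$wavelength + spec$phase) -
        spec$amplitude * sin(spec$phase)
      switch(spec$plane,
        `x-y` = cbind(x = x, y = wave, z = 0 * x),
        `x-z` = cbind(x = x, y = 0 * x, z = wave),
        both = {
          wave2 <- spec$amplitude * cos(2 * pi * x / spec$wavelength + spec$phase) -
            spec$amplitude * cos(spec$phase)
          cbind(x = x, y = wave, z = wave2)
        })
    },
    helix = {
      x <- t * spec$length
      u <- 2 * pi * x / spec$pitch
      cbind(x = x,
            y = spec$helix_radius * sin(u),
            z = spec$helix_radius * (cos(u) - 1))
    },
    piecewise = {
      wp <- spec$waypoints
      seg <- segment_lengths(wp)
      cum <- c(0, cumsum(seg))
      total <- cum[length(cum)]
      assert_that(total > 0, "piecewise waypoints are all coincident")
      s <- t * total
      xi <- stats::approx(cum, wp[, 1], xout = s, rule = 2)$y
      yi <- stats::approx(cum, wp[, 2], xout = s, rule = 2)$y
      zi <- stats::approx(cum, wp[, 3], xout = s, rule = 2)$y
      cbind(x = xi, y = yi, z = zi)
    },
    stop_config(sprintf("unknown centerline kind '%s'", spec$kind)))
}

#' Generate an ordered centerline polyline with ground-truth sinuosity
#'
#' Evaluates the parametric curve at `n_points` evenly spaced parameter values
#' (base first, tip last) and computes its arc length by dense numerical
#' quadrature: the curve is evaluated on a fine parameter grid and the polyline
#' length of that grid converges to the arc length. The ground-truth sinuosity
#' is `100 * arc_length / chord`, where the chord is the base-to-tip distance.
#'
#' @param spec a [centerline_spec()].
#' @param n_points number of points on the returned polyline (>= 2).
#' @param quadrature_n number of grid points used for the arc-length
#'   quadrature. For piecewise centerlines the exact waypoint polyline length
#'   is used instead.
#' @return An object of class `centerline`: a list with `points` (n x 3 matrix,
#'   micrometres), `arc_length`, `chord`, `sinuosity` (percent) and `spec`.
#' @examples
#' cl <- make_centerline(centerline_spec("straight", length = 150), 50)
#' cl$sinuosity  # 100: a straight line's path equals its chord
#' @export
make_centerline <- function(spec, n_points = 100, quadrature_n = 20001) {
  assert_that(inherits(spec, "centerline_spec"), "spec must be a centerline_spec")
  assert_that(n_points >= 2, "n_points must be >= 2")
  points <- eval_centerline(spec, seq(0, 1, length.out = n_points))
  arc <- if (spec$kind == "piecewise") {
    polyline_length(spec$waypoints)
  } else {
    polyline_length(eval_centerline(spec, seq(0, 1, length.out = quadrature_n)))
  }
  ends <- eval_centerline(spec, c(0, 1))
  chord <- sqrt(sum((ends[2, ] - ends[1, ])^2))
  assert_that(chord > 0, "degenerate centerline: base and tip coincide")
  structure(list(points = points, arc_length = arc, chord = chord,
                 sinuosity = 100 * arc / chord, spec = spec),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline: %s, %d points, arc %.2f um, chord %.2f um, sinuosity %.2f%%>\n",
              x$spec$kind, nrow(x$points), x$arc_length, x$chord, x$sinuosity))
  invisible(x)
}

#' Semicircular centerline specification
#'
#' Convenience constructor for a semicircular arc (chord along x, bulge along
#' y), expressed as a dense piecewise centerline. Its sinuosity is the closed
#' form \eqn{100 \pi / 2 \approx 157.08}: a half-circle of radius r has path
#' length \eqn{\pi r} over a chord of \eqn{2 r}.
#'
#' @param radius arc radius in micrometres.
#' @param n_waypoints number of waypoints on the arc.
#' @return A `centerline_spec` of kind `"piecewise"`.
#' @export
centerline_semicircle <- function(radius, n_waypoints = 721) {
  theta <- seq(0, pi, length.out = n_waypoints)
  centerline_spec("piecewise",
                  waypoints = cbind(x = radius * (1 - cos(theta)),
                                    y = radius * sin(theta),
                                    z = 0))
}
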
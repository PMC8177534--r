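# Stage 2 of the sinuosity pipeline: order slice centroids into a 3D path by
# simulated annealing, fragment at direction changes, LOWESS-smooth each
# fragment, reassemble and measure sinuosity and diameters.

#' Simulated-annealing parameters for path ordering
#'
#' Geometric cooling schedule for the open-tour ordering problem with a fixed
#' starting point. The default temperature is the mean pairwise distance of
#' the point cloud, cooled by `cooling_rate` each iteration, with 2-opt
#' segment reversal and single-point relocation moves.
#'
#' @param initial_temperature starting temperature (micrometres); `NULL` uses
#'   the mean pairwise point distance.
#' @param cooling_rate multiplicative cooling factor per iteration, in (0, 1).
#' @param iterations number of proposal iterations per restart (>= 1).
#' @param restarts number of independent annealing restarts; the first starts
#'   from the nearest-neighbour tour, later ones from seeded random tours, and
#'   the best polished tour wins.
#' @param seed RNG seed; ordering is bit-reproducible given the seed.
#' @return An object of class `sa_params`.
#' @export
sa_params <- function(initial_temperature = NULL, cooling_rate = 0.995,
                      iterations = 10000, restarts = 3, seed = 1L) {
  assert_that(is.null(initial_temperature) || initial_temperature > 0,
              "initial_temperature must be > 0 or NULL")
  assert_that(cooling_rate > 0 && cooling_rate < 1,
              "cooling_rate must be in (0, 1)")
  assert_that(iterations >= 1, "iterations must be >= 1")
  assert_that(restarts >= 1, "restarts must be >= 1")
  structure(list(initial_temperature = initial_temperature,
                 cooling_rate = cooling_rate,
                 iterations = as.integer(iterations),
                 restarts = as.integer(restarts), seed = seed),
            class = "sa_params")
}

path_cost <- function(dmat, ord) {
  n <- length(ord)
  sum(dmat[cbind(ord[-n], ord[-1L])])
}

# First-improvement descent on an open path with fixed first position,
# alternating 2-opt segment reversals and single-point relocations until
# neither move improves the tour.
two_opt_descent <- function(dmat, ord) {
  n <- length(ord)
  repeat {
    improved <- FALSE
    # 2-opt reversals
    for (i in 2:(n - 1L)) {
      for (j in (i + 1L):n) {
        delta <- dmat[ord[i - 1L], ord[j]] - dmat[ord[i - 1L], ord[i]]
        if (j < n) {
          delta <- delta + dmat[ord[i], ord[j + 1L]] - dmat[ord[j], ord[j + 1L]]
        }
        if (delta < -1e-12) {
          ord[i:j] <- rev(ord[i:j])
          improved <- TRUE
        }
      }
    }
    # single-point relocations
    for (i in 2:n) {
      removed <- dmat[ord[i - 1L], ord[i]] +
        (if (i < n) dmat[ord[i], ord[i + 1L]] - dmat[ord[i - 1L], ord[i + 1L]] else 0)
      for (j in setdiff(2:n, c(i - 1L, i))) {
        # insert point ord[i] after current position j (skipping no-ops)
        added <- dmat[ord[j], ord[i]] +
          (if (j < n) dmat[ord[i], ord[j + 1L]] - dmat[ord[j], ord[j + 1L]] else 0)
        if (added - removed < -1e-12) {
          p <- ord[i]
          ord <- append(ord[-i], p, after = j - (i < j))
          improved <- TRUE
          break
        }
      }
    }
    if (!improved) break
  }
  list(ord = ord, cost = path_cost(dmat, ord))
}

#' Order 3D points into a path by simulated annealing
#'
#' Finds a short open tour through all points beginning at a fixed base point
#' (the cell's base): the ordering in which slice centroids represent the cell
#' in 3D. The initial tour is nearest-neighbour from the base; annealing then
#' applies 2-opt reversals and point relocations under geometric cooling. The
#' best ordering encountered is returned, so the final tour cost never exceeds
#' the initial (or input) ordering's cost.
#'
#' @param points n x 3 numeric matrix of micrometre coordinates (n >= 2).
#' @param base_index row index of the fixed starting point.
#' @param sa an [sa_params()].
#' @return An object of class `center_path`: list with `points` (ordered
#'   matrix, base first), `order` (row permutation of the input), `cost`,
#'   `initial_cost` and `input_cost`.
#' @export
order_path <- function(points, base_index = 1L, sa = sa_params()) {
  points <- as.matrix(points)
  n <- nrow(points)
  assert_that(n >= 2, "need at least two points to order")
  assert_that(base_index >= 1 && base_index <= n, "base_index out of range")
  dmat <- as.matrix(stats::dist(points))
  input_cost <- path_cost(dmat, seq_len(n))

  # nearest-neighbour construction from the base
  ord <- integer(n)
  ord[1L] <- base_index
  remaining <- setdiff(seq_len(n), base_index)
  for (i in seq_len(n - 1L)) {
    d <- dmat[ord[i], remaining]
    j <- which.min(d)
    ord[i + 1L] <- remaining[j]
    remaining <- remaining[-j]
  }
  initial_cost <- path_cost(dmat, ord)

  best_ord <- ord
  best_cost <- initial_cost
  if (n > 3L) {
    t0 <- if (is.null(sa$initial_temperature)) {
      mean(dmat[upper.tri(dmat)])
    } else {
      sa$initial_temperature
    }
    anneal_once <- function(start_ord) {
      cur <- start_ord
      cost <- path_cost(dmat, cur)
      inner_best <- cur
      inner_cost <- cost
      temp <- t0
      for (it in seq_len(sa$iterations)) {
        if (runif(1) < 0.5) {
          # 2-opt: reverse a segment, keeping position 1 fixed
          ij <- sort(sample(2:n, 2L))
          cand <- cur
          cand[ij[1]:ij[2]] <- rev(cand[ij[1]:ij[2]])
        } else {
          # relocate one point to another position
          i <- sample(2:n, 1L)
          j <- sample(setdiff(2:n, i), 1L)
          cand <- append(cur[-i], cur[i], after = j - 1L)
        }
        cand_cost <- path_cost(dmat, cand)
        delta <- cand_cost - cost
        if (delta < 0 || runif(1) < exp(-delta / temp)) {
          cur <- cand
          cost <- cand_cost
          if (cost < inner_cost) {
            inner_cost <- cost
            inner_best <- cur
          }
        }
        temp <- temp * sa$cooling_rate
      }
      # deterministic descent to the nearest local optimum polishes any
      # residual crossings the annealing left behind
      two_opt_descent(dmat, inner_best)
    }
    run <- with_seed(sa$seed, {
      for (r in seq_len(sa$restarts)) {
        start <- if (r == 1L) ord else c(base_index, sample(setdiff(seq_len(n), base_index)))
        res <- anneal_once(start)
        if (res$cost < best_cost) {
          best_cost <- res$cost
          best_ord <- res$ord
        }
      }
      list(ord = best_ord, cost = best_cost)
    })
    best_ord <- run$ord
    best_cost <- run$cost
  }
  structure(list(points = points[best_ord, , drop = FALSE],
                 order = best_ord, cost = best_cost,
                 initial_cost = initial_cost, input_cost = input_cost),
            class = "center_path")
}

#' @export
print.center_path <- function(x, ...) {
  cat(sprintf("<center_path: %d points, length %.2f um (initial %.2f um)>\n",
              nrow(x$points), x$cost, x$initial_cost))
  invisible(x)
}

# Pick the abscissa axis: largest coordinate extent ("auto") or a fixed axis.
resolve_abscissa <- function(points, abscissa) {
  if (identical(abscissa, "auto")) {
    ext <- apply(points, 2, function(v) diff(range(v)))
    return(c("x", "y", "z")[which.max(ext)])
  }
  assert_that(abscissa %in% c("x", "y", "z"), "abscissa must be 'auto', 'x', 'y' or 'z'")
  abscissa
}

#' Split an ordered path where its direction changes significantly
#'
#' The local direction of each step is its angle to the abscissa axis,
#' measured in the two coordinate planes that contain the abscissa. A new
#' fragment begins at the point where a step's direction deviates from the
#' reference direction of the current fragment (its first step) by more than
#' `angle_threshold` in either plane: the path is split where a significant
#' cumulative change in direction occurs. Fragments partition the points and
#' always hold at least two points (singletons are merged into the preceding
#' fragment).
#'
#' @param path a `center_path` or an ordered n x 3 point matrix.
#' @param angle_threshold direction-change threshold in degrees.
#' @param abscissa `"auto"` (axis of largest extent), `"x"`, `"y"` or `"z"`.
#' @return A list of `path_fragment` objects: point matrices in path order
#'   with attributes `abscissa` and `range` (row indices into the path).
#' @export
split_by_direction <- function(path, angle_threshold = 45, abscissa = "auto") {
  points <- if (inherits(path, "center_path")) path$points else as.matrix(path)
  n <- nrow(points)
  assert_that(n >= 2, "path needs at least two points")
  assert_that(angle_threshold > 0, "angle_threshold must be > 0")
  a_axis <- resolve_abscissa(points, abscissa)
  other <- setdiff(c("x", "y", "z"), a_axis)
  da <- diff(points[, a_axis])
  du <- diff(points[, other[1]])
  dv <- diff(points[, other[2]])
  ang_u <- atan2(du, da) * 180 / pi
  ang_v <- atan2(dv, da) * 180 / pi

  starts <- 1L
  ref_u <- ang_u[1L]; ref_v <- ang_v[1L]
  for (j in seq_len(n - 1L)[-1L]) {
    if (abs(wrap180(ang_u[j] - ref_u)) > angle_threshold ||
        abs(wrap180(ang_v[j] - ref_v)) > angle_threshold) {
      starts <- c(starts, j)
      ref_u <- ang_u[j]; ref_v <- ang_v[j]
    }
  }
  ends <- c(starts[-1L] - 1L, n)
  # merge singleton fragments into their predecessor
  keep_s <- starts; keep_e <- ends
  i <- 2L
  while (i <= length(keep_s)) {
    if (keep_e[i] - keep_s[i] < 1L) {
      keep_e[i - 1L] <- keep_e[i]
      keep_s <- keep_s[-i]; keep_e <- keep_e[-i]
    } else {
      i <- i + 1L
    }
  }
  if (keep_e[1L] - keep_s[1L] < 1L && length(keep_s) > 1L) {
    keep_s <- keep_s[-1L]
    keep_s[1L] <- 1L
  }
  lapply(seq_along(keep_s), function(i) {
    idx <- keep_s[i]:keep_e[i]
    structure(points[idx, , drop = FALSE], abscissa = a_axis, range = range(idx),
              class = c("path_fragment", "matrix", "array"))
  })
}

#' LOWESS-smooth one path fragment
#'
#' Regresses each of the two transverse coordinates on the abscissa
#' independently with locally weighted scatterplot smoothing (span `frac` of
#' the fragment's points), keeping the abscissa values, the point count and
#' the order -- so the 3D dataset is maintained. A degenerate fragment whose
#' abscissa has no spread is returned unchanged with a warning.
#'
#' @param fragment a `path_fragment` (or n x 3 matrix; then `abscissa` should
#'   be given).
#' @param frac LOWESS span as a fraction of the fragment's points, in (0, 1].
#' @param iter number of LOWESS robustness iterations.
#' @param abscissa abscissa axis; defaults to the fragment's attribute, and
#'   `"auto"` picks the fragment's own axis of largest extent (within a
#'   fragment the direction is roughly constant, so its dominant axis is a
#'   valid regression abscissa even when the whole path turns).
#' @return The smoothed fragment, same class and attributes.
#' @export
smooth_fragment <- function(fragment, frac = 0.1, iter = 3, abscissa = NULL) {
  assert_that(frac > 0 && frac <= 1, "frac must be in (0, 1]")
  points <- as.matrix(fragment)
  assert_that(nrow(points) >= 2, "fragment needs at least two points")
  a_axis <- abscissa %||% attr(fragment, "abscissa") %||% "x"
  if (identical(a_axis, "auto")) a_axis <- resolve_abscissa(points, "auto")
  other <- setdiff(c("x", "y", "z"), a_axis)
  a <- points[, a_axis]
  if (diff(range(a)) == 0) {
    warning("degenerate fragment: no spread along abscissa '", a_axis,
            "'; returned unsmoothed", call. = FALSE)
    return(fragment)
  }
  ord <- order(a)
  out <- points
  for (ax in other) {
    fit <- lowess(a, points[, ax], f = frac, iter = iter, delta = 0)
    smoothed <- numeric(nrow(points))
    smoothed[ord] <- fit$y
    out[, ax] <- smoothed
  }
  attributes(out) <- attributes(fragment)
  out
}

#' Assemble smoothed fragments and measure sinuosity
#'
#' Concatenates the fragments in path order into one regressed path and
#' computes the regressed path length L (sum of segment lengths), the chord D
#' (base-to-tip distance) and the sinuosity S = 100 L / D percent. A straight
#' cell has S = 100; the triangle inequality guarantees S >= 100.
#'
#' @param fragments list of fragments (point matrices) in path order.
#' @return An object of class `sinuosity_result`: list with
#'   `path_length_um`, `chord_um`, `sinuosity_pct`, `n_fragments`, `points`.
#' @export
assemble_and_measure <- function(fragments) {
  assert_that(length(fragments) >= 1, "need at least one fragment")
  points <- do.call(rbind, lapply(fragments, as.matrix))
  L <- polyline_length(points)
  D <- sqrt(sum((points[nrow(points), ] - points[1L, ])^2))
  if (D == 0) stop_config("degenerate path: base and tip coincide")
  structure(list(path_length_um = L, chord_um = D,
                 sinuosity_pct = 100 * L / D,
                 n_fragments = length(fragments), points = points),
            class = "sinuosity_result")
}

#' @export
print.sinuosity_result <- function(x, ...) {
  cat(sprintf("<sinuosity: %.2f%% (L = %.2f um, D = %.2f um, %d fragment%s)>\n",
              x$sinuosity_pct, x$path_length_um, x$chord_um, x$n_fragments,
              if (x$n_fragments == 1) "" else "s"))
  invisible(x)
}

#' Measure 3D sinuosity of a tubular cell from an image stack
#'
#' Full pipeline: per-slice segmentation ([collect_cogs()]), path ordering by
#' simulated annealing ([order_path()]), fragmentation at direction changes
#' ([split_by_direction()]), per-fragment LOWESS smoothing
#' ([smooth_fragment()]) in both transverse planes, and measurement
#' ([assemble_and_measure()]).
#'
#' @param stack an [image_stack()].
#' @param threshold `"otsu"` or a fixed numeric threshold.
#' @param min_fraction noise-filter area fraction.
#' @param angle_threshold direction-change split threshold, degrees.
#' @param frac LOWESS span.
#' @param sa an [sa_params()].
#' @param abscissa `"auto"`, `"x"`, `"y"` or `"z"`.
#' @param base_index index of the base point among the collected centroids, or
#'   `"auto"` to use the point farthest from the cloud centroid (a path
#'   endpoint for elongated clouds).
#' @return A `sinuosity_result` with extra fields `n_points` and `cogs`.
#' @export
measure_sinuosity <- function(stack, threshold = "otsu", min_fraction = 0.01,
                              angle_threshold = 45, frac = 0.1,
                              sa = sa_params(), abscissa = "auto",
                              base_index = "auto") {
  cogs <- collect_cogs(stack, threshold = threshold, min_fraction = min_fraction)
  pts <- cogs$points
  if (identical(base_index, "auto")) {
    ctr <- colMeans(pts)
    base_index <- which.max(rowSums(sweep(pts, 2, ctr)^2))
  }
  path <- order_path(pts, base_index = base_index, sa = sa)
  fragments <- split_by_direction(path, angle_threshold = angle_threshold,
                                  abscissa = abscissa)
  # each fragment is smoothed against its own dominant axis so that steep
  # fragments (running mainly transverse to the global abscissa) are still
  # regressed rather than passed through unsmoothed
  smoothed <- lapply(fragments, smooth_fragment, frac = frac,
                     abscissa = if (identical(abscissa, "auto")) "auto")
  res <- assemble_and_measure(smoothed)
  res$n_points <- nrow(pts)
  res$cogs <- cogs
  res
}

#' Sample the cell diameter along the path
#'
#' At stations spaced every `spacing` micrometres of arc length along the
#' path, the diameter is the minimum caliper width (the "shortest diameter")
#' of the contour whose centre of gravity lies nearest the station. The
#' automated analogue of manual shortest-diameter sampling along the shank.
#' Stations with no contour within one spacing are skipped with a warning.
#'
#' @param contours list of `slice_contour` objects (from [collect_cogs()]).
#' @param path a `center_path` or ordered point matrix (micrometres).
#' @param voxel_size `(vx, vy, vz)` micrometres, to convert contour pixels.
#' @param spacing station spacing in micrometres.
#' @return An object of class `diameter_profile`: data frame with
#'   `position_um` and `diameter_um`, plus `mean` and `sd` attributes.
#' @export
measure_diameters <- function(contours, path, voxel_size, spacing = 5) {
  points <- if (inherits(path, "center_path")) path$points else as.matrix(path)
  assert_that(spacing > 0, "spacing must be > 0")
  seg <- segment_lengths(points)
  arc <- c(0, cumsum(seg))
  stations <- seq(0, max(arc), by = spacing)
  if (!length(stations)) stations <- 0
  station_xyz <- cbind(
    stats::approx(arc, points[, 1], xout = stations, rule = 2)$y,
    stats::approx(arc, points[, 2], xout = stations, rule = 2)$y,
    stats::approx(arc, points[, 3], xout = stations, rule = 2)$y)
  cog_xyz <- t(vapply(contours, function(ct) {
    c(ct$cog[["x"]] * voxel_size[1], ct$cog[["y"]] * voxel_size[2],
      ct$z_index * voxel_size[3])
  }, numeric(3)))
  out <- data.frame(position_um = stations, diameter_um = NA_real_)
  skipped <- 0L
  for (i in seq_along(stations)) {
    d2 <- rowSums(sweep(cog_xyz, 2, station_xyz[i, ])^2)
    j <- which.min(d2)
    if (sqrt(d2[j]) > spacing) {
      skipped <- skipped + 1L
      next
    }
    poly_um <- cbind(contours[[j]]$polygon[, "x"] * voxel_size[1],
                     contours[[j]]$polygon[, "y"] * voxel_size[2])
    out$diameter_um[i] <- min_caliper_width(poly_um)
  }
  if (skipped > 0) {
    warning(sprintf("%d station(s) had no contour within %.3g um and were skipped",
                    skipped, spacing), call. = FALSE)
  }
  out <- out[!is.na(out$diameter_um), , drop = FALSE]
  structure(out, mean = mean(out$diameter_um), sd = sd(out$diameter_um),
            class = c("diameter_profile", "data.frame"))
}

# Minimum caliper width of a point set: for each convex-hull edge, the
# farthest hull point from the edge's line; the width is the minimum over
# edges (rotating calipers on the hull).
min_caliper_width <- function(points) {
  points <- as.matrix(points)
  h <- grDevices::chull(points)
  hull <- points[h, , drop = FALSE]
  m <- nrow(hull)
  if (m < 2) return(0)
  if (m == 2) return(0)
  widths <- vapply(seq_len(m), function(i) {
    p1 <- hull[i, ]
    p2 <- hull[if (i == m) 1L else i + 1L, ]
    e <- p2 - p1
    len <- sqrt(sum(e^2))
    if (len == 0) return(Inf)
    # distance of every hull point from the edge line
    max(abs((hull[, 1] - p1[1]) * (-e[2]) + (hull[, 2] - p1[2]) * e[1]) / len)
  }, numeric(1))
  min(widths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
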
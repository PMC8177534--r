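test_that("ordering trivial configurations works without annealing surprises", {
  # 3 collinear points fed in scrambled order come out monotone
  pts <- cbind(x = c(10, 0, 5), y = 0, z = 0)
  path <- order_path(pts, base_index = 2L)
  expect_equal(path$points[, "x"], c(0, 5, 10))

  # n = 2 is the identity
  two <- cbind(x = c(0, 1), y = c(0, 0), z = c(0, 0))
  expect_equal(order_path(two, 1L)$order, c(1L, 2L))

  # fixed seed is bit-reproducible
  set.seed(99)
  cloud <- matrix(runif(45), 15, 3, dimnames = list(NULL, c("x", "y", "z")))
  a <- order_path(cloud, 1L, sa_params(seed = 5L))
  b <- order_path(cloud, 1L, sa_params(seed = 5L))
  expect_identical(a$order, b$order)
})

test_that("annealed tours never cost more than the input ordering", {
  set.seed(3)
  for (i in 1:5) {
    pts <- matrix(runif(30, 0, 50), 10, 3, dimnames = list(NULL, c("x", "y", "z")))
    path <- order_path(pts, 1L, sa_params(seed = i))
    expect_lte(path$cost, path$input_cost + 1e-9)
    expect_lte(path$cost, path$initial_cost + 1e-9)
  }
})

test_that("annealing matches the exhaustive open-tour optimum on small instances", {
  hits <- 0L
  for (s in 1:10) {
    set.seed(s)
    pts <- matrix(runif(21, 0, 100), 7, 3, dimnames = list(NULL, c("x", "y", "z")))
    opt <- brute_force_open_tour(pts, 1L)
    res <- order_path(pts, 1L, sa_params(seed = s))
    expect_lte(res$cost, opt * 1.01)
    hits <- hits + (abs(res$cost - opt) < 1e-9)
  }
  expect_gte(hits, 9L)
})

test_that("direction splitting fragments the path where direction accumulates", {
  # straight path: one fragment at any positive threshold
  straight <- cbind(x = seq(0, 10), y = 0, z = 0)
  expect_length(split_by_direction(straight, 10), 1)

  # right-angle L at threshold 45: exactly two fragments, split at the corner
  ell <- cbind(x = c(0:5, rep(5, 5)), y = c(rep(0, 6), 1:5), z = 0)
  frs <- split_by_direction(ell, 45, abscissa = "x")
  expect_length(frs, 2)
  # the corner point opens the second fragment; the partition covers the path
  expect_equal(nrow(frs[[1]]), 5)
  expect_equal(nrow(frs[[2]]), 6)
  expect_equal(sum(vapply(frs, nrow, integer(1))), nrow(ell))

  # gentle sinusoid whose per-step direction never deviates beyond the
  # threshold stays a single fragment; oracle = explicit per-step angles
  x <- seq(0, 100, by = 1)
  y <- 3 * sin(2 * pi * x / 60)
  ang <- atan2(diff(y), diff(x)) * 180 / pi
  expect_lt(max(abs(ang - ang[1])), 60)  # oracle premise
  expect_length(split_by_direction(cbind(x = x, y = y, z = 0), 60, "x"), 1)

  # fragments always partition the path points, in order
  wavy <- cbind(x = seq(0, 150, by = 1.5),
                y = 10 * sin(2 * pi * seq(0, 150, by = 1.5) / 50), z = 0)
  frs2 <- split_by_direction(wavy, 45, "x")
  expect_gt(length(frs2), 1)
  expect_equal(do.call(rbind, lapply(frs2, unclass))[, "x"], wavy[, "x"],
               ignore_attr = TRUE)
  expect_true(all(vapply(frs2, nrow, integer(1)) >= 2))
})

test_that("LOWESS smoothing preserves straight fragments and damps noise", {
  frag <- structure(cbind(x = seq(0, 50, by = 0.5), y = 2 * seq(0, 50, by = 0.5),
                          z = 1), abscissa = "x",
                    class = c("path_fragment", "matrix", "array"))
  sm <- smooth_fragment(frag, frac = 0.3)
  expect_lt(max(abs(sm[, "y"] - frag[, "y"])), 1e-6)
  expect_lt(max(abs(sm[, "z"] - frag[, "z"])), 1e-6)

  # noisy straight fragment: smoothed RMS deviation below the raw noise RMS
  set.seed(11)
  x <- seq(0, 100, length.out = 100)
  noise <- rnorm(100, 0, 1)
  nf <- structure(cbind(x = x, y = 5 + noise, z = 0), abscissa = "x",
                  class = c("path_fragment", "matrix", "array"))
  smn <- smooth_fragment(nf, frac = 0.3)
  expect_lt(sqrt(mean((smn[, "y"] - 5)^2)), sqrt(mean(noise^2)))

  # frac = 1 keeps a linear fragment linear
  lin <- structure(cbind(x = x, y = 3 * x - 7, z = 0), abscissa = "x",
                   class = c("path_fragment", "matrix", "array"))
  sml <- smooth_fragment(lin, frac = 1)
  expect_lt(max(abs(sml[, "y"] - lin[, "y"])), 1e-6)

  # degenerate fragment (no abscissa spread) falls back to identity + warning
  deg <- structure(cbind(x = rep(1, 5), y = 1:5, z = 0), abscissa = "x",
                   class = c("path_fragment", "matrix", "array"))
  expect_warning(out <- smooth_fragment(deg), "degenerate")
  expect_equal(unclass(out), unclass(deg), ignore_attr = TRUE)
})

test_that("assembly measures L, D and S with the closed forms", {
  straight <- list(cbind(x = seq(0, 10), y = 0, z = 0))
  res <- assemble_and_measure(straight)
  expect_equal(res$sinuosity_pct, 100)

  # dense semicircular path: S = 100 * pi / 2
  th <- seq(0, pi, length.out = 2000)
  semi <- list(cbind(x = 20 * (1 - cos(th)), y = 20 * sin(th), z = 0))
  expect_equal(assemble_and_measure(semi)$sinuosity_pct, 157.08, tolerance = 1e-4)

  # closed loop: degenerate chord
  loop <- list(cbind(x = c(0, 1, 1, 0, 0), y = c(0, 0, 1, 1, 0), z = 0))
  expect_error(assemble_and_measure(loop), "degenerate")
})

test_that("sinuosity is invariant under rigid motion and uniform scaling", {
  set.seed(21)
  pts <- cbind(x = seq(0, 60, by = 1.2),
               y = 6 * sin(seq(0, 60, by = 1.2) / 8), z = 0)
  measure <- function(p) {
    colnames(p) <- c("x", "y", "z")
    frs <- split_by_direction(p, 45, "auto")
    assemble_and_measure(lapply(frs, smooth_fragment, frac = 0.1,
                                abscissa = "auto"))$sinuosity_pct
  }
  s0 <- measure(pts)
  # random rotation (QR of a random matrix) + translation + scaling
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  moved <- sweep(pts %*% t(q) * 2.5, 2, c(100, -40, 7), "+")
  expect_equal(measure(moved), s0, tolerance = 0.01)
  expect_gte(s0, 100)
})

test_that("diameters report the shortest caliper width along the path", {
  stk <- small_straight_tube(length = 30, radius = 3)
  cogs <- collect_cogs(stk)
  path <- order_path(cogs$points, 1L, sa_params(seed = 1L))
  prof <- measure_diameters(cogs$contours, path, stk$voxel_size, spacing = 5)
  expect_true(all(abs(prof$diameter_um - 6) <= 1))

  # spacing longer than the path: a single station at the base
  prof1 <- measure_diameters(cogs$contours, path, stk$voxel_size, spacing = 500)
  expect_equal(nrow(prof1), 1)
  expect_equal(prof1$position_um, 0)
})

test_that("minimum caliper width of an ellipse is its minor axis", {
  th <- seq(0, 2 * pi, length.out = 720)
  ellipse <- cbind(15 * cos(th), 10 * sin(th))
  expect_equal(rhizotrace:::min_caliper_width(ellipse), 20, tolerance = 0.01)
})
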
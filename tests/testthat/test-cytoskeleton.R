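make_test_stack <- function(slices, voxel_size = c(0.2, 0.2, 0.395)) {
  voxels <- array(0, dim = c(dim(slices[[1]]), length(slices)))
  for (k in seq_along(slices)) voxels[, , k] <- slices[[k]]
  image_stack(voxels, voxel_size = voxel_size)
}

test_that("cortical projection is the per-pixel maximum of the selected slices", {
  s <- matrix(runif(100), 10, 10)
  stk <- make_test_stack(list(s, s, s, s))
  expect_equal(unclass(project_cortical(stk, 4)), s, ignore_attr = TRUE)

  # bright pixels in different slices all appear in the projection
  sl <- replicate(4, matrix(0, 8, 8), simplify = FALSE)
  sl[[1]][2, 2] <- 7; sl[[2]][5, 5] <- 9; sl[[3]][8, 1] <- 3
  proj <- project_cortical(make_test_stack(sl), 4)
  expect_equal(proj[2, 2], 7)
  expect_equal(proj[5, 5], 9)
  expect_equal(proj[8, 1], 3)

  # projection dominates every slice pointwise and is idempotent
  set.seed(2)
  sl2 <- replicate(5, matrix(runif(64), 8, 8), simplify = FALSE)
  stk2 <- make_test_stack(sl2)
  p2 <- project_cortical(stk2, 4)
  for (k in 1:4) expect_true(all(p2 >= sl2[[k]]))
  again <- project_cortical(make_test_stack(list(unclass(p2))), 1)
  expect_equal(unclass(again), unclass(p2), ignore_attr = TRUE)

  expect_error(project_cortical(make_test_stack(sl2), 9), "fewer")
})

test_that("microtubule pixel extraction recovers the generator's filament mask", {
  tex <- make_filament_texture(filament_texture_spec(48, 4, orientation_sd = 30,
                                                     noise_sd = 0, seed = 2L))
  mt <- mt_pixel_mask(tex$image)
  jac <- sum(mt$mask & tex$mask) / sum(mt$mask | tex$mask)
  expect_gte(jac, 0.95)

  expect_error(mt_pixel_mask(matrix(0, 16, 16)), "no signal")
  full <- mt_pixel_mask(matrix(7, 16, 16))
  expect_true(all(full$mask))
})

test_that("bundling skewness matches the moment oracle and its invariances", {
  # direct moment computation: 90 pixels at 100, 10 at 1000 -> g1 = 8/3
  v <- c(rep(100, 90), rep(1000, 10))
  m <- mean(v); m2 <- mean((v - m)^2); m3 <- mean((v - m)^3)
  expect_equal(m3 / m2^1.5, 8 / 3, tolerance = 1e-12)  # oracle self-check
  expect_equal(bundling_skewness(v), 8 / 3, tolerance = 1e-12)

  # symmetric bimodal intensities have zero skewness
  expect_equal(bundling_skewness(c(rep(100, 10), rep(200, 10))), 0)

  # invariant under positive affine transforms
  set.seed(4)
  w <- rgamma(400, shape = 2)
  expect_equal(bundling_skewness(3.7 * w + 11), bundling_skewness(w),
               tolerance = 1e-9)

  expect_error(bundling_skewness(rep(5, 10)), "variance")
  expect_error(bundling_skewness(c(1, 2)), "three")
})

test_that("parallelness is 1 for one orientation and 0 for balanced perpendicular mass", {
  m <- matrix(FALSE, 40, 60)
  m[c(10, 20, 30), 5:55] <- TRUE  # three horizontal lines
  a <- skeleton_parallelness(m)
  expect_equal(a$parallelness, 1, tolerance = 1e-12)
  expect_true(all(abs(a$angles - 0) < 1e-9))

  # equal mass at 0 and 90 degrees
  m2 <- matrix(FALSE, 64, 64)
  m2[32, 5:60] <- TRUE
  m2[5:60, 45] <- TRUE
  a2 <- skeleton_parallelness(m2)
  expect_equal(a2$parallelness, 0, tolerance = 1e-9)

  expect_error(skeleton_parallelness(matrix(FALSE, 10, 10)), "skeleton")
})

test_that("parallelness is rotation-invariant within discretization tolerance", {
  tex <- make_filament_texture(filament_texture_spec(16, 1, orientation_sd = 15,
                                                     seed = 8L))
  p0 <- skeleton_parallelness(tex$mask)$parallelness
  # 90 degree rotation of the image is exact on the pixel grid
  p90 <- skeleton_parallelness(t(tex$mask)[ncol(tex$mask):1, ])$parallelness
  expect_lt(abs(p0 - p90), 0.05)
})

test_that("tighter orientation spread yields higher parallelness", {
  p10 <- skeleton_parallelness(make_filament_texture(
    filament_texture_spec(24, 1, orientation_sd = 10, seed = 5L))$mask)$parallelness
  p40 <- skeleton_parallelness(make_filament_texture(
    filament_texture_spec(24, 1, orientation_sd = 40, seed = 5L))$mask)$parallelness
  expect_gt(p10, p40)
})

test_that("profile ratios reproduce constructed channel relations", {
  flat <- matrix(50, 80, 100)
  pr <- profile_ratio(flat, flat, apex = c(5, 40), direction = c(1, 0),
                      length_um = 35, step_um = 5, pixel_size = 0.5)
  expect_true(all(pr$ratio == 1))
  expect_equal(pr$position_um, seq(0, 35, by = 5))

  pr2 <- profile_ratio(2 * flat, flat, apex = c(5, 40), direction = c(1, 0),
                       length_um = 35, step_um = 5, pixel_size = 0.5)
  expect_true(all(pr2$ratio == 2))

  # linear apex-to-base gradient over a flat reference: monotone ratio
  grad <- matrix(rep(seq(100, 30, length.out = 100), each = 80), 80, 100)
  pr3 <- profile_ratio(grad, flat, apex = c(5, 40), direction = c(1, 0),
                       length_um = 35, step_um = 5, pixel_size = 0.5)
  expect_true(all(diff(pr3$ratio) < 0))
  expected <- approx(seq(0, 99 * 0.5, by = 0.5),
                     seq(100, 30, length.out = 100), xout = 2.5 + pr3$position_um)$y / 50
  expect_equal(pr3$ratio, expected, tolerance = 1e-6)

  # zero-denominator stations are reported as missing
  zeros <- matrix(0, 80, 100)
  pr4 <- profile_ratio(flat, zeros, apex = c(5, 40), direction = c(1, 0),
                       length_um = 10, step_um = 5, pixel_size = 0.5)
  expect_true(all(is.na(pr4$ratio)))

  expect_error(profile_ratio(flat, flat, apex = c(95, 40), direction = c(1, 0),
                             length_um = 35, pixel_size = 0.5), "domain")
})
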
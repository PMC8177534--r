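test_that("thresholding handles flat, fixed-value and bimodal slices", {
  zero <- matrix(0, 20, 20)
  expect_false(any(threshold_slice(zero, 10)))
  expect_false(any(threshold_slice(zero, "otsu")))

  # fixed threshold uses >= so a disc exactly at the threshold is included
  img <- matrix(10, 40, 40)
  img[15:25, 15:25] <- 200
  expect_equal(sum(threshold_slice(img, 200)), 121)

  # bimodal disc: auto threshold recovers the disc to Jaccard >= 0.98
  truth <- matrix(FALSE, 64, 64)
  xy <- expand.grid(r = 1:64, c = 1:64)
  truth[as.matrix(xy[ (xy$r - 32)^2 + (xy$c - 32)^2 <= 12^2, ])] <- TRUE
  noisy <- matrix(10, 64, 64)
  noisy[truth] <- 200
  set.seed(1)
  noisy <- noisy + matrix(rnorm(64 * 64, 0, 5), 64, 64)
  mask <- threshold_slice(noisy, "otsu")
  jac <- sum(mask & truth) / sum(mask | truth)
  expect_gte(jac, 0.98)
})

test_that("contours report component area and unweighted pixel centre of gravity", {
  m <- matrix(FALSE, 30, 30)
  m[6:15, 6:15] <- TRUE  # 10x10 square at 0-based offset (5,5)
  cts <- extract_contours(m)
  expect_length(cts, 1)
  expect_equal(cts[[1]]$area, 100)
  expect_equal(unname(cts[[1]]$cog), c(9.5, 9.5))

  m2 <- matrix(FALSE, 40, 40)
  m2[5:10, 5:10] <- TRUE
  m2[25:32, 25:32] <- TRUE
  expect_length(extract_contours(m2), 2)

  expect_length(extract_contours(matrix(FALSE, 10, 10)), 0)
})

test_that("centre of gravity of a centrally symmetric component is its centre", {
  m <- matrix(FALSE, 41, 41)
  xy <- expand.grid(r = 1:41, c = 1:41)
  m[as.matrix(xy[(xy$r - 21)^2 + (xy$c - 21)^2 <= 8^2, ])] <- TRUE
  ct <- extract_contours(m)[[1]]
  expect_equal(unname(ct$cog), c(20, 20))
})

test_that("the noise filter keeps exactly contours larger than the area fraction", {
  fake <- function(area) structure(list(z_index = 0L, polygon = NULL, area = area,
                                        cog = c(x = 0, y = 0)), class = "slice_contour")
  image_area <- 512 * 512
  small <- fake(2000)   # ~0.76% of a 512x512 image: dropped
  large <- fake(3000)   # ~1.14%: kept
  kept <- filter_noise(list(small, large), image_area)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$area, 3000)

  # min_fraction = 0 is the identity
  expect_length(filter_noise(list(small, large), image_area, min_fraction = 0), 2)

  # idempotent, and monotone in min_fraction
  cts <- lapply(c(500, 2000, 3000, 9000), fake)
  once <- filter_noise(cts, image_area)
  expect_identical(filter_noise(once, image_area), once)
  for (f in c(0, 0.005, 0.01, 0.02)) {
    a <- filter_noise(cts, image_area, min_fraction = f)
    b <- filter_noise(cts, image_area, min_fraction = f * 2 + 0.001)
    expect_true(all(vapply(b, function(x) x$area, numeric(1)) %in%
                      vapply(a, function(x) x$area, numeric(1))))
  }
})

test_that("collect_cogs produces collinear micrometre points for a straight tube", {
  stk <- small_straight_tube(length = 30, radius = 3)
  cogs <- collect_cogs(stk)
  expect_gte(nrow(cogs$points), 2)
  expect_lte(diff(range(cogs$points[, "x"])), stk$voxel_size[1])
  expect_lte(diff(range(cogs$points[, "y"])), stk$voxel_size[2])
  expect_equal(cogs$points[, "z"], cogs$table$z_index * stk$voxel_size[3])
})

test_that("an empty stack is an insufficient-signal error", {
  stk <- image_stack(array(0, dim = c(16, 16, 4)), voxel_size = c(1, 1, 1))
  expect_error(collect_cogs(stk), "insufficient signal")
})

test_that("a noisy tube still yields exactly one kept contour on nearly every slice", {
  sp <- tube_render_spec(centerline_spec("straight", length = 40), radius = 3,
                         voxel_size = c(0.5, 0.5, 1), wall_intensity = 200,
                         background_intensity = 10, noise_sd = 20, seed = 9L)
  stk <- render_tube_stack(sp)
  cogs <- collect_cogs(stk)
  per_slice <- table(cogs$table$z_index)
  frac_single <- sum(per_slice == 1) / dim(stk)[3]
  expect_gte(frac_single, 0.95)
})
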
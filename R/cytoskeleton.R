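# Microtubule phenotype quantification: cortical maximum-intensity
# projection, microtubule pixel extraction, bundling skewness, skeleton
# parallelness, and the two-channel longitudinal intensity-ratio profile.

#' Maximum-intensity projection of the cortical-most optical slices
#'
#' Projects the first `n_slices` slices of the stack (the cortical side; pass
#' `from = "last"` if the cortex is at the far end) by per-pixel maximum. The
#' operation is idempotent on its own output.
#'
#' @param stack an [image_stack()].
#' @param n_slices number of cortical slices to project (default 4).
#' @param from `"first"` or `"last"`: which end of the stack is cortical.
#' @return A matrix of class `cortical_projection` with attribute
#'   `pixel_size` (micrometres, `(vx, vy)`).
#' @export
project_cortical <- function(stack, n_slices = 4, from = c("first", "last")) {
  from <- match.arg(from)
  assert_that(inherits(stack, "image_stack"), "stack must be an image_stack")
  nz <- dim(stack$voxels)[3]
  if (n_slices > nz) {
    stop_config(sprintf("stack has %d slice(s), fewer than the %d requested", nz, n_slices))
  }
  ks <- if (from == "first") seq_len(n_slices) else seq(nz - n_slices + 1L, nz)
  proj <- get_slice(stack, ks[1])
  for (k in ks[-1]) proj <- pmax(proj, get_slice(stack, k))
  structure(proj, pixel_size = stack$voxel_size[1:2],
            class = c("cortical_projection", "matrix", "array"))
}

#' Extract microtubule pixels from a projection
#'
#' Rolling-median background subtraction followed by Otsu thresholding of the
#' residual image. Returns the binary microtubule mask together with the
#' original intensities of the masked pixels, the input of the bundling and
#' parallelness metrics. A flat positive image (no contrast, pure signal)
#' yields a full-domain mask; an image with no pixel above threshold raises a
#' "no signal" error.
#'
#' @param projection 2D intensity matrix (e.g. a [project_cortical()] output).
#' @param background_radius radius of the rolling-median background filter,
#'   pixels.
#' @return An object of class `mt_pixel_set`: list with `mask` (logical
#'   matrix) and `intensities` (original intensities of masked pixels).
#' @export
mt_pixel_mask <- function(projection, background_radius = 15) {
  img <- unclass(as.matrix(projection))
  assert_that(length(img) > 0, "projection must be non-empty")
  rng <- range(img)
  if (diff(rng) == 0) {
    if (rng[1] > 0) {
      mask <- matrix(TRUE, nrow(img), ncol(img))
      return(structure(list(mask = mask, intensities = img[mask]),
                       class = "mt_pixel_set"))
    }
    stop_config("no signal: projection contains no microtubule pixels")
  }
  norm <- (img - rng[1]) / diff(rng)
  bg <- EBImage::medianFilter(norm, size = as.integer(background_radius))
  resid <- pmax(norm - bg, 0)
  if (max(resid) == 0) stop_config("no signal: projection contains no microtubule pixels")
  th <- EBImage::otsu(resid, range = c(0, max(resid)), levels = 256L)
  mask <- resid > th
  if (!any(mask)) stop_config("no signal: projection contains no microtubule pixels")
  structure(list(mask = mask, intensities = img[mask]), class = "mt_pixel_set")
}

#' Bundling skewness of microtubule pixel intensities
#'
#' Sample skewness \eqn{g_1 = m_3 / m_2^{3/2}} (third standardized moment) of
#' the fluorescence intensity distribution over microtubule pixels. Bundled
#' filaments stack fluorophores in shared pixels and produce a bright-tailed,
#' right-skewed distribution, so higher skewness indicates more bundling;
#' unbundled arrays give lower values. The statistic is invariant under
#' positive affine intensity transforms a*I + c (a > 0).
#'
#' @param mt an `mt_pixel_set`, or a numeric vector of pixel intensities.
#' @return The skewness (a single number).
#' @examples
#' bundling_skewness(c(rep(100, 90), rep(1000, 10)))  # 2.667: bright tail
#' @export
bundling_skewness <- function(mt) {
  v <- if (inherits(mt, "mt_pixel_set")) mt$intensities else as.numeric(mt)
  assert_that(length(v) >= 3, "need at least three microtubule pixels")
  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 == 0) stop_config("skewness undefined: zero intensity variance")
  mean((v - m)^3) / m2^1.5
}

#' Parallelness of the skeletonized microtubule array
#'
#' Skeletonizes the microtubule mask (Zhang-Suen thinning), removes branch
#' points, decomposes the skeleton into line segments of at least
#' `min_length` pixels, and measures each segment's axial orientation in
#' [0, 180) degrees by principal component analysis of its pixel coordinates.
#' The parallelness score is the circular order parameter on doubled angles
#' (the mean resultant length \eqn{|mean(e^{2 i \theta})|}, weighted by
#' segment length): 1 when all segments share one orientation, 0 for equal
#' mass at perpendicular orientations.
#'
#' @param mt an `mt_pixel_set`, or a logical mask matrix.
#' @param min_length minimum segment size in pixels.
#' @return An object of class `angle_sample`: list with `angles` (degrees in
#'   [0, 180)), `lengths` (segment pixel counts) and `parallelness`.
#' @export
skeleton_parallelness <- function(mt, min_length = 5) {
  mask <- if (inherits(mt, "mt_pixel_set")) mt$mask else as.matrix(mt) > 0
  skel <- thin_mask(mask)
  # branch points by crossing number: >= 3 background-to-foreground
  # transitions around the pixel (robust on diagonal staircases, where the
  # raw 8-neighbour count exceeds 2 on ordinary line pixels)
  segments <- skel & neighbor_transitions(skel) < 3
  storage.mode(segments) <- "double"
  if (!any(segments > 0)) stop_config("no skeleton segments found")
  labels <- EBImage::bwlabel(segments)
  idx <- which(labels > 0)
  lab <- labels[idx]
  rows <- ((idx - 1L) %% nrow(mask)) + 1L
  cols <- ((idx - 1L) %/% nrow(mask)) + 1L
  angles <- c(); lengths <- c()
  for (l in seq_len(max(lab))) {
    sel <- lab == l
    if (sum(sel) < min_length) next
    xy <- cbind(cols[sel], rows[sel])
    ctr <- sweep(xy, 2, colMeans(xy))
    ev <- eigen(crossprod(ctr), symmetric = TRUE)$vectors[, 1]
    ang <- atan2(ev[2], ev[1]) * 180 / pi
    angles <- c(angles, ang %% 180)
    lengths <- c(lengths, sum(sel))
  }
  if (!length(angles)) stop_config("no skeleton segments of sufficient length")
  r2 <- complex(modulus = lengths, argument = 2 * angles * pi / 180)
  structure(list(angles = angles, lengths = lengths,
                 parallelness = Mod(sum(r2)) / sum(lengths)),
            class = "angle_sample")
}

# Crossing number: 0->1 transitions in the circular 8-neighbour sequence.
neighbor_transitions <- function(mask) {
  p <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  p[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.logical(mask)
  ri <- 2:(nrow(mask) + 1L); ci <- 2:(ncol(mask) + 1L)
  nb <- list(p[ri - 1L, ci], p[ri - 1L, ci + 1L], p[ri, ci + 1L],
             p[ri + 1L, ci + 1L], p[ri + 1L, ci], p[ri + 1L, ci - 1L],
             p[ri, ci - 1L], p[ri - 1L, ci - 1L])
  a <- matrix(0L, nrow(mask), ncol(mask))
  for (j in 1:8) {
    nxt <- if (j == 8L) 1L else j + 1L
    a <- a + (!nb[[j]] & nb[[nxt]])
  }
  a
}

# 8-neighbour count of each TRUE pixel.
neighbor_count <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.integer(mask)
  n <- matrix(0L, nrow(mask), ncol(mask))
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    n <- n + m[(2:(nrow(mask) + 1L)) + di, (2:(ncol(mask) + 1L)) + dj]
  }
  n
}

#' Morphological skeleton by Zhang-Suen thinning
#'
#' Iteratively peels boundary pixels in the standard two-subiteration scheme
#' until the mask is one pixel wide everywhere, preserving connectivity.
#'
#' @param mask logical matrix.
#' @return Logical matrix of the skeleton.
#' @export
thin_mask <- function(mask) {
  p <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  p[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.logical(mask)
  ri <- 2:(nrow(mask) + 1L); ci <- 2:(ncol(mask) + 1L)
  shift <- function(m, di, dj) m[ri + di, ci + dj]
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # neighbours clockwise from north: p2 p3 p4 p5 p6 p7 p8 p9
      p2 <- shift(p, -1, 0); p3 <- shift(p, -1, 1); p4 <- shift(p, 0, 1)
      p5 <- shift(p, 1, 1); p6 <- shift(p, 1, 0); p7 <- shift(p, 1, -1)
      p8 <- shift(p, 0, -1); p9 <- shift(p, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- cbind(c(p2), c(p3), c(p4), c(p5), c(p6), c(p7), c(p8), c(p9), c(p2))
      a <- matrix(rowSums(!seqs[, 1:8, drop = FALSE] & seqs[, 2:9, drop = FALSE]),
                  nrow(mask), ncol(mask))
      cond <- p[ri, ci] & b >= 2 & b <= 6 & a == 1
      if (sub == 1) {
        cond <- cond & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- cond & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        changed <- TRUE
        q <- p[ri, ci]
        q[cond] <- FALSE
        p[ri, ci] <- q
      }
    }
    if (!changed) break
  }
  p[ri, ci]
}

#' Two-channel intensity-ratio profile along a longitudinal line
#'
#' Samples both channels along a line of `length_um` micrometres starting at
#' the apex point and running in `direction`, averaging over a short
#' transverse window at each station, and reports the per-station ratio of
#' the channel means (A / B). Stations where the channel-B mean is zero have
#' an undefined ratio, reported as `NA`.
#'
#' @param channel_a,channel_b 2D intensity matrices, geometrically aligned.
#' @param apex apex point `(x, y)` in pixels (0-based).
#' @param direction direction of the line into the cell: an `(dx, dy)` vector
#'   or an angle in degrees.
#' @param length_um profile length in micrometres (default 35).
#' @param step_um station spacing in micrometres.
#' @param width_px transverse averaging window in pixels (odd; default 3).
#' @param pixel_size pixel size in micrometres.
#' @return A data frame with `position_um`, `mean_a`, `mean_b`, `ratio`.
#' @export
profile_ratio <- function(channel_a, channel_b, apex, direction,
                          length_um = 35, step_um = 0.5, width_px = 3,
                          pixel_size = 0.2) {
  a <- as.matrix(channel_a); b <- as.matrix(channel_b)
  assert_that(all(dim(a) == dim(b)), "channels must have identical dimensions")
  if (length(direction) == 1) {
    direction <- c(cos(direction * pi / 180), sin(direction * pi / 180))
  }
  u <- direction / sqrt(sum(direction^2))
  perp <- c(-u[2], u[1])
  stations <- seq(0, length_um, by = step_um)
  offs <- (seq_len(width_px) - (width_px + 1) / 2)  # in pixels
  mean_a <- mean_b <- numeric(length(stations))
  for (i in seq_along(stations)) {
    ctr <- apex + stations[i] / pixel_size * u
    pts <- t(vapply(offs, function(o) ctr + o * perp, numeric(2)))
    va <- bilinear_sample(a, pts)
    vb <- bilinear_sample(b, pts)
    if (anyNA(va) || anyNA(vb)) {
      stop_config("profile line leaves the image domain")
    }
    mean_a[i] <- mean(va); mean_b[i] <- mean(vb)
  }
  ratio <- ifelse(mean_b > 0, mean_a / mean_b, NA_real_)
  data.frame(position_um = stations, mean_a = mean_a, mean_b = mean_b,
             ratio = ratio)
}

# Bilinear interpolation at 0-based (x, y) pixel coordinates.
bilinear_sample <- function(img, pts) {
  x <- pts[, 1]; y <- pts[, 2]
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x0 >= 0 & y0 >= 0 & x0 <= ncol(img) - 2 + (fx == 0) & y0 <= nrow(img) - 2 + (fy == 0)
  out <- rep(NA_real_, length(x))
  for (i in which(ok)) {
    j <- x0[i] + 1L; r <- y0[i] + 1L
    j2 <- min(j + 1L, ncol(img)); r2 <- min(r + 1L, nrow(img))
    out[i] <- (1 - fx[i]) * (1 - fy[i]) * img[r, j] +
      fx[i] * (1 - fy[i]) * img[r, j2] +
      (1 - fx[i]) * fy[i] * img[r2, j] +
      fx[i] * fy[i] * img[r2, j2]
  }
  out
}
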
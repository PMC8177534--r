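# Stage 1 of the sinuosity pipeline: per-slice thresholding, contour
# extraction, noise filtering and centre-of-gravity computation.

#' Threshold one optical slice
#'
#' Produces a binary mask with `TRUE` where intensity is at or above the
#' threshold. The threshold is either a fixed value or selected per slice by
#' Otsu's method, which suits the bimodal background/cell fluorescence of
#' stained tubular cells. A slice with no intensity range (e.g. all zero)
#' yields an empty mask rather than an error.
#'
#' @param slice_image 2D numeric matrix of intensities.
#' @param method `"otsu"` or a single numeric threshold value.
#' @return Logical matrix of the same dimensions.
#' @export
threshold_slice <- function(slice_image, method = "otsu") {
  assert_that(is.matrix(slice_image) && length(slice_image) > 0,
              "slice_image must be a non-empty 2D matrix")
  if (is.numeric(method)) {
    return(slice_image >= method)
  }
  assert_that(identical(method, "otsu"), "method must be 'otsu' or a numeric value")
  rng <- range(slice_image)
  if (diff(rng) == 0) {
    return(matrix(FALSE, nrow(slice_image), ncol(slice_image)))
  }
  norm <- (slice_image - rng[1]) / diff(rng)
  th <- EBImage::otsu(norm, range = c(0, 1), levels = 256L)
  slice_image >= th * diff(rng) + rng[1]
}

#' Extract connected-component contours from a binary mask
#'
#' One contour per connected foreground component. The area is the component
#' pixel count and the centre of gravity (CoG) the unweighted mean of the
#' component's pixel coordinates (contour plus inner pixels), reported 0-based
#' with `x` along columns and `y` along rows. The oriented boundary polygon is
#' attached for caliper-width measurements.
#'
#' @param mask logical (or 0/1) 2D matrix.
#' @param z_index optional slice index stored on each contour.
#' @return A list of `slice_contour` objects (fields `z_index`, `polygon`,
#'   `area`, `cog`); empty list for an empty mask.
#' @export
extract_contours <- function(mask, z_index = NA_integer_) {
  assert_that(is.matrix(mask), "mask must be a 2D matrix")
  storage.mode(mask) <- "double"
  if (!any(mask > 0)) return(list())
  labels <- EBImage::bwlabel(mask)
  polys <- EBImage::ocontour(labels)
  idx <- which(labels > 0)
  lab <- labels[idx]
  rows <- ((idx - 1L) %% nrow(mask)) + 1L
  cols <- ((idx - 1L) %/% nrow(mask)) + 1L
  out <- vector("list", max(lab))
  for (l in seq_len(max(lab))) {
    sel <- lab == l
    # ocontour coordinates are 0-based (dim1, dim2) = (row, col)
    poly <- polys[[l]][, c(2, 1), drop = FALSE]
    colnames(poly) <- c("x", "y")
    out[[l]] <- structure(list(z_index = z_index,
                               polygon = poly,
                               area = sum(sel),
                               cog = c(x = mean(cols[sel]) - 1,
                                       y = mean(rows[sel]) - 1)),
                          class = "slice_contour")
  }
  out
}

#' Drop contours smaller than a fraction of the image area
#'
#' Keeps exactly the contours whose pixel area is strictly larger than
#' `min_fraction` of the total image area -- the noise-removal rule of the
#' sinuosity pipeline (contours larger than 1\% of the image are retained).
#' The filter is idempotent and monotone in `min_fraction`.
#'
#' @param contours list of `slice_contour` objects.
#' @param image_area total image area in pixels (> 0).
#' @param min_fraction area fraction below which contours are dropped.
#' @return The kept contours, in input order.
#' @export
filter_noise <- function(contours, image_area, min_fraction = 0.01) {
  assert_that(image_area > 0, "image_area must be > 0")
  assert_that(min_fraction >= 0, "min_fraction must be >= 0")
  Filter(function(ct) ct$area > min_fraction * image_area, contours)
}

#' Collect per-slice centres of gravity as 3D points
#'
#' Runs threshold, contour extraction and the noise filter on every slice and
#' converts each surviving contour's CoG into physical micrometres:
#' `(cog_x * vx, cog_y * vy, z_index * vz)` with 0-based slice indices.
#' Slices holding several surviving contours contribute one point each; path
#' ordering downstream resolves their membership.
#'
#' @param stack an [image_stack()].
#' @param threshold `"otsu"` or a fixed numeric threshold, passed to
#'   [threshold_slice()].
#' @param min_fraction noise-filter fraction, passed to [filter_noise()].
#' @return A list with `points` (n x 3 matrix of micrometre coordinates,
#'   columns x, y, z), `table` (data frame: z_index, area_px, cog columns) and
#'   `contours` (the kept `slice_contour` objects). Errors with
#'   "insufficient signal" when fewer than two points survive.
#' @export
collect_cogs <- function(stack, threshold = "otsu", min_fraction = 0.01) {
  assert_that(inherits(stack, "image_stack"), "stack must be an image_stack")
  vx <- stack$voxel_size[1]; vy <- stack$voxel_size[2]; vz <- stack$voxel_size[3]
  kept <- list()
  for (k in seq_len(n_slices(stack))) {
    img <- get_slice(stack, k)
    mask <- threshold_slice(img, threshold)
    cts <- extract_contours(mask, z_index = k - 1L)
    kept <- c(kept, filter_noise(cts, image_area = length(img), min_fraction = min_fraction))
  }
  if (length(kept) < 2L) {
    stop_config("insufficient signal: fewer than two contours survive segmentation")
  }
  tab <- data.frame(
    z_index = vapply(kept, function(ct) ct$z_index, integer(1)),
    area_px = vapply(kept, function(ct) ct$area, numeric(1)),
    cog_x_px = vapply(kept, function(ct) ct$cog[["x"]], numeric(1)),
    cog_y_px = vapply(kept, function(ct) ct$cog[["y"]], numeric(1))
  )
  tab$x_um <- tab$cog_x_px * vx
  tab$y_um <- tab$cog_y_px * vy
  tab$z_um <- tab$z_index * vz
  points <- cbind(x = tab$x_um, y = tab$y_um, z = tab$z_um)
  list(points = points, table = tab, contours = kept)
}
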
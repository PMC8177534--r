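#' Construct an image stack
#'
#' Container for a 3D grayscale voxel grid with physical voxel sizes. Voxels
#' are stored as an array with dimensions `(y, x, z)`: `voxels[, , k]` is the
#' k-th optical slice as an image matrix (rows = y, columns = x). Indexing is
#' 0-based in physical terms: the pixel at array position `(i, j)` of slice
#' `k` has physical coordinates `((j - 1) * vx, (i - 1) * vy, (k - 1) * vz)`
#' micrometres.
#'
#' @param voxels 3D numeric array `(y, x, z)` of non-negative intensities.
#'   A single matrix is promoted to a one-slice stack.
#' @param voxel_size numeric length-3 vector `(vx, vy, vz)` in micrometres.
#' @param metadata optional list of provenance/ground-truth metadata.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, voxel_size = c(0.4, 0.4, 0.4), metadata = list()) {
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(dim(voxels), 1L))
  assert_that(is.array(voxels) && length(dim(voxels)) == 3,
              "voxels must be a 3D array (y, x, z)")
  assert_that(all(dim(voxels) >= 1), "all stack dimensions must be >= 1")
  assert_that(length(voxel_size) == 3 && all(voxel_size > 0),
              "voxel_size must be three positive values (vx, vy, vz)")
  assert_that(all(voxels >= 0), "intensities must be non-negative")
  structure(list(voxels = voxels,
                 voxel_size = as.numeric(voxel_size),
                 metadata = metadata),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack: %d x %d x %d (x,y,z) voxels at %.3g x %.3g x %.3g um>\n",
              d[2], d[1], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  if (!is.null(x$metadata$truth_sinuosity)) {
    cat(sprintf("  ground-truth sinuosity: %.2f%%\n", x$metadata$truth_sinuosity))
  }
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

n_slices <- function(stack) dim(stack$voxels)[3]

get_slice <- function(stack, k) stack$voxels[, , k]

#' Write an image stack as a multi-page TIFF with a ground-truth sidecar
#'
#' Intensities are stored as 16-bit grayscale; the scale factor used to map
#' arbitrary units into the 16-bit range is recorded in the YAML sidecar
#' together with the voxel sizes and any ground-truth metadata, so
#' [read_image_stack()] restores the original values.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path; the sidecar is written at `<path>.yml`.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  assert_that(inherits(stack, "image_stack"), "stack must be an image_stack")
  mx <- max(stack$voxels)
  scale <- if (mx > 0) 65535 / mx else 1
  pages <- lapply(seq_len(n_slices(stack)), function(k) {
    round(get_slice(stack, k) * scale) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  sidecar <- c(list(voxel_size = as.numeric(stack$voxel_size),
                    intensity_scale = scale),
               stack$metadata)
  yaml::write_yaml(sidecar, paste0(path, ".yml"))
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param path TIFF path. If the `<path>.yml` sidecar exists, voxel sizes,
#'   intensity scale and metadata are restored from it.
#' @param voxel_size fallback voxel sizes when no sidecar is present.
#' @return An [image_stack()].
#' @export
read_image_stack <- function(path, voxel_size = c(0.4, 0.4, 0.4)) {
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  scale <- 1 / 65535
  metadata <- list()
  sidecar_path <- paste0(path, ".yml")
  if (file.exists(sidecar_path)) {
    sidecar <- yaml::read_yaml(sidecar_path)
    voxel_size <- as.numeric(sidecar$voxel_size)
    scale <- 1 / sidecar$intensity_scale
    metadata <- sidecar[setdiff(names(sidecar), c("voxel_size", "intensity_scale"))]
  }
  voxels <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) voxels[, , k] <- pages[[k]] * 65535 * scale
  image_stack(voxels, voxel_size = voxel_size, metadata = metadata)
}
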
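#' Synthetic post-ablation image
#'
#' Generates a synthetic post-operative volume in which the ablated
#' region carries a bright (high intensity) margin over the background,
#' emulating the appearance of a fresh thermal lesion on T2-weighted
#' imaging: intensity = background + contrast inside the lesion, plus
#' additive Gaussian noise. The generator is deterministic under a fixed
#' seed and does not disturb the caller's RNG state.
#'
#' @param lesion_mask Logical 3D array, or a \code{lesion_mask} from
#'   [rasterize_lesion()].
#' @param voxel_size Isotropic voxel size, mm (taken from a
#'   \code{lesion_mask} input if missing).
#' @param contrast Lesion-background intensity gap (> 0).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Integer noise seed.
#' @param background Background mean intensity.
#' @return Object of class \code{postop_image}: \code{intensities}
#'   (3D array), \code{voxel_size}, \code{origin}, \code{background},
#'   \code{contrast}, \code{noise_sd}, \code{seed}.
#' @examples
#' m <- array(FALSE, c(20, 20, 20)); m[8:12, 8:12, 8:12] <- TRUE
#' img <- make_postop_image(m, voxel_size = 1, contrast = 100,
#'                          noise_sd = 5, seed = 1)
#' measure_volume(img, threshold = 150)
#' @export
make_postop_image <- function(lesion_mask, voxel_size = NULL,
                              contrast = 100, noise_sd = 0, seed = 1,
                              background = 100) {
  origin <- c(0, 0, 0)
  if (inherits(lesion_mask, "lesion_mask")) {
    if (is.null(voxel_size)) voxel_size <- lesion_mask$voxel_size
    origin <- lesion_mask$origin
    lesion_mask <- lesion_mask$mask
  }
  if (is.null(voxel_size) || !(voxel_size > 0))
    stop("parameter error: voxel_size must be > 0")
  if (!(contrast > 0)) stop("parameter error: contrast must be > 0")
  if (noise_sd < 0) stop("parameter error: noise_sd must be >= 0")
  stopifnot(is.logical(lesion_mask) || all(lesion_mask %in% c(0, 1)))
  img <- background + contrast * as.numeric(lesion_mask)
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else if (exists(".Random.seed", globalenv()))
              rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    img <- img + stats::rnorm(length(img), 0, noise_sd)
  }
  structure(list(intensities = array(img, dim = dim(lesion_mask)),
                 voxel_size = voxel_size, origin = origin,
                 background = background, contrast = contrast,
                 noise_sd = noise_sd, seed = seed),
            class = "postop_image")
}

#' @export
print.postop_image <- function(x, ...) {
  cat(sprintf(
    "<postop_image> %s voxels at %.2f mm, background %.0f, contrast %.0f, noise sd %.1f\n",
    paste(dim(x$intensities), collapse = " x "), x$voxel_size,
    x$background, x$contrast, x$noise_sd))
  invisible(x)
}

#' Measure the ablated volume on a post-ablation image
#'
#' Counts voxels at or above the intensity threshold (the high-intensity
#' lesion margin) and multiplies by the voxel volume. The natural
#' threshold is the midpoint between background and lesion mean.
#'
#' @param image A [make_postop_image()] result, or a plain array with
#'   \code{voxel_size} given.
#' @param threshold Intensity threshold; defaults to the
#'   background + contrast/2 midpoint for \code{postop_image} inputs.
#' @param voxel_size Required for plain-array input, mm.
#' @return Volume in mm^3 (0, with a warning, if no voxel reaches the
#'   threshold).
#' @export
measure_volume <- function(image, threshold = NULL, voxel_size = NULL) {
  if (inherits(image, "postop_image")) {
    if (is.null(threshold))
      threshold <- image$background + image$contrast / 2
    voxel_size <- image$voxel_size
    image <- image$intensities
  }
  if (is.null(voxel_size)) stop("voxel_size required for array input")
  if (is.null(threshold)) stop("threshold required")
  n <- sum(image >= threshold)
  if (n == 0) warning("no voxel at or above the threshold; volume is 0")
  n * voxel_size^3
}
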
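#' Gaussian smoothing with a 5x5x5 kernel
#'
#' Separable convolution with a normalized truncated Gaussian (unit sum, so
#' constant volumes and interior voxel sums are preserved). Borders use
#' replicate padding.
#'
#' @param volume numeric 3D array.
#' @param size odd kernel size per axis.
#' @param sigma Gaussian sd in voxels.
#' @return smoothed volume.
#' @export
gaussian_smooth3 <- function(volume, size = 5, sigma = 1) {
  assert_finite_volume(volume)
  stopifnot(size %% 2 == 1, sigma > 0)
  h <- (size - 1) / 2
  k <- dnorm(-h:h, sd = sigma)
  k <- k / sum(k)
  conv_axis <- function(a, axis) {
    n <- dim(a)[axis]
    out <- array(0, dim(a))
    for (s in -h:h) {
      idx <- pmin(pmax(seq_len(n) + s, 1), n)
      shifted <- switch(axis, a[idx, , , drop = FALSE],
                        a[, idx, , drop = FALSE], a[, , idx, drop = FALSE])
      out <- out + k[s + h + 1] * shifted
    }
    out
  }
  out <- conv_axis(volume, 1)
  out <- conv_axis(out, 2)
  conv_axis(out, 3)
}

#' Global binarization of a response volume
#'
#' A voxel is foreground iff its intensity is greater than or equal to the
#' threshold. The threshold and method are recorded as attributes
#' (provenance).
#'
#' @param volume numeric 3D array.
#' @param method `"otsu"` (256-bin between-class-variance maximisation),
#'   `"fixed"` or `"percentile"`.
#' @param value threshold for `"fixed"`; probability in (0, 1) for
#'   `"percentile"`.
#' @return integer 0/1 array with attributes `threshold` and `method`.
#' @export
binarize <- function(volume, method = c("otsu", "fixed", "percentile"),
                     value = NULL) {
  assert_finite_volume(volume)
  method <- match.arg(method)
  thr <- switch(method,
    otsu = otsu_threshold(volume),
    fixed = {
      if (is.null(value)) stop("`value` required for method = \"fixed\"",
                               call. = FALSE)
      value
    },
    percentile = {
      if (is.null(value) || value <= 0 || value >= 1)
        stop("`value` must be a probability for method = \"percentile\"",
             call. = FALSE)
      quantile(volume, value, names = FALSE)
    })
  out <- as.integer(volume >= thr)
  dim(out) <- dim(volume)
  attr(out, "threshold") <- thr
  attr(out, "method") <- method
  out
}

#' Label 26-connected components of a binary volume
#'
#' @param binary 0/1 (or logical) 3D array.
#' @return integer array of component labels (0 = background).
#' @export
label_components <- function(binary) {
  b <- as_mask(binary)
  .label_components_cpp(b, dim(b))
}

#' Remove small connected components
#'
#' 26-connected components with fewer than `min_volume` voxels are removed;
#' all others are untouched. Idempotent, and monotone in `min_volume`.
#'
#' @param binary 0/1 3D array.
#' @param min_volume minimum component voxel count to keep (>= 0).
#' @return filtered 0/1 array.
#' @export
filter_components <- function(binary, min_volume = 27) {
  stopifnot(min_volume >= 0)
  b <- as_mask(binary)
  if (min_volume <= 1) return(b)
  lab <- .label_components_cpp(b, dim(b))
  nlab <- max(lab)
  if (nlab == 0) return(b)
  counts <- tabulate(lab[lab > 0], nlab)
  keep <- counts >= min_volume
  out <- as.integer(lab > 0 & keep[pmax(lab, 1L)])
  dim(out) <- dim(b)
  out
}

#' Topology-preserving 3D skeletonization
#'
#' Iterative thinning to a one-voxel-wide medial representation: six
#' directional sub-iterations per cycle delete simple border voxels
#' (points whose removal changes neither object nor background topology
#' under (26, 6) connectivity) that are not curve endpoints, until stable.
#' The skeleton is a subset of the input and has the same number of
#' 26-connected components.
#'
#' @param binary 0/1 3D array.
#' @return 0/1 skeleton array.
#' @export
skeletonize3d <- function(binary) {
  b <- as_mask(binary)
  .skeletonize3d_cpp(b, dim(b))
}

#' 2D skeletonization of an en face projection
#'
#' Thinning of a binary 2D image under (8, 4) connectivity, implemented as
#' the 3D thinning of a single-slice volume.
#'
#' @param image binary matrix.
#' @return 0/1 matrix.
#' @export
skeletonize2d <- function(image) {
  stopifnot(is.matrix(image))
  v <- array(as.integer(image != 0), c(1L, nrow(image), ncol(image)))
  out <- .skeletonize3d_cpp(v, dim(v))
  matrix(out, nrow(image), ncol(image))
}

#' Response-to-vessel conversion
#'
#' The standard chain: Gaussian smoothing, global thresholding,
#' small-component removal, 3D skeletonization.
#'
#' @param volume response (or denoised intensity) volume.
#' @param method,value thresholding, see [binarize()].
#' @param min_volume component-size threshold, see [filter_components()].
#' @param smooth_size,smooth_sigma smoothing kernel, see
#'   [gaussian_smooth3()].
#' @return list with `binary`, `skeleton` and `threshold`.
#' @export
vesselize <- function(volume, method = "otsu", value = NULL,
                      min_volume = 27, smooth_size = 5, smooth_sigma = 1) {
  sm <- gaussian_smooth3(volume, smooth_size, smooth_sigma)
  bin <- binarize(sm, method, value)
  thr <- attr(bin, "threshold")
  bin <- filter_components(bin, min_volume)
  list(binary = bin, skeleton = skeletonize3d(bin), threshold = thr)
}
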
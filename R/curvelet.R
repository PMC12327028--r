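#' Construct a 3D curvelet tight frame
#'
#' Builds a multiscale, multi-directional frequency-domain decomposition of
#' a 3D volume: smooth radial annuli (dyadic in frequency) times smooth
#' angular wedges whose centres are distributed over the cube faces. The raw
#' windows are globally normalized so that the sum of squared windows equals
#' one at every frequency, which makes the frame exactly tight: the forward
#' transform conserves energy (Parseval) and the inverse reconstructs the
#' input to machine precision. Coefficient bands are stored at full volume
#' size (no decimation).
#'
#' @param dims volume shape `c(nz, nx, ny)`.
#' @param n_scales number of detail scales; default
#'   `max(1, ceiling(log2(min(dims))) - 3)`. The low-pass residual is stored
#'   as scale 0; scale 1 is the finest.
#' @param wedge_faces wedges per cube face edge and scale: an integer vector
#'   of length `n_scales` (finest first). Default: 4 at the two finest
#'   scales, 2 at coarser ones (a face grid of `n x n` wedges over the three
#'   axis-aligned faces gives `3 n^2` wedges per scale).
#' @return an object of class `curvelet_system` with fields `dims`,
#'   `n_scales`, `windows` (list of arrays), and `bands` (a tibble of band
#'   metadata: scale, wedge, and central direction `dz, dx, dy`).
#' @export
curvelet_system <- function(dims, n_scales = NULL, wedge_faces = NULL) {
  stopifnot(length(dims) == 3, all(dims >= 8))
  dims <- as.integer(dims)
  if (is.null(n_scales)) n_scales <- max(1L, ceiling(log2(min(dims))) - 3L)
  stopifnot(n_scales >= 1)
  if (is.null(wedge_faces))
    wedge_faces <- ifelse(seq_len(n_scales) <= 2, 4L, 2L)
  stopifnot(length(wedge_faces) == n_scales, all(wedge_faces >= 1))

  g <- freq_grids(dims)
  rho <- sqrt(g$fz^2 + g$fx^2 + g$fy^2)
  rho_n <- rho / 0.5
  t <- log2(pmax(rho_n, 1e-12))
  sstep <- function(u) {
    u <- pmin(pmax(u, 0), 1)
    u^2 * (3 - 2 * u)
  }
  # unit frequency directions (0 at the DC bin)
  inv <- ifelse(rho > 0, 1 / rho, 0)
  uz <- g$fz * inv; ux <- g$fx * inv; uy <- g$fy * inv

  windows <- list()
  meta <- list()
  b <- 0L
  # low-pass residual (scale 0)
  b <- b + 1L
  windows[[b]] <- 1 - sstep(t + n_scales + 1)
  meta[[b]] <- data.frame(band = b, scale = 0L, wedge = 0L,
                          dz = NA_real_, dx = NA_real_, dy = NA_real_)
  for (j in seq_len(n_scales)) {
    radial <- if (j == 1) sstep(t + 2) else
      sstep(t + j + 1) * (1 - sstep(t + j))
    centers <- wedge_centers(wedge_faces[j])
    sig <- 0.5 * (pi / 2) / wedge_faces[j]
    for (w in seq_len(nrow(centers))) {
      d <- centers[w, ]
      cosang <- pmin(abs(uz * d[1] + ux * d[2] + uy * d[3]), 1)
      ang <- acos(cosang)
      b <- b + 1L
      windows[[b]] <- radial * exp(-(ang / sig)^2)
      meta[[b]] <- data.frame(band = b, scale = j, wedge = w,
                              dz = d[1], dx = d[2], dy = d[3])
    }
  }
  # exact squared partition of unity
  s2 <- Reduce(`+`, lapply(windows, function(w) w^2))
  inv_s <- 1 / sqrt(s2)
  windows <- lapply(windows, function(w) w * inv_s)
  # Hermitian symmetrization in squared magnitude: the Nyquist planes of an
  # even grid are their own negatives, so |u.d| alone is not symmetric
  # there; averaging U(k)^2 with U(-k)^2 restores U(-k) = U(k) while
  # keeping the squared partition exact, hence real coefficients and
  # machine-precision inversion.
  ni <- lapply(dims, function(n) c(1L, n:2L))
  windows <- lapply(windows, function(w)
    sqrt((w^2 + w[ni[[1]], ni[[2]], ni[[3]]]^2) / 2))
  structure(list(dims = dims, n_scales = as.integer(n_scales),
                 wedge_faces = as.integer(wedge_faces),
                 windows = windows,
                 bands = tibble::as_tibble(do.call(rbind, meta))),
            class = "curvelet_system")
}

# wedge centre directions: n x n grid over each of the 3 cube faces,
# as unit vectors (z, x, y); opposite faces are identified (windows use |u.d|)
wedge_centers <- function(n) {
  o <- seq(-1 + 1 / n, 1 - 1 / n, length.out = n)
  grid <- expand.grid(a = o, b = o)
  out <- NULL
  for (axis in 1:3) {
    d <- matrix(0, nrow(grid), 3)
    d[, axis] <- 1
    others <- setdiff(1:3, axis)
    d[, others[1]] <- grid$a
    d[, others[2]] <- grid$b
    out <- rbind(out, d / sqrt(rowSums(d^2)))
  }
  out
}

#' @export
print.curvelet_system <- function(x, ...) {
  cat(sprintf("<curvelet_system> %s, %d detail scales, %d bands\n",
              paste(x$dims, collapse = "x"), x$n_scales,
              length(x$windows)))
  invisible(x)
}

#' Forward 3D curvelet transform
#'
#' Linear, energy-preserving analysis of a volume into directional
#' multiscale coefficient bands.
#'
#' @param volume numeric 3D array matching the system's dims; all values
#'   must be finite.
#' @param system a [curvelet_system()]; built on the fly if `NULL`.
#' @return object of class `curvelet_coeffs`: list with `blocks` (one real
#'   array per band) and `system`.
#' @export
fdct3 <- function(volume, system = NULL) {
  assert_finite_volume(volume)
  if (is.null(system)) system <- curvelet_system(dim(volume))
  stopifnot(inherits(system, "curvelet_system"),
            identical(dim(volume), dim(system$windows[[1]])))
  n <- prod(system$dims)
  fhat <- fft(volume)
  blocks <- lapply(system$windows, function(w) Re(fft(w * fhat,
                                                      inverse = TRUE)) / n)
  structure(list(blocks = blocks, system = system), class = "curvelet_coeffs")
}

#' Inverse 3D curvelet transform
#'
#' Exact (machine-precision) inverse of [fdct3()].
#'
#' @param coeffs a `curvelet_coeffs` object.
#' @return numeric 3D array.
#' @export
ifdct3 <- function(coeffs) {
  stopifnot(inherits(coeffs, "curvelet_coeffs"))
  sys <- coeffs$system
  if (length(coeffs$blocks) != length(sys$windows))
    stop("coefficient blocks inconsistent with the system", call. = FALSE)
  for (b in seq_along(coeffs$blocks))
    if (!identical(dim(coeffs$blocks[[b]]), sys$dims))
      stop("coefficient block ", b, " has been tampered with (wrong shape)",
           call. = FALSE)
  n <- prod(sys$dims)
  acc <- array(0 + 0i, sys$dims)
  for (b in seq_along(coeffs$blocks))
    acc <- acc + sys$windows[[b]] * fft(coeffs$blocks[[b]])
  Re(fft(acc, inverse = TRUE)) / n
}

#' Estimate the noise standard deviation from finest-scale coefficients
#'
#' Robust estimate: median absolute deviation (about zero) of all
#' finest-scale coefficients divided by 0.6745. This is the coefficient-
#' domain noise scale used by [hard_threshold()].
#'
#' @param coeffs a `curvelet_coeffs` object.
#' @return scalar noise sd estimate.
#' @export
estimate_sigma <- function(coeffs) {
  stopifnot(inherits(coeffs, "curvelet_coeffs"))
  finest <- which(coeffs$system$bands$scale == 1L)
  if (length(finest) == 0) stop("no finest-scale bands", call. = FALSE)
  x <- unlist(coeffs$blocks[finest], use.names = FALSE)
  mad(x, center = 0)
}

#' Scale-dependent hard thresholding of curvelet coefficients
#'
#' A coefficient at scale `s` is kept iff `|c| >= c_scale[s] * sigma`, else
#' zeroed (exact hard rule; the low-pass residual is exempt as it carries
#' bulk anatomy, not noise).
#'
#' @param coeffs a `curvelet_coeffs` object.
#' @param sigma noise sd (e.g. from [estimate_sigma()]); must be >= 0.
#' @param c_scale per-scale threshold multipliers, finest first; default 4
#'   at the finest scale and 3 elsewhere.
#' @return thresholded `curvelet_coeffs`.
#' @export
hard_threshold <- function(coeffs, sigma, c_scale = NULL) {
  stopifnot(inherits(coeffs, "curvelet_coeffs"), sigma >= 0)
  ns <- coeffs$system$n_scales
  if (is.null(c_scale)) c_scale <- c(4, rep(3, ns - 1))
  stopifnot(length(c_scale) == ns, all(c_scale >= 0))
  scales <- coeffs$system$bands$scale
  for (b in seq_along(coeffs$blocks)) {
    s <- scales[b]
    if (s == 0L) next
    thr <- c_scale[s] * sigma
    if (thr > 0) {
      blk <- coeffs$blocks[[b]]
      blk[abs(blk) < thr] <- 0
      coeffs$blocks[[b]] <- blk
    }
  }
  coeffs
}

#' Select stripe-aligned coefficient sub-bands
#'
#' Stripe noise is a line artifact along one spatial axis; its spectrum is
#' concentrated in the frequency plane normal to that axis. The stripe band
#' set contains every detail band whose central frequency direction lies
#' within `tol_deg` of that plane.
#'
#' @param system a [curvelet_system()].
#' @param axis spatial stripe axis: `"x"` (fast), `"y"` (slow) or `"z"`.
#' @param tol_deg angular tolerance in degrees.
#' @return integer vector of band indices.
#' @export
stripe_bands <- function(system, axis = c("x", "y", "z"), tol_deg = 15) {
  stopifnot(inherits(system, "curvelet_system"))
  axis <- match.arg(axis)
  bd <- system$bands
  comp <- switch(axis, z = bd$dz, x = bd$dx, y = bd$dy)
  sel <- bd$scale > 0 & abs(comp) <= sin(tol_deg * pi / 180)
  bd$band[sel]
}

#' Direction-selective stripe suppression
#'
#' Within each selected sub-band, coefficients whose magnitude is strictly
#' below the sub-band mean magnitude are kept; all others (the stripe
#' outliers, including the equality case) are zeroed. Bands outside the set
#' are untouched.
#'
#' @param coeffs a `curvelet_coeffs` object.
#' @param bands integer band indices, e.g. from [stripe_bands()].
#' @return filtered `curvelet_coeffs`.
#' @export
stripe_filter <- function(coeffs, bands) {
  stopifnot(inherits(coeffs, "curvelet_coeffs"))
  if (length(bands) == 0) {
    warning("empty stripe band set: returning coefficients unchanged",
            call. = FALSE)
    return(coeffs)
  }
  stopifnot(all(bands %in% seq_along(coeffs$blocks)),
            all(coeffs$system$bands$scale[bands] > 0))
  for (b in bands) {
    blk <- coeffs$blocks[[b]]
    m <- mean(abs(blk))
    blk[abs(blk) >= m] <- 0
    coeffs$blocks[[b]] <- blk
  }
  coeffs
}

#' Two-step curvelet-domain denoising of an OCTA volume
#'
#' Forward transform, scale-dependent hard thresholding (Gaussian noise),
#' direction-selective sub-band suppression (stripe noise), inverse
#' transform.
#'
#' @param volume numeric 3D array.
#' @param system optional pre-built [curvelet_system()].
#' @param sigma `"auto"` (estimate via [estimate_sigma()]) or a fixed
#'   numeric noise sd.
#' @param c_scale per-scale threshold multipliers (see [hard_threshold()]).
#' @param stripe_axis stripe axis for [stripe_bands()], or `NULL` to skip
#'   stripe filtering.
#' @param stripe_tol_deg angular tolerance for the stripe band set.
#' @param threshold apply the hard-thresholding step?
#' @return denoised volume, with attributes `sigma` (the noise sd actually
#'   used) and `stripe_bands`.
#' @export
denoise_volume <- function(volume, system = NULL, sigma = "auto",
                           c_scale = NULL, stripe_axis = "x",
                           stripe_tol_deg = 15, threshold = TRUE) {
  assert_finite_volume(volume)
  if (is.null(system)) system <- curvelet_system(dim(volume))
  co <- fdct3(volume, system)
  sig <- if (identical(sigma, "auto")) estimate_sigma(co) else {
    stopifnot(is.numeric(sigma), sigma >= 0)
    sigma
  }
  if (isTRUE(threshold)) co <- hard_threshold(co, sig, c_scale)
  sb <- integer(0)
  if (!is.null(stripe_axis)) {
    sb <- stripe_bands(system, stripe_axis, stripe_tol_deg)
    if (length(sb) > 0) co <- stripe_filter(co, sb)
  }
  out <- ifdct3(co)
  attr(out, "sigma") <- sig
  attr(out, "stripe_bands") <- sb
  out
}

#' Coefficient energy within a band set
#'
#' Sum of squared coefficients over the given bands; handy for quantifying
#' how much stripe energy a filter removed.
#'
#' @param coeffs a `curvelet_coeffs` object.
#' @param bands integer band indices (default: all bands).
#' @export
band_energy <- function(coeffs, bands = seq_along(coeffs$blocks)) {
  stopifnot(inherits(coeffs, "curvelet_coeffs"))
  sum(vapply(coeffs$blocks[bands], function(b) sum(b^2), 0))
}
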
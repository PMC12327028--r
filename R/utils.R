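#' Peak signal-to-noise ratio between two volumes
#'
#' @param x,reference numeric arrays of identical shape.
#' @param peak signal peak; defaults to `max(abs(reference))`.
#' @return PSNR in dB (`Inf` for identical arrays).
#' @export
psnr <- function(x, reference, peak = max(abs(reference))) {
  stopifnot(identical(dim(x), dim(reference)))
  mse <- mean((x - reference)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Round half away from zero
#'
#' Reported longitudinal statistics are rounded half-away-from-zero (the
#' convention used for the bundled reference series), unlike base R's
#' round-half-even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# shape checks -------------------------------------------------------------

assert_volume <- function(x, name = deparse(substitute(x))) {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop(sprintf("`%s` must be a 3D array (z, x, y)", name), call. = FALSE)
  invisible(x)
}

assert_finite_volume <- function(x, name = deparse(substitute(x))) {
  assert_volume(x, name)
  if (!all(is.finite(x)))
    stop(sprintf("`%s` contains non-finite voxels", name), call. = FALSE)
  invisible(x)
}

# coerce logical/numeric mask to integer 0/1 array
as_mask <- function(x, name = deparse(substitute(x))) {
  assert_volume(x, name)
  v <- as.integer(x != 0)
  dim(v) <- dim(x)
  v
}

# fftfreq in cycles per voxel for axis length n
fftfreq <- function(n) {
  k <- 0:(n - 1)
  f <- k / n
  f[f >= 0.5] <- f[f >= 0.5] - 1
  f
}

# full-grid frequency arrays for dims (nz, nx, ny)
freq_grids <- function(dims) {
  fz <- fftfreq(dims[1]); fx <- fftfreq(dims[2]); fy <- fftfreq(dims[3])
  list(
    fz = array(rep(fz, times = dims[2] * dims[3]), dims),
    fx = array(rep(rep(fx, each = dims[1]), times = dims[3]), dims),
    fy = array(rep(fy, each = dims[1] * dims[2]), dims)
  )
}

# mirror (reflect-101) padding indices for axis of length n, pad p
reflect_idx <- function(n, p) {
  if (p == 0) return(seq_len(n))
  if (p >= n) stop("padding exceeds axis length", call. = FALSE)
  c(seq(p + 1, 2), seq_len(n), seq(n - 1, n - p))
}

# Otsu threshold on a numeric vector/array via a 256-bin histogram.
otsu_threshold <- function(x, nbins = 256) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1)
  h <- as.numeric(tabulate(pmin(findInterval(x, br, rightmost.closed = TRUE),
                                nbins), nbins))
  w <- cumsum(h)
  mids <- (br[-1] + br[-(nbins + 1)]) / 2
  m <- cumsum(h * mids)
  n <- w[nbins]; mt <- m[nbins]
  w0 <- w[-nbins]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- m[-nbins] / w0
  mu1 <- (mt - m[-nbins]) / w1
  between <- w0 * w1 * (mu0 - mu1)^2
  between[!valid] <- -Inf
  k <- which.max(between)
  br[k + 1]  # upper edge of the last background bin
}
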
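#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Tile-wise histogram equalization with clipping, used to boost the low
#' contrast of structural B-scans before segmentation. The image is divided
#' into a grid of tiles; each tile's histogram is clipped at
#' `clip_limit` times the mean bin count, the excess is redistributed
#' uniformly, and pixel values are remapped by bilinear interpolation of the
#' neighbouring tile CDFs. Output values lie in `[0, 1]`.
#'
#' With `tiles = c(1, 1)` and `clip_limit = Inf` the operation reduces to
#' plain global histogram equalization.
#'
#' @param image 2D numeric matrix (a B-scan, axial z in rows).
#' @param clip_limit histogram clip limit as a multiple of the mean bin
#'   count (>= 1; `Inf` disables clipping).
#' @param tiles tile grid `c(rows, cols)`.
#' @param nbins number of histogram bins.
#' @return matrix of the same shape with values in `[0, 1]`.
#' @export
clahe_enhance <- function(image, clip_limit = 2, tiles = c(8, 8),
                          nbins = 256) {
  stopifnot(is.matrix(image), all(is.finite(image)), clip_limit >= 1,
            length(tiles) == 2, all(tiles >= 1))
  rng <- range(image)
  if (diff(rng) == 0) {
    warning("constant image: returned unchanged", call. = FALSE)
    return(image)
  }
  x <- (image - rng[1]) / diff(rng)
  nr <- nrow(x); nc <- ncol(x)
  tr <- min(tiles[1], nr); tc <- min(tiles[2], nc)
  # tile edges (approximately equal tiles)
  redges <- round(seq(0, nr, length.out = tr + 1))
  cedges <- round(seq(0, nc, length.out = tc + 1))
  bin <- pmin(floor(x * nbins) + 1L, nbins)

  # per-tile clipped-CDF mappings: nbins x tr x tc
  maps <- array(0, c(nbins, tr, tc))
  centers_r <- numeric(tr); centers_c <- numeric(tc)
  for (i in seq_len(tr)) {
    ri <- (redges[i] + 1):redges[i + 1]
    centers_r[i] <- mean(range(ri))
    for (j in seq_len(tc)) {
      ci <- (cedges[j] + 1):cedges[j + 1]
      centers_c[j] <- mean(range(ci))
      h <- tabulate(bin[ri, ci], nbins)
      npix <- sum(h)
      if (is.finite(clip_limit)) {
        clip <- clip_limit * npix / nbins
        excess <- sum(pmax(h - clip, 0))
        h <- pmin(h, clip) + excess / nbins
      }
      maps[, i, j] <- cumsum(h) / npix
    }
  }
  # bilinear interpolation between tile centres, clamped at the borders
  ri <- findInterval(seq_len(nr), centers_r)
  ci <- findInterval(seq_len(nc), centers_c)
  r0 <- pmax(ri, 1); r1 <- pmin(ri + 1, tr)
  c0 <- pmax(ci, 1); c1 <- pmin(ci + 1, tc)
  wr <- ifelse(r1 == r0, 0,
               (seq_len(nr) - centers_r[r0]) / (centers_r[r1] - centers_r[r0]))
  wc <- ifelse(c1 == c0, 0,
               (seq_len(nc) - centers_c[c0]) / (centers_c[c1] - centers_c[c0]))
  wr <- pmin(pmax(wr, 0), 1); wc <- pmin(pmax(wc, 0), 1)

  out <- matrix(0, nr, nc)
  for (j in seq_len(nc)) {
    b <- bin[, j]
    m00 <- maps[cbind(b, r0, rep(c0[j], nr))]
    m10 <- maps[cbind(b, r1, rep(c0[j], nr))]
    m01 <- maps[cbind(b, r0, rep(c1[j], nr))]
    m11 <- maps[cbind(b, r1, rep(c1[j], nr))]
    out[, j] <- (1 - wc[j]) * ((1 - wr) * m00 + wr * m10) +
      wc[j] * ((1 - wr) * m01 + wr * m11)
  }
  out
}
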
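# spherical Bessel function j1(z) = sin(z)/z^2 - cos(z)/z, stable near 0
sph_bessel1 <- function(z) {
  out <- numeric(length(z))
  small <- abs(z) < 1e-4
  zs <- z[small]
  out[small] <- zs / 3 - zs^3 / 30
  zl <- z[!small]
  out[!small] <- sin(zl) / zl^2 - cos(zl) / zl
  out
}

#' Oriented-flux matrix field at a given radius
#'
#' For every voxel x, computes the 3x3 symmetric matrix `Q(x, r)` whose
#' entries are the outward flux of the (Gaussian-smoothed) image gradient
#' through the sphere of radius `r` centred at x, weighted by the projection
#' directions: `Q_ij = \int_{|n|=1} d_i(G*f)(x + r n) n_j r^2 dOmega`. At a
#' bright tubular voxel the two cross-section eigenvalues of Q are strongly
#' negative while the along-tube one is near zero.
#'
#' Computed in the Fourier domain via the analytic transform of the sphere
#' surface measure,
#' `Qhat_ij(u) = -8 pi^2 r^2 fhat(u) Ghat(u) (u_i u_j / |u|) j1(2 pi r |u|)`,
#' after mirror padding to avoid wrap-around.
#'
#' @param volume numeric 3D array.
#' @param r sphere radius in voxels (>= 1 and < half the smallest dim).
#' @param sigma Gaussian pre-smoothing scale in voxels.
#' @return object of class `oriented_flux_field`: list of the six unique
#'   components `q11, q12, q13, q22, q23, q33` (axis order z, x, y) plus
#'   `r` and `sigma`.
#' @export
oriented_flux_matrix <- function(volume, r, sigma = 1) {
  assert_finite_volume(volume)
  d <- dim(volume)
  if (r < 1) stop("`r` must be >= 1 voxel", call. = FALSE)
  if (r >= min(d) / 2)
    stop("`r` larger than half the smallest volume dimension", call. = FALSE)
  p <- ceiling(r) + 4L
  iz <- reflect_idx(d[1], p); ix <- reflect_idx(d[2], p)
  iy <- reflect_idx(d[3], p)
  vp <- volume[iz, ix, iy]
  dp <- dim(vp)
  g <- freq_grids(dp)
  absu <- sqrt(g$fz^2 + g$fx^2 + g$fy^2)
  ghat <- exp(-2 * pi^2 * sigma^2 * absu^2)
  base <- -8 * pi^2 * r^2 * fft(vp) * ghat *
    ifelse(absu > 0, sph_bessel1(2 * pi * r * absu) / absu, 0)
  n <- prod(dp)
  crop <- function(a) a[p + seq_len(d[1]), p + seq_len(d[2]),
                        p + seq_len(d[3])]
  comp <- function(ui, uj) crop(Re(fft(base * ui * uj, inverse = TRUE)) / n)
  out <- list(q11 = comp(g$fz, g$fz), q12 = comp(g$fz, g$fx),
              q13 = comp(g$fz, g$fy), q22 = comp(g$fx, g$fx),
              q23 = comp(g$fx, g$fy), q33 = comp(g$fy, g$fy),
              r = r, sigma = sigma)
  class(out) <- "oriented_flux_field"
  out
}

#' Sorted eigenvalues of a symmetric 3x3 matrix field
#'
#' Per-voxel spectral decomposition of an oriented-flux field. The field is
#' stored by its six unique components, so symmetry holds by representation;
#' eigenvalues are real and returned sorted (`l1 <= l2 <= l3`), and
#' `l1 + l2 + l3` equals the matrix trace to numerical precision.
#'
#' @param field an `oriented_flux_field` (or any list with components
#'   `q11, q12, q13, q22, q23, q33` of identical shape).
#' @return object of class `eigen_field`: list of arrays `l1, l2, l3`.
#' @export
eig_sym3 <- function(field) {
  comps <- c("q11", "q12", "q13", "q22", "q23", "q33")
  if (!all(comps %in% names(field)))
    stop("`field` must contain the six symmetric matrix components",
         call. = FALSE)
  d <- dim(field$q11)
  ev <- .eig_sym3_cpp(field$q11, field$q12, field$q13,
                      field$q22, field$q23, field$q33)
  for (k in 1:3) dim(ev[[k]]) <- d
  class(ev) <- "eigen_field"
  ev
}

#' Multi-radius optimally-oriented-flux vessel response
#'
#' For each radius r in `radii`, computes the oriented-flux matrix field,
#' its eigenvalues `l1 <= l2 <= l3`, and the per-voxel response
#' `max(-lambda / r^2, 0)` where `lambda` is the eigenvalue combination
#' selected by `rule` (mean of the two most negative eigenvalues by default,
#' matching the elliptical cross-section of dermal vessels). The final
#' response is the maximum over radii, which is non-negative everywhere and
#' scales linearly with image intensity.
#'
#' @param volume numeric 3D array.
#' @param radii integer radii in voxels (default 2:6).
#' @param rule eigenvalue combination: `"mean12"` for `(l1 + l2)/2` or
#'   `"lambda1"` for `l1` alone.
#' @param sigma Gaussian pre-smoothing scale passed to
#'   [oriented_flux_matrix()].
#' @param return_scale also return the argmax radius per voxel?
#' @return the response volume (attributes `radii`, `rule`), or, when
#'   `return_scale = TRUE`, a list with `response` and `scale` (radius of
#'   the maximal response; NA where the response is 0).
#' @export
oof_response <- function(volume, radii = 2:6, rule = c("mean12", "lambda1"),
                         sigma = 1, return_scale = FALSE) {
  rule <- match.arg(rule)
  stopifnot(length(radii) >= 1, all(radii >= 1))
  resp <- array(0, dim(volume))
  scale <- array(NA_real_, dim(volume))
  for (r in radii) {
    q <- oriented_flux_matrix(volume, r, sigma = sigma)
    ev <- eig_sym3(q)
    lam <- if (rule == "mean12") (ev$l1 + ev$l2) / 2 else ev$l1
    rr <- pmax(-lam / r^2, 0)
    upd <- rr > resp
    resp[upd] <- rr[upd]
    scale[upd] <- r
  }
  attr(resp, "radii") <- radii
  attr(resp, "rule") <- rule
  if (return_scale) list(response = resp, scale = scale) else resp
}
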
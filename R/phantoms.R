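#' Smooth sinusoidal boundary height field
#'
#' Builds a height field `z = b(x, y)` as a constant plus a single sinusoid,
#' used to emulate the curved epidermal/dermal interfaces of skin OCT
#' volumes. With `amplitude = 0` the boundary is flat.
#'
#' @param shape_xy lateral voxel counts `c(nx, ny)`.
#' @param base mean axial position (voxels, 1-based).
#' @param amplitude sinusoid amplitude in voxels.
#' @param periods number of full periods along x and y, `c(px, py)`.
#' @param phase phase offset in radians.
#' @return an `nx` x `ny` matrix of axial positions.
#' @export
boundary_sinusoid <- function(shape_xy, base, amplitude = 0,
                              periods = c(1, 0), phase = 0) {
  nx <- shape_xy[1]; ny <- shape_xy[2]
  xg <- matrix((0:(nx - 1)) / nx, nx, ny)
  yg <- matrix(rep((0:(ny - 1)) / ny, each = nx), nx, ny)
  base + amplitude * sin(2 * pi * (periods[1] * xg + periods[2] * yg) + phase)
}

#' Random smooth boundary field (sum of low-frequency sinusoids)
#'
#' @inheritParams boundary_sinusoid
#' @param n_waves number of sinusoidal components.
#' @param seed integer seed (drawn with an isolated RNG state).
#' @export
boundary_random <- function(shape_xy, base, amplitude = 3, n_waves = 2,
                            seed = 1) {
  withr::with_seed(seed, {
    b <- matrix(base, shape_xy[1], shape_xy[2])
    for (k in seq_len(n_waves)) {
      b <- b + boundary_sinusoid(
        shape_xy, 0, amplitude / n_waves,
        periods = c(sample(1:3, 1), sample(0:2, 1)),
        phase = runif(1, 0, 2 * pi)
      )
    }
    b
  })
}

#' Specification of a layered structural phantom
#'
#' Describes a three-class (background / epidermis / dermis) tissue slab with
#' curved boundary surfaces, multiplicative Gamma speckle and additive
#' Gaussian noise. Boundaries are axial positions (1-based voxel indices):
#' `ab1` is the first epidermis voxel, `ab2` the first dermis voxel and
#' `ab3` one-past-last dermis voxel, so the epidermis occupies
#' `z in [ab1, ab2)`.
#'
#' @param shape voxel counts `c(nz, nx, ny)` (axial first).
#' @param ab1,ab2,ab3 scalars or `nx` x `ny` matrices of axial boundary
#'   positions with `ab1 < ab2 < ab3` everywhere.
#' @param layer_intensities mean reflectivity per class,
#'   `c(background, epidermis, dermis)`, all non-negative.
#' @param speckle_shape shape parameter of the unit-mean Gamma speckle field;
#'   `Inf` disables speckle. Smaller values give heavier speckle; 4 is a
#'   typical coherent-imaging surrogate.
#' @param additive_sigma standard deviation of additive Gaussian noise.
#' @param seed integer seed; identical specs and seeds give bit-identical
#'   volumes.
#' @return an object of class `layered_phantom_spec`.
#' @export
layered_phantom_spec <- function(shape,
                                 ab1 = 0.25 * shape[1],
                                 ab2 = 0.5 * shape[1],
                                 ab3 = 0.85 * shape[1],
                                 layer_intensities = c(background = 0.05,
                                                       epidermis = 0.6,
                                                       dermis = 0.35),
                                 speckle_shape = 4,
                                 additive_sigma = 0.02,
                                 seed = 1) {
  stopifnot(length(shape) == 3, shape[1] >= 4, all(shape >= 1))
  expand <- function(b) {
    if (is.matrix(b)) {
      stopifnot(nrow(b) == shape[2], ncol(b) == shape[3])
      b
    } else matrix(b, shape[2], shape[3])
  }
  ab1 <- expand(ab1); ab2 <- expand(ab2); ab3 <- expand(ab3)
  if (!all(ab1 < ab2) || !all(ab2 < ab3))
    stop("boundary surfaces must satisfy ab1 < ab2 < ab3 everywhere",
         call. = FALSE)
  if (any(ab1 < 1) || any(ab3 > shape[1] + 1))
    stop("boundary surfaces outside the axial range", call. = FALSE)
  if (any(layer_intensities < 0))
    stop("layer intensities must be non-negative", call. = FALSE)
  stopifnot(speckle_shape > 0, additive_sigma >= 0)
  structure(list(shape = as.integer(shape), ab1 = ab1, ab2 = ab2, ab3 = ab3,
                 layer_intensities = layer_intensities,
                 speckle_shape = speckle_shape,
                 additive_sigma = additive_sigma, seed = as.integer(seed)),
            class = "layered_phantom_spec")
}

#' Generate a layered structural phantom volume
#'
#' @param spec a [layered_phantom_spec()].
#' @return list with `volume` (numeric array, class means x speckle +
#'   Gaussian noise) and `labels` (integer array; 0 background, 1 epidermis,
#'   2 dermis; exact, noise-free class assignment).
#' @export
make_layered_volume <- function(spec) {
  stopifnot(inherits(spec, "layered_phantom_spec"))
  d <- spec$shape
  zz <- array(seq_len(d[1]), d)
  a1 <- aperm(array(spec$ab1, c(d[2], d[3], d[1])), c(3, 1, 2))
  a2 <- aperm(array(spec$ab2, c(d[2], d[3], d[1])), c(3, 1, 2))
  a3 <- aperm(array(spec$ab3, c(d[2], d[3], d[1])), c(3, 1, 2))
  labels <- (zz >= a1 & zz < a2) + 2L * (zz >= a2 & zz < a3)
  storage.mode(labels) <- "integer"
  means <- spec$layer_intensities[labels + 1L]
  dim(means) <- d
  vol <- withr::with_seed(spec$seed, {
    n <- prod(d)
    sp <- if (is.finite(spec$speckle_shape))
      rgamma(n, shape = spec$speckle_shape, rate = spec$speckle_shape)
    else rep(1, n)
    means * sp + rnorm(n, 0, spec$additive_sigma)
  })
  dim(vol) <- d
  list(volume = vol, labels = labels)
}

#' Straight tube descriptor for vessel phantoms
#'
#' @param from,to centerline endpoints `c(z, x, y)` (1-based voxel
#'   coordinates; may lie outside the volume, in which case the tube is
#'   clipped with a warning).
#' @param radius tube radius in voxels (>= 1).
#' @param intensity tube intensity.
#' @export
tube <- function(from, to, radius = 3, intensity = 1) {
  stopifnot(length(from) == 3, length(to) == 3, radius >= 1, intensity > 0)
  structure(list(from = as.numeric(from), to = as.numeric(to),
                 radius = radius, intensity = intensity), class = "tube")
}

#' Specification of a tubular vessel phantom
#'
#' Describes an angiographic volume containing straight tubes plus the
#' artifact families seen in raw OCTA decorrelation volumes: additive
#' Gaussian noise, salt-and-pepper noise, full-extent stripe lines along the
#' fast axis, and decaying axial tails adjacent to vessels at strictly lower
#' intensity than the vessel signal.
#'
#' @param shape voxel counts `c(nz, nx, ny)`.
#' @param tubes list of [tube()] objects.
#' @param gaussian_sigma additive Gaussian noise sd.
#' @param salt_pepper_fraction fraction of voxels replaced by salt (max
#'   intensity) or pepper (0), half each.
#' @param stripe_count number of stripe lines (along the fast axis, at
#'   random axial/slow positions).
#' @param stripe_amplitude stripe amplitude as a multiple of the background
#'   noise sd (`gaussian_sigma`; if that is 0 a reference scale of 5% of the
#'   maximum tube intensity is used).
#' @param tail_factor intensity of the tail artifact relative to the vessel
#'   signal, in `[0, 1)`; 0 disables tails.
#' @param tail_decay exponential decay length of the tail (voxels).
#' @param tail_direction `"up"` (towards smaller z) or `"down"`; physical
#'   OCT tails commonly extend away from the illumination.
#' @param background background intensity level.
#' @param seed integer seed.
#' @export
vessel_phantom_spec <- function(shape, tubes,
                                gaussian_sigma = 0,
                                salt_pepper_fraction = 0,
                                stripe_count = 0, stripe_amplitude = 5,
                                tail_factor = 0, tail_decay = 5,
                                tail_direction = c("up", "down"),
                                background = 0, seed = 1) {
  stopifnot(length(shape) == 3, all(shape >= 4))
  if (inherits(tubes, "tube")) tubes <- list(tubes)
  stopifnot(length(tubes) >= 1, all(vapply(tubes, inherits, TRUE, "tube")))
  if (tail_factor < 0 || tail_factor >= 1)
    stop("`tail_factor` must be in [0, 1): tails are strictly dimmer than ",
         "the vessel signal", call. = FALSE)
  stopifnot(gaussian_sigma >= 0, salt_pepper_fraction >= 0,
            salt_pepper_fraction < 1, stripe_count >= 0, tail_decay > 0)
  structure(list(shape = as.integer(shape), tubes = tubes,
                 gaussian_sigma = gaussian_sigma,
                 salt_pepper_fraction = salt_pepper_fraction,
                 stripe_count = as.integer(stripe_count),
                 stripe_amplitude = stripe_amplitude,
                 tail_factor = tail_factor, tail_decay = tail_decay,
                 tail_direction = match.arg(tail_direction),
                 background = background, seed = as.integer(seed)),
            class = "vessel_phantom_spec")
}

# rasterize one tube into intensity (0 outside) on the full grid
rasterize_tube <- function(tb, shape) {
  p0 <- tb$from; p1 <- tb$to; r <- tb$radius
  lo <- pmax(floor(pmin(p0, p1) - r - 1), 1)
  hi <- pmin(ceiling(pmax(p0, p1) + r + 1), shape)
  if (any(pmin(p0, p1) - r < 0.5) || any(pmax(p0, p1) + r > shape + 0.5))
    warning("tube extends outside the volume and was clipped", call. = FALSE)
  out <- array(0, shape)
  if (any(lo > hi)) return(out)
  zi <- lo[1]:hi[1]; xi <- lo[2]:hi[2]; yi <- lo[3]:hi[3]
  nb <- c(length(zi), length(xi), length(yi))
  pz <- array(zi, nb)
  px <- aperm(array(xi, nb[c(2, 1, 3)]), c(2, 1, 3))
  py <- aperm(array(yi, nb[c(3, 1, 2)]), c(2, 3, 1))
  d <- p1 - p0
  len2 <- sum(d^2)
  if (len2 == 0) {
    dist2 <- (pz - p0[1])^2 + (px - p0[2])^2 + (py - p0[3])^2
  } else {
    t <- ((pz - p0[1]) * d[1] + (px - p0[2]) * d[2] + (py - p0[3]) * d[3]) /
      len2
    t <- pmin(pmax(t, 0), 1)
    dist2 <- (pz - (p0[1] + t * d[1]))^2 + (px - (p0[2] + t * d[2]))^2 +
      (py - (p0[3] + t * d[3]))^2
  }
  inside <- dist2 <= r^2
  sub <- array(0, nb)
  sub[inside] <- tb$intensity
  out[zi, xi, yi] <- sub
  out
}

# centerline voxels of one tube (unique rounded samples inside the volume)
tube_centerline <- function(tb, shape) {
  len <- sqrt(sum((tb$to - tb$from)^2))
  ts <- seq(0, 1, length.out = max(2, ceiling(len * 4) + 1))
  pts <- round(outer(ts, tb$to - tb$from) +
                 matrix(tb$from, length(ts), 3, byrow = TRUE))
  pts <- unique(pts)
  keep <- pts[, 1] >= 1 & pts[, 1] <= shape[1] &
    pts[, 2] >= 1 & pts[, 2] <= shape[2] &
    pts[, 3] >= 1 & pts[, 3] <= shape[3]
  pts <- pts[keep, , drop = FALSE]
  colnames(pts) <- c("z", "x", "y")
  pts
}

#' Generate a tubular vessel phantom volume
#'
#' The ground-truth mask and centerlines are rasterized before any noise or
#' artifact is applied and are unaffected by every noise parameter.
#'
#' @param spec a [vessel_phantom_spec()].
#' @return list with `volume` (intensity volume with artifacts), `mask`
#'   (integer ground-truth tube mask), and `centerlines` (matrix of voxel
#'   coordinates, columns z, x, y, 1-based).
#' @export
make_vessel_volume <- function(spec) {
  stopifnot(inherits(spec, "vessel_phantom_spec"))
  d <- spec$shape
  signal <- array(0, d)
  for (tb in spec$tubes) signal <- pmax(signal, rasterize_tube(tb, d))
  mask <- as.integer(signal > 0)
  dim(mask) <- d
  centerlines <- do.call(rbind, lapply(spec$tubes, tube_centerline, shape = d))
  max_int <- max(vapply(spec$tubes, `[[`, 0, "intensity"))

  vol <- spec$background + signal
  # axial tail artifacts adjacent to vessels
  if (spec$tail_factor > 0) {
    dist <- matrix(Inf, d[2], d[3])
    tail <- array(0, d)
    zs <- if (spec$tail_direction == "up") d[1]:1 else 1:d[1]
    for (z in zs) {
      mz <- mask[z, , ] > 0
      tailval <- spec$tail_factor * max_int * exp(-(dist - 1) / spec$tail_decay)
      tail[z, , ][!mz & is.finite(dist)] <- tailval[!mz & is.finite(dist)]
      dist <- ifelse(mz, 1, dist + 1)
    }
    vol <- pmax(vol, tail)
  }
  withr::with_seed(spec$seed, {
    if (spec$gaussian_sigma > 0)
      vol <- vol + rnorm(length(vol), 0, spec$gaussian_sigma)
    if (spec$salt_pepper_fraction > 0) {
      n_sp <- round(spec$salt_pepper_fraction * length(vol))
      idx <- sample.int(length(vol), n_sp)
      half <- seq_len(n_sp %/% 2)
      vol[idx[half]] <- max(max_int, 1)
      vol[idx[-half]] <- 0
    }
    if (spec$stripe_count > 0) {
      ref <- if (spec$gaussian_sigma > 0) spec$gaussian_sigma else
        0.05 * max_int
      amp <- spec$stripe_amplitude * ref
      for (k in seq_len(spec$stripe_count)) {
        z <- sample.int(d[1], 1); y <- sample.int(d[3], 1)
        vol[z, , y] <- vol[z, , y] + amp
      }
    }
  })
  dim(vol) <- d
  list(volume = vol, mask = mask, centerlines = centerlines)
}

#' Write phantom centerlines as CSV (0-based voxel coordinates)
#'
#' @param centerlines matrix with columns z, x, y (1-based, as returned by
#'   [make_vessel_volume()]).
#' @param path output CSV path.
#' @export
write_centerlines <- function(centerlines, path) {
  df <- as.data.frame(centerlines - 1L)
  names(df) <- c("z", "x", "y")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
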
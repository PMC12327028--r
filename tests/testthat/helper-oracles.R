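# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (direct loops, spectral sampling, base eigen).

# brute-force point-in-cylinder rasterization: loop over every voxel and
# test its distance to the centerline segment
oracle_cylinder_mask <- function(shape, p0, p1, radius) {
  mask <- array(0L, shape)
  d <- p1 - p0
  len2 <- sum(d^2)
  for (y in seq_len(shape[3]))
    for (x in seq_len(shape[2]))
      for (z in seq_len(shape[1])) {
        p <- c(z, x, y)
        t <- if (len2 == 0) 0 else
          min(max(sum((p - p0) * d) / len2, 0), 1)
        if (sum((p - p0 - t * d)^2) <= radius^2) mask[z, x, y] <- 1L
      }
  mask
}

# flood-fill component labelling (6.. no: 26-connectivity), plain R BFS
oracle_flood_labels <- function(binary) {
  d <- dim(binary)
  lab <- array(0L, d)
  cur <- 0L
  offs <- as.matrix(expand.grid(dz = -1:1, dx = -1:1, dy = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  idx_all <- which(binary != 0 & lab == 0L)
  for (start in which(binary != 0)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0) {
      i <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ai <- arrayInd(i, d)
      for (k in seq_len(nrow(offs))) {
        p <- ai + offs[k, ]
        if (any(p < 1) || any(p > d)) next
        j <- p[1] + d[1] * (p[2] - 1) + d[1] * d[2] * (p[3] - 1)
        if (binary[j] != 0 && lab[j] == 0L) {
          lab[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

# brute-force oriented-flux matrix at one voxel: spectral gradient of the
# Gaussian-smoothed volume, Fourier-upsampled, trilinearly sampled on a
# Fibonacci sphere and integrated against the outer product with the normal
oracle_oof_Q <- function(volume, x0, r, sigma = 1, upsample = 4,
                         n_sphere = 600, pad = 8) {
  d <- dim(volume)
  iz <- octavess:::reflect_idx(d[1], pad)
  ix <- octavess:::reflect_idx(d[2], pad)
  iy <- octavess:::reflect_idx(d[3], pad)
  vp <- volume[iz, ix, iy]
  dp <- dim(vp)
  g <- octavess:::freq_grids(dp)
  gh <- exp(-2 * pi^2 * sigma^2 * (g$fz^2 + g$fx^2 + g$fy^2))
  fh <- fft(vp) * gh
  up <- function(spec) {
    n <- dim(spec)
    N <- upsample * n
    big <- array(0 + 0i, N)
    lo <- lapply(1:3, function(a) c(1:(n[a] / 2), (N[a] - n[a] / 2 + 1):N[a]))
    big[lo[[1]], lo[[2]], lo[[3]]] <- spec
    Re(fft(big, inverse = TRUE)) / prod(n)
  }
  gz <- up(fh * 2i * pi * g$fz)
  gx <- up(fh * 2i * pi * g$fx)
  gy <- up(fh * 2i * pi * g$fy)
  trilin <- function(a, p) {
    f <- floor(p); w <- p - f
    acc <- 0
    for (dz in 0:1) for (dx in 0:1) for (dy in 0:1) {
      wt <- (if (dz) w[1] else 1 - w[1]) * (if (dx) w[2] else 1 - w[2]) *
        (if (dy) w[3] else 1 - w[3])
      id <- pmin(pmax(f + c(dz, dx, dy), 1), dim(a))
      acc <- acc + wt * a[id[1], id[2], id[3]]
    }
    acc
  }
  i <- seq(0, n_sphere - 1)
  phi <- acos(1 - 2 * (i + 0.5) / n_sphere)
  th <- pi * (1 + sqrt(5)) * i
  ns <- cbind(cos(phi), sin(phi) * cos(th), sin(phi) * sin(th))
  Q <- matrix(0, 3, 3)
  for (k in seq_len(n_sphere)) {
    n <- ns[k, ]
    pt <- (x0 + pad + r * n - 1) * upsample + 1
    gr <- c(trilin(gz, pt), trilin(gx, pt), trilin(gy, pt))
    Q <- Q + outer(gr, n)
  }
  Q * (4 * pi * r^2 / n_sphere)
}

# capped interior tube phantom used by several vesselize/OOF tests
capped_tube_phantom <- function() {
  make_vessel_volume(vessel_phantom_spec(
    c(20, 80, 20), tube(c(10, 11, 10), c(10, 70, 10), radius = 3,
                        intensity = 1)))
}
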
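test_that("constant volumes give zero flux matrices and zero response", {
  v <- array(3, c(16, 16, 16))
  q <- oriented_flux_matrix(v, r = 2)
  inner <- 5:12
  for (comp in c("q11", "q12", "q13", "q22", "q23", "q33"))
    expect_lt(max(abs(q[[comp]][inner, inner, inner])), 1e-8)
  r <- oof_response(v, radii = c(2, 3))
  expect_true(all(r[inner, inner, inner] < 1e-8))
  expect_true(all(r >= 0))
})

test_that("radius bounds are enforced", {
  v <- array(0, c(12, 12, 12))
  expect_error(oriented_flux_matrix(v, r = 0.5), ">= 1")
  expect_error(oriented_flux_matrix(v, r = 6), "half the smallest")
})

test_that("per-voxel eigenvalues match a general-purpose eigen oracle", {
  withr::with_seed(8, m <- matrix(rnorm(6 * 1000), 1000, 6))
  field <- list(q11 = array(m[, 1], c(10, 10, 10)),
                q12 = array(m[, 2], c(10, 10, 10)),
                q13 = array(m[, 3], c(10, 10, 10)),
                q22 = array(m[, 4], c(10, 10, 10)),
                q23 = array(m[, 5], c(10, 10, 10)),
                q33 = array(m[, 6], c(10, 10, 10)))
  ev <- eig_sym3(field)
  for (i in seq_len(1000)) {
    M <- matrix(c(m[i, 1], m[i, 2], m[i, 3],
                  m[i, 2], m[i, 4], m[i, 5],
                  m[i, 3], m[i, 5], m[i, 6]), 3, 3)
    ref <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
    expect_equal(c(ev$l1[i], ev$l2[i], ev$l3[i]), ref, tolerance = 1e-10)
  }
  # sorted order and trace conservation everywhere
  expect_true(all(ev$l1 <= ev$l2 & ev$l2 <= ev$l3))
  expect_equal(ev$l1 + ev$l2 + ev$l3, field$q11 + field$q22 + field$q33,
               tolerance = 1e-8)
})

test_that("diagonal matrices and rotations behave as expected", {
  one <- function(q) array(q, c(1, 1, 1))
  ev <- eig_sym3(list(q11 = one(-2), q12 = one(0), q13 = one(0),
                      q22 = one(-1), q23 = one(0), q33 = one(0)))
  expect_equal(c(ev$l1[1], ev$l2[1], ev$l3[1]), c(-2, -1, 0))
  # similarity invariance: R M R^T has identical eigenvalues
  withr::with_seed(9, {
    A <- matrix(rnorm(9), 3, 3)
    M <- A + t(A)
    R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  })
  Mr <- R %*% M %*% t(R)
  as_field <- function(M) list(q11 = one(M[1, 1]), q12 = one(M[1, 2]),
                               q13 = one(M[1, 3]), q22 = one(M[2, 2]),
                               q23 = one(M[2, 3]), q33 = one(M[3, 3]))
  e1 <- eig_sym3(as_field(M)); e2 <- eig_sym3(as_field(Mr))
  expect_equal(c(e1$l1, e1$l2, e1$l3), c(e2$l1, e2$l2, e2$l3),
               tolerance = 1e-10)
})

test_that("FFT flux matrix matches brute-force spherical integration", {
  d <- c(24, 24, 24)
  ph <- suppressWarnings(make_vessel_volume(vessel_phantom_spec(
    d, tube(c(12, 3, 12), c(12, 22, 12), radius = 3, intensity = 1))))
  q <- oriented_flux_matrix(ph$volume, r = 3, sigma = 1)
  for (x0 in list(c(12, 12, 12), c(12, 10, 12), c(13, 12, 11))) {
    Qb <- oracle_oof_Q(ph$volume, x0, r = 3, sigma = 1)
    Qf <- matrix(c(q$q11[x0[1], x0[2], x0[3]], q$q12[x0[1], x0[2], x0[3]],
                   q$q13[x0[1], x0[2], x0[3]], q$q12[x0[1], x0[2], x0[3]],
                   q$q22[x0[1], x0[2], x0[3]], q$q23[x0[1], x0[2], x0[3]],
                   q$q13[x0[1], x0[2], x0[3]], q$q23[x0[1], x0[2], x0[3]],
                   q$q33[x0[1], x0[2], x0[3]]), 3, 3)
    expect_lt(max(abs(Qf - Qb)) / max(abs(Qb)), 0.05)
  }
})

test_that("scale selection recovers the tube radius within one voxel", {
  d <- c(24, 40, 24)
  ph <- make_vessel_volume(vessel_phantom_spec(
    d, tube(c(12, 5, 12), c(12, 36, 12), radius = 3, intensity = 1)))
  rs <- oof_response(ph$volume, radii = 2:6, return_scale = TRUE)
  cl <- ph$centerlines
  cl <- cl[cl[, 2] >= 10 & cl[, 2] <= 31, , drop = FALSE]  # interior
  sel <- rs$scale[cl]
  expect_true(all(abs(sel - 3) <= 1))
  # centerline response clearly exceeds background
  bg <- rs$response[ph$mask == 0]
  expect_gt(min(rs$response[cl]), quantile(bg, 0.95))
})

test_that("an out-of-axis tube responds within 15% of an aligned one", {
  d <- c(32, 32, 32)
  ax <- make_vessel_volume(vessel_phantom_spec(
    d, tube(c(16, 5, 16), c(16, 28, 16), 3, 1)))
  dg <- make_vessel_volume(vessel_phantom_spec(
    d, tube(c(8, 8, 16), c(24, 24, 16), 3, 1)))
  r_ax <- oof_response(ax$volume)
  r_dg <- oof_response(dg$volume)
  cl_ax <- ax$centerlines[ax$centerlines[, 2] %in% 10:22, , drop = FALSE]
  cl_dg <- dg$centerlines[dg$centerlines[, 2] %in% 12:20, , drop = FALSE]
  expect_lt(abs(max(r_dg[cl_dg]) - max(r_ax[cl_ax])) / max(r_ax[cl_ax]),
            0.15)
})

test_that("the response scales linearly with image intensity", {
  ph <- make_vessel_volume(vessel_phantom_spec(
    c(20, 24, 20), tube(c(10, 3, 10), c(10, 21, 10), 2, 1)))
  r1 <- oof_response(ph$volume, radii = c(2, 3))
  r2 <- oof_response(2 * ph$volume, radii = c(2, 3))
  expect_equal(r2, 2 * r1, tolerance = 1e-10, ignore_attr = TRUE)
})
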
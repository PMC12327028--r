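sys32 <- curvelet_system(c(32, 32, 32))

test_that("transform is linear: zero maps to zero, scalars factor out", {
  z <- fdct3(array(0, c(32, 32, 32)), sys32)
  expect_true(all(vapply(z$blocks, function(b) all(b == 0), TRUE)))
  withr::with_seed(1, v <- array(rnorm(32^3), c(32, 32, 32)))
  ca <- fdct3(v, sys32)
  cb <- fdct3(2.5 * v, sys32)
  for (b in seq_along(ca$blocks))
    expect_equal(cb$blocks[[b]], 2.5 * ca$blocks[[b]], tolerance = 1e-12)
})

test_that("tight frame: Parseval energy ratio is 1 within 1e-6", {
  withr::with_seed(2, v <- array(rnorm(32^3), c(32, 32, 32)))
  co <- fdct3(v, sys32)
  expect_equal(band_energy(co) / sum(v^2), 1, tolerance = 1e-6)
})

test_that("inverse transform reconstructs exactly", {
  imp <- array(0, c(32, 32, 32)); imp[16, 17, 15] <- 1
  rec <- ifdct3(fdct3(imp, sys32))
  expect_lt(max(abs(rec - imp)), 1e-6)
  ph <- make_vessel_volume(vessel_phantom_spec(
    c(32, 32, 32), tube(c(16, 4, 16), c(16, 29, 16), 3, 1)))
  rec2 <- ifdct3(fdct3(ph$volume, sys32))
  expect_lt(sqrt(sum((rec2 - ph$volume)^2) / sum(ph$volume^2)), 1e-6)
  zc <- fdct3(array(0, c(32, 32, 32)), sys32)
  expect_true(all(ifdct3(zc) == 0))
})

test_that("non-finite input and tampered blocks are rejected", {
  v <- array(0, c(32, 32, 32)); v[1] <- NA
  expect_error(fdct3(v, sys32), "non-finite")
  withr::with_seed(3, v2 <- array(rnorm(32^3), c(32, 32, 32)))
  co <- fdct3(v2, sys32)
  co$blocks[[2]] <- co$blocks[[2]][1:8, 1:8, 1:8]
  expect_error(ifdct3(co), "tampered")
})

test_that("noise sd estimate matches direct finest-band sampling", {
  withr::with_seed(4, v <- array(rnorm(32^3, 0, 1), c(32, 32, 32)))
  co <- fdct3(v, sys32)
  fin <- which(sys32$bands$scale == 1)
  direct_sd <- sd(unlist(co$blocks[fin]))
  expect_lt(abs(estimate_sigma(co) - direct_sd) / direct_sd, 0.10)
})

test_that("noise sd estimate is near zero on a clean smooth phantom", {
  ph <- suppressWarnings(make_vessel_volume(vessel_phantom_spec(
    c(32, 32, 32), tube(c(16, 4, 16), c(16, 29, 16), 4, 1))))
  v <- gaussian_smooth3(ph$volume)
  co <- fdct3(v, sys32)
  peak_coeff <- max(abs(unlist(co$blocks)))
  expect_lt(estimate_sigma(co), 0.01 * peak_coeff)
})

test_that("doubling the noise doubles the sd estimate", {
  ratios <- vapply(1:3, function(s) {
    withr::with_seed(s, {
      n1 <- array(rnorm(32^3, 0, 0.5), c(32, 32, 32))
      n2 <- array(rnorm(32^3, 0, 1.0), c(32, 32, 32))
    })
    estimate_sigma(fdct3(n2, sys32)) / estimate_sigma(fdct3(n1, sys32))
  }, 0)
  expect_lt(abs(mean(ratios) - 2) / 2, 0.05)
})

test_that("hard thresholding obeys its contracts", {
  withr::with_seed(5, v <- array(rnorm(32^3), c(32, 32, 32)))
  co <- fdct3(v, sys32)
  ns <- sys32$n_scales
  # zero threshold: identity
  ht0 <- hard_threshold(co, sigma = 1, c_scale = rep(0, ns))
  expect_identical(ht0$blocks, co$blocks)
  # threshold above the global max kills everything except the low pass
  big <- max(abs(unlist(co$blocks))) * 2
  htb <- hard_threshold(co, sigma = big, c_scale = rep(1, ns))
  detail <- which(sys32$bands$scale > 0)
  expect_true(all(vapply(htb$blocks[detail], function(b) all(b == 0), TRUE)))
  # magnitudes never increase; support shrinks; larger C nests inside smaller
  h1 <- hard_threshold(co, sigma = 0.02, c_scale = rep(2, ns))
  h2 <- hard_threshold(co, sigma = 0.02, c_scale = rep(4, ns))
  for (b in detail) {
    expect_true(all(abs(h1$blocks[[b]]) <= abs(co$blocks[[b]])))
    expect_true(all(h1$blocks[[b]][co$blocks[[b]] == 0] == 0))
    expect_true(all(h1$blocks[[b]][h2$blocks[[b]] != 0] != 0))
  }
})

test_that("stripe band selection targets the plane normal to the stripe axis", {
  sb <- stripe_bands(sys32, "x", tol_deg = 15)
  expect_gt(length(sb), 0)
  expect_true(all(abs(sys32$bands$dx[sb]) <= sin(15 * pi / 180)))
  expect_true(all(sys32$bands$scale[sb] > 0))
})

test_that("stripe filter keeps sub-mean coefficients and empty sets warn", {
  withr::with_seed(6, v <- array(rnorm(32^3), c(32, 32, 32)))
  co <- fdct3(v, sys32)
  expect_warning(same <- stripe_filter(co, integer(0)), "empty")
  expect_identical(same$blocks, co$blocks)
  sb <- stripe_bands(sys32, "x")
  filt <- stripe_filter(co, sb)
  for (b in sb) {
    m <- mean(abs(co$blocks[[b]]))
    below <- abs(co$blocks[[b]]) < m
    expect_identical(filt$blocks[[b]][below], co$blocks[[b]][below])
    expect_true(all(filt$blocks[[b]][!below] == 0))
  }
})

test_that("denoising with both filters disabled is the identity", {
  withr::with_seed(7, v <- array(rnorm(32^3), c(32, 32, 32)))
  out <- denoise_volume(v, sys32, threshold = FALSE, stripe_axis = NULL)
  expect_lt(sqrt(sum((out - v)^2) / sum(v^2)), 1e-6)
})

test_that("denoising raises PSNR and tube contrast on a noisy stripe phantom", {
  spec <- vessel_phantom_spec(c(32, 32, 32),
                              tube(c(16, 4, 16), c(16, 29, 16), 3, 1),
                              gaussian_sigma = 0.1, stripe_count = 3,
                              stripe_amplitude = 6, seed = 5)
  ph <- make_vessel_volume(spec)
  clean <- make_vessel_volume(vessel_phantom_spec(c(32, 32, 32),
                                                  spec$tubes))$volume
  den <- denoise_volume(ph$volume, sys32)
  expect_gt(psnr(den, clean), psnr(ph$volume, clean))
  expect_true(all(is.finite(den)))
  expect_identical(dim(den), dim(ph$volume))
  # background std shrinks, tube-to-background contrast grows
  tub <- ph$mask == 1; bg <- ph$mask == 0
  expect_lt(sd(den[bg]), sd(ph$volume[bg]))
  expect_gt(mean(den[tub]) / mean(abs(den[bg])),
            mean(ph$volume[tub]) / mean(abs(ph$volume[bg])))
})

test_that("denoising is near-idempotent with the noise sd frozen", {
  spec <- vessel_phantom_spec(c(32, 32, 32),
                              tube(c(16, 4, 16), c(16, 29, 16), 3, 1),
                              gaussian_sigma = 0.1, stripe_count = 3,
                              seed = 5)
  ph <- make_vessel_volume(spec)
  sg <- estimate_sigma(fdct3(ph$volume, sys32))
  d1 <- denoise_volume(ph$volume, sys32, sigma = sg)
  d2 <- denoise_volume(d1, sys32, sigma = sg)
  change1 <- sqrt(sum((d1 - ph$volume)^2) / sum(ph$volume^2))
  change2 <- sqrt(sum((d2 - d1)^2) / sum(d1^2))
  expect_lt(change2, 0.5 * change1)
})
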
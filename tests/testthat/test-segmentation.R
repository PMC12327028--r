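test_that("boundaries of a flat three-layer phantom are recovered exactly", {
  ph <- make_layered_volume(layered_phantom_spec(
    c(100, 10, 6), ab1 = 20, ab2 = 50, ab3 = 80,
    speckle_shape = Inf, additive_sigma = 0))
  bs <- extract_boundaries(ph$labels)
  expect_true(all(bs$ab1 == 20))
  expect_true(all(bs$ab2 == 50))
  expect_true(all(bs$ab3 == 80))
  expect_equal(nrow(bs$qc), 0)
})

test_that("sinusoidal boundaries round-trip through label extraction", {
  shape <- c(80, 32, 8)
  b2 <- boundary_sinusoid(shape[2:3], 40, 5, periods = c(2, 1))
  sp <- layered_phantom_spec(shape, ab1 = 15, ab2 = b2, ab3 = 70,
                             speckle_shape = Inf, additive_sigma = 0)
  ph <- make_layered_volume(sp)
  bs <- extract_boundaries(ph$labels)
  # generator labels voxel z as dermis iff z >= b2, so the first dermis
  # voxel is ceiling(b2)
  expect_true(all(bs$ab2 == ceiling(b2)))
})

test_that("columns with a missing class are flagged undefined, not filled", {
  labels <- array(0L, c(30, 4, 2))
  labels[10:15, , ] <- 1L
  labels[16:25, , ] <- 2L
  labels[16:25, 2, 1] <- 0L   # remove dermis from one A-line
  bs <- extract_boundaries(labels)
  expect_true(is.na(bs$ab2[2, 1]))
  expect_true(is.na(bs$ab3[2, 1]))
  expect_false(anyNA(bs$ab1))
  expect_true(any(bs$qc$x == 2 & bs$qc$y == 1 & bs$qc$class == "dermis"))
})

test_that("split label runs keep the longest run and flag QC", {
  labels <- array(0L, c(40, 2, 1))
  labels[5:8, , ] <- 1L     # short epidermis fragment
  labels[12:25, 1, 1] <- 1L # the real epidermis run on column 1
  labels[26:35, , ] <- 2L
  bs <- extract_boundaries(labels)
  expect_equal(bs$ab1[1, 1], 12)
  expect_true(any(bs$qc$n_runs == 2))
})

test_that("boundary error is exact on identity, offsets and NA subsets", {
  ph <- make_layered_volume(layered_phantom_spec(
    c(60, 8, 4), ab1 = 10, ab2 = 25, ab3 = 50,
    speckle_shape = Inf, additive_sigma = 0))
  bs <- extract_boundaries(ph$labels)
  expect_true(all(boundary_error(bs, bs)$mae_voxels == 0))
  shifted <- bs
  for (b in c("ab1", "ab2", "ab3")) shifted[[b]] <- bs[[b]] + 3
  expect_true(all(boundary_error(shifted, bs)$mae_voxels == 3))
  # hand-computed 4-column case with undefined columns
  mk <- function(v) matrix(v, 4, 1)
  p <- structure(list(ab1 = mk(c(10, 12, NA, 16)), ab2 = mk(c(20, 22, 24, 26)),
                      ab3 = mk(c(30, 32, 34, 36)),
                      qc = tibble::tibble()), class = "boundary_surfaces")
  t <- structure(list(ab1 = mk(c(11, 12, 13, NA)), ab2 = mk(c(21, 21, 24, 26)),
                      ab3 = mk(c(30, 32, 34, 36)),
                      qc = tibble::tibble()), class = "boundary_surfaces")
  be <- boundary_error(p, t)
  expect_equal(be$mae_voxels[be$boundary == "ab1"], (1 + 0) / 2)  # cols 1,2
  expect_equal(be$n_columns[be$boundary == "ab1"], 2)
  expect_equal(be$mae_voxels[be$boundary == "ab2"], (1 + 1 + 0 + 0) / 4)
  expect_equal(be$mae_voxels[be$boundary == "ab3"], 0)
})

test_that("thickness maps: flat layers, sinusoid variance, empty layers", {
  ph <- make_layered_volume(layered_phantom_spec(
    c(100, 8, 4), ab1 = 20, ab2 = 50, ab3 = 80,
    speckle_shape = Inf, additive_sigma = 0))
  ts <- thickness_stats(ph$labels, voxel_size_um = 5)
  expect_true(all(ts$epidermis$values == 150))
  expect_equal(ts$epidermis$variance, 0)
  expect_equal(ts$dermis$mean, 150)
  # sinusoidal dermis boundary with amplitude a: thickness variance a^2/2
  a <- 6
  shape <- c(100, 64, 8)
  b2 <- boundary_sinusoid(shape[2:3], 50, a, periods = c(2, 0))
  ph2 <- make_layered_volume(layered_phantom_spec(
    shape, ab1 = 20, ab2 = b2, ab3 = 90,
    speckle_shape = Inf, additive_sigma = 0))
  ts2 <- thickness_stats(ph2$labels, voxel_size_um = 5)
  expect_lt(abs(ts2$dermis$variance - a^2 / 2 * 25) / (a^2 / 2 * 25), 0.10)
  # missing layer: NA summary, not a crash
  labels <- array(0L, c(30, 4, 2)); labels[10:20, , ] <- 1L
  ts3 <- thickness_stats(labels)
  expect_true(is.na(ts3$dermis$mean))
  expect_equal(ts3$dermis$n_defined, 0)
})

test_that("thickness summaries are invariant to lateral permutation", {
  ph <- make_layered_volume(layered_phantom_spec(
    c(60, 16, 6),
    ab1 = boundary_sinusoid(c(16, 6), 12, 3),
    ab2 = boundary_sinusoid(c(16, 6), 25, 4, phase = 1),
    ab3 = 50, speckle_shape = Inf, additive_sigma = 0))
  withr::with_seed(13, perm <- sample(16))
  ts1 <- thickness_stats(ph$labels)
  ts2 <- thickness_stats(ph$labels[, perm, ])
  expect_equal(ts1$epidermis$mean, ts2$epidermis$mean)
  expect_equal(ts1$epidermis$variance, ts2$epidermis$variance)
})

test_that("a 2-fold 1-epoch training run completes, serializes and reloads", {
  tr <- make_training_bscans(6, zx = c(32, 32), seed = 5)
  spec <- seg_model_spec(depth = 2, base_channels = 2, epochs = 1, folds = 2,
                         seed = 3)
  m <- train_unet(tr$images, tr$labels, spec)
  expect_s3_class(m, "unet_model")
  expect_true(all(c("fold", "epoch", "train_loss") %in% names(tidy(m))))
  expect_setequal(unique(m$curves$fold), c(0L, 1L, 2L))
  f <- withr::local_tempfile(fileext = ".rds")
  save_unet(m, f)
  m2 <- load_unet(f)
  p1 <- predict_bscan(m, tr$images[, , 1])
  p2 <- predict_bscan(m2, tr$images[, , 1])
  expect_identical(p1, p2)  # deterministic inference
  expect_true(all(p1 %in% 0:2))
})

test_that("cross-validation folds are disjoint and cover all samples", {
  tr <- make_training_bscans(7, zx = c(32, 32), seed = 6)
  spec <- seg_model_spec(depth = 2, base_channels = 2, epochs = 1, folds = 3,
                         seed = 4)
  m <- train_unet(tr$images, tr$labels, spec)
  expect_equal(sort(unique(m$fold_assignment)), 1:3)
  expect_equal(length(m$fold_assignment), 7)
})

test_that("training on a constant class collapses to that class", {
  withr::with_seed(14, imgs <- array(runif(32 * 32 * 4), c(32, 32, 4)))
  labs <- array(0L, c(32, 32, 4))
  m <- train_unet(imgs, labs,
                  seg_model_spec(depth = 2, base_channels = 4, epochs = 6,
                                 folds = 2, cross_validate = FALSE,
                                 clahe = FALSE, seed = 3))
  pred <- predict_bscan(m, imgs[, , 1])
  expect_equal(mean(pred == 0L), 1)
  # all-background input maps to all-background labels
  vol <- array(0.5 + 0 * imgs[, , 1], c(32, 32, 2))
  expect_true(all(predict_labels(m, vol) == 0L))
})

test_that("invalid labels and too few samples are rejected", {
  tr <- make_training_bscans(3, zx = c(32, 32), seed = 7)
  bad <- tr$labels; bad[1] <- 5L
  spec <- seg_model_spec(depth = 2, base_channels = 2, epochs = 1, folds = 2)
  expect_error(train_unet(tr$images, bad, spec), "\\{0, 1, 2\\}")
  spec10 <- seg_model_spec(depth = 2, base_channels = 2, epochs = 1,
                           folds = 10)
  expect_error(train_unet(tr$images, tr$labels, spec10), "at least")
})

test_that("10-fold cross-validation on 70 phantom B-scans is accurate", {
  tr <- make_training_bscans(70, zx = c(32, 32), seed = 21)
  spec <- seg_model_spec(depth = 2, base_channels = 4, epochs = 6,
                         folds = 10, lr = 3e-3, seed = 11)
  m <- train_unet(tr$images, tr$labels, spec)
  g <- glance(m)
  expect_gt(g$mean_val_accuracy, 0.95)
})
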
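#' Segmentation model specification
#'
#' Hyper-parameters for the compact U-Net used to segment CLAHE-enhanced
#' B-scans into background / epidermis / dermis. Defaults are sized for
#' phantom-scale training on a single CPU.
#'
#' @param depth number of down-sampling stages (>= 2).
#' @param base_channels channels of the first encoder level (doubling per
#'   level).
#' @param epochs training epochs.
#' @param folds cross-validation folds (>= 2).
#' @param lr Adam learning rate.
#' @param loss_weights weights of the composite loss,
#'   `c(cross_entropy, dice)`; the class-weighted cross-entropy counters
#'   the heavy background/tissue class imbalance of skin B-scans and the
#'   soft Dice term rewards region overlap.
#' @param class_weights per-class weights for the cross-entropy term, or
#'   `NULL` to use inverse class frequencies of the training set.
#' @param clahe apply [clahe_enhance()] to every B-scan before the network?
#' @param clip_limit,tiles CLAHE parameters.
#' @param cross_validate run the k-fold loop (in addition to the final fit
#'   on all data)?
#' @param seed integer seed controlling initialisation, shuffling and fold
#'   assignment.
#' @export
seg_model_spec <- function(depth = 3, base_channels = 16, epochs = 20,
                           folds = 10, lr = 2e-3,
                           loss_weights = c(ce = 0.5, dice = 0.5),
                           class_weights = NULL, clahe = TRUE,
                           clip_limit = 2, tiles = c(8, 8),
                           cross_validate = TRUE, seed = 1) {
  stopifnot(depth >= 2, base_channels >= 1, epochs >= 1, folds >= 2, lr > 0,
            length(loss_weights) == 2, all(loss_weights >= 0))
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 epochs = as.integer(epochs), folds = as.integer(folds),
                 lr = lr, loss_weights = as.numeric(loss_weights),
                 class_weights = class_weights, clahe = clahe,
                 clip_limit = clip_limit, tiles = tiles,
                 cross_validate = isTRUE(cross_validate),
                 seed = as.integer(seed)),
            class = "seg_model_spec")
}

as_bscan_list <- function(x, name) {
  if (is.list(x)) return(x)
  if (is.array(x) && length(dim(x)) == 3)
    return(lapply(seq_len(dim(x)[3]), function(i) x[, , i]))
  stop(sprintf("`%s` must be a list of matrices or a 3D array", name),
       call. = FALSE)
}

# preprocessing shared by training and inference
preprocess_bscan <- function(img, spec) {
  if (isTRUE(spec$clahe) && diff(range(img)) > 0) {
    clahe_enhance(img, clip_limit = spec$clip_limit, tiles = spec$tiles)
  } else {
    rng <- range(img)
    if (diff(rng) == 0) img * 0 else (img - rng[1]) / diff(rng)
  }
}

# reflect-pad a matrix so both dims are multiples of 2^depth
pad_pow2 <- function(img, depth) {
  m <- 2^depth
  pr <- (m - nrow(img) %% m) %% m
  pc <- (m - ncol(img) %% m) %% m
  if (pr > 0) img <- img[c(seq_len(nrow(img)), nrow(img) - seq_len(pr)), ,
                         drop = FALSE]
  if (pc > 0) img <- img[, c(seq_len(ncol(img)), ncol(img) - seq_len(pc)),
                         drop = FALSE]
  list(img = img, rows = nrow(img) - pr, cols = ncol(img) - pc)
}

#' Train the B-scan segmentation U-Net
#'
#' Optionally runs k-fold cross-validation (disjoint folds covering every
#' sample exactly once), then fits the returned model on all provided
#' B-scans. Training is deterministic for a fixed spec and seed.
#'
#' @param bscans list of 2D matrices (or a `Z x X x N` array) of structural
#'   B-scans.
#' @param labels matching list/array of integer label maps with values in
#'   `{0, 1, 2}` (background, epidermis, dermis).
#' @param spec a [seg_model_spec()].
#' @return an object of class `unet_model` with elements `params`, `arch`,
#'   `spec`, `class_weights` and `curves` (tibble of per-fold, per-epoch
#'   train/validation loss and validation pixel accuracy; fold 0 is the
#'   final fit on all data).
#' @export
train_unet <- function(bscans, labels, spec = seg_model_spec()) {
  stopifnot(inherits(spec, "seg_model_spec"))
  bscans <- as_bscan_list(bscans, "bscans")
  labels <- as_bscan_list(labels, "labels")
  n <- length(bscans)
  if (n != length(labels)) stop("bscans/labels length mismatch",
                                call. = FALSE)
  lv <- unique(unlist(lapply(labels, unique)))
  if (!all(lv %in% 0:2))
    stop("labels must take values in {0, 1, 2}", call. = FALSE)
  if (spec$cross_validate && n < spec$folds)
    stop("need at least `folds` labelled B-scans", call. = FALSE)
  images <- lapply(bscans, preprocess_bscan, spec = spec)
  m <- 2^spec$depth
  ok <- vapply(images, function(x) all(dim(x) %% m == 0), TRUE)
  if (!all(ok))
    stop("B-scan dimensions must be multiples of 2^depth for training",
         call. = FALSE)
  cw <- spec$class_weights
  if (is.null(cw)) {
    counts <- table(factor(unlist(labels), levels = 0:2))
    cw <- as.numeric(sum(counts) / (3 * pmax(counts, 1)))
    cw <- cw / mean(cw)
  }
  spec$class_weights <- cw

  curves <- list()
  final <- NULL
  fold_id <- NULL
  withr::with_seed(spec$seed, {
    if (spec$cross_validate) {
      fold_id <- sample(rep(seq_len(spec$folds), length.out = n))
      for (f in seq_len(spec$folds)) {
        net <- unet_init(spec$depth, spec$base_channels)
        fit <- unet_fit(images, labels, net, spec,
                        idx = which(fold_id != f),
                        val_idx = which(fold_id == f))
        curves[[length(curves) + 1]] <-
          dplyr::mutate(fit$curves, fold = f, .before = 1)
      }
    }
    net <- unet_init(spec$depth, spec$base_channels)
    fit <- unet_fit(images, labels, net, spec, idx = seq_len(n))
    curves[[length(curves) + 1]] <-
      dplyr::mutate(fit$curves, fold = 0L, .before = 1)
    final <- fit$params
  })
  structure(list(params = final,
                 arch = list(depth = spec$depth, base = spec$base_channels,
                             in_ch = 1L, n_classes = 3L),
                 spec = spec, class_weights = cw,
                 fold_assignment = fold_id,
                 curves = dplyr::bind_rows(curves)),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model> depth %d, base %d channels, %d parameters\n",
              x$arch$depth, x$arch$base,
              sum(vapply(x$params, length, 0L))))
  invisible(x)
}

#' Tidy per-epoch training curves of a segmentation model
#'
#' @param x a `unet_model`.
#' @param ... unused.
#' @return tibble with columns fold, epoch, train_loss, val_loss,
#'   val_accuracy (fold 0 is the final fit on all data).
#' @export
tidy.unet_model <- function(x, ...) x$curves

#' One-row summary of a segmentation model
#'
#' @inheritParams tidy.unet_model
#' @export
glance.unet_model <- function(x, ...) {
  cv <- dplyr::filter(x$curves, .data$fold > 0)
  last <- dplyr::slice_max(dplyr::group_by(cv, .data$fold), .data$epoch,
                           n = 1)
  tibble::tibble(folds = x$spec$folds, epochs = x$spec$epochs,
                 mean_val_accuracy = mean(last$val_accuracy),
                 mean_val_loss = mean(last$val_loss))
}

#' Predict a label map for a single B-scan
#'
#' @param model a trained `unet_model`.
#' @param image 2D numeric matrix.
#' @return integer matrix of class labels in `{0, 1, 2}`.
#' @export
predict_bscan <- function(model, image) {
  stopifnot(inherits(model, "unet_model"), is.matrix(image))
  img <- preprocess_bscan(image, model$spec)
  pd <- pad_pow2(img, model$arch$depth)
  x <- pd$img
  dim(x) <- c(dim(x), 1L)
  prob <- unet_forward(model$params, model$arch, x)$prob
  pred <- apply(prob, c(1, 2), which.max) - 1L
  pred[seq_len(pd$rows), seq_len(pd$cols), drop = FALSE]
}

#' Segment a structural volume slice by slice
#'
#' Cuts the volume into B-scans along the slow axis, feeds each through the
#' trained network and re-stacks the per-slice argmax class maps into a 3D
#' label volume. Inference is deterministic for a fixed model.
#'
#' @param model a trained `unet_model`.
#' @param volume numeric 3D array (z, x, y).
#' @return integer label volume of the same shape (0 background,
#'   1 epidermis, 2 dermis).
#' @export
predict_labels <- function(model, volume) {
  assert_finite_volume(volume)
  d <- dim(volume)
  out <- array(0L, d)
  for (y in seq_len(d[3])) out[, , y] <- predict_bscan(model, volume[, , y])
  out
}

#' Save / load a trained segmentation model
#'
#' @param model a `unet_model`.
#' @param path file path (RDS).
#' @export
save_unet <- function(model, path) {
  stopifnot(inherits(model, "unet_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "unet_model"))
    stop("`path` does not contain a unet_model", call. = FALSE)
  model
}

#' Extract boundary surfaces from a label volume
#'
#' Per A-line (axial column), `ab1` is the first epidermis voxel, `ab2` the
#' first dermis voxel and `ab3` one-past-last dermis voxel. Columns with
#' multiple runs of a class keep the longest run and are QC-flagged;
#' columns missing a class are marked undefined (NA), never interpolated.
#' Monotone ordering `ab1 <= ab2 <= ab3` is enforced on every defined
#' column.
#'
#' @param labels integer label volume (0/1/2).
#' @return object of class `boundary_surfaces`: matrices `ab1`, `ab2`,
#'   `ab3` (x by y, axial voxel positions, NA where undefined) and a `qc`
#'   tibble of flagged columns.
#' @export
extract_boundaries <- function(labels) {
  assert_volume(labels)
  d <- dim(labels)
  ab1 <- ab2 <- ab3 <- matrix(NA_real_, d[2], d[3])
  flags <- list()
  for (y in seq_len(d[3])) {
    sl <- labels[, , y]
    for (x in seq_len(d[2])) {
      r <- rle(sl[, x])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (cls in 1:2) {
        runs <- which(r$values == cls)
        if (length(runs) == 0) {
          flags[[length(flags) + 1]] <- c(x, y, cls, 0L)
          next
        }
        if (length(runs) > 1) {
          flags[[length(flags) + 1]] <- c(x, y, cls, length(runs))
          runs <- runs[which.max(r$lengths[runs])]
        }
        if (cls == 1) {
          ab1[x, y] <- starts[runs]
        } else {
          ab2[x, y] <- starts[runs]
          ab3[x, y] <- ends[runs] + 1
        }
      }
    }
  }
  def <- !is.na(ab1) & !is.na(ab2)
  ab2[def] <- pmax(ab1[def], ab2[def])
  def3 <- !is.na(ab2) & !is.na(ab3)
  ab3[def3] <- pmax(ab2[def3], ab3[def3])
  qc <- if (length(flags)) {
    fm <- do.call(rbind, flags)
    tibble::tibble(x = fm[, 1], y = fm[, 2],
                   class = c("epidermis", "dermis")[fm[, 3]],
                   n_runs = fm[, 4])
  } else {
    tibble::tibble(x = integer(), y = integer(), class = character(),
                   n_runs = integer())
  }
  structure(list(ab1 = ab1, ab2 = ab2, ab3 = ab3, qc = qc),
            class = "boundary_surfaces")
}

#' Tidy boundary surfaces into a long tibble
#'
#' @param x a `boundary_surfaces` object.
#' @param ... unused.
#' @export
tidy.boundary_surfaces <- function(x, ...) {
  d <- dim(x$ab1)
  grid <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  dplyr::bind_rows(lapply(c("ab1", "ab2", "ab3"), function(b)
    tibble::tibble(boundary = b, x = grid$x, y = grid$y,
                   z = as.vector(x[[b]]))))
}

#' Mean absolute axial deviation between boundary surfaces
#'
#' Computed per boundary over the columns where both surfaces are defined.
#'
#' @param pred,truth `boundary_surfaces` objects on the same lateral grid.
#' @return tibble with columns `boundary`, `mae_voxels`, `n_columns`.
#' @export
boundary_error <- function(pred, truth) {
  stopifnot(inherits(pred, "boundary_surfaces"),
            inherits(truth, "boundary_surfaces"),
            identical(dim(pred$ab1), dim(truth$ab1)))
  rows <- lapply(c("ab1", "ab2", "ab3"), function(b) {
    ok <- !is.na(pred[[b]]) & !is.na(truth[[b]])
    tibble::tibble(boundary = b,
                   mae_voxels = if (any(ok))
                     mean(abs(pred[[b]][ok] - truth[[b]][ok])) else NA_real_,
                   n_columns = sum(ok))
  })
  out <- dplyr::bind_rows(rows)
  if (all(out$n_columns == 0))
    stop("no commonly-defined columns", call. = FALSE)
  out
}

#' Per-layer thickness maps and summary statistics
#'
#' Thickness is the axial boundary difference (in voxels) scaled by the
#' axial voxel size: `ab2 - ab1` for the epidermis and `ab3 - ab2` for the
#' dermis. Columns with undefined boundaries are excluded from the summary.
#'
#' @param labels integer label volume.
#' @param voxel_size_um axial voxel size in micrometres.
#' @return named list of two `thickness_map` objects (`epidermis`,
#'   `dermis`), each with `values` (x by y matrix, um), `mean`, `variance`
#'   and `n_defined`.
#' @export
thickness_stats <- function(labels, voxel_size_um = 5) {
  bs <- extract_boundaries(labels)
  one <- function(layer, values) {
    ok <- is.finite(values)
    structure(list(layer = layer, values = values,
                   voxel_size_um = voxel_size_um,
                   mean = if (any(ok)) mean(values[ok]) else NA_real_,
                   variance = if (sum(ok) > 1) var(as.vector(values[ok]))
                              else NA_real_,
                   n_defined = sum(ok)),
              class = "thickness_map")
  }
  list(epidermis = one("epidermis", (bs$ab2 - bs$ab1) * voxel_size_um),
       dermis = one("dermis", (bs$ab3 - bs$ab2) * voxel_size_um))
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("<thickness_map> %s: mean %.1f um, variance %.1f um^2 (%d columns)\n",
              x$layer, x$mean, x$variance, x$n_defined))
  invisible(x)
}

#' Tidy a thickness map into x, y, thickness_um
#'
#' @param x a `thickness_map`.
#' @param ... unused.
#' @export
tidy.thickness_map <- function(x, ...) {
  d <- dim(x$values)
  tibble::tibble(x = rep(seq_len(d[1]), d[2]),
                 y = rep(seq_len(d[2]), each = d[1]),
                 thickness_um = as.vector(x$values))
}

#' @rdname tidy.thickness_map
#' @export
glance.thickness_map <- function(x, ...) {
  tibble::tibble(layer = x$layer, mean_um = x$mean, variance_um2 = x$variance,
                 n_defined = x$n_defined)
}

#' Generate labelled synthetic B-scans for segmentation training
#'
#' Convenience wrapper around the layered phantom generator: builds a
#' layered volume whose slow axis has one slice per requested B-scan, with
#' randomly curved boundaries, speckle and additive noise, and returns the
#' slices plus exact labels.
#'
#' @param n number of B-scans.
#' @param zx B-scan shape `c(nz, nx)`.
#' @param boundary_amplitude lateral boundary undulation (voxels).
#' @param speckle_shape,additive_sigma noise parameters, see
#'   [layered_phantom_spec()].
#' @param seed integer seed.
#' @return list with `images` and `labels` (both `nz x nx x n` arrays).
#' @export
make_training_bscans <- function(n, zx = c(64, 64), boundary_amplitude = 4,
                                 speckle_shape = 4, additive_sigma = 0.02,
                                 seed = 1) {
  shape <- c(zx[1], zx[2], n)
  base1 <- 0.25 * zx[1]; base2 <- 0.5 * zx[1]; base3 <- 0.85 * zx[1]
  spec <- layered_phantom_spec(
    shape,
    ab1 = boundary_random(shape[2:3], base1, boundary_amplitude, seed = seed),
    ab2 = boundary_random(shape[2:3], base2, boundary_amplitude,
                          seed = seed + 1),
    ab3 = boundary_random(shape[2:3], base3, boundary_amplitude,
                          seed = seed + 2),
    speckle_shape = speckle_shape, additive_sigma = additive_sigma,
    seed = seed
  )
  ph <- make_layered_volume(spec)
  list(images = ph$volume, labels = ph$labels)
}
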
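#' Training configuration
#'
#' Captures the training regime: stratified mini-batches of 14 slices, 7 of
#' which show the lung and 7 of which do not, geometric and noise
#' augmentation, and stochastic gradient descent with momentum on per-pixel
#' cross-entropy.
#'
#' @param batch_size slices per mini-batch (default 14).
#' @param lung_slices_per_batch slices containing lung per batch (default
#'   7); must not exceed `batch_size`.
#' @param lr SGD learning rate (> 0).
#' @param momentum SGD momentum coefficient in \[0, 1).
#' @param epochs number of passes over the majority stratum.
#' @param val_fraction fraction of training *cases* (never slices) held out
#'   for validation, to avoid slice-level leakage.
#' @param aug augmentation amplitudes: `rot_deg_max` (random rotation,
#'   degrees), `deform_grid` (control points per axis of the smooth
#'   deformation), `deform_sigma_px` (displacement sd, pixels),
#'   `noise_sigma` (Gaussian image noise, normalised intensity units).
#' @param seed master seed driving batch order, augmentation and weight
#'   initialisation.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 14L, lung_slices_per_batch = 7L,
                         lr = 0.01, momentum = 0.9, epochs = 10L,
                         val_fraction = 0.15,
                         aug = list(rot_deg_max = 10, deform_grid = 4,
                                    deform_sigma_px = 2, noise_sigma = 0.02),
                         seed = 0L) {
  assert_that(lung_slices_per_batch <= batch_size,
              "lung_slices_per_batch must not exceed batch_size")
  assert_that(lr > 0, "lr must be positive")
  assert_that(momentum >= 0 && momentum < 1, "momentum must be in [0, 1)")
  aug <- modifyList(list(rot_deg_max = 10, deform_grid = 4,
                         deform_sigma_px = 2, noise_sigma = 0.02), aug)
  structure(
    list(batch_size = as.integer(batch_size),
         lung_slices_per_batch = as.integer(lung_slices_per_batch),
         lr = lr, momentum = momentum, epochs = as.integer(epochs),
         val_fraction = val_fraction, aug = aug, seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Build slice records from phantom cases
#'
#' Runs the forward preprocessing (body crop, window, rescale) on every
#' case and emits one record per axial slice: the normalised image, the
#' matching label slice, whether any lung voxel is present, and the case
#' id.
#'
#' @param cases list of `phantom_case` objects (or lists with `volume` and
#'   `lung_mask`).
#' @param target_size slice size fed to the network.
#' @return A tibble with list-columns `image` and `label`, plus `has_lung`
#'   and `case_id`.
#' @export
slice_records <- function(cases, target_size = c(256L, 256L)) {
  rows <- purrr::map(cases, function(cs) {
    pp <- preprocess_volume(cs$volume, target_size = target_size)
    labs <- forward_mask_slices(cs$lung_mask, pp$transform)
    nz <- dim(pp$images)[3]
    tibble(
      image = lapply(seq_len(nz), function(z) pp$images[, , z]),
      label = lapply(seq_len(nz), function(z) labs[, , z]),
      has_lung = vapply(seq_len(nz), function(z) any(labs[, , z] > 0L), TRUE),
      case_id = cs$volume$id
    )
  })
  dplyr::bind_rows(rows)
}

#' Stratified mini-batch index plan for one epoch
#'
#' Every batch holds exactly `lung_slices_per_batch` lung slices and
#' `batch_size - lung_slices_per_batch` non-lung slices. The majority
#' stratum is covered once per epoch in a seeded random permutation; the
#' minority stratum is resampled with replacement to fill the batches.
#'
#' @param has_lung logical vector over records.
#' @param config a [train_config()].
#' @return A list of integer index vectors, one per batch.
#' @export
stratified_batches <- function(has_lung, config = train_config()) {
  idx_lung <- which(has_lung)
  idx_bg <- which(!has_lung)
  if (length(idx_lung) == 0) abort("stratum 'lung' is empty: no slice shows the lung")
  if (length(idx_bg) == 0) abort("stratum 'non-lung' is empty: every slice shows the lung")
  k_lung <- config$lung_slices_per_batch
  k_bg <- config$batch_size - k_lung
  n_batches <- max(ceiling(length(idx_lung) / k_lung),
                   ceiling(length(idx_bg) / k_bg))
  draw <- function(pool, need) {
    perm <- sample(pool)
    if (length(perm) < need) {
      perm <- c(perm, sample(pool, need - length(perm), replace = TRUE))
    }
    perm[seq_len(need)]
  }
  lung_seq <- draw(idx_lung, n_batches * k_lung)
  bg_seq <- draw(idx_bg, n_batches * k_bg)
  lapply(seq_len(n_batches), function(b) {
    c(lung_seq[(b - 1) * k_lung + seq_len(k_lung)],
      bg_seq[(b - 1) * k_bg + seq_len(k_bg)])
  })
}

#' Augment an image/label slice pair
#'
#' Applies the same random rotation (uniform in `±rot_deg_max`) and smooth
#' non-linear deformation (Gaussian displacements on a coarse control grid,
#' bilinearly upsampled to a dense field) to image and label — bilinear
#' interpolation for the image, nearest-neighbour for the label, so the
#' label set can only shrink — then adds Gaussian noise to the image only.
#' With all amplitudes zero the pair is returned unchanged. Randomness
#' comes from R's RNG.
#'
#' @param image numeric matrix in \[0, 1\].
#' @param label integer matrix, same shape.
#' @param aug amplitude list, see [train_config()].
#' @return A list with `image` and `label`.
#' @export
augment_slice <- function(image, label,
                          aug = list(rot_deg_max = 10, deform_grid = 4,
                                     deform_sigma_px = 2, noise_sigma = 0.02)) {
  assert_that(identical(dim(image), dim(label)), "image and label must align")
  h <- nrow(image); w <- ncol(image)
  angle <- if (aug$rot_deg_max > 0) runif(1, -aug$rot_deg_max, aug$rot_deg_max) * pi / 180 else 0
  if (aug$deform_sigma_px > 0) {
    gy <- matrix(rnorm(aug$deform_grid^2, 0, aug$deform_sigma_px),
                 aug$deform_grid, aug$deform_grid)
    gx <- matrix(rnorm(aug$deform_grid^2, 0, aug$deform_sigma_px),
                 aug$deform_grid, aug$deform_grid)
    dy <- .cpp_resize2d(gy, h, w, FALSE)
    dx <- .cpp_resize2d(gx, h, w, FALSE)
  } else {
    dy <- dx <- matrix(0, h, w)
  }
  if (angle == 0 && aug$deform_sigma_px <= 0) {
    img2 <- image
    lab2 <- label
  } else {
    img2 <- .cpp_warp2d(image, angle, dy, dx, FALSE, 0)
    lab2 <- .cpp_warp2d(label + 0, angle, dy, dx, TRUE, 0)
    storage.mode(lab2) <- "integer"
  }
  if (aug$noise_sigma > 0) {
    img2 <- img2 + matrix(rnorm(h * w, 0, aug$noise_sigma), h, w)
  }
  list(image = img2, label = lab2)
}

slice_dice <- function(pred, lab) {
  # foreground micro-DSC over a stack of label slices
  p <- pred > 0L; l <- lab > 0L
  s <- sum(p) + sum(l)
  if (s == 0) return(1)
  2 * sum(p & l) / s
}

#' Train a segmentation model
#'
#' Minimises per-pixel cross-entropy over the three classes with SGD +
#' momentum on stratified, augmented mini-batches. A case-level validation
#' split monitors foreground DSC each epoch and the best-validation
#' weights are restored at the end. Training aborts with a diagnostic if
#' the loss becomes non-finite.
#'
#' @param model a `seg_model` from [build_model()].
#' @param records slice tibble from [slice_records()].
#' @param config a [train_config()].
#' @param quiet suppress per-epoch messages.
#' @return The trained `seg_model`, with the training history attached as
#'   `attr(, "history")` (tibble: epoch, loss, val_dsc).
#' @export
train_model <- function(model, records, config = train_config(), quiet = TRUE) {
  assert_that(inherits(model, "seg_model"), "model must be a seg_model")
  assert_that(nrow(records) > 0, "no training records")
  h <- nrow(records$image[[1]]); w <- ncol(records$image[[1]])
  withr::with_seed(config$seed, {
    case_ids <- unique(records$case_id)
    n_val <- floor(config$val_fraction * length(case_ids))
    val_cases <- if (n_val > 0) sample(case_ids, n_val) else character()
    is_val <- records$case_id %in% val_cases
    tr <- records[!is_val, ]
    va <- records[is_val, ]
    history <- vector("list", config$epochs)
    best <- list(dsc = -Inf, state = NULL)
    for (ep in seq_len(config$epochs)) {
      batches <- stratified_batches(tr$has_lung, config)
      losses <- numeric(length(batches))
      for (b in seq_along(batches)) {
        ids <- batches[[b]]
        imgs <- array(0, c(h, w, length(ids)))
        labs <- array(0L, c(h, w, length(ids)))
        for (i in seq_along(ids)) {
          a <- augment_slice(tr$image[[ids[i]]], tr$label[[ids[i]]], config$aug)
          imgs[, , i] <- a$image
          labs[, , i] <- a$label
        }
        losses[b] <- .net_train_batch(model$handle, imgs, labs,
                                      config$lr, config$momentum)
        if (!is.finite(losses[b])) {
          abort(sprintf("training diverged: non-finite loss at epoch %d batch %d (lr=%g)",
                        ep, b, config$lr))
        }
      }
      val_dsc <- NA_real_
      if (nrow(va) > 0) {
        vi <- array(unlist(va$image), c(h, w, nrow(va)))
        vp <- .net_predict(model$handle, vi)
        vl <- array(unlist(va$label), c(h, w, nrow(va)))
        val_dsc <- slice_dice(vp, vl)
        if (val_dsc >= best$dsc) best <- list(dsc = val_dsc, state = .net_state(model$handle))
      }
      history[[ep]] <- tibble(epoch = ep, loss = mean(losses), val_dsc = val_dsc)
      if (!quiet) {
        message(sprintf("epoch %d/%d  loss %.4f  val DSC %s", ep, config$epochs,
                        mean(losses),
                        if (is.na(val_dsc)) "-" else sprintf("%.4f", val_dsc)))
      }
    }
    if (!is.null(best$state)) .net_load_state(model$handle, best$state)
  })
  model$input_size <- c(h, w)
  attr(model, "history") <- dplyr::bind_rows(history)
  model
}

#' @export
tidy.seg_model <- function(x, ...) {
  hist <- attr(x, "history")
  if (is.null(hist)) {
    return(tibble(epoch = integer(), loss = numeric(), val_dsc = numeric()))
  }
  hist
}
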
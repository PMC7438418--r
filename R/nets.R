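#' Network configuration
#'
#' Describes one of the two slice-segmentation architectures. Both are
#' encoder–decoder networks with skip connections in the classic U-net
#' topology, with batch normalisation after every convolution
#' (conv → BN → ReLU); the `resunet` variant additionally carries an
#' identity (or 1x1-projected) residual connection around every down- and
#' up-sampling double-convolution block. Up-sampling uses learned 2x2
#' transposed convolutions. The default profile (base width 64, depth 4)
#' follows the original U-net sizing; a reduced profile (e.g. base width
#' 16 at 128x128 input) is practical for CPU-scale work.
#'
#' @param variant `"unet"` or `"resunet"`.
#' @param base_width number of filters at the first level (>= 4).
#' @param depth number of down-samplings (>= 1); input sizes must be
#'   divisible by `2^depth`.
#' @param num_classes number of output classes; 3 (background, right lung,
#'   left lung).
#' @param in_channels input channels; 1 (a normalised HU slice).
#' @return An object of class `net_config`.
#' @export
net_config <- function(variant = c("unet", "resunet"), base_width = 64L,
                       depth = 4L, num_classes = 3L, in_channels = 1L) {
  variant <- match.arg(variant)
  assert_that(depth >= 1, "depth must be >= 1")
  assert_that(base_width >= 4, "base_width must be >= 4")
  assert_that(num_classes == 3L, "the pipeline segments 3 classes (background/right/left)")
  assert_that(in_channels == 1L, "slices are single-channel")
  structure(
    list(variant = variant, base_width = as.integer(base_width),
         depth = as.integer(depth), num_classes = as.integer(num_classes),
         in_channels = as.integer(in_channels)),
    class = "net_config"
  )
}

#' @export
print.net_config <- function(x, ...) {
  cat(sprintf("<net_config> %s, base width %d, depth %d, %d classes\n",
              x$variant, x$base_width, x$depth, x$num_classes))
  invisible(x)
}

#' Build a segmentation model
#'
#' Instantiates the network with He-initialised weights. Weight
#' initialisation draws from R's RNG, so `set.seed()` before building makes
#' the model reproducible.
#'
#' @param config a [net_config()].
#' @return An object of class `seg_model` wrapping the native network
#'   handle.
#' @export
build_model <- function(config = net_config()) {
  assert_that(inherits(config, "net_config"), "config must be a net_config")
  handle <- .net_create(config$variant, config$base_width, config$depth,
                        config$num_classes, config$in_channels)
  structure(list(handle = handle, config = config, input_size = NULL),
            class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf("<seg_model> %s (base %d, depth %d), %s parameters\n",
              x$config$variant, x$config$base_width, x$config$depth,
              format(n_params(x), big.mark = ",")))
  if (!is.null(x$input_size))
    cat(sprintf("  trained at input size %d x %d\n", x$input_size[1], x$input_size[2]))
  invisible(x)
}

#' Number of trainable parameters
#' @param model a `seg_model`.
#' @return Parameter count.
#' @export
n_params <- function(model) {
  assert_that(inherits(model, "seg_model"), "model must be a seg_model")
  .net_nparams(model$handle)
}

check_input_stack <- function(images) {
  if (is.matrix(images)) images <- array(images, c(dim(images), 1L))
  assert_that(is.array(images) && length(dim(images)) == 3,
              "images must be an (H, W, n) array or a single matrix")
  images
}

#' Predict labels for normalised slices
#'
#' Runs the network in inference mode (batch-norm uses running statistics,
#' so results do not depend on how slices are batched) and decodes by
#' per-pixel argmax over the class scores.
#'
#' @param model a trained `seg_model`.
#' @param images matrix `(H, W)` or array `(H, W, n)` of slices in \[0, 1\].
#' @return Integer array of labels in \{0, 1, 2\}, same spatial shape.
#' @export
predict_slice <- function(model, images) {
  assert_that(inherits(model, "seg_model"), "model must be a seg_model")
  single <- is.matrix(images)
  images <- check_input_stack(images)
  if (min(images) < 0 || max(images) > 1) {
    warn("input values outside [0, 1]; did you forget normalize_slice()?")
  }
  out <- .net_predict(model$handle, images)
  if (single) out[, , 1] else out
}

#' Raw class scores for normalised slices
#'
#' @param model a `seg_model`.
#' @param images matrix or `(H, W, n)` array in \[0, 1\].
#' @param train if `TRUE`, run with batch statistics (training mode).
#' @return Numeric array `(H, W, num_classes, n)`.
#' @export
model_logits <- function(model, images, train = FALSE) {
  assert_that(inherits(model, "seg_model"), "model must be a seg_model")
  images <- check_input_stack(images)
  .net_logits(model$handle, images, train)
}

#' Extract model weights as plain R objects
#'
#' The returned state (weights, batch-norm running statistics, and the
#' architecture description) fully determines inference behaviour and can
#' be saved with `saveRDS()`.
#'
#' @param model a `seg_model`.
#' @return A list state.
#' @export
model_state <- function(model) {
  st <- .net_state(model$handle)
  st$input_size <- model$input_size
  st
}

#' Restore a model from a saved state
#'
#' @param state a list from [model_state()].
#' @return A `seg_model`.
#' @export
model_from_state <- function(state) {
  cfg <- net_config(state$variant, state$base, state$depth,
                    state$classes, state$in_channels)
  model <- build_model(cfg)
  .net_load_state(model$handle, state)
  model$input_size <- state$input_size
  model
}

#' Save / load a model checkpoint
#'
#' Checkpoints embed the architecture configuration, so loading needs no
#' separate config.
#'
#' @param model a `seg_model`.
#' @param path file path (`.rds`).
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the restored `seg_model`.
#' @export
save_model <- function(model, path) {
  saveRDS(model_state(model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  assert_that(file.exists(path), sprintf("no such checkpoint: %s", path))
  model_from_state(readRDS(path))
}

#' @export
glance.seg_model <- function(x, ...) {
  tibble(variant = x$config$variant, base_width = x$config$base_width,
         depth = x$config$depth, n_params = n_params(x),
         input_h = (x$input_size %||% c(NA_integer_, NA_integer_))[1],
         input_w = (x$input_size %||% c(NA_integer_, NA_integer_))[2])
}
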
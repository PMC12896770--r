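# Model configuration and the shape calculus that makes the architecture
# auditable. The reference network has four conv blocks (channels
# 1->4->8->16->32, 3x3 kernel, padding 1, ReLU, 2x2 max pool) and fully
# connected layers 320 -> 128 -> 64 -> 2; depth-2/3/5 variants follow the
# same doubling schedule.

#' Flattened feature dimension after the convolutional stage
#'
#' Traces an input of `input_shape` through `n_conv_layers` same-padded 3x3
#' convolutions, each followed by 2x2 max pooling with floor division, and
#' returns `channels * height * width` of the final feature map. For the
#' 80x41 input and 4 layers this is `32 * 5 * 2 = 320`.
#'
#' @param input_shape Integer pair (mel bands, frames).
#' @param n_conv_layers Number of conv blocks (1 to 5).
#' @return Flatten dimension (count).
#' @export
flatten_dim <- function(input_shape = c(80L, 41L), n_conv_layers = 4L) {
  if (n_conv_layers < 1 || n_conv_layers > 5)
    stop("n_conv_layers must lie in [1, 5]")
  h <- input_shape[1]; w <- input_shape[2]
  ch <- 1L
  for (l in seq_len(n_conv_layers)) {
    ch <- if (l == 1) 4L else ch * 2L
    h <- h %/% 2L
    w <- w %/% 2L
    if (h == 0 || w == 0)
      stop("architecture error: spatial dimension reached 0 at layer ", l)
  }
  as.integer(ch * h * w)
}

#' CNN architecture configuration
#'
#' @param n_conv_layers Number of conv blocks (depth sweep uses 2-5;
#'   default 4, the reference architecture).
#' @param input_shape Input (bands, frames); fixed to 80x41 by the frontend.
#' @param n_classes Number of output classes.
#' @return A `model_config`: channel schedule, fully connected dimensions,
#'   kernel/pool geometry.
#' @export
model_config <- function(n_conv_layers = 4L, input_shape = c(80L, 41L),
                         n_classes = 2L) {
  n_conv_layers <- as.integer(n_conv_layers)
  fdim <- flatten_dim(input_shape, n_conv_layers)
  cfg <- list(
    n_conv_layers = n_conv_layers,
    input_shape = as.integer(input_shape),
    channel_schedule = c(1L, as.integer(4 * 2^(seq_len(n_conv_layers) - 1))),
    kernel = c(3L, 3L), padding = 1L, pool = c(2L, 2L),
    fc_dims = c(fdim, 128L, 64L, as.integer(n_classes)),
    n_classes = as.integer(n_classes))
  stopifnot(length(cfg$channel_schedule) == n_conv_layers + 1L,
            cfg$fc_dims[1] == fdim)
  class(cfg) <- "model_config"
  cfg
}

#' Build (initialize) a classifier from a configuration
#'
#' Weights use a seeded uniform fan-in scheme
#' (`U(-1/sqrt(fan_in), 1/sqrt(fan_in))`); two builds from the same seed are
#' identical.
#' @param config A [model_config()].
#' @param seed Initialization seed.
#' @return A `ddk_cnn` object (config + parameter list).
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  params <- cpp_cnn_init(config$channel_schedule, config$fc_dims,
                         as.integer(seed))
  structure(list(config = config, params = params, seed = as.integer(seed)),
            class = "ddk_cnn")
}

as_spec_array <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (length(dim(x)) != 3) stop("expected an 80x41xN array of spectrograms")
  x
}

#' Raw class scores for a batch of spectrograms
#' @param model A `ddk_cnn`.
#' @param x 80x41 matrix or 80x41xN array.
#' @return N x 2 score matrix (columns HC, PD).
#' @export
predict_scores <- function(model, x) {
  x <- as_spec_array(x)
  if (!all(dim(x)[1:2] == model$config$input_shape))
    stop("input shape ", paste(dim(x)[1:2], collapse = "x"),
         " does not match model input ",
         paste(model$config$input_shape, collapse = "x"))
  s <- cpp_cnn_forward(model$params, x)
  colnames(s) <- c("HC", "PD")
  s
}

#' Class probabilities for a batch of spectrograms
#'
#' Softmax of the class scores; each row is non-negative and sums to 1.
#' @inheritParams predict_scores
#' @return N x 2 probability matrix (columns HC, PD).
#' @export
predict_proba <- function(model, x) {
  s <- predict_scores(model, x)
  e <- exp(s - apply(s, 1, max))
  e / rowSums(e)
}

#' Number of trainable parameters
#' @param model A `ddk_cnn`.
#' @return Total count of weights and biases.
#' @export
n_params <- function(model) {
  sum(vapply(rapply(model$params, length, how = "unlist"), identity, numeric(1)))
}
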
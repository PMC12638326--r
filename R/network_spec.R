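#' Specification of the eight-block 3D convolutional age regressor
#'
#' The architecture has eight blocks: blocks 1-5 are 3x3x3 convolution
#' (zero padding 1), 3D batch normalisation, 2x2x2 max pooling (stride 2,
#' floor division) and ReLU; block 6 is a 1x1x1 convolution with batch
#' normalisation and ReLU; block 7 flattens the feature map, applies
#' dropout (training only) and a fully connected layer to a
#' `feature_dim`-entry vector; block 8 is a linear regression over the
#' features concatenated with the covariates (sex and scanner for a
#' single-map network), outputting a scalar predicted age.  With the
#' default channels `[32, 64, 128, 256, 256, 64]` and a 91 x 109 x 91
#' input, the spatial extent after block 6 is 2 x 3 x 2 and the block-7
#' output has 100 entries.
#'
#' Pooling uses floor division; axes already reduced to a single voxel are
#' passed through unchanged, so small desk-scale grids (e.g. 24 x 28 x 24)
#' remain usable.
#'
#' @param input_shape three voxel counts.
#' @param conv_channels six output channel counts for the six convolutions.
#' @param feature_dim length of the block-7 feature vector.
#' @param dropout_rate dropout fraction in block 7, training mode only.
#' @param normalise_input per-volume z-scoring before the first block.
#' @return object of class `network_spec`.
#' @export
network_spec <- function(input_shape = c(91L, 109L, 91L),
                         conv_channels = c(32L, 64L, 128L, 256L, 256L, 64L),
                         feature_dim = 100L,
                         dropout_rate = 0.5,
                         normalise_input = TRUE) {
  input_shape <- as.integer(input_shape)
  conv_channels <- as.integer(conv_channels)
  if (length(input_shape) != 3 || any(input_shape < 2))
    stop_wm("input_shape must be three axis lengths of at least 2 voxels")
  if (length(conv_channels) != 6 || any(conv_channels < 1))
    stop_wm("conv_channels must give six positive channel counts")
  if (feature_dim < 1) stop_wm("feature_dim must be at least 1")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop_wm("dropout_rate must lie in [0, 1)")
  structure(list(input_shape = input_shape,
                 conv_channels = conv_channels,
                 feature_dim = as.integer(feature_dim),
                 dropout_rate = dropout_rate,
                 normalise_input = isTRUE(normalise_input),
                 covariates_single = c("sex", "scanner"),
                 covariates_fusion = c("sex", "scanner", "icv")),
            class = "network_spec")
}

#' Narrow desk-scale network specification
#'
#' A reduced configuration (quarter-scale grid, narrow channels, small
#' feature vector) sized so that a full five-map training run completes in
#' minutes on one CPU core while preserving the eight-block structure.
#'
#' @param input_shape,conv_channels,feature_dim,dropout_rate see
#'   [network_spec()].
#' @return object of class `network_spec`.
#' @export
desk_network_spec <- function(input_shape = c(24L, 28L, 24L),
                              conv_channels = c(8L, 16L, 32L, 32L, 32L, 16L),
                              feature_dim = 16L,
                              dropout_rate = 0.5) {
  network_spec(input_shape = input_shape, conv_channels = conv_channels,
               feature_dim = feature_dim, dropout_rate = dropout_rate)
}

pool_dims <- function(d) ifelse(d > 1, d %/% 2L, 1L)

#' Layer-by-layer shape trace of the network
#'
#' @param spec a [network_spec()].
#' @return data.frame with one row per block giving output channels and
#'   spatial extent (blocks 7 and 8 report vector lengths).
#' @export
shape_trace <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  d <- spec$input_shape
  rows <- list()
  for (k in 1:5) {
    d <- pool_dims(d)  # conv is padded, pooling halves
    rows[[k]] <- data.frame(block = k, layer = "conv3-bn-pool-relu",
                            channels = spec$conv_channels[k],
                            d1 = d[1], d2 = d[2], d3 = d[3],
                            vector_length = NA_integer_)
  }
  rows[[6]] <- data.frame(block = 6L, layer = "conv1-bn-relu",
                          channels = spec$conv_channels[6],
                          d1 = d[1], d2 = d[2], d3 = d[3],
                          vector_length = NA_integer_)
  flat <- spec$conv_channels[6] * prod(d)
  rows[[7]] <- data.frame(block = 7L, layer = "flatten-dropout-fc",
                          channels = NA_integer_, d1 = NA_integer_,
                          d2 = NA_integer_, d3 = NA_integer_,
                          vector_length = spec$feature_dim)
  rows[[8]] <- data.frame(block = 8L, layer = "linear-regression",
                          channels = NA_integer_, d1 = NA_integer_,
                          d2 = NA_integer_, d3 = NA_integer_,
                          vector_length = 1L)
  out <- do.call(rbind, rows)
  attr(out, "flat_dim") <- flat
  out
}
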
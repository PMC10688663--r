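# User-facing building blocks: LHA attention, SSPDC pyramid convolution,
# index-preserving max pooling / unpooling, and bilinear upsampling.
# These operate on single H x W x C feature maps; the batched twins in
# nn-ops.R do the actual work.

#' Parameters of the lightweight hybrid attention (LHA) module
#'
#' The LHA module gates a feature map with a channel attention vector and a
#' spatial attention map, both sigmoid-bounded in (0, 1).  Its learnable
#' parameters are a shared length-3 kernel for the 1-D convolution along the
#' channel axis (applied to both the max-pooled and mean-pooled channel
#' descriptors) plus one bias, and a 7x7 kernel with bias for the spatial
#' branch.
#'
#' @param channel_kernel numeric length-3 weight vector of the channel-axis
#'   1-D convolution.
#' @param channel_bias single bias added to the channel attention logits.
#' @param spatial_kernel 7x7 numeric matrix for the spatial branch.
#' @param spatial_bias single bias added to the spatial attention logits.
#' @return An object of class `"lha_params"`.
#' @examples
#' p <- lha_params(channel_kernel = c(0, 1, 0))
#' channel_attention(array(0, c(4, 4, 5)), p)
#' @export
lha_params <- function(channel_kernel = c(0, 1, 0), channel_bias = 0,
                       spatial_kernel = matrix(0, 7, 7), spatial_bias = 0) {
  channel_kernel <- as.numeric(channel_kernel)
  if (length(channel_kernel) != 3L)
    stop("`channel_kernel` must have length 3")
  spatial_kernel <- as.matrix(spatial_kernel)
  if (!all(dim(spatial_kernel) == c(7L, 7L)))
    stop("`spatial_kernel` must be a 7 x 7 matrix")
  stopifnot(length(channel_bias) == 1L, length(spatial_bias) == 1L,
            all(is.finite(channel_kernel)), all(is.finite(spatial_kernel)),
            is.finite(channel_bias), is.finite(spatial_bias))
  structure(list(channel_kernel = channel_kernel,
                 channel_bias = as.numeric(channel_bias),
                 spatial_kernel = spatial_kernel,
                 spatial_bias = as.numeric(spatial_bias)),
            class = "lha_params")
}

#' Channel attention vector of the LHA module
#'
#' Computes, per channel, the global max and global mean of the feature map,
#' runs the shared zero-padded 1-D convolution along the channel axis over
#' both descriptors, sums them with the bias and applies a sigmoid.  Every
#' weight therefore lies strictly in (0, 1).
#'
#' @param fm an H x W x C numeric array (an H x W matrix is taken as C = 1).
#' @param params an [lha_params()] object.
#' @return Numeric vector of length C with entries in (0, 1).
#' @export
channel_attention <- function(fm, params = lha_params()) {
  fm <- as_feature_map(fm)
  stopifnot(inherits(params, "lha_params"))
  dm <- dim(fm)
  M <- dm[1] * dm[2]
  xm <- array(fm, c(M, dm[3]))
  mx <- matrix(apply(xm, 2, max), ncol = 1)
  av <- matrix(colMeans(xm), ncol = 1)
  s <- conv1d_k3(mx, params$channel_kernel) +
    conv1d_k3(av, params$channel_kernel) + params$channel_bias
  as.vector(sigmoid(s))
}

#' Spatial attention map of the LHA module
#'
#' Adds the per-pixel channel-wise max map and mean map, convolves the sum
#' with a same-padded 7x7 kernel and applies a sigmoid, yielding an H x W
#' map of weights strictly in (0, 1).
#'
#' @inheritParams channel_attention
#' @return H x W numeric matrix with entries in (0, 1).
#' @export
spatial_attention <- function(fm, params = lha_params()) {
  fm <- as_feature_map(fm)
  stopifnot(inherits(params, "lha_params"))
  dm <- dim(fm)
  C <- dm[3]
  mmax <- fm[, , 1]
  if (C > 1L) for (c in 2:C) mmax <- pmax(mmax, fm[, , c])
  mavg <- apply(fm, c(1, 2), mean)
  smap <- array(mmax + mavg, c(dm[1], dm[2], 1L, 1L))
  conv <- nn_conv2d_fwd(smap, array(params$spatial_kernel, c(7L, 7L, 1L, 1L)),
                        b = params$spatial_bias)
  matrix(sigmoid(conv$y), dm[1], dm[2])
}

#' Apply the lightweight hybrid attention module
#'
#' Rescales the feature map by its channel attention vector (broadcast over
#' space) and its spatial attention map (broadcast over channels):
#' `out = fm * ca(fm) * sa(fm)`.  Because both gates lie in (0, 1), the
#' module never increases the magnitude of any activation.
#'
#' @inheritParams channel_attention
#' @return Array with the same dimensions as `fm`.
#' @export
apply_lha <- function(fm, params = lha_params()) {
  fm <- as_feature_map(fm)
  dm <- dim(fm)
  ca <- channel_attention(fm, params)
  sa <- spatial_attention(fm, params)
  fm * rep(ca, each = dm[1] * dm[2]) * as.vector(sa)
}

#' Parameters of the separable spatial pyramid dilated convolution (SSPDC)
#'
#' SSPDC runs three 3x3 depthwise convolutions at dilation rates 1, 2 and 3
#' (effective receptive fields 3x3, 5x5 and 7x7), concatenates the branch
#' outputs along the channel axis, and fuses them with a 1x1 pointwise
#' convolution from `3 * c_in` to `c_out` channels with a per-output bias.
#'
#' @param c_in,c_out input and output channel counts.
#' @param dw list of three 3 x 3 x `c_in` depthwise kernel arrays (one per
#'   dilation branch).  Defaults to identity kernels (centre tap 1).
#' @param pw pointwise weight matrix of dimension `3 * c_in` x `c_out`.
#'   Defaults to averaging the three branch copies of each input channel
#'   when `c_out == c_in`, else zeros.
#' @param bias numeric vector of length `c_out`.
#' @return An object of class `"sspdc_params"`.
#' @export
sspdc_params <- function(c_in, c_out = c_in, dw = NULL, pw = NULL,
                         bias = rep(0, c_out)) {
  c_in <- as.integer(c_in); c_out <- as.integer(c_out)
  stopifnot(c_in >= 1L, c_out >= 1L)
  if (is.null(dw)) {
    ident <- array(0, c(3, 3, c_in)); ident[2, 2, ] <- 1
    dw <- list(ident, ident, ident)
  }
  if (length(dw) != 3L) stop("`dw` must list exactly three depthwise kernels")
  for (k in dw) if (!all(dim(k) == c(3L, 3L, c_in)))
    stop("each depthwise kernel must be 3 x 3 x c_in")
  if (is.null(pw)) {
    pw <- matrix(0, 3L * c_in, c_out)
    if (c_out == c_in)
      for (b in 0:2) pw[cbind(b * c_in + seq_len(c_in), seq_len(c_in))] <- 1 / 3
  }
  pw <- as.matrix(pw)
  if (!all(dim(pw) == c(3L * c_in, c_out)))
    stop("`pw` must be (3 * c_in) x c_out")
  if (length(bias) != c_out) stop("`bias` must have length c_out")
  structure(list(c_in = c_in, c_out = c_out, dw = dw, pw = pw,
                 bias = as.numeric(bias)),
            class = "sspdc_params")
}

#' Forward pass of the SSPDC block
#'
#' @param fm an H x W x C numeric array with C equal to `params$c_in`.
#' @param params an [sspdc_params()] object.
#' @return H x W x `c_out` array; the spatial shape is preserved (same-size
#'   zero padding in every branch).
#' @examples
#' x <- array(rnorm(8 * 8 * 5), c(8, 8, 5))
#' dim(sspdc_forward(x, sspdc_params(5, 8)))
#' @export
sspdc_forward <- function(fm, params) {
  fm <- as_feature_map(fm)
  stopifnot(inherits(params, "sspdc_params"))
  if (dim(fm)[3] != params$c_in)
    stop(sprintf("feature map has %d channels but params expect %d",
                 dim(fm)[3], params$c_in))
  out <- nn_sspdc_fwd(fm_batch1(fm), params$dw[[1]], params$dw[[2]],
                      params$dw[[3]], params$pw, params$bias)
  array(out$y, dim(out$y)[1:3])
}

#' Max pooling with stored argmax indices
#'
#' 2x2 stride-2 max pooling.  Ties within a window break to the first
#' occurrence in row-major order (top-left, top-right, bottom-left,
#' bottom-right).  The returned indices are 0-based (row, col) positions on
#' the pre-pool grid, one per pooled cell and channel, for later use by
#' [max_unpool()].
#'
#' @param fm an H x W x C array with even H and W.
#' @return List with `values` (H/2 x W/2 x C array) and `indices`, itself a
#'   list of integer arrays `row` and `col` of the same shape as `values`.
#' @export
maxpool_with_indices <- function(fm) {
  fm <- as_feature_map(fm)
  out <- nn_maxpool_fwd(fm_batch1(fm))
  dmo <- dim(out$y)[1:3]
  code <- array(out$code, dmo)
  vals <- array(out$y, dmo)
  row0 <- (slice.index(code, 1) - 1L) * 2L + as.integer(code >= 3L)
  col0 <- (slice.index(code, 2) - 1L) * 2L + as.integer(code %in% c(2L, 4L))
  list(values = vals,
       indices = list(row = array(as.integer(row0), dmo),
                      col = array(as.integer(col0), dmo)))
}

#' Sparse unpooling from stored max-pooling indices
#'
#' Doubles the spatial size, placing each pooled value at its recorded
#' argmax position and zeros everywhere else.  This is the SegNet-style
#' decoder upsampling that replaces learned deconvolution.  Because the
#' remaining positions are zero-filled, pooling the result recovers the
#' input exactly on non-negative maps (which is what the ReLU stages feed
#' to the pooling layers).
#'
#' @param fm pooled values, an h x w x C array (or matrix).
#' @param indices the `indices` element returned by [maxpool_with_indices()].
#' @return A 2h x 2w x C array.
#' @export
max_unpool <- function(fm, indices) {
  fm <- as_feature_map(fm)
  dm <- dim(fm)
  row <- indices$row; col <- indices$col
  if (is.matrix(row)) row <- array(row, c(dim(row), 1L))
  if (is.matrix(col)) col <- array(col, c(dim(col), 1L))
  if (!all(dim(row) == dm) || !all(dim(col) == dm))
    stop("index geometry does not match the pooled feature map")
  cell_r <- (slice.index(fm, 1) - 1L) * 2L
  cell_c <- (slice.index(fm, 2) - 1L) * 2L
  dr <- row - cell_r; dc <- col - cell_c
  if (any(dr < 0L | dr > 1L | dc < 0L | dc > 1L))
    stop("stored index lies outside its 2x2 pooling window")
  code <- 1L + dc + 2L * dr
  out <- nn_unpool_fwd(fm_batch1(fm), array(code, c(dm, 1L)))
  array(out$y, dim(out$y)[1:3])
}

#' Bilinear 2x upsampling
#'
#' Doubles H and W by separable bilinear interpolation using the half-pixel
#' centre convention (output sample i reads source coordinate
#' (i + 0.5)/2 - 0.5, clamped at the borders).  No learned parameters.
#'
#' @param fm an H x W x C array (or H x W matrix).
#' @return A 2H x 2W x C array.
#' @export
bilinear_upsample2x <- function(fm) {
  fm <- as_feature_map(fm)
  out <- nn_bilinear2x_fwd(fm_batch1(fm))
  array(out$y, dim(out$y)[1:3])
}
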
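# Channel attention operators. Feature maps are H x W x C numeric arrays.
# Two flavours are provided:
#   * squeeze-excitation (SE): global average pool -> bottleneck MLP
#     (C -> C/r -> C, ReLU then sigmoid) -> per-channel rescaling. Used in
#     the shallow backbone stages, where it emphasises channels carrying
#     strong morphological cues.
#   * efficient channel attention (ECA): the bottleneck is replaced by a
#     single bias-free 1-D convolution across the channel statistic, with
#     kernel size chosen adaptively from the channel count. Used on the
#     three neck outputs feeding the prediction heads.
# Both are purely channel-wise: they multiply every channel by a scalar in
# (0,1), so they preserve shape, bound the output by the input, and commute
# with any spatial permutation.

#' Global average pooling of a feature map
#'
#' Reduces an `H x W x C` feature map to the length-`C` vector of
#' per-channel means (the "channel statistic").
#'
#' @param x Numeric `H x W x C` array.
#' @return Numeric vector of length `C`.
#' @export
global_average_pool <- function(x) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  apply(x, 3, mean)
}

#' Parameters of a squeeze-excitation block
#'
#' Two bias-free dense maps `W1: C -> C/r` and `W2: C/r -> C`, initialized
#' with small seeded uniform values. The bottleneck width is floored at 1
#' so the block is defined for any channel count.
#'
#' @param C Channel count.
#' @param r Reduction rate (default 16).
#' @param seed Seed for initialization.
#' @return List with `W1`, `W2`, `r`.
#' @export
se_params <- function(C, r = 16L, seed = 1L) {
  stopifnot(C >= 1, r >= 1)
  Cr <- max(1L, C %/% r)
  with_seed(seed, {
    lim1 <- sqrt(6 / C); lim2 <- sqrt(6 / Cr)
    list(W1 = matrix(runif(Cr * C, -lim1, lim1), Cr, C),
         W2 = matrix(runif(C * Cr, -lim2, lim2), C, Cr),
         r = as.integer(r))
  })
}

#' Squeeze-excitation gating
#'
#' Computes per-channel weights `sigmoid(W2 %*% relu(W1 %*% z))` from a
#' channel statistic `z`.
#'
#' @param z Numeric vector of length `C`.
#' @param params Parameters from [se_params()].
#' @return Numeric vector of channel weights, each strictly in (0, 1).
#' @export
se_excite <- function(z, params) {
  if (length(z) != ncol(params$W1)) {
    stop("shape error: statistic length ", length(z), " does not match W1 (",
         ncol(params$W1), " columns)")
  }
  a <- pmax(params$W1 %*% z, 0)
  as.numeric(sigmoid(params$W2 %*% a))
}

#' Squeeze-excitation channel attention
#'
#' Rescales each channel of the (already convolved) feature map by its
#' excitation weight: `out[,,c] = w_c * x[,,c]`.
#'
#' @param x Numeric `H x W x C` feature map.
#' @param params Parameters from [se_params()].
#' @return A feature map of identical shape.
#' @export
se_attention <- function(x, params) {
  w <- se_excite(global_average_pool(x), params)
  scale_channels(x, w)
}

scale_channels <- function(x, w) {
  d <- dim(x)
  stopifnot(length(w) == d[3])
  x * rep(w, each = d[1] * d[2])
}

#' Adaptive 1-D kernel size for efficient channel attention
#'
#' `k = || log2(C)/gamma + b/gamma ||_odd`: the odd integer nearest to
#' `log2(C)/gamma + b/gamma`, with even integers and exact ties resolved
#' upward, floored at 1. Non-decreasing in `C`.
#'
#' @param C Channel count (>= 1).
#' @param gamma,b Mapping constants (defaults 2 and 1).
#' @return An odd integer kernel size.
#' @export
#' @examples
#' eca_kernel_size(2)    # 1
#' eca_kernel_size(16)   # 3
#' eca_kernel_size(256)  # 5
eca_kernel_size <- function(C, gamma = 2L, b = 1L) {
  if (!is.numeric(C) || length(C) != 1L || C < 1) {
    stop("domain error: C must be a single integer >= 1")
  }
  psi <- log2(C) / gamma + b / gamma
  lo <- 2L * floor((psi - 1) / 2) + 1L  # largest odd <= psi (or next below)
  hi <- lo + 2L
  k <- if ((psi - lo) < (hi - psi)) lo else hi  # ties go up
  max(1L, as.integer(k))
}

#' Kernel of an efficient-channel-attention block
#'
#' A single bias-free 1-D convolution filter of length
#' [eca_kernel_size()]`(C)`, initialized with small seeded uniform values.
#'
#' @param C Channel count.
#' @param seed Seed for initialization.
#' @param gamma,b Passed to [eca_kernel_size()].
#' @return Numeric vector (the kernel).
#' @export
eca_params <- function(C, seed = 1L, gamma = 2L, b = 1L) {
  k <- eca_kernel_size(C, gamma, b)
  with_seed(seed, runif(k, -sqrt(6 / k), sqrt(6 / k)))
}

# Zero-padded 1-D convolution of a vector with a shared kernel of odd
# length k; output length equals input length.
conv1d_channel <- function(z, kernel) {
  k <- length(kernel)
  stopifnot(k %% 2 == 1)
  half <- (k - 1L) / 2L
  zp <- c(rep(0, half), z, rep(0, half))
  out <- numeric(length(z))
  for (j in seq_len(k)) {
    out <- out + kernel[j] * zp[seq_along(z) + (j - 1L)]
  }
  out
}

#' Efficient channel attention
#'
#' Pools the feature map to its channel statistic, convolves the statistic
#' with a single shared 1-D kernel (zero-padded so each channel interacts
#' with its `k`-neighborhood only), applies a sigmoid, and rescales the
#' channels by the resulting weights.
#'
#' @param x Numeric `H x W x C` feature map.
#' @param kernel 1-D kernel (odd length); default [eca_params()] for the
#'   map's channel count.
#' @return A feature map of identical shape.
#' @export
eca_attention <- function(x, kernel = NULL) {
  C <- dim(x)[3]
  if (is.null(kernel)) kernel <- eca_params(C)
  z <- global_average_pool(x)
  w <- sigmoid(conv1d_channel(z, kernel))
  scale_channels(x, w)
}
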
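# Convolutional block attention over 1D latents: channel attention (which
# channels matter) followed by spatial attention (which positions matter).
# Both produce multiplicative sigmoid weights in (0,1); the stages are also
# exposed as standalone functional operations for inspection and testing.

#' Construct a channel-attention module
#'
#' Shared two-layer MLP (no biases) applied to the average-pooled and
#' max-pooled per-channel summaries; hidden width is
#' `max(channels %/% ratio, 1)` with ReLU activation, the second layer is
#' linear, and the two paths are summed before the sigmoid.
#'
#' @param channels Number of channels of the attended tensor.
#' @param ratio Reduction divisor for the MLP hidden width (default 8).
#' @param seed Integer seed for weight initialization.
#' @param init `"glorot"` (default) or `"zero"` (useful for the analytic
#'   zero-weight fixtures: all maps equal 0.5).
#' @return Object of class `channel_attention` with weights `W0`
#'   (channels x hidden) and `W1` (hidden x channels).
#' @export
channel_attention_module <- function(channels, ratio = 8L, seed = 1L,
                                     init = c("glorot", "zero")) {
  init <- match.arg(init)
  hidden <- max(channels %/% ratio, 1L)
  set.seed(as.integer(seed))
  if (init == "zero") {
    W0 <- matrix(0, channels, hidden)
    W1 <- matrix(0, hidden, channels)
  } else {
    W0 <- glorot_init(c(channels, hidden), channels, hidden)
    W1 <- glorot_init(c(hidden, channels), hidden, channels)
  }
  structure(list(W0 = W0, W1 = W1, ratio = as.integer(ratio),
                 hidden = hidden),
            class = "channel_attention")
}

#' Construct a spatial-attention module
#'
#' A single-output-channel, same-padded 1D convolution (no bias) over the
#' stacked per-position channel mean and channel max.
#'
#' @param kernel_size Odd convolution kernel length (default 7).
#' @param seed Integer seed.
#' @param init `"glorot"` or `"zero"`.
#' @return Object of class `spatial_attention` with weights `W`
#'   (kernel_size x 2 x 1).
#' @export
spatial_attention_module <- function(kernel_size = 7L, seed = 1L,
                                     init = c("glorot", "zero")) {
  init <- match.arg(init)
  kernel_size <- as.integer(kernel_size)
  if (kernel_size %% 2L == 0L) stop("kernel_size must be odd")
  set.seed(as.integer(seed))
  W <- if (init == "zero") array(0, c(kernel_size, 2L, 1L))
       else glorot_init(c(kernel_size, 2L, 1L), 2L * kernel_size, kernel_size)
  structure(list(W = W, kernel_size = kernel_size),
            class = "spatial_attention")
}

as_batch3 <- function(F) {
  if (is.matrix(F)) array(F, c(1L, nrow(F), ncol(F))) else F
}

# ---- channel stage ---------------------------------------------------------

channel_stage_fw <- function(F, W0, W1) {
  dn <- dim(F)
  n <- dn[1]; L <- dn[2]; C <- dn[3]
  Fm <- aperm(F, c(2, 1, 3))
  dim(Fm) <- c(L, n * C)
  avg <- matrix(colMeans(Fm), n, C)
  mx <- matrix(F[, 1, ], n, C)
  argm <- matrix(1L, n, C)
  if (L > 1) {
    for (l in 2:L) {
      cand <- matrix(F[, l, ], n, C)
      upd <- cand > mx
      mx[upd] <- cand[upd]
      argm[upd] <- l
    }
  }
  ha_pre <- avg %*% W0; ha <- pmax(ha_pre, 0)
  hm_pre <- mx %*% W0; hm <- pmax(hm_pre, 0)
  z <- ha %*% W1 + hm %*% W1
  cmap <- sigmoid(z)
  Carr <- aperm(array(cmap, c(n, C, L)), c(1, 3, 2))
  list(Y = F * Carr, map = cmap,
       cache = list(F = F, avg = avg, mx = mx, argm = argm, ha = ha, hm = hm,
                    ha_pre = ha_pre, hm_pre = hm_pre, cmap = cmap,
                    Carr = Carr, W0 = W0, W1 = W1, n = n, L = L, C = C))
}

channel_stage_bw <- function(cache, dY) {
  cc <- cache
  n <- cc$n; L <- cc$L; C <- cc$C
  # split into the direct multiplicative path and the path through the map
  prod_ <- aperm(dY * cc$F, c(2, 1, 3))
  dim(prod_) <- c(L, n * C)
  dmap <- matrix(colSums(prod_), n, C)
  dF <- dY * cc$Carr
  dz <- dmap * cc$cmap * (1 - cc$cmap)
  dW1 <- crossprod(cc$ha, dz) + crossprod(cc$hm, dz)
  dha <- (dz %*% t(cc$W1)) * (cc$ha_pre > 0)
  dhm <- (dz %*% t(cc$W1)) * (cc$hm_pre > 0)
  dW0 <- crossprod(cc$avg, dha) + crossprod(cc$mx, dhm)
  davg <- dha %*% t(cc$W0)
  dmx <- dhm %*% t(cc$W0)
  dF <- dF + aperm(array(davg / L, c(n, C, L)), c(1, 3, 2))
  for (l in seq_len(L)) {
    dF[, l, ] <- matrix(dF[, l, ], n, C) + dmx * (cc$argm == l)
  }
  list(dF = dF, dW0 = dW0, dW1 = dW1)
}

# ---- spatial stage ---------------------------------------------------------

spatial_stage_fw <- function(F, W) {
  dn <- dim(F)
  n <- dn[1]; L <- dn[2]; C <- dn[3]
  Fm <- F
  dim(Fm) <- c(n * L, C)
  savg <- matrix(rowMeans(Fm), n, L)
  smx <- matrix(Fm[, 1], n, L)
  argm <- matrix(1L, n, L)
  if (C > 1) {
    for (ch in 2:C) {
      cand <- matrix(Fm[, ch], n, L)
      upd <- cand > smx
      smx[upd] <- cand[upd]
      argm[upd] <- ch
    }
  }
  P <- array(0, c(n, L, 2L))
  P[, , 1] <- savg
  P[, , 2] <- smx
  cv <- conv1d_fw(P, W, b = 0, stride = 1L, pad = "same")
  smap <- matrix(cv$Y, n, L)
  smap <- sigmoid(smap)
  Sarr <- array(smap, c(n, L, C))
  list(Y = F * Sarr, map = smap,
       cache = list(F = F, argm = argm, smap = smap, Sarr = Sarr,
                    conv = cv$cache, n = n, L = L, C = C))
}

spatial_stage_bw <- function(cache, dY) {
  cc <- cache
  n <- cc$n; L <- cc$L; C <- cc$C
  prod_ <- dY * cc$F
  dim(prod_) <- c(n * L, C)
  dmap <- matrix(rowSums(prod_), n, L)
  dF <- dY * cc$Sarr
  dz <- dmap * cc$smap * (1 - cc$smap)
  dim(dz) <- c(n, L, 1L)
  cb <- conv1d_bw(cc$conv, dz)
  dP <- cb$dX
  dF <- dF + array(dP[, , 1] / C, c(n, L, C))
  dsmx <- matrix(dP[, , 2], n, L)
  for (ch in seq_len(C)) {
    dF[, , ch] <- matrix(dF[, , ch], n, L) + dsmx * (cc$argm == ch)
  }
  list(dF = dF, dW = cb$dW)
}

cbam_fw <- function(F, W0, W1, Wsp, order = c("channel_first",
                                              "spatial_first")) {
  order <- match.arg(order)
  if (order == "channel_first") {
    s1 <- channel_stage_fw(F, W0, W1)
    s2 <- spatial_stage_fw(s1$Y, Wsp)
  } else {
    s1 <- spatial_stage_fw(F, Wsp)
    s2 <- channel_stage_fw(s1$Y, W0, W1)
  }
  list(Y = s2$Y, cache = list(s1 = s1$cache, s2 = s2$cache, order = order))
}

cbam_bw <- function(cache, dY) {
  if (cache$order == "channel_first") {
    b2 <- spatial_stage_bw(cache$s2, dY)
    b1 <- channel_stage_bw(cache$s1, b2$dF)
    list(dF = b1$dF, dW0 = b1$dW0, dW1 = b1$dW1, dWsp = b2$dW)
  } else {
    b2 <- channel_stage_bw(cache$s2, dY)
    b1 <- spatial_stage_bw(cache$s1, b2$dF)
    list(dF = b1$dF, dW0 = b2$dW0, dW1 = b2$dW1, dWsp = b1$dW)
  }
}

#' Channel attention map
#'
#' Per-channel average pool and max pool over positions, each passed through
#' the module's shared two-layer MLP, summed, and mapped through a sigmoid.
#'
#' @param F A positions x channels matrix (one sample) or an
#'   `(n, positions, channels)` array.
#' @param module A [channel_attention_module()].
#' @return Vector over channels in (0,1) (matrix `n x channels` for batched
#'   input).
#' @export
channel_attention <- function(F, module) {
  stopifnot(inherits(module, "channel_attention"))
  single <- is.matrix(F)
  out <- channel_stage_fw(as_batch3(F), module$W0, module$W1)$map
  if (single) drop(out) else out
}

#' Spatial attention map
#'
#' Per-position channel mean and channel max stacked into a two-channel
#' sequence, convolved (same-padded, single output channel) and mapped
#' through a sigmoid.
#'
#' @param F A positions x channels matrix or an `(n, positions, channels)`
#'   array.
#' @param module A [spatial_attention_module()].
#' @return Vector over positions in (0,1) (matrix `n x positions` for
#'   batched input).
#' @export
spatial_attention <- function(F, module) {
  stopifnot(inherits(module, "spatial_attention"))
  single <- is.matrix(F)
  out <- spatial_stage_fw(as_batch3(F), module$W)$map
  if (single) drop(out) else out
}

#' Apply the full attention block
#'
#' Channel attention then spatial attention (the reversed order is available
#' behind `order = "spatial_first"` for ablation only): `F' = C(F) * F`
#' broadcast over positions, `F'' = S(F') * F'` broadcast over channels.
#' Output shape equals input shape.
#'
#' @param F A positions x channels matrix or `(n, positions, channels)`
#'   array.
#' @param ca A [channel_attention_module()].
#' @param sa A [spatial_attention_module()].
#' @param order `"channel_first"` (default) or `"spatial_first"`.
#' @return Tensor of the same shape as `F`.
#' @export
apply_cbam <- function(F, ca, sa, order = c("channel_first",
                                            "spatial_first")) {
  stopifnot(inherits(ca, "channel_attention"),
            inherits(sa, "spatial_attention"))
  order <- match.arg(order)
  single <- is.matrix(F)
  out <- cbam_fw(as_batch3(F), ca$W0, ca$W1, sa$W, order)$Y
  if (single) matrix(out[1, , ], dim(out)[2], dim(out)[3]) else out
}
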
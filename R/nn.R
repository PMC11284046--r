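# Internal neural-network primitives: batched 1D layers with hand-derived
# backward passes. Batch tensors are arrays (n_samples, length, channels);
# dense activations are (n_samples, width) matrices. All randomness goes
# through R's RNG so runs are reproducible from a seed.

#' Gaussian Error Linear Unit
#'
#' Tanh approximation
#' `0.5 * x * (1 + tanh(sqrt(2/pi) * (x + 0.044715 * x^3)))`, applied
#' elementwise. Used as the activation of the convolutional, transposed
#' convolutional and hidden dense layers.
#'
#' @param x Numeric vector/array.
#' @return Same shape as `x`.
#' @examples
#' gelu(0)  # 0
#' gelu(1)  # 0.841192
#' @export
gelu <- function(x) {
  0.5 * x * (1 + tanh(sqrt(2 / pi) * (x + 0.044715 * x^3)))
}

# derivative of the tanh-approximate GELU
gelu_grad <- function(x) {
  c0 <- sqrt(2 / pi)
  u <- c0 * (x + 0.044715 * x^3)
  th <- tanh(u)
  0.5 * (1 + th) + 0.5 * x * (1 - th^2) * c0 * (1 + 3 * 0.044715 * x^2)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Glorot/Xavier uniform initialization
glorot_init <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

# ---- dense -----------------------------------------------------------------

dense_fw <- function(X, W, b) {
  Y <- X %*% W
  Y + rep(b, each = nrow(Y))
}

dense_bw <- function(X, W, dY, need_dx = TRUE) {
  list(dX = if (need_dx) tcrossprod(dY, W), dW = crossprod(X, dY),
       db = colSums(dY))
}

# ---- conv1d ----------------------------------------------------------------

# X: (n, L, Cin); W: (f, Cin, Cout); b: length Cout.
# Same-padding follows the ceil(L / stride) rule, extra zero on the right.
conv1d_fw <- function(X, W, b, stride, pad = c("same", "explicit"),
                      pad_l = 0L, pad_r = 0L) {
  pad <- match.arg(pad)
  dn <- dim(X)
  n <- dn[1]; L <- dn[2]; Cin <- dn[3]
  f <- dim(W)[1]; Cout <- dim(W)[3]
  if (dim(W)[2] != Cin) stop("conv1d: channel mismatch")
  if (pad == "same") {
    L_out <- as.integer(ceiling(L / stride))
    tot <- max((L_out - 1L) * stride + f - L, 0L)
    pad_l <- tot %/% 2L
    pad_r <- tot - pad_l
  } else {
    L_out <- (L + pad_l + pad_r - f) %/% stride + 1L
    if (L_out < 1) stop("conv1d: output length < 1")
  }
  Lp <- L + pad_l + pad_r
  Xp <- array(0, c(n, Lp, Cin))
  Xp[, pad_l + seq_len(L), ] <- X
  I <- outer(0:(f - 1L), (seq_len(L_out) - 1L) * stride + 1L, "+") # f x L_out
  Xg <- Xp[, as.vector(I), , drop = FALSE]
  dim(Xg) <- c(n, f, L_out, Cin)
  Xg2 <- aperm(Xg, c(1, 3, 2, 4))
  dim(Xg2) <- c(n * L_out, f * Cin)
  Y <- Xg2 %*% matrix(W, f * Cin, Cout)
  Y <- Y + rep(b, each = n * L_out)
  dim(Y) <- c(n, L_out, Cout)
  list(Y = Y,
       cache = list(Xg2 = Xg2, I = I, pad_l = pad_l, n = n, L = L, Lp = Lp,
                    L_out = L_out, f = f, Cin = Cin, Cout = Cout,
                    W = W))
}

conv1d_bw <- function(cache, dY) {
  cc <- cache
  dYm <- dY
  dim(dYm) <- c(cc$n * cc$L_out, cc$Cout)
  dW <- crossprod(cc$Xg2, dYm)
  dim(dW) <- c(cc$f, cc$Cin, cc$Cout)
  db <- colSums(dYm)
  dXg2 <- tcrossprod(dYm, matrix(cc$W, cc$f * cc$Cin, cc$Cout))
  dim(dXg2) <- c(cc$n, cc$L_out, cc$f, cc$Cin)
  dXg <- aperm(dXg2, c(1, 3, 2, 4)) # n, f, L_out, Cin
  dXp <- array(0, c(cc$n, cc$Lp, cc$Cin))
  for (j in seq_len(cc$f)) {
    pos <- cc$I[j, ]
    dXp[, pos, ] <- dXp[, pos, ] + dXg[, j, , ]
  }
  dX <- dXp[, cc$pad_l + seq_len(cc$L), , drop = FALSE]
  list(dX = dX, dW = dW, db = db)
}

# ---- max pooling (window = stride = p, floor division) ---------------------

maxpool_fw <- function(X, p) {
  dn <- dim(X)
  n <- dn[1]; L <- dn[2]; C <- dn[3]
  Lo <- L %/% p
  if (Lo < 1) stop("maxpool: pool size exceeds length")
  Y <- X[, seq(1L, by = p, length.out = Lo), , drop = FALSE]
  arg <- array(1L, c(n, Lo, C))
  if (p > 1) {
    for (j in 2:p) {
      cand <- X[, seq(j, by = p, length.out = Lo), , drop = FALSE]
      upd <- cand > Y
      Y[upd] <- cand[upd]
      arg[upd] <- j
    }
  }
  list(Y = Y, cache = list(arg = arg, p = p, n = n, L = L, Lo = Lo, C = C))
}

maxpool_bw <- function(cache, dY) {
  cc <- cache
  dX <- array(0, c(cc$n, cc$L, cc$C))
  for (j in seq_len(cc$p)) {
    dX[, seq(j, by = cc$p, length.out = cc$Lo), ] <- dY * (cc$arg == j)
  }
  dX
}

# ---- upsampling (repeat each position r times) -----------------------------

upsample_fw <- function(X, r) {
  L <- dim(X)[2]
  X[, rep(seq_len(L), each = r), , drop = FALSE]
}

upsample_bw <- function(dY, r) {
  dn <- dim(dY)
  n <- dn[1]; C <- dn[3]; L <- dn[2] %/% r
  dim(dY) <- c(n, r, L, C)
  colSums(aperm(dY, c(2, 1, 3, 4)))
}

# ---- transposed convolution ------------------------------------------------
# Realized as zero-dilation by the stride (+ output padding stride-1) followed
# by a stride-1 convolution with padding kernel-1-p per side; equivalent to
# conv1DTranspose with output length stride * in_len for odd kernels with
# p = (kernel-1)/2.

tconv_fw <- function(X, W, b, stride) {
  dn <- dim(X)
  n <- dn[1]; L <- dn[2]; Cin <- dn[3]
  f <- dim(W)[1]
  p <- (f - 1L) %/% 2L
  Ld <- stride * (L - 1L) + 1L + (stride - 1L) # incl. output padding
  Xd <- array(0, c(n, Ld, Cin))
  pos <- seq(1L, by = stride, length.out = L)
  Xd[, pos, ] <- X
  cv <- conv1d_fw(Xd, W, b, stride = 1L, pad = "explicit",
                  pad_l = f - 1L - p, pad_r = f - 1L - p)
  cv$cache$tconv <- list(stride = stride, L = L, pos = pos)
  cv
}

tconv_bw <- function(cache, dY) {
  bw <- conv1d_bw(cache, dY)
  tc <- cache$tconv
  bw$dX <- bw$dX[, tc$pos, , drop = FALSE]
  bw
}
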
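# Multi-branch 1D convolutional autoencoder with an attention block between
# the encoders and decoders. Each omics block gets its own encoder/decoder
# branch; branch latents (which share a channel count) are concatenated
# along the position axis, refined by the shared attention block, split back
# and decoded. Training minimizes half the mean squared reconstruction
# error plus an L2 penalty on the trainable weights.

#' Build a (multi-branch) convolutional autoencoder
#'
#' One branch per omics block: dense layers with GELU, reshape to a
#' single-channel sequence, then Conv1D(+GELU)+MaxPool blocks down to the
#' latent. The decoder mirrors each branch (UpSample + transposed
#' convolution with GELU, a final single-filter transposed convolution
#' collapsing channels, then dense layers; the width-restoring output layer
#' is linear). When `attention = TRUE` a channel+spatial attention block is
#' inserted between the concatenated encoder latents and the decoders and
#' is trained jointly with the autoencoder.
#'
#' @param specs An [arch_spec()] or list of them, one per omics block. All
#'   branches must end in the same channel count.
#' @param input_dims Integer vector of per-block feature widths.
#' @param attention Attach the attention block? Default `TRUE`.
#' @param ratio Channel-attention MLP reduction divisor (default 8; hidden
#'   width is floored at 1).
#' @param sa_kernel Spatial-attention kernel length (odd, default 7).
#' @param attention_order `"channel_first"` (default) or `"spatial_first"`
#'   (ablation only).
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `caem_model` (untrained; `training_log` is
#'   empty).
#' @export
build_cae <- function(specs, input_dims, attention = TRUE, ratio = 8L,
                      sa_kernel = 7L, attention_order = c("channel_first",
                                                          "spatial_first"),
                      seed = 1L) {
  attention_order <- match.arg(attention_order)
  if (inherits(specs, "arch_spec")) specs <- list(specs)
  input_dims <- as.integer(input_dims)
  stopifnot(length(specs) == length(input_dims), length(specs) >= 1)
  traces <- mapply(shape_trace, specs, input_dims, SIMPLIFY = FALSE)
  lat <- lapply(traces, attr, "latent_shape")
  chans <- vapply(lat, function(z) z[["channels"]], integer(1))
  if (length(unique(chans)) != 1L) {
    stop("build_cae: all branches must share one latent channel count; got ",
         paste(chans, collapse = ", "))
  }
  C <- chans[1]
  positions <- vapply(lat, function(z) z[["positions"]], integer(1))
  pe <- new.env(parent = emptyenv())
  set.seed(as.integer(seed))
  for (b in seq_along(specs)) {
    sp <- specs[[b]]
    prev <- input_dims[b]
    for (i in seq_along(sp$dense_units)) {
      u <- sp$dense_units[i]
      assign(sprintf("b%d.enc.dense%d.W", b, i),
             glorot_init(c(prev, u), prev, u), envir = pe)
      assign(sprintf("b%d.enc.dense%d.b", b, i), numeric(u), envir = pe)
      prev <- u
    }
    cin <- 1L
    for (j in seq_along(sp$conv_blocks)) {
      bk <- sp$conv_blocks[[j]]
      assign(sprintf("b%d.enc.conv%d.W", b, j),
             glorot_init(c(bk$kernel, cin, bk$filters),
                         bk$kernel * cin, bk$filters), envir = pe)
      assign(sprintf("b%d.enc.conv%d.b", b, j), numeric(bk$filters),
             envir = pe)
      cin <- bk$filters
    }
    # decoder: reversed blocks
    cin <- C
    for (j in rev(seq_along(sp$conv_blocks))) {
      bk <- sp$conv_blocks[[j]]
      assign(sprintf("b%d.dec.tconv%d.W", b, j),
             glorot_init(c(bk$kernel, cin, bk$filters),
                         bk$kernel * cin, bk$filters), envir = pe)
      assign(sprintf("b%d.dec.tconv%d.b", b, j), numeric(bk$filters),
             envir = pe)
      cin <- bk$filters
    }
    assign(sprintf("b%d.dec.collapse.W", b),
           glorot_init(c(3L, cin, 1L), 3L * cin, 1L), envir = pe)
    assign(sprintf("b%d.dec.collapse.b", b), numeric(1L), envir = pe)
    widths <- c(rev(sp$dense_units), input_dims[b])
    for (i in seq_len(length(widths) - 1L)) {
      assign(sprintf("b%d.dec.dense%d.W", b, i),
             glorot_init(c(widths[i], widths[i + 1L]),
                         widths[i], widths[i + 1L]), envir = pe)
      assign(sprintf("b%d.dec.dense%d.b", b, i), numeric(widths[i + 1L]),
             envir = pe)
    }
  }
  if (attention) {
    hidden <- max(C %/% ratio, 1L)
    assign("cbam.W0", glorot_init(c(C, hidden), C, hidden), envir = pe)
    assign("cbam.W1", glorot_init(c(hidden, C), hidden, C), envir = pe)
    assign("cbam.Wsp", glorot_init(c(sa_kernel, 2L, 1L), 2L * sa_kernel,
                                   sa_kernel), envir = pe)
  }
  structure(list(specs = specs, input_dims = input_dims, params = pe,
                 traces = traces, latent_positions = positions,
                 channels = C, attention = attention,
                 attention_order = attention_order,
                 ratio = as.integer(ratio), sa_kernel = as.integer(sa_kernel),
                 seed = as.integer(seed), training_log = numeric(0),
                 epochs_trained = 0L),
            class = "caem_model")
}

#' @export
print.caem_model <- function(x, ...) {
  cat(sprintf(
    "<caem_model: %d branch(es), input %s, latent %s x %d ch, %s%s>\n",
    length(x$specs), paste(x$input_dims, collapse = "+"),
    paste(x$latent_positions, collapse = "+"), x$channels,
    if (x$attention) paste0("attention (", x$attention_order, ")")
    else "no attention",
    if (x$epochs_trained > 0) sprintf(", trained %d epochs", x$epochs_trained)
    else ", untrained"))
  invisible(x)
}

pget <- function(model, name) get(name, envir = model$params)

block_cols <- function(input_dims) {
  ends <- cumsum(input_dims)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  Map(function(s, e) s:e, starts, ends)
}

# forward through one branch encoder; returns latent + caches
encode_branch_fw <- function(model, b, X, want_cache = FALSE) {
  sp <- model$specs[[b]]
  caches <- list(dense = list(), conv = list())
  A <- X
  for (i in seq_along(sp$dense_units)) {
    Z <- dense_fw(A, pget(model, sprintf("b%d.enc.dense%d.W", b, i)),
                  pget(model, sprintf("b%d.enc.dense%d.b", b, i)))
    if (want_cache) caches$dense[[i]] <- list(X = A, Z = Z)
    A <- gelu(Z)
  }
  H <- array(A, c(nrow(A), ncol(A), 1L))
  for (j in seq_along(sp$conv_blocks)) {
    bk <- sp$conv_blocks[[j]]
    cv <- conv1d_fw(H, pget(model, sprintf("b%d.enc.conv%d.W", b, j)),
                    pget(model, sprintf("b%d.enc.conv%d.b", b, j)),
                    stride = bk$stride, pad = "same")
    A3 <- gelu(cv$Y)
    mp <- maxpool_fw(A3, bk$pool)
    if (want_cache) {
      caches$conv[[j]] <- list(conv = cv$cache, Z = cv$Y, pool = mp$cache)
    }
    H <- mp$Y
  }
  list(H = H, caches = caches)
}

encode_branch_bw <- function(model, b, caches, dH, gr) {
  sp <- model$specs[[b]]
  for (j in rev(seq_along(sp$conv_blocks))) {
    cc <- caches$conv[[j]]
    dA3 <- maxpool_bw(cc$pool, dH)
    dZ <- dA3 * gelu_grad(cc$Z)
    bw <- conv1d_bw(cc$conv, dZ)
    acc_grad(gr, sprintf("b%d.enc.conv%d.W", b, j), bw$dW)
    acc_grad(gr, sprintf("b%d.enc.conv%d.b", b, j), bw$db)
    dH <- bw$dX
  }
  dA <- matrix(dH, dim(dH)[1], dim(dH)[2])
  for (i in rev(seq_along(sp$dense_units))) {
    cc <- caches$dense[[i]]
    dZ <- dA * gelu_grad(cc$Z)
    # the input layer's dX is never consumed; skip its (wide) GEMM
    bw <- dense_bw(cc$X, pget(model, sprintf("b%d.enc.dense%d.W", b, i)),
                   dZ, need_dx = i > 1L)
    acc_grad(gr, sprintf("b%d.enc.dense%d.W", b, i), bw$dW)
    acc_grad(gr, sprintf("b%d.enc.dense%d.b", b, i), bw$db)
    dA <- bw$dX
  }
  invisible(NULL)
}

decode_branch_fw <- function(model, b, H, want_cache = FALSE) {
  sp <- model$specs[[b]]
  caches <- list(tconv = list(), dense = list())
  for (j in rev(seq_along(sp$conv_blocks))) {
    bk <- sp$conv_blocks[[j]]
    H <- upsample_fw(H, bk$pool)
    tv <- tconv_fw(H, pget(model, sprintf("b%d.dec.tconv%d.W", b, j)),
                   pget(model, sprintf("b%d.dec.tconv%d.b", b, j)),
                   stride = bk$stride)
    if (want_cache) caches$tconv[[j]] <- list(cache = tv$cache, Z = tv$Y)
    H <- gelu(tv$Y)
  }
  cv <- conv1d_fw(H, pget(model, sprintf("b%d.dec.collapse.W", b)),
                  pget(model, sprintf("b%d.dec.collapse.b", b)),
                  stride = 1L, pad = "same")
  if (want_cache) caches$collapse <- list(cache = cv$cache, Z = cv$Y)
  Hc <- gelu(cv$Y)
  A <- matrix(Hc, dim(Hc)[1], dim(Hc)[2])
  nd <- length(sp$dense_units)
  for (i in seq_len(nd)) {
    Z <- dense_fw(A, pget(model, sprintf("b%d.dec.dense%d.W", b, i)),
                  pget(model, sprintf("b%d.dec.dense%d.b", b, i)))
    if (want_cache) caches$dense[[i]] <- list(X = A, Z = Z)
    A <- if (i == nd) Z else gelu(Z) # linear output layer
  }
  list(xhat = A, caches = caches)
}

decode_branch_bw <- function(model, b, caches, dxhat, gr) {
  sp <- model$specs[[b]]
  nd <- length(sp$dense_units)
  dA <- dxhat
  for (i in rev(seq_len(nd))) {
    cc <- caches$dense[[i]]
    dZ <- if (i == nd) dA else dA * gelu_grad(cc$Z)
    bw <- dense_bw(cc$X, pget(model, sprintf("b%d.dec.dense%d.W", b, i)), dZ)
    acc_grad(gr, sprintf("b%d.dec.dense%d.W", b, i), bw$dW)
    acc_grad(gr, sprintf("b%d.dec.dense%d.b", b, i), bw$db)
    dA <- bw$dX
  }
  cc <- caches$collapse
  dHc <- array(dA, dim(cc$Z))
  dZ <- dHc * gelu_grad(cc$Z)
  bw <- conv1d_bw(cc$cache, dZ)
  acc_grad(gr, sprintf("b%d.dec.collapse.W", b), bw$dW)
  acc_grad(gr, sprintf("b%d.dec.collapse.b", b), bw$db)
  dH <- bw$dX
  for (j in seq_along(sp$conv_blocks)) {
    bk <- sp$conv_blocks[[j]]
    cc <- caches$tconv[[j]]
    dZ <- dH * gelu_grad(cc$Z)
    bw <- tconv_bw(cc$cache, dZ)
    acc_grad(gr, sprintf("b%d.dec.tconv%d.W", b, j), bw$dW)
    acc_grad(gr, sprintf("b%d.dec.tconv%d.b", b, j), bw$db)
    dH <- upsample_bw(bw$dX, bk$pool)
  }
  dH
}

acc_grad <- function(gr, name, val) {
  if (exists(name, envir = gr, inherits = FALSE)) {
    assign(name, get(name, envir = gr, inherits = FALSE) + val, envir = gr)
  } else {
    assign(name, val, envir = gr)
  }
  invisible(NULL)
}

# full forward; returns latents (post-attention), recon, caches
caem_forward <- function(model, X, want_cache = FALSE) {
  n <- nrow(X)
  cols <- block_cols(model$input_dims)
  B <- length(model$specs)
  enc <- vector("list", B)
  for (b in seq_len(B)) {
    enc[[b]] <- encode_branch_fw(model, b, X[, cols[[b]], drop = FALSE],
                                 want_cache)
  }
  totpos <- sum(model$latent_positions)
  C <- model$channels
  Fcat <- array(0, c(n, totpos, C))
  pos_end <- cumsum(model$latent_positions)
  pos_start <- c(1L, utils::head(pos_end, -1L) + 1L)
  for (b in seq_len(B)) {
    Fcat[, pos_start[b]:pos_end[b], ] <- enc[[b]]$H
  }
  if (model$attention) {
    at <- cbam_fw(Fcat, pget(model, "cbam.W0"), pget(model, "cbam.W1"),
                  pget(model, "cbam.Wsp"), model$attention_order)
    F2 <- at$Y
    at_cache <- if (want_cache) at$cache else NULL
  } else {
    F2 <- Fcat
    at_cache <- NULL
  }
  dec <- vector("list", B)
  xhat <- matrix(0, n, sum(model$input_dims))
  for (b in seq_len(B)) {
    d <- decode_branch_fw(model, b,
                          F2[, pos_start[b]:pos_end[b], , drop = FALSE],
                          want_cache)
    dec[[b]] <- d
    xhat[, cols[[b]]] <- d$xhat
  }
  list(latent = F2, xhat = xhat, enc = enc, dec = dec, at_cache = at_cache,
       pos_start = pos_start, pos_end = pos_end, cols = cols)
}

caem_backward <- function(model, fwd, X) {
  n <- nrow(X)
  gr <- new.env(parent = emptyenv())
  dxhat <- (fwd$xhat - X) / n
  B <- length(model$specs)
  dF2 <- array(0, dim(fwd$latent))
  for (b in seq_len(B)) {
    dH <- decode_branch_bw(model, b, fwd$dec[[b]]$caches,
                           dxhat[, fwd$cols[[b]], drop = FALSE], gr)
    dF2[, fwd$pos_start[b]:fwd$pos_end[b], ] <- dH
  }
  if (model$attention) {
    ab <- cbam_bw(fwd$at_cache, dF2)
    acc_grad(gr, "cbam.W0", ab$dW0)
    acc_grad(gr, "cbam.W1", ab$dW1)
    acc_grad(gr, "cbam.Wsp", ab$dWsp)
    dFcat <- ab$dF
  } else {
    dFcat <- dF2
  }
  for (b in seq_len(B)) {
    encode_branch_bw(model, b, fwd$enc[[b]]$caches,
                     dFcat[, fwd$pos_start[b]:fwd$pos_end[b], ,
                           drop = FALSE], gr)
  }
  gr
}

#' Autoencoder cost
#'
#' `(1/(2N)) * sum_i ||x_i - xhat_i||^2 + lambda * weight_norm_sq`, with `N`
#' the batch size and the L2 term taken over the trainable weights.
#'
#' @param x Input batch (matrix, samples in rows) or vector.
#' @param x_hat Reconstruction of the same shape.
#' @param weight_norm_sq Sum of squared trainable weights.
#' @param lambda L2 coefficient (>= 0).
#' @return Scalar loss.
#' @examples
#' cae_loss(c(1, 0), c(0, 0))                    # 0.5
#' cae_loss(c(1, 0), c(0, 0), 4, lambda = 1e-3)  # 0.504
#' @export
cae_loss <- function(x, x_hat, weight_norm_sq = 0, lambda = 0) {
  if (!identical(dim(x), dim(x_hat)) || length(x) != length(x_hat)) {
    stop("cae_loss: x and x_hat must have identical shapes")
  }
  stopifnot(lambda >= 0)
  N <- if (is.matrix(x)) nrow(x) else 1L
  sum((x - x_hat)^2) / (2 * N) + lambda * weight_norm_sq
}

weight_names <- function(model) {
  nm <- sort(ls(model$params))
  nm[grepl("\\.W", nm)]
}

model_weight_norm_sq <- function(model) {
  sum(vapply(weight_names(model),
             function(nm) sum(pget(model, nm)^2), numeric(1)))
}

extract_block_matrix <- function(data, input_dims) {
  X <- if (inherits(data, "standardized_matrix")) data$values
       else as.matrix(data)
  if (ncol(X) != sum(input_dims)) {
    stop("data has ", ncol(X), " features but the model expects ",
         sum(input_dims))
  }
  X
}

#' Train a convolutional autoencoder
#'
#' Minimizes [cae_loss()] by minibatch Adam (step size `learning_rate`,
#' batch size `batch_size`); the per-epoch mean batch loss (including the
#' L2 term) is appended to `training_log`. Deterministic for a fixed seed
#' under a fixed BLAS thread policy.
#'
#' @param model A [build_cae()] model.
#' @param data A [standardize()]d matrix (or plain samples x features
#'   matrix) whose width equals the model's total input width.
#' @param epochs Number of epochs (0 is a no-op).
#' @param lambda L2 weight-decay coefficient (default 1e-4).
#' @param batch_size Minibatch size (default 16).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed Integer seed for shuffling (defaults to the model seed).
#' @param verbose Print the per-epoch loss?
#' @return The trained model (updated `training_log`, `epochs_trained`).
#' @export
train_cae <- function(model, data, epochs = 100L, lambda = 1e-4,
                      batch_size = 16L, learning_rate = 1e-3,
                      seed = model$seed, verbose = FALSE) {
  stopifnot(inherits(model, "caem_model"), epochs >= 0, lambda >= 0)
  if (epochs == 0) return(model)
  X <- extract_block_matrix(data, model$input_dims)
  n <- nrow(X)
  # the optimizer updates parameters in place; copy them first so the
  # training loop only ever mutates buffers this call owns (references
  # taken from the model before training stay unchanged)
  pe_old <- model$params
  pe <- new.env(parent = emptyenv())
  for (nm in ls(pe_old)) {
    assign(nm, get(nm, envir = pe_old) + 0, envir = pe)
  }
  model$params <- pe
  nms <- sort(ls(pe))
  is_w <- grepl("\\.W", nms)
  zero_like <- function(nm) {
    p <- get(nm, envir = pe)
    array(0, dim(p) %||% length(p))
  }
  mstate <- lapply(nms, zero_like)
  vstate <- lapply(nms, zero_like)
  set.seed(as.integer(seed))
  t_step <- 0L
  wns <- model_weight_norm_sq(model) # thereafter maintained by the updater
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- perm[s:min(s + batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      fwd <- caem_forward(model, Xb, want_cache = TRUE)
      recon <- sum((Xb - fwd$xhat)^2) / (2 * nrow(Xb))
      loss <- recon + lambda * wns
      if (!is.finite(loss)) {
        stop("train_cae: non-finite loss at epoch ", ep,
             " (divergence); reduce the learning rate")
      }
      ep_loss <- ep_loss + loss
      gr <- caem_backward(model, fwd, Xb)
      grads <- lapply(nms, function(nm) get(nm, envir = gr))
      params <- lapply(nms, function(nm) get(nm, envir = pe))
      t_step <- t_step + 1L
      wns <- adam_step_inplace(params, grads, mstate, vstate, is_w,
                               learning_rate, 0.9, 0.999, 1e-8, t_step,
                               lambda)
    }
    ep_loss <- ep_loss / length(starts)
    model$training_log <- c(model$training_log, ep_loss)
    if (verbose) {
      message(sprintf("epoch %d/%d  loss %.6f", ep, epochs, ep_loss))
    }
  }
  model$epochs_trained <- model$epochs_trained + as.integer(epochs)
  model
}

#' Encode samples to the attention-refined latent
#'
#' Runs the encoder branches and (by default) the attached attention block,
#' returning the per-sample latent tensor.
#'
#' @param model A `caem_model`.
#' @param data Data matrix or `standardized_matrix` matching the model
#'   width.
#' @param apply_attention Apply the attention block (if attached)? Default
#'   `TRUE`.
#' @param allow_untrained Permit encoding with an untrained model (useful
#'   for shape checks). Default `FALSE`.
#' @return A `latent_tensor`: array `(n_samples, positions, channels)` with
#'   attributes `block_positions` (per-branch position counts) and
#'   `source_omics`.
#' @export
encode <- function(model, data, apply_attention = TRUE,
                   allow_untrained = FALSE) {
  stopifnot(inherits(model, "caem_model"))
  if (model$epochs_trained == 0L && !allow_untrained) {
    stop("encode: model is untrained; pass allow_untrained = TRUE to ",
         "encode anyway")
  }
  X <- extract_block_matrix(data, model$input_dims)
  cols <- block_cols(model$input_dims)
  B <- length(model$specs)
  n <- nrow(X)
  Fcat <- array(0, c(n, sum(model$latent_positions), model$channels))
  pos_end <- cumsum(model$latent_positions)
  pos_start <- c(1L, utils::head(pos_end, -1L) + 1L)
  for (b in seq_len(B)) {
    e <- encode_branch_fw(model, b, X[, cols[[b]], drop = FALSE])
    Fcat[, pos_start[b]:pos_end[b], ] <- e$H
  }
  if (model$attention && apply_attention) {
    Fcat <- cbam_fw(Fcat, pget(model, "cbam.W0"), pget(model, "cbam.W1"),
                    pget(model, "cbam.Wsp"), model$attention_order)$Y
  }
  structure(Fcat, class = "latent_tensor",
            block_positions = model$latent_positions,
            source_omics = vapply(model$specs, function(s) s$name,
                                  character(1)))
}

#' Reconstruct samples through the full autoencoder
#'
#' @inheritParams encode
#' @return Matrix `n_samples x total_input_width`.
#' @export
reconstruct <- function(model, data, allow_untrained = FALSE) {
  stopifnot(inherits(model, "caem_model"))
  if (model$epochs_trained == 0L && !allow_untrained) {
    stop("reconstruct: model is untrained; pass allow_untrained = TRUE")
  }
  X <- extract_block_matrix(data, model$input_dims)
  caem_forward(model, X)$xhat
}
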
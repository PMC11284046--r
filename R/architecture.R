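#' Output length of a 1D convolution
#'
#' Length arithmetic for strided 1D convolutions. In `"same"` mode the
#' output length is `ceiling(in_len / stride)` (the padding is chosen by the
#' layer so that this holds); in `"valid"` mode it is
#' `floor((in_len - kernel + 2 * pad) / stride) + 1`.
#'
#' @param in_len Input length (positive integer).
#' @param kernel Kernel size.
#' @param stride Stride.
#' @param pad_mode `"same"` or `"valid"`.
#' @param pad Explicit zero padding per side, used only in `"valid"` mode.
#' @return Output length (integer).
#' @examples
#' conv_out_len(512, 3, 2)                # 256
#' conv_out_len(7, 3, 2, "valid", pad = 0) # 3
#' @export
conv_out_len <- function(in_len, kernel, stride, pad_mode = c("same", "valid"),
                         pad = 0L) {
  pad_mode <- match.arg(pad_mode)
  stopifnot(in_len >= 1, kernel >= 1, stride >= 1, pad >= 0)
  out <- if (pad_mode == "same") {
    as.integer(ceiling(in_len / stride))
  } else {
    as.integer(floor((in_len - kernel + 2 * pad) / stride) + 1)
  }
  if (out < 1) {
    stop("conv_out_len: output length ", out, " < 1 for in_len=", in_len,
         ", kernel=", kernel, ", stride=", stride, ", pad=", pad)
  }
  out
}

#' Output length of a 1D transposed convolution
#'
#' `stride * (in_len - 1) + kernel_size - 2 * padding`. The model builder
#' additionally uses an output padding of `stride - 1` trailing zeros so that
#' a stride-2 transposed convolution exactly doubles the length; this helper
#' implements the plain formula.
#'
#' @param in_len Input length.
#' @param stride Stride (upsampling factor of the transposed convolution).
#' @param kernel_size Kernel size.
#' @param padding Padding removed from the output borders.
#' @return Output length (integer).
#' @examples
#' tconv_out_len(64, 1, 3, 1)  # 64
#' tconv_out_len(64, 2, 3, 0)  # 129
#' @export
tconv_out_len <- function(in_len, stride, kernel_size, padding) {
  stopifnot(in_len >= 1, stride >= 1, kernel_size >= 1, padding >= 0)
  out <- as.integer(stride * (in_len - 1) + kernel_size - 2 * padding)
  if (out < 1) {
    stop("tconv_out_len: output length ", out, " < 1 for in_len=", in_len,
         ", stride=", stride, ", kernel=", kernel_size,
         ", padding=", padding)
  }
  out
}

#' Declare a convolutional-autoencoder architecture
#'
#' An architecture is an encoder-side stack: fully connected widths followed
#' by convolution blocks (Conv1D with GELU, then max-pooling). The decoder
#' mirrors the encoder: per block, upsampling by the pool size and a
#' transposed convolution undoing the conv stride; a final single-filter
#' transposed convolution collapses channels before a dense layer restores
#' the exact input width.
#'
#' @param dense_units Integer vector of encoder dense widths (e.g. `512`).
#' @param conv_blocks List of blocks, each a list/vector with elements
#'   `filters`, `kernel`, `stride`, `pool`.
#' @param name Optional label.
#' @return An object of class `arch_spec`.
#' @examples
#' arch_spec(512, list(c(filters = 16, kernel = 3, stride = 2, pool = 2),
#'                     c(filters = 4, kernel = 3, stride = 2, pool = 4)))
#' @export
arch_spec <- function(dense_units, conv_blocks, name = "custom") {
  dense_units <- as.integer(dense_units)
  stopifnot(length(dense_units) >= 1, all(dense_units >= 1))
  conv_blocks <- lapply(conv_blocks, function(b) {
    b <- as.list(b)
    stopifnot(all(c("filters", "kernel", "stride", "pool") %in% names(b)))
    b <- lapply(b[c("filters", "kernel", "stride", "pool")], as.integer)
    if (b$filters < 1 || b$kernel < 1 || b$stride < 1 || b$pool < 1) {
      stop("arch_spec: every conv block needs filters, kernel, stride, pool >= 1")
    }
    if (b$kernel %% 2L == 0L) {
      stop("arch_spec: kernel size must be odd (same-padding symmetry)")
    }
    b
  })
  if (length(conv_blocks) < 1) stop("arch_spec: need at least one conv block")
  structure(list(dense_units = dense_units, conv_blocks = conv_blocks,
                 name = name),
            class = "arch_spec")
}

#' @export
print.arch_spec <- function(x, ...) {
  cat("<arch_spec '", x$name, "'>\n", sep = "")
  cat("  dense:", paste(x$dense_units, collapse = " -> "), "\n")
  for (b in x$conv_blocks) {
    cat(sprintf("  conv1d: %d filters, kernel %d, stride %d | maxpool %d\n",
                b$filters, b$kernel, b$stride, b$pool))
  }
  invisible(x)
}

#' Built-in architecture presets
#'
#' `"brca_wide"` is the preset used for high-dimensional blocks (gene
#' expression, DNA methylation): Dense 512, Conv1D(16 filters)+MaxPool 2,
#' Conv1D(4 filters)+MaxPool 4. `"brca_mirna"` and `"gbm"` share the narrow
#' stack Dense 128, Conv1D(4 filters)+MaxPool 4. All convolutions use kernel
#' 3, stride 2, same padding. Every preset ends in a latent of 16 positions
#' by 4 channels.
#'
#' @param name One of `"brca_wide"`, `"brca_mirna"`, `"gbm"`.
#' @return An `arch_spec`.
#' @export
arch_preset <- function(name = c("brca_wide", "brca_mirna", "gbm")) {
  name <- match.arg(name)
  switch(name,
    brca_wide = arch_spec(
      512L,
      list(list(filters = 16L, kernel = 3L, stride = 2L, pool = 2L),
           list(filters = 4L, kernel = 3L, stride = 2L, pool = 4L)),
      name = "brca_wide"),
    brca_mirna = arch_spec(
      128L,
      list(list(filters = 4L, kernel = 3L, stride = 2L, pool = 4L)),
      name = "brca_mirna"),
    gbm = arch_spec(
      128L,
      list(list(filters = 4L, kernel = 3L, stride = 2L, pool = 4L)),
      name = "gbm"))
}

#' Pick one architecture per omics block
#'
#' The `"brca"` preset assigns the wide stack to gene-expression and
#' DNA-methylation blocks and the narrow stack to miRNA; `"gbm"` (and
#' `"auto"`, the default for arbitrary data) assigns the shared narrow stack
#' to every block.
#'
#' @param preset `"brca"`, `"gbm"` or `"auto"`.
#' @param omics_types Character vector of block types (used by `"brca"`).
#' @return List of `arch_spec`, one per block.
#' @export
default_specs <- function(preset = c("auto", "brca", "gbm"), omics_types) {
  preset <- match.arg(preset)
  if (preset == "brca") {
    allowed <- c("gene_expression", "dna_methylation", "mirna_expression")
    if (!all(omics_types %in% allowed)) {
      stop("preset 'brca' supports only omics types ",
           paste(allowed, collapse = ", "))
    }
    lapply(omics_types, function(t) {
      if (t == "mirna_expression") arch_preset("brca_mirna")
      else arch_preset("brca_wide")
    })
  } else {
    lapply(seq_along(omics_types), function(i) arch_preset("gbm"))
  }
}

#' Trace layer-by-layer output shapes of an architecture
#'
#' Applies the length arithmetic of [conv_out_len()] (same mode),
#' integer-division max-pooling, upsampling and [tconv_out_len()] (with
#' output padding `stride - 1`, so each decoder block exactly doubles the
#' length) to an input width, returning every layer's output shape. Errors
#' if any intermediate length would fall below 1 or if the decoder cannot
#' mirror back onto the encoder dense width.
#'
#' @param spec An `arch_spec`.
#' @param input_dim Input feature width.
#' @return A data.frame with columns `stage`, `layer`, `out_len`,
#'   `channels`, carrying the latent shape in attribute `"latent_shape"`
#'   (`c(positions, channels)`).
#' @examples
#' tr <- shape_trace(arch_preset("brca_wide"), 17814)
#' attr(tr, "latent_shape")  # 16 positions x 4 channels
#' @export
shape_trace <- function(spec, input_dim) {
  stopifnot(inherits(spec, "arch_spec"), input_dim >= 1)
  input_dim <- as.integer(input_dim)
  last_dense <- spec$dense_units[length(spec$dense_units)]
  if (input_dim < last_dense) {
    stop("shape_trace: input_dim (", input_dim,
         ") must be >= final dense width (", last_dense, ")")
  }
  rows <- list()
  add <- function(stage, layer, len, ch) {
    rows[[length(rows) + 1L]] <<- data.frame(stage = stage, layer = layer,
                                             out_len = len, channels = ch)
  }
  add("encoder", "input", input_dim, 1L)
  len <- input_dim
  for (i in seq_along(spec$dense_units)) {
    len <- spec$dense_units[i]
    add("encoder", paste0("dense_", i), len, 1L)
  }
  ch <- 1L
  for (j in seq_along(spec$conv_blocks)) {
    b <- spec$conv_blocks[[j]]
    len <- conv_out_len(len, b$kernel, b$stride, "same")
    ch <- b$filters
    add("encoder", paste0("conv_", j), len, ch)
    if (b$pool > len) {
      stop("shape_trace: pool size ", b$pool, " exceeds length ", len,
           " at conv block ", j)
    }
    len <- len %/% b$pool
    if (len < 1) stop("shape_trace: length < 1 after pooling at block ", j)
    add("encoder", paste0("maxpool_", j), len, ch)
  }
  latent <- c(positions = len, channels = ch)
  # decoder mirror
  for (j in rev(seq_along(spec$conv_blocks))) {
    b <- spec$conv_blocks[[j]]
    len <- len * b$pool
    add("decoder", paste0("upsample_", j), len, ch)
    # output padding stride-1 => length becomes stride * len exactly
    len <- tconv_out_len(len, b$stride, b$kernel, (b$kernel - 1L) %/% 2L) +
      (b$stride - 1L)
    ch <- b$filters
    add("decoder", paste0("tconv_", j), len, ch)
  }
  ch <- 1L
  add("decoder", "tconv_collapse", len, ch)
  if (len != last_dense) {
    stop("shape_trace: decoder length ", len,
         " does not mirror the encoder dense width ", last_dense,
         " (pooling must divide lengths exactly)")
  }
  for (i in rev(seq_along(spec$dense_units))) {
    out_w <- if (i == 1L) input_dim else spec$dense_units[i - 1L]
    add("decoder", paste0("dense_", i), out_w, 1L)
  }
  out <- do.call(rbind, rows)
  attr(out, "latent_shape") <- latent
  out
}

#' Latent shape of an architecture on a given input width
#'
#' @inheritParams shape_trace
#' @return Integer vector `c(positions, channels)`.
#' @export
latent_shape <- function(spec, input_dim) {
  attr(shape_trace(spec, input_dim), "latent_shape")
}

#' Serialize / deserialize an architecture to YAML
#'
#' @param spec An `arch_spec`.
#' @param path File path.
#' @return `arch_to_yaml` invisibly returns `path`; `arch_from_yaml`
#'   returns an `arch_spec`.
#' @export
arch_to_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "arch_spec"))
  yaml::write_yaml(list(name = spec$name,
                        dense_units = as.integer(spec$dense_units),
                        conv_blocks = spec$conv_blocks), path)
  invisible(path)
}

#' @rdname arch_to_yaml
#' @export
arch_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  arch_spec(y$dense_units, y$conv_blocks, name = y$name %||% "custom")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
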
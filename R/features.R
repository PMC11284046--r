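#' Assemble the classifier feature matrix
#'
#' Concatenates, per sample, the flattened attention-refined latent
#' (row-major: positions fastest within each channel) with the decoder
#' reconstruction. The resulting matrix is what the boosted-tree classifier
#' consumes; `latent_only = TRUE` restricts it to the latent part for users
#' who want a compact feature set.
#'
#' @param latents A `latent_tensor` from [encode()] (or an
#'   `(n, positions, channels)` array).
#' @param reconstructions Matrix `n x input_width` from [reconstruct()];
#'   ignored when `latent_only = TRUE`.
#' @param latent_only Drop the reconstruction block? Default `FALSE`.
#' @return Object of class `assembled_features`: `values`
#'   (`n x d_assembled`) and `layout`, an ordered list of
#'   `(source, width)` records.
#' @export
assemble_features <- function(latents, reconstructions = NULL,
                              latent_only = FALSE) {
  stopifnot(length(dim(latents)) == 3)
  dn <- dim(latents)
  n <- dn[1]
  lat_w <- dn[2] * dn[3]
  lat <- unclass(latents)
  attributes(lat) <- list(dim = dn)
  dim(lat) <- c(n, lat_w) # (position, channel) pairs, positions fastest
  layout <- list(list(source = "latent", width = lat_w))
  if (latent_only) {
    vals <- lat
  } else {
    if (is.null(reconstructions)) {
      stop("assemble_features: reconstructions required unless latent_only")
    }
    reconstructions <- as.matrix(reconstructions)
    if (ncol(reconstructions) < 1) {
      stop("assemble_features: zero-width reconstruction block")
    }
    if (nrow(reconstructions) != n) {
      stop("assemble_features: sample-count mismatch (", n, " vs ",
           nrow(reconstructions), ")")
    }
    vals <- cbind(lat, reconstructions)
    layout <- c(layout,
                list(list(source = "reconstruction",
                          width = ncol(reconstructions))))
  }
  colnames(vals) <- NULL
  structure(list(values = vals, layout = layout),
            class = "assembled_features")
}

#' @export
print.assembled_features <- function(x, ...) {
  w <- vapply(x$layout, function(l) l$width, numeric(1))
  s <- vapply(x$layout, function(l) l$source, character(1))
  cat(sprintf("<assembled_features: %d samples x %d (%s)>\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", s, w), collapse = " + ")))
  invisible(x)
}

#' @export
dim.assembled_features <- function(x) dim(x$values)

#' Extract one source block from assembled features
#'
#' @param assembled An [assemble_features()] object.
#' @param source Source name present in the layout (`"latent"`,
#'   `"reconstruction"`).
#' @return The matrix of columns contributed by that source.
#' @export
slice_features <- function(assembled, source) {
  stopifnot(inherits(assembled, "assembled_features"))
  srcs <- vapply(assembled$layout, function(l) l$source, character(1))
  i <- match(source, srcs)
  if (is.na(i)) {
    stop("slice_features: unknown source '", source, "'; available: ",
         paste(srcs, collapse = ", "))
  }
  widths <- vapply(assembled$layout, function(l) l$width, numeric(1))
  ends <- cumsum(widths)
  starts <- c(1, utils::head(ends, -1) + 1)
  assembled$values[, starts[i]:ends[i], drop = FALSE]
}
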
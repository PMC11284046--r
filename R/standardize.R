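#' Per-sample standardization
#'
#' Maps each sample (row) to mean 0 and population standard deviation 1:
#' `x' = (x - mean(x)) / sd_pop(x)` with the population (divide-by-n)
#' standard deviation. Rows with zero variance map to all-zeros. This is a
#' per-sample transform, so it never mixes information across samples and is
#' leakage-free with respect to train/test splits. The more common
#' per-feature scaling is available via `per_feature = TRUE` but is off by
#' default.
#'
#' @param x A samples x features numeric matrix, or an [omics_matrix()]
#'   (transposed internally so rows become samples).
#' @param per_feature If `TRUE`, additionally standardize columns
#'   (features) after the per-sample pass. Default `FALSE`.
#' @return An object of class `standardized_matrix`: list with `values`
#'   (samples x features), `sample_ids`, `blocks` (feature-range
#'   provenance, when known) and `row_means_removed = TRUE`.
#' @examples
#' standardize(matrix(c(1, 2, 3), nrow = 1))$values  # -1.2247 0 1.2247
#' @export
standardize <- function(x, per_feature = FALSE) {
  blocks <- NULL
  sample_ids <- NULL
  if (inherits(x, "omics_matrix")) {
    blocks <- x$blocks
    sample_ids <- x$sample_ids
    x <- t(x$values)
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) < 1) stop("standardize: matrix needs at least one column")
  n <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  sdp <- sqrt(rowSums(xc^2) / n)
  zero <- sdp == 0
  sdp[zero] <- 1
  out <- xc / sdp
  out[zero, ] <- 0
  if (per_feature) {
    cm <- colMeans(out)
    out <- sweep(out, 2L, cm)
    csd <- sqrt(colSums(out^2) / nrow(out))
    csd[csd == 0] <- 1
    out <- sweep(out, 2L, csd, "/")
  }
  if (is.null(blocks)) {
    blocks <- data.frame(omics_type = "other", start = 1L,
                         end = ncol(out))
  }
  structure(list(values = out, sample_ids = sample_ids,
                 blocks = blocks, row_means_removed = TRUE),
            class = "standardized_matrix")
}

#' @export
print.standardized_matrix <- function(x, ...) {
  cat(sprintf("<standardized_matrix: %d samples x %d features, %d block(s)>\n",
              nrow(x$values), ncol(x$values), nrow(x$blocks)))
  invisible(x)
}

#' @export
dim.standardized_matrix <- function(x) dim(x$values)

#' Stratified train/test splits
#'
#' `"five_fold"` partitions the samples into 5 disjoint test sets whose
#' sizes differ by at most one; `"ratio_3_1"` produces a single split with a
#' quarter of the samples (`floor(n/4)`) held out. Both schemes are
#' stratified by subtype so that small classes appear in every training
#' partition whenever possible, and both are deterministic for a fixed
#' seed.
#'
#' @param labels A [label_vector()] (its length defines `n`).
#' @param scheme `"five_fold"` or `"ratio_3_1"`.
#' @param seed Integer seed.
#' @return A list of splits; each split is `list(train = idx, test = idx)`
#'   with 1-based sample indices.
#' @export
split_samples <- function(labels, scheme = c("five_fold", "ratio_3_1"),
                          seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(labels, "label_vector"))
  y <- labels$labels
  n <- length(y)
  K <- length(labels$class_names)
  if (n < K) stop("split_samples: fewer samples than classes")
  ord <- local({
    set.seed(as.integer(seed))
    unlist(lapply(sort(unique(y)), function(k) {
      idx <- which(y == k)
      if (length(idx) > 1) sample(idx) else idx
    }), use.names = FALSE)
  })
  splits <- if (scheme == "five_fold") {
    fold <- rep_len(1:5, n) # cyclic over stratum-ordered samples
    lapply(1:5, function(f) {
      list(train = sort(ord[fold != f]), test = sort(ord[fold == f]))
    })
  } else {
    grp <- rep_len(c("train", "train", "train", "test"), n)
    list(list(train = sort(ord[grp == "train"]),
              test = sort(ord[grp == "test"])))
  }
  for (s in splits) {
    missing <- setdiff(unique(y), unique(y[s$train]))
    if (length(missing)) {
      warning("split_samples: class(es) ",
              paste(labels$class_names[missing + 1L], collapse = ", "),
              " absent from a training partition")
    }
  }
  splits
}
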
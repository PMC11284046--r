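#' Construct an omics matrix
#'
#' Canonical container for one omics layer: a numeric matrix in features x
#' samples orientation with unique feature and sample identifiers and an
#' omics-type tag.
#'
#' @param values Numeric matrix, features in rows and samples in columns.
#' @param feature_ids Character vector, one per row.
#' @param sample_ids Character vector, one per column.
#' @param omics_type One of `"gene_expression"`, `"mirna_expression"`,
#'   `"dna_methylation"`, `"other"`.
#' @return An object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, feature_ids, sample_ids,
                         omics_type = c("other", "gene_expression",
                                        "mirna_expression",
                                        "dna_methylation")) {
  omics_type <- match.arg(omics_type)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(feature_ids)) {
    stop("omics_matrix: ", nrow(values), " rows but ",
         length(feature_ids), " feature_ids")
  }
  if (ncol(values) != length(sample_ids)) {
    stop("omics_matrix: ", ncol(values), " columns but ",
         length(sample_ids), " sample_ids")
  }
  if (anyDuplicated(feature_ids)) {
    stop("omics_matrix: duplicate feature_ids: ",
         paste(utils::head(unique(feature_ids[duplicated(feature_ids)]), 5),
               collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("omics_matrix: duplicate sample_ids: ",
         paste(utils::head(unique(sample_ids[duplicated(sample_ids)]), 5),
               collapse = ", "))
  }
  if (ncol(values) < 2) stop("omics_matrix: need at least 2 samples")
  if (nrow(values) < 1) stop("omics_matrix: need at least 1 feature")
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop("omics_matrix: non-finite value at feature '",
         feature_ids[bad[1]], "', sample '", sample_ids[bad[2]], "'")
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(list(values = values, feature_ids = feature_ids,
                 sample_ids = sample_ids, omics_type = omics_type),
            class = "omics_matrix")
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix: %s, %d features x %d samples>\n",
              x$omics_type, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Load a delimited omics table
#'
#' Reads a TSV/CSV table (delimiter auto-detected, gzip accepted) with one
#' header row and a leading ID column into an [omics_matrix()]. Either
#' orientation is accepted; the result is always features x samples.
#'
#' @param path File path.
#' @param omics_type Omics-type tag; see [omics_matrix()].
#' @param orientation `"features_by_samples"` (rows are features, default)
#'   or `"samples_by_features"`.
#' @return An `omics_matrix`.
#' @export
load_omics <- function(path, omics_type = "other",
                       orientation = c("features_by_samples",
                                       "samples_by_features")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("load_omics: file not found: ", path)
  # gzip magic bytes; gzfile() reads plain files transparently as well
  magic <- readBin(path, "raw", n = 2L)
  is_gz <- length(magic) == 2L && magic[1] == as.raw(0x1f) &&
    magic[2] == as.raw(0x8b)
  # fread silently uniquifies duplicate header names; check them raw
  con <- gzfile(path, "rt")
  hdr_line <- readLines(con, n = 1L)
  close(con)
  hdr <- strsplit(hdr_line, "[\t,;]")[[1]][-1L]
  if (anyDuplicated(hdr)) {
    stop("load_omics: duplicate sample_ids in header: ",
         paste(utils::head(unique(hdr[duplicated(hdr)]), 5),
               collapse = ", "))
  }
  src <- if (is_gz) {
    con <- gzfile(path, "rt")
    on.exit(close(con), add = TRUE)
    paste(readLines(con), collapse = "\n")
  } else {
    path
  }
  dt <- if (is_gz) {
    data.table::fread(text = src, header = TRUE, sep = "auto",
                      colClasses = list(character = 1L),
                      na.strings = c("NA", "NaN", ""))
  } else {
    data.table::fread(path, header = TRUE, sep = "auto",
                      colClasses = list(character = 1L),
                      na.strings = c("NA", "NaN", ""))
  }
  if (ncol(dt) < 2) stop("load_omics: table needs an ID column plus data")
  ids <- as.character(dt[[1L]])
  vals <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    col <- which(!vapply(dt[, -1L], is.numeric, logical(1)))[1L]
    bad_row <- which(is.na(suppressWarnings(
      as.numeric(dt[[col + 1L]]))))[1L]
    stop("load_omics: non-numeric cell at row '", ids[bad_row],
         "', column '", names(dt)[col + 1L], "' in ", path)
  }
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop("load_omics: missing value (NA) at row '", ids[bad[1]],
         "', column '", colnames(vals)[bad[2]], "' in ", path)
  }
  if (orientation == "samples_by_features") {
    omics_matrix(t(vals), feature_ids = colnames(vals), sample_ids = ids,
                 omics_type = omics_type)
  } else {
    omics_matrix(vals, feature_ids = ids, sample_ids = colnames(vals),
                 omics_type = omics_type)
  }
}

#' Concatenate omics blocks along the feature dimension
#'
#' All blocks must profile the same sample set (order may differ; samples
#' are aligned by ID to the first block's order). Block provenance is kept
#' so each original block can be recovered by slicing.
#'
#' @param blocks List of `omics_matrix` objects.
#' @return An `omics_matrix` whose feature dimension is the sum of the block
#'   feature dimensions, with a `blocks` element recording
#'   `(omics_type, start, end)` feature ranges.
#' @export
concat_omics <- function(blocks) {
  stopifnot(is.list(blocks), length(blocks) >= 1)
  lapply(blocks, function(b) stopifnot(inherits(b, "omics_matrix")))
  ref <- blocks[[1L]]$sample_ids
  for (i in seq_along(blocks)) {
    ids <- blocks[[i]]$sample_ids
    if (!setequal(ids, ref)) {
      only_a <- setdiff(ref, ids)
      only_b <- setdiff(ids, ref)
      stop("concat_omics: sample-ID mismatch in block ", i,
           "; only in block 1: {", paste(utils::head(only_a, 5), collapse = ","),
           "}; only in block ", i, ": {",
           paste(utils::head(only_b, 5), collapse = ","), "}")
    }
  }
  aligned <- lapply(blocks, function(b) b$values[, ref, drop = FALSE])
  vals <- do.call(rbind, aligned)
  fid <- unlist(lapply(seq_along(blocks), function(i) {
    paste0(blocks[[i]]$omics_type, ".", i, ":", blocks[[i]]$feature_ids)
  }))
  if (length(blocks) == 1L) fid <- blocks[[1L]]$feature_ids
  widths <- vapply(blocks, function(b) nrow(b$values), integer(1))
  ends <- cumsum(widths)
  out <- omics_matrix(vals, fid, ref,
                      omics_type = if (length(blocks) == 1L)
                        blocks[[1L]]$omics_type else "other")
  out$blocks <- data.frame(
    omics_type = vapply(blocks, function(b) b$omics_type, character(1)),
    start = c(1L, utils::head(ends, -1L) + 1L),
    end = ends)
  out
}

#' Construct a subtype label vector
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param labels Class assignments: factor, character, or integer codes in
#'   `0..K-1`.
#' @param class_names Optional explicit class name set (defines `K` and the
#'   code order); inferred from `labels` otherwise.
#' @return An object of class `label_vector` with elements `sample_ids`,
#'   `labels` (integer codes `0..K-1`) and `class_names`.
#' @export
label_vector <- function(sample_ids, labels, class_names = NULL) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("label_vector: duplicate sample_ids")
  if (is.numeric(labels) && !is.null(class_names)) {
    codes <- as.integer(labels)
  } else {
    f <- if (is.null(class_names)) factor(labels)
         else factor(labels, levels = class_names)
    if (anyNA(f)) stop("label_vector: label outside class_names")
    class_names <- levels(f)
    codes <- as.integer(f) - 1L
  }
  K <- length(class_names)
  if (any(codes < 0L | codes >= K)) {
    stop("label_vector: class codes must lie in 0..K-1")
  }
  if (length(codes) != length(sample_ids)) {
    stop("label_vector: lengths differ")
  }
  structure(list(sample_ids = sample_ids, labels = codes,
                 class_names = class_names),
            class = "label_vector")
}

#' @export
print.label_vector <- function(x, ...) {
  cat(sprintf("<label_vector: %d samples, %d classes (%s)>\n",
              length(x$labels), length(x$class_names),
              paste(x$class_names, collapse = ", ")))
  invisible(x)
}

#' Read a two-column sample/subtype label table
#'
#' @param path TSV/CSV with columns `sample_id`, `subtype` (header optional
#'   names; first two columns are used).
#' @return A [label_vector()].
#' @export
read_labels <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "auto",
                          colClasses = "character")
  if (ncol(dt) < 2) stop("read_labels: need two columns (sample_id, subtype)")
  label_vector(dt[[1L]], dt[[2L]])
}
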
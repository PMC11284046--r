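# Shared builders for in-code fixtures. Everything is generated at test
# time; nothing binary is stored.

# small omics_matrix with reproducible values
toy_omics <- function(n_features = 6, n_samples = 4, type = "other",
                      seed = 1, prefix = "f", samples = NULL) {
  set.seed(seed)
  omics_matrix(matrix(rnorm(n_features * n_samples), n_features),
               feature_ids = paste0(prefix, seq_len(n_features)),
               sample_ids = samples %||%
                 paste0("s", seq_len(n_samples)),
               omics_type = type)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write a delimited omics table and return its path
write_omics_tsv <- function(tab, sep = "\t", ids = NULL, gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".tsv.gz" else ".tsv")
  df <- data.frame(id = ids %||% paste0("f", seq_len(nrow(tab))), tab,
                   check.names = FALSE)
  data.table::fwrite(df, path, sep = sep, compress = if (gz) "gzip"
                                                     else "none")
  path
}

# write a full synthetic dataset to dir; returns run_config data argument
write_dataset <- function(dat, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_along(dat$blocks), function(b) {
    om <- dat$blocks[[b]]
    p <- file.path(dir, paste0("block", b, "_", om$omics_type, ".tsv"))
    df <- data.frame(id = om$feature_ids, om$values, check.names = FALSE)
    names(df) <- c("id", om$sample_ids)
    data.table::fwrite(df, p, sep = "\t")
    p
  }, character(1))
  lab <- file.path(dir, "labels.tsv")
  data.table::fwrite(
    data.frame(sample_id = dat$labels$sample_ids,
               subtype = dat$labels$class_names[dat$labels$labels + 1L]),
    lab, sep = "\t")
  types <- vapply(dat$blocks, function(b) b$omics_type, character(1))
  list(paths = paths, labels = lab, omics_types = types)
}

# tiny two-branch model for engine tests
tiny_model <- function(attention = TRUE, seed = 5) {
  spec <- arch_spec(16L, list(list(filters = 4L, kernel = 3L, stride = 2L,
                                   pool = 2L)), "toy")
  build_cae(list(spec, spec), c(20L, 18L), attention = attention,
            ratio = 2L, sa_kernel = 3L, seed = seed)
}
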
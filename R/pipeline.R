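# End-to-end orchestration: load or simulate data, standardize, train the
# attentive autoencoder per split (feature extraction sees training samples
# only), assemble classifier features, fit the boosted-tree classifier and
# evaluate on the held-out samples. Every artifact carries the hash of the
# configuration that produced it.

#' Assemble a pipeline run configuration
#'
#' @param data `NULL`, or a list with `paths` (character vector of per-omics
#'   tables, optionally named by omics type), `labels` (label-table path)
#'   and optional `omics_types`.
#' @param fixture `NULL`, or a [make_fixture()] name to simulate inputs.
#' @param preset Architecture preset passed to [default_specs()]; `"auto"`
#'   picks a stack per block width.
#' @param epochs Autoencoder training epochs (default 100).
#' @param lambda L2 weight penalty (default 1e-4).
#' @param batch_size,learning_rate Optimizer settings.
#' @param attention Use the attention block (default `TRUE`).
#' @param attention_order `"channel_first"` or `"spatial_first"`.
#' @param cbam_ratio,cbam_kernel Attention hyperparameters.
#' @param latent_only Classifier features restricted to the latent block?
#' @param gbdt A [gbdt_config()].
#' @param scheme Split scheme: `"ratio_3_1"` (default) or `"five_fold"`.
#' @param seed Master seed; per-fold seeds are derived from it.
#' @param out_dir Output directory for artifacts.
#' @return Object of class `run_config`.
#' @export
run_config <- function(data = NULL, fixture = NULL, preset = "auto",
                       epochs = 100L, lambda = 1e-4, batch_size = 16L,
                       learning_rate = 1e-3, attention = TRUE,
                       attention_order = "channel_first", cbam_ratio = 8L,
                       cbam_kernel = 7L, latent_only = FALSE,
                       gbdt = gbdt_config(), scheme = "ratio_3_1",
                       seed = 1L, out_dir = tempfile("caem_run_")) {
  if (is.null(data) && is.null(fixture)) {
    stop("run_config: provide either data paths or a fixture name")
  }
  stopifnot(epochs >= 0, inherits(gbdt, "gbdt_config"))
  scheme <- match.arg(scheme, c("ratio_3_1", "five_fold"))
  preset <- match.arg(preset, c("auto", "brca", "gbm"))
  structure(list(data = data, fixture = fixture, preset = preset,
                 epochs = as.integer(epochs), lambda = lambda,
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, attention = attention,
                 attention_order = attention_order,
                 cbam_ratio = as.integer(cbam_ratio),
                 cbam_kernel = as.integer(cbam_kernel),
                 latent_only = latent_only, gbdt = gbdt, scheme = scheme,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Hash of a run configuration
#'
#' MD5 over the canonical JSON serialization of every scientific setting
#' (the output directory is excluded so relocated runs hash identically).
#'
#' @param config A [run_config()].
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  x$gbdt <- unclass(x$gbdt)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

# picks an architecture per block width for preset = "auto"
auto_spec <- function(d) {
  if (d >= 128L) {
    arch_preset("gbm")
  } else if (d >= 32L) {
    arch_spec(32L, list(list(filters = 4L, kernel = 3L, stride = 2L,
                             pool = 2L)), name = "narrow32")
  } else if (d >= 16L) {
    arch_spec(16L, list(list(filters = 4L, kernel = 3L, stride = 2L,
                             pool = 2L)), name = "narrow16")
  } else {
    stop("auto preset needs at least 16 features per block; got ", d)
  }
}

resolve_inputs <- function(config) {
  if (!is.null(config$fixture)) {
    fx <- make_fixture(config$fixture,
                       dir = file.path(config$out_dir, "data"))
    blocks <- fx$blocks
    labels <- fx$labels
  } else {
    paths <- config$data$paths
    types <- config$data$omics_types %||% names(paths) %||%
      rep("other", length(paths))
    blocks <- Map(function(p, t) load_omics(p, omics_type = t),
                  paths, types)
    names(blocks) <- NULL
    labels <- read_labels(config$data$labels)
  }
  ref_ids <- blocks[[1L]]$sample_ids
  pos <- match(ref_ids, labels$sample_ids)
  if (anyNA(pos)) {
    stop("run_train: sample(s) missing from the label table: ",
         paste(utils::head(ref_ids[is.na(pos)], 5), collapse = ", "))
  }
  labels <- label_vector(ref_ids, labels$labels[pos],
                         class_names = labels$class_names)
  list(blocks = blocks, labels = labels)
}

resolve_specs <- function(config, blocks) {
  dims <- vapply(blocks, function(b) nrow(b$values), integer(1))
  types <- vapply(blocks, function(b) b$omics_type, character(1))
  if (config$preset == "auto") {
    lapply(dims, auto_spec)
  } else {
    default_specs(config$preset, types)
  }
}

fit_fold <- function(config, std, labels, split, fold_seed) {
  Xtr <- std$values[split$train, , drop = FALSE]
  dims <- std$blocks$end - std$blocks$start + 1L
  specs <- attr(std, "specs")
  model <- build_cae(specs, dims, attention = config$attention,
                     ratio = config$cbam_ratio,
                     sa_kernel = config$cbam_kernel,
                     attention_order = config$attention_order,
                     seed = fold_seed)
  model <- train_cae(model, Xtr, epochs = config$epochs,
                     lambda = config$lambda,
                     batch_size = config$batch_size,
                     learning_rate = config$learning_rate,
                     seed = fold_seed)
  feats <- function(idx) {
    Xs <- std$values[idx, , drop = FALSE]
    lat <- encode(model, Xs, allow_untrained = TRUE)
    rec <- if (config$latent_only) NULL
           else reconstruct(model, Xs, allow_untrained = TRUE)
    assemble_features(lat, rec, latent_only = config$latent_only)
  }
  ftr <- feats(split$train)
  fte <- feats(split$test)
  ytr <- label_vector(labels$sample_ids[split$train],
                      labels$labels[split$train],
                      class_names = labels$class_names)
  gcfg <- config$gbdt
  gcfg$seed <- fold_seed
  clf <- fit_gbdt(ftr, ytr, gcfg)
  pred <- stats::predict(clf, fte)
  yte <- label_vector(labels$sample_ids[split$test],
                      labels$labels[split$test],
                      class_names = labels$class_names)
  rep_ <- evaluate(yte, pred$labels)
  list(metrics = rep_, model = model, classifier = clf,
       training_log = model$training_log)
}

#' Run the full training/evaluation pipeline
#'
#' Executes load (or simulate) -> per-sample standardization -> per-split
#' autoencoder training with attention -> latent + reconstruction feature
#' assembly -> boosted-tree fitting -> held-out evaluation, and writes
#' `metrics.json`, per-fold loss curves, and a reproducibility manifest to
#' the configured output directory. The autoencoder is retrained inside
#' every split on training samples only.
#'
#' @param config A [run_config()].
#' @return Object of class `caem_run`: `folds` (per-split metrics and
#'   fitted models), `summary` (mean and sd of each metric across folds),
#'   `config`, `config_hash`, `paths`.
#' @export
run_train <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  inp <- resolve_inputs(config)
  specs <- resolve_specs(config, inp$blocks)
  conc <- concat_omics(inp$blocks)
  std <- standardize(conc)
  attr(std, "specs") <- specs
  splits <- split_samples(inp$labels, config$scheme, seed = config$seed)
  folds <- vector("list", length(splits))
  for (i in seq_along(splits)) {
    folds[[i]] <- fit_fold(config, std, inp$labels, splits[[i]],
                           fold_seed = config$seed + i)
    log_path <- file.path(config$out_dir,
                          sprintf("loss_curve_fold%d.tsv", i))
    data.table::fwrite(
      data.table::data.table(epoch = seq_along(folds[[i]]$training_log),
                             loss = folds[[i]]$training_log),
      log_path, sep = "\t")
  }
  metric_names <- c("accuracy", "precision", "recall", "f1")
  per_fold <- lapply(folds, function(f) f$metrics[metric_names])
  summary <- lapply(metric_names, function(mn) {
    v <- vapply(per_fold, function(p) p[[mn]], numeric(1))
    list(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0)
  })
  names(summary) <- metric_names
  metrics <- list(
    config_hash = hash,
    scheme = config$scheme,
    n_folds = length(folds),
    folds = lapply(folds, function(f) {
      m <- f$metrics
      list(accuracy = m$accuracy, precision = m$precision,
           recall = m$recall, f1 = m$f1, n_test = m$n,
           confusion = m$confusion)
    }),
    summary = summary)
  metrics_path <- file.path(config$out_dir, "metrics.json")
  jsonlite::write_json(metrics, metrics_path, auto_unbox = TRUE,
                       digits = NA, matrix = "rowmajor")
  manifest <- list(
    package = "caemgbdt",
    version = as.character(utils::packageVersion("caemgbdt")),
    r_version = as.character(getRversion()),
    config_hash = hash,
    config = local({
      x <- unclass(config)
      x$gbdt <- unclass(x$gbdt)
      x
    }),
    fold_seeds = config$seed + seq_along(splits))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  structure(list(folds = folds, summary = summary, config = config,
                 config_hash = hash,
                 paths = list(metrics = metrics_path,
                              manifest = manifest_path,
                              out_dir = config$out_dir)),
            class = "caem_run")
}

#' @export
print.caem_run <- function(x, ...) {
  cat(sprintf("<caem_run: %s, %d fold(s), hash %s>\n",
              x$config$scheme, length(x$folds),
              substr(x$config_hash, 1, 8)))
  for (mn in names(x$summary)) {
    cat(sprintf("  %-9s %.1f +- %.1f\n", mn, x$summary[[mn]]$mean,
                x$summary[[mn]]$sd))
  }
  invisible(x)
}

#' Run ablation variants under identical seeds and splits
#'
#' Trains the configured pipeline and each requested variant with the same
#' seeds and splits and tabulates the metrics side by side. Variants:
#' `"no_cbam"` removes the attention block, `"spatial_first"` swaps the
#' attention order, `"latent_only"` drops the reconstruction from the
#' classifier features.
#'
#' @param config A [run_config()] (the baseline).
#' @param variants Non-empty character vector of variant names.
#' @return Object of class `caem_ablation`: `table` (one row per variant
#'   plus baseline) and `runs`.
#' @export
run_ablation <- function(config, variants) {
  stopifnot(inherits(config, "run_config"))
  if (length(variants) == 0) {
    stop("run_ablation: variants must be a non-empty list")
  }
  variants <- match.arg(variants, c("no_cbam", "spatial_first",
                                    "latent_only"),
                        several.ok = TRUE)
  alter <- function(cfg, v) {
    if (v == "no_cbam") cfg$attention <- FALSE
    if (v == "spatial_first") cfg$attention_order <- "spatial_first"
    if (v == "latent_only") cfg$latent_only <- TRUE
    cfg
  }
  names_all <- c("baseline", variants)
  runs <- vector("list", length(names_all))
  for (i in seq_along(names_all)) {
    v <- names_all[i]
    cfg <- config
    if (v != "baseline") cfg <- alter(cfg, v)
    cfg$out_dir <- file.path(config$out_dir, "ablation", v)
    runs[[i]] <- run_train(cfg)
  }
  names(runs) <- names_all
  tab <- do.call(rbind, lapply(names_all, function(v) {
    s <- runs[[v]]$summary
    data.frame(variant = v, accuracy = s$accuracy$mean,
               precision = s$precision$mean, recall = s$recall$mean,
               f1 = s$f1$mean, config_hash = runs[[v]]$config_hash,
               stringsAsFactors = FALSE)
  }))
  out_path <- file.path(config$out_dir, "ablation", "ablation.tsv")
  dir.create(dirname(out_path), recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(tab, out_path, sep = "\t")
  structure(list(table = tab, runs = runs, path = out_path),
            class = "caem_ablation")
}

#' @export
print.caem_ablation <- function(x, ...) {
  cat("<caem_ablation>\n")
  print(x$table[, c("variant", "accuracy", "precision", "recall", "f1")])
  invisible(x)
}
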
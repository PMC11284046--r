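# Synthetic multi-omics data with planted subtype structure: per-block
# baseline feature means, per-subtype additive mean shifts on a sparse
# informative subset, and i.i.d. Gaussian noise. The generator exists so
# that every pipeline stage is exercisable (and its failure modes
# measurable) without any external download.

#' Configuration of the synthetic multi-omics generator
#'
#' @param n_samples Number of samples.
#' @param block_dims Integer vector of per-omics feature widths.
#' @param K Number of latent subtypes.
#' @param informative_frac Fraction of features per block carrying subtype
#'   signal (default 0.1).
#' @param effect_size Per-subtype mean shift in units of `noise_sd`
#'   (default 2).
#' @param noise_sd Gaussian noise standard deviation (default 1).
#' @param class_proportions Vector of K class fractions summing to 1
#'   (default balanced).
#' @param omics_types Optional per-block omics-type tags.
#' @param seed Integer seed.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples, block_dims, K,
                             informative_frac = 0.1, effect_size = 2,
                             noise_sd = 1, class_proportions = NULL,
                             omics_types = NULL, seed = 1L) {
  n_samples <- as.integer(n_samples)
  block_dims <- as.integer(block_dims)
  K <- as.integer(K)
  if (K > n_samples) stop("synthetic_config: K exceeds n_samples")
  if (informative_frac < 0 || informative_frac > 1) {
    stop("synthetic_config: informative_frac must be in [0, 1]")
  }
  if (effect_size < 0) stop("synthetic_config: effect_size must be >= 0")
  if (is.null(class_proportions)) {
    class_proportions <- rep(1 / K, K)
  }
  if (length(class_proportions) != K ||
      abs(sum(class_proportions) - 1) > 1e-8) {
    stop("synthetic_config: class_proportions must be K fractions summing to 1")
  }
  if (is.null(omics_types)) {
    defaults <- c("gene_expression", "mirna_expression", "dna_methylation")
    omics_types <- if (length(block_dims) <= 3) {
      defaults[seq_along(block_dims)]
    } else {
      rep("other", length(block_dims))
    }
  }
  structure(list(n_samples = n_samples, block_dims = block_dims, K = K,
                 informative_frac = informative_frac,
                 effect_size = effect_size, noise_sd = noise_sd,
                 class_proportions = class_proportions,
                 omics_types = omics_types, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic multi-omics dataset
#'
#' For each block, baseline feature means are drawn `N(0, 1)`; an
#' `informative_frac` subset of features receives per-subtype shifts of
#' magnitude `effect_size * noise_sd` (random sign per class and feature);
#' `N(0, noise_sd^2)` noise is added. Labels follow `class_proportions`
#' (largest-remainder rounding, order shuffled). Fully reproducible from
#' the seed.
#'
#' @param config A [synthetic_config()].
#' @return List with `blocks` (list of [omics_matrix()]), `labels` (a
#'   [label_vector()]), `mask` (per-block logical vectors marking planted
#'   informative features) and `config`.
#' @export
generate_multiomics <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_samples
  K <- config$K
  counts <- floor(config$class_proportions * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- config$class_proportions * n - counts
    counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1L
  }
  y <- sample(rep.int(0:(K - 1), counts))
  sample_ids <- sprintf("sample_%03d", seq_len(n))
  blocks <- vector("list", length(config$block_dims))
  mask <- vector("list", length(config$block_dims))
  for (b in seq_along(config$block_dims)) {
    d <- config$block_dims[b]
    baseline <- stats::rnorm(d)
    n_inf <- round(config$informative_frac * d)
    inf <- rep(FALSE, d)
    if (n_inf > 0) inf[sample.int(d, n_inf)] <- TRUE
    shift <- matrix(0, K, d)
    if (n_inf > 0 && config$effect_size > 0) {
      signs <- matrix(sample(c(-1, 1), K * n_inf, replace = TRUE), K, n_inf)
      # every informative feature must separate at least one class pair:
      # if all classes drew the same sign, flip one class at random
      flat <- which(abs(colSums(signs)) == K)
      if (length(flat)) {
        rows <- sample.int(K, length(flat), replace = TRUE)
        signs[cbind(rows, flat)] <- -signs[cbind(rows, flat)]
      }
      shift[, inf] <- config$effect_size * config$noise_sd * signs
    }
    vals <- matrix(baseline, d, n) + t(shift[y + 1L, , drop = FALSE]) +
      matrix(stats::rnorm(d * n, sd = config$noise_sd), d, n)
    blocks[[b]] <- omics_matrix(
      vals,
      feature_ids = sprintf("%s_f%05d", substr(config$omics_types[b], 1, 4),
                            seq_len(d)),
      sample_ids = sample_ids,
      omics_type = config$omics_types[b])
    mask[[b]] <- inf
  }
  labels <- label_vector(sample_ids, y,
                         class_names = paste0("subtype_", seq_len(K)))
  list(blocks = blocks, labels = labels, mask = mask, config = config)
}

fixture_config <- function(name, seed = NULL) {
  switch(name,
    tiny = synthetic_config(
      n_samples = 40, block_dims = c(200L, 30L, 300L), K = 3,
      informative_frac = 0.15, effect_size = 3, noise_sd = 1,
      seed = seed %||% 42L),
    strong4 = synthetic_config(
      n_samples = 120, block_dims = c(200L, 30L, 300L), K = 4,
      informative_frac = 0.15, effect_size = 4, noise_sd = 1,
      seed = seed %||% 7L),
    brca_shaped = synthetic_config(
      n_samples = 104, block_dims = c(17814L, 354L, 23094L), K = 4,
      informative_frac = 0.05, effect_size = 2, noise_sd = 1,
      seed = seed %||% 101L),
    gbm_shaped = synthetic_config(
      n_samples = 213, block_dims = c(12042L, 534L, 1305L), K = 4,
      informative_frac = 0.05, effect_size = 2, noise_sd = 1,
      seed = seed %||% 202L),
    stop("unknown fixture: ", name))
}

#' Write a named synthetic fixture to disk
#'
#' `"tiny"` (40 samples, 200+30+300 features, K = 3, strong signal; fast
#' enough for continuous testing), `"strong4"` (120 samples, K = 4, effect
#' size 4), `"brca_shaped"` (104 samples, 17,814+354+23,094 features,
#' K = 4) and `"gbm_shaped"` (213 samples, 12,042+534+1,305 features,
#' K = 4). Writes one TSV per omics block, a two-column label table, and a
#' JSON manifest with the full generator configuration.
#'
#' @param name Fixture name.
#' @param dir Output directory (created if needed).
#' @param seed Optional seed override (each fixture has a documented
#'   default).
#' @return Invisibly, a list with `paths` (per-block TSVs), `labels_path`,
#'   `manifest_path`, `omics_types` and the generated data (`blocks`,
#'   `labels`, `mask`).
#' @export
make_fixture <- function(name = c("tiny", "strong4", "brca_shaped",
                                  "gbm_shaped"),
                         dir, seed = NULL) {
  name <- match.arg(name)
  cfg <- fixture_config(name, seed)
  dat <- generate_multiomics(cfg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(dat$blocks))
  for (b in seq_along(dat$blocks)) {
    om <- dat$blocks[[b]]
    paths[b] <- file.path(dir, paste0(om$omics_type, ".tsv"))
    dt <- data.table::data.table(id = om$feature_ids)
    dt <- cbind(dt, data.table::as.data.table(om$values))
    data.table::setnames(dt, c("id", om$sample_ids))
    data.table::fwrite(dt, paths[b], sep = "\t")
  }
  labels_path <- file.path(dir, "labels.tsv")
  data.table::fwrite(
    data.table::data.table(
      sample_id = dat$labels$sample_ids,
      subtype = dat$labels$class_names[dat$labels$labels + 1L]),
    labels_path, sep = "\t")
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(fixture = name, config = unclass(cfg)),
                       manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(list(paths = paths, labels_path = labels_path,
                 manifest_path = manifest_path,
                 omics_types = cfg$omics_types, blocks = dat$blocks,
                 labels = dat$labels, mask = dat$mask, config = cfg))
}
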
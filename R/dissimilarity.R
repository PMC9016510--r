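#' Build the synthetic reference set (Addcl1 sampling)
#'
#' Creates an artificial data set of the same size as the original PCG table
#' by resampling each column independently from its own empirical
#' distribution. Column marginals are preserved while all between-column
#' dependence is destroyed; a forest classifying original vs synthetic rows
#' therefore encodes exactly the dependence structure of the original data.
#'
#' @param original A cohort tibble (its `pcg_<name>` columns are used), or a
#'   plain 0/1 matrix / data frame of clustering features.
#' @param taxonomy Taxonomy tibble (used only when `original` is a cohort).
#' @param seed Resampling seed.
#' @return A `pcg_reference`: tibble with a `provenance` column
#'   (`"original"` / `"synthetic"`) followed by the feature columns; original
#'   rows come first.
#' @export
make_reference <- function(original, taxonomy = default_taxonomy(), seed = 1L) {
  feats <- reference_features(original, taxonomy)
  n <- nrow(feats)
  if (n == 0L) {
    abort("original table must be nonempty.", class = "pcg_validation_error")
  }
  synth <- with_preserved_seed(as.integer(seed), {
    as.data.frame(lapply(feats, function(col) sample(col, n, replace = TRUE)))
  })
  out <- dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(provenance = "original"), feats),
    dplyr::bind_cols(tibble::tibble(provenance = "synthetic"),
                     tibble::as_tibble(synth))
  )
  structure(out, class = c("pcg_reference", class(out)), n_original = n)
}

reference_features <- function(original, taxonomy) {
  if (is.data.frame(original) && any(pcg_cols(taxonomy) %in% names(original))) {
    tibble::as_tibble(as.data.frame(pcg_matrix(original, taxonomy)))
  } else if (is.matrix(original)) {
    tibble::as_tibble(as.data.frame(original), .name_repair = "unique")
  } else {
    tibble::as_tibble(original)
  }
}

#' Random-forest ensemble configuration
#'
#' @param n_forests Number of independently seeded forests whose proximity
#'   matrices are averaged (default 10).
#' @param n_trees Trees per forest (default 500).
#' @param mtry Features tried per split; default `floor(sqrt(p))`.
#' @param min_node_size Minimal terminal-node size (default 1, the usual
#'   classification default).
#' @param max_depth Maximal tree depth; `NULL` = unlimited.
#' @param seed Base seed; forest `i` uses `seed + i - 1`.
#' @return A `forest_config` list.
#' @export
forest_config <- function(n_forests = 10L, n_trees = 500L, mtry = NULL,
                          min_node_size = 1L, max_depth = NULL, seed = 1L) {
  if (n_forests < 1L || n_trees < 1L) {
    abort("n_forests and n_trees must be >= 1.", class = "pcg_validation_error")
  }
  structure(list(n_forests = as.integer(n_forests), n_trees = as.integer(n_trees),
                 mtry = mtry, min_node_size = as.integer(min_node_size),
                 max_depth = max_depth, seed = as.integer(seed)),
            class = "forest_config")
}

#' Train the original-vs-synthetic forest ensemble
#'
#' Fits `cfg$n_forests` random-forest classifiers (bootstrap resampling) on
#' the binary task of telling original rows from synthetic-reference rows,
#' and records each forest's out-of-bag (OOB) misclassification rate: every
#' point is predicted only by trees whose bootstrap excluded it. An OOB error
#' near 0.5 means the forest cannot tell the cohort from its
#' independence-resampled shadow, i.e. there is little dependence structure
#' in the data.
#'
#' @param ref A `pcg_reference` from [make_reference()].
#' @param cfg A [forest_config()].
#' @return A `pcg_forests` list: `forests` (ranger fits), `oob_errors`
#'   (length `n_forests`), `oob_mean`, `config`.
#' @export
train_forests <- function(ref, cfg = forest_config()) {
  if (!inherits(ref, "pcg_reference")) {
    abort("`ref` must come from make_reference().", class = "pcg_validation_error")
  }
  y <- factor(ref$provenance, levels = c("original", "synthetic"))
  if (min(table(y)) < 2L) {
    abort("need at least 2 points per class.", class = "pcg_validation_error")
  }
  x <- as.data.frame(ref[, setdiff(names(ref), "provenance")])
  mtry <- cfg$mtry %||% max(1L, floor(sqrt(ncol(x))))
  forests <- purrr::map(seq_len(cfg$n_forests), function(i) {
    ranger::ranger(
      x = x, y = y,
      num.trees = cfg$n_trees, mtry = mtry,
      min.node.size = cfg$min_node_size,
      max.depth = cfg$max_depth %||% 0L,
      seed = cfg$seed + i - 1L, num.threads = 1L,
      oob.error = TRUE, respect.unordered.factors = TRUE
    )
  })
  oob <- purrr::map_dbl(forests, "prediction.error")
  structure(list(forests = forests, oob_errors = oob, oob_mean = mean(oob),
                 config = cfg),
            class = "pcg_forests")
}

#' Leaf co-membership proximity matrix of one forest
#'
#' Entry (i, j) counts the trees in which points i and j fall into the same
#' terminal leaf; the diagonal equals the number of trees.
#'
#' @param forest A single fitted `ranger` forest.
#' @param data The feature rows (original + synthetic) to score.
#' @return A dense symmetric integer-valued matrix.
#' @export
proximity_matrix <- function(forest, data) {
  if (!inherits(forest, "ranger")) {
    abort("`forest` must be a fitted ranger forest.", class = "pcg_state_error")
  }
  data <- as.data.frame(data)
  nodes <- stats::predict(forest, data = data, type = "terminalNodes",
                          num.threads = 1L)$predictions
  n <- nrow(nodes); n_tree <- ncol(nodes)
  # one global leaf id per (tree, node); co-leaf counts via sparse crossprod
  offsets <- c(0, cumsum(apply(nodes, 2, max) + 1L))[seq_len(n_tree)]
  global <- sweep(nodes, 2, offsets, "+")
  leaf_id <- match(as.vector(global), sort(unique(as.vector(global))))
  z <- Matrix::sparseMatrix(i = rep(seq_len(n), times = n_tree), j = leaf_id, x = 1)
  prox <- as.matrix(Matrix::tcrossprod(z))
  dimnames(prox) <- NULL
  prox
}

#' Mean random-forest dissimilarity over an ensemble
#'
#' Runs the full unsupervised-RF dissimilarity step: trains the ensemble with
#' [train_forests()], computes each forest's leaf co-membership proximity
#' over all points (original and synthetic), averages the matrices, and
#' applies the distance transform `1 - proximity / n_trees`.
#'
#' @inheritParams train_forests
#' @return A `pcg_dissimilarity` list: `proximity` (mean co-leaf counts, in
#'   `[0, n_trees]`, diagonal `n_trees`), `distance` (in `[0, 1]`, zero
#'   diagonal), `oob_errors`, `oob_mean`, `n_original`, `provenance`,
#'   `config`.
#' @export
mean_dissimilarity <- function(ref, cfg = forest_config()) {
  fitted <- train_forests(ref, cfg)
  x <- as.data.frame(ref[, setdiff(names(ref), "provenance")])
  prox <- NULL
  for (f in fitted$forests) {
    p <- proximity_matrix(f, x)
    prox <- if (is.null(prox)) p else prox + p
  }
  prox <- prox / cfg$n_forests
  dist <- 1 - prox / cfg$n_trees
  diag(dist) <- 0
  structure(list(proximity = prox, distance = dist,
                 oob_errors = fitted$oob_errors, oob_mean = fitted$oob_mean,
                 n_original = attr(ref, "n_original"),
                 provenance = ref$provenance, config = cfg),
            class = "pcg_dissimilarity")
}

#' @rdname mean_dissimilarity
#' @export
rf_dissimilarity <- mean_dissimilarity

#' @export
print.pcg_dissimilarity <- function(x, ...) {
  cat(sprintf("<pcg_dissimilarity> %d points (%d original), %d forests x %d trees\n",
              nrow(x$distance), x$n_original, x$config$n_forests, x$config$n_trees))
  cat(sprintf("  mean OOB misclassification error: %.3f\n", x$oob_mean))
  invisible(x)
}

#' @export
#' @method tidy pcg_dissimilarity
tidy.pcg_dissimilarity <- function(x, ...) {
  tibble::tibble(forest = seq_along(x$oob_errors), oob_error = x$oob_errors)
}

#' @export
#' @method glance pcg_dissimilarity
glance.pcg_dissimilarity <- function(x, ...) {
  tibble::tibble(n_points = nrow(x$distance), n_original = x$n_original,
                 n_forests = x$config$n_forests, n_trees = x$config$n_trees,
                 oob_mean = x$oob_mean)
}

#' Persist / load a dissimilarity result
#'
#' The distance matrix is written as CSV (a plain-text matrix) next to a JSON
#' sidecar holding the ensemble metadata (forest/tree counts, seed, per-forest
#' OOB errors, provenance split).
#'
#' @param x A `pcg_dissimilarity`.
#' @param path Basename; writes `<path>.csv` and `<path>.json`.
#' @export
write_dissimilarity <- function(x, path) {
  readr::write_csv(tibble::as_tibble(as.data.frame(x$distance),
                                     .name_repair = "minimal"),
                   paste0(path, ".csv"), col_names = FALSE)
  jsonlite::write_json(
    list(n_forests = x$config$n_forests, n_trees = x$config$n_trees,
         seed = x$config$seed, oob_errors = x$oob_errors, oob_mean = x$oob_mean,
         n_original = x$n_original, provenance = x$provenance),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
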
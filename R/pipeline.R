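# Reserved label codes for groups set aside before density clustering.
# Detected clusters use 0..k-1 and outliers -1, as in the HDBSCAN output.
LABEL_CODES <- c(no_pcg = -2L, hypertension_only = -3L, mental_only = -4L,
                 other_single = -5L, not_sampled = -6L)

label_name_of <- function(label) {
  nm <- names(LABEL_CODES)[match(label, LABEL_CODES)]
  dplyr::case_when(
    !is.na(nm) ~ nm,
    label == -1L ~ "outlier",
    TRUE ~ paste0("cluster_", label)
  )
}

#' Partition a cohort ahead of clustering
#'
#' Reproduces the pre-clustering filters: patients with no PCGs, patients
#' whose PCGs all belong to the hypertension category, and patients whose
#' PCGs all belong to the mental category form three "single" groups set
#' aside before the expensive pipeline; patients confined to exactly one
#' *other* disease category are likewise excluded from clustering (they
#' carry no co-occurrence information) but kept as an audited
#' `other_single` group. The remainder is clusterable and, above a size
#' threshold, thinned to a uniform random subsample for tractability of the
#' quadratic-cost stages.
#'
#' @param cohort Cohort tibble.
#' @param taxonomy Taxonomy tibble.
#' @param subsample_fraction Fraction of clusterable patients retained when
#'   subsampling triggers (default 0.10).
#' @param seed Subsampling seed.
#' @param subsample_threshold Clusterable-set size above which subsampling is
#'   applied (default 5000), so small cohorts are not thinned away.
#' @param hypertension_category,mental_category Names of the two disease
#'   categories defining the single-disease groups.
#' @return A `pcg_partition`: tibble (`patient_id`, `group`) where `group`
#'   is one of `no_pcg`, `hypertension_only`, `mental_only`, `other_single`,
#'   `clusterable`, `not_sampled`, with a `counts` attribute.
#' @export
partition_cohort <- function(cohort, taxonomy = default_taxonomy(),
                             subsample_fraction = 0.1, seed = 1L,
                             subsample_threshold = 5000L,
                             hypertension_category = "hypertension",
                             mental_category = "mental") {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L) {
    abort("cohort must be a nonempty data frame.", class = "pcg_validation_error")
  }
  taxonomy <- validate_taxonomy(taxonomy)
  prof <- category_profile(cohort, taxonomy)
  counts <- rowSums(prof)
  span <- rowSums(prof > 0L)
  hyp <- prof[, hypertension_category]
  men <- prof[, mental_category]

  group <- dplyr::case_when(
    counts == 0L ~ "no_pcg",
    hyp == counts ~ "hypertension_only",
    men == counts ~ "mental_only",
    span == 1L ~ "other_single",
    TRUE ~ "clusterable"
  )
  idx_cl <- which(group == "clusterable")
  if (length(idx_cl) > subsample_threshold) {
    keep <- with_preserved_seed(as.integer(seed), {
      sample(idx_cl, round(subsample_fraction * length(idx_cl)))
    })
    group[setdiff(idx_cl, keep)] <- "not_sampled"
  }
  out <- tibble::tibble(patient_id = cohort$patient_id, group = group)
  structure(out, class = c("pcg_partition", class(out)),
            counts = table(factor(group, levels = c(
              "no_pcg", "hypertension_only", "mental_only", "other_single",
              "clusterable", "not_sampled"))),
            subsample_fraction = subsample_fraction, seed = as.integer(seed))
}

#' Run the complete clustering pipeline
#'
#' Chains every stage of the unsupervised-RF clustering procedure on a
#' cohort: pre-clustering partition -> synthetic reference (Addcl1) ->
#' forest-averaged proximity and distance -> 2-D stress-majorization MDS
#' (synthetic points included, then dropped) -> HDBSCAN on the original
#' points' coordinates -> per-patient label assembly.
#'
#' @param cohort Cohort tibble.
#' @param taxonomy Taxonomy tibble.
#' @param forest_cfg A [forest_config()]; its seed is overridden by the
#'   stage seeds derived from `seed`.
#' @param mds_n_init,mds_max_iter,mds_tol MDS settings (see [mds_embed()]).
#' @param min_cluster_size,min_samples HDBSCAN settings (see
#'   [detect_clusters()]).
#' @param subsample_fraction,subsample_threshold See [partition_cohort()].
#' @param seed Master seed; per-stage seeds are `seed + 0..3` (partition,
#'   reference, forests, MDS). Fixed seed implies identical labels.
#' @return A `pcg_pipeline` with elements `assignment` (tibble
#'   `patient_id`, `label`, `label_name`), `partition`, `dissimilarity`,
#'   `embedding`, `clusters`, and `metrics` (OOB mean, stress,
#'   persistences, counts).
#' @export
run_full_pipeline <- function(cohort, taxonomy = default_taxonomy(),
                              forest_cfg = forest_config(),
                              mds_n_init = 4L, mds_max_iter = 300L,
                              mds_tol = 1e-4,
                              min_cluster_size = NULL, min_samples = NULL,
                              subsample_fraction = 0.1,
                              subsample_threshold = 5000L, seed = 1L) {
  seed <- as.integer(seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "pcg_pipeline_error", parent = e)
    })
  }
  partition <- stage("partition", partition_cohort(
    cohort, taxonomy, subsample_fraction, seed = seed,
    subsample_threshold = subsample_threshold))

  cl_ids <- partition$patient_id[partition$group == "clusterable"]
  assignment <- tibble::tibble(
    patient_id = partition$patient_id,
    label = unname(LABEL_CODES[partition$group])
  )

  if (length(cl_ids) == 0L) {
    warn("no clusterable patients; returning partition labels only.")
    assignment$label_name <- label_name_of(assignment$label)
    return(new_pcg_pipeline(assignment, partition, NULL, NULL, NULL, seed))
  }

  sub <- cohort[match(cl_ids, cohort$patient_id), ]
  ref <- stage("reference", make_reference(sub, taxonomy, seed = seed + 1L))
  forest_cfg$seed <- seed + 2L
  diss <- stage("dissimilarity", mean_dissimilarity(ref, forest_cfg))
  emb <- stage("mds", mds_embed(diss$distance, n_init = mds_n_init,
                                max_iter = mds_max_iter, tol = mds_tol,
                                seed = seed + 3L))
  orig_coords <- emb$coords[diss$provenance == "original", , drop = FALSE]
  clusters <- stage("hdbscan", detect_clusters(
    orig_coords, min_cluster_size = min_cluster_size, min_samples = min_samples))

  assignment$label[match(cl_ids, assignment$patient_id)] <- clusters$labels
  assignment$label_name <- label_name_of(assignment$label)
  new_pcg_pipeline(assignment, partition, diss, emb, clusters, seed)
}

new_pcg_pipeline <- function(assignment, partition, diss, emb, clusters, seed) {
  metrics <- list(
    seed = seed,
    counts = as.list(attr(partition, "counts")),
    oob_mean = if (!is.null(diss)) diss$oob_mean else NA_real_,
    oob_errors = if (!is.null(diss)) diss$oob_errors else numeric(0),
    stress = if (!is.null(emb)) emb$stress else NA_real_,
    n_clusters = if (!is.null(clusters)) nrow(clusters$persistence) else 0L,
    persistence = if (!is.null(clusters)) clusters$persistence$persistence else numeric(0)
  )
  structure(list(assignment = assignment, partition = partition,
                 dissimilarity = diss, embedding = emb, clusters = clusters,
                 metrics = metrics),
            class = "pcg_pipeline")
}

#' @export
print.pcg_pipeline <- function(x, ...) {
  m <- x$metrics
  cat("<pcg_pipeline>\n")
  cat("  partition: ", paste(sprintf("%s=%d", names(attr(x$partition, "counts")),
                                     as.integer(attr(x$partition, "counts"))),
                             collapse = ", "), "\n", sep = "")
  cat(sprintf("  oob_mean=%.3f  stress=%.3f  clusters=%d\n",
              m$oob_mean, m$stress, m$n_clusters))
  if (length(m$persistence)) {
    cat("  persistence:", paste(sprintf("%.3f", m$persistence), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
#' @method tidy pcg_pipeline
tidy.pcg_pipeline <- function(x, ...) {
  tibble::as_tibble(x$assignment)
}

#' @export
#' @method glance pcg_pipeline
glance.pcg_pipeline <- function(x, ...) {
  m <- x$metrics
  tibble::tibble(n_patients = nrow(x$assignment),
                 n_clusterable = sum(x$partition$group == "clusterable"),
                 n_clusters = m$n_clusters,
                 oob_mean = m$oob_mean, stress = m$stress)
}

#' @export
#' @method autoplot pcg_pipeline
autoplot.pcg_pipeline <- function(object, ...) {
  if (is.null(object$embedding)) {
    abort("pipeline has no embedding to plot.", class = "pcg_state_error")
  }
  orig <- object$dissimilarity$provenance == "original"
  df <- tibble::tibble(
    x = object$embedding$coords[orig, 1],
    y = object$embedding$coords[orig, 2],
    label = factor(label_name_of(object$clusters$labels))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7, ...) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Clusters in the MDS projection",
                  colour = "cluster")
}

#' Adjusted Rand index of recovered clusters against planted archetypes
#'
#' Compares the pipeline's detected labels with the generator's
#' `true_archetype` column on clusterable, non-outlier patients. Ground
#' truth is available only for synthetic cohorts; the label column is
#' ignored by every other pipeline stage.
#'
#' @param pipeline A `pcg_pipeline`.
#' @param cohort The cohort it was run on (must carry `true_archetype`).
#' @return The adjusted Rand index (1 = perfect recovery, ~0 = chance).
#' @export
recovery_ari <- function(pipeline, cohort) {
  if (!"true_archetype" %in% names(cohort)) {
    abort("cohort has no true_archetype column.", class = "pcg_validation_error")
  }
  a <- pipeline$assignment
  keep <- a$label >= 0L
  if (!any(keep)) return(NA_real_)
  truth <- cohort$true_archetype[match(a$patient_id[keep], cohort$patient_id)]
  mclust::adjustedRandIndex(a$label[keep], truth)
}
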
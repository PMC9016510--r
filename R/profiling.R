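#' Descriptive statistics per cluster
#'
#' Builds a descriptive-statistics table with one row per assigned label
#' (detected clusters, outliers, and the pre-extracted single groups):
#' size and share of the cohort, age, sex split, deductible, gatekeeping
#' share, mean PCG count, multimorbid share, the four cost means, the four
#' utilization means, and the most prevalent PCGs.
#'
#' @param cohort Cohort tibble.
#' @param assignment Tibble with `patient_id`, `label` (and optionally
#'   `label_name`), e.g. `pipeline$assignment`; every patient must be
#'   labelled.
#' @param taxonomy Taxonomy tibble.
#' @param n_top_pcgs How many top-prevalence PCG names to report.
#' @return A tibble of cluster profiles, ordered by label; `pct` values sum
#'   to 100.
#' @export
profile_clusters <- function(cohort, assignment, taxonomy = default_taxonomy(),
                             n_top_pcgs = 4L) {
  if (inherits(assignment, "pcg_pipeline")) assignment <- assignment$assignment
  miss <- setdiff(cohort$patient_id, assignment$patient_id)
  if (length(miss) > 0 || anyNA(assignment$label)) {
    abort("every patient must be labelled.", class = "pcg_validation_error")
  }
  lab <- assignment$label[match(cohort$patient_id, assignment$patient_id)]
  m <- pcg_matrix(cohort, taxonomy)
  dat <- dplyr::mutate(cohort, .label = lab,
                       .pcg_count = as.integer(rowSums(m)),
                       .multimorbid = rowSums(m) >= 2L)
  n_total <- nrow(dat)

  prof <- dat |>
    dplyr::group_by(.data$.label) |>
    dplyr::summarise(
      n = dplyr::n(),
      pct = 100 * dplyr::n() / n_total,
      age_mean = mean(.data$age), age_sd = stats::sd(.data$age),
      n_men = sum(.data$sex == "male"), n_women = sum(.data$sex == "female"),
      deductible_mean = mean(.data$deductible),
      gatekeeper_share = mean(.data$gatekeeper),
      pcg_count_mean = mean(.data$.pcg_count),
      multimorbid_share = mean(.data$.multimorbid),
      ambulatory_cost_mean = mean(.data$ambulatory_cost),
      inpatient_cost_mean = mean(.data$inpatient_cost),
      medication_cost_mean = mean(.data$medication_cost),
      total_cost_mean = mean(.data$total_cost),
      hospital_days_mean = mean(.data$hospital_days),
      hospitalizations_mean = mean(.data$hospitalizations),
      consultations_total_mean = mean(.data$consultations_total),
      consultations_generalist_mean = mean(.data$consultations_generalist),
      .groups = "drop"
    ) |>
    dplyr::rename(label = ".label") |>
    dplyr::arrange(.data$label)

  top <- purrr::map_chr(prof$label, function(l) {
    prev <- colMeans(m[lab == l, , drop = FALSE])
    if (all(prev == 0)) return("")
    paste(names(sort(prev[prev > 0], decreasing = TRUE))[
      seq_len(min(n_top_pcgs, sum(prev > 0)))], collapse = ",")
  })
  prof$top_pcgs <- top
  prof$label_name <- label_name_of(prof$label)
  dplyr::relocate(prof, "label", "label_name")
}

#' Joint PCG distribution of one cluster
#'
#' The 34 x 34 symmetric co-occurrence matrix of a cluster: entry (a, b)
#' counts the cluster members carrying both PCG a and PCG b; the diagonal
#' holds per-PCG patient counts. Clusters of jointly appearing PCGs show
#' heavy off-diagonals, "single disease" clusters are purely diagonal.
#'
#' @inheritParams profile_clusters
#' @param label The cluster label to profile.
#' @return A `pcg_joint`: list with `matrix` (34 x 34 integer counts),
#'   `marginals` (per-PCG prevalence among members), `label`, `n`.
#' @export
joint_pcg_distribution <- function(cohort, assignment, label,
                                   taxonomy = default_taxonomy()) {
  if (inherits(assignment, "pcg_pipeline")) assignment <- assignment$assignment
  lab <- assignment$label[match(cohort$patient_id, assignment$patient_id)]
  if (!label %in% lab) {
    abort(sprintf("no patients carry label %s.", label),
          class = "pcg_validation_error")
  }
  m <- pcg_matrix(cohort, taxonomy)[lab == label, , drop = FALSE]
  joint <- crossprod(m)
  storage.mode(joint) <- "integer"
  structure(list(matrix = joint, marginals = colMeans(m),
                 label = label, n = nrow(m)),
            class = "pcg_joint")
}

#' @export
print.pcg_joint <- function(x, ...) {
  cat(sprintf("<pcg_joint> label %s, %d patients, %d PCGs present\n",
              x$label, x$n, sum(diag(x$matrix) > 0)))
  invisible(x)
}

#' @export
#' @method tidy pcg_joint
tidy.pcg_joint <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$matrix, stringsAsFactors = FALSE)) |>
    rlang::set_names(c("pcg_a", "pcg_b", "count")) |>
    dplyr::mutate(count = as.integer(.data$count))
}

#' @export
#' @method autoplot pcg_joint
autoplot.pcg_joint <- function(object, drop_absent = TRUE, ...) {
  df <- tidy(object)
  if (drop_absent) {
    present <- rownames(object$matrix)[diag(object$matrix) > 0]
    df <- dplyr::filter(df, .data$pcg_a %in% present, .data$pcg_b %in% present)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pcg_a, y = .data$pcg_b,
                                   fill = .data$count)) +
    ggplot2::geom_tile(...) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5)) +
    ggplot2::labs(title = sprintf("Joint PCG distribution, label %s", object$label),
                  x = NULL, y = NULL)
}

#' Attach archetype names to detected clusters
#'
#' Rule-based, advisory naming of detected clusters from their profiles,
#' mirroring how the reference study read its descriptive table: the
#' cluster with the most PCGs and top costs is the complex high-cost
#' high-need group; the oldest cluster with above-average inpatient use is
#' the oldest-at-high-risk group; a near-one mean PCG count with the
#' highest medication costs marks patients with one costly disease; a
#' multimorbid cluster with below-average total costs is the slightly
#' complex group. Ties break by total cost (descending); unmatched clusters
#' are `unlabelled_<k>`. Naming never feeds back into clustering.
#'
#' @param profiles Profile tibble from [profile_clusters()] (only rows with
#'   `label >= 0` are named).
#' @return A tibble (`label`, `archetype_name`).
#' @export
name_clusters <- function(profiles) {
  cand <- dplyr::filter(profiles, .data$label >= 0L) |>
    dplyr::arrange(dplyr::desc(.data$total_cost_mean))
  out <- tibble::tibble(label = cand$label, archetype_name = NA_character_)
  if (nrow(cand) == 0L) return(out)
  take <- function(lab, name) {
    out$archetype_name[out$label == lab] <<- name
    cand <<- dplyr::filter(cand, .data$label != lab)
  }

  # most PCGs, ties by cost -> complex high-cost high-need
  i <- which.max(cand$pcg_count_mean)
  take(cand$label[i], "complex_high_cost")

  # oldest with above-average inpatient burden -> oldest at high risk
  if (nrow(cand) > 0) {
    i <- which.max(cand$age_mean)
    if (nrow(cand) == 1L ||
        cand$inpatient_cost_mean[i] >= mean(cand$inpatient_cost_mean) ||
        cand$hospital_days_mean[i] >= mean(cand$hospital_days_mean)) {
      take(cand$label[i], "oldest_high_risk")
    }
  }

  # about one PCG with the highest medication costs -> one costly disease
  if (nrow(cand) > 0) {
    near_one <- which(abs(cand$pcg_count_mean - 1) <= 0.35)
    if (length(near_one) > 0) {
      i <- near_one[which.max(cand$medication_cost_mean[near_one])]
      take(cand$label[i], "one_costly_disease")
    }
  }

  # multimorbid but below-average costs -> slightly complex
  if (nrow(cand) > 0) {
    avg_cost <- mean(profiles$total_cost_mean[profiles$label >= 0L])
    ok <- which(cand$multimorbid_share >= 0.5 & cand$total_cost_mean <= avg_cost)
    if (length(ok) > 0) take(cand$label[ok[1]], "slightly_complex")
  }

  k <- which(is.na(out$archetype_name))
  out$archetype_name[k] <- paste0("unlabelled_", out$label[k])
  out
}

#' Write Table-style profiles and joint distributions
#'
#' @param profiles Tibble from [profile_clusters()].
#' @param path CSV path.
#' @export
write_profiles <- function(profiles, path) {
  readr::write_csv(profiles, path)
  invisible(path)
}
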
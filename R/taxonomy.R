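#' Default pharmacy-based cost group (PCG) taxonomy
#'
#' The pipeline clusters patients on 34 binary PCG indicators grouped into 15
#' disease categories. The official Swiss 34-PCG list and its clinical
#' category grouping are not publicly distributed, so this default is a
#' synthetic stand-in: it contains every PCG name used by the shipped
#' archetypes (hypertension, mental, pain, asthma/COPD, thyroid, glaucoma,
#' diabetes, cancer, Parkinson, cardiac, inflammatory, immune, HIV,
#' other-mental, ...) filled out to exactly 34 PCGs in 15 categories. Users
#' holding the official list can substitute it with [read_taxonomy()]; no part
#' of the pipeline depends on the specific names.
#'
#' @return A tibble with columns `id` (0-based index), `pcg` (unique PCG
#'   name) and `category` (one of 15 disease-category labels).
#' @export
#' @examples
#' tax <- default_taxonomy()
#' nrow(tax)                      # 34
#' dplyr::n_distinct(tax$category) # 15
default_taxonomy <- function() {
  tab <- tibble::tribble(
    ~pcg,                      ~category,
    "hypertension",            "hypertension",
    "hypertension_renal",      "hypertension",
    "hypertension_combination","hypertension",
    "mental",                  "mental",
    "depression",              "mental",
    "psychosis",               "mental",
    "pain",                    "pain",
    "neuropathic_pain",        "pain",
    "asthma_copd",             "respiratory",
    "cystic_fibrosis",         "respiratory",
    "thyroid",                 "thyroid",
    "glaucoma",                "glaucoma",
    "diabetes",                "diabetes",
    "diabetes_complicated",    "diabetes",
    "cancer",                  "cancer",
    "cancer_hormonal",         "cancer",
    "parkinson",               "parkinson",
    "cardiac",                 "cardiac",
    "heart_failure",           "cardiac",
    "arrhythmia",              "cardiac",
    "anticoagulation",         "cardiac",
    "inflammatory",            "inflammatory",
    "rheumatoid_arthritis",    "inflammatory",
    "crohns_colitis",          "inflammatory",
    "immune",                  "immune",
    "transplant",              "immune",
    "hiv",                     "hiv",
    "other_mental",            "other_mental",
    "dementia",                "other_mental",
    "cholesterol",             "metabolic_other",
    "gout",                    "metabolic_other",
    "osteoporosis",            "metabolic_other",
    "epilepsy",                "metabolic_other",
    "kidney_disease",          "metabolic_other"
  )
  tab$id <- seq_len(nrow(tab)) - 1L
  validate_taxonomy(tab[, c("id", "pcg", "category")])
}

#' Validate a PCG taxonomy table
#'
#' A valid taxonomy has exactly 34 uniquely named PCGs, each mapped to exactly
#' one of exactly 15 disease categories.
#'
#' @param taxonomy A data frame with columns `pcg` and `category` (an `id`
#'   column is added if absent).
#' @return The taxonomy as a tibble with columns `id`, `pcg`, `category`,
#'   invisibly usable downstream.
#' @export
validate_taxonomy <- function(taxonomy) {
  if (!is.data.frame(taxonomy) || !all(c("pcg", "category") %in% names(taxonomy))) {
    abort("taxonomy must be a data frame with columns `pcg` and `category`.",
          class = "pcg_config_error")
  }
  taxonomy <- tibble::as_tibble(taxonomy)
  if (nrow(taxonomy) != 34L) {
    abort(sprintf("taxonomy must define exactly 34 PCGs (got %d).", nrow(taxonomy)),
          class = "pcg_config_error")
  }
  if (anyDuplicated(taxonomy$pcg)) {
    abort("taxonomy PCG names must be unique.", class = "pcg_config_error")
  }
  n_cat <- dplyr::n_distinct(taxonomy$category)
  if (n_cat != 15L) {
    abort(sprintf("taxonomy must use exactly 15 disease categories (got %d).", n_cat),
          class = "pcg_config_error")
  }
  if (!"id" %in% names(taxonomy)) taxonomy$id <- seq_len(nrow(taxonomy)) - 1L
  taxonomy[, c("id", "pcg", "category")]
}

#' Read / write a taxonomy mapping file
#'
#' The mapping is stored as a two-column CSV (`pcg`, `category`); the
#' round-trip is lossless.
#'
#' @param path File path.
#' @return `read_taxonomy()` returns a validated taxonomy tibble.
#' @export
read_taxonomy <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    pcg = readr::col_character(), category = readr::col_character()
  ))
  validate_taxonomy(tab)
}

#' @rdname read_taxonomy
#' @param taxonomy A taxonomy tibble as returned by [default_taxonomy()].
#' @export
write_taxonomy <- function(taxonomy, path) {
  taxonomy <- validate_taxonomy(taxonomy)
  readr::write_csv(taxonomy[, c("pcg", "category")], path)
  invisible(path)
}

#' Names of the PCG indicator columns in a cohort table
#'
#' @inheritParams write_taxonomy
#' @return Character vector `pcg_<name>` in taxonomy order.
#' @export
pcg_cols <- function(taxonomy = default_taxonomy()) {
  paste0("pcg_", taxonomy$pcg)
}

# Extract the n x 34 binary PCG matrix from a cohort tibble (or pass through
# an already-binary matrix/vector), validating values and dimension.
pcg_matrix <- function(x, taxonomy = default_taxonomy()) {
  cols <- pcg_cols(taxonomy)
  if (is.data.frame(x)) {
    missing <- setdiff(cols, names(x))
    if (length(missing) > 0) {
      abort(sprintf("cohort is missing PCG column(s): %s",
                    paste(head(missing, 5), collapse = ", ")),
            class = "pcg_validation_error")
    }
    m <- as.matrix(x[, cols])
  } else if (is.matrix(x)) {
    m <- x
  } else {
    m <- matrix(as.numeric(x), nrow = 1)
  }
  if (ncol(m) != nrow(taxonomy)) {
    abort(sprintf("PCG vector length must be %d (got %d).", nrow(taxonomy), ncol(m)),
          class = "pcg_validation_error")
  }
  if (!all(m %in% c(0, 1))) {
    abort("PCG flags must be 0/1.", class = "pcg_validation_error")
  }
  storage.mode(m) <- "integer"
  colnames(m) <- taxonomy$pcg
  m
}

#' Count assigned PCGs per patient
#'
#' @param x A cohort tibble with `pcg_<name>` columns, a binary matrix with 34
#'   columns, or a single length-34 0/1 vector.
#' @param taxonomy Taxonomy tibble; defaults to [default_taxonomy()].
#' @return Integer vector of PCG counts (one per row of `x`).
#' @export
#' @examples
#' pcg_count(rep(0, 34))  # 0
pcg_count <- function(x, taxonomy = default_taxonomy()) {
  as.integer(rowSums(pcg_matrix(x, taxonomy)))
}

#' Is a patient multimorbid?
#'
#' Multimorbidity is defined as assignment of two or more PCGs within the
#' observation year.
#'
#' @inheritParams pcg_count
#' @return Logical vector, `TRUE` where the PCG count is >= 2.
#' @export
is_multimorbid <- function(x, taxonomy = default_taxonomy()) {
  pcg_count(x, taxonomy) >= 2L
}

#' Per-category PCG counts
#'
#' Collapses the 34 PCG flags onto the 15 disease categories.
#'
#' @inheritParams pcg_count
#' @return An integer matrix (rows = patients, columns = the 15 categories in
#'   taxonomy order); row sums equal [pcg_count()].
#' @export
category_profile <- function(x, taxonomy = default_taxonomy()) {
  taxonomy <- validate_taxonomy(taxonomy)
  m <- pcg_matrix(x, taxonomy)
  cats <- unique(taxonomy$category)
  # 34 x 15 membership indicator; counts by matrix product
  memb <- sapply(cats, function(cc) as.integer(taxonomy$category == cc))
  out <- m %*% memb
  storage.mode(out) <- "integer"
  colnames(out) <- cats
  out
}

# Number of distinct disease categories spanned by each patient's PCGs.
category_span <- function(x, taxonomy = default_taxonomy()) {
  as.integer(rowSums(category_profile(x, taxonomy) > 0L))
}
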
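#' Build one population-archetype specification
#'
#' An archetype is a latent patient type driving the synthetic cohort
#' generator: it fixes a PCG pool, a co-occurrence pattern, and the
#' demographic / cost / utilization levels of its members.
#'
#' @param label Archetype name.
#' @param proportion Fraction of the cohort.
#' @param mean_pcg_count Expected number of PCGs per member.
#' @param multimorbid_share Expected fraction of members with >= 2 PCGs.
#' @param pcg_pool Character vector of PCG names the archetype draws from.
#' @param cooccurrence One of `"joint"` (a shared patient-level severity makes
#'   pool PCGs positively correlated), `"rare_joint"` (independent draws at
#'   low per-PCG rates), `"single"` (a fixed small number of distinct PCGs).
#' @param pcg_weights Optional nonnegative weights over `pcg_pool` shaping the
#'   per-PCG draw rates (e.g. two dominant "signature" PCGs plus rare
#'   auxiliaries); `NULL` means uniform. The expected PCG count stays
#'   `mean_pcg_count` regardless of the weights.
#' @param age_mean,age_sd Age distribution (years, truncated at 50).
#' @param male_share Fraction male.
#' @param deductible_mean Mean annual deductible (CHF).
#' @param gatekeeper_share Fraction enrolled in a gatekeeping model.
#' @param ambulatory_cost_mean,inpatient_cost_mean,medication_cost_mean Mean
#'   annual costs (CHF); total cost is their sum by construction.
#' @param hospital_days_mean,hospitalizations_mean,consultations_total_mean,consultations_generalist_mean
#'   Mean annual utilization counts.
#' @return A one-row tibble (pool as a list-column).
#' @export
archetype_spec <- function(label, proportion, mean_pcg_count, multimorbid_share,
                           pcg_pool, cooccurrence,
                           age_mean, age_sd, male_share,
                           deductible_mean, gatekeeper_share,
                           ambulatory_cost_mean, inpatient_cost_mean,
                           medication_cost_mean,
                           hospital_days_mean, hospitalizations_mean,
                           consultations_total_mean, consultations_generalist_mean,
                           pcg_weights = NULL) {
  cooccurrence <- match.arg(cooccurrence, c("joint", "rare_joint", "single"))
  if (!is.null(pcg_weights) && length(pcg_weights) != length(pcg_pool)) {
    abort("pcg_weights must match pcg_pool in length.",
          class = "pcg_validation_error")
  }
  tibble::tibble(
    label = label, proportion = proportion,
    mean_pcg_count = mean_pcg_count, multimorbid_share = multimorbid_share,
    pcg_pool = list(as.character(pcg_pool)),
    pcg_weights = list(pcg_weights), cooccurrence = cooccurrence,
    age_mean = age_mean, age_sd = age_sd, male_share = male_share,
    deductible_mean = deductible_mean, gatekeeper_share = gatekeeper_share,
    ambulatory_cost_mean = ambulatory_cost_mean,
    inpatient_cost_mean = inpatient_cost_mean,
    medication_cost_mean = medication_cost_mean,
    hospital_days_mean = hospital_days_mean,
    hospitalizations_mean = hospitalizations_mean,
    consultations_total_mean = consultations_total_mean,
    consultations_generalist_mean = consultations_generalist_mean
  )
}

new_cohort_spec <- function(n_patients, archetypes, seed = 1L, separation = 1,
                            cost_cv = 1, deductible_cv = 0.5, nb_size = 1) {
  structure(
    list(n_patients = as.integer(n_patients), archetypes = archetypes,
         seed = as.integer(seed), separation = separation,
         cost_cv = cost_cv, deductible_cv = deductible_cv, nb_size = nb_size),
    class = "cohort_spec"
  )
}

#' Default synthetic-cohort specification (published-table archetypes)
#'
#' Encodes the eight population archetypes of the reference claims cohort of
#' 18,732 insured people aged >= 50: an outlier group, four clusterable
#' multimorbidity archetypes, and three "single" groups (no PCGs, only
#' hypertension PCGs, only mental-disease PCGs). Proportions are taken from
#' the printed group counts (321 / 817 / 709 / 531 / 1056 / 12,720 / 1,813 /
#' 765), and per-archetype mean PCG counts, multimorbid shares, ages, costs
#' and utilization from the published descriptive statistics.
#'
#' @param n_patients Cohort size; default 18,732.
#' @param separation Scalar in \[0, 1\]: 1 keeps archetype PCG pools as
#'   configured, 0 replaces every drawn PCG by a draw from the pooled union.
#' @param seed Generation seed stored in the spec.
#' @return A `cohort_spec` object.
#' @export
#' @examples
#' spec <- default_cohort_spec()
#' sum(spec$archetypes$proportion)  # 1
default_cohort_spec <- function(n_patients = 18732L, separation = 1, seed = 1L) {
  n_ref <- 18732
  arch <- dplyr::bind_rows(
    archetype_spec("outlier", 321 / n_ref, 1.2, 0.1,
                   c("pain", "neuropathic_pain", "osteoporosis", "cholesterol"),
                   "joint", 66.3, 10.8, 0.40, 511, 0.4, 7967, 2134, 2683,
                   4.3, 0.4, 16.0, 10.0),
    archetype_spec("complex_high_cost", 817 / n_ref, 2.1, 0.8,
                   c("mental", "hypertension", "pain", "asthma_copd", "cholesterol"),
                   "joint", 66.3, 10.6, 0.40, 448, 0.4, 11731, 3109, 4073,
                   6.6, 0.5, 20.2, 11.6),
    archetype_spec("slightly_complex", 709 / n_ref, 1.7, 0.6,
                   c("thyroid", "hypertension", "glaucoma", "cholesterol", "osteoporosis"),
                   "joint", 67.8, 10.2, 0.29, 535, 0.4, 7477, 1811, 2221,
                   3.6, 0.3, 17.0, 9.8),
    archetype_spec("oldest_high_risk", 531 / n_ref, 1.3, 0.3,
                   c("asthma_copd", "parkinson", "cardiac", "heart_failure", "pain"),
                   "rare_joint", 69.4, 10.9, 0.53, 524, 0.4, 9728, 2749, 3587,
                   5.6, 0.4, 17.5, 11.3),
    archetype_spec("one_costly_disease", 1056 / n_ref, 1.1, 0.1,
                   c("cancer", "diabetes", "inflammatory", "immune",
                     "other_mental", "glaucoma", "hiv"),
                   "single", 68.1, 11.2, 0.51, 562, 0.4, 10362, 1575, 4450,
                   3.4, 0.3, 16.1, 9.4),
    archetype_spec("no_pcg", 12720 / n_ref, 0.0, 0.0,
                   character(0),
                   "single", 64.0, 10.4, 0.45, 908, 0.5, 4074, 1199, 965,
                   2.0, 0.2, 9.9, 6.0),
    archetype_spec("hypertension_only", 1813 / n_ref, 1.0, 0.0,
                   c("hypertension", "hypertension_renal", "hypertension_combination"),
                   "single", 67.6, 9.7, 0.64, 612, 0.5, 5462, 1372, 1732,
                   2.4, 0.3, 12.7, 8.3),
    archetype_spec("mental_only", 765 / n_ref, 1.0, 0.0,
                   c("mental", "depression", "psychosis"),
                   "single", 63.2, 10.9, 0.29, 558, 0.5, 7571, 1585, 1961,
                   3.5, 0.3, 18.5, 9.5)
  )
  new_cohort_spec(n_patients, arch, seed = seed, separation = separation)
}

#' Planted-archetype benchmark specification
#'
#' A cohort of four equally sized, clusterable archetypes with disjoint PCG
#' pools spanning distinct disease categories, used for planted-partition
#' recovery experiments. Each pool holds two high-prevalence "signature"
#' PCGs plus four low-rate auxiliaries (weights 3:3:1:1:1:1), the way real
#' multimorbidity segments share a disease core: members present the
#' signatures plus a varying auxiliary mix, span at least two disease
#' categories (hence survive the pre-clustering filters), and archetypes
#' stay internally cohesive rather than mutually equidistant.
#'
#' @inheritParams default_cohort_spec
#' @param mean_pcg_count Expected PCGs per patient in every archetype.
#' @return A `cohort_spec` object.
#' @export
planted_cohort_spec <- function(n_patients = 1500L, separation = 1,
                                mean_pcg_count = 2.8, seed = 1L) {
  pools <- list(
    planted_a = c("mental", "depression", "pain", "neuropathic_pain",
                  "asthma_copd", "cholesterol"),
    planted_b = c("hypertension", "hypertension_renal", "thyroid",
                  "glaucoma", "osteoporosis", "gout"),
    planted_c = c("cardiac", "heart_failure", "arrhythmia", "parkinson",
                  "epilepsy", "kidney_disease"),
    planted_d = c("cancer", "diabetes", "inflammatory", "immune",
                  "hiv", "transplant")
  )
  demo <- list(  # age / cost / use levels are incidental for recovery runs
    c(64, 10, 0.45, 600, 0.5, 8000, 2000, 2500, 3, 0.3, 15, 9),
    c(67, 10, 0.50, 600, 0.5, 8000, 2000, 2500, 3, 0.3, 15, 9),
    c(72, 9, 0.55, 550, 0.4, 9000, 2500, 3000, 4, 0.4, 16, 10),
    c(68, 11, 0.50, 580, 0.4, 9500, 1800, 4000, 3, 0.3, 15, 9)
  )
  arch <- dplyr::bind_rows(purrr::map2(names(pools), demo, function(lab, d) {
    archetype_spec(lab, 0.25, mean_pcg_count, NA_real_, pools[[lab]],
                   "rare_joint", d[1], d[2], d[3], d[4], d[5], d[6], d[7],
                   d[8], d[9], d[10], d[11], d[12],
                   pcg_weights = c(3, 3, 1, 1, 1, 1))
  }))
  new_cohort_spec(n_patients, arch, seed = seed, separation = separation)
}

#' Validate a cohort specification
#'
#' @param spec A `cohort_spec`.
#' @param taxonomy Taxonomy the pools must be drawn from.
#' @return The spec, invisibly; errors on violation.
#' @export
validate_cohort_spec <- function(spec, taxonomy = default_taxonomy()) {
  if (!inherits(spec, "cohort_spec")) {
    abort("`spec` must be a cohort_spec object.", class = "pcg_validation_error")
  }
  if (spec$n_patients <= 0L) {
    abort("n_patients must be positive.", class = "pcg_validation_error")
  }
  a <- spec$archetypes
  if (abs(sum(a$proportion) - 1) > 1e-8) {
    abort("archetype proportions must sum to 1.", class = "pcg_validation_error")
  }
  bad_pool <- purrr::map_lgl(a$pcg_pool, ~ !all(.x %in% taxonomy$pcg))
  if (any(bad_pool)) {
    abort(sprintf("archetype pool(s) outside the taxonomy: %s",
                  paste(a$label[bad_pool], collapse = ", ")),
          class = "pcg_validation_error")
  }
  empty <- purrr::map_lgl(a$pcg_pool, ~ length(.x) == 0) & a$mean_pcg_count > 0
  if (any(empty)) {
    abort(sprintf("archetype(s) with empty pool but positive mean PCG count: %s",
                  paste(a$label[empty], collapse = ", ")),
          class = "pcg_validation_error")
  }
  if (spec$separation < 0 || spec$separation > 1) {
    abort("separation must lie in [0, 1].", class = "pcg_validation_error")
  }
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d patients, %d archetypes, separation %.2f, seed %d\n",
              x$n_patients, nrow(x$archetypes), x$separation, x$seed))
  print(x$archetypes[, c("label", "proportion", "mean_pcg_count",
                         "multimorbid_share", "cooccurrence")])
  invisible(x)
}

# Largest-remainder apportionment of n over proportions p (sums exactly to n).
apportion <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Deterministic per-archetype allocation of PCG counts hitting round(s*n)
# multimorbid members and round(m*n) total PCGs exactly. Returns an integer
# vector of per-patient PCG counts (length n).
allocate_pcg_counts <- function(n, mean_pcg, mm_share, pool_size, label = "") {
  if (n == 0L) return(integer(0))
  if (mean_pcg == 0) return(rep(0L, n))
  n_mm <- as.integer(round(mm_share * n))
  total <- as.integer(round(mean_pcg * n))
  rem <- total - 2L * n_mm
  if (rem < 0L) {
    abort(sprintf(
      "archetype '%s': mean_pcg_count %.2f too low for multimorbid_share %.2f.",
      label, mean_pcg, mm_share), class = "pcg_validation_error")
  }
  n_single <- min(rem, n - n_mm)
  extra <- rem - n_single                      # additional PCGs for multimorbid members
  counts <- c(rep(2L, n_mm), rep(1L, n_single), rep(0L, n - n_mm - n_single))
  if (extra > 0L) {
    if (n_mm == 0L) {
      abort(sprintf("archetype '%s': cannot place %d extra PCGs without multimorbid members.",
                    label, extra), class = "pcg_validation_error")
    }
    add <- rep(extra %/% n_mm, n_mm)
    r <- extra %% n_mm
    if (r > 0) add[seq_len(r)] <- add[seq_len(r)] + 1L
    counts[seq_len(n_mm)] <- counts[seq_len(n_mm)] + as.integer(add)
  }
  if (max(counts) > pool_size) {
    abort(sprintf("archetype '%s': allocation needs %d distinct PCGs but pool has %d.",
                  label, max(counts), pool_size), class = "pcg_validation_error")
  }
  counts
}

# Draw the n x 34 PCG flag matrix for one archetype.
draw_pcg_flags <- function(n, arch, taxonomy, mode, special_categories) {
  p <- nrow(taxonomy)
  flags <- matrix(0L, n, p, dimnames = list(NULL, taxonomy$pcg))
  pool <- arch$pcg_pool[[1]]
  if (n == 0L || length(pool) == 0L || arch$mean_pcg_count == 0) return(flags)
  pool_idx <- match(pool, taxonomy$pcg)
  m <- arch$mean_pcg_count

  if (mode == "exact_counts") {
    counts <- allocate_pcg_counts(n, m, arch$multimorbid_share, length(pool),
                                  arch$label)
    # pool restricted for 1-PCG members of multi-category archetypes, so such
    # members cannot masquerade as single-hypertension / single-mental patients
    pool_cats <- taxonomy$category[pool_idx]
    restricted <- pool_idx[!pool_cats %in% special_categories]
    multi_cat <- length(unique(pool_cats)) > 1L
    for (i in seq_len(n)) {
      k <- counts[i]
      if (k == 0L) next
      if (k == 1L && multi_cat && length(restricted) > 0L) {
        flags[i, sample(restricted, 1L)] <- 1L
      } else {
        flags[i, sample(pool_idx, k)] <- 1L
      }
    }
    return(flags)
  }

  wts <- arch$pcg_weights[[1]] %||% rep(1, length(pool))
  base_pr <- pmin(1, m * wts / sum(wts))   # per-PCG rates, E[count] = m

  switch(arch$cooccurrence,
    joint = {
      # shared per-patient severity multiplier induces positive co-occurrence
      w <- sample(c(0.7, 1.3), n, replace = TRUE)
      pr <- pmin(1, outer(w, base_pr))
      flags[, pool_idx] <- matrix(rbinom(n * length(pool), 1L, pr),
                                  n, length(pool))
    },
    rare_joint = {
      pr <- matrix(base_pr, n, length(pool), byrow = TRUE)
      flags[, pool_idx] <- matrix(rbinom(n * length(pool), 1L, pr),
                                  n, length(pool))
    },
    single = {
      k <- floor(m) + rbinom(n, 1L, m - floor(m))
      k <- pmin(k, length(pool))
      for (i in seq_len(n)) {
        if (k[i] > 0L) flags[i, sample(pool_idx, k[i])] <- 1L
      }
    }
  )
  flags
}

# Blend archetype pools toward the shared union pool: each set flag is, with
# probability (1 - separation), relocated to a uniformly drawn union-pool PCG.
apply_separation <- function(flags, separation, union_idx) {
  if (separation >= 1 || length(union_idx) == 0L) return(flags)
  set <- which(flags == 1L, arr.ind = TRUE)
  if (nrow(set) == 0L) return(flags)
  move <- runif(nrow(set)) > separation
  if (!any(move)) return(flags)
  rows <- set[move, 1L]
  flags[set[move, , drop = FALSE]] <- 0L
  dest <- sample(union_idx, sum(move), replace = TRUE)
  flags[cbind(rows, dest)] <- 1L
  flags
}

#' Generate a synthetic insured-population cohort
#'
#' Draws one row per insured person: 34 binary PCG flags, demographics,
#' insurance attributes, annual costs (CHF) and utilization counts, plus the
#' generator-only ground-truth archetype label (`true_archetype`), which every
#' pipeline stage except evaluation must ignore.
#'
#' In `"stochastic"` mode archetype membership is multinomial and PCG counts
#' hit their targets in expectation. In `"exact_counts"` mode archetype sizes
#' are the largest-remainder apportionment of `round(proportion * n)` and each
#' archetype's total PCG count and multimorbid head-count are hit exactly by a
#' deterministic allocation of 0/1/2/3+-PCG patients.
#'
#' Costs are log-normal with archetype means (coefficient of variation
#' `spec$cost_cv`, default 1, the heavy right tail typical of claims data) and
#' `total_cost` is the exact sum of the three components. Utilization counts
#' are negative binomial (dispersion `spec$nb_size`); generalist consultations
#' are a binomial thinning of total consultations, so the constraint
#' generalist <= total holds row-wise.
#'
#' @param spec A `cohort_spec`.
#' @param mode `"stochastic"` or `"exact_counts"`.
#' @param taxonomy Taxonomy tibble.
#' @param seed Overrides `spec$seed` when given. Fixed seed implies a
#'   bit-identical cohort.
#' @return A tibble of patient records.
#' @export
#' @examples
#' coh <- generate_cohort(default_cohort_spec(n_patients = 200), seed = 7)
#' dplyr::count(coh, true_archetype)
generate_cohort <- function(spec, mode = c("stochastic", "exact_counts"),
                            taxonomy = default_taxonomy(), seed = NULL) {
  mode <- match.arg(mode)
  taxonomy <- validate_taxonomy(taxonomy)
  validate_cohort_spec(spec, taxonomy)
  seed <- as.integer(seed %||% spec$seed)
  a <- spec$archetypes
  special_categories <- intersect(c("hypertension", "mental"), taxonomy$category)
  union_idx <- match(unique(unlist(a$pcg_pool)), taxonomy$pcg)

  with_preserved_seed(seed, {
    n_arch <- if (mode == "exact_counts") {
      apportion(spec$n_patients, a$proportion)
    } else {
      as.integer(tabulate(sample.int(nrow(a), spec$n_patients, replace = TRUE,
                                     prob = a$proportion), nbins = nrow(a)))
    }

    parts <- purrr::map(seq_len(nrow(a)), function(j) {
      arch <- a[j, ]
      n <- n_arch[j]
      if (n == 0L) return(NULL)
      flags <- draw_pcg_flags(n, arch, taxonomy, mode, special_categories)
      flags <- apply_separation(flags, spec$separation, union_idx)

      cv <- spec$cost_cv
      sdlog <- sqrt(log(1 + cv^2))
      draw_cost <- function(mu) {
        if (mu <= 0) return(rep(0, n))
        rlnorm(n, log(mu) - sdlog^2 / 2, sdlog)
      }
      dcv <- spec$deductible_cv
      dsd <- sqrt(log(1 + dcv^2))
      amb <- draw_cost(arch$ambulatory_cost_mean)
      inp <- draw_cost(arch$inpatient_cost_mean)
      med <- draw_cost(arch$medication_cost_mean)
      cons_tot <- rnbinom(n, size = spec$nb_size, mu = arch$consultations_total_mean)
      p_gen <- min(1, arch$consultations_generalist_mean /
                        max(arch$consultations_total_mean, 1e-9))
      rec <- tibble::tibble(
        age = pmax(50, rnorm(n, arch$age_mean, arch$age_sd)),
        sex = ifelse(rbinom(n, 1L, arch$male_share) == 1L, "male", "female"),
        deductible = rlnorm(n, log(arch$deductible_mean) - dsd^2 / 2, dsd),
        gatekeeper = rbinom(n, 1L, arch$gatekeeper_share) == 1L,
        ambulatory_cost = amb, inpatient_cost = inp, medication_cost = med,
        total_cost = amb + inp + med,
        hospital_days = rnbinom(n, size = spec$nb_size, mu = arch$hospital_days_mean),
        hospitalizations = rnbinom(n, size = spec$nb_size,
                                   mu = arch$hospitalizations_mean),
        consultations_total = cons_tot,
        consultations_generalist = rbinom(n, cons_tot, p_gen),
        true_archetype = arch$label
      )
      dplyr::bind_cols(tibble::as_tibble(as.data.frame(flags)) |>
                         rlang::set_names(pcg_cols(taxonomy)), rec)
    })
    cohort <- dplyr::bind_rows(parts)
    # stable shuffle so archetypes are interleaved as in real data
    cohort <- cohort[sample.int(nrow(cohort)), ]
    cohort$patient_id <- sprintf("P%06d", seq_len(nrow(cohort)))
    dplyr::relocate(cohort, "patient_id")
  })
}

#' Per-PCG marginal prevalences of a cohort
#'
#' @param cohort Cohort tibble with `pcg_<name>` columns.
#' @param taxonomy Taxonomy tibble.
#' @return Named numeric vector of 34 fractions in taxonomy order.
#' @export
marginal_prevalences <- function(cohort, taxonomy = default_taxonomy()) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L) {
    abort("cohort must be a nonempty data frame.", class = "pcg_validation_error")
  }
  colMeans(pcg_matrix(cohort, taxonomy))
}

#' Read / write a cohort CSV
#'
#' Cohorts are persisted as plain CSV with one column per patient field and
#' one `pcg_<name>` column per taxonomy PCG. `read_cohort()` validates the
#' schema and names the first missing column in its error.
#'
#' @param path CSV path.
#' @param taxonomy Taxonomy the PCG columns must match.
#' @return `read_cohort()` returns the cohort tibble.
#' @export
read_cohort <- function(path, taxonomy = default_taxonomy()) {
  cohort <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("patient_id", pcg_cols(taxonomy), "age", "sex", "deductible",
                "gatekeeper", "ambulatory_cost", "inpatient_cost",
                "medication_cost", "total_cost", "hospital_days",
                "hospitalizations", "consultations_total",
                "consultations_generalist")
  missing <- setdiff(required, names(cohort))
  if (length(missing) > 0) {
    abort(sprintf("cohort file %s is missing required column `%s`.",
                  path, missing[1]), class = "pcg_validation_error")
  }
  cohort
}

#' @rdname read_cohort
#' @param cohort Cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' Read / write a cohort specification as YAML
#'
#' @param path YAML path.
#' @return `read_cohort_spec()` returns a `cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  y <- yaml::read_yaml(path)
  arch <- dplyr::bind_rows(purrr::map(y$archetypes, function(ar) {
    ar$pcg_pool <- list(as.character(unlist(ar$pcg_pool)))
    ar$pcg_weights <- list(if (is.null(ar$pcg_weights)) NULL else
                             as.numeric(unlist(ar$pcg_weights)))
    tibble::as_tibble(ar)
  }))
  new_cohort_spec(y$n_patients, arch, seed = y$seed, separation = y$separation,
                  cost_cv = y$cost_cv, deductible_cv = y$deductible_cv,
                  nb_size = y$nb_size)
}

#' @rdname read_cohort_spec
#' @param spec A `cohort_spec`.
#' @export
write_cohort_spec <- function(spec, path) {
  arch <- purrr::transpose(spec$archetypes)
  arch <- purrr::map(arch, function(ar) {
    ar$pcg_pool <- as.list(ar$pcg_pool)
    ar$pcg_weights <- if (is.null(ar$pcg_weights)) NULL else as.list(ar$pcg_weights)
    ar
  })
  yaml::write_yaml(
    list(n_patients = spec$n_patients, seed = spec$seed,
         separation = spec$separation, cost_cv = spec$cost_cv,
         deductible_cv = spec$deductible_cv, nb_size = spec$nb_size,
         archetypes = arch),
    path)
  invisible(path)
}

# Run code under a fixed seed without clobbering the caller's RNG stream.
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
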
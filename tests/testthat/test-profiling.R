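toy_assignment <- function(cohort, labels) {
  tibble::tibble(patient_id = cohort$patient_id, label = as.integer(labels))
}

test_that("cluster profiles match a direct recount on a hand-built fixture", {
  flags <- flags_for(list(
    c("hypertension", "pain"), c("hypertension", "pain", "diabetes"),
    "mental", character(0), c("cancer", "hiv"),
    "thyroid", c("thyroid", "glaucoma"), character(0),
    c("cardiac", "heart_failure", "parkinson"), "pain"
  ))
  coh <- make_toy_cohort(flags,
    age = c(55, 60, 65, 70, 75, 80, 85, 90, 95, 100),
    ambulatory_cost = seq(100, 1000, by = 100))
  coh$total_cost <- coh$ambulatory_cost + coh$inpatient_cost + coh$medication_cost
  labels <- c(0, 0, 0, 1, 1, 1, 1, 2, 2, 2)
  prof <- profile_clusters(coh, toy_assignment(coh, labels))

  expect_equal(prof$n, c(3L, 4L, 3L))
  expect_equal(sum(prof$n), nrow(coh))
  expect_equal(sum(prof$pct), 100)
  # spreadsheet-style recomputation for cluster 0
  expect_equal(prof$age_mean[1], mean(c(55, 60, 65)))
  expect_equal(prof$pcg_count_mean[1], mean(c(2, 3, 1)))
  expect_equal(prof$multimorbid_share[1], 2 / 3)
  expect_equal(prof$ambulatory_cost_mean[1], mean(c(100, 200, 300)))
  # cluster 1: one multimorbid patient out of four
  expect_equal(prof$pcg_count_mean[2], mean(c(0, 2, 1, 2)))
  expect_equal(prof$multimorbid_share[2], 0.5)
  expect_true(grepl("thyroid", prof$top_pcgs[2]))
})

test_that("degenerate clusters profile correctly", {
  flags <- flags_for(list(character(0), character(0), c("diabetes", "cancer")))
  coh <- make_toy_cohort(flags)
  prof <- profile_clusters(coh, toy_assignment(coh, c(-2, -2, 0)))
  no_pcg <- prof[prof$label == -2L, ]
  expect_equal(no_pcg$pcg_count_mean, 0)
  expect_equal(no_pcg$multimorbid_share, 0)
  expect_equal(no_pcg$top_pcgs, "")
  expect_equal(prof$multimorbid_share[prof$label == 0L], 1)   # single 2-PCG patient

  expect_error(profile_clusters(coh, toy_assignment(coh, c(0, NA, 0))),
               class = "pcg_validation_error")
  expect_error(profile_clusters(coh, toy_assignment(coh, c(0, 0, 0))[-1, ]),
               class = "pcg_validation_error")
})

test_that("joint PCG distributions equal a brute-force pairwise recount", {
  set.seed(77)
  flags <- matrix(rbinom(20 * 34, 1, 0.15), 20, 34)
  coh <- make_toy_cohort(flags)
  jd <- joint_pcg_distribution(coh, toy_assignment(coh, rep(0, 20)), 0)
  expect_equal(unname(jd$matrix), bf_joint(flags))
  expect_true(isSymmetric(jd$matrix))
  expect_equal(unname(diag(jd$matrix)), unname(colSums(flags)))
  # off-diagonals bounded by the smaller marginal
  mins <- outer(diag(jd$matrix), diag(jd$matrix), pmin)
  expect_true(all(jd$matrix <= mins))
  expect_error(joint_pcg_distribution(coh, toy_assignment(coh, rep(0, 20)), 9),
               class = "pcg_validation_error")
})

test_that("single-disease clusters have purely diagonal joint matrices", {
  flags <- flags_for(list("cancer", "diabetes", "cancer", "hiv"))
  coh <- make_toy_cohort(flags)
  jd <- joint_pcg_distribution(coh, toy_assignment(coh, rep(0, 4)), 0)
  off <- jd$matrix; diag(off) <- 0L
  expect_true(all(off == 0L))

  both <- flags_for(list(c("hypertension", "pain"), c("hypertension", "pain")))
  coh2 <- make_toy_cohort(both)
  jd2 <- joint_pcg_distribution(coh2, toy_assignment(coh2, rep(0, 2)), 0)
  expect_equal(jd2$matrix["hypertension", "pain"], 2L)
})

test_that("rule-based naming reproduces the published cluster reading", {
  # profile rows shaped like the published descriptive table (4 detected clusters)
  profs <- tibble::tibble(
    label = 0:3,
    age_mean = c(66.3, 67.8, 69.4, 68.1),
    pcg_count_mean = c(2.1, 1.7, 1.3, 1.1),
    multimorbid_share = c(0.8, 0.6, 0.3, 0.1),
    inpatient_cost_mean = c(3109, 1811, 2749, 1575),
    medication_cost_mean = c(4073, 2221, 3587, 4450),
    total_cost_mean = c(19950, 12440, 17057, 17312),
    hospital_days_mean = c(6.6, 3.6, 5.6, 3.4)
  )
  nm <- name_clusters(profs)
  expect_equal(nm$archetype_name[nm$label == 0], "complex_high_cost")
  expect_equal(nm$archetype_name[nm$label == 1], "slightly_complex")
  expect_equal(nm$archetype_name[nm$label == 2], "oldest_high_risk")
  expect_equal(nm$archetype_name[nm$label == 3], "one_costly_disease")

  # a lone detected cluster receives exactly one name
  single <- profs[1, ]
  nm1 <- name_clusters(single)
  expect_equal(nrow(nm1), 1L)
  expect_equal(nm1$archetype_name, "complex_high_cost")
})

test_that("profiling an exact-counts cohort reproduces the spec values at table precision", {
  spec <- default_cohort_spec(n_patients = 4000L)
  coh <- generate_cohort(spec, mode = "exact_counts", seed = 80)
  # label patients by their generating archetype
  labs <- match(coh$true_archetype, spec$archetypes$label) - 1L
  prof <- profile_clusters(coh, toy_assignment(coh, labs))
  for (j in seq_len(nrow(spec$archetypes))) {
    row <- prof[prof$label == j - 1L, ]
    expect_equal(round(row$pcg_count_mean, 1), spec$archetypes$mean_pcg_count[j])
    expect_equal(round(row$multimorbid_share, 1), spec$archetypes$multimorbid_share[j])
  }
  expect_equal(sum(prof$n), 4000L)
})
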
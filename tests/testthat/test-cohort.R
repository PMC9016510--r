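test_that("default cohort spec mirrors the published population", {
  spec <- default_cohort_spec()
  a <- spec$archetypes
  expect_equal(sum(a$proportion), 1, tolerance = 1e-12)
  expect_equal(a$mean_pcg_count[a$label == "complex_high_cost"], 2.1)
  expect_equal(a$mean_pcg_count[a$label == "no_pcg"], 0)
  expect_equal(a$multimorbid_share[a$label == "complex_high_cost"], 0.8)
  expect_equal(spec$n_patients, 18732L)
  # proportions carry the printed group counts, not rounded percentages
  expect_equal(round(a$proportion[a$label == "no_pcg"] * 18732), 12720)
  expect_equal(round(a$proportion[a$label == "hypertension_only"] * 18732), 1813)
})

test_that("invalid specs are rejected", {
  spec <- default_cohort_spec()
  bad <- spec; bad$archetypes$proportion[1] <- bad$archetypes$proportion[1] + 0.2
  expect_error(validate_cohort_spec(bad), class = "pcg_validation_error")

  bad <- spec; bad$archetypes$pcg_pool[[2]] <- character(0)
  expect_error(generate_cohort(bad), class = "pcg_validation_error")

  bad <- spec; bad$archetypes$pcg_pool[[2]] <- c("not_a_pcg")
  expect_error(validate_cohort_spec(bad), class = "pcg_validation_error")

  bad <- spec; bad$separation <- 1.5
  expect_error(validate_cohort_spec(bad), class = "pcg_validation_error")
})

test_that("exact_counts mode hits archetype sizes, PCG totals and multimorbid counts", {
  spec <- default_cohort_spec(n_patients = 2000L)
  coh <- generate_cohort(spec, mode = "exact_counts", seed = 2)
  expect_equal(nrow(coh), 2000L)
  k <- pcg_count(coh)
  tab <- table(coh$true_archetype)
  for (j in seq_len(nrow(spec$archetypes))) {
    a <- spec$archetypes[j, ]
    n_j <- as.integer(tab[a$label])
    in_a <- coh$true_archetype == a$label
    expect_equal(sum(k[in_a]), round(a$mean_pcg_count * n_j))
    expect_equal(sum(k[in_a] >= 2), round(a$multimorbid_share * n_j))
  }
  # largest-remainder sizes sum to n and are within 1 of proportional shares
  expect_true(all(abs(as.integer(tab) -
                        2000 * spec$archetypes$proportion[
                          match(names(tab), spec$archetypes$label)]) <= 1))
})

test_that("stochastic generation matches archetype means in expectation", {
  spec <- planted_cohort_spec(n_patients = 2500L, mean_pcg_count = 2.8)
  coh <- generate_cohort(spec, seed = 8)
  k <- pcg_count(coh)
  means <- tapply(k, coh$true_archetype, mean)
  expect_true(all(abs(means - 2.8) < 0.15))

  # balanced version of the default population so every archetype is large
  spec2 <- default_cohort_spec(n_patients = 12000L)
  spec2$archetypes$proportion <- rep(1 / 8, 8)
  coh2 <- generate_cohort(spec2, seed = 9)
  k2 <- pcg_count(coh2)
  means2 <- tapply(k2, coh2$true_archetype, mean)
  m_target <- spec2$archetypes$mean_pcg_count[
    match(names(means2), spec2$archetypes$label)]
  expect_true(all(abs(means2 - m_target) <= 0.1))
})

test_that("every generated record satisfies the accounting identities", {
  coh <- generate_cohort(default_cohort_spec(n_patients = 1500L), seed = 4)
  expect_equal(coh$total_cost,
               coh$ambulatory_cost + coh$inpatient_cost + coh$medication_cost)
  expect_true(all(coh$consultations_generalist <= coh$consultations_total))
  expect_true(all(coh$age >= 50))
  expect_true(all(coh$deductible >= 0))
  expect_true(all(coh$hospital_days >= 0 & coh$hospital_days == round(coh$hospital_days)))
})

test_that("generation is bit-for-bit reproducible under a fixed seed", {
  spec <- default_cohort_spec(n_patients = 800L)
  a <- generate_cohort(spec, seed = 31)
  b <- generate_cohort(spec, seed = 31)
  expect_identical(a, b)
  c <- generate_cohort(spec, seed = 32)
  expect_false(identical(a, c))
})

test_that("a single archetype with zero mean PCG count yields all-zero flag vectors", {
  spec <- default_cohort_spec()
  one <- spec
  one$archetypes <- spec$archetypes[spec$archetypes$label == "no_pcg", ]
  one$archetypes$proportion <- 1
  one$n_patients <- 50L
  coh <- generate_cohort(one, seed = 3)
  expect_true(all(pcg_count(coh) == 0L))
})

test_that("marginal prevalences equal a direct per-column recount", {
  spec <- default_cohort_spec(n_patients = 50L)
  coh <- generate_cohort(spec, seed = 12)
  prev <- marginal_prevalences(coh)
  expect_length(prev, 34L)
  for (nm in pcg_cols()) {   # brute-force recount
    expect_equal(unname(prev[sub("^pcg_", "", nm)]), mean(coh[[nm]]))
  }
  one <- make_toy_cohort(flags_for(list("thyroid")))
  p1 <- marginal_prevalences(one)
  expect_equal(unname(p1["thyroid"]), 1)
  expect_equal(sum(p1), 1)
  expect_error(marginal_prevalences(one[0, ]), class = "pcg_validation_error")
})

test_that("cohort CSV and spec YAML round-trip", {
  spec <- planted_cohort_spec(n_patients = 120L, separation = 0.7)
  coh <- generate_cohort(spec, seed = 5)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, csv)
  back <- read_cohort(csv)
  expect_equal(nrow(back), 120L)
  expect_equal(as.data.frame(back[, pcg_cols()]), as.data.frame(coh[, pcg_cols()]))

  # schema validation names the missing column
  broken <- coh[, setdiff(names(coh), "pcg_thyroid")]
  csv2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(broken, csv2)
  expect_error(read_cohort(csv2), "pcg_thyroid", class = "pcg_validation_error")

  yml <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_spec(spec, yml)
  spec2 <- read_cohort_spec(yml)
  expect_equal(spec2$n_patients, spec$n_patients)
  expect_equal(spec2$separation, spec$separation)
  expect_equal(spec2$archetypes$label, spec$archetypes$label)
  expect_equal(spec2$archetypes$pcg_pool, spec$archetypes$pcg_pool)
  expect_identical(generate_cohort(spec2, seed = 5), coh)
})
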
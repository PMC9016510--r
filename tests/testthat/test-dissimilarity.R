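test_that("synthetic reference preserves marginals and degenerate columns", {
  flags <- cbind(a = rep(1L, 40), b = rep(0L, 40), c = rep(c(0L, 1L), 20))
  ref <- make_reference(flags, seed = 7)
  expect_s3_class(ref, "pcg_reference")
  expect_equal(attr(ref, "n_original"), 40L)
  expect_equal(ref$provenance, rep(c("original", "synthetic"), each = 40))
  synth <- ref[ref$provenance == "synthetic", -1]
  expect_true(all(synth$a == 1L))       # degenerate marginals reproduced exactly
  expect_true(all(synth$b == 0L))
  expect_error(make_reference(flags[0, ]), class = "pcg_validation_error")
})

test_that("column-wise resampling destroys between-column correlation", {
  set.seed(10)
  x <- rbinom(2000, 1, 0.5)
  flags <- cbind(a = x, b = x)            # perfectly correlated pair
  ref <- make_reference(flags, seed = 11)
  synth <- ref[ref$provenance == "synthetic", -1]
  expect_equal(stats::cor(flags)[1, 2], 1)
  expect_lt(abs(stats::cor(synth$a, synth$b)), 0.1)
  # marginal prevalence converges to the original's
  expect_lt(abs(mean(synth$a) - mean(x)), 0.05)
})

test_that("forest training records one OOB error per forest and validates inputs", {
  set.seed(3)
  flags <- matrix(rbinom(60 * 6, 1, 0.4), 60, 6)
  ref <- make_reference(flags, seed = 1)
  ff <- train_forests(ref, forest_config(n_forests = 3, n_trees = 20, seed = 5))
  expect_length(ff$oob_errors, 3L)
  expect_true(all(ff$oob_errors >= 0 & ff$oob_errors <= 1))
  expect_equal(ff$oob_mean, mean(ff$oob_errors))
  expect_error(train_forests(flags), class = "pcg_validation_error")
  tiny <- make_reference(matrix(c(0, 1), 1, 2), seed = 1)
  expect_error(train_forests(tiny), class = "pcg_validation_error")
})

test_that("OOB error sits at chance on structureless data and below on structured data", {
  set.seed(21)
  # independent columns: original and reference are the same distribution
  null_flags <- matrix(rbinom(2000 * 10, 1, 0.3), 2000, 10)
  ref0 <- make_reference(null_flags, seed = 22)
  f0 <- train_forests(ref0, forest_config(n_forests = 3, n_trees = 150, seed = 23))
  expect_lt(abs(f0$oob_mean - 0.5), 0.05)

  # two dense disjoint blocks: strong dependence, easily separable
  block <- rbind(
    cbind(matrix(1L, 1000, 5), matrix(0L, 1000, 5)),
    cbind(matrix(0L, 1000, 5), matrix(1L, 1000, 5))
  )
  noisy <- block
  noisy[cbind(sample(2000, 400, TRUE), sample(10, 400, TRUE))] <- 1L
  ref1 <- make_reference(noisy, seed = 24)
  f1 <- train_forests(ref1, forest_config(n_forests = 3, n_trees = 150, seed = 25))
  expect_lt(f1$oob_mean, 0.4)
})

test_that("proximity equals the brute-force (tree, pair) count and self-proximity n_trees", {
  set.seed(31)
  flags <- matrix(rbinom(8 * 5, 1, 0.5), 8, 5)
  ref <- make_reference(flags, seed = 32)
  ff <- train_forests(ref, forest_config(n_forests = 1, n_trees = 3, seed = 33))
  x <- as.data.frame(ref[, -1])
  prox <- proximity_matrix(ff$forests[[1]], x)

  nodes <- stats::predict(ff$forests[[1]], data = x, type = "terminalNodes",
                          num.threads = 1)$predictions
  expect_equal(prox, bf_proximity(nodes))
  expect_equal(diag(prox), rep(3, 16))
  expect_true(isSymmetric(prox))
  expect_error(proximity_matrix("not a forest", x), class = "pcg_state_error")
})

test_that("mean dissimilarity obeys the distance transform and its bounds", {
  set.seed(41)
  flags <- matrix(rbinom(30 * 6, 1, 0.4), 30, 6)
  ref <- make_reference(flags, seed = 42)
  cfg <- forest_config(n_forests = 4, n_trees = 10, seed = 43)
  diss <- mean_dissimilarity(ref, cfg)

  expect_equal(diss$distance, {
    d <- 1 - diss$proximity / 10; diag(d) <- 0; d
  })
  expect_equal(diag(diss$proximity), rep(10, 60))
  expect_true(all(diss$distance >= 0 & diss$distance <= 1))
  expect_true(isSymmetric(diss$distance))
  expect_equal(diag(diss$distance), rep(0, 60))
  expect_length(diss$oob_errors, 4L)

  # averaged proximity equals the brute-force average over forests
  ff <- train_forests(ref, cfg)
  x <- as.data.frame(ref[, -1])
  acc <- 0
  for (f in ff$forests) {
    nodes <- stats::predict(f, data = x, type = "terminalNodes",
                            num.threads = 1)$predictions
    acc <- acc + bf_proximity(nodes)
  }
  expect_equal(diss$proximity, acc / 4)
})

test_that("fixed seeds give a bit-identical dissimilarity result", {
  set.seed(51)
  flags <- matrix(rbinom(40 * 8, 1, 0.35), 40, 8)
  ref <- make_reference(flags, seed = 52)
  cfg <- forest_config(n_forests = 2, n_trees = 25, seed = 53)
  a <- mean_dissimilarity(ref, cfg)
  b <- mean_dissimilarity(ref, cfg)
  expect_identical(a$proximity, b$proximity)
  expect_identical(a$distance, b$distance)
  expect_identical(a$oob_errors, b$oob_errors)
})

test_that("dissimilarity persists with its JSON sidecar", {
  set.seed(61)
  flags <- matrix(rbinom(20 * 5, 1, 0.5), 20, 5)
  diss <- mean_dissimilarity(make_reference(flags, seed = 62),
                             forest_config(n_forests = 2, n_trees = 5, seed = 63))
  base <- withr::local_tempfile()
  write_dissimilarity(diss, base)
  meta <- jsonlite::read_json(paste0(base, ".json"))
  expect_equal(meta$n_trees, 5L)
  expect_length(meta$oob_errors, 2L)
  back <- as.matrix(readr::read_csv(paste0(base, ".csv"), col_names = FALSE,
                                    show_col_types = FALSE))
  expect_equal(unname(back), unname(diss$distance), tolerance = 1e-12)
})
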
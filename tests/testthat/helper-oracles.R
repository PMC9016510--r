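# Independent brute-force oracles and small in-code fixtures.

# naive O(T * n^2) co-leaf count from a terminal-node matrix (rows = points,
# columns = trees): loop over every tree and every pair
bf_proximity <- function(nodes) {
  n <- nrow(nodes)
  p <- matrix(0, n, n)
  for (t in seq_len(ncol(nodes))) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (nodes[i, t] == nodes[j, t]) p[i, j] <- p[i, j] + 1
      }
    }
  }
  p
}

# double-loop normalized stress, independent of stress_of()
bf_stress <- function(coords, d) {
  n <- nrow(d)
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dh <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      num <- num + (d[i, j] - dh)^2
      den <- den + d[i, j]^2
    }
  }
  sqrt(num / den)
}

# brute-force per-cluster joint PCG counts
bf_joint <- function(flags) {
  p <- ncol(flags)
  out <- matrix(0L, p, p)
  for (a in seq_len(p)) {
    for (b in seq_len(p)) {
      out[a, b] <- sum(flags[, a] == 1L & flags[, b] == 1L)
    }
  }
  out
}

# a tiny deterministic cohort tibble built from an explicit flag matrix
make_toy_cohort <- function(flags, taxonomy = default_taxonomy(), ...) {
  n <- nrow(flags)
  colnames(flags) <- pcg_cols(taxonomy)
  extra <- list(...)
  base <- tibble::tibble(
    patient_id = sprintf("T%03d", seq_len(n)),
    age = rep(60, n), sex = rep("female", n), deductible = rep(500, n),
    gatekeeper = rep(FALSE, n),
    ambulatory_cost = rep(100, n), inpatient_cost = rep(50, n),
    medication_cost = rep(25, n), total_cost = rep(175, n),
    hospital_days = rep(0L, n), hospitalizations = rep(0L, n),
    consultations_total = rep(2L, n), consultations_generalist = rep(1L, n)
  )
  for (nm in names(extra)) base[[nm]] <- extra[[nm]]
  dplyr::bind_cols(base, tibble::as_tibble(as.data.frame(flags)))
}

# flag matrix with given PCG names set per patient
flags_for <- function(pcg_lists, taxonomy = default_taxonomy()) {
  m <- matrix(0L, length(pcg_lists), nrow(taxonomy))
  for (i in seq_along(pcg_lists)) {
    m[i, match(pcg_lists[[i]], taxonomy$pcg)] <- 1L
  }
  m
}
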
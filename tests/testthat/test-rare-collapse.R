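test_that("allele frequencies come from parents (trios) or all sibs (DSPs)", {
  fams <- list(trio(1, 0, 1, id = "a"), trio(0, 1, 0, id = "b"))
  expect_equal(estimate_allele_frequencies(fams, "trio"), 2 / 8)
  sibs <- list(dsp(1, 0, id = "a"), dsp(0, 0, id = "b"))
  expect_equal(estimate_allele_frequencies(sibs, "dsp"), 1 / 8)
  # all sources missing at a marker -> NA
  fam_na <- list(nuclear_family("c", father = c(NA, 1), mother = c(NA, 0),
                                offspring = matrix(c(1, 1), 1), traits = 1))
  fr <- estimate_allele_frequencies(fam_na, "trio")
  expect_true(is.na(fr[1]))
  expect_equal(fr[2], 0.25)
})

test_that("weight schemes follow their formulas and exclude degenerate markers", {
  expect_equal(compute_weights("frequency", freqs = 0.01, n_families = 500),
               1 / sqrt(500 * 0.01 * 0.99), tolerance = 1e-12)
  expect_equal(round(compute_weights("frequency", freqs = 0.01,
                                     n_families = 500), 5), 0.44947)
  expect_equal(compute_weights("informative_count",
                               informative_counts = c(25L, 0L)),
               c(0.2, NA))
  w <- compute_weights("frequency", freqs = c(0, 0.5, 1), n_families = 10)
  expect_true(is.na(w[1]) && is.na(w[3]) && !is.na(w[2]))
  expect_equal(compute_weights("unweighted", freqs = c(0.1, 0.2)), c(1, 1))
  expect_error(compute_weights("external", external_weights = c(-1, 2)),
               "nonnegative")
})

test_that("fixed-threshold selection is strict", {
  fr <- c(0.004, 0.01, 0.2)
  expect_equal(select_rare(fr, 0.01), 1L)
  expect_equal(select_rare(fr, 1.0), 1:3)
  expect_length(select_rare(c(0.005, 0.01), 0.005), 0)
  expect_length(select_rare(c(NA, 0.001), 0.01), 1)
})

test_that("collapsed test matches hand computation and reduces to single-marker FBAT", {
  # one family, two markers, u = (0.5, 0.5), D = (0.25, 0.25)
  fam <- nuclear_family("a", father = c(1, 1), mother = c(0, 0),
                        offspring = matrix(c(1, 1), 1), traits = 1)
  b <- covariance_bundle(marker_contribution_table(list(fam)))
  r <- collapsed_test(b)
  expect_equal(r$W, 1)
  expect_equal(r$variance, 1)   # sum of all elements of V_A = [[.25,.25],[.25,.25]]
  expect_equal(r$z, 1)
  r2 <- collapsed_test(b, weights = c(2, 0))
  expect_equal(r2$W, 1)
  expect_equal(r2$variance, 1)  # 4 * 0.25
  expect_equal(r2$z, 1)

  # single-marker reduction
  fams <- list(trio(1, 1, 2, id = "a"), trio(1, 0, 1, id = "b"))
  b1 <- covariance_bundle(marker_contribution_table(fams))
  single <- fbat_single_marker(fams, 1)
  red <- collapsed_test(b1, subset = 1L)
  expect_equal(red$z, single$z)
  expect_equal(red$p_value, single$p_value)

  expect_true(collapsed_test(b1, subset = integer(0))$untestable)
})

test_that("W equals the trait-by-weighted-copies covariance form", {
  set.seed(31)
  n <- 80
  M <- 5
  f <- matrix(rbinom(n * M, 2, 0.3), n, M)
  m <- matrix(rbinom(n * M, 2, 0.3), n, M)
  x <- ifelse(f == 1, matrix(rbinom(n * M, 1, 0.5), n, M), f / 2) +
       ifelse(m == 1, matrix(rbinom(n * M, 1, 0.5), n, M), m / 2)
  tr <- rbinom(n, 1, 0.7)  # mix of affected and unaffected offspring
  fams <- lapply(seq_len(n), function(i)
    nuclear_family(i, father = f[i, ], mother = m[i, ],
                   offspring = matrix(x[i, ], 1), traits = tr[i]))
  b <- covariance_bundle(marker_contribution_table(fams))
  w <- runif(M, 0.5, 2)
  r <- collapsed_test(b, weights = w)
  # covariance form: sum_i T_i * sum_j w_j (X_ij - E[X_ij])
  W_cov <- sum(tr * ((x - (f + m) / 2) %*% w))
  expect_equal(r$W, W_cov, tolerance = 1e-10)
})

test_that("weights are independent of transmissions", {
  set.seed(77)
  n <- 60
  M <- 4
  f <- matrix(rbinom(n * M, 2, 0.2), n, M)
  m <- matrix(rbinom(n * M, 2, 0.2), n, M)
  draw_children <- function() {
    ifelse(f == 1, matrix(rbinom(n * M, 1, 0.5), n, M), f / 2) +
      ifelse(m == 1, matrix(rbinom(n * M, 1, 0.5), n, M), m / 2)
  }
  build <- function(x) lapply(seq_len(n), function(i)
    nuclear_family(i, father = f[i, ], mother = m[i, ],
                   offspring = matrix(x[i, ], 1), traits = 1))
  fams1 <- build(draw_children())
  fams2 <- build(draw_children())   # same parents, re-drawn transmissions
  fr1 <- estimate_allele_frequencies(fams1, "trio")
  fr2 <- estimate_allele_frequencies(fams2, "trio")
  expect_identical(fr1, fr2)
  expect_identical(compute_weights("frequency", freqs = fr1, n_families = n),
                   compute_weights("frequency", freqs = fr2, n_families = n))
  # informative-family counts depend on parents only as well
  b1 <- covariance_bundle(marker_contribution_table(fams1))
  b2 <- covariance_bundle(marker_contribution_table(fams2))
  expect_identical(b1$n_informative, b2$n_informative)
})

test_that("duplicating every family doubles W and variance, scaling z by sqrt(2)", {
  fams <- list(trio(1, 1, 2, id = "a"), trio(1, 0, 1, id = "b"),
               trio(1, 1, 0, id = "c"))
  b1 <- covariance_bundle(marker_contribution_table(fams))
  fams2 <- c(fams, lapply(fams, function(f) { f$family_id <- paste0(f$family_id, "x"); f }))
  b2 <- covariance_bundle(marker_contribution_table(fams2))
  r1 <- collapsed_test(b1)
  r2 <- collapsed_test(b2)
  expect_equal(r2$W, 2 * r1$W)
  expect_equal(r2$variance, 2 * r1$variance)
  expect_equal(r2$z, sqrt(2) * r1$z, tolerance = 1e-12)
})

test_that("fbat_rare wraps threshold, weighting and MM modes coherently", {
  set.seed(99)
  prof <- build_effect_profile(n_variants = 20, n_dsv = 0)
  st <- simulate_ascertained_sample(prof, "trio", n = 150)
  fams <- extract_nuclear_families(st$dataset)
  r <- fbat_rare(fams, weights = "frequency")
  expect_s3_class(r, "fbat_rare")
  expect_true(is.finite(r$result$p_value) || r$result$untestable)
  rt <- fbat_rare(fams, threshold = 0.01)
  expect_true(all(r$freqs[rt$result$marker_subset] < 0.01))
  rmm <- fbat_rare(fams, method = "mm", threshold = 0.05)
  expect_s3_class(rmm$result, "fbat_mm")
  tsv <- tempfile(fileext = ".tsv")
  write_results_tsv(list(r, rt), tsv, region = "simulated")
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$n_families, c(150L, 150L))
})
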
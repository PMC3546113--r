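test_that("Mendelian conditional moments match brute-force enumeration for all 9 parental pairs", {
  for (f in 0:2) for (m in 0:2) {
    d <- offspring_transmission_distribution(f, m)
    e <- enumerate_transmissions(f, m)
    expect_equal(sum(d$probabilities), 1, tolerance = 1e-12)
    expect_equal(d$mean, e$mean, tolerance = 1e-12)
    expect_equal(d$variance, e$variance, tolerance = 1e-12)
    # centering: probability-weighted deviations sum to zero
    expect_lt(abs(sum(d$probabilities * (d$support - d$mean))), 1e-12)
  }
  # spot values
  expect_equal(offspring_transmission_distribution(1, 0)$probabilities,
               c(0.5, 0.5))
  d11 <- offspring_transmission_distribution(1, 1)
  expect_equal(d11$probabilities, c(0.25, 0.5, 0.25))
  expect_equal(d11$variance, 0.5)
  d20 <- offspring_transmission_distribution(2, 0)
  expect_equal(d20$support, 1L)
  expect_equal(d20$variance, 0)
})

test_that("sibpair conditional distribution equals the mating-type enumeration", {
  # For every distinct unordered pair, each compatible parental mating type
  # gives the two orderings probability 1/2 (offspring exchangeability), so
  # the mixture over mating types does too.
  for (pair in list(c(1, 0), c(2, 0), c(2, 1))) {
    oracle <- sibpair_ordering_probs(pair)
    expect_true(length(oracle) >= 1)
    expect_true(all(abs(oracle - 0.5) < 1e-12))
    d <- sibpair_conditional_distribution(pair)
    expect_equal(d$probabilities, c(0.5, 0.5))
    expect_equal(d$assignments[1, ], pair)
    expect_equal(d$assignments[2, ], rev(pair))
  }
  d <- sibpair_conditional_distribution(c(1, 1))
  expect_equal(d$probabilities, 1)
  expect_error(sibpair_conditional_distribution(c(1, 0, 2)),
               "unsupported configuration")
})

test_that("per-family contributions match hand values", {
  c1 <- family_marker_contribution(trio(1, 1, 2), 1)
  expect_equal(c1$u, 1)
  expect_equal(c1$model_variance, 0.5)
  expect_true(c1$informative)

  c2 <- family_marker_contribution(trio(2, 2, 2), 1)
  expect_equal(c2$u, 0)
  expect_equal(c2$model_variance, 0)
  expect_false(c2$informative)

  c3 <- family_marker_contribution(dsp(1, 0), 1)
  expect_equal(c3$u, 0.5)
  expect_equal(c3$model_variance, 0.25)
})

test_that("single-marker FBAT reproduces arithmetic from the per-family oracle", {
  fams <- list(trio(1, 1, 2, id = "a"), trio(1, 1, 2, id = "b"))
  r <- fbat_single_marker(fams, 1)
  expect_equal(r$S, 2)
  expect_equal(r$variance, 1)
  expect_equal(r$z, 2)
  expect_equal(r$p_value, 2 * pnorm(-2), tolerance = 1e-10)
  expect_equal(r$n_informative, 2L)

  r2 <- fbat_single_marker(list(dsp(1, 0)), 1)
  expect_equal(r2$z, 1)
  expect_equal(r2$p_value, 2 * pnorm(-1), tolerance = 1e-10)

  r3 <- fbat_single_marker(list(trio(2, 2, 2), trio(0, 0, 0)), 1)
  expect_true(r3$untestable)
  expect_true(is.na(r3$z))
})

test_that("model variance zero implies zero score; DSP sib order is irrelevant", {
  # flip which sib is listed first: S and variance unchanged
  f1 <- list(dsp(2, 0, 1, 0), dsp(1, 0, 1, 0))
  f2 <- list(dsp(0, 2, 0, 1), dsp(0, 1, 0, 1))
  r1 <- fbat_single_marker(f1, 1)
  r2 <- fbat_single_marker(f2, 1)
  expect_equal(r1$S, r2$S)
  expect_equal(r1$variance, r2$variance)

  ct <- marker_contribution_table(f1)
  expect_true(all(ct$U[ct$D == 0] == 0))
  expect_equal(ct$informative, ct$D > 0)
})

test_that("missing genotypes drop a family from that marker only", {
  fam_ok <- trio(c(1, 1), c(1, 1), c(2, 2), id = "a")
  fam_na <- nuclear_family("b", father = c(1, NA), mother = c(1, 1),
                           offspring = matrix(c(2, 2), 1), traits = 1)
  ct <- marker_contribution_table(list(fam_ok, fam_na))
  expect_equal(ct$U[2, ], c(1, 0))
  expect_equal(ct$D[2, ], c(0.5, 0))
  expect_equal(ct$U[1, ], c(1, 1))
})

test_that("null z for a common marker is approximately standard normal", {
  # direct construction: parents drawn at a common frequency, affection
  # independent of genotype (so every sampled trio is a valid null family)
  set.seed(2024)
  reps <- 400L
  n <- 300L
  p <- 0.3
  z <- vapply(seq_len(reps), function(r) {
    f <- rbinom(n, 2, p); m <- rbinom(n, 2, p)
    tf <- rbinom(n, 1, 0.5); tm <- rbinom(n, 1, 0.5)
    x <- ifelse(f == 1, tf, f / 2) + ifelse(m == 1, tm, m / 2)
    u <- x - (f + m) / 2
    sum(u) / sqrt(sum(0.25 * ((f == 1) + (m == 1))))
  }, numeric(1))
  expect_lt(abs(mean(z)), 3 / sqrt(reps))
  rej <- mean(abs(z) > 1.96)
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
  # and the same arithmetic through the package interface on one replicate
  set.seed(1)
  f <- rbinom(50, 2, p); m <- rbinom(50, 2, p)
  tf <- rbinom(50, 1, 0.5); tm <- rbinom(50, 1, 0.5)
  x <- ifelse(f == 1, tf, f / 2) + ifelse(m == 1, tm, m / 2)
  fams <- lapply(seq_len(50), function(i) trio(f[i], m[i], x[i], id = i))
  r <- fbat_single_marker(fams, 1)
  expect_equal(r$S, sum(x - (f + m) / 2))
  expect_equal(r$variance, sum(0.25 * ((f == 1) + (m == 1))))
})
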
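test_that("Wright sampler reduces to Uniform(0,1) at beta = 1, sigma = 0", {
  set.seed(1)
  u <- sample_wright_frequencies(
    1e4, wright_params(beta1 = 1, beta2 = 1, sigma = 0,
                       min_freq = 1e-9, max_freq = 1 - 1e-9))
  ks <- suppressWarnings(ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("default Wright parameters concentrate mass below 1% frequency", {
  set.seed(2)
  q <- sample_wright_frequencies(1e4)
  expect_gt(mean(q < 0.01), 0.5)
  expect_true(all(q >= 1e-5 & q <= 0.999))
})

test_that("Wright sampler matches quadrature of the density (chi-square GOF)", {
  params <- wright_params()
  set.seed(3)
  q <- sample_wright_frequencies(1e5, params)
  dens <- function(x) exp((params$beta1 - 1) * log(x) +
                          (params$beta2 - 1) * log1p(-x) +
                          params$sigma * (1 - x))
  breaks <- c(1e-5, 1e-4, 1e-3, 1e-2, 0.1, 0.5, 0.999)
  mass <- vapply(seq_len(length(breaks) - 1), function(i)
    integrate(dens, breaks[i], breaks[i + 1], rel.tol = 1e-10)$value,
    numeric(1))
  probs <- mass / sum(mass)
  counts <- table(cut(q, breaks, include.lowest = TRUE))
  gof <- suppressWarnings(chisq.test(as.numeric(counts), p = probs))
  expect_gt(gof$p.value, 0.001)
})

test_that("Balding-Nichols shift has mean p and variance F p (1-p)", {
  set.seed(4)
  p <- 0.01; F <- 0.01
  x <- balding_nichols_shift(rep(p, 1e5), F)
  expect_equal(mean(x), p, tolerance = 0.03)
  expect_equal(var(x), F * p * (1 - p), tolerance = 0.05)
  # degenerate limit: tiny F returns essentially the input frequencies
  y <- balding_nichols_shift(rep(0.3, 1000), 1e-6)
  expect_lt(max(abs(y - 0.3)), 0.01)
})

test_that("effect profiles assign DSVs and relative risks as specified", {
  set.seed(5)
  prof <- build_effect_profile(n_dsv = 10, effect = list(type = "equal", rr = 2))
  expect_length(prof$dsv_indices, 10)
  expect_true(all(prof$freqs_pop1[prof$dsv_indices] < 0.01))
  expect_equal(sum(prof$rr == 2), 10)
  expect_equal(sum(prof$rr == 1), 40)

  # varying effects: endpoints pinned, exponential interpolation in between
  pv <- build_effect_profile(
    freqs = c(0.001, 0.005, 0.009, 0.3, 0.2), n_variants = 5, n_dsv = 3,
    effect = list(type = "varying", rr_min = 1.5, rr_max = 3))
  p <- pv$freqs_pop1[pv$dsv_indices]
  rr <- pv$rr[pv$dsv_indices]
  expect_equal(rr[which.min(p)], 3, tolerance = 1e-10)
  expect_equal(rr[which.max(p)], 1.5, tolerance = 1e-10)
  b <- log(3 / 1.5) / (max(p) - min(p))
  a <- 3 * exp(b * min(p))
  expect_equal(rr, a * exp(-b * p), tolerance = 1e-10)

  # null profile
  p0 <- build_effect_profile(n_dsv = 0)
  expect_length(p0$dsv_indices, 0)
  expect_true(all(p0$rr == 1))
})

test_that("disease probability follows the relative-risk model with a cap", {
  prof <- build_effect_profile(
    freqs = c(0.005, 0.004, 0.3), n_variants = 3, n_dsv = 2,
    effect = list(type = "equal", rr = 2), baseline = 0.05)
  dsv <- prof$dsv_indices
  x0 <- rep(0, 3)
  expect_equal(disease_probability(x0, prof), 0.05)
  x1 <- x0; x1[dsv[1]] <- 1
  expect_equal(disease_probability(x1, prof), 0.10)
  x2 <- x0; x2[dsv[1]] <- 2
  expect_equal(disease_probability(x2, prof), 0.20)
  # cap at 1: three copies across RR = 3 DSVs from baseline 0.05
  prof3 <- build_effect_profile(
    freqs = c(0.005, 0.004, 0.3), n_variants = 3, n_dsv = 2,
    effect = list(type = "equal", rr = 3), baseline = 0.05)
  x3 <- rep(0, 3)
  x3[prof3$dsv_indices] <- c(2, 1)
  expect_equal(disease_probability(x3, prof3), 1)
})

test_that("offspring inherit whole parental haplotypes (no recombination)", {
  prof <- build_effect_profile(freqs = rep(0.005, 4), n_variants = 4,
                               n_dsv = 4, effect = list(type = "equal", rr = 1))
  n <- 6
  pool <- list(pop = rep(1L, n),
               Hf1 = matrix(1, n, 4), Hf2 = matrix(0, n, 4),
               Hm1 = matrix(1, n, 4), Hm2 = matrix(0, n, 4),
               tf1 = c(1, 1, 0, 0, 1, 0), tm1 = c(1, 0, 1, 0, 0, 1))
  cg <- rvfbat:::complete_genotypes(pool, prof, seq_len(n), list(c("tf1", "tm1")))
  child <- cg$children[[1]]
  # each child genotype is constant across markers: the sum of one whole
  # haplotype from each parent (all-1 or all-0)
  expect_equal(child, matrix(pool$tf1 + pool$tm1, n, 4))
  expect_equal(cg$father, matrix(1, n, 4))
})

test_that("ascertainment preserves the baseline affection rate under the null", {
  set.seed(6)
  prof <- build_effect_profile(n_variants = 10, n_dsv = 0, baseline = 0.05)
  st <- simulate_ascertained_sample(prof, "trio", n = 400)
  prev <- st$n_affected_generated / st$n_offspring_generated
  se <- sqrt(0.05 * 0.95 / st$n_offspring_generated)
  expect_lt(abs(prev - 0.05), 4 * se)

  # DSP design: P(discordant pair) ~ 2 * 0.05 * 0.95 under the null
  set.seed(7)
  st2 <- simulate_ascertained_sample(prof, "dsp", n = 150)
  n_pairs <- st2$n_offspring_generated / 2
  p_disc <- 150 / n_pairs
  pd <- 2 * 0.05 * 0.95
  expect_lt(abs(p_disc - pd), 4 * sqrt(pd * (1 - pd) / n_pairs))
  # one affected and one unaffected sibling per family
  expect_equal(unname(st2$dataset$individuals$phenotype),
               rep(c(1, 0), 150))
})

test_that("null ascertainment leaves offspring genotype distribution unchanged", {
  # affection independent of genotype: allele counts of ascertained children
  # match the population Binomial(2, p) at a common marker
  set.seed(8)
  p <- 0.3
  prof <- build_effect_profile(freqs = c(p, 0.004), n_variants = 2, n_dsv = 1,
                               effect = list(type = "equal", rr = 1))
  st <- simulate_ascertained_sample(prof, "trio", n = 600)
  kid <- grepl("_3$", st$dataset$individuals$individual_id)
  x <- st$dataset$genotypes[kid, 1]
  gof <- chisq.test(tabulate(x + 1, 3), p = dbinom(0:2, 2, p))
  expect_gt(gof$p.value, 0.001)
})

test_that("identical seeds reproduce identical studies; case-control attaches correctly", {
  prof <- local({ set.seed(9); build_effect_profile(n_dsv = 5) })
  s1 <- local({ set.seed(10); simulate_ascertained_sample(prof, "trio", 50,
                                                          with_case_control = TRUE) })
  s2 <- local({ set.seed(10); simulate_ascertained_sample(prof, "trio", 50,
                                                          with_case_control = TRUE) })
  expect_identical(s1$dataset$genotypes, s2$dataset$genotypes)
  expect_identical(s1$case_control$genotypes, s2$case_control$genotypes)
  expect_identical(s1$n_offspring_generated, s2$n_offspring_generated)
  expect_equal(sum(s1$case_control$status), 50)
  expect_equal(nrow(s1$case_control$genotypes), 100)
  # cases are the affected trio offspring
  kid <- grepl("_3$", s1$dataset$individuals$individual_id)
  expect_equal(s1$case_control$genotypes[1:50, ],
               unname(s1$dataset$genotypes[kid, ]))
})
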
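#' Configuration of a simulation experiment
#'
#' Bundles everything a type-I error, power, or prevalence/PAR run needs:
#' the scenario (region size, number of DSVs, effect specification, baseline
#' risk, optional stratification), the family design, the methods to run,
#' replication settings and the master seed.  Per-replicate seeds are
#' spawned deterministically from the master seed, and all methods see the
#' identical dataset within a replicate, so method comparisons are paired.
#'
#' @param n_variants,n_dsv,effect,baseline,wright,stratification Scenario
#'   settings, passed to \code{\link{build_effect_profile}} each replicate.
#' @param design \code{"trio"} or \code{"dsp"}.
#' @param n_families Ascertained sample size per replicate (affected trios
#'   or discordant sibpairs; also the number of cases/controls).
#' @param methods Character vector of method labels: \code{"FT.fam.<t>"}
#'   (unweighted fixed-threshold family burden), \code{"FT.MM.<t>"}
#'   (multimarker on the sub-threshold set), \code{"FT.CC.<t>"}
#'   (case-control burden score), \code{"NT.fam"} (no-threshold
#'   frequency-weighted family burden), \code{"NT.CC"} (modified
#'   Madsen-Browning weighted sum), with \code{<t>} a frequency threshold.
#' @param reps Number of replicates (default 500).
#' @param alphas Nominal levels at which rejections are recorded.
#' @param seed Master seed.
#' @return Object of class \code{"experiment_config"}.
#' @export
experiment_config <- function(n_variants = 50L, n_dsv = 10L,
                              effect = list(type = "equal", rr = 1),
                              baseline = 0.05, wright = wright_params(),
                              stratification = NULL,
                              design = c("trio", "dsp"), n_families = 500L,
                              methods = default_methods(),
                              reps = 500L, alphas = c(0.05, 0.01),
                              seed = 1L) {
  design <- match.arg(design)
  stopifnot(reps >= 1L, all(alphas > 0 & alphas < 1))
  structure(list(n_variants = n_variants, n_dsv = n_dsv, effect = effect,
                 baseline = baseline, wright = wright,
                 stratification = stratification, design = design,
                 n_families = n_families, methods = methods, reps = reps,
                 alphas = alphas, seed = seed),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @param thresholds Frequency cutoffs for the fixed-threshold methods.
#' @export
default_methods <- function(thresholds = c(0.005, 0.01, 0.05)) {
  c(paste0("FT.fam.", thresholds), paste0("FT.MM.", thresholds),
    paste0("FT.CC.", thresholds), "NT.fam", "NT.CC")
}

parse_method <- function(label) {
  if (label == "NT.fam") return(list(kind = "NT.fam", threshold = NA_real_))
  if (label == "NT.CC") return(list(kind = "NT.CC", threshold = NA_real_))
  m <- regmatches(label, regexec("^(FT\\.(?:fam|MM|CC))\\.([0-9.]+)$", label))[[1]]
  if (length(m) != 3L) stop("unknown method label: ", label)
  list(kind = m[2], threshold = as.numeric(m[3]))
}

## p-values of every configured method on one simulated replicate
replicate_pvalues <- function(study, config) {
  families <- extract_nuclear_families(study$dataset)
  contribs <- marker_contribution_table(families, offset = 0)
  # markers that cannot be rescaled (all-zero scores) are dropped routinely
  # at rare-variant sample sizes; the per-region warning is noise here
  bundle <- suppressWarnings(covariance_bundle(contribs))
  freqs <- estimate_allele_frequencies(families, config$design)
  cc <- study$case_control
  ccfreqs <- if (!is.null(cc)) cc_allele_frequencies(cc)
  w_freq <- compute_weights("frequency", freqs = freqs,
                            n_families = length(families))
  vapply(config$methods, function(label) {
    spec <- parse_method(label)
    switch(spec$kind,
      FT.fam = collapsed_test(bundle,
                              subset = select_rare(freqs, spec$threshold))$p_value,
      FT.MM = multimarker_test(bundle,
                               subset = select_rare(freqs, spec$threshold))$p_value,
      FT.CC = burden_score_test(cc,
                                subset = select_rare(ccfreqs, spec$threshold))$p_value,
      NT.fam = collapsed_test(bundle, weights = w_freq)$p_value,
      NT.CC = weighted_sum_test(cc)$p_value)
  }, numeric(1))
}

needs_cc <- function(methods)
  any(grepl("^FT\\.CC", methods) | methods == "NT.CC")

run_rate_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  methods <- config$methods
  if (config$design == "dsp" && needs_cc(methods)) {
    methods <- methods[!(grepl("^FT\\.CC", methods) | methods == "NT.CC")]
    warning("case-control comparators are defined for the trio design only; dropped")
  }
  cfg <- config; cfg$methods <- methods
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max, config$reps)
  P <- matrix(NA_real_, config$reps, length(methods),
              dimnames = list(NULL, methods))
  for (r in seq_len(config$reps)) {
    set.seed(rep_seeds[r])
    profile <- build_effect_profile(
      n_variants = config$n_variants, n_dsv = config$n_dsv,
      effect = config$effect, baseline = config$baseline,
      wright = config$wright, stratification = config$stratification)
    study <- simulate_ascertained_sample(
      profile, design = config$design, n = config$n_families,
      with_case_control = needs_cc(methods))
    P[r, ] <- replicate_pvalues(study, cfg)
  }
  rows <- expand.grid(method = methods, alpha = config$alphas,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$design <- config$design
  rows$rate <- NA_real_; rows$se <- NA_real_
  rows$reps_used <- NA_integer_; rows$n_untestable <- NA_integer_
  for (i in seq_len(nrow(rows))) {
    p <- P[, rows$method[i]]
    ok <- !is.na(p)
    rate <- mean(p[ok] < rows$alpha[i])
    rows$rate[i] <- rate
    rows$se[i] <- sqrt(rate * (1 - rate) / sum(ok))
    rows$reps_used[i] <- sum(ok)
    rows$n_untestable[i] <- sum(!ok)
  }
  attr(rows, "pvalues") <- P
  attr(rows, "config") <- config
  class(rows) <- c("rate_table", "data.frame")
  rows
}

#' Type-I error experiment
#'
#' Replicates a null scenario (all relative risks equal to 1), runs every
#' configured method on each simulated dataset, and tabulates the two-sided
#' rejection proportion at each nominal level.  Replicates on which a
#' method is untestable (empty marker subset or zero variance) are counted
#' separately and excluded from that method's denominator.
#'
#' @param config An \code{\link{experiment_config}} whose effect is null.
#' @return A \code{rate_table} data frame with columns method, alpha,
#'   design, rate, se (binomial Monte-Carlo standard error), reps_used and
#'   n_untestable; the per-replicate p-value matrix is attached as
#'   attribute \code{"pvalues"}.
#' @export
run_type1_experiment <- function(config) {
  rr <- if (identical(config$effect$type, "equal")) config$effect$rr
        else c(config$effect$rr_min, config$effect$rr_max)
  if (config$n_dsv > 0L && any(rr != 1))
    stop("type-I error experiment requires a null scenario (all RR = 1)")
  run_rate_experiment(config)
}

#' Power experiment
#'
#' Same replication engine as \code{\link{run_type1_experiment}} but under
#' an alternative scenario (DSVs with relative risk above 1); the tabulated
#' rejection proportions are empirical power.
#'
#' @inheritParams run_type1_experiment
#' @return A \code{rate_table} data frame (see
#'   \code{\link{run_type1_experiment}}).
#' @export
run_power_experiment <- function(config) {
  run_rate_experiment(config)
}

#' Levin's attributable-risk formula
#'
#' \eqn{PAR = f (R - 1) / (1 + f (R - 1))} for exposure prevalence f and
#' risk ratio R.
#'
#' @param f Exposure prevalence.
#' @param r Risk (odds) ratio.
#' @return Attributable fraction (negative values permitted when R < 1).
#' @export
levin_par <- function(f, r) f * (r - 1) / (1 + f * (r - 1))

#' Total population attributable risk of a region
#'
#' Estimates, from a case-control sample, the per-variant attributable
#' fraction of each true DSV by Levin's formula — exposure prevalence taken
#' as the variant's minor-allele frequency among controls, risk ratio as
#' the allelic odds ratio with a 0.5 continuity correction on every cell —
#' and sums over the DSVs.  The sum is not truncated at zero, so a null
#' region averages to approximately zero.
#'
#' @param sample A \code{\link{case_control_sample}}.
#' @param dsv_indices Marker indices of the true DSVs (simulation truth).
#' @return Total PAR estimate (a single number).
#' @export
estimate_total_par <- function(sample, dsv_indices) {
  stopifnot(inherits(sample, "case_control_sample"))
  if (length(dsv_indices) == 0L) return(0)
  y <- sample$status
  X <- sample$genotypes[, dsv_indices, drop = FALSE]
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  a <- colSums(X[y == 1L, , drop = FALSE])        # minor alleles in cases
  c0 <- colSums(X[y == 0L, , drop = FALSE])       # minor alleles in controls
  or <- ((a + 0.5) * (2 * n0 - c0 + 0.5)) / ((2 * n1 - a + 0.5) * (c0 + 0.5))
  f <- c0 / (2 * n0)
  sum(levin_par(f, or))
}

#' Prevalence and total-PAR summary over replicates
#'
#' Regenerates the scenario \code{reps} times; per replicate, estimates the
#' disease prevalence as (affected offspring)/(total offspring generated)
#' during the ascertainment of the case series, and the total PAR from the
#' matched case-control sample via \code{\link{estimate_total_par}} using
#' the replicate's true DSV indices.  Reports means and standard deviations
#' over replicates.
#'
#' @param config An \code{\link{experiment_config}} (trio design).
#' @return Data frame with one row per quantity (\code{prevalence},
#'   \code{total_par}) and columns mean, sd, reps; the per-replicate values
#'   are attached as attribute \code{"replicates"}.
#' @export
estimate_prevalence_and_par <- function(config) {
  stopifnot(inherits(config, "experiment_config"), config$design == "trio")
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max, config$reps)
  prev <- par <- numeric(config$reps)
  for (r in seq_len(config$reps)) {
    set.seed(rep_seeds[r])
    profile <- build_effect_profile(
      n_variants = config$n_variants, n_dsv = config$n_dsv,
      effect = config$effect, baseline = config$baseline,
      wright = config$wright, stratification = config$stratification)
    study <- simulate_ascertained_sample(profile, design = "case_control",
                                         n = config$n_families)
    prev[r] <- study$n_affected_generated / study$n_offspring_generated
    par[r] <- estimate_total_par(study$case_control, profile$dsv_indices)
  }
  out <- data.frame(quantity = c("prevalence", "total_par"),
                    mean = c(mean(prev), mean(par)),
                    sd = c(stats::sd(prev), stats::sd(par)),
                    reps = config$reps)
  attr(out, "replicates") <- data.frame(prevalence = prev, total_par = par)
  out
}
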
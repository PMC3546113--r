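#' Parameters of Wright's equilibrium allele-frequency distribution
#'
#' Density proportional to
#' \eqn{q^{\beta_1 - 1} (1-q)^{\beta_2 - 1} e^{\sigma (1-q)}} on a truncated
#' support, describing variant frequencies under weak purifying selection.
#' Defaults follow the standard rare-variant simulation setting
#' (\eqn{\beta_1 = \beta_2 = 0.001}, \eqn{\sigma = 12}) with support
#' truncated to (1e-5, 0.999).
#'
#' @param beta1,beta2 Scaled mutation rates (positive).
#' @param sigma Selection parameter.
#' @param min_freq,max_freq Truncation interval for the frequencies.
#' @return Object of class \code{"wright_params"}.
#' @export
wright_params <- function(beta1 = 0.001, beta2 = 0.001, sigma = 12,
                          min_freq = 1e-5, max_freq = 0.999) {
  stopifnot(beta1 > 0, beta2 > 0, min_freq > 0, min_freq < max_freq,
            max_freq < 1)
  structure(list(beta1 = beta1, beta2 = beta2, sigma = sigma,
                 min_freq = min_freq, max_freq = max_freq),
            class = "wright_params")
}

## Unnormalized log-density of Wright's distribution.
wright_log_density <- function(q, params) {
  (params$beta1 - 1) * log(q) + (params$beta2 - 1) * log1p(-q) +
    params$sigma * (1 - q)
}

## Inverse-CDF table on a dense log-spaced grid over the truncation support.
## The boundary singularities q^(beta-1) are integrable; log spacing puts
## most grid points where the low-frequency mass is.
wright_cdf_grid <- function(params, n_grid = 20001L) {
  grid <- exp(seq(log(params$min_freq), log(params$max_freq),
                  length.out = n_grid))
  ld <- wright_log_density(grid, params)
  d <- exp(ld - max(ld))
  dq <- diff(grid)
  cdf <- c(0, cumsum((d[-1] + d[-n_grid]) / 2 * dq))
  list(grid = grid, cdf = cdf / cdf[n_grid])
}

#' Sample variant frequencies from Wright's distribution
#'
#' Independent draws via inverse-CDF interpolation on a dense log-spaced
#' grid over the truncated support of the unnormalized density.
#'
#' @param n Number of frequencies to draw.
#' @param params A \code{\link{wright_params}} object.
#' @param n_grid Grid resolution for the inverse-CDF table.
#' @return Numeric vector of frequencies in the support interval.
#' @export
sample_wright_frequencies <- function(n, params = wright_params(),
                                      n_grid = 20001L) {
  tab <- wright_cdf_grid(params, n_grid)
  stats::approx(tab$cdf, tab$grid, xout = stats::runif(n),
                ties = "ordered", rule = 2)$y
}

#' Balding-Nichols frequency shift between subpopulations
#'
#' Draws, for each input frequency p, a subpopulation frequency from
#' \eqn{Beta(p(1-F)/F, (1-p)(1-F)/F)}, which has mean p and variance
#' \eqn{F p (1-p)} — the Balding-Nichols model with fixation index F.
#'
#' @param freqs Ancestral frequencies in (0, 1).
#' @param fst Fixation index in (0, 1).
#' @return Shifted frequency vector, same length as \code{freqs}.
#' @export
balding_nichols_shift <- function(freqs, fst) {
  stopifnot(fst > 0, fst < 1, all(freqs > 0), all(freqs < 1))
  k <- (1 - fst) / fst
  stats::rbeta(length(freqs), freqs * k, (1 - freqs) * k)
}

#' Build the truth record for a simulated genetic region
#'
#' Samples (or accepts) per-variant population frequencies, designates the
#' disease-susceptibility variants (DSVs) uniformly at random among variants
#' with frequency below 1 percent, and assigns their relative risks.  With
#' \code{effect = list(type = "equal", rr = R)} every DSV has relative risk
#' R; with \code{list(type = "varying", rr_min, rr_max)} the DSV at the
#' lowest selected frequency gets \code{rr_max}, the highest gets
#' \code{rr_min}, and intermediate frequencies interpolate exponentially as
#' \eqn{RR(p) = a e^{-b p}}.  Population stratification is introduced by
#' drawing second-subpopulation DSV frequencies from the Balding-Nichols
#' model and assigning the two subpopulations different baseline risks.
#'
#' @param n_variants Number of variants in the region (default 50).
#' @param n_dsv Number of DSVs (0 gives a pure null profile).
#' @param effect Effect specification list, see above; default equal
#'   relative risk 1 (null).
#' @param baseline Baseline disease risk of (the first) subpopulation.
#' @param wright \code{\link{wright_params}} for the frequency draws.
#' @param freqs Optional frequency vector to use instead of sampling.
#' @param stratification Optional list with elements \code{fst},
#'   \code{baseline2}, \code{mixture} (proportion of subpopulation 1,
#'   default 0.5) and \code{shift_all} (apply the Balding-Nichols shift to
#'   all markers rather than only DSVs; default FALSE).
#' @param max_retries Resampling budget when fewer than \code{n_dsv}
#'   variants fall below 1 percent.
#' @return Object of class \code{"effect_profile"}: frequencies for each
#'   subpopulation, DSV indices, per-variant relative risks (1 for
#'   non-DSVs), baseline risks, mixture proportion, and the number of
#'   frequency resamples used.
#' @export
build_effect_profile <- function(n_variants = 50L, n_dsv = 10L,
                                 effect = list(type = "equal", rr = 1),
                                 baseline = 0.05, wright = wright_params(),
                                 freqs = NULL, stratification = NULL,
                                 max_retries = 100L) {
  retries <- 0L
  if (is.null(freqs)) {
    repeat {
      freqs <- sample_wright_frequencies(n_variants, wright)
      if (n_dsv == 0L || sum(freqs < 0.01) >= n_dsv) break
      retries <- retries + 1L
      if (retries > max_retries)
        stop("could not obtain ", n_dsv,
             " variants below 1% frequency after ", max_retries, " resamples")
    }
  } else {
    stopifnot(length(freqs) == n_variants)
    if (n_dsv > 0L && sum(freqs < 0.01) < n_dsv)
      stop("supplied frequencies have fewer than n_dsv variants below 1%")
  }
  dsv <- if (n_dsv > 0L) sort(sample(which(freqs < 0.01), n_dsv)) else integer(0)
  rr <- rep(1, n_variants)
  if (n_dsv > 0L) {
    if (identical(effect$type, "equal")) {
      rr[dsv] <- effect$rr
    } else if (identical(effect$type, "varying")) {
      p <- freqs[dsv]
      pmin <- min(p); pmax <- max(p)
      if (pmax > pmin) {
        b <- log(effect$rr_max / effect$rr_min) / (pmax - pmin)
        a <- effect$rr_max * exp(b * pmin)
        rr[dsv] <- a * exp(-b * p)
      } else rr[dsv] <- effect$rr_max
    } else stop("unknown effect type: ", effect$type)
  }
  freqs2 <- baseline2 <- mixture <- NULL
  if (!is.null(stratification)) {
    freqs2 <- freqs
    shift <- if (isTRUE(stratification$shift_all)) seq_len(n_variants) else dsv
    if (length(shift))
      freqs2[shift] <- balding_nichols_shift(freqs[shift], stratification$fst)
    baseline2 <- stratification$baseline2 %||% baseline
    mixture <- stratification$mixture %||% 0.5
  }
  structure(list(freqs_pop1 = freqs, freqs_pop2 = freqs2, dsv_indices = dsv,
                 rr = rr, baseline_pop1 = baseline, baseline_pop2 = baseline2,
                 mixture = mixture, n_resamples = retries),
            class = "effect_profile")
}

#' Disease probability under the relative-risk model
#'
#' \eqn{P(Y = 1 | X) = f_0 \prod_s RR_s^{X_s}} over the DSVs, capped at 1
#' (multi-copy carriers of strong variants can push the product above 1;
#' the cap is the minimal fix).
#'
#' @param genotype_counts Genotype vector (length M) or matrix
#'   (individuals x M) of minor-allele counts.
#' @param profile An \code{\link{build_effect_profile}} result.
#' @param subpop Which subpopulation's baseline risk to use (1 or 2).
#' @return Probability (vector when a matrix is supplied).
#' @export
disease_probability <- function(genotype_counts, profile, subpop = 1L) {
  f0 <- if (subpop == 1L || is.null(profile$baseline_pop2))
    profile$baseline_pop1 else profile$baseline_pop2
  dsv <- profile$dsv_indices
  if (length(dsv) == 0L) {
    n <- if (is.matrix(genotype_counts)) nrow(genotype_counts) else 1L
    return(rep(f0, n))
  }
  X <- if (is.matrix(genotype_counts)) genotype_counts[, dsv, drop = FALSE]
       else matrix(genotype_counts[dsv], nrow = 1)
  pmin(1, f0 * exp(as.numeric(X %*% log(profile$rr[dsv]))))
}

## ---- internal generation machinery -------------------------------------

## Bernoulli haplotype block: n rows, frequencies per column taken from the
## row's subpopulation (pop is 1/2; P is a 2 x k matrix of frequencies).
draw_haplotypes <- function(n, cols_p, pop) {
  k <- ncol(cols_p)
  P <- cols_p[pop, , drop = FALSE]
  matrix(as.numeric(stats::runif(n * k) < P), n, k)
}

## Generate nuclear families until `n_cases` affected offspring (trio) or
## `n_cases` discordant pairs (dsp) have been produced.  Haplotypes are
## drawn per variant independently; each offspring inherits one whole
## haplotype from each parent (no recombination).  Only the DSV columns are
## generated during the ascertainment sweep; the remaining marker columns
## are filled in afterwards for the families that are kept.
sim_family_pool <- function(profile, design, n_cases, n_controls = 0L,
                            cap = 5e6) {
  M <- length(profile$freqs_pop1)
  dsv <- profile$dsv_indices
  strat <- !is.null(profile$freqs_pop2)
  mix <- profile$mixture %||% 1
  p1 <- profile$freqs_pop1
  p2 <- if (strat) profile$freqs_pop2 else p1
  f0 <- c(profile$baseline_pop1,
          profile$baseline_pop2 %||% profile$baseline_pop1)
  Pd <- rbind(p1[dsv], p2[dsv])        # 2 x |dsv| (possibly 0-column)
  logrr <- log(profile$rr[dsv])
  per_fam <- if (design == "dsp") 2L else 1L

  f0bar <- mix * f0[1] + (1 - mix) * f0[2]
  hit_rate <- if (design == "dsp") 2 * f0bar * (1 - f0bar) else f0bar
  acc <- list(); n_hit <- 0L; n_fam <- 0L
  repeat {
    nb <- min(2e5, max(2000L, ceiling((n_cases - n_hit) / hit_rate * 1.2)))
    pop <- if (strat) 1L + (stats::runif(nb) >= mix) else rep(1L, nb)
    Hf1 <- draw_haplotypes(nb, Pd, pop); Hf2 <- draw_haplotypes(nb, Pd, pop)
    Hm1 <- draw_haplotypes(nb, Pd, pop); Hm2 <- draw_haplotypes(nb, Pd, pop)
    batch <- list(pop = pop, Hf1 = Hf1, Hf2 = Hf2, Hm1 = Hm1, Hm2 = Hm2)
    for (k in seq_len(per_fam)) {
      tf <- stats::rbinom(nb, 1L, 0.5); tm <- stats::rbinom(nb, 1L, 0.5)
      child <- (tf * Hf1 + (1 - tf) * Hf2) + (tm * Hm1 + (1 - tm) * Hm2)
      pr <- if (length(dsv)) pmin(1, f0[pop] * exp(as.numeric(child %*% logrr)))
            else f0[pop]
      aff <- stats::runif(nb) < pr
      batch[[paste0("tf", k)]] <- tf
      batch[[paste0("tm", k)]] <- tm
      batch[[paste0("aff", k)]] <- aff
    }
    acc[[length(acc) + 1L]] <- batch
    n_hit <- n_hit + if (design == "dsp")
      sum(batch$aff1 != batch$aff2) else sum(batch$aff1)
    n_fam <- n_fam + nb
    if (n_hit >= n_cases) break
    if (n_fam * per_fam > cap)
      stop("generation cap exceeded: ascertainment probability is ",
           "effectively zero for this configuration")
  }
  cat_field <- function(f) do.call(c, lapply(acc, `[[`, f))
  rb_field <- function(f) do.call(rbind, lapply(acc, `[[`, f))
  pop <- cat_field("pop")
  aff1 <- cat_field("aff1")
  hit <- if (design == "dsp") aff1 != cat_field("aff2") else aff1
  cut <- which(hit)[n_cases]              # family index achieving the target
  list(pop = pop, hit = hit, cut = cut,
       aff1 = aff1, aff2 = if (design == "dsp") cat_field("aff2"),
       tf1 = cat_field("tf1"), tm1 = cat_field("tm1"),
       tf2 = if (design == "dsp") cat_field("tf2"),
       tm2 = if (design == "dsp") cat_field("tm2"),
       Hf1 = rb_field("Hf1"), Hf2 = rb_field("Hf2"),
       Hm1 = rb_field("Hm1"), Hm2 = rb_field("Hm2"),
       n_offspring_generated = cut * per_fam,
       n_affected_generated = if (design == "dsp")
         sum(aff1[seq_len(cut)]) + sum(cat_field("aff2")[seq_len(cut)])
       else n_cases)
}

## Fill in the non-DSV marker columns for the selected families and return
## full genotype matrices (father, mother, and one child per transmission
## pair supplied).
complete_genotypes <- function(pool, profile, sel, trans) {
  M <- length(profile$freqs_pop1)
  dsv <- profile$dsv_indices
  other <- setdiff(seq_len(M), dsv)
  strat <- !is.null(profile$freqs_pop2)
  p1 <- profile$freqs_pop1
  p2 <- if (strat) profile$freqs_pop2 else p1
  Po <- rbind(p1[other], p2[other])
  ns <- length(sel)
  pop <- pool$pop[sel]
  Gf1 <- draw_haplotypes(ns, Po, pop); Gf2 <- draw_haplotypes(ns, Po, pop)
  Gm1 <- draw_haplotypes(ns, Po, pop); Gm2 <- draw_haplotypes(ns, Po, pop)
  assemble <- function(Hd, Ho) {
    out <- matrix(0, ns, M)
    out[, dsv] <- Hd; out[, other] <- Ho
    out
  }
  Fg <- assemble(pool$Hf1[sel, , drop = FALSE] + pool$Hf2[sel, , drop = FALSE],
                 Gf1 + Gf2)
  Mg <- assemble(pool$Hm1[sel, , drop = FALSE] + pool$Hm2[sel, , drop = FALSE],
                 Gm1 + Gm2)
  children <- lapply(trans, function(tr) {
    tf <- pool[[tr[1]]][sel]; tm <- pool[[tr[2]]][sel]
    cd <- (tf * pool$Hf1[sel, , drop = FALSE] +
           (1 - tf) * pool$Hf2[sel, , drop = FALSE]) +
          (tm * pool$Hm1[sel, , drop = FALSE] +
           (1 - tm) * pool$Hm2[sel, , drop = FALSE])
    co <- (tf * Gf1 + (1 - tf) * Gf2) + (tm * Gm1 + (1 - tm) * Gm2)
    assemble(cd, co)
  })
  list(father = Fg, mother = Mg, children = children, pop = pop)
}

#' Simulate an ascertained family or case-control study
#'
#' Generates nuclear families under the relative-risk disease model and
#' ascertains them by design: \code{"trio"} keeps families with an affected
#' offspring until \code{n} affected trios are collected (optionally also
#' assembling a matched case-control sample: the \code{n} affected offspring
#' as cases plus \code{n} unaffected offspring from different families as
#' controls); \code{"dsp"} keeps discordant sibpairs (one affected, one
#' unaffected sibling, parents untyped); \code{"case_control"} returns only
#' the case-control sample.  Parental haplotypes are drawn per variant
#' independently and each offspring inherits one whole haplotype from each
#' parent (no recombination).  In stratified profiles each family's
#' subpopulation is drawn from the mixture, with both parents from the same
#' subpopulation.  Genotypes in the returned dataset are recoded to the
#' sample minor allele (judged from the design's founders) so that written
#' PED files and frequency estimates are consistently minor-allele based.
#'
#' @param profile An \code{\link{build_effect_profile}} truth record.
#' @param design \code{"trio"}, \code{"dsp"} or \code{"case_control"}.
#' @param n Number of ascertained units (affected trios, discordant pairs,
#'   or cases).
#' @param with_case_control For the trio design, also build the matched
#'   case-control sample.
#' @param cap Guard on the total number of offspring generated.
#' @return Object of class \code{"simulated_study"}: list with
#'   \code{dataset} (a \code{\link{pedigree_dataset}}, or NULL for the pure
#'   case-control design), \code{case_control} (a
#'   \code{\link{case_control_sample}} or NULL), \code{profile},
#'   \code{design}, \code{n_offspring_generated} and
#'   \code{n_affected_generated} (counts up to the ascertainment cut, for
#'   prevalence estimation).
#' @export
simulate_ascertained_sample <- function(profile, design = c("trio", "dsp",
                                                            "case_control"),
                                        n = 500L, with_case_control = FALSE,
                                        cap = 5e6) {
  design <- match.arg(design)
  stopifnot(inherits(profile, "effect_profile"), n >= 1L)
  M <- length(profile$freqs_pop1)
  need_cc <- with_case_control || design == "case_control"

  if (design == "dsp") {
    pool <- sim_family_pool(profile, "dsp", n, cap = cap)
    sel <- which(pool$hit)[seq_len(n)]
    cg <- complete_genotypes(pool, profile, sel,
                             list(c("tf1", "tm1"), c("tf2", "tm2")))
    X1 <- cg$children[[1L]]; X2 <- cg$children[[2L]]
    a1 <- pool$aff1[sel]
    # affected sibling listed first
    sib_a <- X1; sib_u <- X2
    sib_a[!a1, ] <- X2[!a1, ]; sib_u[!a1, ] <- X1[!a1, ]
    flip <- minor_flip_columns(rbind(sib_a, sib_u))
    sib_a <- apply_flip(sib_a, flip); sib_u <- apply_flip(sib_u, flip)
    ds <- build_ped_dataset_dsp(sib_a, sib_u, flip)
    return(structure(list(dataset = ds, case_control = NULL,
                          profile = profile, design = design,
                          n_offspring_generated = pool$n_offspring_generated,
                          n_affected_generated = pool$n_affected_generated),
                     class = "simulated_study"))
  }

  n_controls <- if (need_cc) n else 0L
  pool <- sim_family_pool(profile, "trio", n, n_controls, cap = cap)
  cases <- which(pool$hit)[seq_len(n)]
  controls <- integer(0)
  if (need_cc) {
    pre_cut <- seq_len(pool$cut)
    unaff <- pre_cut[!pool$aff1[pre_cut]]
    if (length(unaff) < n)  # extremely high prevalence: look past the cut
      unaff <- which(!pool$aff1)
    if (length(unaff) < n)
      stop("not enough unaffected offspring to form the control sample")
    controls <- unaff[seq_len(n)]
  }
  sel <- c(cases, controls)
  cg <- complete_genotypes(pool, profile, sel, list(c("tf1", "tm1")))
  Xg <- cg$children[[1L]]
  Fg <- cg$father; Mg <- cg$mother
  case_rows <- seq_len(n)
  flip <- minor_flip_columns(rbind(Fg[case_rows, , drop = FALSE],
                                   Mg[case_rows, , drop = FALSE]))
  Fg <- apply_flip(Fg, flip); Mg <- apply_flip(Mg, flip)
  Xg <- apply_flip(Xg, flip)

  dataset <- if (design == "trio")
    build_ped_dataset_trio(Fg[case_rows, , drop = FALSE],
                           Mg[case_rows, , drop = FALSE],
                           Xg[case_rows, , drop = FALSE], flip) else NULL
  cc <- NULL
  if (need_cc) {
    status <- c(rep(1L, n), rep(0L, n))
    cc <- case_control_sample(Xg, status)
  }
  structure(list(dataset = dataset, case_control = cc, profile = profile,
                 design = design,
                 n_offspring_generated = pool$n_offspring_generated,
                 n_affected_generated = pool$n_affected_generated),
            class = "simulated_study")
}

## Columns whose "2"-allele frequency among the given founder genotypes
## exceeds 1/2: the coded allele is not the sample minor allele there.
minor_flip_columns <- function(founder_geno) {
  colMeans(founder_geno) / 2 > 0.5
}

apply_flip <- function(G, flip) {
  if (any(flip)) G[, flip] <- 2 - G[, flip, drop = FALSE]
  G
}

marker_table <- function(M, flip) {
  data.frame(marker_id = paste0("V", seq_len(M)),
             chromosome = "1", position = seq_len(M) * 1000L,
             allele_minor = ifelse(flip, "1", "2"),
             allele_major = ifelse(flip, "2", "1"),
             stringsAsFactors = FALSE)
}

build_ped_dataset_trio <- function(Fg, Mg, Xg, flip) {
  n <- nrow(Fg)
  fid <- paste0("F", seq_len(n))
  individuals <- data.frame(
    family_id = rep(fid, each = 3L),
    individual_id = paste0(rep(fid, each = 3L), "_", rep(1:3, n)),
    father_id = as.vector(rbind("0", "0", paste0(fid, "_1"))),
    mother_id = as.vector(rbind("0", "0", paste0(fid, "_2"))),
    sex = rep(c(1L, 2L, 1L), n),
    phenotype = rep(c(NA_real_, NA_real_, 1), n),
    stringsAsFactors = FALSE)
  G <- matrix(0L, 3L * n, ncol(Fg))
  G[seq(1L, 3L * n, by = 3L), ] <- Fg
  G[seq(2L, 3L * n, by = 3L), ] <- Mg
  G[seq(3L, 3L * n, by = 3L), ] <- Xg
  pedigree_dataset(individuals, G, marker_table(ncol(Fg), flip))
}

build_ped_dataset_dsp <- function(sib_a, sib_u, flip) {
  n <- nrow(sib_a)
  fid <- paste0("S", seq_len(n))
  individuals <- data.frame(
    family_id = rep(fid, each = 2L),
    individual_id = paste0(rep(fid, each = 2L), "_", rep(1:2, n)),
    father_id = "0", mother_id = "0",
    sex = rep(c(1L, 1L), n),
    phenotype = rep(c(1, 0), n),
    stringsAsFactors = FALSE)
  G <- matrix(0L, 2L * n, ncol(sib_a))
  G[seq(1L, 2L * n, by = 2L), ] <- sib_a
  G[seq(2L, 2L * n, by = 2L), ] <- sib_u
  pedigree_dataset(individuals, G, marker_table(ncol(sib_a), flip))
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("Simulated %s study: %d offspring generated, %d affected\n",
              x$design, x$n_offspring_generated, x$n_affected_generated))
  if (!is.null(x$dataset)) print(x$dataset)
  if (!is.null(x$case_control))
    cat(sprintf("  case-control sample: %d cases, %d controls\n",
                sum(x$case_control$status == 1L),
                sum(x$case_control$status == 0L)))
  invisible(x)
}
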
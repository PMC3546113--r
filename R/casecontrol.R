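#' Construct a case-control sample
#'
#' @param genotypes Individuals x markers matrix of minor-allele counts.
#' @param status Disease status vector (1 = case, 0 = control).
#' @return Object of class \code{"case_control_sample"}.
#' @export
case_control_sample <- function(genotypes, status) {
  genotypes <- as.matrix(genotypes)
  status <- as.integer(status)
  stopifnot(nrow(genotypes) == length(status), all(status %in% 0:1),
            any(status == 1L), any(status == 0L))
  structure(list(genotypes = genotypes, status = status),
            class = "case_control_sample")
}

#' Pooled allele-frequency estimates from cases and controls
#'
#' Minor-allele frequency per marker over all sampled individuals (cases and
#' controls together), the frequency source used for thresholding in the
#' population-based comparator tests.
#'
#' @param sample A \code{\link{case_control_sample}}.
#' @return Numeric vector of frequencies.
#' @export
cc_allele_frequencies <- function(sample) {
  colMeans(sample$genotypes, na.rm = TRUE) / 2
}

#' Fixed-threshold burden score test for case-control samples
#'
#' The simplest member of the general score-test family for pooled rare
#' variants: per-individual burden \eqn{B_i = \sum_{j \in subset} X_{ij}},
#' intercept-only logistic score \eqn{U = \sum_i (Y_i - \bar Y) B_i} with
#' null variance \eqn{V = \bar Y (1 - \bar Y) \sum_i (B_i - \bar B)^2},
#' and \eqn{z = U/\sqrt{V}} referred to N(0,1), two-sided.  The marker
#' subset is conventionally chosen by pooled case+control frequency below a
#' threshold (see \code{\link{select_rare}} with
#' \code{\link{cc_allele_frequencies}}).
#'
#' @param sample A \code{\link{case_control_sample}}.
#' @param subset Marker indices to collapse (default: all markers).
#' @return Object of class \code{"cc_test"} with \code{z}, \code{p_value},
#'   \code{statistic} (the score U), \code{variance} and \code{untestable}.
#' @export
burden_score_test <- function(sample, subset = NULL) {
  stopifnot(inherits(sample, "case_control_sample"))
  X <- sample$genotypes
  if (is.null(subset)) subset <- seq_len(ncol(X))
  y <- sample$status
  if (length(subset) == 0L)
    return(cc_result("burden score", NA, NA, NA, NA, untestable = TRUE))
  B <- rowSums(X[, subset, drop = FALSE])
  ybar <- mean(y)
  U <- sum((y - ybar) * B)
  V <- ybar * (1 - ybar) * sum((B - mean(B))^2)
  if (V <= 0)
    return(cc_result("burden score", U, V, NA, NA, untestable = TRUE))
  z <- U / sqrt(V)
  cc_result("burden score", U, V, z, 2 * stats::pnorm(-abs(z)))
}

#' Modified Madsen-Browning weighted-sum test
#'
#' Weighted-sum rank test for rare variants in a case-control sample, with
#' allele frequencies estimated from cases and controls pooled (the
#' modification; the original estimated them from controls only).  Each
#' marker gets weight \eqn{w_j = 1/\sqrt{n \hat q_j (1 - \hat q_j)}} with
#' the smoothed estimate \eqn{\hat q_j = (m_j + 1)/(2n + 2)} (\eqn{m_j} =
#' pooled minor-allele count, n = total sample size); individual scores
#' \eqn{\gamma_i = \sum_j w_j X_{ij}} are ranked with midranks, and the
#' rank sum over cases is standardized by the tie-corrected Wilcoxon normal
#' approximation (two-sided).  Setting \code{n_perm > 0} replaces the normal
#' approximation with a Monte-Carlo permutation p-value for verification.
#'
#' @param sample A \code{\link{case_control_sample}}.
#' @param subset Marker indices to include (default: all markers).
#' @param n_perm Number of status permutations; 0 (default) uses the
#'   asymptotic normal approximation.
#' @return Object of class \code{"cc_test"} with \code{z}, \code{p_value},
#'   \code{statistic} (the case rank sum) and \code{untestable}.
#' @export
weighted_sum_test <- function(sample, subset = NULL, n_perm = 0) {
  stopifnot(inherits(sample, "case_control_sample"))
  X <- sample$genotypes
  if (is.null(subset)) subset <- seq_len(ncol(X))
  y <- sample$status
  n <- length(y)
  m <- colSums(X[, subset, drop = FALSE])
  q <- (m + 1) / (2 * n + 2)
  w <- 1 / sqrt(n * q * (1 - q))
  gamma <- as.numeric(X[, subset, drop = FALSE] %*% w)
  r <- rank(gamma)                         # midranks
  R <- sum(r[y == 1L])
  n1 <- sum(y == 1L); n0 <- n - n1
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  V <- n1 * n0 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (V <= 0)
    return(cc_result("weighted sum", R, V, NA, NA, untestable = TRUE))
  z <- (R - n1 * (n + 1) / 2) / sqrt(V)
  if (n_perm > 0) {
    obs <- abs(R - n1 * (n + 1) / 2)
    exceed <- sum(vapply(seq_len(n_perm), function(b) {
      abs(sum(r[sample.int(n, n1)]) - n1 * (n + 1) / 2) >= obs - 1e-12
    }, logical(1)))
    p <- (exceed + 1) / (n_perm + 1)
  } else {
    p <- 2 * stats::pnorm(-abs(z))
  }
  cc_result("weighted sum", R, V, z, p)
}

cc_result <- function(method, statistic, variance, z, p, untestable = FALSE) {
  structure(list(method = method, statistic = statistic, variance = variance,
                 z = z, p_value = p, untestable = untestable),
            class = "cc_test")
}

#' @export
print.cc_test <- function(x, ...) {
  cat(sprintf("Case-control %s test\n", x$method))
  if (x$untestable) cat("  untestable: no score variation\n")
  else cat(sprintf("  statistic = %.4f, z = %.4f, two-sided p = %.4g\n",
                   x$statistic, x$z, x$p_value))
  invisible(x)
}
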
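#' Conditional offspring genotype distribution given parental genotypes
#'
#' Distribution of the offspring minor-allele count under random Mendelian
#' transmission from two typed parents, assuming additive coding.  This is the
#' null conditional distribution used by all family-based statistics when both
#' parents are available: each parent transmits one of its two alleles with
#' probability 1/2, independently.
#'
#' @param father_count,mother_count Parental minor-allele counts in 0,1,2.
#' @return An object of class \code{"geno_dist"}: a list with \code{support}
#'   (attainable offspring counts), \code{probabilities}, and the implied
#'   \code{mean} and \code{variance}.
#' @examples
#' offspring_transmission_distribution(1, 1)  # 0/1/2 with prob 1/4, 1/2, 1/4
#' @export
offspring_transmission_distribution <- function(father_count, mother_count) {
  stopifnot(father_count %in% 0:2, mother_count %in% 0:2)
  # per-parent transmitted-allele distribution over {0, 1}
  tr <- function(g) if (g == 0L) c(1, 0) else if (g == 2L) c(0, 1) else c(0.5, 0.5)
  pf <- tr(as.integer(father_count))
  pm <- tr(as.integer(mother_count))
  probs <- c(pf[1] * pm[1], pf[1] * pm[2] + pf[2] * pm[1], pf[2] * pm[2])
  keep <- probs > 0
  support <- (0:2)[keep]
  probs <- probs[keep]
  mu <- sum(support * probs)
  structure(list(support = support, probabilities = probs, mean = mu,
                 variance = sum((support - mu)^2 * probs)),
            class = "geno_dist")
}

#' Conditional distribution for a sibpair without parental genotypes
#'
#' When parents are untyped, conditioning on the sufficient statistics for the
#' unobserved parental genotypes reduces, for a two-offspring sibship, to
#' exchangeability of the two offspring: the conditional null distribution is
#' over the orderings of the observed unordered genotype pair.  Distinct
#' genotypes yield the two orderings with probability 1/2 each; identical
#' genotypes give a point mass (and contribute no information).
#'
#' @param sib_counts Length-2 vector of observed minor-allele counts.
#' @return A list with \code{assignments} (a matrix, one row per ordered
#'   assignment of genotypes to the two siblings) and \code{probabilities}.
#' @export
sibpair_conditional_distribution <- function(sib_counts) {
  if (length(sib_counts) != 2L)
    stop("unsupported configuration: sufficient-statistic conditioning is ",
         "implemented for exactly two offspring without parental genotypes")
  stopifnot(all(sib_counts %in% 0:2))
  x <- as.numeric(sib_counts)
  if (x[1] == x[2]) {
    list(assignments = matrix(x, nrow = 1), probabilities = 1)
  } else {
    list(assignments = rbind(x, rev(x), deparse.level = 0),
         probabilities = c(0.5, 0.5))
  }
}

## Per-family contribution across all markers, vectorised over markers.
## Returns list(u = numeric(M), d = numeric(M)).  Markers where any genotype
## used in the conditioning is missing are zeroed (the family is dropped for
## that marker only).
family_contribution_row <- function(family, offset = 0) {
  X <- family$offspring_genotypes
  tr <- family$offspring_traits - offset
  tr[is.na(tr)] <- 0          # offspring without phenotype contribute nothing
  M <- ncol(X)
  if (family$design_tag == "trio") {
    f <- family$father_genotypes
    m <- family$mother_genotypes
    ex <- (f + m) / 2
    v <- 0.25 * ((f == 1) + (m == 1))
    cent <- sweep(X, 2L, ex)                    # X - E[X | parents]
    u <- as.numeric(crossprod(tr, cent))
    d <- sum(tr^2) * v
    miss <- is.na(f) | is.na(m) | colSums(is.na(X)) > 0
  } else {                                       # sibship without parents
    if (nrow(X) != 2L)
      stop("unsupported configuration: sibships without typed parents must ",
           "have exactly 2 offspring (family ", family$family_id, ")")
    half <- (X[1L, ] - X[2L, ]) / 2
    u <- (tr[1L] - tr[2L]) * half
    d <- u^2
    miss <- colSums(is.na(X)) > 0
  }
  if (any(miss)) {
    u[miss] <- 0
    d[miss] <- 0
  }
  # guard against -0 and numeric fuzz on uninformative markers
  u[d == 0] <- 0
  list(u = u, d = d)
}

#' Per-family, per-marker FBAT contribution
#'
#' Computes the family's contribution to the FBAT score at one marker:
#' \eqn{u = \sum_k (T_k - \mu)(X_k - E[X_k])} over the family's offspring,
#' where the conditional expectation and the null variance of \eqn{u} come
#' from Mendelian transmission given typed parents, or from offspring
#' exchangeability for a sibpair without parents.
#'
#' @param family A \code{nuclear_family} object
#'   (see \code{\link{extract_nuclear_families}}).
#' @param marker_index Column index of the marker.
#' @param offset Trait offset subtracted before forming the covariance;
#'   0 for affected-only and discordant-sibpair designs.
#' @return A list with \code{family_id}, \code{marker_index}, \code{u},
#'   \code{model_variance} and \code{informative} (\code{model_variance > 0}).
#' @export
family_marker_contribution <- function(family, marker_index, offset = 0) {
  row <- family_contribution_row(family, offset)
  list(family_id = family$family_id,
       marker_index = as.integer(marker_index),
       u = row$u[marker_index],
       model_variance = row$d[marker_index],
       informative = row$d[marker_index] > 0)
}

#' FBAT contributions for all families and markers
#'
#' Builds the full contribution table consumed by the single-marker,
#' multimarker and collapsed tests: matrices of per-family scores \code{U}
#' and model-based null variances \code{D} (families in rows, markers in
#' columns).  Homogeneous lists of single-offspring trios or of sibpairs are
#' stacked and computed with matrix arithmetic.
#'
#' @param families List of \code{nuclear_family} objects.
#' @param offset Trait offset (default 0).
#' @return A list of class \code{"fbat_contribs"} with elements \code{U},
#'   \code{D}, \code{informative} (logical matrix) and \code{family_ids}.
#' @export
marker_contribution_table <- function(families, offset = 0) {
  stopifnot(length(families) > 0)
  tags <- vapply(families, `[[`, "", "design_tag")
  noff <- vapply(families, function(f) nrow(f$offspring_genotypes), 0L)
  M <- ncol(families[[1L]]$offspring_genotypes)
  n <- length(families)

  if (all(tags == "trio") && all(noff == 1L)) {
    Fg <- do.call(rbind, lapply(families, `[[`, "father_genotypes"))
    Mg <- do.call(rbind, lapply(families, `[[`, "mother_genotypes"))
    X <- do.call(rbind, lapply(families, function(f) f$offspring_genotypes[1L, ]))
    tr <- vapply(families, function(f) f$offspring_traits[1L], 0) - offset
    tr[is.na(tr)] <- 0
    U <- tr * (X - (Fg + Mg) / 2)
    D <- tr^2 * (0.25 * ((Fg == 1) + (Mg == 1)))
    miss <- is.na(Fg) | is.na(Mg) | is.na(X)
    U[miss] <- 0
    D[miss] <- 0
    U[D == 0] <- 0
  } else if (all(tags == "sibship") && all(noff == 2L)) {
    X1 <- do.call(rbind, lapply(families, function(f) f$offspring_genotypes[1L, ]))
    X2 <- do.call(rbind, lapply(families, function(f) f$offspring_genotypes[2L, ]))
    t1 <- vapply(families, function(f) f$offspring_traits[1L], 0)
    t2 <- vapply(families, function(f) f$offspring_traits[2L], 0)
    dt <- t1 - t2
    dt[is.na(dt)] <- 0
    U <- dt * (X1 - X2) / 2
    D <- U^2
    miss <- is.na(X1) | is.na(X2)
    U[miss] <- 0
    D[miss] <- 0
  } else {
    U <- matrix(0, n, M)
    D <- matrix(0, n, M)
    for (i in seq_len(n)) {
      row <- family_contribution_row(families[[i]], offset)
      U[i, ] <- row$u
      D[i, ] <- row$d
    }
  }
  structure(list(U = U, D = D, informative = D > 0,
                 family_ids = vapply(families, `[[`, "", "family_id")),
            class = "fbat_contribs")
}

#' Single-marker FBAT test
#'
#' The classic family-based association test for one marker under additive
#' coding: \eqn{S = \sum_i u_i} over families, with the null variance summed
#' from the per-family conditional variances, \eqn{Z = S/\sqrt{Var(S)}}
#' referred to N(0,1) (two-sided).
#'
#' @inheritParams marker_contribution_table
#' @param marker_index Marker column to test.
#' @return Object of class \code{"fbat_test"}: list with \code{S},
#'   \code{variance}, \code{z}, \code{p_value}, \code{n_informative} and
#'   \code{untestable} (\code{TRUE} when the total null variance is zero, in
#'   which case \code{z} and \code{p_value} are \code{NA}).
#' @export
fbat_single_marker <- function(families, marker_index, offset = 0) {
  ct <- marker_contribution_table(families, offset)
  u <- ct$U[, marker_index]
  d <- ct$D[, marker_index]
  S <- sum(u)
  v <- sum(d)
  if (v > 0) {
    z <- S / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
    untestable <- FALSE
  } else {
    z <- NA_real_
    p <- NA_real_
    untestable <- TRUE
  }
  structure(list(S = S, variance = v, z = z, p_value = p,
                 n_informative = sum(d > 0), untestable = untestable,
                 marker_index = as.integer(marker_index)),
            class = "fbat_test")
}

#' @export
print.fbat_test <- function(x, ...) {
  cat("Single-marker FBAT (additive)\n")
  cat(sprintf("  marker %d: S = %.4f, Var = %.4f, informative families = %d\n",
              x$marker_index, x$S, x$variance, x$n_informative))
  if (x$untestable) {
    cat("  untestable: no informative families\n")
  } else {
    cat(sprintf("  Z = %.4f, two-sided p = %.4g\n", x$z, x$p_value))
  }
  invisible(x)
}
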
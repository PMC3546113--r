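#' Empirical covariance of per-family FBAT scores
#'
#' Cross-product matrix \eqn{V_E[j,k] = \sum_i u_{ij} u_{ik}} of the
#' family-level contributions.  Under the conditional null each \eqn{u_{ij}}
#' has mean zero, so no centering term is applied.
#'
#' @param contribs An \code{fbat_contribs} table (see
#'   \code{\link{marker_contribution_table}}) or the score matrix \code{U}
#'   itself (families in rows).
#' @return Symmetric M x M matrix.
#' @export
empirical_covariance <- function(contribs) {
  U <- if (inherits(contribs, "fbat_contribs")) contribs$U else as.matrix(contribs)
  crossprod(U)
}

#' Adjusted covariance matrix
#'
#' Replaces the empirical variances on the diagonal of \eqn{V_E} with the
#' model-based (exact) conditional variances while keeping the empirical
#' correlation structure:
#' \deqn{V_A[j,k] = \sqrt{D_j D_k}\; V_E[j,k] / \sqrt{V_E[j,j] V_E[k,k]}.}
#' The diagonal of the result equals \code{D} exactly.
#'
#' @param V_E Empirical covariance matrix on the kept markers.
#' @param D Model-based variances for the same markers (all positive).
#' @return Symmetric matrix with diagonal \code{D}.
#' @export
adjusted_covariance <- function(V_E, D) {
  stopifnot(nrow(V_E) == length(D), all(D > 0), all(diag(V_E) > 0))
  s <- sqrt(D / diag(V_E))
  V_A <- V_E * tcrossprod(s)
  diag(V_A) <- D
  V_A
}

#' Score vector and covariance bundle for a marker set
#'
#' Assembles everything the multimarker and collapsed tests need: the score
#' vector S, the empirical covariance V_E, the model-based variances D, and
#' the adjusted covariance V_A.  Markers with zero total model variance carry
#' no information (their scores are identically zero) and are excluded from
#' \code{kept_markers}; a marker with positive model variance but zero
#' empirical variance cannot be rescaled and is dropped with a warning.
#'
#' @param contribs An \code{fbat_contribs} table.
#' @return Object of class \code{"cov_bundle"}: list with full-length
#'   \code{S} and \code{D}, matrices \code{V_E} and \code{V_A} on the kept
#'   markers, \code{kept_markers} (indices into the original marker order),
#'   and \code{n_informative} (per-marker informative-family counts).
#' @export
covariance_bundle <- function(contribs) {
  stopifnot(inherits(contribs, "fbat_contribs"))
  S <- colSums(contribs$U)
  D <- colSums(contribs$D)
  kept <- which(D > 0)
  VE_full <- empirical_covariance(contribs)
  bad <- kept[diag(VE_full)[kept] <= 0]
  if (length(bad)) {
    warning("dropping ", length(bad),
            " marker(s) with zero empirical variance despite positive model variance")
    kept <- setdiff(kept, bad)
  }
  V_E <- VE_full[kept, kept, drop = FALSE]
  V_A <- if (length(kept)) adjusted_covariance(V_E, D[kept]) else V_E
  structure(list(S = S, V_E = V_E, D = D, V_A = V_A, kept_markers = kept,
                 n_informative = colSums(contribs$informative),
                 informative = contribs$informative),
            class = "cov_bundle")
}

## Moore-Penrose pseudo-inverse with relative singular-value cutoff; also
## returns the numerical rank.  Rare variants make V_A near-singular
## routinely, hence the generalized inverse rather than solve().
pinv_rank <- function(A, tol = 1e-8) {
  if (nrow(A) == 0L) return(list(pinv = A, rank = 0L))
  sv <- svd(A)
  keep <- sv$d > max(sv$d) * tol
  r <- sum(keep)
  pinv <- if (r == 0L) matrix(0, nrow(A), ncol(A))
          else sv$v[, keep, drop = FALSE] %*%
               (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  list(pinv = pinv, rank = as.integer(r))
}

#' FBAT multimarker chi-square test
#'
#' Tests a set of markers jointly: \eqn{T = S' V_A^{-} S} with the
#' Moore-Penrose generalized inverse of the adjusted covariance, referred to
#' a chi-square distribution with degrees of freedom equal to the numerical
#' rank of \eqn{V_A}.  The chi-square approximation relies on per-marker
#' asymptotic normality and is known to be conservative for very rare
#' variants.
#'
#' @param bundle A \code{cov_bundle}.
#' @param subset Optional marker indices (original order) restricting the
#'   test, e.g. the output of \code{\link{select_rare}}.  Intersected with
#'   the bundle's kept markers.
#' @return Object of class \code{"fbat_mm"}: list with \code{statistic},
#'   \code{df}, \code{p_value}, \code{markers} (indices actually tested) and
#'   \code{untestable}.
#' @export
multimarker_test <- function(bundle, subset = NULL) {
  stopifnot(inherits(bundle, "cov_bundle"))
  idx <- bundle$kept_markers
  if (!is.null(subset)) idx <- intersect(idx, subset)
  if (length(idx) == 0L)
    return(structure(list(statistic = NA_real_, df = NA_integer_,
                          p_value = NA_real_, markers = integer(0),
                          untestable = TRUE), class = "fbat_mm"))
  pos <- match(idx, bundle$kept_markers)
  V <- bundle$V_A[pos, pos, drop = FALSE]
  S <- bundle$S[idx]
  pr <- pinv_rank(V)
  stat <- as.numeric(crossprod(S, pr$pinv %*% S))
  p <- stats::pchisq(stat, df = pr$rank, lower.tail = FALSE)
  structure(list(statistic = stat, df = pr$rank, p_value = p,
                 markers = idx, untestable = FALSE),
            class = "fbat_mm")
}

#' @export
print.fbat_mm <- function(x, ...) {
  cat("FBAT multimarker test\n")
  if (x$untestable) {
    cat("  untestable: no informative markers in the tested set\n")
  } else {
    cat(sprintf("  markers tested = %d, chi-square = %.4f, df = %d, p = %.4g\n",
                length(x$markers), x$statistic, x$df, x$p_value))
  }
  invisible(x)
}
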
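#' Allele-frequency estimates that are independent of transmissions
#'
#' For trios, minor-allele frequencies are estimated from the parents; for
#' discordant sibpairs (no parental genotypes), from all siblings.  Either
#' source is a function of the conditioning statistics only, so frequencies
#' (and any weights or thresholds built from them) do not depend on the
#' transmissions being tested.
#'
#' @param families List of \code{nuclear_family} objects.
#' @param design \code{"trio"} (estimate from parents) or \code{"dsp"}
#'   (estimate from all siblings).
#' @return Numeric vector of per-marker frequency estimates; \code{NA} where
#'   no source individual has data.
#' @export
estimate_allele_frequencies <- function(families, design = c("trio", "dsp")) {
  design <- match.arg(design)
  G <- if (design == "trio") {
    do.call(rbind, lapply(families, function(f) {
      rbind(f$father_genotypes, f$mother_genotypes)
    }))
  } else {
    do.call(rbind, lapply(families, `[[`, "offspring_genotypes"))
  }
  if (is.null(G) || nrow(G) == 0L)
    stop("no source individuals for frequency estimation")
  n_ok <- colSums(!is.na(G))
  p <- colSums(G, na.rm = TRUE) / (2 * n_ok)
  p[n_ok == 0L] <- NA_real_
  p
}

#' Marker weights for the weighted rare-variant FBAT
#'
#' Two built-in schemes upweight rarer variants: \code{"informative_count"}
#' sets \eqn{w_j = 1/\sqrt{n^{inf}_j}} with \eqn{n^{inf}_j} the number of
#' informative families at marker j, and \code{"frequency"} (the
#' Madsen-Browning-style scheme) sets
#' \eqn{w_j = 1/\sqrt{n \hat p_j (1 - \hat p_j)}} with n the total number of
#' nuclear families and \eqn{\hat p_j} the estimate from
#' \code{\link{estimate_allele_frequencies}} — inversely proportional to the
#' null standard deviation of the allele count in a random sample.  External
#' (e.g. functional-annotation) weights are passed through unchanged.
#'
#' @param scheme One of \code{"unweighted"}, \code{"informative_count"},
#'   \code{"frequency"}, \code{"external"}.
#' @param freqs Frequency estimates (needed for \code{"frequency"}).
#' @param informative_counts Per-marker informative-family counts (needed
#'   for \code{"informative_count"}).
#' @param n_families Total number of nuclear families (frequency scheme).
#' @param external_weights Nonnegative weight per marker (external scheme).
#' @return Weight vector with \code{NA} at markers excluded by the scheme
#'   (monomorphic frequency estimate, or no informative family).
#' @export
compute_weights <- function(scheme = c("unweighted", "informative_count",
                                       "frequency", "external"),
                            freqs = NULL, informative_counts = NULL,
                            n_families = NULL, external_weights = NULL) {
  scheme <- match.arg(scheme)
  switch(scheme,
    unweighted = {
      M <- length(freqs %||% informative_counts %||% external_weights)
      if (M == 0L) stop("cannot infer marker count for unweighted scheme")
      rep(1, M)
    },
    informative_count = {
      stopifnot(!is.null(informative_counts))
      w <- 1 / sqrt(informative_counts)
      w[informative_counts == 0L] <- NA_real_
      w
    },
    frequency = {
      stopifnot(!is.null(freqs), !is.null(n_families))
      w <- 1 / sqrt(n_families * freqs * (1 - freqs))
      w[is.na(freqs) | freqs <= 0 | freqs >= 1] <- NA_real_
      w
    },
    external = {
      stopifnot(!is.null(external_weights))
      if (any(external_weights < 0, na.rm = TRUE))
        stop("external weights must be nonnegative")
      as.numeric(external_weights)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fixed-threshold marker selection
#'
#' Indices of markers whose estimated minor-allele frequency is strictly
#' below the threshold.  Conventional thresholds for defining rare variants
#' are 0.005, 0.01 and 0.05.
#'
#' @param freqs Frequency estimates; \code{NA} entries are never selected.
#' @param threshold Frequency cutoff t; markers with \eqn{\hat p_j < t} are
#'   kept.
#' @return Integer vector of selected marker indices.
#' @export
select_rare <- function(freqs, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  which(!is.na(freqs) & freqs < threshold)
}

#' Collapsed (burden) rare-variant FBAT
#'
#' The region-level statistic \eqn{W = \sum_{j \in subset} w_j S_j}, a
#' weighted sum of single-marker FBAT scores — equivalently the covariance
#' between the trait and the weighted total minor-allele count over the
#' region.  Its null variance is the quadratic form \eqn{w' V_A w} on the
#' adjusted covariance matrix, which for unit weights is exactly the sum of
#' all elements of \eqn{V_A}.  \eqn{Z = W/\sqrt{Var(W)}} is referred to
#' N(0,1), two-sided.
#'
#' @param bundle A \code{cov_bundle} (see \code{\link{covariance_bundle}}).
#' @param weights Weight vector over all markers (NA allowed outside the
#'   subset); defaults to unit weights.
#' @param subset Marker indices to collapse (original marker order);
#'   defaults to all of the bundle's kept markers.
#' @return Object of class \code{"fbat_collapse"}: list with \code{W},
#'   \code{variance}, \code{z}, \code{p_value}, \code{marker_subset} (indices
#'   actually used: requested subset intersected with informative markers),
#'   \code{weights} (on that subset), \code{n_informative} and
#'   \code{untestable}.
#' @export
collapsed_test <- function(bundle, weights = NULL, subset = NULL) {
  stopifnot(inherits(bundle, "cov_bundle"))
  idx <- bundle$kept_markers
  if (!is.null(subset)) idx <- intersect(idx, subset)
  if (is.null(weights)) weights <- rep(1, length(bundle$S))
  stopifnot(length(weights) == length(bundle$S))
  idx <- idx[!is.na(weights[idx])]
  if (length(idx) == 0L)
    return(structure(list(W = NA_real_, variance = NA_real_, z = NA_real_,
                          p_value = NA_real_, marker_subset = integer(0),
                          weights = numeric(0), n_informative = 0L,
                          untestable = TRUE), class = "fbat_collapse"))
  w <- weights[idx]
  pos <- match(idx, bundle$kept_markers)
  V <- bundle$V_A[pos, pos, drop = FALSE]
  W <- sum(w * bundle$S[idx])
  v <- as.numeric(crossprod(w, V %*% w))
  if (v > 0) {
    z <- W / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
    untestable <- FALSE
  } else {
    z <- NA_real_; p <- NA_real_; untestable <- TRUE
  }
  n_inf <- sum(rowSums(bundle$informative[, idx, drop = FALSE]) > 0)
  structure(list(W = W, variance = v, z = z, p_value = p,
                 marker_subset = idx, weights = w,
                 n_informative = n_inf,
                 untestable = untestable),
            class = "fbat_collapse")
}

#' @export
print.fbat_collapse <- function(x, ...) {
  cat("Collapsed rare-variant FBAT\n")
  cat(sprintf("  markers collapsed = %d\n", length(x$marker_subset)))
  if (x$untestable) {
    cat("  untestable: empty marker subset or zero variance\n")
  } else {
    cat(sprintf("  W = %.4f, Var(W) = %.4f, Z = %.4f, two-sided p = %.4g\n",
                x$W, x$variance, x$z, x$p_value))
  }
  invisible(x)
}

#' Region-level rare-variant FBAT analysis
#'
#' One-stop interface: given the nuclear families of a region, runs the
#' collapsed/weighted/fixed-threshold FBAT or the multimarker chi-square
#' test.  Marker frequencies used for thresholding and for the frequency
#' weights are estimated from parents (trios) or all siblings (sibpairs), so
#' they are independent of the transmissions being tested.
#'
#' @param families List of \code{nuclear_family} objects (all the same
#'   design).
#' @param method \code{"collapse"} (burden Z test, default) or \code{"mm"}
#'   (multimarker chi-square).
#' @param threshold Optional frequency cutoff; when given, only markers with
#'   estimated frequency strictly below it are analysed.
#' @param weights Weighting scheme for the collapsed statistic:
#'   \code{"none"}, \code{"informative"}, \code{"frequency"}, or a numeric
#'   vector of external weights (one per marker).
#' @param offset Trait offset (default 0, the affected-only / DSP choice).
#' @return Object of class \code{"fbat_rare"} wrapping the underlying test
#'   result plus the frequency estimates, design, and analysis settings.
#' @examples
#' ## two affected trios, both parents heterozygous, homozygous child
#' fam <- list(
#'   nuclear_family("f1", father = 1L, mother = 1L,
#'                  offspring = matrix(2L, 1, 1), traits = 1),
#'   nuclear_family("f2", father = 1L, mother = 1L,
#'                  offspring = matrix(2L, 1, 1), traits = 1))
#' fbat_rare(fam)
#' @export
fbat_rare <- function(families, method = c("collapse", "mm"),
                      threshold = NULL, weights = "none", offset = 0) {
  method <- match.arg(method)
  tags <- unique(vapply(families, `[[`, "", "design_tag"))
  if (length(tags) != 1L)
    stop("mixed family designs in one analysis are not supported")
  design <- if (tags == "trio") "trio" else "dsp"
  contribs <- marker_contribution_table(families, offset)
  bundle <- covariance_bundle(contribs)
  freqs <- estimate_allele_frequencies(families, design)
  subset <- if (is.null(threshold)) NULL else select_rare(freqs, threshold)
  if (method == "mm") {
    fit <- multimarker_test(bundle, subset)
  } else {
    w <- if (is.numeric(weights)) {
      compute_weights("external", external_weights = weights)
    } else {
      switch(match.arg(weights, c("none", "informative", "frequency")),
        none = compute_weights("unweighted", freqs = freqs),
        informative = compute_weights("informative_count",
                                      informative_counts = bundle$n_informative),
        frequency = compute_weights("frequency", freqs = freqs,
                                    n_families = length(families)))
    }
    fit <- collapsed_test(bundle, weights = w, subset = subset)
  }
  structure(list(result = fit, method = method, design = design,
                 threshold = threshold,
                 weights = if (is.numeric(weights)) "external" else weights,
                 offset = offset, freqs = freqs,
                 n_families = length(families),
                 n_markers = length(freqs)),
            class = "fbat_rare")
}

#' @export
print.fbat_rare <- function(x, ...) {
  cat(sprintf("Rare-variant FBAT analysis (%s design, %d families, %d markers)\n",
              x$design, x$n_families, x$n_markers))
  cat(sprintf("  method = %s, threshold = %s, weights = %s, offset = %g\n",
              x$method,
              if (is.null(x$threshold)) "none" else format(x$threshold),
              x$weights, x$offset))
  print(x$result)
  invisible(x)
}

#' @export
summary.fbat_rare <- function(object, ...) {
  r <- object$result
  df <- data.frame(
    design = object$design,
    n_families = object$n_families,
    n_markers_kept = length(if (object$method == "mm") r$markers else r$marker_subset),
    mode = object$method,
    threshold = if (is.null(object$threshold)) NA_real_ else object$threshold,
    weights = object$weights,
    W = if (object$method == "mm") r$statistic else r$W,
    var = if (object$method == "mm") NA_real_ else r$variance,
    z = if (object$method == "mm") NA_real_ else r$z,
    p = r$p_value,
    n_informative = if (object$method == "mm") NA_integer_ else r$n_informative,
    stringsAsFactors = FALSE)
  class(df) <- c("summary.fbat_rare", "data.frame")
  df
}

#' Append region results to a TSV file
#'
#' Serializes one or more \code{fbat_rare} results in the tabular schema
#' region / n_families / n_markers_kept / mode / threshold / W / var / z /
#' p / n_informative.
#'
#' @param results A single \code{fbat_rare} object or a list of them.
#' @param file Output path or connection.
#' @param region Region label(s) recycled across results.
#' @return The written data frame, invisibly.
#' @export
write_results_tsv <- function(results, file, region = "region1") {
  if (inherits(results, "fbat_rare")) results <- list(results)
  rows <- do.call(rbind, lapply(results, summary))
  rows <- cbind(region = rep_len(region, nrow(rows)), rows)
  utils::write.table(rows, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}
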
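# Feature overlap versus marker-identity thresholds, and feature spectra.

#' Mean shared / unique features versus marker-identity thresholds
#'
#' For each threshold t, over all unordered strain pairs whose marker
#' identity is at least t (cumulative OTU-style thresholds): mean_shared =
#' mean intersection size and mean_unique = mean symmetric-difference size
#' of the two strains' feature sets. A threshold met by no pair reports
#' n_pairs = 0 and NA means. `binned = TRUE` instead assigns each pair to
#' the interval [t_k, t_{k+1}) of the threshold grid.
#'
#' @param identity an [IdentityMatrix-class].
#' @param features a [FeatureAnnotation-class]; its strains must be a subset
#'   of the identity matrix's.
#' @param thresholds increasing percent-identity thresholds in [0, 100].
#' @param flag optional feature flag acting as a pre-filter (see
#'   [featureSets()]).
#' @param binned use binned rather than cumulative threshold semantics.
#' @return data.frame: threshold, n_pairs, mean_shared, mean_unique.
#' @export
overlapCurve <- function(identity, features, thresholds = c(97, 98, 99, 100),
                         flag = NULL, binned = FALSE) {
  if (any(thresholds < 0 | thresholds > 100))
    stop("thresholds must lie in [0, 100]")
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  sets <- featureSets(features, flag = flag)
  strains <- intersect(strainNames(identity), names(sets))
  if (!all(strainNames(features) %in% strainNames(identity)))
    stop("feature strains must be a subset of identity strains")
  iv <- matrixValues(identity)[strains, strains, drop = FALSE]
  pairs <- combn(strains, 2)
  pid <- iv[cbind(pairs[1, ], pairs[2, ])]
  shared <- mapply(function(a, b) length(intersect(sets[[a]], sets[[b]])),
                   pairs[1, ], pairs[2, ])
  unique_ <- mapply(function(a, b) length(union(sets[[a]], sets[[b]])) -
                      length(intersect(sets[[a]], sets[[b]])),
                    pairs[1, ], pairs[2, ])
  rows <- lapply(seq_along(thresholds), function(k) {
    t <- thresholds[k]
    sel <- if (binned) {
      hi <- if (k < length(thresholds)) thresholds[k + 1] else Inf
      pid >= t & pid < hi
    } else pid >= t
    n <- sum(sel)
    data.frame(threshold = t, n_pairs = n,
               mean_shared = if (n) mean(shared[sel]) else NA_real_,
               mean_unique = if (n) mean(unique_[sel]) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Feature family-size spectrum and prevalence fractions
#'
#' Histogram of feature family sizes (number of carrier strains per feature)
#' and per-feature prevalence fractions (carriers / total strains);
#' zero-prevalence features are excluded from the fraction report.
#'
#' @param features a [FeatureAnnotation-class].
#' @param flag optional feature flag pre-filter.
#' @return list: `size_histogram` (named integer vector: family size ->
#'   number of features), `prevalence` (named numeric, per feature),
#'   `n_features`.
#' @export
featureSpectra <- function(features, flag = NULL) {
  sets <- featureSets(features, flag = flag)
  if (!length(unlist(sets))) stop("annotation has no features")
  carriers <- table(unlist(sets))
  n_strains <- length(strainNames(features))
  hist <- table(factor(as.integer(carriers), levels = seq_len(n_strains)))
  list(size_histogram = setNames(as.integer(hist), names(hist)),
       prevalence = setNames(as.numeric(carriers) / n_strains,
                             names(carriers)),
       n_features = length(carriers))
}
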
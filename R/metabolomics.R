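# Metabolite-table preprocessing: replicate-presence filtering, ion-mode
# merging, missing-value handling, glog + autoscaling, ANOVA with FDR,
# score normalization and heatmap clustering order.

#' Build a raw trait matrix from a long LC-MS table
#'
#' A strain x metabolite value survives only if it is detected — abundance
#' above the media-control baseline, mean(control) + 3 sd(control) for that
#' metabolite and ion mode — in at least `min_replicates` of
#' `total_replicates` replicates (a replicate counts if detected in either
#' mode). Surviving values are the replicate-summed abundance per ion mode,
#' taking the larger of the two mode sums. Undetected combinations are NA.
#'
#' @param table long data.frame as produced by [simulateLcms()] (columns
#'   strain, replicate, ion_mode, metabolite, abundance, is_control).
#' @param min_replicates detection threshold (default 3).
#' @param total_replicates replicates per strain (default 5).
#' @param collapse_replicates if FALSE, return a sample-level matrix with
#'   one row per strain:replicate (mode-max of per-replicate abundances,
#'   same detection rule) for replicate-aware analyses such as ANOVA.
#' @return a [TraitMatrix-class] at stage "raw"; NA marks missing values.
#' @export
buildTraitMatrix <- function(table, min_replicates = 3, total_replicates = 5,
                             collapse_replicates = TRUE) {
  if (min_replicates > total_replicates)
    stop("min_replicates must be <= total_replicates")
  ctrl <- table[table$is_control, , drop = FALSE]
  smp <- table[!table$is_control, , drop = FALSE]
  # detection baseline per metabolite x mode
  key <- interaction(ctrl$metabolite, ctrl$ion_mode, drop = TRUE)
  base_mean <- tapply(ctrl$abundance, key, mean)
  base_sd <- tapply(ctrl$abundance, key, sd)
  base_sd[is.na(base_sd)] <- 0
  thr <- base_mean + 3 * base_sd
  skey <- paste(smp$metabolite, smp$ion_mode, sep = ".")
  lim <- thr[skey]
  lim[is.na(lim)] <- 0  # no control measured: anything observed counts
  smp$detected <- smp$abundance > lim
  strains <- unique(smp$strain)
  mets <- unique(smp$metabolite)
  det <- tapply(smp$detected, list(paste(smp$strain, smp$metabolite,
                                         smp$replicate)), any)
  # replicates detecting each strain x metabolite
  dkey <- sub(" [^ ]+$", "", names(det))
  n_det <- tapply(as.integer(det), dkey, sum)
  ok <- n_det >= min_replicates
  if (collapse_replicates) {
    sums <- tapply(smp$abundance,
                   list(paste(smp$strain, smp$metabolite), smp$ion_mode), sum)
    value <- apply(sums, 1L, max, na.rm = TRUE)
    m <- matrix(NA_real_, length(strains), length(mets),
                dimnames = list(strains, mets))
    for (nm in names(value)) {
      if (!isTRUE(ok[nm])) next
      parts <- strsplit(nm, " ", fixed = TRUE)[[1]]
      m[parts[1], parts[2]] <- value[nm]
    }
    TraitMatrix(m, stage = "raw")
  } else {
    reps <- sort(unique(smp$replicate))
    rows <- as.vector(outer(strains, reps, paste, sep = ":"))
    sums <- tapply(smp$abundance,
                   list(paste(smp$strain, smp$replicate, smp$metabolite),
                        smp$ion_mode), sum)
    value <- apply(sums, 1L, max, na.rm = TRUE)
    m <- matrix(NA_real_, length(rows), length(mets),
                dimnames = list(rows, mets))
    for (nm in names(value)) {
      parts <- strsplit(nm, " ", fixed = TRUE)[[1]]
      if (!isTRUE(ok[paste(parts[1], parts[3])])) next
      m[paste0(parts[1], ":", parts[2]), parts[3]] <- value[nm]
    }
    TraitMatrix(m, stage = "raw")
  }
}

#' Remove high-missing metabolites and impute the rest
#'
#' Drops metabolite columns whose missing fraction exceeds
#' `max_missing_fraction` (default: more than 50% missing are removed), then
#' replaces remaining NAs with half of the minimum positive value observed
#' anywhere in the matrix.
#'
#' @param m a raw-stage [TraitMatrix-class].
#' @param max_missing_fraction tolerated missing fraction (default 0.5).
#' @return a [TraitMatrix-class] at stage "imputed".
#' @export
imputeAndFilterMissing <- function(m, max_missing_fraction = 0.5) {
  stopifnot(is(m, "TraitMatrix"))
  if (traitStage(m) != "raw") stop("expected a raw-stage TraitMatrix")
  x <- matrixValues(m)
  keep <- colMeans(is.na(x)) <= max_missing_fraction
  if (!any(keep)) stop("all metabolite columns exceed the missing threshold")
  x <- x[, keep, drop = FALSE]
  if (anyNA(x)) {
    pos <- x[!is.na(x) & x > 0]
    if (!length(pos)) stop("no positive values available for imputation")
    x[is.na(x)] <- min(pos) / 2
  }
  TraitMatrix(x, stage = "imputed", metadata = m@metadata)
}

#' Generalized log transform
#'
#' glog(x) = log2((x + sqrt(x^2 + lambda)) / 2); at lambda -> 0 this tends
#' to log2(x), and glog(0; lambda = 1) = -1.
#'
#' @param x numeric vector or matrix.
#' @param lambda positive transform offset (default 1).
#' @return transformed values, same shape.
#' @export
glog <- function(x, lambda = 1) {
  if (lambda <= 0) stop("lambda must be > 0")
  log2((x + sqrt(x^2 + lambda)) / 2)
}

#' Generalized-log transform and autoscale a trait matrix
#'
#' Applies [glog()] elementwise, then autoscales: per metabolite column,
#' subtract the mean and divide by the sample standard deviation, so each
#' column has mean 0 and SD 1. Zero-variance columns are dropped with a
#' warning.
#'
#' @param m an imputed-stage [TraitMatrix-class].
#' @param lambda glog offset (default 1).
#' @return a [TraitMatrix-class] at stage "autoscaled".
#' @export
glogAutoscale <- function(m, lambda = 1) {
  stopifnot(is(m, "TraitMatrix"))
  if (traitStage(m) != "imputed")
    stop("expected an imputed-stage TraitMatrix")
  x <- glog(matrixValues(m), lambda)
  sds <- apply(x, 2L, sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance metabolite columns: ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  x <- scale(x, center = TRUE, scale = TRUE)
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  TraitMatrix(x, stage = "autoscaled", metadata = m@metadata)
}

#' Per-metabolite one-way ANOVA with Benjamini-Hochberg FDR
#'
#' Tests each metabolite for differential abundance across groups (strains
#' by default, when rows are strain:replicate samples) with a one-way fixed
#' effects ANOVA, then adjusts p-values by Benjamini-Hochberg. Metabolites
#' with a degenerate design (any group with fewer than 2 observations, or
#' zero residual and between-group variance) are skipped with a warning.
#'
#' @param m a [TraitMatrix-class] whose rows are observations.
#' @param groups factor (or coercible) of length nrow assigning each row to
#'   a group; default: the strain part of "strain:replicate" rownames.
#' @param alpha FDR level for the significant set (default 0.05).
#' @return data.frame: metabolite, F, p, q, significant; skipped metabolites
#'   are absent.
#' @export
anovaFdr <- function(m, groups = NULL, alpha = 0.05) {
  stopifnot(is(m, "TraitMatrix"))
  x <- matrixValues(m)
  if (is.null(groups)) groups <- sub(":.*$", "", rownames(x))
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  res <- lapply(colnames(x), function(met) {
    v <- x[, met]
    keep <- !is.na(v)
    vv <- v[keep]; gg <- droplevels(g[keep])
    if (nlevels(gg) < 2 || any(table(gg) < 2) || var(vv) == 0) return(NULL)
    fit <- aov(vv ~ gg)
    s <- summary(fit)[[1]]
    data.frame(metabolite = met, F = s[1, "F value"], p = s[1, "Pr(>F)"])
  })
  skipped <- colnames(x)[vapply(res, is.null, logical(1))]
  if (length(skipped))
    warning("skipped degenerate metabolites: ",
            paste(skipped, collapse = ", "))
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no testable metabolite")
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q < alpha
  rownames(out) <- NULL
  out
}

#' Normalize an association-score matrix column-wise to [0, 1]
#'
#' Divides each metabolite column of a consumed genome-metabolite score
#' matrix by its maximum, so the top strain scores exactly 1. All-zero (or
#' non-positive) columns are dropped with a warning.
#'
#' @param scores numeric matrix (strains x metabolites) or a
#'   [TraitMatrix-class].
#' @return a [TraitMatrix-class] at stage "normalized_score".
#' @export
normalizeScores <- function(scores) {
  x <- if (is(scores, "TraitMatrix")) matrixValues(scores) else scores
  mx <- apply(x, 2L, max, na.rm = TRUE)
  bad <- !is.finite(mx) | mx <= 0
  if (any(bad)) {
    warning("dropping columns without a positive score: ",
            paste(colnames(x)[bad], collapse = ", "))
    x <- x[, !bad, drop = FALSE]
    mx <- mx[!bad]
  }
  if (!ncol(x)) stop("no column with a positive score")
  TraitMatrix(sweep(x, 2L, mx, "/"), stage = "normalized_score")
}

#' Ward clustering order for heatmap layout
#'
#' Agglomerative Ward (ward.D2) clustering on Euclidean distances of the
#' rows and of the columns; returns the dendrograms and their leaf orders.
#'
#' @param m a [TraitMatrix-class] or numeric matrix (>= 2 rows).
#' @return list: `row_order`, `col_order` (leaf label orders), `row_hclust`,
#'   `col_hclust`.
#' @export
wardClusterOrder <- function(m) {
  x <- if (is(m, "TraitMatrix")) matrixValues(m) else m
  if (nrow(x) < 2) stop("need at least 2 rows")
  hr <- hclust(dist(x), method = "ward.D2")
  hc <- if (ncol(x) >= 2) hclust(dist(t(x)), method = "ward.D2") else NULL
  list(row_order = rownames(x)[hr$order],
       col_order = if (is.null(hc)) colnames(x) else colnames(x)[hc$order],
       row_hclust = hr, col_hclust = hc)
}
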
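# Trait, feature-annotation and LC-MS table simulators.

#' Assign synthetic feature families of one category
#'
#' Stand-in for external annotation calls (resistance elements, gene cluster
#' families, carbohydrate-active enzyme families, metabolic hallmarks). Two
#' modes: features tied to accessory gene families inherit their
#' presence/absence pattern exactly; independent features are Bernoulli draws
#' at a per-feature prevalence.
#'
#' @param pa a [PresenceAbsenceMatrix-class].
#' @param category "resistance", "gcf", "cazy" or "hallmark".
#' @param n_families number of features to create (>= 1).
#' @param prevalence_distribution `"tied"` (default) to sample accessory
#'   families and inherit their patterns, or a numeric vector of per-feature
#'   prevalences in [0, 1] (recycled) for independent draws.
#' @param flag_levels optional character vector; each feature gets one flag
#'   drawn uniformly (e.g. `c("strict", "loose")`).
#' @param seed integer seed.
#' @return a [FeatureAnnotation-class]. Tied features record their source
#'   family in attribute-like metadata: feature ids are
#'   `<category>_<i>@<family>`.
#' @export
assignFeatureFamilies <- function(pa, category, n_families,
                                  prevalence_distribution = "tied",
                                  flag_levels = NULL, seed = NULL) {
  if (!category %in% .feature_categories)
    stop("unknown category: ", category)
  if (n_families < 1) stop("n_families must be >= 1")
  pam <- paMatrix(pa)
  strains <- rownames(pam)
  with_seed(seed, {
    if (identical(prevalence_distribution, "tied")) {
      acc <- colnames(pam)[colMeans(pam) < 1]
      if (!length(acc)) acc <- colnames(pam)
      src <- sample(acc, n_families, replace = n_families > length(acc))
      ids <- sprintf("%s_%03d@%s", category, seq_len(n_families), src)
      carrier <- pam[, src, drop = FALSE]
    } else {
      prev <- rep_len(as.numeric(prevalence_distribution), n_families)
      ids <- sprintf("%s_%03d", category, seq_len(n_families))
      carrier <- matrix(runif(length(strains) * n_families) <
                          rep(prev, each = length(strains)),
                        nrow = length(strains),
                        dimnames = list(strains, NULL))
    }
    colnames(carrier) <- ids
    flags <- character()
    if (!is.null(flag_levels)) {
      flags <- setNames(sample(flag_levels, n_families, replace = TRUE), ids)
    }
    features <- lapply(setNames(strains, strains),
                       function(s) ids[carrier[s, ]])
    FeatureAnnotation(category, strains, features, flags = flags)
  })
}

#' Phylogenetic covariance matrix of a tree
#'
#' Tip-by-tip matrix of shared root-to-MRCA branch length; the diagonal is
#' each tip's root-to-tip depth. This is the covariance of a unit-rate
#' Brownian motion on the tree.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @return symmetric positive semi-definite numeric matrix with tip dimnames.
#' @export
phyloCovariance <- function(tree) {
  ape::vcv.phylo(tree)
}

#' Simulate metabolite traits: Brownian motion plus white noise
#'
#' Brownian-motion traits are multivariate normal with covariance sigma2 x
#' V(tree); white-noise traits are iid normal with the same marginal scale
#' (sigma2 x mean tip depth) but no tree structure.
#'
#' @param tree generating `ape::phylo`.
#' @param n_bm number of Brownian-motion metabolites.
#' @param n_noise number of white-noise metabolites.
#' @param sigma2 Brownian-motion rate (variance per unit branch length, > 0).
#' @param seed integer seed.
#' @return a [TraitMatrix-class] (stage "raw") with per-column generator tags
#'   "bm"/"white_noise" and metadata `sigma2`.
#' @export
simulateTraits <- function(tree, n_bm, n_noise = 0, sigma2 = 1, seed = NULL) {
  if (n_bm + n_noise < 1) stop("need at least one trait")
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  V <- phyloCovariance(tree)
  n <- nrow(V)
  with_seed(seed, {
    cols <- list()
    if (n_bm > 0) {
      R <- chol(sigma2 * V)  # V = R'R
      z <- matrix(rnorm(n * n_bm), n, n_bm)
      cols$bm <- crossprod(R, z)
    }
    if (n_noise > 0) {
      s <- sqrt(sigma2 * mean(diag(V)))
      cols$noise <- matrix(rnorm(n * n_noise, sd = s), n, n_noise)
    }
    values <- do.call(cbind, cols)
    rownames(values) <- rownames(V)
    colnames(values) <- sprintf("met%03d", seq_len(n_bm + n_noise))
    TraitMatrix(values, stage = "raw",
                generator = c(rep("bm", n_bm), rep("white_noise", n_noise)),
                metadata = list(sigma2 = sigma2, n_tips = n))
  })
}

#' Simulate a replicated two-ion-mode LC-MS table with media controls
#'
#' Maps each simulated trait value x to a true abundance `baseline * 2^x`,
#' observes it in `n_replicates` replicates and two ion modes (pos/neg signal
#' split 60/40) with log-normal measurement noise, adds media-control
#' replicates at `control_level`, and deletes sample rows completely at
#' random with probability `missing_rate` (missing values are absent rows,
#' as an LC-MS feature table reports them).
#'
#' @param traits a [TraitMatrix-class] of simulated traits.
#' @param n_replicates replicates per strain (>= 1).
#' @param missing_rate probability a sample row is dropped (0 <= r < 1).
#' @param control_level media-control abundance level.
#' @param baseline abundance corresponding to trait value 0.
#' @param noise_sdlog sdlog of the log-normal replicate noise.
#' @param seed integer seed.
#' @return long-format data.frame with columns strain, replicate, ion_mode,
#'   metabolite, abundance, is_control; control rows use strain "media".
#' @export
simulateLcms <- function(traits, n_replicates = 5, missing_rate = 0.1,
                         control_level = 50, baseline = 1000,
                         noise_sdlog = 0.2, seed = NULL) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  x <- matrixValues(traits)
  strains <- rownames(x)
  mets <- colnames(x)
  mode_frac <- c(pos = 0.6, neg = 0.4)
  with_seed(seed, {
    grid <- expand.grid(strain = strains, replicate = seq_len(n_replicates),
                        ion_mode = c("pos", "neg"), metabolite = mets,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    true <- baseline * 2^x[cbind(grid$strain, grid$metabolite)]
    mu <- true * mode_frac[grid$ion_mode]
    grid$abundance <- mu * exp(rnorm(nrow(grid), sd = noise_sdlog))
    grid$is_control <- FALSE
    ctrl <- expand.grid(strain = "media", replicate = seq_len(n_replicates),
                        ion_mode = c("pos", "neg"), metabolite = mets,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    ctrl$abundance <- control_level * exp(rnorm(nrow(ctrl), sd = noise_sdlog))
    ctrl$is_control <- TRUE
    if (missing_rate > 0) {
      grid <- grid[runif(nrow(grid)) >= missing_rate, , drop = FALSE]
    }
    out <- rbind(grid, ctrl)
    rownames(out) <- NULL
    out
  })
}
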
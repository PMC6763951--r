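# Blomberg's K and its randomization test, screened per metabolite against
# alternative tree topologies.

# Precompute everything K needs from V once; reused across permutations and
# metabolites on the same tree.
k_context <- function(V) {
  n <- nrow(V)
  Vi <- tryCatch(chol2inv(chol(V)), error = function(e) NULL)
  if (is.null(Vi)) {
    warning("phylogenetic covariance is singular; using a pseudo-inverse")
    Vi <- MASS::ginv(V)
  }
  one <- rep(1, n)
  Vi1 <- Vi %*% one
  s <- sum(Vi1)  # 1' V^-1 1
  expected <- (sum(diag(V)) - n / s) / (n - 1)
  list(n = n, Vi = Vi, Vi1 = Vi1, s = s, expected = expected,
       labels = rownames(V))
}

# K for each column of a trait matrix X (tips x traits), given a context.
k_stat <- function(X, ctx) {
  a <- as.numeric(crossprod(ctx$Vi1, X)) / ctx$s  # GLS root state per trait
  C <- sweep(X, 2L, a)                            # x - a
  mse0 <- colSums(C^2) / (ctx$n - 1)
  mse <- colSums(C * (ctx$Vi %*% C)) / (ctx$n - 1)
  (mse0 / mse) / ctx$expected
}

#' Blomberg's K for one trait
#'
#' Ratio of the observed mean-squared deviation of tip values from their
#' phylogenetically weighted mean to the variance-scaled (GLS) deviation,
#' standardized by its Brownian-motion expectation on the tree:
#' K = (MSE0 / MSE) / ((tr V - n / (1' V^-1 1)) / (n - 1)), with
#' MSE0 = (x - a)'(x - a) / (n - 1), MSE = (x - a)' V^-1 (x - a) / (n - 1)
#' and a the GLS estimate of the root state. K is about 1 for traits that
#' evolved by Brownian motion on the tree, near 0 for tree-independent
#' traits, and exactly 1 for any trait on a star tree with equal depths.
#'
#' @param trait named numeric vector of tip values (names = tip labels),
#'   length >= 4, not constant.
#' @param V phylogenetic covariance matrix (see [phyloCovariance()]) or an
#'   `ape::phylo`.
#' @return K (dimensionless, >= 0).
#' @export
blombergK <- function(trait, V) {
  if (inherits(V, "phylo")) V <- phyloCovariance(V)
  x <- align_trait(trait, V)
  ctx <- k_context(V)
  as.numeric(k_stat(matrix(x, ncol = 1), ctx))
}

align_trait <- function(trait, V) {
  if (length(trait) < 4) stop("need at least 4 tips")
  if (!is.null(names(trait))) {
    if (!setequal(names(trait), rownames(V)))
      stop("trait names and tip labels differ: ",
           paste(symdiff_chr(names(trait), rownames(V)), collapse = ", "))
    trait <- trait[rownames(V)]
  } else if (length(trait) != nrow(V)) {
    stop("trait length does not match the tree")
  }
  if (var(trait) == 0) stop("constant trait: K undefined")
  unname(trait)
}

symdiff_chr <- function(a, b) c(setdiff(a, b), setdiff(b, a))

#' Permutation test for Blomberg's K
#'
#' Shuffles the trait values across the tips `n_randomizations` times and
#' reports p = (1 + #\{K_perm >= K_obs\}) / (n + 1) (add-one rule; never 0).
#'
#' @param trait named numeric vector of tip values.
#' @param V covariance matrix or `ape::phylo`.
#' @param n_randomizations number of tip shuffles (default 1000).
#' @param seed integer seed.
#' @return list: `K`, `p`, `n_randomizations`.
#' @export
kPermutationTest <- function(trait, V, n_randomizations = 1000, seed = NULL) {
  if (n_randomizations < 1) stop("n_randomizations must be >= 1")
  if (inherits(V, "phylo")) V <- phyloCovariance(V)
  x <- align_trait(trait, V)
  ctx <- k_context(V)
  k_perm_core(x, ctx, n_randomizations, seed)
}

k_perm_core <- function(x, ctx, n_randomizations, seed) {
  k_obs <- as.numeric(k_stat(matrix(x, ncol = 1), ctx))
  perms <- with_seed(seed, {
    vapply(seq_len(n_randomizations), function(i) sample(x), numeric(ctx$n))
  })
  k_perm <- k_stat(perms, ctx)
  p <- (1 + sum(k_perm >= k_obs)) / (n_randomizations + 1)
  list(K = k_obs, p = p, n_randomizations = n_randomizations)
}

#' Screen metabolites for phylogenetic signal against several trees
#'
#' Runs [kPermutationTest()] for every metabolite x tree combination and
#' flags the incongruence readout: metabolites significant (p < alpha) on at
#' least one tree but not on all trees. Per-metabolite random streams are
#' derived from `seed` by counter, so results do not depend on column order.
#'
#' @param traits a [TraitMatrix-class] (any stage; K is invariant to the
#'   per-metabolite affine transforms of autoscaling).
#' @param trees named list of `ape::phylo` trees sharing the trait strains.
#' @param n_randomizations shuffles per test (default 1000).
#' @param alpha significance level (default 0.01).
#' @param seed integer seed.
#' @return data.frame: metabolite, tree, K, p, n_randomizations,
#'   significant; plus attribute `"incongruent"` listing metabolites
#'   significant for some but not all trees.
#' @export
signalScreen <- function(traits, trees, n_randomizations = 1000,
                         alpha = 0.01, seed = NULL) {
  stopifnot(is(traits, "TraitMatrix"))
  if (is.null(names(trees)))
    names(trees) <- sprintf("tree%d", seq_along(trees))
  x <- matrixValues(traits)
  for (nm in names(trees)) {
    bad <- symdiff_chr(trees[[nm]]$tip.label, rownames(x))
    if (length(bad))
      stop("strain mismatch for tree '", nm, "': ",
           paste(bad, collapse = ", "))
  }
  rows <- list()
  for (ti in seq_along(trees)) {
    V <- phyloCovariance(trees[[ti]])
    ctx <- k_context(V)
    for (mi in seq_len(ncol(x))) {
      trait <- align_trait(setNames(x[, mi], rownames(x)), V)
      r <- k_perm_core(trait, ctx, n_randomizations,
                       seed = derive_seed(seed %||% 0, 1000 * ti + mi))
      rows[[length(rows) + 1L]] <-
        data.frame(metabolite = colnames(x)[mi], tree = names(trees)[ti],
                   K = r$K, p = r$p, n_randomizations = n_randomizations,
                   significant = r$p < alpha)
    }
  }
  out <- do.call(rbind, rows)
  sig_by_met <- tapply(out$significant, out$metabolite, sum)
  incongruent <- names(sig_by_met)[sig_by_met > 0 &
                                     sig_by_met < length(trees)]
  attr(out, "incongruent") <- incongruent
  out
}
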
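# Tree inference and comparison: Jukes-Cantor distances, neighbor joining,
# UPGMA, Jaccard composition distances, bootstrap supports, scaled patristic
# divergence, and Robinson-Foulds discordance.

#' Jukes-Cantor distance matrix from an alignment
#'
#' d = -(3/4) ln(1 - (4/3) p), with p the mismatch fraction over mutually
#' non-gapped columns (an N never matches). Saturated pairs (p >= 0.75,
#' where the formula diverges) are set to `cap` with a warning.
#'
#' @param msa character matrix (sequences x sites) or named character vector
#'   of equal-length (possibly gapped) sequences.
#' @param cap saturation distance in substitutions/site (default 5).
#' @return symmetric numeric distance matrix with zero diagonal.
#' @export
jcDistanceMatrix <- function(msa, cap = 5) {
  if (!is.matrix(msa)) msa <- strings_to_seq_matrix(msa)
  n <- nrow(msa)
  if (n < 2) stop("need at least 2 sequences")
  d <- matrix(0, n, n, dimnames = list(rownames(msa), rownames(msa)))
  saturated <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- msa[i, ]; b <- msa[j, ]
      keep <- a != "-" & b != "-"
      if (!any(keep)) stop("no comparable columns for pair ",
                           rownames(msa)[i], " / ", rownames(msa)[j])
      p <- mean(a[keep] != b[keep] | a[keep] == "N")
      if (p >= 0.75) {
        d[i, j] <- d[j, i] <- cap
        saturated <- TRUE
      } else {
        d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
      }
    }
  }
  if (saturated)
    warning("saturated pairs (p >= 0.75) capped at d = ", cap)
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining with deterministic tie-breaking (the
#' lowest-index pair among equal Q values) and negative-branch handling:
#' a negative estimated branch length is clamped to zero and the deficit
#' transferred to its sister edge, preserving the path length between the
#' joined pair. Consistent on additive distance matrices.
#'
#' @param d symmetric numeric distance matrix with labels.
#' @return unrooted `ape::phylo`.
#' @export
njTree <- function(d) {
  check_dist(d)
  n <- nrow(d)
  if (n < 3) stop("need at least 3 taxa")
  labels <- rownames(d)
  # each active node is a newick fragment
  reps <- labels
  D <- d
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    # lowest-index pair (row-major) among minima
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    cl <- clamp_pair(li, lj)
    new_rep <- sprintf("(%s:%.10g,%s:%.10g)", reps[i], cl[1], reps[j], cl[2])
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    # merged cluster takes slot i; slot j is removed
    D[i, ] <- D[, i] <- du
    D[i, i] <- 0
    reps[i] <- new_rep
    keep <- setdiff(seq_len(m), j)
    D <- D[keep, keep, drop = FALSE]
    reps <- reps[keep]
    rownames(D) <- colnames(D) <- seq_len(m - 1)
  }
  # terminal three-taxon star: three-point formulas
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 reps[1], la, reps[2], lb, reps[3], lc)
  tree <- ape::read.tree(text = nwk)
  tree
}

clamp_pair <- function(li, lj) {
  if (li < 0) { lj <- lj + li; li <- 0 }
  if (lj < 0) { li <- li + lj; lj <- 0 }
  c(max(li, 0), max(lj, 0))
}

check_dist <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance input must be a square matrix")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (is.null(rownames(d))) stop("distance matrix needs labels")
  invisible(TRUE)
}

#' UPGMA tree
#'
#' Unweighted pair group method with arithmetic mean: repeatedly merges the
#' closest cluster pair (ties broken by the lowest-index pair in current
#' cluster order), places the merge node at half the inter-cluster average
#' distance, and averages distances weighted by cluster size. The result is
#' ultrametric.
#'
#' @param d symmetric numeric distance matrix with labels.
#' @return rooted ultrametric `ape::phylo`.
#' @export
upgmaTree <- function(d) {
  check_dist(d)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 taxa")
  reps <- rownames(d)
  sizes <- rep(1, n)
  heights <- rep(0, n)
  D <- d
  while (nrow(D) > 1) {
    m <- nrow(D)
    W <- D; diag(W) <- Inf
    idx <- which(W == min(W), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    h <- D[i, j] / 2
    new_rep <- sprintf("(%s:%.10g,%s:%.10g)",
                       reps[i], h - heights[i], reps[j], h - heights[j])
    du <- (sizes[i] * D[i, ] + sizes[j] * D[j, ]) / (sizes[i] + sizes[j])
    # merged cluster takes slot i; slot j is removed
    D[i, ] <- D[, i] <- du
    D[i, i] <- 0
    reps[i] <- new_rep
    sizes[i] <- sizes[i] + sizes[j]
    heights[i] <- h
    keep <- setdiff(seq_len(m), j)
    D <- D[keep, keep, drop = FALSE]
    reps <- reps[keep]
    sizes <- sizes[keep]
    heights <- heights[keep]
    rownames(D) <- colnames(D) <- seq_len(m - 1)
  }
  ape::read.tree(text = paste0(reps[1], ";"))
}

#' Jaccard distance matrix from genome composition
#'
#' 1 - |intersection| / |union| of family sets per strain pair. Two strains
#' with no families at all get distance 0 by convention (with a message).
#'
#' @param pa a [PresenceAbsenceMatrix-class] or logical matrix.
#' @return symmetric distance matrix in [0, 1].
#' @export
jaccardDistanceMatrix <- function(pa) {
  pam <- if (is(pa, "PresenceAbsenceMatrix")) paMatrix(pa) else pa
  if (nrow(pam) < 2) stop("need at least 2 strains")
  storage.mode(pam) <- "double"
  inter <- tcrossprod(pam)
  sizes <- diag(inter)
  uni <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / uni
  if (any(uni == 0)) {
    d[uni == 0] <- 0
    message("strain pairs with empty union assigned Jaccard distance 0")
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(pam), rownames(pam))
  d
}

# ---- bipartitions ----

# Non-trivial splits of an unrooted tree, canonicalised so a split never
# contains the first tip of the reference label ordering. Returns a character
# vector of sorted comma-joined tip sets.
tree_splits <- function(tree, ref_labels = sort(tree$tip.label)) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  parts <- ape::prop.part(tree)
  out <- character()
  for (p in parts) {
    tips <- tree$tip.label[p]
    if (length(tips) <= 1L || length(tips) >= ntip - 1L) next
    if (ref_labels[1] %in% tips) tips <- setdiff(ref_labels, tips)
    out <- c(out, paste(sort(tips), collapse = ","))
  }
  unique(out)
}

#' Robinson-Foulds distance between two trees
#'
#' Number of non-trivial bipartitions present in exactly one of the two
#' unrooted trees (unweighted RF). Bounded by 2(n - 3) for n tips.
#'
#' @param t1,t2 `ape::phylo` trees over the same tip set.
#' @return integer RF distance.
#' @export
rfDistance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees must share the same tip set")
  ref <- sort(t1$tip.label)
  s1 <- tree_splits(t1, ref)
  s2 <- tree_splits(t2, ref)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' Bootstrap supports for a distance-method tree
#'
#' Resamples data columns (alignment sites or family columns) with
#' replacement, rebuilds the tree per replicate, and annotates each internal
#' edge of the point-estimate tree with the percentage of replicate trees
#' containing its bipartition. Supports are stored as internal node labels.
#'
#' @param data character alignment matrix (for `distance = "jc"`) or a
#'   [PresenceAbsenceMatrix-class]/logical matrix (for `distance =
#'   "jaccard"`).
#' @param method tree method: "nj" or "upgma".
#' @param distance distance backbone: "jc" or "jaccard".
#' @param n_reps bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @return the point-estimate `ape::phylo` with `node.label` holding integer
#'   percent supports ("" for the root).
#' @export
bootstrapSupport <- function(data, method = c("nj", "upgma"),
                             distance = c("jc", "jaccard"),
                             n_reps = 100, seed = NULL) {
  method <- match.arg(method)
  distance <- match.arg(distance)
  if (n_reps < 1) stop("n_reps must be >= 1")
  dat <- if (is(data, "PresenceAbsenceMatrix")) paMatrix(data) else data
  dist_fun <- switch(distance,
    jc = function(m) suppressWarnings(jcDistanceMatrix(m)),
    jaccard = function(m) suppressMessages(jaccardDistanceMatrix(m)))
  build <- switch(method, nj = njTree, upgma = upgmaTree)
  point <- build(dist_fun(dat))
  ref <- sort(point$tip.label)
  target <- tree_splits(point, ref)
  hits <- setNames(numeric(length(target)), target)
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      cols <- sample.int(ncol(dat), replace = TRUE)
      rep_tree <- build(dist_fun(dat[, cols, drop = FALSE]))
      rep_splits <- tree_splits(rep_tree, ref)
      hits[target %in% rep_splits] <- hits[target %in% rep_splits] + 1
    }
  })
  support <- round(100 * hits / n_reps)
  annotate_supports(point, support, ref)
}

# Attach per-split supports as internal node labels of `tree`.
annotate_supports <- function(tree, support, ref) {
  ntip <- length(tree$tip.label)
  labs <- rep("", tree$Nnode)
  for (node in (ntip + 1L):(ntip + tree$Nnode)) {
    tips <- tree$tip.label[unlist(ape::prop.part(tree)[node - ntip])]
    if (length(tips) <= 1L || length(tips) >= ntip - 1L) next
    key <- if (ref[1] %in% tips) paste(sort(setdiff(ref, tips)), collapse = ",")
           else paste(sort(tips), collapse = ",")
    if (key %in% names(support)) labs[node - ntip] <- as.character(support[[key]])
  }
  tree$node.label <- labs
  tree
}

#' Scaled patristic divergence matrix
#'
#' Patristic (path-length) distances between tips, divided by the maximum
#' off-diagonal entry so divergence runs from 0 (no distance) to exactly 1
#' (the longest distance). An all-zero tree yields an all-zero matrix with a
#' warning.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @return symmetric matrix in [0, 1] with zero diagonal.
#' @export
scaledPatristic <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  mx <- max(d)
  if (mx == 0) {
    warning("all branch lengths zero; divergence matrix is all zero")
    return(d)
  }
  d <- d / mx
  d[sort(rownames(d)), sort(rownames(d))]
}
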
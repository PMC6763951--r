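test_that("JC distances: formula, saturation cap, and dist.dna agreement", {
  a <- strrep("A", 100)
  m <- rbind(x = strsplit(a, "")[[1]], y = strsplit(a, "")[[1]])
  expect_equal(jcDistanceMatrix(m)["x", "y"], 0)

  # p = 0.0375: d = -(3/4) ln(1 - 0.05)
  s1 <- rand_dna(1, 400, seed = 71)
  s2 <- mutate_at(s1, seq(10, 390, length.out = 15))
  d <- jcDistanceMatrix(c(x = s1, y = s2))["x", "y"]
  expect_equal(d, -0.75 * log(1 - 4 * 0.0375 / 3), tolerance = 1e-12)
  expect_equal(d, 0.03846, tolerance = 1e-3)

  # saturation: p >= 0.75 is capped with a warning
  s3 <- paste0(strrep("A", 100))
  s4 <- paste0(strrep("C", 100))
  expect_warning(ds <- jcDistanceMatrix(c(x = s3, y = s4)), "capped")
  expect_equal(ds["x", "y"], 5)

  # oracle: ape::dist.dna(model = "JC69") on a random gapless alignment
  tr <- simulateSpeciesTree(6, seed = 72)
  aln <- evolveAlignment(tr, 2000, 1, seed = 73)
  mine <- jcDistanceMatrix(aln)
  bin <- ape::as.DNAbin(apply(aln, c(1, 2), tolower))
  ref <- as.matrix(ape::dist.dna(bin, model = "JC69"))
  expect_equal(mine[rownames(ref), colnames(ref)], ref, tolerance = 1e-10)
})

test_that("NJ: worked additive example with exact branch lengths", {
  D <- matrix(c(0, 2, 6, 6,
                2, 0, 6, 6,
                6, 6, 0, 2,
                6, 6, 2, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- njTree(D)
  # generating split AB|CD with leaf edges 1,1,1,1 and internal edge 4
  expect_equal(rfDistance(tr, ape::read.tree(text = "((A:1,B:1):4,C:1,D:1);")),
               0)
  co <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(co, D, tolerance = 1e-10)
  expect_equal(sort(tr$edge.length), c(1, 1, 1, 1, 4), tolerance = 1e-10)
  expect_error(njTree(D[1:2, 1:2]), "3 taxa")
  Dn <- D; Dn[1, 2] <- 3
  expect_error(njTree(Dn), "symmetric")
})

test_that("NJ reproduces generating topologies from additive distances", {
  set.seed(74)
  for (i in 1:25) {
    tr <- ape::rtree(7)
    d <- ape::cophenetic.phylo(tr)
    expect_equal(rfDistance(njTree(d), tr), 0)
    # cross-check against the reference NJ implementation
    expect_equal(rfDistance(njTree(d), ape::nj(as.dist(d))), 0)
  }
})

test_that("UPGMA: worked example, tie-break contract, ultrametricity", {
  D <- matrix(c(0, 2, 4, 4,
                2, 0, 4, 4,
                4, 4, 0, 2,
                4, 4, 2, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- upgmaTree(D)
  expect_equal(rfDistance(tr, ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")),
               0)
  depths <- ape::node.depth.edgelength(tr)[1:4]
  expect_equal(depths, rep(2, 4), tolerance = 1e-10)   # root height 2

  # all-equal distances: lowest-index merges give a caterpillar over labels
  De <- matrix(3, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(De) <- 0
  nwk <- ape::write.tree(upgmaTree(De))
  expect_equal(nwk, "(((A:1.5,B:1.5):0,C:1.5):0,D:1.5);")

  # ultrametric on random matrices
  set.seed(75)
  for (i in 1:10) {
    n <- 6
    d <- matrix(0, n, n); d[upper.tri(d)] <- runif(15, 1, 10); d <- d + t(d)
    dimnames(d) <- list(letters[1:n], letters[1:n])
    expect_true(ape::is.ultrametric(upgmaTree(d), tol = 1e-8))
  }
})

test_that("UPGMA agrees with average-linkage hclust on random instances", {
  set.seed(76)
  for (i in 1:200) {
    n <- 5
    d <- matrix(0, n, n); d[upper.tri(d)] <- runif(10, 1, 10); d <- d + t(d)
    dimnames(d) <- list(letters[1:n], letters[1:n])
    co1 <- ape::cophenetic.phylo(upgmaTree(d))[letters[1:n], letters[1:n]]
    co2 <- as.matrix(cophenetic(hclust(as.dist(d), method = "average")))
    expect_equal(co1, co2[letters[1:n], letters[1:n]], tolerance = 1e-8)
  }
})

test_that("Jaccard distances: set arithmetic and vegan oracle", {
  pa <- pa_from_sets(list(A = c("1", "2", "3"), B = c("2", "3", "4")))
  expect_equal(jaccardDistanceMatrix(pa)["A", "B"], 0.5)
  pa2 <- pa_from_sets(list(A = c("1", "2"), B = c("1", "2")))
  expect_equal(jaccardDistanceMatrix(pa2)["A", "B"], 0)
  pa3 <- pa_from_sets(list(A = c("1", "2"), B = c("3", "4")))
  expect_equal(jaccardDistanceMatrix(pa3)["A", "B"], 1)

  set.seed(77)
  m <- matrix(runif(8 * 30) < 0.5, 8, 30,
              dimnames = list(paste0("s", 1:8), paste0("f", 1:30)))
  m[, colSums(m) > 0, drop = FALSE] -> m
  mine <- jaccardDistanceMatrix(m)
  ref <- as.matrix(vegan::vegdist(m * 1, method = "jaccard", binary = TRUE))
  expect_equal(mine[rownames(ref), colnames(ref)], ref, tolerance = 1e-10)
  # metric axioms: triangle inequality on the tested instance
  n <- nrow(mine)
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_lte(mine[i, j], mine[i, k] + mine[k, j] + 1e-12)
})

test_that("bootstrap supports: congruent data give 100, seeds reproduce", {
  # every column supports AB|CD
  block <- function(ch, n) matrix(ch, 2, n)
  aln <- rbind(A = rep(c("A", "C"), 25), B = rep(c("A", "C"), 25),
               C = rep(c("T", "G"), 25), D = rep(c("T", "G"), 25))
  tr <- bootstrapSupport(aln, method = "nj", distance = "jc", n_reps = 50,
                         seed = 78)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))

  # n_reps = 1: supports are 0 or 100 only
  tr1 <- bootstrapSupport(aln, method = "nj", distance = "jc", n_reps = 1,
                          seed = 79)
  sup1 <- suppressWarnings(as.numeric(tr1$node.label))
  expect_true(all(sup1[!is.na(sup1)] %in% c(0, 100)))

  # determinism on presence/absence bootstrap
  set.seed(80)
  m <- matrix(runif(6 * 40) < 0.5, 6, 40,
              dimnames = list(paste0("s", 1:6), paste0("f", 1:40)))
  b1 <- bootstrapSupport(m, "upgma", "jaccard", n_reps = 20, seed = 81)
  b2 <- bootstrapSupport(m, "upgma", "jaccard", n_reps = 20, seed = 81)
  expect_identical(ape::write.tree(b1), ape::write.tree(b2))
})

test_that("scaled patristic divergence: arithmetic and invariances", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  d <- scaledPatristic(tr)
  expect_equal(d["A", "B"], 0.5)
  expect_equal(d["A", "C"], 1)
  expect_equal(d["B", "C"], 1)
  expect_equal(max(d), 1)
  # rescaling every branch length leaves the scaled matrix unchanged
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 7.3
  expect_equal(scaledPatristic(tr2), d)
  tr0 <- tr; tr0$edge.length <- rep(0, length(tr0$edge.length))
  expect_warning(d0 <- scaledPatristic(tr0), "zero")
  expect_true(all(d0 == 0))
})

test_that("Robinson-Foulds: enumerated cases, bound, phangorn oracle", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(rfDistance(t1, t1), 0)
  expect_equal(rfDistance(t1, t2), 2)
  expect_error(rfDistance(t1, ape::read.tree(text = "((A,B),(C,E));")),
               "tip set")
  set.seed(82)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    a <- ape::rtree(n); b <- ape::rtree(n)
    b$tip.label <- sample(a$tip.label)
    rf <- rfDistance(a, b)
    expect_lte(rf, 2 * (n - 3))
    expect_equal(rf, as.integer(phangorn::RF.dist(a, b)))
  }
})
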
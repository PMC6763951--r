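test_that("species tree simulation: construction, determinism, validation", {
  tr <- simulateSpeciesTree(5, seed = 11)
  expect_s3_class(tr, "phylo")
  expect_length(tr$tip.label, 5)
  expect_true(all(tr$edge.length > 0))
  expect_equal(max(ape::node.depth.edgelength(tr)), 0.3, tolerance = 1e-12)

  expect_identical(ape::write.tree(simulateSpeciesTree(7, seed = 3)),
                   ape::write.tree(simulateSpeciesTree(7, seed = 3)))
  expect_error(simulateSpeciesTree(2), "n_taxa")

  # 3 taxa: a single unrooted topology exists
  tr3 <- simulateSpeciesTree(3, seed = 1)
  expect_equal(ape::unroot(tr3)$Nnode, 1L)
})

test_that("JC alignment evolution matches the closed-form identity", {
  # two tips at known JC distance d = 0.3
  tr <- ape::read.tree(text = "(A:0.15,B:0.15,C:0.0001);")
  len <- 10000
  aln <- evolveAlignment(tr, len, rate_multiplier = 1, seed = 42)
  p_ident <- mean(aln["A", ] == aln["B", ])
  d <- 0.3
  expected <- 1 / 4 + 3 / 4 * exp(-4 * d / 3)
  se <- sqrt(expected * (1 - expected) / len)
  expect_lt(abs(p_ident - expected), 3 * se)

  # zero rate: tips identical to each other (and to the shared root)
  aln0 <- evolveAlignment(tr, 200, rate_multiplier = 0, seed = 1)
  expect_true(all(aln0["A", ] == aln0["B", ]))
  expect_true(all(aln0["A", ] == aln0["C", ]))

  # determinism
  expect_identical(evolveAlignment(tr, 500, 1, seed = 7),
                   evolveAlignment(tr, 500, 1, seed = 7))
  expect_error(evolveAlignment(tr, 0, 1), "length")
})

test_that("gene content: zero rates give root content, core is universal", {
  tr <- simulateSpeciesTree(6, seed = 2)
  pa0 <- evolveGeneContent(tr, core_size = 20, accessory_pool = 100,
                           gain_rate = 0, loss_rate = 0, seed = 1)
  m <- paMatrix(pa0)
  expect_equal(ncol(m), 20)      # nothing beyond the root's core content
  expect_true(all(m))

  pa <- evolveGeneContent(tr, core_size = 20, accessory_pool = 200,
                          gain_rate = 40, loss_rate = 5, seed = 3)
  prev <- colMeans(paMatrix(pa))
  core_cols <- grepl("^core", familyNames(pa))
  expect_true(all(prev[core_cols] == 1))
  expect_equal(sum(core_cols), 20)
})

test_that("fast accessory turnover makes most accessory families rare", {
  tr <- simulateSpeciesTree(16, seed = 5)
  # high gain and high loss: families flicker in and out -> rare
  pa <- evolveGeneContent(tr, core_size = 10, accessory_pool = 5000,
                          gain_rate = 400, loss_rate = 40, seed = 8)
  prev <- colMeans(paMatrix(pa))
  acc <- prev[grepl("^acc", familyNames(pa))]
  expect_gt(length(acc), 100)
  expect_gt(mean(acc < 0.1), 0.5)
})

test_that("with no loss, accessory presence is clade-monophyletic", {
  tr <- simulateSpeciesTree(8, seed = 4)
  pa <- evolveGeneContent(tr, core_size = 5, accessory_pool = 200,
                          gain_rate = 60, loss_rate = 0, seed = 9)
  m <- paMatrix(pa)
  acc <- familyNames(pa)[grepl("^acc", familyNames(pa))]
  expect_gt(length(acc), 5)
  for (f in acc) {
    carriers <- rownames(m)[m[, f]]
    if (length(carriers) %in% c(1L, nrow(m))) next
    expect_true(ape::is.monophyletic(tr, carriers))
  }
})

test_that("BM traits have the tree's covariance structure", {
  # variance of tip difference on a star tree of depth t is 2 sigma2 t
  tr <- star_tree(4, depth = 0.8)
  sim <- simulateTraits(tr, n_bm = 2000, sigma2 = 1.5, seed = 21)
  x <- matrixValues(sim)
  v <- var(x["t01", ] - x["t02", ])
  expect_lt(abs(v - 2 * 1.5 * 0.8) / (2 * 1.5 * 0.8), 0.1)

  # sister tips with a long shared stem: correlation ~ shared/total depth
  tr2 <- ape::read.tree(text = "((A:1,B:1):4,C:5);")
  sim2 <- simulateTraits(tr2, n_bm = 4000, sigma2 = 1, seed = 22)
  x2 <- matrixValues(sim2)
  expect_lt(abs(cor(x2["A", ], x2["B", ]) - 4 / 5), 0.05)

  # white-noise traits carry no tree signal
  tr3 <- simulateSpeciesTree(12, seed = 6)
  sim3 <- simulateTraits(tr3, n_bm = 0, n_noise = 500, seed = 23)
  x3 <- matrixValues(sim3)
  pd <- ape::cophenetic.phylo(tr3)[rownames(x3), rownames(x3)]
  cors <- apply(x3, 2, function(tr_col) {
    td <- as.vector(pd[upper.tri(pd)])
    dd <- as.vector(abs(outer(tr_col, tr_col, "-"))[upper.tri(pd)])
    cor(td, dd)
  })
  expect_lt(abs(mean(cors)), 0.05)

  expect_identical(matrixValues(simulateTraits(tr3, 3, 2, seed = 1)),
                   matrixValues(simulateTraits(tr3, 3, 2, seed = 1)))
})

test_that("LC-MS table: replicate structure, controls and dropout", {
  tr <- star_tree(4)
  traits <- simulateTraits(tr, n_bm = 6, seed = 31)

  tab0 <- simulateLcms(traits, n_replicates = 5, missing_rate = 0,
                       seed = 32)
  smp <- tab0[!tab0$is_control, ]
  expect_equal(nrow(smp), 4 * 5 * 2 * 6)   # strains x reps x modes x mets
  counts <- table(smp$strain, smp$metabolite, smp$ion_mode)
  expect_true(all(counts == 5))
  expect_true(all(tab0$abundance >= 0))
  expect_setequal(unique(tab0$strain[tab0$is_control]), "media")

  tab <- simulateLcms(traits, n_replicates = 5, missing_rate = 0.4,
                      seed = 33)
  n_expected <- 4 * 5 * 2 * 6
  dropout <- 1 - nrow(tab[!tab$is_control, ]) / n_expected
  se <- sqrt(0.4 * 0.6 / n_expected)
  expect_lt(abs(dropout - 0.4), 3 * se)
  expect_error(simulateLcms(traits, missing_rate = 1), "missing_rate")
})

test_that("feature assignment: tied features inherit family patterns", {
  tr <- simulateSpeciesTree(10, seed = 7)
  pa <- evolveGeneContent(tr, core_size = 10, accessory_pool = 100,
                          gain_rate = 50, loss_rate = 5, seed = 10)
  fa <- assignFeatureFamilies(pa, "gcf", 15, seed = 12)
  sets <- featureSets(fa)
  src <- sub("^.*@", "", unique(unlist(sets)))
  m <- paMatrix(pa)
  # feature Jaccard between two strains equals family Jaccard restricted to
  # the tied families (brute-force set comparison)
  tied <- unique(sub("^.*@", "", unlist(featureSets(fa))))
  for (pair in list(c(1, 2), c(3, 7), c(5, 10))) {
    a <- strainNames(pa)[pair[1]]; b <- strainNames(pa)[pair[2]]
    fj <- length(intersect(sets[[a]], sets[[b]])) /
      max(1, length(union(sets[[a]], sets[[b]])))
    fams_a <- familyNames(pa)[m[a, ]]; fams_b <- familyNames(pa)[m[b, ]]
    # restrict to tied families, weighting by how many features tie to each
    feat <- unique(unlist(sets))
    fam_of_feat <- sub("^.*@", "", feat)
    in_a <- fam_of_feat %in% fams_a; in_b <- fam_of_feat %in% fams_b
    gj <- sum(in_a & in_b) / max(1, sum(in_a | in_b))
    expect_equal(fj, gj)
  }
  expect_error(assignFeatureFamilies(pa, "plasmid", 3), "category")

  # independent draws at prevalence 0 put the feature in no strain
  fa0 <- assignFeatureFamilies(pa, "cazy", 4,
                               prevalence_distribution = 0, seed = 13)
  expect_equal(length(unlist(featureSets(fa0))), 0L)
  # prevalence 1: in every strain
  fa1 <- assignFeatureFamilies(pa, "cazy", 2,
                               prevalence_distribution = 1, seed = 14)
  expect_true(all(lengths(featureSets(fa1)) == 2L))
})
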
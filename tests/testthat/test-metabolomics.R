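test_that("replicate-presence filter and ion-mode merging", {
  # met1: detected in 3 of 5 replicates (pos sum 40, neg sum 90 -> 90)
  # met2: detected in 2 of 5 -> dropped
  rows <- list(const_ctrl(c("met1", "met2")))
  for (r in 1:3) {
    rows <- c(rows, list(lcms_row("s1", r, "pos", "met1", 40 / 3),
                         lcms_row("s1", r, "neg", "met1", 30)))
  }
  for (r in 1:2) rows <- c(rows, list(lcms_row("s1", r, "pos", "met2", 500)))
  # second strain so the matrix has content beyond s1
  for (r in 1:5) rows <- c(rows, list(lcms_row("s2", r, "pos", "met1", 20),
                                      lcms_row("s2", r, "pos", "met2", 20)))
  tab <- do.call(rbind, rows)
  tm <- buildTraitMatrix(tab, min_replicates = 3, total_replicates = 5)
  x <- matrixValues(tm)
  expect_equal(x["s1", "met1"], 90)       # the larger ion-mode sum
  expect_true(is.na(x["s1", "met2"]))     # 2 of 5 fails the rule
  expect_equal(x["s2", "met1"], 100)
  expect_equal(traitStage(tm), "raw")
  expect_error(buildTraitMatrix(tab, min_replicates = 6,
                                total_replicates = 5), "min_replicates")
})

test_that("detection is relative to the media-control baseline", {
  # control mean 100 (sd 0): only abundances above 100 count as detected
  rows <- list(const_ctrl("met1", level = 100, reps = 3))
  for (r in 1:5) rows <- c(rows, list(lcms_row("s1", r, "pos", "met1", 99)))
  for (r in 1:5) rows <- c(rows, list(lcms_row("s2", r, "pos", "met1", 101)))
  tab <- do.call(rbind, rows)
  x <- matrixValues(buildTraitMatrix(tab))
  expect_true(is.na(x["s1", "met1"]))
  expect_equal(x["s2", "met1"], 505)
})

test_that("missing-column removal and half-minimum imputation", {
  m <- matrix(NA_real_, 10, 2,
              dimnames = list(paste0("s", 1:10), c("gone", "kept")))
  m[1:4, "gone"] <- 5          # 6 of 10 missing -> removed at 0.5
  m[1:8, "kept"] <- c(2, 3:9)  # 2 of 10 missing; matrix minimum positive = 2
  tm <- TraitMatrix(m, stage = "raw")
  out <- imputeAndFilterMissing(tm, 0.5)
  x <- matrixValues(out)
  expect_equal(colnames(x), "kept")
  expect_equal(unname(x[9:10, "kept"]), c(1, 1))  # half of the minimum
  expect_equal(traitStage(out), "imputed")

  # no missing values: identity transformation
  full <- TraitMatrix(matrix(1:6 + 0, 3, 2,
                             dimnames = list(letters[1:3], c("a", "b"))),
                      stage = "raw")
  expect_equal(matrixValues(imputeAndFilterMissing(full)),
               matrixValues(full))
  allna <- TraitMatrix(matrix(NA_real_, 3, 1,
                              dimnames = list(letters[1:3], "x")),
                       stage = "raw")
  expect_error(imputeAndFilterMissing(allna), "threshold")
})

test_that("glog formula and autoscaling invariants", {
  expect_equal(glog(0, 1), -1)
  # lambda -> 0 recovers log2 for positive x
  expect_equal(glog(8, 1e-12), log2(8), tolerance = 1e-9)
  expect_error(glog(1, 0), "lambda")

  set.seed(95)
  m <- matrix(rexp(60), 10, 6,
              dimnames = list(paste0("s", 1:10), paste0("m", 1:6)))
  tm <- TraitMatrix(m, stage = "imputed")
  out <- glogAutoscale(tm)
  x <- matrixValues(out)
  expect_equal(unname(colMeans(x)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(x, 2, sd)), rep(1, 6), tolerance = 1e-12)
  expect_equal(traitStage(out), "autoscaled")
  # stage tags enforce the pipeline order
  expect_error(glogAutoscale(out), "imputed-stage")
  expect_error(imputeAndFilterMissing(out), "raw-stage")
  # zero-variance columns are dropped with a warning
  m2 <- cbind(m, flat = rep(2, 10))
  expect_warning(out2 <- glogAutoscale(TraitMatrix(m2, stage = "imputed")),
                 "flat")
  expect_false("flat" %in% colnames(matrixValues(out2)))
})

test_that("ANOVA with BH correction: worked q-values and degenerate cases", {
  # Benjamini-Hochberg on p = (0.01, 0.02, 0.04) gives q = (0.03, 0.03, 0.04)
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), method = "BH"),
               c(0.03, 0.03, 0.04))

  set.seed(96)
  g <- rep(c("a", "b", "c"), each = 4)
  rows <- paste0(g, ":", rep(1:4, 3))
  m <- cbind(diff = c(rnorm(4, 0), rnorm(4, 3), rnorm(4, 6)),
             null = rnorm(12),
             flat = rep(1, 12))
  rownames(m) <- rows
  tm <- TraitMatrix(m, stage = "raw")
  expect_warning(res <- anovaFdr(tm, groups = g, alpha = 0.05), "flat")
  expect_setequal(res$metabolite, c("diff", "null"))
  expect_true(res$significant[res$metabolite == "diff"])
  expect_equal(res$q, p.adjust(res$p, method = "BH"))
  # oracle: F and p match stats::oneway.test with equal variances
  ref <- stats::oneway.test(m[, "diff"] ~ g, var.equal = TRUE)
  expect_equal(res$F[res$metabolite == "diff"], unname(ref$statistic))
  expect_equal(res$p[res$metabolite == "diff"], unname(ref$p.value))
  expect_error(anovaFdr(tm, groups = rep("a", 12)), "2 groups")
})

test_that("ANOVA controls the FDR under the null and gains power with effect", {
  set.seed(97)
  g <- rep(paste0("s", 1:4), each = 5)
  false_rates <- replicate(40, {
    m <- matrix(rnorm(20 * 20), 20,
                dimnames = list(paste0(g, ":", 1:20), paste0("m", 1:20)))
    res <- anovaFdr(TraitMatrix(m, stage = "raw"), groups = g)
    mean(res$significant)
  })
  expect_lte(mean(false_rates), 0.05 + 0.02)

  power <- vapply(c(0, 1, 3), function(eff) {
    hits <- replicate(20, {
      m <- matrix(rnorm(20 * 5) + eff * as.integer(factor(g)) / 4, 20, 5,
                  dimnames = list(paste0(g, ":", 1:20), paste0("m", 1:5)))
      mean(anovaFdr(TraitMatrix(m, stage = "raw"), groups = g)$significant)
    })
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(power) >= 0))
  expect_gt(power[3], power[1])
})

test_that("score normalization: column max becomes exactly 1", {
  m <- cbind(a = c(2, 4, 8), b = c(0.2, 1, 0.5), zero = c(0, 0, 0))
  rownames(m) <- paste0("s", 1:3)
  expect_warning(out <- normalizeScores(m), "zero")
  x <- matrixValues(out)
  expect_equal(unname(x[, "a"]), c(0.25, 0.5, 1))
  expect_equal(unname(x[, "b"]), c(0.2, 1, 0.5))   # already max-1: unchanged
  expect_false("zero" %in% colnames(x))
  expect_equal(traitStage(out), "normalized_score")
  # ordering within a column is preserved
  expect_equal(order(x[, "a"]), order(m[, "a"]))
})

test_that("Ward clustering order: planted blocks stay contiguous", {
  set.seed(98)
  m <- rbind(matrix(rnorm(5 * 6, 0), 5, 6),
             matrix(rnorm(5 * 6, 10), 5, 6))
  rownames(m) <- paste0("s", 1:10); colnames(m) <- paste0("f", 1:6)
  ord <- wardClusterOrder(m)
  pos <- match(paste0("s", 1:10), ord$row_order)
  expect_true(max(pos[1:5]) < min(pos[6:10]) ||
                min(pos[1:5]) > max(pos[6:10]))
  expect_setequal(ord$row_order, rownames(m))   # a permutation of the rows
  expect_setequal(ord$col_order, colnames(m))
  # duplicate rows merge first, at height 0
  m2 <- m; m2[2, ] <- m2[1, ]
  h <- wardClusterOrder(m2)$row_hclust
  expect_equal(h$height[1], 0)
  expect_setequal(abs(h$merge[1, ]), c(1, 2))
})
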
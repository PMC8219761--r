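test_that("default bucketing yields 491 bins, 455 after water removal, on any covering spectrum", {
  sp <- flatSpectrumSet(level = 3)
  b <- bucketSpectra(sp)
  expect_equal(ncol(binValues(b)), 491L)
  # flat intensity c integrates to c * width in every bin
  expect_true(all(abs(binValues(b) - 3 * 0.02) < 1e-9))
  bw <- removeWater(b)
  expect_equal(ncol(binValues(bw)), 455L)
  expect_true(all(binEdges(bw)[, "left"] < 4.40 - 1e-9 |
                    binEdges(bw)[, "left"] > 5.10 + 1e-9))

  # a generated spectrum gives the same counts
  sc <- generateCohort(generatorSpec(nPairs = 2, seed = 13))
  for (exp_type in c("noesy", "cpmg", "diffusion")) {
    bb <- removeWater(bucketSpectra(spectrumSets(sc)[[exp_type]]))
    expect_equal(ncol(binValues(bb)), 455L)
  }

  # coverage and parameter errors
  short <- flatSpectrumSet(ppm = seq(8, 0.5, by = -0.01))
  expect_error(bucketSpectra(short), "coverage error")
  expect_error(bucketSpectra(sp, width = 0), "width")
  expect_error(removeWater(b, low = 6, high = 5), "parameter error")
  # water window outside the spectral range leaves the matrix unchanged
  expect_equal(ncol(binValues(removeWater(b, low = 11, high = 12))), 491L)
  expect_error(removeWater(b, low = 0, high = 11), "no bins left")
})

test_that("total-integral normalization is dilution-invariant", {
  sp <- flatSpectrumSet(level = 1, nSubjects = 3)
  sp@intensity[2, ] <- sp@intensity[2, ] * 10      # global scaling
  sp@intensity[3, ] <- runif(length(sp@ppm))
  bn <- normalizeTotalIntegral(removeWater(bucketSpectra(sp)))
  expect_true(all(abs(rowSums(binValues(bn)) - 1) < 1e-9))
  # proportional spectra normalize to identical rows
  expect_equal(binValues(bn)[1, ], binValues(bn)[2, ], tolerance = 1e-9)
  # zero-sum row is rejected
  sp@intensity[1, ] <- 0
  expect_error(normalizeTotalIntegral(removeWater(bucketSpectra(sp))),
               "value error")
  # normalization is refused before water removal
  expect_error(removeWater(normalizeTotalIntegral(removeWater(
    bucketSpectra(flatSpectrumSet())))), "before normalization")
})

test_that("PCA screening explains rank-1 structure and flags injected artifacts", {
  # rank-1 matrix: one component carries all variance
  set.seed(3)
  X <- outer(runif(20, 0.5, 2), runif(30))
  res <- pcaScreen(X, nComponents = 2)
  expect_equal(res$explained_variance[1], 1, tolerance = 1e-9)

  # a subject left unnormalized while all others are normalized sticks out
  sc <- generateCohort(generatorSpec(nPairs = 20, seed = 5))
  b <- removeWater(bucketSpectra(spectrumSets(sc)$noesy))
  vals <- binValues(b) / rowSums(binValues(b))
  vals[7, ] <- 50 * binValues(b)[7, ] / sum(binValues(b)[7, ])
  res2 <- pcaScreen(vals, nComponents = 2)
  expect_true(res2$outlier[7])
  expect_equal(unname(which.max(res2$t2)), 7L)

  # an outlier-free normalized cohort flags at most the nominal share
  bn <- normalizeTotalIntegral(b)
  res3 <- pcaScreen(bn, nComponents = 2)
  expect_lte(mean(res3$outlier), 0.075)
  expect_error(pcaScreen(bn, nComponents = 400), "parameter error")
})

test_that("OPLS-DA with no orthogonal components reproduces direct PLS-DA", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(10:24, 1); p <- sample(5:40, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rep(c("low_mbd", "high_mbd"), length.out = n)
    fit <- oplsdaFit(X, y, nOrthogonal = 0)
    Xtest <- matrix(rnorm(5 * p), 5, p)
    mine <- oplsdaPredict(fit, Xtest)
    oracle <- directPlsPredict(X, ifelse(y == "high_mbd", 1, -1), Xtest)
    expect_equal(ifelse(mine$class == "high_mbd", 1, -1), oracle)
  }
})

test_that("OPLS-DA scores satisfy the orthogonality invariants on every fit", {
  set.seed(8)
  for (k in c(1L, 3L, 6L)) {
    X <- matrix(rnorm(40 * 60), 40, 60)
    y <- rep(c("a", "b"), 20)
    fit <- oplsdaFit(X, y, nOrthogonal = k)
    tp <- fit@scoresPred
    for (j in seq_len(k)) {
      to <- fit@scoresOrtho[, j]
      expect_lt(abs(sum(tp * to)),
                1e-8 * sqrt(sum(tp^2)) * sqrt(sum(to^2)))
      expect_lt(abs(sum(fit@weightsPred * fit@weightsOrtho[, j])), 1e-8)
    }
    # flipping the coding negates scores and complements predictions
    fit_flip <- oplsdaFit(X, y, nOrthogonal = k, positiveClass = "a")
    expect_equal(fit_flip@scoresPred, -tp, tolerance = 1e-9)
    pr <- oplsdaPredict(fit, X)$class
    pr_flip <- oplsdaPredict(fit_flip, X)$class
    expect_true(all(pr == pr_flip))   # same labels, opposite coding
  }
  expect_error(oplsdaFit(matrix(rnorm(40), 10, 4), rep("a", 10), 0),
               "label error")
  expect_error(oplsdaFit(matrix(rnorm(40), 10, 4),
                         rep(c("a", "b"), 5), 6), "rank error")
})

test_that("MCCV reaches 1 on separable data, chance on nulls and indistinguishable classes", {
  set.seed(9)
  X <- rbind(matrix(rnorm(200), 20, 10), matrix(rnorm(200, mean = 5), 20, 10))
  y <- rep(c("low_mbd", "high_mbd"), each = 20)
  r <- mccv(X, y, nOrthogonal = 1, nCycles = 50, seed = 3)
  expect_equal(mean(r@accuracy), 1.0)
  expect_equal(mean(r@sensitivity), 1.0)

  # duplicated (near-identical) subjects in both classes carry no genuine
  # class signal: no above-chance discrimination is possible (held-out
  # subjects match a training row of the opposite class, so the classifier
  # can even fall below chance by memorization)
  base <- matrix(rnorm(20 * 12), 20, 12)
  Xd <- rbind(base, base + matrix(rnorm(20 * 12, sd = 1e-6), 20, 12))
  yd <- rep(c("low_mbd", "high_mbd"), each = 20)
  rd <- mccv(Xd, yd, nOrthogonal = 0, nCycles = 50, seed = 4)
  expect_lt(mean(rd@accuracy), 0.6)

  # label-permuted null cohort stays within the chance band
  set.seed(10)
  Xn <- matrix(rnorm(174 * 60), 174, 60)
  yn <- sample(rep(c("low_mbd", "high_mbd"), 87))
  rn <- mccv(Xn, yn, nOrthogonal = 2, nCycles = 100, seed = 5)
  expect_gte(mean(rn@accuracy), 0.40)
  expect_lte(mean(rn@accuracy), 0.60)

  # reproducibility under a fixed seed
  r2 <- mccv(X, y, nOrthogonal = 1, nCycles = 50, seed = 3)
  expect_identical(r2@accuracy, r@accuracy)
})

test_that("permutation test attains its minimum p on separable data", {
  set.seed(11)
  X <- rbind(matrix(rnorm(150), 15, 10), matrix(rnorm(150, 4), 15, 10))
  y <- rep(c("low_mbd", "high_mbd"), each = 15)
  pt <- permutationTest(X, y, nOrthogonal = 0, nCycles = 15,
                        nPermutations = 100, seed = 6)
  expect_equal(pt@permutationP, 1 / 101, tolerance = 1e-12)
  expect_equal(pt@nPermutations, 100L)
  expect_length(pt@nullAccuracy, 100L)
  expect_error(permutationTest(X, y, nPermutations = 0), "parameter error")
})

test_that("MCCV accuracy rises monotonically with the generator effect size", {
  base <- defaultFeatureEffects()
  accs <- sapply(c(0, 0.6, 1.2, 2, 3.2), function(s) {
    mean(sapply(1:3, function(r) {
      spec <- generatorSpec(nPairs = 150, seed = 37 * r + round(100 * s),
                            featureEffects = base * s,
                            covariateModel = list(bmi_label_beta = 0))
      sc <- generateCohort(spec, withSpectra = FALSE)
      prep <- preparePanel(quantPanel(sc))
      mean(mccv(t(standardizedValues(prep)), cohortTable(sc)$group,
                nOrthogonal = 2, nCycles = 40, seed = 7)@accuracy)
    }))
  })
  expect_gt(cor(accs, seq_along(accs), method = "spearman"), 0.9)
})
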
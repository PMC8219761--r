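test_that("generated cohorts have the designed size and are seed-deterministic", {
  spec <- generatorSpec(nPairs = 87, seed = 1)
  sc <- generateCohort(spec, withSpectra = FALSE)
  expect_equal(nrow(cohortTable(sc)), 174L)
  expect_equal(length(unique(cohortTable(sc)$pair_id)), 87L)
  expect_equal(nrow(quantPanel(sc)), 21L + 7L + 95L)
  expect_silent(validateCohort(cohortTable(sc)))

  sc2 <- generateCohort(spec, withSpectra = FALSE)
  expect_identical(cohortTable(sc2), cohortTable(sc))
  expect_identical(concentrations(quantPanel(sc2)),
                   concentrations(quantPanel(sc)))

  # byte-identical CSV exports under the same spec
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  exportSyntheticCohort(sc, d1)
  exportSyntheticCohort(sc2, d2)
  for (f in c("cohort.csv", "quant.csv", "loq.csv", "truth.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))

  # the generator must not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(generateCohort(spec, withSpectra = FALSE))
  expect_identical(rnorm(3), before)
})

test_that("spectral synthesis is linear in concentration with the analytic Lorentzian integral", {
  feats <- data.frame(name = "probe", family = "metabolite",
                      compound_id = "probe", logMean = 0, logSd = 0.3,
                      bmiLoading = 0)
  lib <- list(probe = list(list(center = 3.0, halfWidth = 0.01,
                                amplitude = 0.8)))
  spec <- generatorSpec(nPairs = 2, seed = 7, featureEffects = c(probe = 0),
                        censorFraction = c(probe = 0), noiseSd = 0,
                        peakLibrary = lib, features = feats)

  conc <- c(probe = 2.5)
  sp <- synthesizeSpectrum(conc, spec, "noesy")
  binned <- bucketSpectra(sp)
  inside <- binEdges(binned)[, "left"] >= 2.8 & binEdges(binned)[, "right"] <= 3.2
  got <- sum(binValues(binned)[1, inside])
  # closed form: A * conc * [atan((r-c)/hw) - atan((l-c)/hw)]
  oracle <- 0.8 * 2.5 * (atan(0.2 / 0.01) - atan(-0.2 / 0.01))
  expect_equal(got, oracle, tolerance = 0.01)

  # doubling the concentration doubles the noise-free integral
  sp2 <- synthesizeSpectrum(c(probe = 5.0), spec, "noesy")
  expect_equal(sum(bucketSpectra(sp2)@values[1, inside]), 2 * got,
               tolerance = 1e-9)

  # zero concentrations: only the water hump, confined to 4.40-5.12 ppm
  sp0 <- synthesizeSpectrum(c(probe = 0), spec, "noesy")
  b0 <- bucketSpectra(sp0)
  outside <- binEdges(b0)[, "right"] <= 4.40 | binEdges(b0)[, "left"] >= 5.12
  expect_true(all(abs(binValues(b0)[1, outside]) < 1e-12))
  expect_gt(sum(binValues(b0)[1, !outside]), 0)

  # unknown concentration name is a library error
  expect_error(synthesizeSpectrum(c(nonexistent = 1), spec, "noesy"),
               "library error")
})

test_that("experiment filters pass narrow and broad resonances selectively", {
  feats <- data.frame(name = c("narrow", "broad"), family = "metabolite",
                      compound_id = NA, logMean = 0, logSd = 0.3,
                      bmiLoading = 0)
  lib <- list(narrow = list(list(center = 2.0, halfWidth = 0.01,
                                 amplitude = 1)),
              broad = list(list(center = 7.0, halfWidth = 0.08,
                                amplitude = 1)))
  spec <- generatorSpec(nPairs = 2, seed = 1, featureEffects = c(narrow = 0),
                        censorFraction = c(narrow = 0), noiseSd = 0,
                        peakLibrary = lib, features = feats)
  conc <- c(narrow = 1, broad = 1)
  at <- function(sp, ppm) sp@intensity[1, which.min(abs(sp@ppm - ppm))]
  cpmg <- synthesizeSpectrum(conc, spec, "cpmg")
  diff_ed <- synthesizeSpectrum(conc, spec, "diffusion")
  noesy <- synthesizeSpectrum(conc, spec, "noesy")
  # narrow resonances pass CPMG unattenuated (up to the broad peak's
  # far tail), broad ones pass diffusion editing
  expect_lt(abs(at(cpmg, 2.0) - at(noesy, 2.0)), 0.01)
  expect_lt(at(cpmg, 7.0), 0.1 * at(noesy, 7.0))
  expect_lt(abs(at(diff_ed, 7.0) - at(noesy, 7.0)), 0.01)
  expect_lt(at(diff_ed, 2.0), 0.1 * at(noesy, 2.0))
})

test_that("LOQ censoring realizes the target fractions exactly", {
  spec <- generatorSpec(nPairs = 50, seed = 3)   # 100 subjects
  sc <- generateCohort(spec, withSpectra = FALSE)
  panel <- quantPanel(sc)
  spec2 <- generatorSpec(nPairs = 50, seed = 3,
                         censorFraction = c(alanine = 0.25, glucose = 0))
  cens <- applyLoqCensoring(panel, spec2)
  expect_equal(sum(belowLOQ(cens)["alanine", ]), 25L)
  expect_equal(sum(belowLOQ(cens)["glucose", ]), 0L)
  expect_error(
    applyLoqCensoring(panel, generatorSpec(nPairs = 50, seed = 3,
                                           censorFraction = c(alanine = 1))),
    "censor fractions")
})

test_that("null generator centers crude odds ratios on one", {
  # all effects zero, no BMI-label path: the crude conditional-logistic
  # estimate should fluctuate around log-OR 0
  betas <- sapply(1:20, function(r) {
    spec <- nullGeneratorSpec(nPairs = 500, seed = 4000 + r,
                              features = data.frame(
                                name = "f1", family = "metabolite",
                                compound_id = NA, logMean = 0, logSd = 0.3,
                                bmiLoading = 0),
                              featureEffects = c(f1 = 0),
                              censorFraction = c(f1 = 0),
                              peakLibrary = list())
    sc <- generateCohort(spec, withSpectra = FALSE)
    prep <- preparePanel(quantPanel(sc))
    fv <- setNames(standardizedValues(prep)["f1", ],
                   subjectIds(quantPanel(sc)))
    fitConditionalLogit(pairDifferenceDesign(cohortTable(sc), fv))$beta
  })
  expect_lt(mean(abs(betas)), 0.1)
})

test_that("the generator recovers its own conditional-logistic truth", {
  # feature effect log(2), 500 pairs: crude OR estimate in [1.7, 2.35]
  ors <- sapply(1:25, function(r) {
    spec <- generatorSpec(nPairs = 500, seed = 5000 + r,
                          featureEffects = c(tyrosine = log(2)),
                          covariateModel = list(bmi_label_beta = 0))
    sc <- generateCohort(spec, withSpectra = FALSE)
    prep <- preparePanel(quantPanel(sc))
    fv <- setNames(standardizedValues(prep)["tyrosine", ],
                   subjectIds(quantPanel(sc)))
    exp(fitConditionalLogit(pairDifferenceDesign(cohortTable(sc),
                                                 fv))$beta)
  })
  expect_gte(mean(ors >= 1.7 & ors <= 2.35), 0.9)
})
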
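test_that("conditional logit equals the discordant-pair closed form and survival::clogit", {
  # binary exposure: OR = (case-only-exposed) / (control-only-exposed)
  delta <- matrix(c(rep(1, 6), rep(-1, 3), rep(0, 5)), ncol = 1,
                  dimnames = list(NULL, "feature"))
  fit <- fitConditionalLogit(delta)
  expect_equal(exp(fit$beta[["feature"]]), 2.0, tolerance = 1e-6)

  set.seed(17)
  for (i in 1:10) {
    a <- sample(3:12, 1); b <- sample(3:12, 1); conc <- sample(0:6, 1)
    d <- matrix(c(rep(1, a), rep(-1, b), rep(0, conc)), ncol = 1,
                dimnames = list(NULL, "feature"))
    expect_equal(exp(fitConditionalLogit(d)$beta[["feature"]]), a / b,
                 tolerance = 1e-6)
  }

  # continuous multi-covariate fits agree with the survival package
  library(survival)
  for (i in 1:5) {
    n <- 70
    d <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("feature", "z")))
    mine <- fitConditionalLogit(d)
    y <- rep(c(1, 0), n); strat <- rep(seq_len(n), each = 2)
    ref <- survival::clogit(y ~ x1 + x2 + strata(strat),
                            data = data.frame(
                              y = y, strat = strat,
                              x1 = as.vector(rbind(d[, 1], 0)),
                              x2 = as.vector(rbind(d[, 2], 0))))
    expect_equal(unname(mine$beta), unname(coef(ref)), tolerance = 1e-7)
    expect_equal(unname(mine$vcov), unname(vcov(ref)), tolerance = 1e-7)
  }
})

test_that("conditional logit honors symmetry, separation and invariance properties", {
  # symmetric differences force beta = 0
  d <- matrix(c(0.5, -0.5, 1.2, -1.2, 2, -2), ncol = 1,
              dimnames = list(NULL, "feature"))
  expect_equal(fitConditionalLogit(d)$beta[["feature"]], 0,
               tolerance = 1e-8)
  # monotone likelihood is flagged
  sep <- matrix(abs(rnorm(12)) + 0.05, ncol = 1,
                dimnames = list(NULL, "feature"))
  fit <- fitConditionalLogit(sep)
  expect_true(fit$separated)
  expect_false(fit$converged)
  # degenerate inputs
  expect_error(fitConditionalLogit(matrix(0, 5, 1,
                                          dimnames = list(NULL, "feature"))),
               "design error")
  expect_error(fitConditionalLogit(cbind(feature = c(1, -1, 2),
                                         dup = c(2, -2, 4))),
               "rank-deficient")

  # pair conditioning removes pair-constant shifts: adding any constant to
  # both members of a pair leaves the difference design unchanged
  co <- makeTinyCohort()
  fv <- setNames(rnorm(8), co$subject_id)
  shift <- rep(rnorm(4), each = 2)
  fv2 <- fv + shift[match(co$pair_id, unique(co$pair_id))[order(co$subject_id)]]
  d1 <- pairDifferenceDesign(co, fv)
  d2 <- pairDifferenceDesign(co, fv2)
  expect_equal(d1$delta, d2$delta, tolerance = 1e-12)
})

test_that("panel runs report per-feature ORs, drop incomplete pairs and flag degenerates", {
  sc <- generateCohort(generatorSpec(nPairs = 60, seed = 31),
                       withSpectra = FALSE)
  prep <- preparePanel(quantPanel(sc))
  co <- cohortTable(sc)
  crude <- runFeaturePanel(prep, co, model = "crude")
  expect_equal(nrow(crude), nrow(prep))
  expect_equal(sum(crude$family == "metabolite"), 15L)
  expect_true(all(crude$n_pairs_used == 60L))
  expect_true(all(crude$or_ > 0))
  expect_true(all(crude$ci_low <= crude$or_ & crude$or_ <= crude$ci_high))
  expect_true(all(crude$p_fdr >= crude$p_value - 1e-12, na.rm = TRUE))

  # adjusted models drop pairs with a missing covariate (ER)
  adjusted <- runFeaturePanel(prep, co, model = "adjusted")
  n_complete <- sum(sapply(split(co$er_status, co$pair_id),
                           function(v) all(!is.na(v))))
  expect_true(all(adjusted$n_pairs_used == n_complete))
  expect_error(
    runFeaturePanel(prep, co, model = "adjusted",
                    adjustment = "not_a_column"),
    "config error")

  # a feature with all-zero within-pair differences is flagged and
  # excluded from the FDR family
  # equal values within each pair -> zero deltas
  conc <- matrix(rep(exp(rnorm(60)), each = 2), nrow = 1,
                 dimnames = list("flatf", co$subject_id))
  flat <- QuantPanel(conc, data.frame(family = "metabolite", loq = 1e-9,
                                      row.names = "flatf"))
  pf <- logSdScale(flat)
  res <- runFeaturePanel(pf, co, model = "crude")
  expect_true(res$degenerate)
  expect_equal(res$or_, 1)
  expect_equal(res$ci_high, Inf)
  expect_true(is.na(res$p_fdr))
})

test_that("BMI confounding inflates crude but not adjusted lipid associations", {
  # generator with no direct lipid effect: the crude VLDL association is
  # driven by the BMI path and shrinks once BMI class is adjusted for
  smaller <- sapply(1:15, function(r) {
    spec <- generatorSpec(nPairs = 87, seed = 3000 + r,
                          featureEffects = c(alanine = 0))
    sc <- generateCohort(spec, withSpectra = FALSE)
    prep <- preparePanel(quantPanel(sc))
    co <- cohortTable(sc)
    fv <- setNames(standardizedValues(prep)["vldl1_triglycerides", ],
                   colnames(standardizedValues(prep)))
    b_c <- fitConditionalLogit(pairDifferenceDesign(co, fv))$beta[["feature"]]
    b_a <- fitConditionalLogit(
      pairDifferenceDesign(co, fv, adjustment = "bmi_class"))$beta[["feature"]]
    abs(b_a) < abs(b_c)
  })
  expect_gte(mean(smaller), 0.8)
})

test_that("BH adjustment matches the brute-force step-up formula", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03))$p_adjusted, rep(0.03, 3))
  expect_equal(bhFdr(0.2)$p_adjusted, 0.2)
  set.seed(41)
  for (i in 1:20) {
    p <- runif(sample(2:40, 1))
    adj <- bhFdr(p)$p_adjusted
    expect_equal(adj, bruteForceBH(p), tolerance = 1e-12)
    # monotone in raw-p rank
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    # permutation equivariance
    perm <- sample(length(p))
    expect_equal(bhFdr(p[perm])$p_adjusted, adj[perm], tolerance = 1e-12)
  }
  expect_error(bhFdr(c(0.5, 1.2)), "parameter error")
  # rejection at the FDR level
  expect_true(bhFdr(c(0.001, 0.9))$rejected[1])
  expect_false(any(bhFdr(rep(0.5, 10))$rejected))
})
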
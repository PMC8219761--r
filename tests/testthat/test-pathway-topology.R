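SIGNIFICANT <- c("alanine", "leucine", "tyrosine", "valine", "lactic_acid",
                 "pyruvic_acid", "acetic_acid")

test_that("hit mapping matches compounds and excludes lipid families", {
  lib <- readPathwayLibrary()
  mh <- mapHits(SIGNIFICANT, lib)
  expect_equal(length(mh$hits), 17L)
  expect_equal(mh$hits[["phenylalanine_tyrosine_tryptophan_biosynthesis"]],
               "tyrosine")
  expect_setequal(mh$hits[["pyruvate_metabolism"]],
                  c("pyruvic_acid", "lactic_acid", "acetic_acid"))

  # feature-table input: lipids dropped by family, NA ids unmapped
  feats <- data.frame(
    feature = c("tyrosine", "triglycerides", "vldl1_triglycerides", "oddity"),
    family = c("metabolite", "lipid_main_fraction",
               "lipoprotein_subfraction", "metabolite"),
    compound_id = c("tyrosine", NA, NA, NA))
  mh2 <- mapHits(feats, lib)
  expect_equal(mh2$mapped, "tyrosine")
  expect_setequal(mh2$excluded_by_family,
                  c("triglycerides", "vldl1_triglycerides"))
  expect_equal(mh2$unmapped, "oddity")

  # empty input: all hit sets empty
  mh0 <- mapHits(character(0), lib)
  expect_true(all(lengths(mh0$hits) == 0L))
})

test_that("hypergeometric enrichment matches the combinatorial sum", {
  expect_equal(oraHypergeometric(0, 5, 5, 50), 1)
  expect_equal(oraHypergeometric(5, 5, 5, 5), 1)
  # exact sum oracle for P(X >= 2)
  oracle <- sum(sapply(2:5, function(k)
    choose(5, k) * choose(45, 5 - k) / choose(50, 5)))
  expect_equal(oraHypergeometric(2, 5, 5, 50), oracle, tolerance = 1e-12)
  # non-increasing in hits at fixed margins
  ps <- sapply(0:5, oraHypergeometric, totalCmpd = 8, nMappedInput = 6,
               universeSize = 40)
  expect_true(all(diff(ps) <= 1e-12))
  expect_error(oraHypergeometric(6, 5, 5, 50), "parameter error")
  expect_error(oraHypergeometric(2, 60, 5, 50), "parameter error")
})

test_that("Holm and BH adjustments match hand-applied formulas and ordering", {
  adj <- adjustPathwayP(c(0.001, 0.5))
  expect_equal(adj$holm_p, c(0.002, 0.5))
  expect_equal(adj$fdr_p, c(0.002, 0.5))
  one <- adjustPathwayP(0.3)
  expect_equal(one$holm_p, 0.3)
  expect_equal(one$fdr_p, 0.3)
  expect_equal(adjustPathwayP(rep(1, 4))$holm_p, rep(1, 4))
  set.seed(19)
  for (i in 1:10) {
    p <- runif(sample(3:20, 1))
    a <- adjustPathwayP(p)
    expect_equal(a$holm_p, bruteForceHolm(p), tolerance = 1e-12)
    expect_equal(a$fdr_p, bruteForceBH(p), tolerance = 1e-12)
    # Holm >= BH >= raw elementwise
    expect_true(all(a$holm_p >= a$fdr_p - 1e-12))
    expect_true(all(a$fdr_p >= p - 1e-12))
  }
})

test_that("topology impact follows relative betweenness with sane fallbacks", {
  path_abc <- rbind(c("A", "B"), c("B", "C"))
  expect_equal(pathwayImpact(path_abc, c("A", "B", "C"), "B"), 1.0)
  expect_equal(pathwayImpact(path_abc, c("A", "B", "C"), c("A", "B", "C")),
               1.0)
  expect_equal(pathwayImpact(path_abc, c("A", "B", "C"), character(0)), 0)
  expect_error(pathwayImpact(path_abc, c("A", "B", "C"), "Z"),
               "parameter error")
  # node relabeling leaves the impact unchanged
  expect_equal(pathwayImpact(rbind(c("x", "y"), c("y", "z")),
                             c("x", "y", "z"), "y"), 1.0)
  # an isolated non-hit compound with zero centrality changes nothing
  expect_equal(pathwayImpact(path_abc, c("A", "B", "C", "D"), "B"), 1.0)
  # 2-node graph: betweenness all zero, degree fallback
  expect_equal(pathwayImpact(rbind(c("A", "B")), c("A", "B"), "A"), 0.5)
  # no edges at all: node-share fallback
  expect_equal(pathwayImpact(matrix(character(0), 0, 2),
                             c("A", "B", "C", "D"), c("A", "B")), 0.5)
})

test_that("the full analysis reproduces the fixture arithmetic and impact filter", {
  res <- runPathwayAnalysis(SIGNIFICANT)
  expect_equal(nrow(res), 17L)
  aro <- res[res$name == "phenylalanine_tyrosine_tryptophan_biosynthesis", ]
  expect_equal(aro$total_cmpd, 4L)
  expect_equal(aro$hits, 1L)
  pyr <- res[res$name == "pyruvate_metabolism", ]
  expect_equal(pyr$total_cmpd, 22L)
  expect_equal(pyr$hits, 3L)
  # exactly the two topology-heavy pathways clear the 0.2 impact bar
  expect_equal(sort(res$name[res$considered]),
               c("phenylalanine_tyrosine_tryptophan_biosynthesis",
                 "pyruvate_metabolism"))
  expect_true(all(res$impact >= 0 & res$impact <= 1))
  expect_true(all(res$holm_p >= res$raw_p - 1e-12))
  expect_true(all(diff(res$raw_p) >= -1e-12))   # sorted by raw p
  # impossible threshold flags nothing
  res2 <- runPathwayAnalysis(SIGNIFICANT, impactThreshold = 1.1)
  expect_false(any(res2$considered))
})
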
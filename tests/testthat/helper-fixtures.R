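# Shared fixtures and independent oracles, all built in code.

# hand-built 4-pair cohort with complete covariates
makeTinyCohort <- function() {
  data.frame(
    subject_id = sprintf("S%02d", 1:8),
    pair_id = rep(sprintf("P%02d", 1:4), each = 2),
    group = rep(c("low_mbd", "high_mbd"), 4),
    age_at_entry = c(50, 52, 60, 58, 45.5, 47, 55, 55),
    exam_type = rep(c("analogical", "analogical", "digital", "analogical"),
                    each = 2),
    exam_purpose = rep("negative", 8),
    exam_era = rep(c("pre2000", "post2000"), each = 4),
    age_at_diagnosis = c(58, 59, 70, 66, 51, 52, 63, 60),
    menopausal_status = c("post", "post", "post", "pre", "pre", "pre",
                          "post", "post"),
    n_ftp = c(2L, 1L, 3L, 0L, 1L, 1L, 2L, 2L),
    breastfeeding = c("yes", "no", "yes", "no", "yes", "yes", "no", "yes"),
    er_status = c("pos", "pos", "neg", "pos", "pos", NA, "pos", "neg"),
    bmi = c(27, 23, 31, 22, 24, 21, 28, 25),
    bmi_class = c(2L, 1L, 3L, 1L, 1L, 1L, 2L, 2L),
    stringsAsFactors = FALSE)
}

# small panel with a known censoring mask
makeSmallPanel <- function() {
  conc <- matrix(c(4, 1, 6, 5, 2, 3, 8, 7,
                   10, 0.3, 12, 11, 0.4, 9, 13, 14),
                 nrow = 2, byrow = TRUE,
                 dimnames = list(c("met_a", "met_b"), sprintf("S%02d", 1:8)))
  meta <- data.frame(family = c("metabolite", "metabolite"),
                     loq = c(2.5, 1.0),
                     compound_id = c("met_a", "met_b"),
                     row.names = c("met_a", "met_b"))
  QuantPanel(conc, meta)
}

# constant-intensity spectra covering the default analysis window
flatSpectrumSet <- function(level = 1, nSubjects = 2,
                            ppm = seq(10.2, 0, by = -0.01)) {
  mat <- matrix(level, nSubjects, length(ppm),
                dimnames = list(sprintf("S%02d", seq_len(nSubjects)), NULL))
  new("SpectrumSet", experiment = "noesy", ppm = ppm, intensity = mat)
}

# brute-force multiple-testing oracles (direct formula application)
bruteForceBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(ord)]
}

bruteForceHolm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- cummax((m - seq_len(m) + 1) * p[ord])
  pmin(adj, 1)[order(ord)]
}

# exact two-sided rank-sum p-value by full enumeration of assignments
enumWilcoxonP <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(n, n1)
  sums <- colSums(matrix(r[combos], nrow = n1))
  mu <- n1 * (n + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# direct SVD-based single-component PLS oracle
directPlsPredict <- function(Xtrain, yCoded, Xtest) {
  mu <- colMeans(Xtrain)
  Ec <- sweep(Xtrain, 2, mu)
  w <- svd(crossprod(Ec, matrix(yCoded)), nu = 1)$u[, 1]
  sc <- drop(sweep(Xtest, 2, mu) %*% w)
  # orient so training scores correlate positively with y
  if (sum(drop(Ec %*% w) * yCoded) < 0) sc <- -sc
  sign(sc)
}
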
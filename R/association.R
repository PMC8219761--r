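## Conditional logistic regression for 1:1 matched sets. The 1:1
## conditional likelihood prod exp(x_case'b) / (exp(x_case'b) +
## exp(x_ctrl'b)) is maximized as an intercept-free binomial
## log-likelihood on within-pair differences with all responses equal to
## one, by Newton-Raphson on the observed information.

.ADJUSTMENT_SET <- c("age_at_diagnosis", "n_ftp", "breastfeeding",
                     "menopausal_status", "er_status", "bmi_class")

## numeric coding of the adjustment covariates for the matched models
.codeCovariate <- function(cohort, name) {
  v <- cohort[[name]]
  switch(name,
         menopausal_status = ifelse(v == "post", 1, 0),
         breastfeeding = ifelse(v == "yes", 1, 0),
         er_status = ifelse(v == "pos", 1, 0),
         as.numeric(v))
}

#' Build a within-pair difference design
#'
#' For each complete pair, the row is (high-MBD member value minus low-MBD
#' member value) for the feature of interest and any adjustment
#' covariates; there is no intercept (pair conditioning absorbs it). Pairs
#' in which either member misses a covariate are dropped and recorded.
#'
#' @param cohort validated cohort data.frame.
#' @param featureValues named numeric vector (by subject id) of the
#'   standardized feature, or NULL for a covariate-only design.
#' @param adjustment character vector of cohort covariate names to
#'   difference alongside the feature.
#' @return list with \code{delta} (pairs-by-terms matrix), \code{pair_ids},
#'   and \code{dropped} (data.frame of pair_id and reason).
#' @export
pairDifferenceDesign <- function(cohort, featureValues = NULL,
                                 adjustment = character()) {
  absent <- setdiff(adjustment, colnames(cohort))
  if (length(absent))
    stop("config error: adjustment covariate(s) absent from cohort: ",
         paste(absent, collapse = ", "))
  cov <- sapply(adjustment, function(a) .codeCovariate(cohort, a))
  if (length(adjustment))
    cov <- matrix(cov, nrow = nrow(cohort),
                  dimnames = list(cohort$subject_id, adjustment))
  pair_ids <- unique(cohort$pair_id)
  hi <- which(cohort$group == "high_mbd")[match(pair_ids,
    cohort$pair_id[cohort$group == "high_mbd"])]
  lo <- which(cohort$group == "low_mbd")[match(pair_ids,
    cohort$pair_id[cohort$group == "low_mbd"])]
  terms <- c(if (!is.null(featureValues)) "feature", adjustment)
  delta <- matrix(NA_real_, length(pair_ids), length(terms),
                  dimnames = list(pair_ids, terms))
  if (!is.null(featureValues))
    delta[, "feature"] <- featureValues[cohort$subject_id[hi]] -
      featureValues[cohort$subject_id[lo]]
  if (length(adjustment))
    delta[, adjustment] <- cov[hi, , drop = FALSE] -
      cov[lo, , drop = FALSE]
  dropped <- data.frame(pair_id = character(), reason = character())
  keep <- complete.cases(delta)
  if (any(!keep))
    dropped <- data.frame(pair_id = pair_ids[!keep],
                          reason = "missing covariate")
  list(delta = delta[keep, , drop = FALSE], pair_ids = pair_ids[keep],
       dropped = dropped)
}

#' Fit a 1:1 conditional logistic regression
#'
#' Newton-Raphson on the intercept-free binomial log-likelihood of the
#' pair differences (all responses 1), to gradient sup-norm below
#' \code{tol}, at most \code{maxIter} iterations. Monotone likelihood
#' (separation) is flagged when any coefficient exceeds 15 in absolute
#' value. Covariance is the inverse observed information.
#'
#' @param delta pairs-by-terms matrix of within-pair differences
#'   (high minus low), or the list returned by [pairDifferenceDesign()].
#' @param tol gradient convergence tolerance (default 1e-8).
#' @param maxIter maximum Newton iterations (default 50).
#' @return list with \code{beta}, \code{vcov}, \code{logLik},
#'   \code{converged}, \code{separated}, \code{iterations},
#'   \code{n_pairs}.
#' @export
fitConditionalLogit <- function(delta, tol = 1e-8, maxIter = 50L) {
  if (is.list(delta) && !is.matrix(delta)) delta <- delta$delta
  X <- as.matrix(delta)
  if (nrow(X) < 1L || all(X == 0))
    stop("design error: no pair with a nonzero difference")
  qr_rank <- qr(X)$rank
  if (qr_rank < ncol(X))
    stop("design error: rank-deficient difference design")
  p <- ncol(X)
  beta <- rep(0, p)
  separated <- FALSE
  converged <- FALSE
  iter <- 0L
  repeat {
    eta <- drop(X %*% beta)
    pr <- plogis(eta)
    grad <- drop(crossprod(X, 1 - pr))
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    if (iter >= maxIter) break
    W <- pr * (1 - pr)
    info <- crossprod(X * sqrt(W))
    step <- tryCatch(solve(info, grad), error = function(e) NULL)
    if (is.null(step)) break
    ## dampen overshooting steps far from the optimum
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    iter <- iter + 1L
    if (max(abs(beta)) > 15) { separated <- TRUE; converged <- FALSE; break }
  }
  eta <- drop(X %*% beta)
  pr <- plogis(eta)
  info <- crossprod(X * sqrt(pr * (1 - pr)))
  vc <- tryCatch(solve(info), error = function(e)
    matrix(NA_real_, p, p))
  dimnames(vc) <- list(colnames(X), colnames(X))
  list(beta = setNames(beta, colnames(X)), vcov = vc,
       logLik = sum(log(pr)), converged = converged,
       separated = separated, iterations = iter, n_pairs = nrow(X))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Adjusted values are \code{p_(i) * m / i} with cumulative-minimum
#' monotonization, capped at 1; a test is rejected iff its adjusted value
#' is at most \code{alpha}.
#'
#' @param p raw p-values in [0, 1].
#' @param alpha FDR level (default 0.05).
#' @return list with \code{p_adjusted} (same order as input) and
#'   \code{rejected} (logical).
#' @export
bhFdr <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("parameter error: p-values must lie in [0, 1]")
  adj <- p.adjust(p, method = "BH")
  list(p_adjusted = adj, rejected = !is.na(adj) & adj <= alpha)
}

#' Run crude or adjusted matched models over a feature panel
#'
#' Fits one conditional logistic regression per retained feature, with the
#' feature (standardized log-concentration, per SD) as the reported term
#' and, for the adjusted model, the confounder set differenced alongside.
#' Matching variables never enter as covariates: they are pair-constant
#' and handled entirely by the pair conditioning. FDR adjustment is
#' applied within each feature family ("per-table", the default) or
#' across all features at once.
#'
#' @param prepared a \linkS4class{PreparedPanel}.
#' @param cohort validated cohort data.frame.
#' @param model \code{"crude"} or \code{"adjusted"}.
#' @param adjustment covariates for the adjusted model (default: age at
#'   diagnosis, parity, breastfeeding, menopausal status, ER status, BMI
#'   class).
#' @param fdrScope \code{"per-table"} (within family) or \code{"global"}.
#' @param alpha FDR level (default 0.05).
#' @return data.frame with one row per feature: \code{feature},
#'   \code{family}, \code{model}, \code{beta}, \code{or_}, \code{ci_low},
#'   \code{ci_high}, \code{p_value}, \code{p_fdr}, \code{fdr_rejected},
#'   \code{n_pairs_used}, \code{degenerate}, \code{separated}.
#' @export
runFeaturePanel <- function(prepared, cohort, model = c("crude", "adjusted"),
                            adjustment = .ADJUSTMENT_SET,
                            fdrScope = c("per-table", "global"),
                            alpha = 0.05) {
  model <- match.arg(model)
  fdrScope <- match.arg(fdrScope)
  adj <- if (model == "adjusted") adjustment else character()
  std <- standardizedValues(prepared)
  fam <- SummarizedExperiment::rowData(prepared)$family
  z <- 1.959964
  rows <- lapply(seq_len(nrow(std)), function(i) {
    fv <- setNames(std[i, ], colnames(std))
    design <- pairDifferenceDesign(cohort, featureValues = fv,
                                   adjustment = adj)
    out <- data.frame(feature = rownames(std)[i], family = fam[i],
                      model = model, beta = NA_real_, or_ = 1,
                      ci_low = 0, ci_high = Inf, p_value = NA_real_,
                      p_fdr = NA_real_, fdr_rejected = FALSE,
                      n_pairs_used = nrow(design$delta),
                      degenerate = FALSE, separated = FALSE,
                      stringsAsFactors = FALSE)
    if (all(design$delta[, "feature"] == 0)) {
      out$degenerate <- TRUE
      return(out)
    }
    fit <- fitConditionalLogit(design$delta)
    b <- fit$beta[["feature"]]
    se <- sqrt(fit$vcov["feature", "feature"])
    out$beta <- b
    out$or_ <- exp(b)
    out$ci_low <- exp(b - z * se)
    out$ci_high <- exp(b + z * se)
    out$p_value <- 2 * pnorm(-abs(b / se))
    out$separated <- fit$separated
    out
  })
  res <- do.call(rbind, rows)
  usable <- !res$degenerate & !is.na(res$p_value)
  res$p_fdr <- NA_real_
  if (fdrScope == "global") {
    fdr <- bhFdr(res$p_value[usable], alpha = alpha)
    res$p_fdr[usable] <- fdr$p_adjusted
    res$fdr_rejected[usable] <- fdr$rejected
  } else {
    for (f in unique(res$family)) {
      sel <- usable & res$family == f
      if (!any(sel)) next
      fdr <- bhFdr(res$p_value[sel], alpha = alpha)
      res$p_fdr[sel] <- fdr$p_adjusted
      res$fdr_rejected[sel] <- fdr$rejected
    }
  }
  res
}
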
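## Baseline-characteristics ("Table 1") machinery: group summaries with
## two-sample t, Wilcoxon rank-sum and Pearson chi-squared tests.

#' Two-sample pooled-variance Student t test
#'
#' Works from summary statistics (means, SDs, group sizes) or from raw
#' vectors via [twoSampleTFromVectors()]. Pooled variance with
#' \code{df = n1 + n2 - 2} reproduces the p-values computable from a
#' published table of means and SDs. Welch's unequal-variance form is
#' available behind \code{welch = TRUE}.
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @param welch use the Welch-Satterthwaite df instead of pooling.
#' @return list with \code{statistic}, \code{df}, \code{p_value}.
#' @export
twoSampleT <- function(mean1, sd1, n1, mean2, sd2, n2, welch = FALSE) {
  if (n1 < 2 || n2 < 2) stop("parameter error: each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("parameter error: negative SD")
  if (welch) {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
    tstat <- (mean1 - mean2) / sqrt(se2)
  } else {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    if (sp2 == 0) {
      # degenerate: no within-group variation at all
      if (mean1 == mean2)
        return(list(statistic = 0, df = df, p_value = 1))
      warning("zero pooled variance with unequal means; p -> 0")
      return(list(statistic = Inf * sign(mean1 - mean2), df = df,
                  p_value = 0))
    }
    tstat <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  list(statistic = tstat, df = df,
       p_value = 2 * pt(-abs(tstat), df))
}

#' @rdname twoSampleT
#' @param x,y raw observation vectors (NAs dropped).
#' @export
twoSampleTFromVectors <- function(x, y, welch = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  twoSampleT(mean(x), sd(x), length(x), mean(y), sd(y), length(y),
             welch = welch)
}

#' Wilcoxon rank-sum test
#'
#' Midranks for ties; exact enumeration p-value for small untied samples,
#' otherwise the normal approximation with tie-corrected variance and
#' continuity correction (the behaviour of \code{stats::wilcox.test}).
#'
#' @param x,y observation vectors, each of length >= 2 (NAs dropped).
#' @param exact force (\code{TRUE}) or suppress (\code{FALSE}) the exact
#'   p-value; default \code{NULL} picks exact for n < 50 without ties.
#' @return list with \code{statistic} (the Mann-Whitney U of \code{x}) and
#'   \code{p_value}.
#' @export
wilcoxonRankSum <- function(x, y, exact = NULL) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("parameter error: each group needs >= 2 observations")
  if (length(unique(c(x, y))) == 1L)
    return(list(statistic = length(x) * length(y) / 2, p_value = 1))
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Pearson chi-squared test of independence
#'
#' Classic Pearson statistic without continuity correction,
#' \code{df = (r - 1)(c - 1)} — the convention that reproduces p-values
#' recomputable from published 2-by-2 contingency tables.
#'
#' @param counts r-by-c matrix of nonnegative integer counts.
#' @return list with \code{statistic}, \code{df}, \code{p_value}.
#' @export
pearsonChi2 <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("structure error: at least a 2x2 table is required")
  if (any(counts < 0)) stop("structure error: negative count")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("structure error: zero row or column total")
  res <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value)
}

.formatP <- function(p, floor = 1e-4) {
  ifelse(p < floor, sprintf("< %.4f", floor), signif(p, 2))
}

#' Build a baseline-characteristics table
#'
#' One row per configured variable, with per-group summaries (mean (SD)
#' for continuous variables, counts (\%) for categorical ones), the test
#' assigned to the variable and its p-value. Missing values are excluded
#' pairwise per variable and the non-missing count reported.
#'
#' @param cohort validated cohort data.frame with a \code{group} column.
#' @param tests named character vector mapping variable name to one of
#'   \code{"t"}, \code{"wilcoxon"}, \code{"chi2"}.
#' @return data.frame with columns \code{variable}, \code{low_summary},
#'   \code{high_summary}, \code{test}, \code{n_used}, \code{p_value},
#'   \code{p_printed}.
#' @export
buildTableOne <- function(cohort,
                          tests = c(age_at_entry = "t",
                                    age_at_diagnosis = "t",
                                    menopausal_status = "chi2",
                                    n_ftp = "chi2",
                                    breastfeeding = "chi2",
                                    er_status = "chi2",
                                    bmi = "t")) {
  bad <- setdiff(unname(tests), c("t", "wilcoxon", "chi2"))
  if (length(bad))
    stop("config error: unknown test name(s) ", paste(bad, collapse = ", "))
  absent <- setdiff(names(tests), colnames(cohort))
  if (length(absent))
    stop("config error: variable(s) not in cohort: ",
         paste(absent, collapse = ", "))
  grp <- cohort$group
  rows <- lapply(names(tests), function(v) {
    val <- cohort[[v]]
    ok <- !is.na(val)
    lo <- val[ok & grp == "low_mbd"]; hi <- val[ok & grp == "high_mbd"]
    test <- tests[[v]]
    if (test %in% c("t", "wilcoxon")) {
      res <- if (test == "t") twoSampleTFromVectors(lo, hi)
             else wilcoxonRankSum(lo, hi)
      low_sum <- sprintf("%.1f (%.1f)", mean(lo), sd(lo))
      high_sum <- sprintf("%.1f (%.1f)", mean(hi), sd(hi))
    } else {
      tab <- table(factor(val[ok]), factor(grp[ok], levels = .GROUPS))
      res <- pearsonChi2(as.matrix(tab))
      pct <- function(cnt) paste(sprintf("%s: %d (%.1f%%)", rownames(tab),
                                         cnt, 100 * cnt / sum(cnt)),
                                 collapse = "; ")
      low_sum <- pct(tab[, "low_mbd"]); high_sum <- pct(tab[, "high_mbd"])
    }
    data.frame(variable = v, low_summary = low_sum, high_summary = high_sum,
               test = test, n_used = sum(ok), p_value = res$p_value,
               p_printed = .formatP(res$p_value),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
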
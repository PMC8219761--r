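## Quantification-table preparation: half-LOQ imputation, below-LOQ
## exclusion, log transform and per-SD standardization.

#' Impute left-censored values with half the LOQ
#'
#' Every cell flagged below the limit of quantification is replaced by
#' \code{loq / 2} (more generally \code{loq * factor}); unflagged cells are
#' untouched. Idempotent: flags are preserved, so a second pass changes
#' nothing.
#'
#' @param panel a \linkS4class{QuantPanel} with the censoring mask set.
#' @param factor imputation multiple of the LOQ (default 0.5).
#' @return the imputed \linkS4class{QuantPanel}.
#' @export
loqImpute <- function(panel, factor = 0.5) {
  conc <- concentrations(panel)
  mask <- belowLOQ(panel)
  imput <- matrix(loq(panel) * factor, nrow(conc), ncol(conc))
  conc[mask] <- imput[mask]
  SummarizedExperiment::assay(panel, "concentration") <- conc
  panel
}

#' Fraction of observations below the LOQ, per feature
#'
#' @param panel a \linkS4class{QuantPanel}.
#' @return named numeric vector of below-LOQ fractions.
#' @export
belowLoqFraction <- function(panel) {
  rowMeans(belowLOQ(panel))
}

#' Exclude features with too many observations below the LOQ
#'
#' A feature is excluded iff its below-LOQ fraction strictly exceeds the
#' threshold (a feature at exactly the threshold is retained). By default
#' the rule is applied to every family; \code{families} restricts it (e.g.
#' \code{"metabolite"} for a metabolites-only reading).
#'
#' @param panel a \linkS4class{QuantPanel}.
#' @param threshold exclusion threshold in [0, 1) (default 0.20).
#' @param families families the rule applies to (default: all).
#' @return list with elements \code{panel} (the filtered
#'   \linkS4class{QuantPanel}) and \code{excluded} (data.frame of dropped
#'   features with their below-LOQ fraction).
#' @export
loqFilter <- function(panel, threshold = 0.20, families = .FAMILIES) {
  if (threshold < 0 || threshold >= 1)
    stop("parameter error: threshold must lie in [0, 1)")
  frac <- belowLoqFraction(panel)
  fam <- SummarizedExperiment::rowData(panel)$family
  drop <- frac > threshold & fam %in% families
  excluded <- data.frame(feature = rownames(panel)[drop],
                         family = fam[drop],
                         belowLoqFraction = unname(frac[drop]))
  list(panel = panel[!drop, ], excluded = excluded)
}

#' Log-transform and standardize a panel per SD
#'
#' Per feature, concentrations are mapped to
#' \eqn{(\ln x - \mathrm{mean}) / \mathrm{SD}} with the mean and sample SD
#' (n-1 denominator) computed over all subjects pooled, so that a
#' one-unit difference is one SD of log-concentration — the scale on which
#' odds ratios per SD are reported. The per-feature log mean and SD are
#' retained for back-transformation.
#'
#' @param panel an imputed \linkS4class{QuantPanel} (all values > 0).
#' @param excluded optional data.frame of features dropped by
#'   [loqFilter()], carried along for reporting.
#' @param loqThreshold threshold recorded alongside (default 0.20).
#' @return a \linkS4class{PreparedPanel}.
#' @export
logSdScale <- function(panel, excluded = data.frame(), loqThreshold = 0.20) {
  conc <- concentrations(panel)
  if (any(conc <= 0))
    stop("value error: non-positive concentration; impute before scaling")
  lg <- log(conc)
  mu <- rowMeans(lg)
  sds <- apply(lg, 1L, sd)
  if (any(sds == 0))
    stop("degenerate-feature error: constant feature(s) ",
         paste(rownames(conc)[sds == 0], collapse = ", "))
  std <- (lg - mu) / sds
  rd <- SummarizedExperiment::rowData(panel)
  rd$logMean <- unname(mu)
  rd$logSD <- unname(sds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(standardized = std),
    rowData = rd, colData = SummarizedExperiment::colData(panel))
  methods::new("PreparedPanel", se, excludedFeatures = excluded,
               loqThreshold = loqThreshold)
}

#' Full panel preparation
#'
#' [loqImpute()] then [loqFilter()] then [logSdScale()], the standard
#' preparation for per-SD matched association models.
#'
#' @param panel a raw censored \linkS4class{QuantPanel}.
#' @param threshold below-LOQ exclusion threshold (default 0.20).
#' @param imputeFactor imputation multiple of the LOQ (default 0.5).
#' @param families families the exclusion rule applies to.
#' @return a \linkS4class{PreparedPanel}.
#' @export
preparePanel <- function(panel, threshold = 0.20, imputeFactor = 0.5,
                         families = .FAMILIES) {
  imputed <- loqImpute(panel, factor = imputeFactor)
  filt <- loqFilter(imputed, threshold = threshold, families = families)
  logSdScale(filt$panel, excluded = filt$excluded,
             loqThreshold = threshold)
}

#' Standardized values of a prepared panel
#'
#' @param prepared a \linkS4class{PreparedPanel}.
#' @return features-by-subjects matrix of standardized log-concentrations.
#' @export
standardizedValues <- function(prepared) {
  SummarizedExperiment::assay(prepared, "standardized")
}
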
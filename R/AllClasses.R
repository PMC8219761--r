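#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assays assayNames rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats sd var rnorm runif rbinom pnorm pt pchisq qf phyper
#'   p.adjust prcomp plogis complete.cases setNames quantile chisq.test
#'   wilcox.test median
#' @importFrom utils read.csv write.csv packageVersion
NULL

.FAMILIES <- c("metabolite", "lipid_main_fraction", "lipoprotein_subfraction")
.EXPERIMENTS <- c("noesy", "cpmg", "diffusion")
.GROUPS <- c("low_mbd", "high_mbd")

#' QuantPanel: a quantified concentration panel with LOQ metadata
#'
#' A \linkS4class{SummarizedExperiment} holding a features-by-subjects
#' concentration matrix (assay \code{"concentration"}), a parallel logical
#' below-LOQ mask (assay \code{"belowLOQ"}), per-feature metadata in
#' \code{rowData} (\code{family}, \code{loq}, \code{compound_id}) and
#' subject records in \code{colData}. Concentrations are non-negative;
#' values flagged below the limit of quantification are left-censored
#' readings retained for downstream half-LOQ imputation.
#'
#' @slot .Data inherits all SummarizedExperiment slots.
#' @seealso [QuantPanel()], [loqImpute()], [loqFilter()]
#' @export
setClass("QuantPanel", contains = "SummarizedExperiment")

setValidity("QuantPanel", function(object) {
  msgs <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("concentration", "belowLOQ") %in% an))
    return("assays 'concentration' and 'belowLOQ' are required")
  conc <- SummarizedExperiment::assay(object, "concentration")
  mask <- SummarizedExperiment::assay(object, "belowLOQ")
  if (!is.numeric(conc)) msgs <- c(msgs, "'concentration' must be numeric")
  if (!is.logical(mask)) msgs <- c(msgs, "'belowLOQ' must be logical")
  if (any(conc < 0, na.rm = TRUE))
    msgs <- c(msgs, "concentrations must be non-negative")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("family", "loq") %in% colnames(rd)))
    return("rowData must contain 'family' and 'loq'")
  if (!all(rd$family %in% .FAMILIES))
    msgs <- c(msgs, sprintf("family must be one of: %s",
                            paste(.FAMILIES, collapse = ", ")))
  if (any(!is.finite(rd$loq)) || any(rd$loq <= 0))
    msgs <- c(msgs, "every LOQ must be finite and > 0")
  if (length(msgs)) msgs else TRUE
})

#' PreparedPanel: a standardized analysis-ready panel
#'
#' Result of LOQ filtering plus log transformation and per-SD scaling.
#' The assay \code{"standardized"} holds, for each retained feature,
#' \code{(ln x - mean)/sd} computed over all subjects. The per-feature
#' log-scale mean and SD used for scaling are kept in \code{rowData}
#' (columns \code{logMean}, \code{logSD}) for back-transformation, and the
#' features dropped by the below-LOQ filter are recorded in
#' \code{excludedFeatures} together with their below-LOQ fraction.
#'
#' @slot excludedFeatures data.frame with columns \code{feature},
#'   \code{family}, \code{belowLoqFraction}.
#' @slot loqThreshold numeric(1), the exclusion threshold applied.
#' @export
setClass("PreparedPanel",
  contains = "SummarizedExperiment",
  slots = c(excludedFeatures = "data.frame", loqThreshold = "numeric"))

setValidity("PreparedPanel", function(object) {
  if (!"standardized" %in% SummarizedExperiment::assayNames(object))
    return("assay 'standardized' is required")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("logMean", "logSD") %in% colnames(rd)))
    return("rowData must record 'logMean' and 'logSD'")
  TRUE
})

#' SpectrumSet: 1D NMR spectra for one experiment type
#'
#' Holds the spectra of all subjects for a single experiment
#' (NOESY, CPMG or diffusion-edited analogue) on a shared, strictly
#' descending ppm axis (high ppm left, the spectroscopy convention).
#'
#' @slot experiment one of \code{"noesy"}, \code{"cpmg"}, \code{"diffusion"}.
#' @slot ppm strictly decreasing numeric grid of chemical shifts (ppm).
#' @slot intensity subjects-by-points non-negative matrix; rownames are
#'   subject identifiers.
#' @export
setClass("SpectrumSet",
  slots = c(experiment = "character", ppm = "numeric", intensity = "matrix"))

setValidity("SpectrumSet", function(object) {
  msgs <- character()
  if (!object@experiment %in% .EXPERIMENTS)
    msgs <- c(msgs, "unknown experiment type")
  if (length(object@ppm) < 2L || any(diff(object@ppm) >= 0))
    msgs <- c(msgs, "ppm axis must be strictly decreasing")
  if (ncol(object@intensity) != length(object@ppm))
    msgs <- c(msgs, "intensity columns must align with the ppm grid")
  if (is.null(rownames(object@intensity)))
    msgs <- c(msgs, "intensity rows must be named by subject")
  if (any(object@intensity < 0))
    msgs <- c(msgs, "intensities must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' BinnedMatrix: bucketed spectral feature matrix
#'
#' Subjects-by-bins matrix of integrated spectral areas. Each bin is a
#' fixed-width chemical-shift window; \code{binEdges} stores (left, right)
#' ppm per bin. After total-integral normalization each row sums to one.
#'
#' @slot values subjects-by-bins non-negative matrix.
#' @slot binEdges bins-by-2 matrix with columns \code{left}, \code{right}.
#' @slot normalized logical(1).
#' @slot experiment character(1), provenance tag.
#' @export
setClass("BinnedMatrix",
  slots = c(values = "matrix", binEdges = "matrix",
            normalized = "logical", experiment = "character"))

setValidity("BinnedMatrix", function(object) {
  msgs <- character()
  if (ncol(object@values) != nrow(object@binEdges))
    msgs <- c(msgs, "one bin-edge row per value column is required")
  if (!identical(colnames(object@binEdges), c("left", "right")))
    msgs <- c(msgs, "binEdges columns must be 'left' and 'right'")
  if (isTRUE(object@normalized)) {
    rs <- rowSums(object@values)
    if (any(abs(rs - 1) > 1e-9))
      msgs <- c(msgs, "normalized rows must sum to 1 within 1e-9")
  }
  if (length(msgs)) msgs else TRUE
})

#' OplsdaModel: orthogonal projections to latent structures discriminant model
#'
#' Single-response OPLS-DA decomposition with one predictive component and
#' \code{nOrthogonal} orthogonal components. Classes are coded -1/+1
#' (\code{classCoding}); columns are mean-centered with the training means.
#'
#' @slot weightsPred,loadingsPred numeric(p) predictive weight and loading.
#' @slot scoresPred numeric(n) predictive scores of the training set.
#' @slot weightsOrtho,loadingsOrtho p-by-k orthogonal weights and loadings.
#' @slot scoresOrtho n-by-k orthogonal scores.
#' @slot columnMeans numeric(p) training column means.
#' @slot classCoding named numeric(2) mapping class labels to -1/+1.
#' @slot nOrthogonal integer(1).
#' @export
setClass("OplsdaModel",
  slots = c(weightsPred = "numeric", loadingsPred = "numeric",
            scoresPred = "numeric", weightsOrtho = "matrix",
            loadingsOrtho = "matrix", scoresOrtho = "matrix",
            columnMeans = "numeric", classCoding = "numeric",
            nOrthogonal = "integer"))

setValidity("OplsdaModel", function(object) {
  msgs <- character()
  k <- object@nOrthogonal
  if (ncol(object@weightsOrtho) != k || ncol(object@scoresOrtho) != k)
    msgs <- c(msgs, "orthogonal component count mismatch")
  if (k > 0) {
    tp <- object@scoresPred
    for (j in seq_len(k)) {
      to <- object@scoresOrtho[, j]
      if (abs(sum(tp * to)) > 1e-8 * sqrt(sum(tp^2)) * sqrt(sum(to^2)))
        msgs <- c(msgs, "predictive scores not orthogonal to orthogonal scores")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' MccvResult: Monte Carlo cross-validation summary
#'
#' Per-cycle accuracy, sensitivity and specificity of repeated stratified
#' train/test splits, with an optional permutation-test p-value whose null
#' distribution is the mean MCCV accuracy under random relabeling.
#'
#' @slot nCycles integer(1).
#' @slot accuracy,sensitivity,specificity numeric per-cycle rates in [0,1].
#' @slot permutationP numeric(0 or 1).
#' @slot nPermutations integer(1); 0 when no permutation test was run.
#' @slot nullAccuracy numeric, per-permutation mean accuracies.
#' @export
setClass("MccvResult",
  slots = c(nCycles = "integer", accuracy = "numeric",
            sensitivity = "numeric", specificity = "numeric",
            permutationP = "numeric", nPermutations = "integer",
            nullAccuracy = "numeric"))

setValidity("MccvResult", function(object) {
  rates <- c(object@accuracy, object@sensitivity, object@specificity)
  msgs <- character()
  if (any(rates < 0 | rates > 1, na.rm = TRUE))
    msgs <- c(msgs, "rates must lie in [0, 1]")
  if (length(object@permutationP) == 1L && object@nPermutations > 0L &&
      object@permutationP < 1 / (object@nPermutations + 1) - 1e-12)
    msgs <- c(msgs, "permutation p below its attainable minimum")
  if (length(msgs)) msgs else TRUE
})

#' PathwayLibrary: compound sets with topology
#'
#' A list of pathways, each a named compound set with an undirected edge
#' list over those compounds, plus the compound universe (the union over
#' the library) used as the over-representation reference.
#'
#' @slot pathways list of \code{list(name, compounds, edges)}; \code{edges}
#'   is a 2-column character matrix (possibly 0-row).
#' @slot universe character, all compound identifiers in the library.
#' @export
setClass("PathwayLibrary",
  slots = c(pathways = "list", universe = "character"))

setValidity("PathwayLibrary", function(object) {
  for (pw in object@pathways) {
    if (!all(c("name", "compounds", "edges") %in% names(pw)))
      return("each pathway needs 'name', 'compounds' and 'edges'")
    if (length(pw$compounds) == 0L)
      return(sprintf("pathway '%s' has an empty compound set", pw$name))
    if (nrow(pw$edges) > 0 && !all(as.vector(pw$edges) %in% pw$compounds))
      return(sprintf("pathway '%s' has an edge endpoint outside its compounds",
                     pw$name))
  }
  if (!all(unlist(lapply(object@pathways, `[[`, "compounds")) %in%
           object@universe))
    return("universe must contain every pathway compound")
  TRUE
})

#' GeneratorSpec: parameters of the synthetic-cohort generator
#'
#' Fully determines a synthetic matched case-case cohort: pair count, seed,
#' per-feature log-odds (per SD of log-concentration) of being the high-MBD
#' member, the covariate model, target below-LOQ censoring fractions, the
#' spectral peak library and noise scale.
#'
#' @slot nPairs integer(1), >= 2.
#' @slot seed integer(1).
#' @slot featureEffects named numeric, log-odds per SD.
#' @slot covariateModel list of distribution parameters and group offsets.
#' @slot censorFraction named numeric in [0, 1).
#' @slot noiseSd numeric(1) spectral white-noise SD.
#' @slot peakLibrary named list: feature -> list of peaks
#'   \code{(center, halfWidth, amplitude)}.
#' @slot features data.frame feature catalogue (name, family, compound_id,
#'   logMean, logSd).
#' @slot ppmGrid numeric, descending acquisition grid.
#' @slot subfractionCorrelation numeric(1) in [0, 1), strength of the
#'   low-rank latent structure tying lipoprotein subfractions together.
#' @export
setClass("GeneratorSpec",
  slots = c(nPairs = "integer", seed = "integer",
            featureEffects = "numeric", covariateModel = "list",
            censorFraction = "numeric", noiseSd = "numeric",
            peakLibrary = "list", features = "data.frame",
            ppmGrid = "numeric", subfractionCorrelation = "numeric"))

setValidity("GeneratorSpec", function(object) {
  msgs <- character()
  if (object@nPairs < 2L) msgs <- c(msgs, "nPairs must be >= 2")
  if (any(object@censorFraction < 0 | object@censorFraction >= 1))
    msgs <- c(msgs, "censor fractions must lie in [0, 1)")
  for (f in names(object@peakLibrary))
    for (pk in object@peakLibrary[[f]])
      if (pk$halfWidth <= 0)
        msgs <- c(msgs, sprintf("non-positive half-width for '%s'", f))
  if (length(msgs)) unique(msgs) else TRUE
})

#' SyntheticCohort: a generated study with its ground truth
#'
#' @slot cohort data.frame of subject records (two rows per pair).
#' @slot panel \linkS4class{QuantPanel} with censoring applied
#'   (pre-imputation: below-LOQ cells hold the censored reading).
#' @slot spectra named list of \linkS4class{SpectrumSet}, one per experiment.
#' @slot truth the \linkS4class{GeneratorSpec} that produced it.
#' @export
setClass("SyntheticCohort",
  slots = c(cohort = "data.frame", panel = "QuantPanel",
            spectra = "list", truth = "GeneratorSpec"))
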
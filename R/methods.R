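#' Construct a QuantPanel
#'
#' @param concentration features-by-subjects numeric matrix with feature
#'   rownames and subject colnames.
#' @param featureMeta data.frame/DataFrame with columns \code{family},
#'   \code{loq} and optionally \code{compound_id}; rows align with
#'   \code{concentration}.
#' @param belowLOQ optional logical mask of the same shape; defaults to
#'   \code{concentration < loq} per feature.
#' @param subjectData optional data.frame of subject records (colData).
#' @return a \linkS4class{QuantPanel}.
#' @export
QuantPanel <- function(concentration, featureMeta, belowLOQ = NULL,
                       subjectData = NULL) {
  concentration <- as.matrix(concentration)
  if (any(concentration < 0, na.rm = TRUE))
    stop("negative concentration encountered")
  fm <- S4Vectors::DataFrame(featureMeta)
  if (!"compound_id" %in% colnames(fm)) fm$compound_id <- NA_character_
  if (is.null(belowLOQ))
    belowLOQ <- sweep(concentration, 1L, fm$loq, `<`)
  storage.mode(belowLOQ) <- "logical"
  dimnames(belowLOQ) <- dimnames(concentration)
  cd <- if (is.null(subjectData)) {
    S4Vectors::DataFrame(row.names = colnames(concentration))
  } else {
    S4Vectors::DataFrame(subjectData, row.names = colnames(concentration))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(concentration = concentration, belowLOQ = belowLOQ),
    rowData = fm, colData = cd)
  methods::new("QuantPanel", se)
}

#' @rdname accessors
#' @export
setMethod("concentrations", "QuantPanel", function(object, ...)
  SummarizedExperiment::assay(object, "concentration"))

#' @rdname accessors
#' @export
setMethod("belowLOQ", "QuantPanel", function(object, ...)
  SummarizedExperiment::assay(object, "belowLOQ"))

#' @rdname accessors
#' @export
setMethod("featureMeta", "QuantPanel", function(object, ...)
  SummarizedExperiment::rowData(object))

#' @rdname accessors
#' @export
setMethod("loq", "QuantPanel", function(object, ...)
  setNames(SummarizedExperiment::rowData(object)$loq, rownames(object)))

#' @rdname accessors
#' @export
setMethod("subjectIds", "QuantPanel", function(object, ...) colnames(object))

#' @rdname accessors
#' @export
setMethod("subjectIds", "SpectrumSet", function(object, ...)
  rownames(object@intensity))

#' @rdname accessors
#' @export
setMethod("binValues", "BinnedMatrix", function(object, ...) object@values)

#' @rdname accessors
#' @export
setMethod("binEdges", "BinnedMatrix", function(object, ...) object@binEdges)

setMethod("show", "QuantPanel", function(object) {
  fam <- table(factor(SummarizedExperiment::rowData(object)$family,
                      levels = .FAMILIES))
  cat("QuantPanel:", nrow(object), "features x", ncol(object), "subjects\n")
  cat(sprintf("  metabolites: %d | lipid main fractions: %d | subfractions: %d\n",
              fam[["metabolite"]], fam[["lipid_main_fraction"]],
              fam[["lipoprotein_subfraction"]]))
  cat(sprintf("  below-LOQ cells: %d\n", sum(belowLOQ(object))))
})

setMethod("show", "PreparedPanel", function(object) {
  cat("PreparedPanel:", nrow(object), "retained features x", ncol(object),
      "subjects\n")
  cat(sprintf("  excluded (> %.0f%% below LOQ): %d\n",
              100 * object@loqThreshold, nrow(object@excludedFeatures)))
})

setMethod("show", "SpectrumSet", function(object) {
  cat(sprintf("SpectrumSet [%s]: %d subjects, %d points, %.2f..%.2f ppm\n",
              object@experiment, nrow(object@intensity), length(object@ppm),
              max(object@ppm), min(object@ppm)))
})

setMethod("show", "BinnedMatrix", function(object) {
  cat(sprintf("BinnedMatrix [%s]: %d subjects x %d bins%s\n",
              object@experiment, nrow(object@values), ncol(object@values),
              if (isTRUE(object@normalized)) " (total-integral normalized)"
              else ""))
})

setMethod("show", "OplsdaModel", function(object) {
  cat(sprintf("OplsdaModel: 1 predictive + %d orthogonal components, %d bins\n",
              object@nOrthogonal, length(object@weightsPred)))
})

setMethod("show", "MccvResult", function(object) {
  cat(sprintf("MccvResult: %d cycles | accuracy %.3f | sensitivity %.3f | specificity %.3f\n",
              object@nCycles, mean(object@accuracy),
              mean(object@sensitivity), mean(object@specificity)))
  if (length(object@permutationP))
    cat(sprintf("  permutation p = %.4f (%d permutations)\n",
                object@permutationP, object@nPermutations))
})

setMethod("show", "PathwayLibrary", function(object) {
  cat(sprintf("PathwayLibrary: %d pathways, %d compounds in universe\n",
              length(object@pathways), length(object@universe)))
})

setMethod("show", "GeneratorSpec", function(object) {
  cat(sprintf("GeneratorSpec: %d pairs, seed %d, %d features (%d with nonzero effect)\n",
              object@nPairs, object@seed, nrow(object@features),
              sum(object@featureEffects != 0)))
})

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf("SyntheticCohort: %d subjects in %d pairs, %d features, %d spectra sets\n",
              nrow(object@cohort), nrow(object@cohort) %/% 2L,
              nrow(object@panel), length(object@spectra)))
})

#' Extract parts of a synthetic cohort
#'
#' @param object a \linkS4class{SyntheticCohort}.
#' @return `cohortTable()` the subject-record data.frame; `quantPanel()` the
#'   censored \linkS4class{QuantPanel}; `spectrumSets()` the named list of
#'   \linkS4class{SpectrumSet}; `generatorTruth()` the generating
#'   \linkS4class{GeneratorSpec}.
#' @name synthetic-accessors
NULL

#' @rdname synthetic-accessors
#' @export
cohortTable <- function(object) object@cohort

#' @rdname synthetic-accessors
#' @export
quantPanel <- function(object) object@panel

#' @rdname synthetic-accessors
#' @export
spectrumSets <- function(object) object@spectra

#' @rdname synthetic-accessors
#' @export
generatorTruth <- function(object) object@truth
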
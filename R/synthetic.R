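## Synthetic matched case-case cohort generator.
##
## The generative model makes the conditional-logistic coefficient the
## literal parameter: for each pair, two members' standardized
## log-concentrations are drawn, and which member is the high-MBD case is
## sampled with probability plogis(beta' * delta) given the within-pair
## standardized differences delta. BMI can enter both the label probability
## and the lipid-feature means, injecting the crude-vs-adjusted divergence
## seen in matched observational panels.

.PARTICLES <- c("vldl_total", "idl_total", "ldl_total", "hdl_total",
                paste0("vldl", 1:5), paste0("ldl", 1:6), paste0("hdl", 1:4))
.CONSTITUENTS <- c("triglycerides", "cholesterol", "free_cholesterol",
                   "phospholipids", "apo")

.METABOLITES <- c("acetic_acid", "alanine", "citric_acid", "creatine",
                  "creatinine", "glucose", "glutamine", "glycine",
                  "histidine", "isoleucine", "lactic_acid", "leucine",
                  "pyruvic_acid", "tyrosine", "valine")
## additional low-abundance metabolites quantified but heavily censored,
## so that the >20% below-LOQ filter has real work to do
.RARE_METABOLITES <- c("acetone", "formic_acid", "methanol",
                       "dimethyl_sulfone", "ornithine", "sarcosine")
.LIPID_MAIN <- c("triglycerides", "cholesterol", "ldl_cholesterol",
                 "hdl_cholesterol", "apo_a1", "apo_a2", "apo_b100")

#' Default feature catalogue of the synthetic panel
#'
#' 21 metabolites (15 routinely quantified plus 6 low-abundance ones that
#' a 20\%-below-LOQ filter removes), 7 lipid main fractions and 95
#' lipoprotein subfractions (19 particle classes times 5 constituents).
#' \code{bmiLoading} is the coefficient of the (standardized) BMI on the
#' feature's standardized log-concentration; triglyceride-rich VLDL
#' features carry the largest loadings.
#'
#' @return data.frame with columns \code{name}, \code{family},
#'   \code{compound_id}, \code{logMean}, \code{logSd}, \code{bmiLoading}.
#' @export
defaultFeatureCatalogue <- function() {
  met <- data.frame(
    name = c(.METABOLITES, .RARE_METABOLITES),
    family = "metabolite",
    compound_id = c(.METABOLITES, .RARE_METABOLITES),
    logMean = log(c(0.05, 0.35, 0.10, 0.04, 0.07, 4.8, 0.55, 0.25,
                    0.08, 0.06, 1.5, 0.12, 0.07, 0.06, 0.22,
                    0.02, 0.02, 0.03, 0.01, 0.03, 0.01)),
    logSd = 0.30, bmiLoading = 0)
  lip <- data.frame(
    name = .LIPID_MAIN, family = "lipid_main_fraction",
    compound_id = NA_character_,
    logMean = log(c(110, 210, 130, 58, 150, 32, 95)),
    logSd = 0.28,
    bmiLoading = c(0.50, 0.25, 0.25, -0.20, -0.10, -0.10, 0.30))
  sub <- expand.grid(constituent = .CONSTITUENTS, particle = .PARTICLES,
                     stringsAsFactors = FALSE)
  sub <- data.frame(
    name = paste(sub$particle, sub$constituent, sep = "_"),
    family = "lipoprotein_subfraction",
    compound_id = NA_character_,
    logMean = log(15), logSd = 0.35,
    bmiLoading = ifelse(grepl("^vldl", sub$particle), 0.50,
                 ifelse(grepl("^hdl", sub$particle), -0.15, 0.20)))
  rbind(met, lip, sub)
}

#' Default per-feature effects on high-MBD membership
#'
#' Log-odds per SD of log-concentration for the conditional-logistic
#' data-generating process. Defaults place direct effects on the seven
#' metabolites that the matched analysis is designed to flag (six inverse,
#' acetic acid direct); lipid features carry no direct effect and acquire
#' their crude associations through the BMI confounding path.
#'
#' @param features feature catalogue (see [defaultFeatureCatalogue()]).
#' @return named numeric vector, one element per feature.
#' @export
defaultFeatureEffects <- function(features = defaultFeatureCatalogue()) {
  eff <- setNames(rep(0, nrow(features)), features$name)
  eff["alanine"] <- log(0.59)
  eff["leucine"] <- log(0.71)
  eff["tyrosine"] <- log(0.59)
  eff["valine"] <- log(0.72)
  eff["lactic_acid"] <- log(0.69)
  eff["pyruvic_acid"] <- log(0.59)
  eff["acetic_acid"] <- log(1.67)
  eff
}

#' Default covariate model
#'
#' Distribution parameters and group offsets emulating the baseline
#' contrasts of a matched low- vs high-MBD case-case series: high-MBD
#' members are younger, more often premenopausal, of lower parity and
#' lower BMI. \code{bmi_label_beta} is the log-odds contribution of the
#' within-pair standardized BMI difference to high-MBD membership (negative:
#' leaner women tend to be the dense-breast member), the lever that makes
#' BMI a genuine confounder for lipid features.
#'
#' @return named list of parameters.
#' @export
defaultCovariateModel <- function() {
  list(
    age_entry_mean = 53, age_entry_sd = 6.5, age_entry_shift = 2.7,
    followup_mean = 8.4, followup_sd = 4.5,
    exam_analogical_prob = 0.862, exam_negative_prob = 0.839,
    exam_post2000_prob = 0.609,
    menopause_post_prob = c(low = 0.753, high = 0.609),
    nftp_probs_low = c(0.092, 0.345, 0.379, 0.184),
    nftp_probs_high = c(0.230, 0.368, 0.379, 0.023),
    breastfeeding_prob = c(low = 0.793, high = 0.655),
    er_pos_prob = c(low = 0.921, high = 0.812), er_missing_prob = 0.167,
    bmi_mean = 25.5, bmi_sd = 4.2, bmi_label_beta = -1.1)
}

#' Load the bundled synthetic peak library
#'
#' @param path JSON file mapping feature name to a list of Lorentzian peaks
#'   \code{(center, halfWidth, amplitude)}; defaults to the bundled
#'   fixture library.
#' @return named list of peak lists.
#' @export
defaultPeakLibrary <- function(path = system.file("extdata",
    "peak_library_synthetic.json", package = "matchedMetabo")) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  raw[["_comment"]] <- NULL
  raw
}

#' Build a generator specification
#'
#' @param nPairs number of matched case-case pairs (default 87, the size of
#'   a complete-set series).
#' @param seed integer RNG seed; generation is a pure function of the spec.
#' @param featureEffects named log-odds per SD (default
#'   [defaultFeatureEffects()]); unnamed features default to 0.
#' @param covariateModel list as in [defaultCovariateModel()]; supplied
#'   entries override defaults element-wise.
#' @param censorFraction named target below-LOQ fractions in [0, 1);
#'   defaults: 0.35 for the six low-abundance metabolites, 0.02 for the
#'   remaining metabolites, 0 for lipids.
#' @param noiseSd spectral white-noise SD (intensity units; default 0.5).
#' @param peakLibrary named list of Lorentzian peaks per feature.
#' @param features feature catalogue data.frame.
#' @param ppmGrid descending acquisition grid (default 10.2 to 0 ppm in
#'   0.002 ppm steps, covering the 0.2-10.02 ppm analysis window).
#' @param subfractionCorrelation latent-factor loading share in [0, 1)
#'   tying subfractions of the same particle class together (default 0.6).
#' @return a \linkS4class{GeneratorSpec}.
#' @export
generatorSpec <- function(nPairs = 87L, seed = 1L,
                          featureEffects = NULL, covariateModel = list(),
                          censorFraction = NULL, noiseSd = 0.5,
                          peakLibrary = defaultPeakLibrary(),
                          features = defaultFeatureCatalogue(),
                          ppmGrid = seq(10.2, 0, by = -0.002),
                          subfractionCorrelation = 0.6) {
  eff <- setNames(rep(0, nrow(features)), features$name)
  if (!is.null(featureEffects)) {
    unknown <- setdiff(names(featureEffects), features$name)
    if (length(unknown))
      stop("spec error: effects for unknown feature(s) ",
           paste(unknown, collapse = ", "))
    eff[names(featureEffects)] <- featureEffects
  } else {
    known <- intersect(names(defaultFeatureEffects(features)), features$name)
    eff[known] <- defaultFeatureEffects(features)[known]
  }
  cm <- defaultCovariateModel()
  cm[names(covariateModel)] <- covariateModel
  cf <- setNames(rep(0, nrow(features)), features$name)
  if (!is.null(censorFraction)) {
    cf[names(censorFraction)] <- censorFraction
  } else {
    cf[intersect(.RARE_METABOLITES, features$name)] <- 0.35
    cf[intersect(.METABOLITES, features$name)] <- 0.02
  }
  methods::new("GeneratorSpec", nPairs = as.integer(nPairs),
               seed = as.integer(seed), featureEffects = eff,
               covariateModel = cm, censorFraction = cf,
               noiseSd = noiseSd, peakLibrary = peakLibrary,
               features = features, ppmGrid = ppmGrid,
               subfractionCorrelation = subfractionCorrelation)
}

#' A fully null generator specification
#'
#' All feature effects zero and no BMI-to-label path, so high-MBD
#' membership is a fair coin within each pair. Used for type-I error and
#' permutation-calibration checks.
#'
#' @param ... passed to [generatorSpec()].
#' @return a \linkS4class{GeneratorSpec}.
#' @export
nullGeneratorSpec <- function(...) {
  args <- list(...)
  cm <- if (is.null(args$covariateModel)) list() else args$covariateModel
  cm$bmi_label_beta <- 0
  args$covariateModel <- cm
  if (is.null(args$featureEffects)) args$featureEffects <- c(alanine = 0)
  do.call(generatorSpec, args)
}

## run expr under a private RNG stream, restoring the caller's state
.withSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  expr
}

.particleFactor <- function(names) {
  sub("([a-z]+[0-9]*)_.*", "\\1", names)
}

#' Generate a synthetic matched case-case cohort
#'
#' Draw order is fixed (pair matching variables; member BMI; latent
#' lipoprotein factors; feature z-scores; label assignment; member
#' covariates; spectral noise) so that a given spec is a pure function of
#' its seed.
#'
#' @param spec a \linkS4class{GeneratorSpec}.
#' @param withSpectra generate the three per-subject spectra (default TRUE;
#'   disable for large association-only simulations). The cohort and panel
#'   are identical either way because spectral noise is drawn last.
#' @return a \linkS4class{SyntheticCohort}.
#' @export
generateCohort <- function(spec, withSpectra = TRUE) {
  methods::validObject(spec)
  .withSeed(spec@seed, {
    n <- spec@nPairs
    m <- 2L * n
    feats <- spec@features
    nf <- nrow(feats)
    cm <- spec@covariateModel

    ## 1. pair-level matching variables
    pair_age <- rnorm(n, cm$age_entry_mean, cm$age_entry_sd)
    exam_type <- ifelse(runif(n) < cm$exam_analogical_prob,
                        "analogical", "digital")
    exam_purpose <- ifelse(runif(n) < cm$exam_negative_prob,
                           "negative", "diagnostic")
    exam_era <- ifelse(runif(n) < cm$exam_post2000_prob,
                       "post2000", "pre2000")

    ## 2. member-level BMI z-scores
    zb <- rnorm(m)

    ## 3. latent particle factors and feature z-scores
    particles <- .particleFactor(feats$name)
    is_sub <- feats$family == "lipoprotein_subfraction"
    fac_names <- unique(particles[is_sub])
    u <- matrix(rnorm(m * length(fac_names)), m,
                dimnames = list(NULL, fac_names))
    eps <- matrix(rnorm(m * nf), m, nf)
    rho <- spec@subfractionCorrelation
    z <- eps
    if (any(is_sub)) {
      idx <- which(is_sub)
      z[, idx] <- sqrt(rho) * u[, particles[idx]] +
        sqrt(1 - rho) * eps[, idx]
    }
    x <- z + outer(zb, feats$bmiLoading)          # standardized-scale values
    s <- sqrt(1 + feats$bmiLoading^2)             # analytic SD of x columns

    ## 4. which member is the high-MBD case
    odd <- seq(1L, m, by = 2L); even <- odd + 1L
    dx <- sweep(x[odd, , drop = FALSE] - x[even, , drop = FALSE], 2L, s, `/`)
    lp <- drop(dx %*% spec@featureEffects) +
      cm$bmi_label_beta * (zb[odd] - zb[even])
    first_is_high <- rbinom(n, 1L, plogis(lp)) == 1L
    group <- character(m)
    group[odd] <- ifelse(first_is_high, "high_mbd", "low_mbd")
    group[even] <- ifelse(first_is_high, "low_mbd", "high_mbd")
    is_high <- group == "high_mbd"

    ## 5. member covariates (group-conditional draws, fixed order)
    age_gap <- pmin(pmax(cm$age_entry_shift + rnorm(n, 0, 1.5), -4.9), 4.9)
    age_entry <- numeric(m)
    age_entry[odd] <- pair_age + ifelse(first_is_high, -age_gap, age_gap) / 2
    age_entry[even] <- pair_age + ifelse(first_is_high, age_gap, -age_gap) / 2
    followup <- pmax(rnorm(m, cm$followup_mean, cm$followup_sd), 1)
    age_diag <- age_entry + followup
    gidx <- ifelse(is_high, "high", "low")
    menop <- ifelse(runif(m) < cm$menopause_post_prob[gidx], "post", "pre")
    nftp <- integer(m)
    for (i in seq_len(m)) {
      pr <- if (is_high[i]) cm$nftp_probs_high else cm$nftp_probs_low
      nftp[i] <- sample(0:3, 1L, prob = pr)
    }
    bf_draw <- runif(m) < cm$breastfeeding_prob[gidx]
    breastfeeding <- ifelse(nftp > 0L & bf_draw, "yes", "no")
    er_u <- runif(m); er_m <- runif(m)
    er_status <- ifelse(er_m < cm$er_missing_prob, NA_character_,
                        ifelse(er_u < cm$er_pos_prob[gidx], "pos", "neg"))
    bmi <- pmax(cm$bmi_mean + cm$bmi_sd * zb, 16)
    bmi_class <- cut(bmi, c(-Inf, 25, 30, Inf), labels = FALSE)

    cohort <- data.frame(
      subject_id = sprintf("S%03d", seq_len(m)),
      pair_id = rep(sprintf("P%03d", seq_len(n)), each = 2L),
      group = group,
      age_at_entry = round(age_entry, 2),
      exam_type = rep(exam_type, each = 2L),
      exam_purpose = rep(exam_purpose, each = 2L),
      exam_era = rep(exam_era, each = 2L),
      age_at_diagnosis = round(age_diag, 2),
      menopausal_status = menop,
      n_ftp = nftp,
      breastfeeding = breastfeeding,
      er_status = er_status,
      bmi = round(bmi, 2),
      bmi_class = bmi_class,
      stringsAsFactors = FALSE)
    validateCohort(cohort)

    ## 6. concentrations and LOQ censoring (quantile-based, no RNG)
    conc <- t(exp(sweep(sweep(x, 2L, feats$logSd, `*`), 2L,
                        feats$logMean, `+`)))
    dimnames(conc) <- list(feats$name, cohort$subject_id)
    meta <- data.frame(family = feats$family, loq = 1,
                       compound_id = feats$compound_id,
                       row.names = feats$name)
    panel <- QuantPanel(conc, meta,
                        belowLOQ = matrix(FALSE, nf, m,
                                          dimnames = dimnames(conc)),
                        subjectData = cohort)
    panel <- applyLoqCensoring(panel, spec)

    ## 7. spectra (noise drawn last; subject-major, experiment-minor order)
    spectra <- list()
    if (withSpectra) {
      for (exp_type in .EXPERIMENTS) {
        ints <- matrix(0, m, length(spec@ppmGrid),
                       dimnames = list(cohort$subject_id, NULL))
        for (i in seq_len(m)) {
          ints[i, ] <- .spectrumIntensity(conc[, i], spec, exp_type)
          if (spec@noiseSd > 0)
            ints[i, ] <- pmax(ints[i, ] +
              rnorm(length(spec@ppmGrid), 0, spec@noiseSd), 0)
        }
        spectra[[exp_type]] <- methods::new("SpectrumSet",
          experiment = exp_type, ppm = spec@ppmGrid, intensity = ints)
      }
    }

    methods::new("SyntheticCohort", cohort = cohort, panel = panel,
                 spectra = spectra, truth = spec)
  })
}

## attenuation of a peak by experiment type: CPMG passes narrow
## (metabolite) resonances, diffusion-edited passes broad lipid envelopes,
## NOESY passes both. Narrow = half-width < 0.03 ppm.
.experimentWeight <- function(experiment, halfWidth) {
  narrow <- halfWidth < 0.03
  switch(experiment,
         noesy = 1,
         cpmg = if (narrow) 1 else 0.05,
         diffusion = if (narrow) 0.05 else 1)
}

## noise-free intensity on the spec grid; Lorentzian form
## A * hw / ((x - c)^2 + hw^2), integral A * pi
.spectrumIntensity <- function(concentrations, spec, experiment) {
  grid <- spec@ppmGrid
  out <- numeric(length(grid))
  for (f in names(spec@peakLibrary)) {
    cf <- concentrations[f]
    if (is.na(cf) || cf == 0) next
    for (pk in spec@peakLibrary[[f]]) {
      w <- .experimentWeight(experiment, pk$halfWidth)
      out <- out + cf * pk$amplitude * w * pk$halfWidth /
        ((grid - pk$center)^2 + pk$halfWidth^2)
    }
  }
  ## residual-water hump, strictly confined to the 4.40-5.12 ppm window
  ## (open interval so bins bordering the window integrate to zero)
  water <- grid > 4.40 + 1e-9 & grid < 5.12 - 1e-9
  out[water] <- out[water] + 40 * 0.08 /
    ((grid[water] - 4.76)^2 + 0.08^2)
  out
}

#' Synthesize one noise-free spectrum
#'
#' Sum of concentration-scaled Lorentzian peaks
#' \eqn{A\,hw/((\delta-c)^2+hw^2)} (integral \eqn{A\pi} per unit
#' concentration), attenuated by experiment type, plus a residual-water
#' hump confined to 4.40-5.12 ppm. White noise of SD \code{spec@noiseSd}
#' is added and the result truncated at zero; pass a spec with
#' \code{noiseSd = 0} for the deterministic part.
#'
#' @param concentrations named numeric vector of feature concentrations.
#' @param spec a \linkS4class{GeneratorSpec} (peak library, grid, noise).
#' @param experiment \code{"noesy"}, \code{"cpmg"} or \code{"diffusion"}.
#' @param subjectId row name for the resulting single-subject set.
#' @return a \linkS4class{SpectrumSet} with one subject.
#' @export
synthesizeSpectrum <- function(concentrations, spec, experiment,
                               subjectId = "S001") {
  nonzero <- names(concentrations)[!is.na(concentrations) &
                                     concentrations != 0]
  ## catalogue features absent from the library are silent (zero
  ## amplitude); a name that matches nothing known at all is a library error
  unknown <- setdiff(nonzero, c(names(spec@peakLibrary), spec@features$name))
  if (length(unknown))
    stop("peak library error: no entry or catalogue row for ",
         paste(unknown, collapse = ", "))
  ints <- .spectrumIntensity(concentrations, spec, experiment)
  if (spec@noiseSd > 0)
    ints <- pmax(ints + rnorm(length(ints), 0, spec@noiseSd), 0)
  mat <- matrix(ints, 1L, dimnames = list(subjectId, NULL))
  methods::new("SpectrumSet", experiment = experiment, ppm = spec@ppmGrid,
               intensity = mat)
}

#' Apply target below-LOQ censoring to a panel
#'
#' For each feature with a positive target fraction, the LOQ is set to the
#' empirical concentration quantile realizing that fraction (the midpoint
#' between the bracketing order statistics, so exactly
#' \code{round(fraction * n)} subjects fall below), and the mask is set
#' accordingly. Features with fraction 0 get a nominal LOQ below the
#' observed minimum and no masking.
#'
#' @param panel a \linkS4class{QuantPanel}.
#' @param spec a \linkS4class{GeneratorSpec} carrying
#'   \code{censorFraction}.
#' @return the censored \linkS4class{QuantPanel} (values untouched; LOQ
#'   metadata and mask updated).
#' @export
applyLoqCensoring <- function(panel, spec) {
  cf <- spec@censorFraction
  if (any(cf >= 1)) stop("spec error: censor fraction must be < 1")
  conc <- concentrations(panel)
  n <- ncol(conc)
  loqs <- numeric(nrow(conc))
  mask <- matrix(FALSE, nrow(conc), n, dimnames = dimnames(conc))
  for (i in seq_len(nrow(conc))) {
    f <- rownames(conc)[i]
    frac <- if (f %in% names(cf)) cf[[f]] else 0
    srt <- sort(conc[i, ])
    k <- round(frac * n)
    if (k >= 1L) {
      loqs[i] <- if (k < n) (srt[k] + srt[k + 1L]) / 2 else srt[n] * 1.01
      mask[i, ] <- conc[i, ] < loqs[i]
    } else {
      loqs[i] <- srt[1L] / 10
    }
  }
  rd <- SummarizedExperiment::rowData(panel)
  rd$loq <- loqs
  SummarizedExperiment::rowData(panel) <- rd
  SummarizedExperiment::assay(panel, "belowLOQ") <- mask
  methods::validObject(panel)
  panel
}

#' Export a synthetic cohort to the delimited interchange layout
#'
#' Writes \code{cohort.csv}, \code{quant.csv}, \code{loq.csv},
#' \code{spectra_<experiment>.csv} (one matrix per experiment) and
#' \code{truth.json} (the generator parameters).
#'
#' @param sc a \linkS4class{SyntheticCohort}.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
exportSyntheticCohort <- function(sc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeCohort(sc@cohort, file.path(dir, "cohort.csv"))
  writeQuantPanel(sc@panel, file.path(dir, "quant.csv"),
                  file.path(dir, "loq.csv"))
  for (exp_type in names(sc@spectra))
    writeSpectra(sc@spectra[[exp_type]],
                 file.path(dir, sprintf("spectra_%s.csv", exp_type)))
  truth <- list(nPairs = sc@truth@nPairs, seed = sc@truth@seed,
                featureEffects = as.list(sc@truth@featureEffects),
                censorFraction = as.list(sc@truth@censorFraction),
                noiseSd = sc@truth@noiseSd,
                covariateModel = sc@truth@covariateModel)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
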
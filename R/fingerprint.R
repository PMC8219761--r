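## Untargeted spectral fingerprint machinery: fixed-width bucketing,
## water-region removal, total-integral normalization, PCA screening and
## OPLS-DA with Monte Carlo cross-validation and permutation testing.

## exact integrals of the piecewise-linear spectra over each [left, right]
## bin; `x` ascending, `y` subjects-by-points, `edges` bins-by-2
.binIntegrals <- function(x, y, edges) {
  h <- sweep((y[, -1, drop = FALSE] + y[, -ncol(y), drop = FALSE]) / 2,
             2L, diff(x), `*`)
  cum <- cbind(0, t(apply(h, 1L, cumsum)))   # antiderivative at grid points
  evalC <- function(t) {
    k <- findInterval(t, x, rightmost.closed = TRUE)
    k <- min(max(k, 1L), length(x) - 1L)
    frac <- (t - x[k]) / (x[k + 1L] - x[k])
    yt <- y[, k] + frac * (y[, k + 1L] - y[, k])
    cum[, k] + (t - x[k]) * (y[, k] + yt) / 2
  }
  bounds <- sort(unique(as.vector(edges)))
  Cb <- vapply(bounds, evalC, numeric(nrow(y)))
  if (nrow(y) == 1L) Cb <- matrix(Cb, nrow = 1L)
  Cb[, match(edges[, 2L], bounds), drop = FALSE] -
    Cb[, match(edges[, 1L], bounds), drop = FALSE]
}

#' Bucket spectra into fixed-width chemical-shift bins
#'
#' Bins are defined by left edges \code{left + k * width} for
#' \code{k = 0..floor((right - left)/width)} inclusive — 491 bins for the
#' defaults (0.20 to 10.00 ppm, 0.02 ppm wide, the last bin covering
#' 10.00-10.02 ppm). Each bin value is the integral of the
#' piecewise-linear intensity over the bin, in ppm units.
#'
#' @param spectra a \linkS4class{SpectrumSet}.
#' @param left,right first and last left bin edge in ppm (defaults 0.20
#'   and 10.00).
#' @param width bin width in ppm (default 0.02).
#' @return a \linkS4class{BinnedMatrix} (pre-water-removal,
#'   unnormalized).
#' @export
bucketSpectra <- function(spectra, left = 0.20, right = 10.00,
                          width = 0.02) {
  if (width <= 0) stop("parameter error: width must be positive")
  ppm <- spectra@ppm
  if (min(ppm) > left + 1e-9 || max(ppm) < right + width - 1e-9)
    stop(sprintf(
      "coverage error: spectrum spans %.3f..%.3f ppm but %.2f..%.2f is required",
      min(ppm), max(ppm), left, right + width))
  k <- 0:floor((right - left) / width + 1e-9)
  edges <- cbind(left = left + k * width, right = left + (k + 1) * width)
  ord <- order(ppm)                      # ascending for integration
  x <- ppm[ord]
  y <- spectra@intensity[, ord, drop = FALSE]
  vals <- .binIntegrals(x, y, edges)
  dimnames(vals) <- list(rownames(y), NULL)
  methods::new("BinnedMatrix", values = vals, binEdges = edges,
               normalized = FALSE, experiment = spectra@experiment)
}

#' Remove the residual-water region
#'
#' Drops every bin whose left edge lies in \code{[low, high - width]};
#' with the default 0.02 ppm bins and the 4.40-5.12 ppm window this
#' removes 36 bins, reducing the default 491-bin matrix to 455 bins.
#'
#' @param binned an unnormalized \linkS4class{BinnedMatrix}.
#' @param low,high water window in ppm (defaults 4.40 and 5.12).
#' @return the reduced \linkS4class{BinnedMatrix}.
#' @export
removeWater <- function(binned, low = 4.40, high = 5.12) {
  if (low >= high) stop("parameter error: low must be below high")
  if (isTRUE(binned@normalized))
    stop("structure error: remove the water region before normalization")
  width <- binned@binEdges[1L, "right"] - binned@binEdges[1L, "left"]
  drop <- binned@binEdges[, "left"] >= low - 1e-9 &
    binned@binEdges[, "left"] <= high - width + 1e-9
  if (all(drop)) stop("structure error: no bins left after water removal")
  methods::new("BinnedMatrix",
               values = binned@values[, !drop, drop = FALSE],
               binEdges = binned@binEdges[!drop, , drop = FALSE],
               normalized = FALSE, experiment = binned@experiment)
}

#' Total-integral normalization
#'
#' Divides each subject's bin vector by its own total area, removing
#' dilution and overall-intensity differences; rows then sum to one.
#'
#' @param binned a water-removed \linkS4class{BinnedMatrix}.
#' @return the normalized \linkS4class{BinnedMatrix}.
#' @export
normalizeTotalIntegral <- function(binned) {
  rs <- rowSums(binned@values)
  if (any(rs <= 0))
    stop("value error: zero or negative total spectral area for subject(s) ",
         paste(rownames(binned@values)[rs <= 0], collapse = ", "))
  methods::new("BinnedMatrix", values = binned@values / rs,
               binEdges = binned@binEdges, normalized = TRUE,
               experiment = binned@experiment)
}

#' PCA screening with Hotelling T-squared outlier flags
#'
#' Mean-centered principal component analysis of the normalized bin
#' matrix; a subject is flagged when its Hotelling T-squared over the
#' retained components exceeds the 97.5\% quantile of the
#' \eqn{k(n-1)/(n-k) F_{k,n-k}} reference distribution.
#'
#' @param binned a normalized \linkS4class{BinnedMatrix} (or matrix).
#' @param nComponents number of components to retain.
#' @return list with \code{scores}, \code{loadings},
#'   \code{explained_variance} (proportions), \code{t2},
#'   \code{outlier} (logical).
#' @export
pcaScreen <- function(binned, nComponents = 2L) {
  X <- if (methods::is(binned, "BinnedMatrix")) binned@values else binned
  n <- nrow(X)
  if (nComponents > min(n, ncol(X)) || nComponents >= n)
    stop("parameter error: too many components for the matrix size")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  k <- nComponents
  scores <- pc$x[, seq_len(k), drop = FALSE]
  lambda <- pc$sdev[seq_len(k)]^2
  lambda[lambda < .Machine$double.eps] <- NA_real_
  t2 <- rowSums(sweep(scores^2, 2L, lambda, `/`), na.rm = TRUE)
  thresh <- k * (n - 1) / (n - k) * qf(0.975, k, n - k)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, loadings = pc$rotation[, seq_len(k), drop = FALSE],
       explained_variance = ev, t2 = t2, outlier = t2 > thresh)
}

.codeClasses <- function(y, positiveClass = NULL) {
  lv <- sort(unique(as.character(y)))
  if (length(lv) != 2L)
    stop("label error: exactly two classes are required")
  if (is.null(positiveClass))
    positiveClass <- if ("high_mbd" %in% lv) "high_mbd" else lv[2L]
  if (!positiveClass %in% lv)
    stop("label error: positive class not among the labels")
  coding <- setNames(ifelse(lv == positiveClass, 1, -1), lv)
  list(coded = unname(coding[as.character(y)]), coding = coding,
       positive = positiveClass)
}

#' Fit a single-response OPLS-DA model
#'
#' Classes are coded -1/+1 and columns mean-centered with the training
#' means. The predictive weight is \eqn{w \propto X^\top y}; each of the
#' \code{nOrthogonal} components is extracted by orthogonalizing the
#' current loading against \eqn{w}
#' (\eqn{w_o \propto p - (w^\top p)\,w}) and deflating \eqn{X} by the
#' resulting score/loading pair; the predictive component is then fit on
#' the fully deflated matrix. With \code{nOrthogonal = 0} this is exactly
#' single-component PLS-DA.
#'
#' @param X subjects-by-bins matrix or \linkS4class{BinnedMatrix}.
#' @param y two-class label vector (one per row of X).
#' @param nOrthogonal number of orthogonal components (>= 0).
#' @param positiveClass label coded +1 (default \code{"high_mbd"} when
#'   present, else the lexicographically larger label).
#' @return an \linkS4class{OplsdaModel}.
#' @export
oplsdaFit <- function(X, y, nOrthogonal = 0L, positiveClass = NULL) {
  if (methods::is(X, "BinnedMatrix")) X <- X@values
  X <- as.matrix(X)
  cls <- .codeClasses(y, positiveClass)
  yc <- cls$coded
  if (min(table(yc)) < 2L)
    stop("label error: each class needs at least 2 subjects")
  nOrthogonal <- as.integer(nOrthogonal)
  if (nOrthogonal < 0L) stop("parameter error: nOrthogonal must be >= 0")
  if (nOrthogonal >= min(dim(X)))
    stop("rank error: nOrthogonal must be below the matrix rank")
  mu <- colMeans(X)
  E <- sweep(X, 2L, mu)
  w <- drop(crossprod(E, yc))
  wn <- sqrt(sum(w^2))
  if (wn == 0) stop("rank error: degenerate class-covariance weight")
  w <- w / wn
  p_dim <- ncol(E)
  Wo <- matrix(0, p_dim, nOrthogonal)
  Po <- matrix(0, p_dim, nOrthogonal)
  To <- matrix(0, nrow(E), nOrthogonal)
  for (j in seq_len(nOrthogonal)) {
    t_pred <- drop(E %*% w)
    p_load <- drop(crossprod(E, t_pred)) / sum(t_pred^2)
    wo <- p_load - sum(w * p_load) * w
    won <- sqrt(sum(wo^2))
    if (won < 1e-12)
      stop("rank error: no orthogonal variation left at component ", j)
    wo <- wo / won
    to <- drop(E %*% wo)
    po <- drop(crossprod(E, to)) / sum(to^2)
    E <- E - tcrossprod(to, po)
    Wo[, j] <- wo; Po[, j] <- po; To[, j] <- to
  }
  t_pred <- drop(E %*% w)
  p_load <- drop(crossprod(E, t_pred)) / sum(t_pred^2)
  methods::new("OplsdaModel", weightsPred = w, loadingsPred = p_load,
               scoresPred = t_pred, weightsOrtho = Wo, loadingsOrtho = Po,
               scoresOrtho = To, columnMeans = mu, classCoding = cls$coding,
               nOrthogonal = nOrthogonal)
}

#' Predict classes with a fitted OPLS-DA model
#'
#' New rows are centered with the training means, deflated by the
#' orthogonal components, projected on the predictive weight and
#' classified by the sign of the score (threshold 0).
#'
#' @param model an \linkS4class{OplsdaModel}.
#' @param newX matrix or \linkS4class{BinnedMatrix} of new subjects.
#' @return list with \code{scores} (predictive scores) and \code{class}
#'   (predicted labels).
#' @export
oplsdaPredict <- function(model, newX) {
  if (methods::is(newX, "BinnedMatrix")) newX <- newX@values
  E <- sweep(as.matrix(newX), 2L, model@columnMeans)
  for (j in seq_len(model@nOrthogonal)) {
    to <- drop(E %*% model@weightsOrtho[, j])
    E <- E - tcrossprod(to, model@loadingsOrtho[, j])
  }
  sc <- drop(E %*% model@weightsPred)
  lv <- names(model@classCoding)
  pred <- ifelse(sc > 0, lv[model@classCoding > 0], lv[model@classCoding < 0])
  list(scores = sc, class = pred)
}

.confusion <- function(truth, pred, positive) {
  tp <- sum(truth == positive & pred == positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  c(accuracy = (tp + tn) / length(truth),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

.mccvCycles <- function(X, y, nOrthogonal, nCycles, trainFraction,
                        positiveClass) {
  lv <- sort(unique(as.character(y)))
  positive <- if (is.null(positiveClass)) {
    if ("high_mbd" %in% lv) "high_mbd" else lv[2L]
  } else positiveClass
  idx_by_class <- split(seq_along(y), as.character(y))
  n_test <- vapply(idx_by_class, function(i)
    max(1L, as.integer(round(length(i) * (1 - trainFraction)))), integer(1))
  if (any(vapply(idx_by_class, length, integer(1)) - n_test < 2L))
    stop("parameter error: not enough subjects per class for the split")
  rates <- matrix(NA_real_, nCycles, 3L,
                  dimnames = list(NULL, c("accuracy", "sensitivity",
                                          "specificity")))
  for (cyc in seq_len(nCycles)) {
    fit <- NULL
    for (attempt in 1:10) {
      test_idx <- unlist(lapply(names(idx_by_class), function(cl)
        sample(idx_by_class[[cl]], n_test[[cl]])))
      train_idx <- setdiff(seq_along(y), test_idx)
      fit <- tryCatch(
        oplsdaFit(X[train_idx, , drop = FALSE], y[train_idx],
                  nOrthogonal = nOrthogonal, positiveClass = positive),
        error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit)) stop("degenerate fold: 10 redraws exhausted")
    pred <- oplsdaPredict(fit, X[test_idx, , drop = FALSE])
    rates[cyc, ] <- .confusion(as.character(y)[test_idx], pred$class,
                               positive)
  }
  rates
}

#' Monte Carlo cross-validation of an OPLS-DA classifier
#'
#' Per cycle: a stratified random split reserves \code{1 - trainFraction}
#' of each class for testing, the model is fit on the rest and accuracy,
#' sensitivity and specificity (high-MBD as the positive class) are
#' computed on the held-out subjects; rates are averaged over cycles.
#'
#' @param X subjects-by-bins matrix or \linkS4class{BinnedMatrix}.
#' @param y two-class labels.
#' @param nOrthogonal orthogonal components of each fit.
#' @param nCycles number of random splits (default 100).
#' @param trainFraction training share (default 0.9).
#' @param seed optional integer; when given, the draw stream is private.
#' @param positiveClass see [oplsdaFit()].
#' @return an \linkS4class{MccvResult} (no permutation p).
#' @export
mccv <- function(X, y, nOrthogonal = 0L, nCycles = 100L,
                 trainFraction = 0.9, seed = NULL, positiveClass = NULL) {
  if (methods::is(X, "BinnedMatrix")) X <- X@values
  run <- function() .mccvCycles(X, y, nOrthogonal, nCycles, trainFraction,
                                positiveClass)
  rates <- if (is.null(seed)) run() else .withSeed(seed, run())
  methods::new("MccvResult", nCycles = as.integer(nCycles),
               accuracy = rates[, "accuracy"],
               sensitivity = rates[, "sensitivity"],
               specificity = rates[, "specificity"],
               permutationP = numeric(0), nPermutations = 0L,
               nullAccuracy = numeric(0))
}

#' Permutation test of MCCV classification accuracy
#'
#' The null distribution is the mean MCCV accuracy recomputed after
#' randomly permuting the class labels, \code{nPermutations} times;
#' \code{p = (1 + #\{null >= observed\}) / (nPermutations + 1)} (add-one
#' estimator, so the attainable minimum is \code{1/(nPermutations + 1)}).
#'
#' @inheritParams mccv
#' @param nPermutations number of label permutations (default 100).
#' @return an \linkS4class{MccvResult} with \code{permutationP} and the
#'   null accuracy distribution filled in.
#' @export
permutationTest <- function(X, y, nOrthogonal = 0L, nCycles = 100L,
                            nPermutations = 100L, trainFraction = 0.9,
                            seed = NULL, positiveClass = NULL) {
  if (nPermutations < 1L)
    stop("parameter error: nPermutations must be >= 1")
  if (methods::is(X, "BinnedMatrix")) X <- X@values
  run <- function() {
    obs <- .mccvCycles(X, y, nOrthogonal, nCycles, trainFraction,
                       positiveClass)
    null_acc <- vapply(seq_len(nPermutations), function(b) {
      yp <- sample(y)
      mean(.mccvCycles(X, yp, nOrthogonal, nCycles, trainFraction,
                       positiveClass)[, "accuracy"])
    }, numeric(1))
    list(obs = obs, null = null_acc)
  }
  res <- if (is.null(seed)) run() else .withSeed(seed, run())
  obs_acc <- mean(res$obs[, "accuracy"])
  pval <- (1 + sum(res$null >= obs_acc)) / (nPermutations + 1)
  methods::new("MccvResult", nCycles = as.integer(nCycles),
               accuracy = res$obs[, "accuracy"],
               sensitivity = res$obs[, "sensitivity"],
               specificity = res$obs[, "specificity"],
               permutationP = pval, nPermutations = as.integer(nPermutations),
               nullAccuracy = res$null)
}
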
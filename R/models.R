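#' Construct a substitution model
#'
#' @param name model name.
#' @param exchangeabilities symmetric 20x20 non-negative matrix (diagonal
#'   ignored).
#' @param frequencies stationary frequencies (positive, renormalized to sum
#'   1).
#' @param gammaShape optional positive shape for discrete-gamma rate
#'   heterogeneity (`NULL` = homogeneous rates).
#' @param nRateCategories number of discrete gamma categories (default 4,
#'   category rates at category means).
#' @return A [SubstitutionModel-class].
#' @export
substitutionModel <- function(name, exchangeabilities, frequencies,
                              gammaShape = NULL, nRateCategories = 4L) {
  S <- as.matrix(exchangeabilities)
  diag(S) <- 0
  p <- frequencies / sum(frequencies)
  new("SubstitutionModel", name = name, exchangeabilities = S,
      frequencies = as.numeric(p),
      gammaShape = if (is.null(gammaShape)) numeric(0) else as.numeric(gammaShape),
      nRateCategories = if (is.null(gammaShape)) 1L else as.integer(nRateCategories))
}

#' Poisson (equal-rates, equal-frequencies) amino-acid model
#'
#' @inheritParams substitutionModel
#' @return A [SubstitutionModel-class].
#' @export
poissonModel <- function(gammaShape = NULL, nRateCategories = 4L) {
  S <- matrix(1, 20, 20); diag(S) <- 0
  substitutionModel(if (is.null(gammaShape)) "Poisson" else
                      paste0("Poisson+G", nRateCategories),
                    S, rep(1 / 20, 20), gammaShape, nRateCategories)
}

#' Empirical amino-acid models (LG, WAG, JTT, ...)
#'
#' Exchangeabilities and stationary frequencies are taken from the published
#' matrices as shipped with \pkg{phangorn}; frequencies default to the
#' matrix's own but can be overridden (e.g. with observed frequencies, the
#' "+F" convention).
#'
#' @param name one of `"LG"`, `"WAG"`, `"JTT"` (any matrix known to
#'   \pkg{phangorn} is accepted).
#' @param frequencies optional replacement frequency vector.
#' @inheritParams substitutionModel
#' @return A [SubstitutionModel-class].
#' @export
empiricalModel <- function(name, gammaShape = NULL, nRateCategories = 4L,
                           frequencies = NULL) {
  ns <- asNamespace("phangorn")
  obj <- tryCatch(get(paste0(".", name), envir = ns),
                  error = function(e) NULL)
  if (is.null(obj) || !all(c("Q", "bf") %in% names(obj)))
    stop("unknown empirical model: ", name)
  S <- matrix(0, 20, 20)
  S[lower.tri(S)] <- obj$Q
  S <- S + t(S)
  p <- if (is.null(frequencies)) as.numeric(obj$bf) else frequencies
  label <- name
  if (!is.null(frequencies)) label <- paste0(label, "+F")
  if (!is.null(gammaShape)) label <- paste0(label, "+G", nRateCategories)
  substitutionModel(label, S, p, gammaShape, nRateCategories)
}

#' Build the normalized instantaneous rate matrix
#'
#' Q is assembled as `Q_ij = s_ij * pi_j` for `i != j`, the diagonal set so
#' rows sum to zero, then rescaled so the expected substitution rate at
#' stationarity, `-sum_i pi_i Q_ii`, equals 1 (branch lengths are then in
#' expected substitutions per site).
#'
#' @param model a [SubstitutionModel-class].
#' @return 20x20 generator matrix with `aminoAcids()` dimnames.
#' @export
buildRateMatrix <- function(model) {
  p <- model@frequencies
  if (any(p <= 0)) stop("zero or negative frequency in model ", model@name)
  Q <- model@exchangeabilities * rep(p, each = 20L)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(p * diag(Q))
  Q <- Q / mu
  dimnames(Q) <- list(aminoAcids(), aminoAcids())
  Q
}

#' Eigendecomposition of a reversible generator
#'
#' Decomposes the similarity-transformed (symmetric) generator
#' `B = diag(sqrt(pi)) Q diag(1/sqrt(pi))` so transition probabilities can be
#' computed stably for any branch length. Internal building block of the
#' likelihood engine; exported for audit.
#'
#' @param model a [SubstitutionModel-class].
#' @return List with eigenvalues `lambda`, eigenvectors `U`, frequencies
#'   `pi`, and `sqrtPi`.
#' @export
modelEigen <- function(model) {
  Q <- buildRateMatrix(model)
  sp <- sqrt(model@frequencies)
  B <- Q * (sp %o% (1 / sp))
  B <- (B + t(B)) / 2   # symmetrize against rounding
  e <- eigen(B, symmetric = TRUE)
  list(lambda = e$values, U = e$vectors, pi = model@frequencies, sqrtPi = sp)
}

#' Transition probability matrix P(t)
#'
#' @param eig a decomposition from [modelEigen()] (or a
#'   [SubstitutionModel-class], decomposed on the fly).
#' @param t branch length (expected substitutions/site), `t >= 0`.
#' @param rate positive rate multiplier (e.g. a discrete-gamma category
#'   rate).
#' @return Row-stochastic 20x20 matrix.
#' @export
transitionProbs <- function(eig, t, rate = 1) {
  if (is(eig, "SubstitutionModel")) eig <- modelEigen(eig)
  if (t < 0) stop("negative branch length")
  if (rate <= 0) stop("rate must be positive")
  ev <- exp(eig$lambda * t * rate)
  P <- sweep(eig$U, 1L, eig$sqrtPi, "/") %*%
    (ev * t(sweep(eig$U, 1L, eig$sqrtPi, "*")))
  P[P < 0] <- 0
  dimnames(P) <- list(aminoAcids(), aminoAcids())
  P
}

#' Discrete-gamma category rates
#'
#' Mean-one gamma with shape `alpha` discretized into `k` equiprobable
#' categories; each category's rate is the category mean (not median).
#'
#' @param alpha positive shape.
#' @param k number of categories.
#' @return Numeric vector of `k` rates with mean 1.
#' @export
discreteGammaRates <- function(alpha, k = 4L) {
  if (alpha <= 0) stop("gamma shape must be positive")
  if (k == 1L) return(1)
  b <- stats::qgamma(seq_len(k - 1L) / k, shape = alpha, rate = alpha)
  Fb <- c(0, stats::pgamma(b, shape = alpha + 1, rate = alpha), 1)
  k * diff(Fb)
}

## category rates for a model (1 if homogeneous)
modelRates <- function(model) {
  if (!length(model@gammaShape)) return(1)
  discreteGammaRates(model@gammaShape, model@nRateCategories)
}
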
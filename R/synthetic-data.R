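## Default generator constants mirror the packaged chalcone training set:
## 25 compounds, four correlated descriptors with the observed means, spreads
## and pairwise correlations, the fitted linear response, and noise at the
## scale of the model's residual standard error.
.SYNTH_NAMES <- c("BCUT_SMR_2", "logP(o/w)", "SlogP_VSA4", "vsurf_IW3")
.SYNTH_MEANS <- c(0.8298, 4.3781, 16.7906, 1.8713)
.SYNTH_SDS <- c(0.0435, 0.3929, 13.5542, 0.7820)
.SYNTH_CORR <- matrix(c(
     1.0000, -0.4640, -0.5413,  0.2441,
    -0.4640,  1.0000,  0.0986, -0.5042,
    -0.5413,  0.0986,  1.0000,  0.1923,
     0.2441, -0.5042,  0.1923,  1.0000), 4, 4)
.SYNTH_COEFS <- c(8.469, 0.636, 0.057, -0.442)
.SYNTH_INTERCEPT <- -3.754
.SYNTH_NOISE_SD <- 0.29

#' Specification for synthetic QSAR datasets
#'
#' Describes a multivariate-normal descriptor block with a linear Gaussian
#' activity response and an 80/20 train/test split — the statistical
#' structure the modelling pipeline assumes. The defaults mirror the packaged
#' chalcone MAO-B training set (its descriptor means, spreads, correlation
#' structure, fitted coefficients and residual scale), so default draws
#' resemble that regime.
#'
#' @param n number of compounds (at least 8).
#' @param descriptorNames character vector of length p.
#' @param means,sds numeric vectors of length p.
#' @param correlation p x p positive-definite correlation matrix
#'   (unit diagonal).
#' @param coefficients true linear coefficients, length p.
#' @param intercept true intercept.
#' @param noiseSd standard deviation of the Gaussian activity noise
#'   (>= 0).
#' @param trainFraction fraction assigned to the training set.
#' @param seed integer seed.
#' @return a list of class \code{"qsarSyntheticSpec"}.
#' @seealso [generateDataset()], [generateNullDataset()]
#' @export
syntheticSpec <- function(n = 25L,
                          descriptorNames = .SYNTH_NAMES,
                          means = .SYNTH_MEANS,
                          sds = .SYNTH_SDS,
                          correlation = .SYNTH_CORR,
                          coefficients = .SYNTH_COEFS,
                          intercept = .SYNTH_INTERCEPT,
                          noiseSd = .SYNTH_NOISE_SD,
                          trainFraction = 0.8,
                          seed = 1L) {
    p <- length(descriptorNames)
    stopifnot(n >= 8L, length(means) == p, length(sds) == p,
              all(sds > 0), length(coefficients) == p, noiseSd >= 0,
              trainFraction > 0, trainFraction <= 1)
    correlation <- as.matrix(correlation)
    if (!isTRUE(all.equal(correlation, t(correlation))) ||
        !isTRUE(all.equal(unname(diag(correlation)), rep(1, p))))
        stop("'correlation' must be symmetric with unit diagonal")
    ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
        stop("'correlation' must be positive definite")
    spec <- list(n = as.integer(n), descriptorNames = descriptorNames,
                 means = means, sds = sds, correlation = correlation,
                 coefficients = coefficients, intercept = intercept,
                 noiseSd = noiseSd, trainFraction = trainFraction,
                 seed = as.integer(seed))
    class(spec) <- "qsarSyntheticSpec"
    spec
}

.drawDescriptors <- function(spec) {
    Sigma <- diag(spec$sds) %*% spec$correlation %*% diag(spec$sds)
    X <- MASS::mvrnorm(spec$n, mu = spec$means, Sigma = Sigma)
    dimnames(X) <- list(sprintf("synth%02d", seq_len(spec$n)),
                        spec$descriptorNames)
    X
}

.assignSplit <- function(n, trainFraction) {
    nTrain <- round(n * trainFraction)
    idx <- sample.int(n, nTrain)
    lab <- rep("test", n)
    lab[idx] <- "train"
    lab
}

#' Generate a synthetic QSAR dataset
#'
#' Draws descriptors from the specified multivariate normal, computes the
#' activity as \eqn{a_0 + \sum_j a_j x_j + \epsilon} with Gaussian noise, and
#' assigns a random train/test split. The same spec (including seed) always
#' produces the identical dataset; the caller's RNG state is untouched. The
#' seed is recorded in the dataset's metadata.
#'
#' @param spec a [syntheticSpec()].
#' @return a [QSARDataset-class] with \code{n} compounds.
#' @examples
#' ds <- generateDataset(syntheticSpec(seed = 7))
#' fitQSAR(ds)
#' @export
generateDataset <- function(spec) {
    stopifnot(inherits(spec, "qsarSyntheticSpec"))
    withSeed(spec$seed, {
        X <- .drawDescriptors(spec)
        y <- spec$intercept + drop(X %*% spec$coefficients) +
            stats::rnorm(spec$n, sd = spec$noiseSd)
        lab <- .assignSplit(spec$n, spec$trainFraction)
        ds <- QSARDataset(X, activity = y, split = lab)
        S4Vectors::metadata(ds)$seed <- spec$seed
        ds
    })
}

#' Generate a null (response-scrambled) dataset
#'
#' As [generateDataset()], but the activity is decoupled from the descriptors
#' by permuting the response across compounds — the data-generating regime a
#' Y-randomization test emulates. Fits on such data should show R2 near
#' p/(n-1) and predominantly negative leave-one-out Q2.
#'
#' @param spec a [syntheticSpec()].
#' @return a [QSARDataset-class].
#' @examples
#' looCrossValidation(generateNullDataset(syntheticSpec(seed = 3)))$q2
#' @export
generateNullDataset <- function(spec) {
    stopifnot(inherits(spec, "qsarSyntheticSpec"))
    withSeed(spec$seed, {
        X <- .drawDescriptors(spec)
        y <- spec$intercept + drop(X %*% spec$coefficients) +
            stats::rnorm(spec$n, sd = spec$noiseSd)
        y <- y[sample.int(spec$n)]   # break the descriptor-response link
        lab <- .assignSplit(spec$n, spec$trainFraction)
        ds <- QSARDataset(X, activity = y, split = lab)
        S4Vectors::metadata(ds)$seed <- spec$seed
        S4Vectors::metadata(ds)$null <- TRUE
        ds
    })
}
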
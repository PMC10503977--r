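## Internal: ordinary least-squares fit of activity on the descriptor matrix.
## Returns the lm object plus the name mapping used to build the formula.
.olsFit <- function(X, y) {
    safe <- make.names(colnames(X), unique = TRUE)
    df <- as.data.frame(X)
    colnames(df) <- safe
    df$.y <- y
    fit <- stats::lm(.y ~ ., data = df)
    co <- stats::coef(fit)
    if (anyNA(co)) {
        bad <- safe %in% names(co)[is.na(co)]
        stop("descriptor matrix is rank deficient; collinear column(s): ",
             paste(colnames(X)[bad], collapse = ", "))
    }
    list(fit = fit, safe = safe, names = colnames(X))
}

#' Fit the linear QSAR activity model
#'
#' Ordinary least-squares regression of pIC50 on the descriptors of the
#' training compounds, the multiple-linear-regression form
#' \eqn{Y = a_0 + a_1 X_1 + \dots + a_p X_p} (a partial-least-squares fit that
#' retains all latent components gives the identical solution, so OLS is used
#' for its determinism).
#'
#' @param x a [QSARDataset-class] whose train subset has more than
#'   \eqn{p + 1} compounds and a full-rank descriptor matrix.
#' @param subset compounds to fit on, \code{"train"} by default.
#' @return a [QSARModel-class].
#' @examples
#' fitQSAR(qsarFixture("table4"))
#' @export
fitQSAR <- function(x, subset = c("train", "all")) {
    subset <- match.arg(subset)
    X <- descriptorMatrix(x, subset)
    y <- activityValues(x, subset)
    if (anyNA(X))
        stop("missing descriptor values in the fitting subset")
    if (anyNA(y))
        stop("missing activity values in the fitting subset")
    if (nrow(X) <= ncol(X) + 1L)
        stop("need more than p + 1 compounds to fit ", ncol(X),
             " descriptors (got ", nrow(X), ")")
    ols <- .olsFit(X, y)
    co <- stats::coef(ols$fit)
    new("QSARModel",
        intercept = unname(co[1]),
        coefficients = stats::setNames(unname(co[-1]), ols$names),
        descriptorNames = ols$names,
        nTrain = nrow(X),
        trainIds = rownames(X))
}

#' Predict activity for compounds
#'
#' Evaluates the fitted linear equation \eqn{a_0 + \sum_j a_j x_j} for each
#' compound of \code{newdata}.
#'
#' @param object a [QSARModel-class].
#' @param newdata a [QSARDataset-class], or a matrix/data frame with (at
#'   least) the model's descriptor columns.
#' @param subset for a \code{QSARDataset}, which compounds to predict
#'   (\code{"all"} by default).
#' @param ... unused.
#' @return named numeric vector of predicted pIC50 values.
#' @examples
#' ds <- qsarFixture("table4")
#' mod <- fitQSAR(ds)
#' predict(mod, testSet(ds))
#' @export
setMethod("predict", "QSARModel", function(object, newdata,
                                           subset = "all", ...) {
    X <- if (is(newdata, "QSARDataset"))
        descriptorMatrix(newdata, subset)
    else as.matrix(as.data.frame(newdata)[, , drop = FALSE])
    missing <- setdiff(object@descriptorNames, colnames(X))
    if (length(missing))
        stop("descriptor(s) absent from newdata: ",
             paste(missing, collapse = ", "))
    X <- X[, object@descriptorNames, drop = FALSE]
    if (anyNA(X)) {
        bad <- which(rowSums(is.na(X)) > 0)[1]
        badcol <- colnames(X)[which(is.na(X[bad, ]))[1]]
        stop(sprintf("missing value of descriptor '%s' for compound '%s'",
                     badcol, rownames(X)[bad]))
    }
    drop(object@intercept + X %*% object@coefficients)
})

#' Goodness-of-fit statistics of a QSAR model
#'
#' Computes, on the model's training compounds, the determination coefficient
#' \eqn{r^2 = 1 - SSE/SST}, the adjusted
#' \eqn{r^2_a = ((n-1) r^2 - p)/(n - 1 - p)}, the root-mean-square error, the
#' mean absolute error, the Fisher statistic
#' \eqn{F = ((SST-SSE)/p) / (SSE/(n-p-1))}, and two-sided t-test p-values for
#' each coefficient.
#'
#' The fit RMSE uses the residual-standard-error convention
#' \eqn{\sqrt{SSE/(n-p-1)}} by default; \code{rmseDenominator = "n"} selects
#' the plain \eqn{\sqrt{SSE/n}} form used for cross-validated errors.
#'
#' @param model a [QSARModel-class].
#' @param x the [QSARDataset-class] it was fitted on.
#' @param subset compounds to evaluate on (the training set by default; the
#'   statistics assume the model was fitted on this subset).
#' @param rmseDenominator \code{"df"} (residual degrees of freedom,
#'   default) or \code{"n"}.
#' @return a list of class \code{"qsarFitStats"} with elements \code{r2},
#'   \code{r2Adj}, \code{rmse}, \code{mae}, \code{fStat}, \code{sse},
#'   \code{sst}, \code{n}, \code{p}, \code{coefPValues}, \code{residuals}.
#' @examples
#' ds <- qsarFixture("table4")
#' fitStatistics(fitQSAR(ds), ds)
#' @export
fitStatistics <- function(model, x, subset = c("train", "all"),
                          rmseDenominator = c("df", "n")) {
    subset <- match.arg(subset)
    rmseDenominator <- match.arg(rmseDenominator)
    X <- descriptorMatrix(x, subset)
    y <- activityValues(x, subset)
    pred <- predict(model, x, subset = subset)
    res <- y - pred
    n <- length(y)
    p <- length(model@coefficients)
    sse <- sum(res^2)
    sst <- sum((y - mean(y))^2)
    if (sst == 0)
        stop("constant activity: r2 undefined (SST = 0)")
    r2 <- 1 - sse / sst
    r2Adj <- ((n - 1) * r2 - p) / (n - 1 - p)
    denom <- if (rmseDenominator == "df") n - p - 1 else n
    ## two-sided t tests of the coefficients, from the same OLS fit
    ols <- .olsFit(X[, model@descriptorNames, drop = FALSE], y)
    ## summary.lm warns on an essentially perfect fit; p-values are then
    ## meaningless but the remaining statistics are still well defined
    pv <- suppressWarnings(summary(ols$fit)$coefficients[-1, 4])
    out <- list(
        r2 = r2, r2Adj = r2Adj,
        rmse = sqrt(sse / denom),
        mae = mean(abs(res)),
        fStat = ((sst - sse) / p) / (sse / (n - p - 1)),
        sse = sse, sst = sst, n = n, p = p,
        coefPValues = stats::setNames(unname(pv), ols$names),
        residuals = res)
    class(out) <- "qsarFitStats"
    out
}

#' @export
print.qsarFitStats <- function(x, ...) {
    cat(sprintf(
        "QSAR fit on %d compounds, %d descriptors\n  r2 = %.4f  r2adj = %.4f  RMSE = %.4f  MAE = %.4f  F = %.2f\n",
        x$n, x$p, x$r2, x$r2Adj, x$rmse, x$mae, x$fStat))
    invisible(x)
}
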
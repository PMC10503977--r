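#' Correlation matrix of descriptors and activity
#'
#' Pearson correlations between every pair of descriptors and between each
#' descriptor and pIC50. By convention the matrix is computed on the training
#' compounds (descriptor screening belongs to model building); set
#' \code{subset = "all"} to use every compound.
#'
#' Constant columns have no defined correlation; their rows/columns are NA and
#' their names are reported in the \code{"undefined"} attribute.
#'
#' @param x a [QSARDataset-class] with at least 3 compounds in the subset.
#' @param subset \code{"train"} (default) or \code{"all"}.
#' @return symmetric numeric matrix over the descriptors plus \code{pIC50},
#'   with unit diagonal.
#' @examples
#' round(correlationMatrix(qsarFixture("table4")), 4)
#' @export
correlationMatrix <- function(x, subset = c("train", "all")) {
    subset <- match.arg(subset)
    X <- descriptorMatrix(x, subset)
    y <- activityValues(x, subset)
    if (nrow(X) < 3L)
        stop("at least 3 compounds are required for correlations")
    M <- cbind(X, pIC50 = y)
    sds <- apply(M, 2, stats::sd)
    const <- names(sds)[sds == 0 | is.na(sds)]
    R <- suppressWarnings(stats::cor(M))
    R[const, ] <- NA_real_
    R[, const] <- NA_real_
    diag(R) <- ifelse(colnames(M) %in% const, NA_real_, 1)
    attr(R, "undefined") <- const
    R
}

## r2 of descriptor j regressed (with intercept) on the remaining descriptors
.vifOne <- function(X, j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    res <- fit$residuals
    tot <- sum((X[, j] - mean(X[, j]))^2)
    if (tot == 0) return(NA_real_)
    r2 <- 1 - sum(res^2) / tot
    1 / (1 - r2)
}

#' Variance inflation factors of the descriptors
#'
#' For each descriptor \eqn{j}, \eqn{VIF_j = 1/(1 - r_j^2)} where
#' \eqn{r_j^2} is the coefficient of determination of descriptor \eqn{j}
#' regressed, with intercept, on the remaining descriptors. Tolerance is the
#' reciprocal. A descriptor exactly expressible from the others (rank
#' deficiency) gets an infinite VIF.
#'
#' @param x a [QSARDataset-class].
#' @param subset \code{"train"} (default) or \code{"all"}.
#' @return named numeric vector of VIFs (\code{toleranceValues} returns the
#'   reciprocals).
#' @examples
#' round(vifValues(qsarFixture("table4")), 4)
#' @export
vifValues <- function(x, subset = c("train", "all")) {
    subset <- match.arg(subset)
    X <- descriptorMatrix(x, subset)
    if (nrow(X) < ncol(X) + 2L)
        stop("need at least p + 2 compounds to compute VIFs")
    v <- vapply(seq_len(ncol(X)), function(j) .vifOne(X, j), numeric(1))
    v[v < 0 | v > 1e12] <- Inf   # numerically exact collinearity
    stats::setNames(v, colnames(X))
}

#' @rdname vifValues
#' @export
toleranceValues <- function(x, subset = c("train", "all")) {
    1 / vifValues(x, subset)
}

#' Pre-model descriptor screening
#'
#' Applies, in order: (1) a variance filter removing constant (or
#' below-threshold-variance) descriptors; (2) a response-correlation filter
#' removing descriptors with \eqn{|cor(x_j, pIC50)|} below
#' \code{minAbsResponseCorr}; (3) iterative multicollinearity reduction,
#' dropping the single largest-VIF descriptor (ties broken towards the later
#' column) until all VIFs are at most \code{maxVIF} (the conventional cut-off
#' of 5 by default).
#'
#' @param x a [QSARDataset-class].
#' @param minVariance descriptors with variance at or below this are dropped
#'   (0 keeps everything non-constant).
#' @param minAbsResponseCorr minimum absolute Pearson correlation with
#'   activity.
#' @param maxVIF maximum tolerated variance inflation factor.
#' @param subset \code{"train"} (default) or \code{"all"}.
#' @return a list of class \code{"qsarScreen"}: \code{kept} (character),
#'   \code{dropped} (named character, reason per dropped descriptor, one of
#'   \code{zero-variance}, \code{low-response-correlation}, \code{high-VIF}),
#'   \code{correlationMatrix}, \code{vif} and \code{tolerance} over the kept
#'   descriptors, and \code{empty} (TRUE when nothing survived).
#' @examples
#' screenDescriptors(qsarFixture("table4"))
#' @export
screenDescriptors <- function(x, minVariance = 0, minAbsResponseCorr = 0,
                              maxVIF = 5, subset = c("train", "all")) {
    subset <- match.arg(subset)
    stopifnot(minVariance >= 0, minAbsResponseCorr >= 0, maxVIF > 0)
    X <- descriptorMatrix(x, subset)
    y <- activityValues(x, subset)
    dropped <- character(0)

    vars <- apply(X, 2, stats::var)
    zv <- colnames(X)[vars <= minVariance | is.na(vars)]
    dropped[zv] <- "zero-variance"
    keep <- setdiff(colnames(X), zv)

    if (minAbsResponseCorr > 0 && length(keep)) {
        rc <- vapply(keep, function(j) abs(stats::cor(X[, j], y)), numeric(1))
        low <- keep[rc < minAbsResponseCorr]
        dropped[low] <- "low-response-correlation"
        keep <- setdiff(keep, low)
    }

    ## iterative VIF reduction; on ties drop the later column in name order
    while (length(keep) >= 2L) {
        sub <- x[keep, ]
        v <- vifValues(sub, subset)
        if (all(v <= maxVIF)) break
        worst <- max(v)
        cand <- names(v)[v == worst]
        drop <- cand[length(cand)]
        dropped[drop] <- "high-VIF"
        keep <- setdiff(keep, drop)
    }

    if (length(keep) == 0L) {
        res <- list(kept = character(0), dropped = dropped,
                    correlationMatrix = NULL, vif = NULL, tolerance = NULL,
                    empty = TRUE)
        class(res) <- "qsarScreen"
        return(res)
    }
    sub <- x[keep, ]
    v <- if (length(keep) >= 2L && nrow(X) >= length(keep) + 2L)
        vifValues(sub, subset) else stats::setNames(rep(1, length(keep)), keep)
    res <- list(kept = keep, dropped = dropped,
                correlationMatrix = correlationMatrix(sub, subset),
                vif = v, tolerance = 1 / v, empty = FALSE)
    class(res) <- "qsarScreen"
    res
}

#' @export
print.qsarScreen <- function(x, ...) {
    cat("Descriptor screen:", length(x$kept), "kept,",
        length(x$dropped), "dropped\n")
    if (length(x$kept)) {
        cat("kept (VIF):\n")
        for (nm in x$kept)
            cat(sprintf("  %-14s %.4f\n", nm, x$vif[[nm]]))
    }
    if (length(x$dropped)) {
        cat("dropped:\n")
        for (nm in names(x$dropped))
            cat(sprintf("  %-14s %s\n", nm, x$dropped[[nm]]))
    }
    invisible(x)
}
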
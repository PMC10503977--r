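#' Leverage (hat) values against a training set
#'
#' The leverage of a compound with descriptor row-vector \eqn{x_i} is
#' \eqn{h_i = x_i^T (X^T X)^{-1} x_i}, with \eqn{X} the intercept-augmented
#' descriptor matrix of the training compounds (standard Williams-plot
#' practice). The warning threshold is \eqn{h^* = 3(d + 1)/n} with \eqn{d}
#' descriptors and \eqn{n} training compounds.
#'
#' @param train a [QSARDataset-class]; its train subset defines the domain.
#' @param query optional [QSARDataset-class] (or matrix) of compounds to
#'   evaluate; defaults to every compound of \code{train}.
#' @return a list with \code{h} (named leverages), \code{hStar}, \code{d},
#'   \code{n}.
#' @examples
#' leverageValues(qsarFixture("table4"))$hStar  # 3 * 5 / 20 = 0.75
#' @export
leverageValues <- function(train, query = NULL) {
    Xtr <- descriptorMatrix(train, "train")
    n <- nrow(Xtr)
    d <- ncol(Xtr)
    Xa <- cbind(1, Xtr)
    XtXinv <- tryCatch(chol2inv(chol(crossprod(Xa))),
                       error = function(e)
                           stop("singular descriptor cross-product: ",
                                conditionMessage(e)))
    Xq <- if (is.null(query)) descriptorMatrix(train, "all")
          else if (is(query, "QSARDataset")) descriptorMatrix(query, "all")
          else as.matrix(query)
    Xq <- cbind(1, Xq[, colnames(Xtr), drop = FALSE])
    h <- rowSums((Xq %*% XtXinv) * Xq)
    list(h = stats::setNames(h, rownames(Xq)), hStar = 3 * (d + 1) / n,
         d = d, n = n)
}

#' Leverage-based applicability domain (Williams plot classification)
#'
#' Computes each compound's leverage against the training descriptor space
#' and its standardized residual (raw residual divided by the training
#' residual standard error \eqn{\sqrt{SSE/(n-p-1)}}), then labels compounds:
#' \code{inside} when \eqn{h \le h^*} and the absolute standardized residual
#' is at most \code{sigmaMult}; \code{structural-outlier} when only the
#' leverage bound is exceeded; \code{response-outlier} when only the residual
#' bound is exceeded; \code{both} otherwise.
#'
#' @param x a [QSARDataset-class] with train/test labels.
#' @param model optional [QSARModel-class]; refitted on the train subset when
#'   omitted.
#' @param sigmaMult residual cut in units of the residual standard error;
#'   2 by default (conventional Williams plots also use 3).
#' @return a list of class \code{"qsarAD"}: \code{leverages}, \code{hStar},
#'   \code{stdResiduals}, \code{labels}, \code{sigmaMult}, \code{rse}.
#' @examples
#' ad <- applicabilityDomain(qsarFixture("table4"))
#' ad$labels[ad$labels != "inside"]  # compound 10d only
#' @export
applicabilityDomain <- function(x, model = NULL, sigmaMult = 2) {
    if (is.null(model)) model <- fitQSAR(x)
    lev <- leverageValues(x)
    idx <- splitLabels(x) %in% c("train", "test")
    yObs <- activityValues(x)[idx]
    yPred <- predict(model, x)[idx]
    st <- fitStatistics(model, x, subset = "train")
    rse <- st$rmse   # sqrt(SSE / (n - p - 1))
    res <- yObs - yPred
    ## an (essentially) exact fit has no residual scale: no response outliers
    std <- if (rse <= 1e-8 * stats::sd(yObs)) res * 0 else res / rse
    h <- lev$h[names(std)]
    lab <- ifelse(h <= lev$hStar & abs(std) <= sigmaMult, "inside",
           ifelse(h > lev$hStar & abs(std) > sigmaMult, "both",
           ifelse(h > lev$hStar, "structural-outlier", "response-outlier")))
    out <- list(leverages = h, hStar = lev$hStar, stdResiduals = std,
                labels = lab, sigmaMult = sigmaMult, rse = rse)
    class(out) <- "qsarAD"
    out
}

#' @export
print.qsarAD <- function(x, ...) {
    cat(sprintf("Applicability domain: h* = %.4f, +/-%g sigma residual cut\n",
                x$hStar, x$sigmaMult))
    tab <- table(factor(x$labels, levels = c("inside", "structural-outlier",
                                             "response-outlier", "both")))
    for (nm in names(tab)) cat(sprintf("  %-18s %d\n", nm, tab[[nm]]))
    out <- names(x$labels)[x$labels != "inside"]
    if (length(out)) cat("  outliers:", paste(out, collapse = ", "), "\n")
    invisible(x)
}

#' Williams plot
#'
#' Standardized residuals against leverages, with the \eqn{h^*} and
#' \eqn{\pm\sigma}-multiple reference lines.
#'
#' @param ad a \code{"qsarAD"} object from [applicabilityDomain()].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, \code{ad}.
#' @export
plotWilliams <- function(ad, ...) {
    stopifnot(inherits(ad, "qsarAD"))
    graphics::plot(ad$leverages, ad$stdResiduals,
                   xlab = "leverage h", ylab = "standardized residual",
                   pch = 19, col = ifelse(ad$labels == "inside", "steelblue",
                                          "firebrick"),
                   xlim = c(0, max(ad$leverages, ad$hStar) * 1.1),
                   ylim = range(c(ad$stdResiduals, -ad$sigmaMult - 0.5,
                                  ad$sigmaMult + 0.5)),
                   ...)
    graphics::abline(v = ad$hStar, lty = 2)
    graphics::abline(h = c(-1, 1) * ad$sigmaMult, lty = 3)
    out <- ad$labels != "inside"
    if (any(out))
        graphics::text(ad$leverages[out], ad$stdResiduals[out],
                       names(ad$labels)[out], pos = 4, cex = 0.8)
    invisible(ad)
}
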
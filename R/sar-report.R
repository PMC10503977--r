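#' Docking affinity versus activity correlation
#'
#' Pearson correlation between pIC50 and docking binding free energy
#' (kcal/mol; more negative = stronger predicted binding), with the
#' least-squares line. A strong negative r (high \eqn{r^2}) indicates that
#' docking ranks the compounds consistently with the measured activities.
#'
#' @param x a [QSARDataset-class] carrying binding affinities, or a numeric
#'   vector of activities.
#' @param affinity numeric vector of binding affinities when \code{x} is a
#'   vector; ignored otherwise.
#' @return a list of class \code{"qsarCorrelation"}: \code{r}, \code{r2},
#'   \code{n}, \code{slope}, \code{intercept}.
#' @examples
#' s4 <- qsarFixture("tableS4")
#' affinityActivityCorrelation(s4$pIC50, s4$binding_affinity)
#' @export
affinityActivityCorrelation <- function(x, affinity = NULL) {
    if (is(x, "QSARDataset")) {
        activity <- activityValues(x)
        affinity <- bindingAffinity(x)
    } else activity <- x
    keep <- !is.na(activity) & !is.na(affinity)
    activity <- activity[keep]; affinity <- affinity[keep]
    if (length(activity) < 3L)
        stop("at least 3 compounds with both activity and affinity required")
    if (stats::sd(activity) == 0 || stats::sd(affinity) == 0)
        stop("constant column: correlation undefined")
    r <- stats::cor(activity, affinity)
    slope <- r * stats::sd(activity) / stats::sd(affinity)
    out <- list(r = r, r2 = r^2, n = length(activity), slope = slope,
                intercept = mean(activity) - slope * mean(affinity))
    class(out) <- "qsarCorrelation"
    out
}

#' @export
print.qsarCorrelation <- function(x, ...) {
    cat(sprintf("affinity~activity: r = %.4f, r2 = %.4f (n = %d)\n",
                x$r, x$r2, x$n))
    invisible(x)
}

#' Relative descriptor contributions
#'
#' Standardized-coefficient contribution of each descriptor:
#' \eqn{c_j = |a_j| sd(x_j) / \sum_k |a_k| sd(x_k)}, with standard
#' deviations taken over the training compounds. Raw coefficient magnitudes
#' are not comparable across descriptors measured in different units;
#' multiplying by the descriptor spread puts them on the response scale, so
#' the ranking is invariant to descriptor rescaling.
#'
#' @param model a [QSARModel-class].
#' @param x the [QSARDataset-class] it was fitted on.
#' @param subset compounds whose descriptor spread is used
#'   (\code{"train"} by default).
#' @return named numeric vector summing to 1, sorted decreasing.
#' @examples
#' ds <- qsarFixture("table4")
#' descriptorContributions(fitQSAR(ds), ds)
#' @export
descriptorContributions <- function(model, x, subset = c("train", "all")) {
    subset <- match.arg(subset)
    X <- descriptorMatrix(x, subset)[, model@descriptorNames, drop = FALSE]
    w <- abs(model@coefficients) * apply(X, 2, stats::sd)
    if (sum(w) == 0)
        stop("all standardized coefficients are zero")
    sort(w / sum(w), decreasing = TRUE)
}
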
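## Reserved colData columns of a QSARDataset; everything else is treated as a
## compound property (MW, LogP, TPSA, ...).
.RESERVED_COLDATA <- c("pIC50", "split", "binding_affinity")

.SPLIT_LEVELS <- c("train", "test", "unassigned")

#' Compound collection for 2D-QSAR modelling
#'
#' \code{QSARDataset} extends
#' \linkS4class{SummarizedExperiment}: the single assay
#' \code{"descriptors"} holds the molecular-descriptor matrix (descriptors in
#' rows, compounds in columns), and \code{colData} carries per-compound
#' metadata: the activity (\code{pIC50}), the \code{split} label
#' (\code{"train"}, \code{"test"} or \code{"unassigned"}), an optional docking
#' \code{binding_affinity} (kcal/mol), and any further physicochemical
#' properties.
#'
#' Validity requires unique compound identifiers, named descriptors, and a
#' non-missing activity for every compound labelled \code{train} or
#' \code{test}.
#'
#' @seealso [QSARDataset()] for construction, [readQSARTable()] to load one
#'   from a delimited file, [qsarFixture()] for the packaged chalcone MAO-B
#'   inhibitor tables.
#' @name QSARDataset-class
#' @aliases QSARDataset-class
#' @exportClass QSARDataset
setClass("QSARDataset", contains = "SummarizedExperiment")

setValidity("QSARDataset", function(object) {
    msg <- NULL
    if (!"descriptors" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'descriptors' is required")
    ids <- colnames(object)
    if (is.null(ids) || anyNA(ids))
        msg <- c(msg, "compound identifiers (colnames) are required")
    else if (anyDuplicated(ids))
        msg <- c(msg, sprintf("duplicate compound ids: %s",
                              paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    if (is.null(rownames(object)))
        msg <- c(msg, "descriptor names (rownames) are required")
    cd <- SummarizedExperiment::colData(object)
    if (!"split" %in% colnames(cd))
        msg <- c(msg, "colData column 'split' is required")
    else if (!all(cd$split %in% .SPLIT_LEVELS))
        msg <- c(msg, sprintf("split labels must be one of %s",
                              paste(.SPLIT_LEVELS, collapse = "/")))
    if (!"pIC50" %in% colnames(cd))
        msg <- c(msg, "colData column 'pIC50' is required (may be NA)")
    else if ("split" %in% colnames(cd)) {
        assigned <- cd$split %in% c("train", "test")
        if (any(assigned & is.na(cd$pIC50)))
            msg <- c(msg, "activity (pIC50) must be present for every train/test compound")
    }
    if (is.null(msg)) TRUE else msg
})

#' Fitted linear QSAR activity model
#'
#' Holds the intercept and per-descriptor coefficients of the linear model
#' \eqn{pIC50 = a_0 + a_1 x_1 + \dots + a_p x_p}, together with the training
#' subset it was fitted on. Created by [fitQSAR()]; used by
#' \code{\link[=predict,QSARModel-method]{predict}}, [fitStatistics()],
#' [externalValidation()], [applicabilityDomain()] and
#' [descriptorContributions()].
#'
#' @slot intercept numeric(1), the constant term \eqn{a_0}.
#' @slot coefficients named numeric, one slope per descriptor.
#' @slot descriptorNames character, order of the model terms.
#' @slot nTrain integer(1), number of training compounds.
#' @slot trainIds character, identifiers of the training compounds.
#'
#' @name QSARModel-class
#' @aliases QSARModel-class
#' @exportClass QSARModel
setClass("QSARModel",
    representation(
        intercept = "numeric",
        coefficients = "numeric",
        descriptorNames = "character",
        nTrain = "integer",
        trainIds = "character"
    )
)

setValidity("QSARModel", function(object) {
    msg <- NULL
    if (length(object@intercept) != 1L || is.na(object@intercept))
        msg <- c(msg, "intercept must be a single non-missing number")
    if (length(object@coefficients) != length(object@descriptorNames))
        msg <- c(msg, "one coefficient per descriptor is required")
    else if (!identical(names(object@coefficients), object@descriptorNames))
        msg <- c(msg, "coefficient names must match descriptorNames")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn QSARModel-class compact display of the fitted equation
#' @param object a \code{QSARModel}
#' @export
setMethod("show", "QSARModel", function(object) {
    co <- object@coefficients
    terms <- sprintf("%s %.4g*%s", ifelse(co < 0, "-", "+"), abs(co), names(co))
    cat("QSARModel with", length(co), "descriptors, fitted on",
        object@nTrain, "compounds\n")
    cat("  pIC50 =", format(object@intercept, digits = 4),
        paste(terms, collapse = " "), "\n")
})

setMethod("show", "QSARDataset", function(object) {
    callNextMethod()
    sp <- splitLabels(object)
    cat(sprintf("split: %d train, %d test, %d unassigned\n",
                sum(sp == "train"), sum(sp == "test"), sum(sp == "unassigned")))
})
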
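#' Construct a QSARDataset
#'
#' Builds the package's central compound container from a compounds-by-
#' descriptors matrix plus per-compound metadata.
#'
#' @param descriptors numeric matrix or data frame, compounds in rows
#'   (rownames = compound ids unless \code{compoundIds} is given), descriptors
#'   in columns.
#' @param activity optional numeric vector of pIC50 values (NA allowed for
#'   unassigned compounds).
#' @param split optional character vector of labels among
#'   \code{"train"}, \code{"test"}, \code{"unassigned"}; defaults to
#'   \code{"unassigned"}.
#' @param properties optional data frame of physicochemical properties
#'   (MW, LogP, TPSA, ...), one row per compound.
#' @param bindingAffinity optional numeric vector of docking scores (kcal/mol).
#' @param compoundIds optional character vector of identifiers overriding the
#'   rownames of \code{descriptors}.
#'
#' @return a [QSARDataset-class] object.
#' @examples
#' X <- matrix(rnorm(20), 5, 4,
#'             dimnames = list(paste0("c", 1:5), paste0("d", 1:4)))
#' ds <- QSARDataset(X, activity = rnorm(5),
#'                   split = c("train", "train", "train", "test", "test"))
#' ds
#' @export
QSARDataset <- function(descriptors, activity = NULL, split = NULL,
                        properties = NULL, bindingAffinity = NULL,
                        compoundIds = NULL) {
    descriptors <- as.matrix(descriptors)
    if (!is.numeric(descriptors))
        stop("'descriptors' must be numeric")
    n <- nrow(descriptors)
    if (is.null(compoundIds))
        compoundIds <- rownames(descriptors)
    if (is.null(compoundIds))
        stop("compound identifiers are required (rownames or 'compoundIds')")
    compoundIds <- as.character(compoundIds)
    if (is.null(colnames(descriptors)))
        stop("descriptor names are required (colnames of 'descriptors')")
    if (is.null(activity)) activity <- rep(NA_real_, n)
    if (is.null(split)) split <- rep("unassigned", n)
    cd <- S4Vectors::DataFrame(pIC50 = as.numeric(activity),
                               split = as.character(split),
                               row.names = compoundIds)
    if (!is.null(bindingAffinity))
        cd$binding_affinity <- as.numeric(bindingAffinity)
    if (!is.null(properties)) {
        properties <- as.data.frame(properties)
        stopifnot(nrow(properties) == n)
        for (nm in colnames(properties)) cd[[nm]] <- properties[[nm]]
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(descriptors = t(descriptors)),
        colData = cd)
    colnames(se) <- compoundIds
    new("QSARDataset", se)
}

.subsetIdx <- function(x, subset = c("all", "train", "test")) {
    subset <- match.arg(subset)
    sp <- splitLabels(x)
    switch(subset,
           all = seq_along(sp),
           train = which(sp == "train"),
           test = which(sp == "test"))
}

#' Descriptor matrix, names and compound identifiers
#'
#' \code{descriptorMatrix} returns the compounds-by-descriptors numeric matrix
#' (the transpose of the stored assay); \code{descriptorNames} and
#' \code{compoundIds} return the corresponding dimnames.
#'
#' @param x a [QSARDataset-class]
#' @param subset one of \code{"all"}, \code{"train"}, \code{"test"}
#' @param ... unused
#' @return a matrix (or character vector for the name accessors)
#' @examples
#' ds <- qsarFixture("table4")
#' dim(descriptorMatrix(ds, subset = "train"))
#' @rdname descriptorMatrix
#' @export
setMethod("descriptorMatrix", "QSARDataset", function(x, subset = "all", ...) {
    t(SummarizedExperiment::assay(x, "descriptors"))[.subsetIdx(x, subset), ,
                                                     drop = FALSE]
})

#' @rdname descriptorMatrix
#' @export
setMethod("descriptorNames", "QSARDataset", function(x) rownames(x))

#' @rdname descriptorMatrix
#' @export
setMethod("compoundIds", "QSARDataset", function(x) colnames(x))

#' Activity (pIC50) of each compound
#'
#' @param x a [QSARDataset-class]
#' @param subset one of \code{"all"}, \code{"train"}, \code{"test"}
#' @param ... unused
#' @return named numeric vector of pIC50 values (NA where unassigned)
#' @rdname activityValues
#' @export
setMethod("activityValues", "QSARDataset", function(x, subset = "all", ...) {
    i <- .subsetIdx(x, subset)
    stats::setNames(SummarizedExperiment::colData(x)$pIC50[i], colnames(x)[i])
})

#' Train/test split labels
#'
#' @param x a [QSARDataset-class]
#' @param value character vector over
#'   \code{"train"}/\code{"test"}/\code{"unassigned"}
#' @return character vector of labels
#' @seealso [splitDataset()] for random assignment
#' @rdname splitLabels
#' @export
setMethod("splitLabels", "QSARDataset", function(x) {
    stats::setNames(SummarizedExperiment::colData(x)$split, colnames(x))
})

#' @rdname splitLabels
#' @export
setReplaceMethod("splitLabels", "QSARDataset", function(x, value) {
    SummarizedExperiment::colData(x)$split <- as.character(value)
    validObject(x)
    x
})

#' Training and test subsets
#'
#' Convenience subsetting by split label.
#' @param x a [QSARDataset-class]
#' @return a [QSARDataset-class] restricted to the requested subset
#' @rdname trainSet
#' @export
setMethod("trainSet", "QSARDataset", function(x) x[, splitLabels(x) == "train"])

#' @rdname trainSet
#' @export
setMethod("testSet", "QSARDataset", function(x) x[, splitLabels(x) == "test"])

#' Physicochemical properties stored with the compounds
#'
#' @param x a [QSARDataset-class]
#' @return data frame of the non-reserved \code{colData} columns (zero columns
#'   when no properties are stored)
#' @rdname compoundProperties
#' @export
setMethod("compoundProperties", "QSARDataset", function(x) {
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    cd[, setdiff(colnames(cd), .RESERVED_COLDATA), drop = FALSE]
})

#' Docking binding affinity (kcal/mol)
#'
#' @param x a [QSARDataset-class]
#' @return named numeric vector, NA when no affinities are stored
#' @rdname bindingAffinity
#' @export
setMethod("bindingAffinity", "QSARDataset", function(x) {
    cd <- SummarizedExperiment::colData(x)
    v <- if ("binding_affinity" %in% colnames(cd)) cd$binding_affinity
         else rep(NA_real_, ncol(x))
    stats::setNames(v, colnames(x))
})
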
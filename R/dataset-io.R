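#' Convert IC50 to pIC50
#'
#' pIC50 is the negative base-10 logarithm of the half-maximal inhibitory
#' concentration expressed in mol/L, so for a concentration in micromolar
#' \code{pIC50 = 6 - log10(ic50)}.
#'
#' @param ic50 positive numeric vector of IC50 values.
#' @param unit concentration unit of \code{ic50}: \code{"uM"} (default),
#'   \code{"nM"} or \code{"M"}.
#' @return numeric vector of pIC50 values.
#' @examples
#' ic50ToPIC50(0.016)  # 7.7959, the most potent compound of the series
#' ic50ToPIC50(8.39)   # 5.0762, the least potent
#' @export
ic50ToPIC50 <- function(ic50, unit = c("uM", "nM", "M")) {
    unit <- match.arg(unit)
    if (!is.numeric(ic50) || any(!is.finite(ic50)) || any(ic50 <= 0))
        stop("IC50 values must be finite and strictly positive")
    offset <- switch(unit, uM = 6, nM = 9, M = 0)
    offset - log10(ic50)
}

#' Read a compound/descriptor/activity table
#'
#' Reads a delimited text file with one header row and one compound per row
#' into a [QSARDataset-class]. All columns other than the id, activity, split,
#' affinity and declared property columns are taken as descriptors and must be
#' numeric; missing cells become NA, never zero.
#'
#' @param path file path of the delimited table.
#' @param idColumn name of the compound-identifier column.
#' @param activityColumn name of the pIC50 column (optional in the file).
#' @param splitColumn name of the split column with values train/test
#'   (optional in the file).
#' @param affinityColumn name of the docking-affinity column, if any.
#' @param propertyColumns character vector of columns to store as
#'   physicochemical properties rather than descriptors.
#' @param sep field separator, comma by default.
#' @return a [QSARDataset-class].
#' @seealso [writeQSARTable()] for the inverse operation.
#' @export
readQSARTable <- function(path, idColumn = "compound",
                          activityColumn = "pIC50", splitColumn = "split",
                          affinityColumn = "binding_affinity",
                          propertyColumns = character(), sep = ",") {
    tab <- tryCatch(
        utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE),
        error = function(e) stop("cannot parse '", path, "': ",
                                 conditionMessage(e)))
    if (nrow(tab) == 0L) stop("'", path, "' contains no compound rows")
    if (!idColumn %in% colnames(tab))
        stop("id column '", idColumn, "' not found in '", path, "'")
    ids <- tab[[idColumn]]
    if (anyDuplicated(ids))
        stop("duplicate compound ids in '", path, "': ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))

    numify <- function(col) {
        x <- trimws(tab[[col]])
        x[x %in% c("", "NA", "-")] <- NA
        v <- suppressWarnings(as.numeric(x))
        bad <- which(!is.na(x) & is.na(v))
        if (length(bad))
            stop(sprintf("non-numeric value '%s' in column '%s', row %d (%s)",
                         x[bad[1]], col, bad[1], ids[bad[1]]))
        v
    }

    special <- c(idColumn, activityColumn, splitColumn, affinityColumn,
                 propertyColumns)
    descCols <- setdiff(colnames(tab), special)
    if (length(descCols) == 0L)
        stop("no descriptor columns found in '", path, "'")
    X <- vapply(descCols, numify, numeric(nrow(tab)))
    dim(X) <- c(nrow(tab), length(descCols))
    dimnames(X) <- list(ids, descCols)

    activity <- if (activityColumn %in% colnames(tab)) numify(activityColumn)
    split <- if (splitColumn %in% colnames(tab)) {
        s <- trimws(tab[[splitColumn]])
        s[is.na(s) | s == ""] <- "unassigned"
        s
    }
    affinity <- if (affinityColumn %in% colnames(tab)) numify(affinityColumn)
    props <- if (length(propertyColumns)) {
        as.data.frame(lapply(stats::setNames(nm = propertyColumns), numify))
    }
    QSARDataset(X, activity = activity, split = split, properties = props,
                bindingAffinity = affinity)
}

#' Write a QSARDataset to a delimited file
#'
#' Writes the compound table in the format [readQSARTable()] reads: id column
#' \code{compound}, descriptor columns, then \code{pIC50}, \code{split} and
#' (when present) \code{binding_affinity} and property columns. Numeric cells
#' are written at full precision so a write/read round trip is exact.
#'
#' @param x a [QSARDataset-class].
#' @param path output file path.
#' @param sep field separator.
#' @return invisibly, \code{path}.
#' @export
writeQSARTable <- function(x, path, sep = ",") {
    out <- data.frame(compound = compoundIds(x), check.names = FALSE,
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(descriptorMatrix(x)))
    out$pIC50 <- unname(activityValues(x))
    out$split <- unname(splitLabels(x))
    ba <- bindingAffinity(x)
    if (!all(is.na(ba))) out$binding_affinity <- unname(ba)
    props <- compoundProperties(x)
    if (ncol(props)) out <- cbind(out, props)
    ## 17 significant digits: doubles survive the round trip bit-exactly
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], function(v)
        ifelse(is.na(v), NA, sprintf("%.17g", v)))
    utils::write.table(out, path, sep = sep, row.names = FALSE,
                       quote = FALSE)
    invisible(path)
}

#' Randomly assign train/test split labels
#'
#' Assigns \code{round(n * trainFraction)} compounds to the training set and
#' the remainder to the test set, reproducibly for a given seed. Existing
#' labels are overwritten. The global RNG state is left untouched.
#'
#' @param x a [QSARDataset-class] with at least two compounds with activity.
#' @param trainFraction fraction of compounds for training, in (0, 1].
#' @param seed integer seed controlling the assignment.
#' @return \code{x} with updated split labels.
#' @examples
#' ds <- qsarFixture("table4")
#' table(splitLabels(splitDataset(ds, 0.8, seed = 1)))
#' @export
splitDataset <- function(x, trainFraction = 0.8, seed = 1L) {
    if (!is.numeric(trainFraction) || trainFraction <= 0 || trainFraction > 1)
        stop("'trainFraction' must lie in (0, 1]")
    act <- activityValues(x)
    if (sum(!is.na(act)) < 2L)
        stop("at least two compounds with activity are required")
    n <- ncol(x)
    nTrain <- round(n * trainFraction)
    idx <- withSeed(seed, sample.int(n, nTrain))
    lab <- rep("test", n)
    lab[idx] <- "train"
    splitLabels(x) <- lab
    x
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`.
withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
        get(".Random.seed", globalenv()) else NULL
    on.exit({
        if (is.null(old)) rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
}
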
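.FIXTURES <- c("table1", "table2", "table3", "table4",
               "tableS1", "tableS2", "tableS4")

#' Packaged chalcone MAO-B inhibitor tables
#'
#' The package ships, as plain-text files under \code{inst/extdata}, the
#' curated dataset of 25 unsaturated ketone (chalcone) MAO-B inhibitors used
#' throughout the documentation and tests. Each table is kept exactly as
#' published, including small cross-table discrepancies (compound 10b's
#' activity is 7.7959 in \code{table1} but 7.7958 in \code{tableS4}; tables
#' 1 and 4 omit compound 9b while S2 and S4 omit 12a), so per-table values are
#' authoritative for that table only.
#'
#' \describe{
#'   \item{\code{table1}}{compound activities (pIC50); data frame.}
#'   \item{\code{table2}}{tolerance, variance inflation factor, coefficient
#'     p-value and activity correlation of the four model descriptors; data
#'     frame. The p-value column is character because one entry is the
#'     censored value \code{"<0.0001"}.}
#'   \item{\code{table3}}{correlation matrix of the four descriptors and
#'     pIC50 on the training compounds; numeric matrix.}
#'   \item{\code{table4}}{the modelling table: four MOE descriptors
#'     (logP(o/w), SlogP_VSA4, vsurf_IW3, BCUT_SMR_2), observed activity and
#'     the 80/20 train/test assignment; returned as a [QSARDataset-class].
#'     The published model predictions (\code{pIC50_pred}) and leave-one-out
#'     predictions (\code{pIC50_loo}) are stored as compound properties.}
#'   \item{\code{tableS1}}{Y-randomization runs: R, R2 and Q2 of the original
#'     model and of 20 response-permuted refits; data frame.}
#'   \item{\code{tableS2}}{physicochemical properties (MW, LogP, HBA, HBD,
#'     TPSA) with the published drug-likeness verdicts and Abbott
#'     bioavailability scores; data frame. The Ghose verdicts depend on WLOGP,
#'     which is not part of the published properties, so they are data here,
#'     not recomputable from the stored columns.}
#'   \item{\code{tableS4}}{observed activity and docking binding affinity
#'     (kcal/mol); data frame.}
#' }
#'
#' @param name one of \code{"table1"}, \code{"table2"}, \code{"table3"},
#'   \code{"table4"}, \code{"tableS1"}, \code{"tableS2"}, \code{"tableS4"}.
#' @return a data frame, matrix, or [QSARDataset-class] (see Details).
#' @examples
#' ds <- qsarFixture("table4")
#' ds
#' head(qsarFixture("tableS4"))
#' @export
qsarFixture <- function(name = .FIXTURES) {
    name <- match.arg(name)
    path <- system.file("extdata", paste0(name, ".csv"), package = "qsarkit",
                        mustWork = TRUE)
    if (name == "table4") {
        return(readQSARTable(path,
                             activityColumn = "pIC50_obs",
                             propertyColumns = c("pIC50_pred", "pIC50_loo")))
    }
    tab <- utils::read.csv(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    if (name == "table3") {
        m <- as.matrix(tab[, -1])
        rownames(m) <- tab[[1]]
        return(m)
    }
    if (name == "tableS2") {
        tab$Ghose_violation[is.na(tab$Ghose_violation)] <- ""
    }
    tab
}
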
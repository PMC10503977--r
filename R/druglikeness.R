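## Each condition: a predicate on the property list plus the text used when
## violated. Conditions whose inputs are absent are reported "not evaluable"
## and excluded from the violation count (properties are inputs here, never
## computed from structures).
.ruleConditions <- function() {
    cond <- function(input, text, fun) list(input = input, text = text,
                                            fun = fun)
    list(
        Lipinski = list(
            allowance = 1L,
            conds = list(
                cond("MW",   "MW>500",  function(p) p$MW <= 500),
                cond("LogP", "LogP>5",  function(p) p$LogP <= 5),
                cond("HBA",  "HBA>10",  function(p) p$HBA <= 10),
                cond("HBD",  "HBD>5",   function(p) p$HBD <= 5))),
        Ghose = list(
            allowance = 0L,
            conds = list(
                cond("MW",    "MW<160",     function(p) p$MW >= 160),
                cond("MW",    "MW>480",     function(p) p$MW <= 480),
                cond("WLOGP", "WLOGP<-0.4", function(p) p$WLOGP >= -0.4),
                cond("WLOGP", "WLOGP>5.6",  function(p) p$WLOGP <= 5.6),
                cond("MR",    "MR<40",      function(p) p$MR >= 40),
                cond("MR",    "MR>130",     function(p) p$MR <= 130),
                cond("Atoms", "atoms<20",   function(p) p$Atoms >= 20),
                cond("Atoms", "atoms>70",   function(p) p$Atoms <= 70))),
        Veber = list(
            allowance = 0L,
            conds = list(
                cond("RotB", "RotB>10",  function(p) p$RotB <= 10),
                cond("TPSA", "TPSA>140", function(p) p$TPSA <= 140))),
        Egan = list(
            allowance = 0L,
            conds = list(
                cond("WLOGP", "WLOGP>5.88", function(p) p$WLOGP <= 5.88),
                cond("TPSA",  "TPSA>131.6", function(p) p$TPSA <= 131.6))),
        Muegge = list(
            allowance = 0L,
            conds = list(
                cond("MW",    "MW<200",    function(p) p$MW >= 200),
                cond("MW",    "MW>600",    function(p) p$MW <= 600),
                cond("XLOGP", "XLOGP<-2",  function(p) p$XLOGP >= -2),
                cond("XLOGP", "XLOGP>5",   function(p) p$XLOGP <= 5),
                cond("TPSA",  "TPSA>150",  function(p) p$TPSA <= 150),
                cond("Rings", "rings>7",   function(p) p$Rings <= 7),
                cond("Carbons", "carbons<5", function(p) p$Carbons > 4),
                cond("Heteroatoms", "heteroatoms<2",
                     function(p) p$Heteroatoms > 1),
                cond("RotB",  "RotB>15",   function(p) p$RotB <= 15),
                cond("HBA",   "HBA>10",    function(p) p$HBA <= 10),
                cond("HBD",   "HBD>5",     function(p) p$HBD <= 5))))
}

.asProps <- function(props) {
    p <- as.list(props)
    if (is.data.frame(props)) {
        stopifnot(nrow(props) == 1L)
        p <- lapply(props, `[[`, 1)
    }
    if (!is.null(p$MW) && !is.na(p$MW) && p$MW <= 0)
        stop("non-physical molecular weight: MW must be positive")
    p
}

#' Rule-based drug-likeness evaluation
#'
#' Applies the five standard drug-likeness filters to a compound's
#' physicochemical properties: Lipinski's rule of five (MW <= 500 Da,
#' LogP <= 5, HBA <= 10, HBD <= 5; one violation tolerated), Veber
#' (rotatable bonds <= 10, TPSA <= 140 A^2), Egan (WLOGP <= 5.88,
#' TPSA <= 131.6), Muegge (200 <= MW <= 600, -2 <= XLOGP <= 5, TPSA <= 150,
#' rings <= 7, carbons > 4, heteroatoms > 1, RotB <= 15, HBA <= 10,
#' HBD <= 5) and Ghose (160 <= MW <= 480, -0.4 <= WLOGP <= 5.6,
#' 40 <= MR <= 130, 20 <= atoms <= 70).
#'
#' Properties are inputs, not computed: any condition whose input is absent
#' from \code{props} is reported under \code{notEvaluable} and excluded from
#' the violation count.
#'
#' @param props a named list, named numeric vector or one-row data frame with
#'   any of: \code{MW} (Da), \code{LogP}, \code{WLOGP}, \code{XLOGP},
#'   \code{HBA}, \code{HBD}, \code{TPSA} (A^2), \code{RotB}, \code{MR},
#'   \code{Atoms}, \code{Rings}, \code{Carbons}, \code{Heteroatoms}.
#' @return a list of class \code{"qsarRules"}: one element per rule with
#'   \code{pass}, \code{violations} (count), \code{violated} (condition
#'   strings) and \code{notEvaluable}.
#' @examples
#' evaluateRules(list(MW = 238.28, LogP = 3.59, HBA = 2, HBD = 0,
#'                    TPSA = 26.30))
#' @export
evaluateRules <- function(props) {
    p <- .asProps(props)
    rules <- .ruleConditions()
    out <- lapply(names(rules), function(rn) {
        rule <- rules[[rn]]
        violated <- character(0)
        notEval <- character(0)
        for (cd in rule$conds) {
            val <- p[[cd$input]]
            if (is.null(val) || is.na(val)) notEval <- c(notEval, cd$text)
            else if (!cd$fun(p)) violated <- c(violated, cd$text)
        }
        list(pass = length(violated) <= rule$allowance,
             violations = length(violated),
             violated = violated,
             notEvaluable = unique(notEval))
    })
    names(out) <- names(rules)
    class(out) <- "qsarRules"
    out
}

#' @export
print.qsarRules <- function(x, ...) {
    for (rn in names(x)) {
        r <- x[[rn]]
        cat(sprintf("%-9s %-4s %d violation%s%s\n", rn,
                    if (r$pass) "Yes" else "No", r$violations,
                    if (r$violations == 1) "" else "s",
                    if (length(r$violated))
                        paste0(": ", paste(r$violated, collapse = ", "))
                    else ""))
    }
    invisible(x)
}

#' Abbott (Martin) bioavailability score
#'
#' Martin's decision rules for the probability class of >10% oral
#' bioavailability in rat: anionic compounds are scored by polar surface
#' area (TPSA <= 75 A^2: 0.85; 75 < TPSA <= 150: 0.56; larger: 0.11), all
#' others by Lipinski compliance (at most one rule-of-five violation: 0.55,
#' otherwise 0.17).
#'
#' @param props as in [evaluateRules()]; TPSA is required for anions, the
#'   rule-of-five inputs otherwise.
#' @param ionization dominant species at physiological pH: \code{"neutral"}
#'   (default), \code{"anion"}, \code{"cation"} or \code{"zwitterion"}.
#' @return one of 0.11, 0.17, 0.55, 0.56, 0.85.
#' @examples
#' bioavailabilityScore(list(MW = 238.28, LogP = 3.59, HBA = 2, HBD = 0,
#'                           TPSA = 26.30))  # 0.55
#' @export
bioavailabilityScore <- function(props, ionization = c("neutral", "anion",
                                                       "cation",
                                                       "zwitterion")) {
    ionization <- match.arg(ionization)
    p <- .asProps(props)
    if (ionization == "anion") {
        if (is.null(p$TPSA) || is.na(p$TPSA))
            stop("TPSA is required for anionic compounds")
        if (p$TPSA <= 75) return(0.85)
        if (p$TPSA <= 150) return(0.56)
        return(0.11)
    }
    ro5 <- evaluateRules(p)$Lipinski$violations
    if (ro5 <= 1) 0.55 else 0.17
}

#' Drug-likeness report for a property table
#'
#' Vectorized wrapper over [evaluateRules()] and [bioavailabilityScore()],
#' returning one row per compound in the layout of the packaged
#' \code{tableS2} fixture.
#'
#' @param props data frame of properties, one compound per row.
#' @param idColumn name of the identifier column (default \code{compound}).
#' @return data frame with the per-rule verdicts (\code{Yes}/\code{No}),
#'   Lipinski violation counts, the Ghose violation string, and the
#'   bioavailability score.
#' @examples
#' druglikenessReport(qsarFixture("tableS2")[1:3, ])
#' @export
druglikenessReport <- function(props, idColumn = "compound") {
    rows <- lapply(seq_len(nrow(props)), function(i) {
        p <- props[i, setdiff(colnames(props), idColumn), drop = FALSE]
        p <- p[vapply(p, is.numeric, logical(1))]
        rr <- evaluateRules(p)
        data.frame(
            compound = if (idColumn %in% colnames(props))
                props[[idColumn]][i] else as.character(i),
            Lipinski = if (rr$Lipinski$pass) "Yes" else "No",
            Lipinski_violations = rr$Lipinski$violations,
            Ghose = if (rr$Ghose$pass) "Yes" else "No",
            Ghose_violation = paste(rr$Ghose$violated, collapse = ", "),
            Veber = if (rr$Veber$pass) "Yes" else "No",
            Egan = if (rr$Egan$pass) "Yes" else "No",
            Muegge = if (rr$Muegge$pass) "Yes" else "No",
            Bioavailability_Score = bioavailabilityScore(p),
            stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
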
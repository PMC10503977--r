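#' Leave-one-out cross-validation
#'
#' Each training compound is held out in turn, the model is refitted on the
#' remaining \eqn{n - 1} compounds and the held-out activity predicted. The
#' cross-validated determination coefficient is
#' \eqn{Q^2_{LOO} = 1 - PRESS/SST} with SST about the full training mean;
#' the cross-validated error uses the plain
#' \eqn{RMSE_{LOO} = \sqrt{PRESS/n}} convention.
#'
#' \code{method = "hat"} uses the algebraically identical hat-matrix shortcut
#' \eqn{e_i / (1 - h_{ii})} for the LOO residuals instead of the explicit
#' refit loop; both routes agree to numerical precision and the loop is the
#' default for transparency.
#'
#' @param x a [QSARDataset-class] whose train subset has at least
#'   \eqn{p + 3} compounds.
#' @param method \code{"refit"} (explicit loop, default) or \code{"hat"}.
#' @return a list of class \code{"qsarLOO"}: \code{predictions} (named),
#'   \code{q2}, \code{rmse}, \code{mae}, \code{press}.
#' @examples
#' looCrossValidation(qsarFixture("table4"))
#' @export
looCrossValidation <- function(x, method = c("refit", "hat")) {
    method <- match.arg(method)
    X <- descriptorMatrix(x, "train")
    y <- activityValues(x, "train")
    n <- nrow(X)
    p <- ncol(X)
    if (n < p + 3L)
        stop("need at least p + 3 training compounds for LOO")
    preds <- .looPredictions(X, y, method)
    press <- sum((y - preds)^2)
    sst <- sum((y - mean(y))^2)
    out <- list(predictions = preds,
                q2 = 1 - press / sst,
                rmse = sqrt(press / n),
                mae = mean(abs(y - preds)),
                press = press)
    class(out) <- "qsarLOO"
    out
}

.looPredictions <- function(X, y, method = "refit") {
    n <- nrow(X)
    if (method == "hat") {
        Xa <- cbind(1, X)
        fit <- stats::lm.fit(Xa, y)
        h <- rowSums((Xa %*% chol2inv(chol(crossprod(Xa)))) * Xa)
        preds <- y - fit$residuals / (1 - h)
    } else {
        preds <- vapply(seq_len(n), function(i) {
            fit <- stats::lm.fit(cbind(1, X[-i, , drop = FALSE]), y[-i])
            if (any(is.na(fit$coefficients)))
                stop("LOO subfit rank deficient when holding out '",
                     rownames(X)[i], "'")
            unname(c(1, X[i, ]) %*% fit$coefficients)
        }, numeric(1))
    }
    stats::setNames(preds, rownames(X))
}

#' @export
print.qsarLOO <- function(x, ...) {
    cat(sprintf("LOO cross-validation (n = %d): Q2 = %.4f  RMSE = %.4f  MAE = %.4f\n",
                length(x$predictions), x$q2, x$rmse, x$mae))
    invisible(x)
}

#' Roy's Rm2 agreement metrics
#'
#' Quantifies how close predicted activities are to observed ones beyond plain
#' correlation, by penalizing the gap between the correlation with and without
#' intercept. With \eqn{r^2} the squared Pearson correlation,
#' \eqn{k = \sum y_{obs} y_{pred} / \sum y_{pred}^2} and
#' \eqn{k' = \sum y_{obs} y_{pred} / \sum y_{obs}^2} the origin-constrained
#' slopes, the through-origin determination coefficients are
#' \deqn{r_0^2 = 1 - \sum(y_{obs} - k\,y_{pred})^2 / \sum(y_{obs} - \bar y_{obs})^2}
#' and the axes-reversed \eqn{r_0'^2}, and
#' \deqn{r_m^2 = r^2 (1 - \sqrt{|r^2 - r_0^2|}),}
#' symmetrically for \eqn{r_m'^2}. Swapping the two arguments maps
#' \eqn{(k, r_m^2) \leftrightarrow (k', r_m'^2)}.
#'
#' With \code{scaled = TRUE} both vectors are first min-max scaled to
#' \eqn{[0, 1]} (Roy's 2013 recommendation, which makes the metric
#' scale-independent); this is the convention under which the packaged
#' chalcone model's cross-validated \eqn{r_m'^2} reproduces the reported 0.57.
#'
#' @param yObs observed activities (length at least 3, non-constant).
#' @param yPred predicted activities, same length.
#' @param scaled apply Roy's 0-1 scaling first (default FALSE).
#' @return a list of class \code{"qsarRm2"}: \code{r2}, \code{k},
#'   \code{kPrime}, \code{r02}, \code{r02Prime}, \code{rm2}, \code{rm2Prime},
#'   \code{rm2Mean}, \code{deltaRm2}.
#' @examples
#' ds <- qsarFixture("table4")
#' loo <- looCrossValidation(ds)
#' rmMetrics(activityValues(ds, "train"), loo$predictions, scaled = TRUE)
#' @export
rmMetrics <- function(yObs, yPred, scaled = FALSE) {
    stopifnot(length(yObs) == length(yPred))
    if (length(yObs) < 3L)
        stop("at least 3 observations are required")
    if (stats::sd(yObs) == 0 || stats::sd(yPred) == 0)
        stop("constant vector: Rm2 metrics undefined")
    if (scaled) {
        sc <- function(v) (v - min(v)) / (max(v) - min(v))
        yObs <- sc(yObs); yPred <- sc(yPred)
    }
    r2 <- stats::cor(yObs, yPred)^2
    k <- sum(yObs * yPred) / sum(yPred^2)
    kPrime <- sum(yObs * yPred) / sum(yObs^2)
    r02 <- 1 - sum((yObs - k * yPred)^2) / sum((yObs - mean(yObs))^2)
    r02p <- 1 - sum((yPred - kPrime * yObs)^2) / sum((yPred - mean(yPred))^2)
    rm2 <- r2 * (1 - sqrt(abs(r2 - r02)))
    rm2p <- r2 * (1 - sqrt(abs(r2 - r02p)))
    out <- list(r2 = r2, k = k, kPrime = kPrime,
                r02 = r02, r02Prime = r02p,
                rm2 = rm2, rm2Prime = rm2p,
                rm2Mean = (rm2 + rm2p) / 2,
                deltaRm2 = abs(rm2 - rm2p),
                scaled = scaled)
    class(out) <- "qsarRm2"
    out
}

#' @export
print.qsarRm2 <- function(x, ...) {
    cat(sprintf("Rm2 metrics%s: rm2 = %.4f  rm2' = %.4f  mean = %.4f  delta = %.4f\n",
                if (x$scaled) " (0-1 scaled)" else "",
                x$rm2, x$rm2Prime, x$rm2Mean, x$deltaRm2))
    cat(sprintf("  r2 = %.4f  k = %.4f  k' = %.4f\n", x$r2, x$k, x$kPrime))
    invisible(x)
}

#' Y-randomization (response-scrambling) test
#'
#' Permutes the training activities \code{nRuns} times, refits the model on
#' the original descriptors each time, and records the fit correlation R, its
#' square and the leave-one-out \eqn{Q^2}. Random models should show low
#' \eqn{R^2} and negative \eqn{Q^2}; the separation from the chance-
#' correlation null is summarized by
#' \deqn{{}^cR_p^2 = R \sqrt{R^2 - \overline{R_r^2}}}
#' with R and \eqn{R^2} from the unpermuted fit and the average taken over
#' the random models' \eqn{R^2} values (\code{average = "r"} instead squares
#' the mean random R, the other convention in circulation).
#'
#' @param x a [QSARDataset-class] with a fitted-ready train subset.
#' @param nRuns number of permutations, at least 10 (default 100).
#' @param seed integer seed; the same seed reproduces the identical runs.
#' @param average \code{"r2"} (default) or \code{"r"}, the averaging
#'   convention inside the cRp2 root.
#' @param permutations optional list of integer permutation vectors to use
#'   instead of random draws (the identity permutation reproduces the
#'   original fit exactly); overrides \code{nRuns} and \code{seed}.
#' @return a list of class \code{"qsarYRand"}: \code{runs} (data frame with
#'   columns R, R2, Q2), \code{avgR}, \code{avgR2}, \code{avgQ2}, \code{crp2},
#'   \code{originalR2}, \code{originalQ2}, \code{seed}, \code{nRuns}.
#' @examples
#' yRandomization(qsarFixture("table4"), nRuns = 20, seed = 42)
#' @export
yRandomization <- function(x, nRuns = 100L, seed = 42L,
                           average = c("r2", "r"), permutations = NULL) {
    average <- match.arg(average)
    if (is.null(permutations) && nRuns < 10L)
        stop("at least 10 randomization runs are required")
    X <- descriptorMatrix(x, "train")
    y <- activityValues(x, "train")
    n <- nrow(X)
    Xa <- cbind(1, X)
    XtXinv <- chol2inv(chol(crossprod(Xa)))
    h <- rowSums((Xa %*% XtXinv) * Xa)
    oneRun <- function(yy) {
        fit <- stats::lm.fit(Xa, yy)
        sst <- sum((yy - mean(yy))^2)
        r2 <- 1 - sum(fit$residuals^2) / sst
        press <- sum((fit$residuals / (1 - h))^2)
        c(R = sqrt(max(r2, 0)), R2 = r2, Q2 = 1 - press / sst)
    }
    orig <- oneRun(y)
    perms <- if (is.null(permutations))
        withSeed(seed, replicate(nRuns, sample.int(n), simplify = FALSE))
    else {
        stopifnot(all(vapply(permutations,
                             function(p) identical(sort(p), seq_len(n)),
                             logical(1))))
        nRuns <- length(permutations)
        permutations
    }
    runs <- t(vapply(perms, function(p) oneRun(y[p]), numeric(3)))
    runs <- as.data.frame(runs)
    avgR <- mean(runs$R); avgR2 <- mean(runs$R2)
    rr2 <- if (average == "r2") avgR2 else avgR^2
    crp2 <- orig[["R"]] * sqrt(max(orig[["R2"]] - rr2, 0))
    out <- list(runs = runs, avgR = avgR, avgR2 = avgR2,
                avgQ2 = mean(runs$Q2), crp2 = crp2,
                originalR2 = orig[["R2"]], originalQ2 = orig[["Q2"]],
                seed = seed, nRuns = nRuns, average = average)
    class(out) <- "qsarYRand"
    out
}

#' @export
print.qsarYRand <- function(x, ...) {
    cat(sprintf("Y-randomization: %d runs (seed %d)\n", x$nRuns, x$seed))
    cat(sprintf("  avg random R = %.3f  R2 = %.3f  Q2 = %.3f\n",
                x$avgR, x$avgR2, x$avgQ2))
    cat(sprintf("  original R2 = %.3f  Q2 = %.3f  cRp2 = %.3f\n",
                x$originalR2, x$originalQ2, x$crp2))
    invisible(x)
}

#' External (test-set) validation with the Golbraikh-Tropsha checklist
#'
#' Predicts the test compounds from a model fitted on the training set and
#' reports \eqn{r^2_{test}} (squared Pearson correlation of observed vs
#' predicted), the predictive
#' \eqn{Q^2_{F2} = 1 - \sum_{test}(y - \hat y)^2 / \sum_{test}(y - \bar y_{train})^2},
#' the origin-constrained slopes k and k', and the four Golbraikh-Tropsha
#' acceptability conditions: \eqn{Q^2_{LOO} > 0.5}; \eqn{r^2_{test} > 0.6};
#' \eqn{(r^2 - r_0^2)/r^2 < 0.1} with \eqn{0.85 \le k \le 1.15} (or the
#' primed variant); and \eqn{|r_0^2 - r_0'^2| < 0.3}.
#'
#' @param model a [QSARModel-class] fitted on the train subset of \code{x}.
#' @param x a [QSARDataset-class] with a non-empty test subset.
#' @return a list of class \code{"qsarExternal"}: \code{r2Test}, \code{q2F2},
#'   \code{k}, \code{kPrime}, \code{rm} (unscaled [rmMetrics()] on the test
#'   set), \code{q2Loo}, \code{predictions}, and \code{checklist} (data frame
#'   with columns criterion, value, pass).
#' @examples
#' ds <- qsarFixture("table4")
#' externalValidation(fitQSAR(ds), ds)
#' @export
externalValidation <- function(model, x) {
    te <- testSet(x)
    if (ncol(te) == 0L)
        stop("test set is empty: external validation impossible")
    yObs <- activityValues(x, "test")
    yPred <- predict(model, x, subset = "test")
    yTrain <- activityValues(x, "train")
    r2Test <- stats::cor(yObs, yPred)^2
    q2F2 <- 1 - sum((yObs - yPred)^2) / sum((yObs - mean(yTrain))^2)
    rm <- rmMetrics(yObs, yPred)
    q2Loo <- looCrossValidation(x, method = "hat")$q2
    cond3a <- (rm$r2 - rm$r02) / rm$r2 < 0.1 && rm$k >= 0.85 && rm$k <= 1.15
    cond3b <- (rm$r2 - rm$r02Prime) / rm$r2 < 0.1 &&
        rm$kPrime >= 0.85 && rm$kPrime <= 1.15
    checklist <- data.frame(
        criterion = c("Q2_LOO > 0.5", "r2_test > 0.6",
                      "(r2-r02)/r2 < 0.1 & 0.85 <= k <= 1.15 (or primed)",
                      "|r02 - r02'| < 0.3"),
        value = c(q2Loo, r2Test,
                  min((rm$r2 - rm$r02) / rm$r2,
                      (rm$r2 - rm$r02Prime) / rm$r2),
                  abs(rm$r02 - rm$r02Prime)),
        pass = c(q2Loo > 0.5, r2Test > 0.6, cond3a || cond3b,
                 abs(rm$r02 - rm$r02Prime) < 0.3),
        stringsAsFactors = FALSE)
    out <- list(r2Test = r2Test, q2F2 = q2F2, k = rm$k, kPrime = rm$kPrime,
                rm = rm, q2Loo = q2Loo, predictions = yPred,
                checklist = checklist)
    class(out) <- "qsarExternal"
    out
}

#' @export
print.qsarExternal <- function(x, ...) {
    cat(sprintf("External validation (n = %d): r2_test = %.4f  Q2F2 = %.4f  k = %.4f  k' = %.4f\n",
                length(x$predictions), x$r2Test, x$q2F2, x$k, x$kPrime))
    for (i in seq_len(nrow(x$checklist)))
        cat(sprintf("  [%s] %s (%.4f)\n",
                    if (x$checklist$pass[i]) "pass" else "FAIL",
                    x$checklist$criterion[i], x$checklist$value[i]))
    invisible(x)
}

#' Full validation battery
#'
#' Convenience wrapper running the whole validation suite on a split dataset:
#' fit statistics, LOO cross-validation, scaled and unscaled Rm2 metrics on
#' the LOO predictions, Y-randomization, and external validation.
#'
#' @param x a [QSARDataset-class] with train and test subsets.
#' @param nRuns permutations for [yRandomization()].
#' @param seed seed for [yRandomization()].
#' @return a list of class \code{"qsarValidation"} with elements
#'   \code{model}, \code{fit}, \code{loo}, \code{rmLoo}, \code{rmLooScaled},
#'   \code{yrand}, \code{external}.
#' @examples
#' validateQSAR(qsarFixture("table4"), nRuns = 20, seed = 42)
#' @export
validateQSAR <- function(x, nRuns = 100L, seed = 42L) {
    model <- fitQSAR(x)
    loo <- looCrossValidation(x)
    yTrain <- activityValues(x, "train")
    out <- list(model = model,
                fit = fitStatistics(model, x),
                loo = loo,
                rmLoo = rmMetrics(yTrain, loo$predictions),
                rmLooScaled = rmMetrics(yTrain, loo$predictions, scaled = TRUE),
                yrand = yRandomization(x, nRuns = nRuns, seed = seed),
                external = externalValidation(model, x))
    class(out) <- "qsarValidation"
    out
}

#' @export
print.qsarValidation <- function(x, ...) {
    show(x$model)
    print(x$fit)
    print(x$loo)
    cat(sprintf("Rm2(LOO): unscaled %.4f / %.4f, scaled %.4f / %.4f\n",
                x$rmLoo$rm2, x$rmLoo$rm2Prime,
                x$rmLooScaled$rm2, x$rmLooScaled$rm2Prime))
    print(x$yrand)
    print(x$external)
    invisible(x)
}
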
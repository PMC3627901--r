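# Tuning the number of selected variables per dimension: subject-structured
# leave-one-subject-out cross-validation (criterion 1) and the in-sample
# cor*var / cov criteria (criterion 2), both applied sequentially dimension
# per dimension.

## Within rows for one fold. Training rows get the decomposition of the
## training samples only; the held-out subject's within rows are computed
## from its own samples (the within deviation is subject-local). For the
## two-factor within* matrix, the population margins (condition and time
## effects) are taken from the training decomposition.
.foldWithin <- function(x, design, testIdx, twoFactor = FALSE) {
    trainIdx <- setdiff(seq_len(nrow(x)), testIdx)
    xTr <- x[trainIdx, , drop = FALSE]
    dTr <- design[trainIdx]
    xTe <- x[testIdx, , drop = FALSE]
    if (!twoFactor) {
        wTr <- .withinRows(xTr, dTr@subject)
        wTe <- .withinRows(xTe, design@subject[testIdx])
        return(list(train = wTr, test = wTe))
    }
    dec <- splitTwoFactor(xTr, dTr)
    dTe <- design[testIdx]
    ## subject-local part: x_sjt - x_sj. - x_s.t + x_s..
    local <- xTe -
        .groupMeanRows(xTe, dTe@condition) -
        .groupMeanRows(xTe, dTe@time) +
        matrix(colMeans(xTe), nrow(xTe), ncol(xTe), byrow = TRUE)
    ## shared fixed-effect offset from the training margins
    condEff <- rowsum(dec@conditionEffect, dTr@condition, reorder = FALSE) /
        as.vector(table(dTr@condition)[levels(dTr@condition)])
    timeEff <- rowsum(dec@timeEffect, dTr@time, reorder = FALSE) /
        as.vector(table(dTr@time)[levels(dTr@time)])
    wTe <- local +
        condEff[as.character(dTe@condition), , drop = FALSE] +
        timeEff[as.character(dTe@time), , drop = FALSE]
    rownames(wTe) <- rownames(xTe)
    list(train = withinStarMatrix(dec), test = wTe)
}

.responseLabels <- function(design, twoFactor) {
    if (twoFactor)
        factor(paste(design@condition, design@time, sep = "."),
               levels = unique(paste(design@condition, design@time, sep = ".")))
    else design@condition
}

#' Leave-one-subject-out classification error at fixed parameters
#'
#' Runs subject-structured cross-validation: each fold holds out all samples
#' of one subject, fits a sparse PLS-DA model on the remaining samples and
#' predicts the held-out subject's condition labels via Ytest = X_test beta.
#' With `multilevel = TRUE` the model is fitted on the within matrix of the
#' training samples; the held-out subject's within rows are computed from its
#' own samples and standardized with the training statistics, so no test
#' information leaks into training. Folds never split a subject.
#'
#' @param x samples-by-features matrix (raw scale).
#' @param design a [RepeatedMeasuresDesign-class]; each subject's samples must
#'   span at least two conditions.
#' @param keepX number of variables selected per dimension (recycled to H).
#' @param H number of dimensions.
#' @param multilevel fit on the within matrix (TRUE) or the raw matrix.
#' @param twoFactor use the two-factor within* matrix and classify the
#'   condition-by-time cells.
#' @return numeric vector of length H: mean classification error across
#'   subjects using 1, ..., H components; attribute `"perSubject"` holds the
#'   H x n fold errors.
#' @seealso [losoCV()] for tuning over a grid.
#' @export
losoError <- function(x, design, keepX, H = 3L, multilevel = TRUE,
                      twoFactor = FALSE) {
    .checkOmicsMatrix(x)
    .checkRowsMatchDesign(x, design)
    H <- as.integer(H)
    labels <- .responseLabels(design, twoFactor)
    subjects <- levels(design@subject)
    perSubject <- matrix(NA_real_, H, length(subjects),
                         dimnames = list(NULL, subjects))
    for (s in subjects) {
        testIdx <- which(design@subject == s)
        trainIdx <- setdiff(seq_len(nrow(x)), testIdx)
        labTr <- droplevels(labels[trainIdx])
        if (nlevels(labTr) < nlevels(labels))
            stop("condition level(s) absent from the training fold for ",
                 "subject ", s, "; use a coarser design or k-fold CV")
        if (multilevel) {
            fw <- .foldWithin(x, design, testIdx, twoFactor)
            xTr <- fw$train; xTe <- fw$test
        } else {
            xTr <- x[trainIdx, , drop = FALSE]
            xTe <- x[testIdx, , drop = FALSE]
        }
        fit <- fitSPLSDA(xTr, labels[trainIdx], H = H, keepX = keepX)
        truth <- as.character(labels[testIdx])
        for (h in seq_len(H)) {
            pred <- predict(fit, xTe, ncomp = h)$class
            perSubject[h, s] <- mean(as.character(pred) != truth)
        }
    }
    err <- rowMeans(perSubject)
    attr(err, "perSubject") <- perSubject
    err
}

#' Tune the number of selected variables by leave-one-subject-out CV
#'
#' Criterion 1: for each dimension in turn (earlier dimensions frozen at their
#' chosen keep), evaluates every grid value by subject-structured
#' cross-validation and picks the keep with the lowest mean classification
#' error, breaking ties toward the smallest keep (the most parsimonious
#' model).
#'
#' @inheritParams losoError
#' @param keepGrid integer vector of candidate keep values (all <= p).
#' @return a [CVResult-class].
#' @export
losoCV <- function(x, design, H = 3L, keepGrid, multilevel = TRUE,
                   twoFactor = FALSE) {
    keepGrid <- sort(unique(as.integer(keepGrid)))
    if (any(keepGrid < 1L) || any(keepGrid > ncol(x)))
        stop("keepGrid values must lie in [1, p]")
    H <- as.integer(H)
    nSubj <- nlevels(design@subject)
    err <- matrix(NA_real_, H, length(keepGrid),
                  dimnames = list(paste0("dim", seq_len(H)), keepGrid))
    perSubject <- array(NA_real_, c(H, length(keepGrid), nSubj),
                        dimnames = list(paste0("dim", seq_len(H)), keepGrid,
                                        levels(design@subject)))
    chosen <- integer(0)
    for (h in seq_len(H)) {
        for (g in seq_along(keepGrid)) {
            res <- losoError(x, design, keepX = c(chosen, keepGrid[g]), H = h,
                             multilevel = multilevel, twoFactor = twoFactor)
            err[h, g] <- res[h]
            perSubject[h, g, ] <- attr(res, "perSubject")[h, ]
        }
        chosen <- c(chosen, keepGrid[which.min(err[h, ])])
    }
    new("CVResult", grid = keepGrid, error = err, perSubject = perSubject,
        chosenKeep = chosen, H = H)
}

setMethod("show", "CVResult", function(object) {
    cat("CVResult: leave-one-subject-out error over keep grid\n")
    print(round(object@error, 4))
    cat("chosen keep per dimension:",
        paste(object@chosenKeep, collapse = ", "), "\n")
})

## number of dimensions retained under the sudden-drop rule
.dropRule <- function(maxima, threshold) {
    nDim <- length(maxima)
    for (h in seq_along(maxima)[-1L]) {
        if (maxima[h] < threshold * maxima[h - 1L]) {
            nDim <- h - 1L
            break
        }
    }
    as.integer(nDim)
}

#' Tune a sparse PLS-DA fit with the in-sample cor*var criterion
#'
#' Criterion 2: on the whole data set, per dimension (on the current deflated
#' matrices) fits the model at each grid value and records
#' cor(xi, omega) * var(xi), where omega is the score of the dummy block; the
#' chosen keep maximizes the criterion. The plain correlation is recorded
#' alongside. The number of dimensions to retain is suggested by the
#' sudden-drop rule (stop before the first dimension whose maximum falls below
#' `dropThreshold` times the previous maximum).
#'
#' @param xw samples-by-features matrix (typically a within matrix; raw scale,
#'   standardized internally).
#' @param groups length-N group labels.
#' @param H number of dimensions to explore.
#' @param keepGrid candidate keep values.
#' @param dropThreshold relative threshold of the drop rule (default 0.8).
#' @return a [Criterion2Result-class].
#' @export
tuneCorVar <- function(xw, groups, H = 3L, keepGrid, dropThreshold = 0.8) {
    keepGrid <- sort(unique(as.integer(keepGrid)))
    H <- as.integer(H)
    sx <- standardizeColumns(xw)
    sy <- standardizeColumns(dummyMatrix(groups))
    keepGrid <- pmin(keepGrid, ncol(sx$x))
    X <- sx$x; Y <- sy$x
    crit <- matrix(NA_real_, H, length(keepGrid),
                   dimnames = list(paste0("dim", seq_len(H)), keepGrid))
    corr <- crit
    chosen <- integer(0)
    for (h in seq_len(H)) {
        for (g in seq_along(keepGrid)) {
            eng <- .splsEngine(X, Y, 1L, keepGrid[g], ncol(Y),
                               zDeflation = "regression")
            xi <- eng$Xi[, 1L]; om <- eng$Omega[, 1L]
            corr[h, g] <- stats::cor(xi, om)
            crit[h, g] <- corr[h, g] * stats::var(xi)
        }
        best <- which.max(crit[h, ])
        chosen <- c(chosen, keepGrid[best])
        eng <- .splsEngine(X, Y, 1L, keepGrid[best], ncol(Y),
                           zDeflation = "regression")
        X <- eng$E; Y <- eng$F
    }
    maxima <- apply(crit, 1L, max)
    new("Criterion2Result", grid = keepGrid, gridZ = integer(0),
        criterion = crit, correlation = corr, chosenKeep = chosen,
        chosenKeepZ = integer(0), dimensionMax = maxima,
        nDimensions = .dropRule(maxima, dropThreshold),
        dropThreshold = dropThreshold, kind = "da")
}

#' Tune a two-block sparse PLS integration with the covariance criterion
#'
#' Per dimension (on the current mode-A deflated matrices) evaluates
#' cov(X_h u_h, Z_h v_h) over the grid of keep values for each block; the
#' chosen pair maximizes the covariance, and the sudden-drop rule suggests the
#' number of dimensions.
#'
#' @param xw,zw row-aligned matrices (raw scale, standardized internally).
#' @param H number of dimensions to explore.
#' @param keepXGrid,keepZGrid candidate keep values per block (defaults keep
#'   all Z features, as when the second assay has few variables).
#' @param dropThreshold relative threshold of the drop rule.
#' @return a [Criterion2Result-class].
#' @export
tuneCov <- function(xw, zw, H = 3L, keepXGrid, keepZGrid = ncol(zw),
                    dropThreshold = 0.8) {
    keepXGrid <- sort(unique(as.integer(keepXGrid)))
    keepZGrid <- sort(unique(as.integer(keepZGrid)))
    H <- as.integer(H)
    sx <- standardizeColumns(xw); sz <- standardizeColumns(zw)
    keepXGrid <- pmin(keepXGrid, ncol(sx$x))
    keepZGrid <- pmin(keepZGrid, ncol(sz$x))
    X <- sx$x; Z <- sz$x
    dims <- c(H, length(keepXGrid), length(keepZGrid))
    crit <- array(NA_real_, dims,
                  dimnames = list(paste0("dim", seq_len(H)), keepXGrid,
                                  keepZGrid))
    corr <- crit
    chosenX <- integer(0); chosenZ <- integer(0)
    N <- nrow(X)
    for (h in seq_len(H)) {
        for (gx in seq_along(keepXGrid)) for (gz in seq_along(keepZGrid)) {
            eng <- .splsEngine(X, Z, 1L, keepXGrid[gx], keepZGrid[gz],
                               zDeflation = "modeA")
            xi <- eng$Xi[, 1L]; om <- eng$Omega[, 1L]
            crit[h, gx, gz] <- stats::cov(xi, om)
            corr[h, gx, gz] <- stats::cor(xi, om)
        }
        best <- which(crit[h, , ] == max(crit[h, , ]), arr.ind = TRUE)
        if (is.null(dim(best))) best <- matrix(best, 1L)
        gx <- best[1L, 1L]
        gz <- if (length(keepZGrid) > 1L) best[1L, 2L] else 1L
        chosenX <- c(chosenX, keepXGrid[gx])
        chosenZ <- c(chosenZ, keepZGrid[gz])
        eng <- .splsEngine(X, Z, 1L, keepXGrid[gx], keepZGrid[gz],
                           zDeflation = "modeA")
        X <- eng$E; Z <- eng$F
    }
    maxima <- apply(crit, 1L, max)
    new("Criterion2Result", grid = keepXGrid, gridZ = keepZGrid,
        criterion = crit, correlation = corr, chosenKeep = chosenX,
        chosenKeepZ = chosenZ, dimensionMax = maxima,
        nDimensions = .dropRule(maxima, dropThreshold),
        dropThreshold = dropThreshold, kind = "integration")
}

setMethod("show", "Criterion2Result", function(object) {
    cat("Criterion2Result (", object@kind, "): per-dimension maxima ",
        paste(round(object@dimensionMax, 3), collapse = ", "), "\n", sep = "")
    cat("chosen keep per dimension:",
        paste(object@chosenKeep, collapse = ", "), "\n")
    if (length(object@chosenKeepZ))
        cat("chosen keepZ per dimension:",
            paste(object@chosenKeepZ, collapse = ", "), "\n")
    cat("dimensions retained by the drop rule (threshold ",
        object@dropThreshold, "): ", object@nDimensions, "\n", sep = "")
})
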
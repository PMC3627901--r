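# Split-up variation: exact additive decomposition of a repeated-measures
# expression matrix into offset, between-subject and within-subject parts,
# with the two-factor extension that purges the random subject interactions.

## subject-local within-subject deviation: x minus the subject's mean profile.
## Only uses each subject's own rows, which is what makes subject-structured
## cross-validation well-defined.
.withinRows <- function(x, subject) {
    subject <- droplevels(as.factor(subject))
    sums <- rowsum(x, subject, reorder = FALSE)
    counts <- as.vector(table(subject)[rownames(sums)])
    means <- sums / counts
    x - means[as.character(subject), , drop = FALSE]
}

.checkRowsMatchDesign <- function(x, design) {
    if (nrow(x) != length(design@sample) ||
        !identical(rownames(x), design@sample))
        stop("rownames of the matrix must equal the design's sample ids, ",
             "in the same order")
}

## group means indexed back to rows: rows of `x` averaged within `f`, then
## replicated over the original rows
.groupMeanRows <- function(x, f) {
    f <- as.factor(f)
    sums <- rowsum(x, f, reorder = FALSE)
    counts <- as.vector(table(f)[rownames(sums)])
    out <- (sums / counts)[as.character(f), , drop = FALSE]
    rownames(out) <- rownames(x)
    out
}

#' One-factor split-up variance decomposition
#'
#' Decomposes each observation x_sjk into the grand mean (offset), the
#' between-subject deviation (subject mean minus grand mean) and the
#' within-subject deviation (observation minus subject mean). The three parts
#' sum to X exactly, the within rows of each subject sum to zero, and the
#' squared Frobenius norms satisfy
#' ||X||^2 = ||offset||^2 + ||between||^2 + ||within||^2 (also in unbalanced
#' designs, with all means arithmetic means over available samples).
#'
#' @param x numeric samples-by-features matrix with dimnames; rownames must
#'   equal `design@sample` in order.
#' @param design a [RepeatedMeasuresDesign-class].
#' @return a [OneFactorDecomposition][VarianceDecomposition-class].
#' @examples
#' d <- repeatedMeasuresDesign(paste0("s", 1:4), c("a", "a", "b", "b"),
#'                             c("A", "B", "A", "B"))
#' x <- matrix(c(1, 3, 5, 7), 4, 1, dimnames = list(paste0("s", 1:4), "g1"))
#' dec <- splitOneFactor(x, d)
#' sumsOfSquares(dec)  # 64, 16, 4 summing to ||X||^2 = 84
#' @export
splitOneFactor <- function(x, design) {
    .checkOmicsMatrix(x)
    .checkRowsMatchDesign(x, design)
    grand <- colMeans(x)
    offset <- matrix(grand, nrow(x), ncol(x), byrow = TRUE,
                     dimnames = dimnames(x))
    subjMeans <- .groupMeanRows(x, design@subject)
    between <- subjMeans - offset
    within <- x - subjMeans
    ss <- c(offset = sum(offset^2), between = sum(between^2),
            within = sum(within^2), total = sum(x^2))
    new("OneFactorDecomposition", offset = offset, between = between,
        within = within, sumsOfSquares = ss, design = design)
}

#' Two-factor split-up variance decomposition
#'
#' Extends [splitOneFactor()] to designs crossed with a second factor (time).
#' The within-subject deviation is further split into the fixed-effect part
#' `withinStar` (condition + time + interaction + residual) and the two
#' random-interaction parts subject-by-condition and subject-by-time.
#' `withinStar` is computed by subtraction
#' (within - subjectByCondition - subjectByTime) so the reconstruction
#' identity holds exactly even in unbalanced designs; the four fixed-effect
#' matrices are exported individually for inspection. All cell means are
#' arithmetic means over available samples.
#'
#' @inheritParams splitOneFactor
#' @return a [TwoFactorDecomposition][VarianceDecomposition-class].
#' @export
splitTwoFactor <- function(x, design) {
    .checkOmicsMatrix(x)
    .checkRowsMatchDesign(x, design)
    if (!hasTimeFactor(design))
        stop("two-factor decomposition needs a design with a time factor")
    subj <- design@subject; cond <- design@condition; time <- design@time
    ## every (subject, condition) and (subject, time) margin must be observed
    mSC <- table(subj, cond); mST <- table(subj, time)
    if (any(mSC == 0L)) {
        i <- which(mSC == 0L, arr.ind = TRUE)[1L, ]
        stop(sprintf("no sample for subject '%s' x condition '%s'",
                     rownames(mSC)[i[1L]], colnames(mSC)[i[2L]]))
    }
    if (any(mST == 0L)) {
        i <- which(mST == 0L, arr.ind = TRUE)[1L, ]
        stop(sprintf("no sample for subject '%s' x time '%s'",
                     rownames(mST)[i[1L]], colnames(mST)[i[2L]]))
    }
    grand <- colMeans(x)
    offset <- matrix(grand, nrow(x), ncol(x), byrow = TRUE,
                     dimnames = dimnames(x))
    subjMean <- .groupMeanRows(x, subj)             # x_s..
    condMean <- .groupMeanRows(x, cond)             # x_.j.
    timeMean <- .groupMeanRows(x, time)             # x_..t
    cellMean <- .groupMeanRows(x, interaction(cond, time, drop = TRUE)) # x_.jt
    scMean <- .groupMeanRows(x, interaction(subj, cond, drop = TRUE))   # x_sj.
    stMean <- .groupMeanRows(x, interaction(subj, time, drop = TRUE))   # x_s.t

    between <- subjMean - offset
    within <- x - subjMean
    subjectByCondition <- scMean - condMean - subjMean + offset
    subjectByTime <- stMean - timeMean - subjMean + offset
    withinStar <- within - subjectByCondition - subjectByTime

    conditionEffect <- condMean - offset
    timeEffect <- timeMean - offset
    interactionEffect <- cellMean - condMean - timeMean + offset
    residualEffect <- withinStar - conditionEffect - timeEffect -
        interactionEffect

    ss <- c(offset = sum(offset^2), between = sum(between^2),
            within = sum(within^2), total = sum(x^2),
            withinStar = sum(withinStar^2),
            subjectByCondition = sum(subjectByCondition^2),
            subjectByTime = sum(subjectByTime^2),
            condition = sum(conditionEffect^2), time = sum(timeEffect^2),
            interaction = sum(interactionEffect^2),
            residual = sum(residualEffect^2))
    new("TwoFactorDecomposition", offset = offset, between = between,
        within = within, sumsOfSquares = ss, design = design,
        withinStar = withinStar, subjectByCondition = subjectByCondition,
        subjectByTime = subjectByTime, conditionEffect = conditionEffect,
        timeEffect = timeEffect, interactionEffect = interactionEffect,
        residualEffect = residualEffect)
}

#' @rdname decomposition-accessors
#' @export
setMethod("offsetMatrix", "VarianceDecomposition",
    function(object) object@offset)
#' @rdname decomposition-accessors
#' @export
setMethod("betweenMatrix", "VarianceDecomposition",
    function(object) object@between)
#' @rdname decomposition-accessors
#' @export
setMethod("withinMatrix", "VarianceDecomposition",
    function(object) object@within)
#' @rdname decomposition-accessors
#' @export
setMethod("withinStarMatrix", "OneFactorDecomposition",
    function(object) object@within)
#' @rdname decomposition-accessors
#' @export
setMethod("withinStarMatrix", "TwoFactorDecomposition",
    function(object) object@withinStar)
#' @rdname decomposition-accessors
#' @export
setMethod("sumsOfSquares", "VarianceDecomposition",
    function(object) object@sumsOfSquares)

#' @rdname variationSummary
#' @export
setMethod("variationSummary", "VarianceDecomposition", function(object) {
    ss <- object@sumsOfSquares
    parts <- setdiff(names(ss), "total")
    out <- data.frame(part = parts, ss = unname(ss[parts]),
                      fraction = unname(ss[parts] / ss[["total"]]))
    attr(out, "identityResidual") <-
        abs(sum(ss[c("offset", "between", "within")]) - ss[["total"]]) /
        max(ss[["total"]], .Machine$double.eps)
    out
})

setMethod("show", "OneFactorDecomposition", function(object) {
    cat("OneFactorDecomposition:", nrow(object@within), "samples x",
        ncol(object@within), "features\n")
    print(variationSummary(object), row.names = FALSE)
})

setMethod("show", "TwoFactorDecomposition", function(object) {
    cat("TwoFactorDecomposition:", nrow(object@within), "samples x",
        ncol(object@within), "features\n")
    print(variationSummary(object), row.names = FALSE)
})
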
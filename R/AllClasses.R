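#' @import methods
NULL

# ---------------------------------------------------------------------------
# Input checking helpers shared across the package
# ---------------------------------------------------------------------------

## An expression matrix is a plain numeric matrix, samples in rows, with
## unique sample ids as rownames and unique feature names as colnames.
.checkOmicsMatrix <- function(x, what = "x") {
    if (!is.matrix(x) || !is.numeric(x))
        stop("'", what, "' must be a numeric matrix (samples in rows)")
    if (anyNA(x))
        stop("'", what, "' contains missing values; impute or filter before use")
    if (nrow(x) < 2L)
        stop("'", what, "' must have at least 2 samples (rows)")
    if (ncol(x) < 1L)
        stop("'", what, "' must have at least 1 feature (column)")
    if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
        stop("'", what, "' must have unique sample ids as rownames")
    if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
        stop("'", what, "' must have unique feature names as colnames")
    invisible(x)
}

# ---------------------------------------------------------------------------
# RepeatedMeasuresDesign
# ---------------------------------------------------------------------------

#' Repeated-measures design
#'
#' Per-sample mapping to subject, condition (e.g. in vitro stimulation) and,
#' optionally, a second crossed factor such as time. Factor levels are kept in
#' first-appearance order. A design is valid when every subject contributes at
#' least two samples (a subject with a single sample has an identically zero
#' within-subject deviation and carries no condition information) and when
#' there is at most one sample per (subject, condition) cell -- or per
#' (subject, condition, time) cell when the time factor is present.
#'
#' @slot sample character vector of unique sample ids.
#' @slot subject factor of subject ids, one per sample.
#' @slot condition factor of condition labels, one per sample.
#' @slot time factor of time labels (zero length when the design has a single
#'   factor).
#'
#' @seealso [repeatedMeasuresDesign()], [readDesign()]
#' @export
setClass("RepeatedMeasuresDesign",
    slots = c(sample = "character", subject = "factor",
              condition = "factor", time = "factor"))

setValidity("RepeatedMeasuresDesign", function(object) {
    n <- length(object@sample)
    msg <- character(0)
    if (length(object@subject) != n || length(object@condition) != n)
        return("sample, subject and condition must have the same length")
    hasTime <- length(object@time) > 0L
    if (hasTime && length(object@time) != n)
        return("time must have the same length as sample")
    if (anyDuplicated(object@sample))
        msg <- c(msg, "duplicated sample ids")
    tab <- table(object@subject)
    if (any(tab < 2L))
        msg <- c(msg, paste0("every subject needs >= 2 samples; offending: ",
                             paste(names(tab)[tab < 2L], collapse = ", ")))
    key <- if (hasTime)
        paste(object@subject, object@condition, object@time, sep = "\r")
    else paste(object@subject, object@condition, sep = "\r")
    if (anyDuplicated(key))
        msg <- c(msg, paste0("more than one sample per (subject, condition",
                             if (hasTime) ", time", ") cell"))
    if (nlevels(object@condition) < 2L)
        msg <- c(msg, "condition must have >= 2 levels")
    if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Variance decompositions
# ---------------------------------------------------------------------------

#' Split-up variance decompositions
#'
#' Results of the split-up variation step: the exact additive decomposition of
#' an expression matrix X into an offset part (columns constant at the grand
#' mean), a between-subject part (subject mean profiles minus the grand mean,
#' replicated over each subject's rows) and a within-subject part (each sample
#' minus its subject's mean profile). `TwoFactorDecomposition` additionally
#' carries the further split of the within part into the fixed-effect matrix
#' `withinStar` (condition + time + interaction + residual) and the two
#' random-interaction matrices subject-by-condition and subject-by-time.
#'
#' @slot offset,between,within N x p matrices summing exactly to X.
#' @slot sumsOfSquares named numeric vector of squared Frobenius norms per part
#'   (plus `total`, the squared norm of X).
#' @slot design the [RepeatedMeasuresDesign-class] used for the split.
#' @slot withinStar within-subject matrix purged of the subject-by-condition
#'   and subject-by-time random interactions (two-factor only).
#' @slot subjectByCondition,subjectByTime random-interaction matrices
#'   (two-factor only).
#' @slot conditionEffect,timeEffect,interactionEffect,residualEffect the four
#'   fixed-effect components whose sum is `withinStar` in a balanced design
#'   (exported for inspection; `withinStar` itself is computed by subtraction
#'   so the reconstruction identity holds exactly even when unbalanced).
#'
#' @seealso [splitOneFactor()], [splitTwoFactor()], [variationSummary()]
#' @aliases OneFactorDecomposition-class TwoFactorDecomposition-class
#' @name VarianceDecomposition-class
#' @export
setClass("VarianceDecomposition",
    representation("VIRTUAL",
        offset = "matrix", between = "matrix", within = "matrix",
        sumsOfSquares = "numeric", design = "RepeatedMeasuresDesign"))

#' @rdname VarianceDecomposition-class
#' @export
setClass("OneFactorDecomposition", contains = "VarianceDecomposition")

#' @rdname VarianceDecomposition-class
#' @export
setClass("TwoFactorDecomposition", contains = "VarianceDecomposition",
    slots = c(withinStar = "matrix",
              subjectByCondition = "matrix", subjectByTime = "matrix",
              conditionEffect = "matrix", timeEffect = "matrix",
              interactionEffect = "matrix", residualEffect = "matrix"))

setValidity("VarianceDecomposition", function(object) {
    x <- object@offset + object@between + object@within
    scale <- max(abs(x), 1)
    ## the split is defined by subtraction, so failure here means corruption
    if (length(object@sumsOfSquares) &&
        !all(c("offset", "between", "within", "total") %in%
             names(object@sumsOfSquares)))
        return("sumsOfSquares must name offset, between, within and total")
    TRUE
})

# ---------------------------------------------------------------------------
# Standardization statistics
# ---------------------------------------------------------------------------

#' Column standardization statistics
#'
#' Column means and standard deviations (denominator N - 1) of a training
#' matrix, kept so that held-out rows can be centred and scaled with the
#' training statistics. Zero-variance columns are dropped at standardization
#' time and recorded in `dropped`.
#'
#' @slot center,scale named numeric vectors over the retained columns.
#' @slot dropped names of columns removed for having zero variance.
#' @export
setClass("StandardizationStats",
    slots = c(center = "numeric", scale = "numeric", dropped = "character"))

setValidity("StandardizationStats", function(object) {
    if (length(object@center) != length(object@scale))
        return("center and scale must have equal length")
    if (any(object@scale <= 0))
        return("scale values must be strictly positive")
    TRUE
})

# ---------------------------------------------------------------------------
# Sparse PLS models
# ---------------------------------------------------------------------------

#' Sparse PLS model (two blocks, mode A)
#'
#' A fitted sparse PLS model relating two row-aligned matrices X (N x p) and
#' Z (N x q). Per dimension h the model stores the unit-norm loading vectors
#' u_h and v_h (columns of `loadingsX` / `loadingsZ`, at most `keepX[h]` /
#' `keepZ[h]` nonzero entries), the score vectors xi_h = X_{h-1} u_h and
#' omega_h = Z_{h-1} v_h (columns of `scoresX` / `scoresZ`), and the local
#' regression coefficients c_h and d_h used for deflation
#' (X_h = X_{h-1} - xi_h c_h'; Z deflated by its own score in mode A, by xi_h
#' in regression mode). `residualX` / `residualZ` are the residual matrices
#' after H deflations.
#'
#' @slot H number of dimensions.
#' @slot keepX,keepZ number of features with nonzero loading per dimension.
#' @slot loadingsX,loadingsZ p x H and q x H loading matrices.
#' @slot scoresX,scoresZ N x H score matrices.
#' @slot coefX,coefZ local regression coefficient matrices (c_h, d_h columns).
#' @slot residualX,residualZ residual matrices after all deflations.
#' @slot statsX,statsZ training [StandardizationStats-class] for each block.
#' @slot converged,iterations per-dimension convergence flag and iteration
#'   count of the alternating soft-thresholding updates.
#' @slot zDeflation "modeA" or "regression".
#'
#' @seealso [fitSPLS()], [fitSPLSDA()], [selectedFeatures()]
#' @export
setClass("SPLSModel",
    slots = c(H = "integer", keepX = "integer", keepZ = "integer",
              loadingsX = "matrix", loadingsZ = "matrix",
              scoresX = "matrix", scoresZ = "matrix",
              coefX = "matrix", coefZ = "matrix",
              residualX = "matrix", residualZ = "matrix",
              statsX = "StandardizationStats", statsZ = "StandardizationStats",
              converged = "logical", iterations = "integer",
              zDeflation = "character"))

setValidity("SPLSModel", function(object) {
    H <- object@H
    msg <- character(0)
    if (ncol(object@loadingsX) != H || ncol(object@scoresX) != H)
        msg <- c(msg, "loading/score matrices must have H columns")
    nrmX <- sqrt(colSums(object@loadingsX^2))
    if (any(abs(nrmX - 1) > 1e-8))
        msg <- c(msg, "X loading vectors must have unit norm")
    nnz <- colSums(object@loadingsX != 0)
    if (any(nnz > object@keepX))
        msg <- c(msg, "nonzero X loadings exceed keepX")
    if (length(msg)) msg else TRUE
})

#' Sparse PLS discriminant analysis model
#'
#' An [SPLSModel-class] whose Z block is the standardized dummy matrix of the
#' sample groups. Additionally stores the group level order, the raw one-hot
#' dummy matrix Y, and the p x G prediction coefficient matrices `beta` (one
#' per number of components 1..H) such that class scores for new data are
#' Yhat = X_std beta, mapped back to the original Y scale.
#'
#' @slot levels group level order (first appearance in the training labels).
#' @slot Y the raw N x G one-hot dummy matrix.
#' @slot beta list of p x G regression coefficient matrices, element h using
#'   the first h dimensions.
#'
#' @seealso [fitSPLSDA()], [predict,SPLSDAModel-method]
#' @export
setClass("SPLSDAModel", contains = "SPLSModel",
    slots = c(levels = "character", Y = "matrix", beta = "list"))

# ---------------------------------------------------------------------------
# Tuning results
# ---------------------------------------------------------------------------

#' Subject-structured cross-validation result
#'
#' Grid of candidate numbers of selected variables against mean
#' leave-one-subject-out classification error, tuned sequentially dimension by
#' dimension (earlier dimensions frozen at their chosen keep). Ties in error
#' are broken toward the smallest keep.
#'
#' @slot grid candidate keep values.
#' @slot error H x length(grid) matrix of mean classification errors.
#' @slot perSubject array (H x grid x subject) of per-fold errors.
#' @slot chosenKeep keep value attaining the minimum per dimension.
#' @slot H number of dimensions tuned.
#' @seealso [losoCV()]
#' @export
setClass("CVResult",
    slots = c(grid = "integer", error = "matrix", perSubject = "array",
              chosenKeep = "integer", H = "integer"))

#' In-sample tuning criterion result
#'
#' Grid search on the in-sample criterion: cor(xi, omega) * var(xi) for
#' discriminant analysis (omega being the Y-block score), cov(xi, omega) for
#' two-block integration. The number of dimensions to retain is chosen by the
#' sudden-drop rule: stop before the first dimension whose maximum falls below
#' `dropThreshold` times the previous dimension's maximum.
#'
#' @slot grid,gridZ candidate keep values for the X (and, for integration, Z)
#'   block; `gridZ` has zero length for discriminant analysis.
#' @slot criterion array of criterion values, dimensions
#'   H x length(grid) (x length(gridZ) for integration).
#' @slot correlation matching array of plain correlations cor(xi, omega).
#' @slot chosenKeep,chosenKeepZ chosen keep per dimension.
#' @slot dimensionMax per-dimension maximum of the criterion.
#' @slot nDimensions dimensions retained under the drop rule.
#' @slot dropThreshold relative threshold of the drop rule.
#' @slot kind "da" or "integration".
#' @seealso [tuneCorVar()], [tuneCov()]
#' @export
setClass("Criterion2Result",
    slots = c(grid = "integer", gridZ = "integer",
              criterion = "array", correlation = "array",
              chosenKeep = "integer", chosenKeepZ = "integer",
              dimensionMax = "numeric", nDimensions = "integer",
              dropThreshold = "numeric", kind = "character"))

# ---------------------------------------------------------------------------
# Simulation specification
# ---------------------------------------------------------------------------

#' Mixed-model simulation specification
#'
#' Parameters of the repeated-measures generator: for each of 10 clusters of
#' 100 genes, X_sjk = mu_jk + pi_sk + eps_sjk with a subject effect
#' pi_sk ~ N(0, sigmaPi^2), residual eps_sjk ~ N(0, sigmaEps^2) and
#' intra-cluster correlation rho within both random terms (genes in different
#' clusters independent). Each cluster shares a condition mean 4-vector mu^k;
#' clusters with a non-constant mu^k are the true discriminative genes.
#' Defaults reproduce the benchmark design: 12 subjects x 4 stimulations
#' (LIPO5, GAG+, GAG-, NS), 6 discriminative clusters with means (4,4,0,0),
#' (3,3,0,0), (5,2,0.2,0.2), (5,2,0,0), (1,1,5,2), (0,0,5,2) and 4 noise
#' clusters alternating (0,0,0,0) and (0.5,0.5,0.5,0.5); sigmaPi = 2,
#' sigmaEps = 0.5, rho = 0.8.
#'
#' @slot nSubjects number of subjects (default 12).
#' @slot conditions condition labels (default the four stimulations).
#' @slot clusterMeans list of per-cluster condition mean vectors.
#' @slot genesPerCluster genes per cluster (default 100).
#' @slot sigmaPi,sigmaEps standard deviations of the subject effect and the
#'   residual.
#' @slot rho intra-cluster correlation, in [0, 1).
#' @slot seed base random seed.
#' @seealso [simulationSpec()], [simulateDataset()]
#' @export
setClass("SimulationSpec",
    slots = c(nSubjects = "integer", conditions = "character",
              clusterMeans = "list", genesPerCluster = "integer",
              sigmaPi = "numeric", sigmaEps = "numeric", rho = "numeric",
              seed = "integer"))

setValidity("SimulationSpec", function(object) {
    msg <- character(0)
    if (object@rho < 0 || object@rho >= 1)
        msg <- c(msg, "rho must lie in [0, 1) for a positive-definite covariance")
    if (object@sigmaPi < 0 || object@sigmaEps < 0)
        msg <- c(msg, "sigmaPi and sigmaEps must be nonnegative")
    G <- length(object@conditions)
    if (G < 2L) msg <- c(msg, "need at least 2 conditions")
    if (!all(vapply(object@clusterMeans, length, 1L) == G))
        msg <- c(msg, "every cluster mean vector must have one entry per condition")
    if (object@nSubjects < 2L) msg <- c(msg, "need at least 2 subjects")
    if (length(msg)) msg else TRUE
})
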
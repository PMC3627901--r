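# Sparse PLS core: column standardization, dummy coding, the alternating
# soft-thresholding engine shared by the two-block (mode A) and discriminant
# variants, deflation, and class prediction.

#' Column-standardize a matrix
#'
#' Centers each column and scales it to unit standard deviation (denominator
#' N - 1). Zero-variance columns are dropped with a message; the returned
#' statistics allow held-out rows to be standardized with the training values
#' via [applyStandardization()].
#'
#' @param x numeric matrix with column names.
#' @return a list with the standardized matrix `x` and `stats`, a
#'   [StandardizationStats-class].
#' @examples
#' standardizeColumns(cbind(g1 = c(1, 3), g2 = c(0, 1)))
#' @export
standardizeColumns <- function(x) {
    if (!is.matrix(x) || !is.numeric(x)) stop("'x' must be a numeric matrix")
    if (nrow(x) < 2L) stop("need at least 2 rows to standardize")
    if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
    ctr <- colMeans(x)
    sds <- sqrt(colSums(sweep(x, 2L, ctr)^2) / (nrow(x) - 1L))
    keep <- sds > 0
    if (!any(keep))
        stop("all columns have zero variance; nothing to standardize")
    if (!all(keep))
        message(sum(!keep), " zero-variance column(s) dropped: ",
                paste(utils::head(colnames(x)[!keep], 5L), collapse = ", "),
                if (sum(!keep) > 5L) ", ...")
    stats <- new("StandardizationStats", center = ctr[keep], scale = sds[keep],
                 dropped = colnames(x)[!keep])
    xs <- sweep(sweep(x[, keep, drop = FALSE], 2L, ctr[keep]), 2L, sds[keep],
                "/")
    list(x = xs, stats = stats)
}

#' Apply training standardization statistics to new rows
#'
#' @param x numeric matrix whose columns include the training features.
#' @param stats a [StandardizationStats-class] from [standardizeColumns()].
#' @return the centred and scaled matrix restricted to the training features.
#' @export
applyStandardization <- function(x, stats) {
    feats <- names(stats@center)
    miss <- setdiff(feats, colnames(x))
    if (length(miss))
        stop("new data lacks ", length(miss), " training feature(s): ",
             paste(utils::head(miss, 5L), collapse = ", "))
    x <- x[, feats, drop = FALSE]
    sweep(sweep(x, 2L, stats@center), 2L, stats@scale, "/")
}

#' One-hot dummy matrix of group labels
#'
#' @param groups length-N vector of group labels (>= 2 distinct values).
#' @return an N x G indicator matrix; column order is the first-appearance
#'   order of the levels (or the factor's level order if `groups` is already
#'   a factor).
#' @examples
#' dummyMatrix(c("A", "A", "B"))
#' @export
dummyMatrix <- function(groups) {
    f <- if (is.factor(groups)) droplevels(groups)
         else factor(groups, levels = unique(as.character(groups)))
    if (nlevels(f) < 2L) stop("need at least 2 group levels")
    if (anyNA(f)) stop("missing group labels")
    Y <- matrix(0, length(f), nlevels(f),
                dimnames = list(names(groups), levels(f)))
    Y[cbind(seq_along(f), as.integer(f))] <- 1
    Y
}

## Keep the `keep` largest-|.| entries of a, soft-shrunk by the (keep+1)-th
## largest absolute value; ties at the boundary broken by first index.
.keepLargest <- function(a, keep) {
    p <- length(a)
    if (keep >= p) return(a)
    ord <- order(-abs(a), seq_len(p))
    lambda <- abs(a[ord[keep + 1L]])
    out <- numeric(p)
    kept <- ord[seq_len(keep)]
    out[kept] <- sign(a[kept]) * pmax(abs(a[kept]) - lambda, 0)
    if (all(out == 0)) out[kept] <- a[kept]  # degenerate all-tied case
    out
}

.unitNorm <- function(v) {
    nrm <- sqrt(sum(v^2))
    if (nrm == 0) stop("zero loading vector encountered; data may be degenerate")
    v / nrm
}

## Core alternating algorithm on already-standardized blocks.
## Per dimension: initialize (u, v) from the leading singular pair of
## X_{h-1}' Z_{h-1}; alternate a <- X'omega -> soft-threshold to keepX ->
## renormalize -> u, then symmetrically v from Z'xi; iterate to convergence;
## deflate X by its own score (X_h = X_{h-1} - xi c'), and Z either by its own
## score (mode A) or by xi (regression mode, used for the DA dummy block).
.splsEngine <- function(X, Z, H, keepX, keepZ,
                        zDeflation = c("modeA", "regression"),
                        tol = 1e-06, maxIter = 500L) {
    zDeflation <- match.arg(zDeflation)
    N <- nrow(X); p <- ncol(X); q <- ncol(Z)
    stopifnot(nrow(Z) == N)
    if (H < 1L || H > min(N - 1L, p))
        stop("H must lie in [1, min(N-1, p)] = [1, ", min(N - 1L, p), "]")
    keepX <- as.integer(rep_len(keepX, H)); keepZ <- as.integer(rep_len(keepZ, H))
    if (any(keepX < 1L) || any(keepX > p))
        stop("keepX values must lie in [1, p]")
    if (any(keepZ < 1L) || any(keepZ > q))
        stop("keepZ values must lie in [1, q]")
    U <- matrix(0, p, H, dimnames = list(colnames(X), NULL))
    V <- matrix(0, q, H, dimnames = list(colnames(Z), NULL))
    Xi <- matrix(0, N, H, dimnames = list(rownames(X), NULL))
    Om <- matrix(0, N, H, dimnames = list(rownames(X), NULL))
    Cc <- matrix(0, p, H, dimnames = list(colnames(X), NULL))
    Dd <- matrix(0, q, H, dimnames = list(colnames(Z), NULL))
    converged <- logical(H); iters <- integer(H)
    for (h in seq_len(H)) {
        M <- crossprod(X, Z)
        sv <- svd(M, nu = 1L, nv = 1L)
        u <- sv$u[, 1L]; v <- sv$v[, 1L]
        omega <- Z %*% v
        it <- 0L
        repeat {
            it <- it + 1L
            uOld <- u; vOld <- v
            u <- .unitNorm(.keepLargest(drop(crossprod(X, omega)), keepX[h]))
            xi <- X %*% u
            v <- .unitNorm(.keepLargest(drop(crossprod(Z, xi)), keepZ[h]))
            omega <- Z %*% v
            if (max(abs(u - uOld)) < tol && max(abs(v - vOld)) < tol) {
                converged[h] <- TRUE
                break
            }
            if (it >= maxIter) {
                warning("dimension ", h, " did not converge after ", maxIter,
                        " iterations")
                break
            }
        }
        if (u[which.max(abs(u))] < 0) {
            u <- -u; xi <- -xi
        }
        if (v[which.max(abs(v))] < 0) {
            v <- -v; omega <- -omega
        }
        xi <- drop(xi); omega <- drop(omega)
        cc <- drop(crossprod(X, xi)) / sum(xi^2)
        X <- X - tcrossprod(xi, cc)
        if (zDeflation == "modeA") {
            dd <- drop(crossprod(Z, omega)) / sum(omega^2)
            Z <- Z - tcrossprod(omega, dd)
        } else {
            dd <- drop(crossprod(Z, xi)) / sum(xi^2)
            Z <- Z - tcrossprod(xi, dd)
        }
        U[, h] <- u; V[, h] <- v; Xi[, h] <- xi; Om[, h] <- omega
        Cc[, h] <- cc; Dd[, h] <- dd
        iters[h] <- it
    }
    list(U = U, V = V, Xi = Xi, Omega = Om, C = Cc, D = Dd,
         E = X, F = Z, keepX = keepX, keepZ = keepZ,
         converged = converged, iterations = iters, zDeflation = zDeflation)
}

.newSPLSModel <- function(class, eng, statsX, statsZ, ...) {
    new(class, H = length(eng$keepX), keepX = eng$keepX, keepZ = eng$keepZ,
        loadingsX = eng$U, loadingsZ = eng$V, scoresX = eng$Xi,
        scoresZ = eng$Omega, coefX = eng$C, coefZ = eng$D,
        residualX = eng$E, residualZ = eng$F, statsX = statsX,
        statsZ = statsZ, converged = eng$converged,
        iterations = eng$iterations, zDeflation = eng$zDeflation, ...)
}

#' Fit a two-block sparse PLS (mode A)
#'
#' Maximizes, per dimension h, cov(X_h u_h, Z_h v_h) over unit-norm loading
#' vectors under L1-induced sparsity parameterized as the number of nonzero
#' loadings (`keepX`, `keepZ`), with both blocks deflated by their own scores
#' (mode A). Intended for integrating two matched within-subject matrices.
#'
#' @param x,z row-aligned samples-by-features matrices (raw scale; both are
#'   column standardized internally).
#' @param H number of dimensions.
#' @param keepX,keepZ number of features with nonzero loadings per dimension
#'   (recycled to length H; defaults keep all).
#' @param tol,maxIter convergence tolerance (max absolute change in the
#'   loading vectors) and iteration cap of the alternating updates.
#' @return an [SPLSModel-class].
#' @seealso [fitSPLSDA()], [selectedFeatures()], [tuneCov()]
#' @export
fitSPLS <- function(x, z, H = 2L, keepX = ncol(x), keepZ = ncol(z),
                    tol = 1e-06, maxIter = 500L) {
    sx <- standardizeColumns(x); sz <- standardizeColumns(z)
    keepX <- pmin(as.integer(keepX), ncol(sx$x))
    keepZ <- pmin(as.integer(keepZ), ncol(sz$x))
    eng <- .splsEngine(sx$x, sz$x, as.integer(H), keepX, keepZ,
                       zDeflation = "modeA", tol = tol, maxIter = maxIter)
    .newSPLSModel("SPLSModel", eng, sx$stats, sz$stats)
}

#' Fit a sparse PLS discriminant analysis model
#'
#' Runs the sparse PLS engine with the Z block set to the standardized one-hot
#' dummy matrix of the group labels: per dimension the criterion
#' cor(Y, X u) var(X u) is maximized through the covariance engine, with an L1
#' constraint inducing at most `keepX[h]` nonzero loadings. The dummy block is
#' left unpenalized and deflated in regression mode by default (keeping the
#' prediction coefficients well-defined); X is deflated by its own score. The
#' p x G coefficient matrices beta (one per number of components) are
#' assembled as W (C' W)^{-1} Q' so that class scores for new data are
#' Yhat = X_std beta.
#'
#' @param x samples-by-features matrix (typically a within-subject matrix;
#'   standardized internally).
#' @param groups length-N group labels (>= 2 levels).
#' @param H number of dimensions; defaults to one less than the number of
#'   groups.
#' @param keepX number of features selected per dimension (recycled to length
#'   H; default keeps all).
#' @param yDeflation deflation mode for the dummy block.
#' @inheritParams fitSPLS
#' @return an [SPLSDAModel-class].
#' @seealso [predict,SPLSDAModel-method], [selectedFeatures()], [losoCV()]
#' @export
fitSPLSDA <- function(x, groups, H = NULL, keepX = ncol(x),
                      yDeflation = c("regression", "modeA"),
                      tol = 1e-06, maxIter = 500L) {
    yDeflation <- match.arg(yDeflation)
    Y <- dummyMatrix(groups)
    if (nrow(Y) != nrow(x)) stop("'groups' must have one label per row of 'x'")
    if (is.null(H)) H <- ncol(Y) - 1L
    H <- as.integer(H)
    if (length(keepX) > H) stop("keepX has more entries than dimensions H")
    sx <- standardizeColumns(x)
    sy <- standardizeColumns(Y)
    keepX <- pmin(as.integer(keepX), ncol(sx$x))
    eng <- .splsEngine(sx$x, sy$x, H, keepX, keepZ = ncol(sy$x),
                       zDeflation = yDeflation, tol = tol, maxIter = maxIter)
    ## prediction coefficients per number of components:
    ## beta_h = W_[,1:h] (C_[,1:h]' W_[,1:h])^{-1} Q_[,1:h]'
    beta <- lapply(seq_len(H), function(h) {
        W <- eng$U[, seq_len(h), drop = FALSE]
        Ch <- eng$C[, seq_len(h), drop = FALSE]
        Q <- eng$D[, seq_len(h), drop = FALSE]
        B <- W %*% solve(crossprod(Ch, W), t(Q))
        dimnames(B) <- list(colnames(sx$x), colnames(Y))
        B
    })
    .newSPLSModel("SPLSDAModel", eng, sx$stats, sy$stats,
                  levels = colnames(Y), Y = Y, beta = beta)
}

#' @rdname selectedFeatures
#' @export
setMethod("selectedFeatures", "SPLSModel", function(object, block = "X") {
    W <- featureLoadings(object, block)
    perDim <- lapply(seq_len(object@H), function(h) {
        w <- W[, h]
        nz <- which(w != 0)
        rownames(W)[nz[order(-abs(w[nz]))]]
    })
    names(perDim) <- paste0("dim", seq_len(object@H))
    c(perDim, list(union = unique(unlist(perDim))))
})

#' @rdname model-accessors
#' @export
setMethod("featureLoadings", "SPLSModel", function(object, block = "X") {
    block <- match.arg(block, c("X", "Z"))
    if (block == "X") object@loadingsX else object@loadingsZ
})

#' @rdname model-accessors
#' @export
setMethod("latentScores", "SPLSModel", function(object, block = "X") {
    block <- match.arg(block, c("X", "Z"))
    if (block == "X") object@scoresX else object@scoresZ
})

#' @rdname groupLevels
#' @export
setMethod("groupLevels", "SPLSDAModel", function(object) object@levels)

#' Predict class membership with a sparse PLS-DA model
#'
#' New rows are centred and scaled with the training standardization
#' statistics, class scores computed as Yhat = X_std beta and mapped back to
#' the scale of the dummy matrix; the predicted class is the column with the
#' largest score (ties broken toward the first level). For multilevel models
#' the caller supplies within-subject deviation rows for the test subjects.
#'
#' @param object a fitted [SPLSDAModel-class].
#' @param newdata numeric matrix containing the model's features as columns.
#' @param ncomp number of components to use (default: all).
#' @return a list with `class` (factor of predicted labels) and `scores`
#'   (N x G matrix of class scores).
#' @export
setMethod("predict", "SPLSDAModel", function(object, newdata, ncomp = object@H) {
    if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
    ncomp <- as.integer(ncomp)
    if (ncomp < 1L || ncomp > object@H)
        stop("ncomp must lie in [1, ", object@H, "]")
    xs <- applyStandardization(newdata, object@statsX)
    yhat <- xs %*% object@beta[[ncomp]]
    ## back to the raw dummy scale (Y was standardized like any block)
    yhat <- sweep(sweep(yhat, 2L, object@statsZ@scale, "*"), 2L,
                  object@statsZ@center, "+")
    cls <- factor(object@levels[max.col(yhat, ties.method = "first")],
                  levels = object@levels)
    names(cls) <- rownames(newdata)
    list(class = cls, scores = yhat)
})

setMethod("show", "SPLSModel", function(object) {
    cat("SPLSModel (mode ", object@zDeflation, "): ",
        nrow(object@scoresX), " samples, ", nrow(object@loadingsX),
        " x ", nrow(object@loadingsZ), " features, H = ", object@H, "\n",
        sep = "")
    cat("  keepX:", paste(object@keepX, collapse = ", "),
        " keepZ:", paste(object@keepZ, collapse = ", "), "\n")
})

setMethod("show", "SPLSDAModel", function(object) {
    cat("SPLSDAModel: ", nrow(object@scoresX), " samples, ",
        nrow(object@loadingsX), " features, ", length(object@levels),
        " groups (", paste(object@levels, collapse = ", "), "), H = ",
        object@H, "\n", sep = "")
    cat("  keepX:", paste(object@keepX, collapse = ", "), "\n")
})
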
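# Mixed-model simulator with correlated gene clusters and the
# classical-vs-multilevel benchmark (gene recovery and leave-one-subject-out
# error at fixed selection sizes).

#' Construct a simulation specification
#'
#' Defaults reproduce the benchmark generator: 12 subjects x 4 stimulations,
#' 10 clusters of 100 genes (6 discriminative, 4 noise), subject effect
#' sd sigmaPi = 2, residual sd sigmaEps = 0.5, intra-cluster correlation
#' rho = 0.8. See [SimulationSpec-class] for the model.
#'
#' @param nSubjects,conditions,genesPerCluster,sigmaPi,sigmaEps,rho,seed see
#'   [SimulationSpec-class].
#' @param clusterMeans list of per-cluster condition mean vectors; clusters
#'   whose mean vector is non-constant are the true discriminative genes.
#' @return a validated [SimulationSpec-class].
#' @examples
#' spec <- simulationSpec()
#' sim <- simulateDataset(spec, seed = 1)
#' dim(sim$x)      # 48 x 1000
#' sum(sim$truth)  # 600
#' @export
simulationSpec <- function(nSubjects = 12L,
                           conditions = c("LIPO5", "GAG+", "GAG-", "NS"),
                           clusterMeans = list(
                               c(4, 4, 0, 0), c(3, 3, 0, 0),
                               c(5, 2, 0.2, 0.2), c(5, 2, 0, 0),
                               c(1, 1, 5, 2), c(0, 0, 5, 2),
                               c(0, 0, 0, 0), c(0.5, 0.5, 0.5, 0.5),
                               c(0, 0, 0, 0), c(0.5, 0.5, 0.5, 0.5)),
                           genesPerCluster = 100L, sigmaPi = 2,
                           sigmaEps = 0.5, rho = 0.8, seed = 1L) {
    new("SimulationSpec", nSubjects = as.integer(nSubjects),
        conditions = as.character(conditions), clusterMeans = clusterMeans,
        genesPerCluster = as.integer(genesPerCluster),
        sigmaPi = sigmaPi, sigmaEps = sigmaEps, rho = rho,
        seed = as.integer(seed))
}

setMethod("show", "SimulationSpec", function(object) {
    nDisc <- sum(vapply(object@clusterMeans,
                        function(m) diff(range(m)) > 0, TRUE))
    cat("SimulationSpec:", object@nSubjects, "subjects x",
        length(object@conditions), "conditions;",
        length(object@clusterMeans), "clusters x", object@genesPerCluster,
        "genes (", nDisc, "discriminative )\n")
    cat("  sigmaPi =", object@sigmaPi, ", sigmaEps =", object@sigmaEps,
        ", rho =", object@rho, "\n")
})

#' Simulate a repeated-measures expression data set
#'
#' Draws X_sjk = mu_jk + pi_sk + eps_sjk with one multivariate-normal draw of
#' the subject effect per (subject, cluster) and one of the residual per
#' (subject, condition, cluster), each with equicorrelated covariance
#' (variance sigma^2 on the diagonal, rho sigma^2 off it, sampled through its
#' Cholesky factor); genes in different clusters are independent.
#' Deterministic given the seed.
#'
#' @param spec a [SimulationSpec-class].
#' @param seed random seed (defaults to the spec's).
#' @param returnComponents also return the raw subject-effect and residual
#'   draws (used for moment checks).
#' @return a list with `x` (N x p matrix, samples in rows), `design`
#'   (a [RepeatedMeasuresDesign-class]), `truth` (logical mask of the
#'   discriminative genes, i.e. genes in clusters with a non-constant mean
#'   vector) and, if requested, `components`.
#' @export
simulateDataset <- function(spec, seed = spec@seed, returnComponents = FALSE) {
    validObject(spec)
    set.seed(as.integer(seed))
    n <- spec@nSubjects
    G <- length(spec@conditions)
    m <- spec@genesPerCluster
    K <- length(spec@clusterMeans)
    N <- n * G
    ## Cholesky factor of the equicorrelation matrix (shared by both terms)
    Rchol <- chol(matrix(spec@rho, m, m) + diag(1 - spec@rho, m))
    condIdx <- rep(seq_len(G), times = n)
    subjIdx <- rep(seq_len(n), each = G)
    x <- matrix(0, N, K * m)
    piAll <- if (returnComponents) matrix(0, n, K * m) else NULL
    epsAll <- if (returnComponents) matrix(0, N, K * m) else NULL
    for (k in seq_len(K)) {
        cols <- ((k - 1L) * m + 1L):(k * m)
        piMat <- (matrix(stats::rnorm(n * m), n, m) %*% Rchol) * spec@sigmaPi
        epsMat <- (matrix(stats::rnorm(N * m), N, m) %*% Rchol) * spec@sigmaEps
        x[, cols] <- spec@clusterMeans[[k]][condIdx] + piMat[subjIdx, ] + epsMat
        if (returnComponents) {
            piAll[, cols] <- piMat
            epsAll[, cols] <- epsMat
        }
    }
    subjLab <- sprintf("s%02d", subjIdx)
    rownames(x) <- paste(subjLab, spec@conditions[condIdx], sep = "_")
    colnames(x) <- sprintf("c%02d_g%03d", rep(seq_len(K), each = m),
                           rep(seq_len(m), K))
    design <- repeatedMeasuresDesign(rownames(x), subjLab,
                                     spec@conditions[condIdx])
    truth <- rep(vapply(spec@clusterMeans,
                        function(mu) diff(range(mu)) > 0, TRUE), each = m)
    names(truth) <- colnames(x)
    out <- list(x = x, design = design, truth = truth)
    if (returnComponents)
        out$components <- list(pi = piAll, eps = epsAll, cluster =
                               rep(seq_len(K), each = m))
    out
}

#' Selection accuracy against the simulated truth
#'
#' @param selected per-dimension feature lists, e.g. from
#'   [selectedFeatures()] (an element named `union` is ignored and recomputed).
#' @param truth named logical mask of the true discriminative genes.
#' @return a list with `perDimension` (percent of each dimension's selected
#'   genes that are truth genes), `overall` (percent of truth genes present in
#'   the union of all selections) and `unionSize`.
#' @export
selectionAccuracy <- function(selected, truth) {
    truthGenes <- names(truth)[truth]
    if (!length(truthGenes)) stop("truth mask marks no genes")
    dims <- selected[setdiff(names(selected), "union")]
    perDim <- vapply(dims, function(s) {
        if (!length(s)) return(NA_real_)
        100 * mean(s %in% truthGenes)
    }, 1.0)
    un <- unique(unlist(dims))
    list(perDimension = perDim,
         overall = 100 * mean(truthGenes %in% un),
         unionSize = length(un))
}

## derive one sub-seed per replicate; kept below 2^31
.runSeeds <- function(seed, nRuns) as.integer(seed) + seq_len(nRuns) * 1000L

#' Benchmark gene recovery: multilevel versus classical selection
#'
#' For each replicate, simulates a data set, fits sparse PLS-DA with a fixed
#' number of genes per dimension on (i) the within matrix (multilevel) and
#' (ii) the raw matrix (classical), and measures the percentage of the true
#' discriminative genes recovered in the union of the selections, plus
#' per-dimension precisions.
#'
#' @param spec a [SimulationSpec-class].
#' @param nRuns number of replicate simulations.
#' @param keepPerDim genes selected on each dimension (default 200).
#' @param H number of dimensions (default 3).
#' @param seed base seed; replicate r uses seed + 1000 r.
#' @return a list with `perRun` (data.frame of per-replicate overall
#'   recoveries) and `summary` (mean per-dimension precision and overall
#'   recovery per method).
#' @seealso [benchmarkErrorRate()]
#' @export
benchmarkSelection <- function(spec, nRuns = 20L, keepPerDim = 200L, H = 3L,
                               seed = spec@seed) {
    seeds <- .runSeeds(seed, nRuns)
    keepX <- rep(as.integer(keepPerDim), H)
    perRun <- data.frame(run = seq_len(nRuns), seed = seeds,
                         multilevel = NA_real_, classical = NA_real_)
    dimAcc <- array(NA_real_, c(nRuns, H, 2L),
                    dimnames = list(NULL, paste0("dim", seq_len(H)),
                                    c("multilevel", "classical")))
    for (r in seq_len(nRuns)) {
        sim <- simulateDataset(spec, seed = seeds[r])
        xw <- withinMatrix(splitOneFactor(sim$x, sim$design))
        groups <- sim$design@condition
        fm <- fitSPLSDA(xw, groups, H = H, keepX = keepX)
        fc <- fitSPLSDA(sim$x, groups, H = H, keepX = keepX)
        am <- selectionAccuracy(selectedFeatures(fm), sim$truth)
        ac <- selectionAccuracy(selectedFeatures(fc), sim$truth)
        perRun$multilevel[r] <- am$overall
        perRun$classical[r] <- ac$overall
        dimAcc[r, , "multilevel"] <- am$perDimension
        dimAcc[r, , "classical"] <- ac$perDimension
    }
    dimMeans <- rbind(
        multilevel = apply(dimAcc[, , "multilevel", drop = FALSE], 2L, mean),
        classical = apply(dimAcc[, , "classical", drop = FALSE], 2L, mean))
    summary <- data.frame(
        method = rownames(dimMeans), dimMeans,
        overall = c(mean(perRun$multilevel), mean(perRun$classical)),
        row.names = NULL)
    list(perRun = perRun, summary = summary,
         orderingFraction = mean(perRun$multilevel > perRun$classical))
}

#' Benchmark leave-one-subject-out error over a selection-size grid
#'
#' For each replicate and each grid value, runs subject-structured
#' leave-one-subject-out cross-validation of sparse PLS-DA fitted on the
#' within matrix (multilevel) and on the raw matrix (classical), recording the
#' mean classification error with 1, ..., H components, then averages over
#' replicates.
#'
#' @inheritParams benchmarkSelection
#' @param keepGrid grid of genes selected per dimension (default 25 to 325 by
#'   25).
#' @return a list with `mean` (data.frame: keep, method, one column per
#'   component count) and `perRun` (4-d array run x keep x method x ncomp).
#' @export
benchmarkErrorRate <- function(spec, nRuns = 20L,
                               keepGrid = seq(25L, 325L, by = 25L), H = 3L,
                               seed = spec@seed) {
    seeds <- .runSeeds(seed, nRuns)
    keepGrid <- as.integer(keepGrid)
    methods <- c("multilevel", "classical")
    perRun <- array(NA_real_,
                    c(nRuns, length(keepGrid), 2L, H),
                    dimnames = list(NULL, keepGrid, methods,
                                    paste0("comp", seq_len(H))))
    for (r in seq_len(nRuns)) {
        sim <- simulateDataset(spec, seed = seeds[r])
        for (g in seq_along(keepGrid)) {
            keepX <- rep(keepGrid[g], H)
            perRun[r, g, "multilevel", ] <-
                losoError(sim$x, sim$design, keepX, H, multilevel = TRUE)
            perRun[r, g, "classical", ] <-
                losoError(sim$x, sim$design, keepX, H, multilevel = FALSE)
        }
    }
    avg <- apply(perRun, c(2L, 3L, 4L), mean)
    mean <- do.call(rbind, lapply(methods, function(m) {
        data.frame(keep = keepGrid, method = m,
                   matrix(avg[, m, ], length(keepGrid), H,
                          dimnames = list(NULL, paste0("comp", seq_len(H)))),
                   check.names = FALSE)
    }))
    list(mean = mean, perRun = perRun)
}
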
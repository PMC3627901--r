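# Sparse PLS engine: standardization, dummy coding, SVD/PCA/brute-force
# oracles, sparsity and deflation invariants, prediction coefficients.

test_that("standardization uses the N-1 denominator and is idempotent", {
    x <- cbind(g1 = c(1, 3), g2 = c(0, 2))
    s <- standardizeColumns(x)
    expect_equal(unname(s$x[, "g1"]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
    expect_equal(unname(s$stats@scale), c(sqrt(2), sqrt(2)))

    s2 <- standardizeColumns(s$x)
    expect_equal(s2$x, s$x, tolerance = 1e-12)

    xc <- cbind(x, flat = c(1, 1))
    expect_message(s3 <- standardizeColumns(xc), "zero-variance")
    expect_identical(colnames(s3$x), c("g1", "g2"))
    expect_identical(s3$stats@dropped, "flat")

    expect_error(standardizeColumns(cbind(a = c(1, 1))), "zero variance")
})

test_that("dummy matrix is one-hot with first-appearance column order", {
    Y <- dummyMatrix(c("A", "A", "B"))
    expect_equal(unname(Y), rbind(c(1, 0), c(1, 0), c(0, 1)))
    expect_identical(colnames(Y), c("A", "B"))

    g <- rep(c("A", "B", "C", "D"), 12)
    Y2 <- dummyMatrix(g)
    expect_identical(dim(Y2), c(48L, 4L))
    expect_equal(unname(colSums(Y2)), rep(12, 4))

    perm <- sample(48)
    expect_equal(dummyMatrix(g[perm]), Y2[perm, colnames(dummyMatrix(g[perm]))])
    expect_error(dummyMatrix(rep("A", 5)), "2 group levels")
})

test_that("with all variables kept the engine matches the dense SVD of each cross-product", {
    set.seed(101)
    for (i in 1:100) {
        n <- sample(8:12, 1); p <- sample(4:7, 1); q <- sample(3:5, 1)
        x <- matrix(rnorm(n * p), n, p,
                    dimnames = list(NULL, paste0("x", 1:p)))
        z <- matrix(rnorm(n * q), n, q,
                    dimnames = list(NULL, paste0("z", 1:q)))
        fit <- fitSPLS(x, z, H = 2, keepX = p, keepZ = q)
        Xd <- scale(x); Zd <- scale(z)
        for (h in 1:2) {
            sv <- svd(crossprod(Xd, Zd), nu = 1, nv = 1)
            expect_equal(abs(drop(crossprod(sv$u, fit@loadingsX[, h]))), 1,
                         tolerance = 1e-6)
            expect_equal(abs(drop(crossprod(sv$v, fit@loadingsZ[, h]))), 1,
                         tolerance = 1e-6)
            ## covariance of the score pair equals the singular value / (n-1)
            expect_equal(abs(cov(fit@scoresX[, h], fit@scoresZ[, h])),
                         sv$d[1] / (n - 1), tolerance = 1e-6)
            ## deflate exactly as the model reports
            Xd <- Xd - tcrossprod(fit@scoresX[, h], fit@coefX[, h])
            Zd <- Zd - tcrossprod(fit@scoresZ[, h], fit@coefZ[, h])
        }
        expect_equal(unname(Xd), unname(fit@residualX), tolerance = 1e-8,
                     ignore_attr = TRUE)
    }
})

test_that("keepX = 1 selects the brute-force optimal single feature", {
    set.seed(55)
    for (i in 1:20) {
        n <- 20
        z <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("z", 1:3)))
        x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("x", 1:5)))
        j <- sample(5, 1)
        x[, j] <- x[, j] + 4 * z[, 1]  # plant one feature tied to Z
        fit <- fitSPLS(x, z, H = 1, keepX = 1, keepZ = 3)
        u <- fit@loadingsX[, 1]
        expect_identical(sum(u != 0), 1L)
        ## for a single feature x_j the objective cov(x_j, Zv) is maximized at
        ## v proportional to Z_std' x_j, with value ||Z_std' x_j|| / (N - 1):
        ## the brute-force optimum is the column with the largest ||Z_std' x_j||
        best <- unname(which.max(colSums(crossprod(scale(z), scale(x))^2)))
        expect_identical(unname(which(u != 0)), best)
        expect_identical(best, j)  # the planted feature wins by construction
    }
})

test_that("sPLS of a matrix with itself recovers the first principal component", {
    set.seed(77)
    x <- matrix(rnorm(15 * 6), 15, 6, dimnames = list(NULL, paste0("g", 1:6)))
    fit <- fitSPLS(x, x, H = 1, keepX = 6, keepZ = 6)
    pc1 <- prcomp(x, center = TRUE, scale. = TRUE)$x[, 1]
    expect_equal(abs(cor(fit@scoresX[, 1], pc1)), 1, tolerance = 1e-6)
    ## self-covariance: cov(xi, omega) = var(xi)
    expect_equal(cov(fit@scoresX[, 1], fit@scoresZ[, 1]),
                 var(fit@scoresX[, 1]), tolerance = 1e-8)
})

test_that("sparsity is exact, loadings unit-norm, scores orthogonal, deflation consistent", {
    set.seed(88)
    n <- 20; p <- 30
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("g", 1:p)))
    g <- rep(c("A", "B", "C", "D"), 5)
    keep <- c(7L, 12L, 30L)
    fit <- fitSPLSDA(x, g, H = 3, keepX = keep)
    expect_identical(as.integer(colSums(fit@loadingsX != 0)), keep)
    expect_equal(unname(sqrt(colSums(fit@loadingsX^2))), rep(1, 3),
                 tolerance = 1e-8)
    expect_equal(unname(sqrt(colSums(fit@loadingsZ^2))), rep(1, 3),
                 tolerance = 1e-8)
    ## score orthogonality under deflation by own scores
    S <- crossprod(fit@scoresX)
    offDiag <- S - diag(diag(S))
    expect_lt(max(abs(offDiag)), 1e-6 * max(diag(S)))
    ## sign convention: largest-|entry| coordinate positive
    for (h in 1:3) {
        u <- fit@loadingsX[, h]
        expect_gt(u[which.max(abs(u))], 0)
    }
    ## deflation identity per dimension
    Xh <- standardizeColumns(x)$x
    for (h in 1:3) {
        ch <- drop(crossprod(Xh, fit@scoresX[, h])) /
            sum(fit@scoresX[, h]^2)
        expect_equal(ch, fit@coefX[, h], tolerance = 1e-8)
        Xh <- Xh - tcrossprod(fit@scoresX[, h], ch)
    }
    expect_equal(Xh, fit@residualX, tolerance = 1e-8)
})

test_that("full-keep sPLS-DA dimension 1 matches the SVD of X'Y and the reference package", {
    set.seed(99)
    n <- 16; p <- 10
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("g", 1:p)))
    x[, 1] <- x[, 1] + rep(c(2, 0), each = n / 2)
    g <- rep(c("A", "B"), each = n / 2)
    fit <- fitSPLSDA(x, g, H = 1, keepX = p)
    sv <- svd(crossprod(scale(x), scale(dummyMatrix(g))), nu = 1)
    expect_equal(abs(drop(crossprod(sv$u, fit@loadingsX[, 1]))), 1,
                 tolerance = 1e-6)

    skip_if_not_installed("mixOmics")
    ref <- mixOmics::splsda(x, factor(g), ncomp = 1, keepX = p)
    uRef <- ref$loadings$X[, 1]
    expect_equal(abs(drop(crossprod(uRef, fit@loadingsX[, 1]))), 1,
                 tolerance = 1e-4)
})

test_that("a separable toy is solved by a single selected feature and beta reproduces training fits", {
    set.seed(12)
    toy <- separableToy()
    fit <- fitSPLSDA(toy$x, toy$design@condition, H = 1, keepX = 1)
    expect_identical(selectedFeatures(fit)$dim1, "signal")
    pred <- predict(fit, toy$x)
    expect_equal(mean(pred$class != toy$design@condition), 0)

    ## beta consistency: X_std beta equals the score-space fitted values
    fit3 <- fitSPLSDA(toy$x, toy$design@condition, H = 2, keepX = c(2, 3))
    Xstd <- applyStandardization(toy$x, fit3@statsX)
    fitted <- fit3@scoresX %*% t(fit3@coefZ)
    expect_equal(Xstd %*% fit3@beta[[2]], fitted, tolerance = 1e-8,
                 ignore_attr = TRUE)
    ## in-sample class predictions reproduced
    predIn <- predict(fit3, toy$x)$class
    expect_equal(as.character(predIn), as.character(toy$design@condition))
})

test_that("flipping the group label order flips loadings' roles but not predictions", {
    set.seed(13)
    toy <- separableToy()
    g1 <- as.character(toy$design@condition)
    fit1 <- fitSPLSDA(toy$x, g1, H = 1)
    g2 <- factor(g1, levels = c("B", "A"))
    fit2 <- fitSPLSDA(toy$x, g2, H = 1)
    p1 <- predict(fit1, toy$x)$class
    p2 <- predict(fit2, toy$x)$class
    expect_identical(as.character(p1), as.character(p2))
})

test_that("prediction at the training column means is a tie broken by the first level", {
    set.seed(14)
    toy <- separableToy()
    fit <- fitSPLSDA(toy$x, toy$design@condition, H = 1)
    centerRow <- matrix(fit@statsX@center, 1,
                        dimnames = list("c", names(fit@statsX@center)))
    pred <- predict(fit, centerRow)
    expect_equal(unname(pred$scores[1, "A"]), unname(pred$scores[1, "B"]),
                 tolerance = 1e-10)
    expect_identical(as.character(pred$class), "A")
    badCols <- toy$x[, 1:2]
    colnames(badCols) <- c("wrong1", "wrong2")
    expect_error(predict(fit, badCols), "training feature")
})

test_that("model selection reports are shaped by keepX, with empty dimensions allowed", {
    set.seed(15)
    x <- matrix(rnorm(24 * 12), 24, 12, dimnames = list(NULL, paste0("g", 1:12)))
    g <- rep(c("A", "B", "C"), 8)
    fit <- fitSPLSDA(x, g, H = 2, keepX = c(3, 5))
    sel <- selectedFeatures(fit)
    expect_identical(lengths(sel[c("dim1", "dim2")]), c(dim1 = 3L, dim2 = 5L))
    expect_lte(length(sel$union), 8L)
    expect_error(fitSPLSDA(x, g, H = 2, keepX = c(1, 2, 3)), "more entries")
    expect_error(fitSPLSDA(x, g, H = 30), "H must lie")
})
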
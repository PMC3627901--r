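# Split-up variation: hand-checked one-factor example, reconstruction and
# sum-of-squares identities, subject locality, and the two-factor extension.

test_that("one-factor decomposition matches the hand-computed example", {
    d <- repeatedMeasuresDesign(paste0("r", 1:4), c("a", "a", "b", "b"),
                                c("A", "B", "A", "B"))
    x <- matrix(c(1, 3, 5, 7), 4, 1, dimnames = list(paste0("r", 1:4), "g1"))
    dec <- splitOneFactor(x, d)
    expect_equal(unname(offsetMatrix(dec)[, 1]), rep(4, 4))
    expect_equal(unname(betweenMatrix(dec)[, 1]), c(-2, -2, 2, 2))
    expect_equal(unname(withinMatrix(dec)[, 1]), c(-1, 1, -1, 1))
    ss <- sumsOfSquares(dec)
    expect_equal(unname(ss[c("offset", "between", "within", "total")]),
                 c(64, 16, 4, 84))
    vs <- variationSummary(dec)
    expect_equal(vs$fraction[match(c("offset", "between", "within"), vs$part)],
                 c(64, 16, 4) / 84)
    expect_lt(attr(vs, "identityResidual"), 1e-12)
})

test_that("degenerate inputs: constant matrix and single subject", {
    d <- repeatedMeasuresDesign(paste0("r", 1:4), c("a", "a", "b", "b"),
                                c("A", "B", "A", "B"))
    x <- matrix(5, 4, 2, dimnames = list(paste0("r", 1:4), c("g1", "g2")))
    dec <- splitOneFactor(x, d)
    expect_equal(max(abs(betweenMatrix(dec))), 0)
    expect_equal(max(abs(withinMatrix(dec))), 0)

    d1 <- repeatedMeasuresDesign(paste0("r", 1:3), rep("a", 3),
                                 c("A", "B", "C"))
    x1 <- matrix(rnorm(6), 3, 2,
                 dimnames = list(paste0("r", 1:3), c("g1", "g2")))
    dec1 <- splitOneFactor(x1, d1)
    expect_equal(max(abs(betweenMatrix(dec1))), 0)  # x_s. == x_.. when n = 1

    xBad <- x1[c(2, 1, 3), ]
    expect_error(splitOneFactor(xBad, d1), "same order")
})

test_that("reconstruction and sum-of-squares identities hold on random unbalanced designs", {
    set.seed(42)
    for (i in 1:200) {
        design <- randomUnbalancedDesign()
        x <- randomMatrixFor(design, p = sample(1:6, 1))
        dec <- splitOneFactor(x, design)
        recon <- offsetMatrix(dec) + betweenMatrix(dec) + withinMatrix(dec)
        expect_lt(max(abs(x - recon)), 1e-10 * max(abs(x)))
        ss <- sumsOfSquares(dec)
        expect_lt(abs(ss[["total"]] -
                      sum(ss[c("offset", "between", "within")])),
                  1e-8 * ss[["total"]])
        ## per-subject within rows sum to zero
        bySubj <- rowsum(withinMatrix(dec), dec@design@subject)
        expect_lt(max(abs(bySubj)), 1e-10 * max(abs(x), 1))
    }
})

test_that("a subject's within rows depend only on its own samples (locality)", {
    set.seed(7)
    design <- randomUnbalancedDesign(nSubjects = 5, nConditions = 4)
    x <- randomMatrixFor(design, p = 4)
    w1 <- withinMatrix(splitOneFactor(x, design))
    target <- design@subject == levels(design@subject)[1]
    x2 <- x
    x2[!target, ] <- x2[!target, ] + matrix(rnorm(sum(!target) * 4, sd = 5),
                                            sum(!target), 4)
    w2 <- withinMatrix(splitOneFactor(x2, design))
    expect_equal(w1[target, ], w2[target, ], tolerance = 1e-12)
})

test_that("two-factor split satisfies its identities and margin checks", {
    set.seed(21)
    design <- twoFactorDesign(nSubjects = 4, nConditions = 3, nTimes = 2)
    x <- randomMatrixFor(design, p = 5)
    dec <- splitTwoFactor(x, design)

    ## within == within* + subject x condition + subject x time
    lhs <- withinMatrix(dec)
    rhs <- withinStarMatrix(dec) + dec@subjectByCondition + dec@subjectByTime
    expect_lt(max(abs(lhs - rhs)), 1e-10 * max(abs(x)))

    ## balanced case: component matrices pairwise orthogonal
    parts <- list(dec@offset, dec@between, dec@conditionEffect,
                  dec@timeEffect, dec@interactionEffect, dec@residualEffect,
                  dec@subjectByCondition, dec@subjectByTime)
    tolOrth <- 1e-8 * sum(x^2)
    for (i in seq_along(parts)) for (j in seq_along(parts)) {
        if (i < j)
            expect_lt(abs(sum(parts[[i]] * parts[[j]])), tolOrth)
    }

    ## within* is the sum of the four fixed-effect matrices in a balanced design
    expect_lt(max(abs(withinStarMatrix(dec) -
                      (dec@conditionEffect + dec@timeEffect +
                       dec@interactionEffect + dec@residualEffect))),
              1e-10 * max(abs(x)))

    ## unbalanced: drop one (s, j, t) cell, identity still holds by construction
    keep <- -5L
    decU <- splitTwoFactor(x[keep, ], design[keep])
    lhsU <- withinMatrix(decU)
    rhsU <- withinStarMatrix(decU) + decU@subjectByCondition +
        decU@subjectByTime
    expect_lt(max(abs(lhsU - rhsU)), 1e-10 * max(abs(x)))

    ## empty (subject, condition) margin is refused with the margin named
    drop2 <- !(design@subject == "s01" & design@condition == "A")
    expect_error(splitTwoFactor(x[drop2, ], design[drop2]),
                 "subject 's01' x condition 'A'")
})

test_that("within* is invariant to additive per-subject offsets", {
    set.seed(22)
    design <- twoFactorDesign(nSubjects = 3, nConditions = 2, nTimes = 2)
    x <- randomMatrixFor(design, p = 3)
    offsets <- rnorm(nlevels(design@subject), sd = 4)
    x2 <- x + offsets[as.integer(design@subject)]
    dec1 <- splitTwoFactor(x, design)
    dec2 <- splitTwoFactor(x2, design)
    expect_equal(withinStarMatrix(dec1), withinStarMatrix(dec2),
                 tolerance = 1e-10)
})

test_that("zero noise with no subject-interaction structure gives zero random interactions", {
    design <- twoFactorDesign(nSubjects = 3, nConditions = 2, nTimes = 2)
    ## pure fixed-effects table: condition effect + time effect + subject offset
    condEff <- c(A = 1, B = -1)[as.character(design@condition)]
    timeEff <- c(t1 = 0.5, t2 = -0.5)[as.character(design@time)]
    subjEff <- c(2, -1, 4)[as.integer(design@subject)]
    x <- matrix(condEff + timeEff + subjEff, ncol = 1,
                dimnames = list(design@sample, "g1"))
    x <- cbind(x, g2 = 2 * x[, 1])
    dec <- splitTwoFactor(x, design)
    expect_lt(max(abs(dec@subjectByCondition)), 1e-12)
    expect_lt(max(abs(dec@subjectByTime)), 1e-12)
})

test_that("one-factor within matrix agrees with the reference implementation", {
    skip_if_not_installed("mixOmics")
    set.seed(5)
    sim <- simulateDataset(simulationSpec(genesPerCluster = 5L), seed = 5)
    dec <- splitOneFactor(sim$x, sim$design)
    ref <- mixOmics::withinVariation(
        sim$x, design = data.frame(sample = as.character(sim$design@subject)))
    expect_equal(unname(withinMatrix(dec)), unname(as.matrix(ref)),
                 tolerance = 1e-10)
})

test_that("pure-noise between fraction shrinks when the subject effect is absent", {
    set.seed(9)
    spec <- simulationSpec(nSubjects = 40L, genesPerCluster = 10L,
                           sigmaPi = 0, sigmaEps = 1,
                           clusterMeans = rep(list(rep(0, 4)), 2))
    sim <- simulateDataset(spec, seed = 9)
    vs <- variationSummary(splitOneFactor(sim$x, sim$design))
    ## E[between SS fraction] ~ (n-1)/(N-1) ~ 1/G when sigma_pi = 0
    expect_lt(vs$fraction[vs$part == "between"], 0.35)
})
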
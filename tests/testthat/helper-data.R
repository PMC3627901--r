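# Fixture builders shared across the test files. All data are generated in
# code; callers control the RNG with set.seed().

## random one-factor design, unbalanced: each subject sees a random subset
## (>= 2) of the conditions, at most once each
randomUnbalancedDesign <- function(nSubjects = sample(2:6, 1),
                                   nConditions = sample(2:4, 1)) {
    conds <- LETTERS[seq_len(nConditions)]
    rows <- do.call(rbind, lapply(seq_len(nSubjects), function(s) {
        k <- (2:nConditions)[sample.int(nConditions - 1L, 1L)]
        g <- sort(sample(nConditions, k))
        data.frame(subject = sprintf("s%02d", s), condition = conds[g])
    }))
    rows$sample <- sprintf("r%03d", seq_len(nrow(rows)))
    repeatedMeasuresDesign(rows$sample, rows$subject, rows$condition)
}

randomMatrixFor <- function(design, p = 5L) {
    n <- length(design@sample)
    matrix(rnorm(n * p), n, p,
           dimnames = list(design@sample, sprintf("g%02d", seq_len(p))))
}

## balanced two-factor cross-over design
twoFactorDesign <- function(nSubjects = 3L, nConditions = 2L, nTimes = 2L) {
    grid <- expand.grid(time = paste0("t", seq_len(nTimes)),
                        condition = LETTERS[seq_len(nConditions)],
                        subject = sprintf("s%02d", seq_len(nSubjects)),
                        stringsAsFactors = FALSE)
    grid$sample <- sprintf("r%03d", seq_len(nrow(grid)))
    repeatedMeasuresDesign(grid$sample, grid$subject, grid$condition,
                           grid$time)
}

## cross-over toy with two groups separated by one informative feature
## (+1 in group A, -1 in group B) plus near-silent noise features
separableToy <- function(nSubjects = 6L, nNoise = 4L, noiseSd = 0.01) {
    design <- repeatedMeasuresDesign(
        sample = sprintf("r%02d", seq_len(2L * nSubjects)),
        subject = rep(sprintf("s%02d", seq_len(nSubjects)), each = 2L),
        condition = rep(c("A", "B"), nSubjects))
    informative <- ifelse(design@condition == "A", 1, -1) +
        rnorm(2L * nSubjects, sd = noiseSd)
    noise <- matrix(rnorm(2L * nSubjects * nNoise, sd = noiseSd),
                    2L * nSubjects, nNoise)
    x <- cbind(informative, noise)
    dimnames(x) <- list(design@sample,
                        c("signal", sprintf("noise%d", seq_len(nNoise))))
    list(x = x, design = design)
}

## sign-align columns of b to a (for comparing loadings up to sign)
alignSign <- function(a, b) {
    b * rep(ifelse(colSums(a * b) < 0, -1, 1), each = nrow(b))
}

## a small spec for fast simulator-based tests
smallSpec <- function(...) simulationSpec(...)
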
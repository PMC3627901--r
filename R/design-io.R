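# Reading and validating expression matrices and design tables, aligning
# matched assays, and writing selection/score reports.

#' Construct a repeated-measures design
#'
#' @param sample character vector of unique sample ids.
#' @param subject,condition per-sample labels; converted to factors with
#'   levels in first-appearance order.
#' @param time optional per-sample labels of a second crossed factor.
#' @return a validated [RepeatedMeasuresDesign-class].
#' @examples
#' repeatedMeasuresDesign(paste0("s", 1:4), c("a", "a", "b", "b"),
#'                        c("A", "B", "A", "B"))
#' @export
repeatedMeasuresDesign <- function(sample, subject, condition, time = NULL) {
    firstAppearance <- function(v) factor(v, levels = unique(as.character(v)))
    new("RepeatedMeasuresDesign",
        sample = as.character(sample),
        subject = firstAppearance(subject),
        condition = firstAppearance(condition),
        time = if (is.null(time)) factor(character(0))
               else firstAppearance(time))
}

#' @describeIn repeatedMeasuresDesign whether the design carries a time factor.
#' @param object a [RepeatedMeasuresDesign-class].
#' @export
hasTimeFactor <- function(object) length(object@time) > 0L

#' Subset a design by sample index
#' @param x a [RepeatedMeasuresDesign-class]; `i` sample indices or ids.
#' @param i,j,drop,... index (j, drop unused).
#' @export
setMethod("[", "RepeatedMeasuresDesign", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) i <- match(i, x@sample)
    repeatedMeasuresDesign(x@sample[i],
        as.character(x@subject)[i], as.character(x@condition)[i],
        if (hasTimeFactor(x)) as.character(x@time)[i] else NULL)
})

#' @rdname groupLevels
#' @export
setMethod("groupLevels", "RepeatedMeasuresDesign",
    function(object) levels(object@condition))

setMethod("show", "RepeatedMeasuresDesign", function(object) {
    cat("RepeatedMeasuresDesign:", length(object@sample), "samples,",
        nlevels(object@subject), "subjects,",
        nlevels(object@condition), "conditions",
        if (hasTimeFactor(object))
            paste0("x ", nlevels(object@time), " time points"), "\n")
    cat("  condition levels:", paste(levels(object@condition), collapse = ", "),
        "\n")
    if (hasTimeFactor(object))
        cat("  time levels:", paste(levels(object@time), collapse = ", "), "\n")
})

#' Read a samples-by-features expression matrix
#'
#' Expects a delimited text file whose header row holds feature names and
#' whose first column holds sample ids. Any non-numeric or missing cell is a
#' parse error naming the offending sample and feature (no silent imputation).
#'
#' @param path path to the file.
#' @param delimiter field delimiter; defaults to tab for `.tsv`/`.txt` and
#'   comma for `.csv`.
#' @param transpose set to TRUE for features-in-rows files.
#' @return a numeric matrix with sample ids as rownames, validated as an
#'   expression matrix (N >= 2, unique names, no missing values).
#' @seealso [readDesign()], [alignMatched()]
#' @export
readExpressionMatrix <- function(path, delimiter = NULL, transpose = FALSE) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (is.null(delimiter))
        delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                             row.names = NULL, colClasses = "character",
                             check.names = FALSE, quote = "\"",
                             comment.char = "")
    if (ncol(raw) < 2L) stop("expected sample ids plus >= 1 feature column")
    ids <- raw[[1L]]
    if (anyDuplicated(ids))
        stop("duplicate sample id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    vals <- as.matrix(raw[, -1L, drop = FALSE])
    suppressWarnings(num <- matrix(as.numeric(vals), nrow(vals), ncol(vals)))
    bad <- which(is.na(num), arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf(
            "non-numeric or missing value at sample '%s', feature '%s' (value '%s')",
            ids[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]],
            vals[bad[1L, 1L], bad[1L, 2L]]))
    dimnames(num) <- list(ids, colnames(vals))
    if (transpose) num <- t(num)
    .checkOmicsMatrix(num, basename(path))
    num
}

#' Write an expression matrix in the package's canonical layout
#'
#' @param x numeric matrix, samples in rows, with dimnames.
#' @param path output path; delimiter chosen from the extension as in
#'   [readExpressionMatrix()].
#' @param delimiter optional explicit delimiter.
#' @export
writeExpressionMatrix <- function(x, path, delimiter = NULL) {
    .checkOmicsMatrix(x)
    if (is.null(delimiter))
        delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- data.frame(sample = rownames(x), x, check.names = FALSE)
    utils::write.table(df, path, sep = delimiter, quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a design table
#'
#' Expects columns `sample`, `subject`, `condition` and optionally `time`.
#' Factor levels are kept in first-appearance order; the result is validated
#' (unique samples, every subject with >= 2 samples, at most one sample per
#' design cell).
#'
#' @param path path to a TSV/CSV file.
#' @param delimiter field delimiter; inferred from the extension by default.
#' @return a [RepeatedMeasuresDesign-class].
#' @export
readDesign <- function(path, delimiter = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (is.null(delimiter))
        delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- utils::read.table(path, sep = delimiter, header = TRUE,
                            colClasses = "character", check.names = FALSE)
    need <- c("sample", "subject", "condition")
    if (!all(need %in% names(df)))
        stop("design table must have columns: ", paste(need, collapse = ", "),
             " (optionally 'time')")
    repeatedMeasuresDesign(df$sample, df$subject, df$condition,
                           if ("time" %in% names(df)) df$time else NULL)
}

#' Write a design table
#' @param design a [RepeatedMeasuresDesign-class].
#' @param path output path (TSV).
#' @export
writeDesign <- function(design, path) {
    df <- data.frame(sample = design@sample,
                     subject = as.character(design@subject),
                     condition = as.character(design@condition))
    if (hasTimeFactor(design)) df$time <- as.character(design@time)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Align two matched assays on common samples
#'
#' Reorders the rows of two matrices measured on the same samples (e.g. gene
#' expression and cytokine secretion) to a common sample order, dropping
#' samples absent from either matrix or from the design, with a message
#' stating how many were dropped.
#'
#' @param x,z numeric samples-by-features matrices sharing sample ids.
#' @param design a [RepeatedMeasuresDesign-class] covering the samples.
#' @return a list with elements `x`, `z` and `design`, row-aligned.
#' @export
alignMatched <- function(x, z, design) {
    .checkOmicsMatrix(x, "x"); .checkOmicsMatrix(z, "z")
    common <- intersect(intersect(rownames(x), rownames(z)), design@sample)
    if (length(common) == 0L)
        stop("no common samples between the two matrices and the design")
    ## keep the design's order for determinism
    common <- design@sample[design@sample %in% common]
    ## subjects left with a single sample carry no within-subject information
    subj <- design@subject[match(common, design@sample)]
    tooFew <- names(which(table(subj) < 2L))
    if (length(tooFew)) {
        message("subject(s) left with a single sample dropped: ",
                paste(tooFew, collapse = ", "))
        common <- common[!(as.character(subj) %in% tooFew)]
        if (length(common) == 0L)
            stop("no samples left after dropping single-sample subjects")
    }
    dropped <- length(unique(c(rownames(x), rownames(z), design@sample))) -
        length(common)
    if (dropped > 0L)
        message(dropped, " sample(s) absent from at least one input dropped; ",
                length(common), " retained")
    list(x = x[common, , drop = FALSE], z = z[common, , drop = FALSE],
         design = design[common])
}

#' Write selection and score reports for a fitted model
#'
#' Writes a TSV with columns `dimension`, `feature_name`, `loading_weight` and
#' `rank` (by absolute weight within dimension) over the features with nonzero
#' loadings, plus a companion TSV of per-sample score vectors.
#'
#' @param model a fitted [SPLSModel-class] or [SPLSDAModel-class].
#' @param path output path of the selection report.
#' @param scoresPath output path of the score table; defaults to `path` with
#'   `_scores` appended before the extension.
#' @param block `"X"` or `"Z"`.
#' @return invisibly, the selection report as a data.frame.
#' @export
writeSelectionReport <- function(model, path,
                                 scoresPath = sub("(\\.[^.]*)?$", "_scores\\1",
                                                  path),
                                 block = "X") {
    if (!is(model, "SPLSModel"))
        stop("'model' must be a fitted sparse PLS(-DA) model")
    W <- featureLoadings(model, block)
    rows <- lapply(seq_len(model@H), function(h) {
        w <- W[, h]
        nz <- which(w != 0)
        if (!length(nz)) return(NULL)
        nz <- nz[order(-abs(w[nz]))]
        data.frame(dimension = h, feature_name = rownames(W)[nz],
                   loading_weight = w[nz], rank = seq_along(nz))
    })
    report <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    if (is.null(report))
        report <- data.frame(dimension = integer(0), feature_name = character(0),
                             loading_weight = numeric(0), rank = integer(0))
    utils::write.table(report, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    scores <- latentScores(model, block)
    sdf <- data.frame(sample = rownames(scores), scores, check.names = FALSE)
    utils::write.table(sdf, scoresPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(report)
}
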
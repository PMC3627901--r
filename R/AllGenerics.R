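#' Accessors for decomposition and model objects
#'
#' `offsetMatrix`, `betweenMatrix` and `withinMatrix` return the parts of a
#' split-up variance decomposition; `withinStarMatrix` returns the two-factor
#' within matrix purged of the random subject interactions (for a one-factor
#' decomposition it coincides with `withinMatrix`). `sumsOfSquares` returns the
#' named vector of per-part squared Frobenius norms.
#'
#' @param object a [VarianceDecomposition-class] (or model) object.
#' @return a matrix (or named numeric vector for `sumsOfSquares`).
#' @name decomposition-accessors
#' @aliases offsetMatrix betweenMatrix withinMatrix withinStarMatrix
#'   sumsOfSquares
NULL

#' @rdname decomposition-accessors
#' @export
setGeneric("offsetMatrix", function(object) standardGeneric("offsetMatrix"))
#' @rdname decomposition-accessors
#' @export
setGeneric("betweenMatrix", function(object) standardGeneric("betweenMatrix"))
#' @rdname decomposition-accessors
#' @export
setGeneric("withinMatrix", function(object) standardGeneric("withinMatrix"))
#' @rdname decomposition-accessors
#' @export
setGeneric("withinStarMatrix",
    function(object) standardGeneric("withinStarMatrix"))
#' @rdname decomposition-accessors
#' @export
setGeneric("sumsOfSquares", function(object) standardGeneric("sumsOfSquares"))

#' Summarize the sources of variation
#'
#' Tabulates the sum of squares of each part of a decomposition, its fraction
#' of the total squared norm of X, and reports the residual of the additive
#' reconstruction identity as an attribute (`"identityResidual"`, relative to
#' the largest absolute entry of X).
#'
#' @param object a [VarianceDecomposition-class] object.
#' @return a data.frame with columns `part`, `ss` and `fraction`.
#' @examples
#' d <- repeatedMeasuresDesign(
#'   sample = paste0("s", 1:4), subject = c("a", "a", "b", "b"),
#'   condition = c("A", "B", "A", "B"))
#' x <- matrix(c(1, 3, 5, 7), 4, 1,
#'   dimnames = list(paste0("s", 1:4), "g1"))
#' variationSummary(splitOneFactor(x, d))
#' @export
setGeneric("variationSummary",
    function(object) standardGeneric("variationSummary"))

#' Features selected by a sparse PLS(-DA) model
#'
#' Returns, for each dimension, the features with a nonzero loading ordered by
#' decreasing absolute weight, plus their union across dimensions.
#'
#' @param object a fitted [SPLSModel-class] or [SPLSDAModel-class].
#' @param block `"X"` or `"Z"`: which block's loadings to inspect.
#' @return a list with one character vector per dimension and an element
#'   `union`.
#' @export
setGeneric("selectedFeatures",
    function(object, block = "X") standardGeneric("selectedFeatures"))

#' Loadings and latent scores of a fitted model
#'
#' @param object a fitted [SPLSModel-class] or [SPLSDAModel-class].
#' @param block `"X"` or `"Z"`.
#' @return `featureLoadings`: a features x H matrix of loading weights;
#'   `latentScores`: an N x H matrix of score vectors.
#' @name model-accessors
NULL

#' @rdname model-accessors
#' @export
setGeneric("featureLoadings",
    function(object, block = "X") standardGeneric("featureLoadings"))
#' @rdname model-accessors
#' @export
setGeneric("latentScores",
    function(object, block = "X") standardGeneric("latentScores"))

#' Group levels of a discriminant model or design
#'
#' @param object an [SPLSDAModel-class] or [RepeatedMeasuresDesign-class].
#' @return character vector of levels in first-appearance order.
#' @export
setGeneric("groupLevels", function(object) standardGeneric("groupLevels"))
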
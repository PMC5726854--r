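#' Accessors for cytodiff S4 objects
#'
#' Small accessor generics for the package's containers: spatial grid, frame
#' times and intensity matrix of a [LineProfileStack-class], and the fitted
#' diffusion coefficient of a [FrapFit-class].
#'
#' @param x an object of the documented class.
#' @return `positions()`/`frameTimes()` numeric vectors, `intensities()` a
#'   matrix, `prebleachProfile()` a numeric vector (length 0 when absent),
#'   `diffusionCoef()` a single numeric (um^2/s, `NA` for non-identifiable
#'   fits).
#' @name cytodiff-accessors
#' @aliases positions frameTimes intensities prebleachProfile diffusionCoef
NULL

#' @rdname cytodiff-accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname cytodiff-accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname cytodiff-accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname cytodiff-accessors
#' @export
setGeneric("prebleachProfile", function(x) standardGeneric("prebleachProfile"))

#' @rdname cytodiff-accessors
#' @export
setGeneric("diffusionCoef", function(x) standardGeneric("diffusionCoef"))
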
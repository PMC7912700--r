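#' @rdname FactorModel-class
#' @param x,object a \code{FactorModel} (or other package object, see methods).
#' @export
setGeneric("loadingMatrix", function(x) standardGeneric("loadingMatrix"))

#' @rdname FactorModel-class
#' @export
setGeneric("factorCorr", function(x) standardGeneric("factorCorr"))

#' @rdname FactorModel-class
#' @export
setGeneric("uniqueVars", function(x) standardGeneric("uniqueVars"))

#' @rdname FactorModel-class
#' @export
setGeneric("nManifest", function(x) standardGeneric("nManifest"))

#' @rdname FactorModel-class
#' @export
setGeneric("nFactors", function(x) standardGeneric("nFactors"))

#' @rdname FactorModel-class
#' @export
setGeneric("variableNames", function(x) standardGeneric("variableNames"))

#' @rdname FactorModel-class
#' @export
setGeneric("factorNames", function(x) standardGeneric("factorNames"))

#' @rdname FactorModel-class
#' @export
setGeneric("communalities", function(x) standardGeneric("communalities"))

#' @rdname JointCovariance-class
#' @export
setGeneric("manifestBlock", function(x) standardGeneric("manifestBlock"))

#' @rdname JointCovariance-class
#' @export
setGeneric("crossBlock", function(x) standardGeneric("crossBlock"))

#' @rdname JointCovariance-class
#' @export
setGeneric("factorBlock", function(x) standardGeneric("factorBlock"))

#' @rdname CanonicalDecomposition-class
#' @export
setGeneric("rhoSq", function(x) standardGeneric("rhoSq"))

#' @rdname CanonicalDecomposition-class
#' @export
setGeneric("contributions", function(x) standardGeneric("contributions"))

#' @rdname CanonicalDecomposition-class
#' @export
setGeneric("factorCoefs", function(x) standardGeneric("factorCoefs"))

#' @rdname CanonicalDecomposition-class
#' @export
setGeneric("manifestCoefs", function(x) standardGeneric("manifestCoefs"))

#' @rdname CanonicalDecomposition-class
#' @export
setGeneric("totalKL", function(x) standardGeneric("totalKL"))

#' @rdname DerivedFactorSystem-class
#' @export
setGeneric("coefMatrix", function(x) standardGeneric("coefMatrix"))

#' @rdname DerivedFactorSystem-class
#' @export
setGeneric("newLoadings", function(x) standardGeneric("newLoadings"))

#' @rdname DerivedFactorSystem-class
#' @export
setGeneric("factorCorrNew", function(x) standardGeneric("factorCorrNew"))
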
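#' @rdname GenotypeMatrix-class
#' @export
setGeneric("genotypes", function(x, ...) standardGeneric("genotypes"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("populations", function(x, ...) standardGeneric("populations"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("locusGroups", function(x, ...) standardGeneric("locusGroups"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("meanDepth", function(x, ...) standardGeneric("meanDepth"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))
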
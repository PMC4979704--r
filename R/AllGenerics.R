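#' @rdname GenotypeTable-class
#' @param x a `GenotypeTable` or `DosageMatrix`.
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' @rdname GenotypeTable-class
#' @export
setGeneric("habitat", function(x) standardGeneric("habitat"))

#' @rdname GenotypeTable-class
#' @export
setGeneric("sampleBatch", function(x) standardGeneric("sampleBatch"))

#' @rdname GenotypeTable-class
#' @export
setGeneric("linkageGroup", function(x) standardGeneric("linkageGroup"))

#' @rdname DosageMatrix-class
#' @param x a `DosageMatrix`.
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname DosageMatrix-class
#' @export
setGeneric("majorAllele", function(x) standardGeneric("majorAllele"))

#' @rdname DosageMatrix-class
#' @export
setGeneric("minorAllele", function(x) standardGeneric("minorAllele"))

#' @rdname DosageMatrix-class
#' @export
setGeneric("minorFreq", function(x) standardGeneric("minorFreq"))
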
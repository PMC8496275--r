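#' @rdname SampleAlignment-class
#' @param x,object a `SampleAlignment`
#' @export
setGeneric("alnMatrix", function(x) standardGeneric("alnMatrix"))

#' @rdname SampleAlignment-class
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @rdname SampleAlignment-class
#' @export
setGeneric("speciesOf", function(x) standardGeneric("speciesOf"))

#' @rdname SampleAlignment-class
#' @export
setGeneric("speciesRoles", function(x) standardGeneric("speciesRoles"))

#' @rdname SampleAlignment-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname SampleAlignment-class
#' @export
setGeneric("alignmentWidth", function(x) standardGeneric("alignmentWidth"))

#' Counts held by a contingency-table object
#'
#' @param x an [MKTable-class] or [CFTable-class]
#' @return named vector of table cells
#' @export
setGeneric("tableCounts", function(x) standardGeneric("tableCounts"))

#' P-value held by a test-result object
#'
#' @param x an [MKTable-class] or [CFTable-class]
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' Substitution events of a SubstitutionMap
#'
#' @param x a [SubstitutionMap-class]
#' @export
setGeneric("substEvents", function(x) standardGeneric("substEvents"))

#' Per-codon parsimony substitution counts
#'
#' @param x a [SubstitutionMap-class]
#' @export
setGeneric("codonHits", function(x) standardGeneric("codonHits"))
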
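#' @rdname GenomicTrack-class
#' @param x a RepliFire object.
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname GenomicTrack-class
#' @export
setGeneric("seqLengths", function(x) standardGeneric("seqLengths"))

#' @rdname GenomicTrack-class
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))

#' @rdname GenomicTrack-class
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))

#' @rdname GenomicTrack-class
#' @export
setGeneric("trackLabel", function(x) standardGeneric("trackLabel"))

#' @rdname GenomeModel-class
#' @param x a RepliFire object.
#' @export
setGeneric("origins", function(x) standardGeneric("origins"))

#' @rdname GenomeModel-class
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname ReplicationState-class
#' @param x a RepliFire object.
#' @export
setGeneric("replicatedFraction",
           function(x) standardGeneric("replicatedFraction"))

#' @rdname ReplicationState-class
#' @export
setGeneric("trueFiredFraction",
           function(x) standardGeneric("trueFiredFraction"))

#' @rdname ReplicationState-class
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname ReplicationProfile-class
#' @param x a RepliFire object.
#' @export
setGeneric("rawRatio", function(x) standardGeneric("rawRatio"))

#' @rdname ReplicationProfile-class
#' @export
setGeneric("smoothedTrack", function(x) standardGeneric("smoothedTrack"))

#' @rdname ReplicationProfile-class
#' @export
setGeneric("cutoffWavelength",
           function(x) standardGeneric("cutoffWavelength"))

#' @rdname CatenaneDistribution-class
#' @param x a RepliFire object.
#' @export
setGeneric("catWeights", function(x) standardGeneric("catWeights"))
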
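#' Accessors for package classes
#'
#' `markers()` and `chromInfo()` return the marker table and chromosome table
#' of a [GeneticMap]; `nMarkers()` counts markers, optionally by chromosome
#' class; `individuals()` returns the list of simulated animals;
#' `qcStages()` the stage table of a [QCReport] and `missingRate()` its
#' missing-call percentage; `scanResults()`, `scanThreshold()` and
#' `significantMarkers()` interrogate a [ScanResult]; `regionWidth()` gives a
#' [Region]'s width in Mb.
#'
#' @param x object.
#' @param ... passed to methods.
#' @return See the individual method descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("markers", function(x, ...) standardGeneric("markers"))

#' @rdname accessors
#' @export
setGeneric("chromInfo", function(x, ...) standardGeneric("chromInfo"))

#' @rdname accessors
#' @export
setGeneric("nMarkers", function(x, ...) standardGeneric("nMarkers"))

#' @rdname accessors
#' @export
setGeneric("individuals", function(x, ...) standardGeneric("individuals"))

#' @rdname accessors
#' @export
setGeneric("qcStages", function(x, ...) standardGeneric("qcStages"))

#' @rdname accessors
#' @export
setGeneric("missingRate", function(x, ...) standardGeneric("missingRate"))

#' @rdname accessors
#' @export
setGeneric("scanResults", function(x, ...) standardGeneric("scanResults"))

#' @rdname accessors
#' @export
setGeneric("scanThreshold", function(x, ...) standardGeneric("scanThreshold"))

#' @rdname accessors
#' @export
setGeneric("significantMarkers",
  function(x, ...) standardGeneric("significantMarkers"))

#' @rdname accessors
#' @export
setGeneric("regionWidth", function(x, ...) standardGeneric("regionWidth"))
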
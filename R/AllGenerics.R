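#' @importFrom BiocGenerics counts
NULL

#' Read counts stored in a WashoutExperiment
#'
#' @param object a \linkS4class{WashoutExperiment}.
#' @return integer matrix, taxa x samples.
#' @export
setMethod("counts", "WashoutExperiment",
          function(object) assay(object, "counts"))

#' @rdname accessors
#' @export
setGeneric("reactor", function(x) standardGeneric("reactor"))

#' @rdname accessors
#' @export
setGeneric("compartment", function(x) standardGeneric("compartment"))

#' @rdname accessors
#' @export
setGeneric("sampleDay", function(x) standardGeneric("sampleDay"))

#' @rdname accessors
#' @export
setGeneric("samplePhase", function(x) standardGeneric("samplePhase"))

#' Sample-level accessors
#'
#' Convenience accessors for the paired-design metadata of a
#' \linkS4class{WashoutExperiment}: reactor label, compartment
#' (granular/effluent), day since seeding and operational phase.
#'
#' @param x a \linkS4class{WashoutExperiment}.
#' @return a vector with one element per sample.
#' @name accessors
#' @aliases reactor compartment sampleDay samplePhase
NULL

setMethod("reactor", "WashoutExperiment", function(x) colData(x)$reactor)
setMethod("compartment", "WashoutExperiment", function(x) colData(x)$compartment)
setMethod("sampleDay", "WashoutExperiment", function(x) colData(x)$day)
setMethod("samplePhase", "WashoutExperiment", function(x) colData(x)$phase)

#' @rdname relativeAbundance
#' @export
setGeneric("relativeAbundance", function(x, ...)
  standardGeneric("relativeAbundance"))

#' @rdname collapseToGenus
#' @export
setGeneric("collapseToGenus", function(x, ...)
  standardGeneric("collapseToGenus"))

#' @rdname pairedIndex
#' @export
setGeneric("pairedIndex", function(x, ...) standardGeneric("pairedIndex"))

#' @rdname brayCurtisMatrix
#' @export
setGeneric("brayCurtisMatrix", function(x, ...)
  standardGeneric("brayCurtisMatrix"))

#' @rdname diversityTable
#' @export
setGeneric("diversityTable", function(x, ...)
  standardGeneric("diversityTable"))

#' @rdname expectedRetention
#' @export
setGeneric("expectedRetention", function(truth, taxon, day)
  standardGeneric("expectedRetention"))

#' Accessors for OrdinationResult
#'
#' @param x an \linkS4class{OrdinationResult}.
#' @return \code{ordinationPoints}: the centred coordinate matrix;
#'   \code{ordinationStress}: the final Kruskal stress-1;
#'   \code{stressTrace}: per-iteration stress of the winning restart.
#' @name ordination-accessors
#' @export
ordinationPoints <- function(x) {
  stopifnot(is(x, "OrdinationResult"))
  x@points
}

#' @rdname ordination-accessors
#' @export
ordinationStress <- function(x) {
  stopifnot(is(x, "OrdinationResult"))
  x@stress
}

#' @rdname ordination-accessors
#' @export
stressTrace <- function(x) {
  stopifnot(is(x, "OrdinationResult"))
  x@trace
}

#' Accessors for PairedIndex
#'
#' @param x a \linkS4class{PairedIndex}.
#' @return \code{samplePairs}: data.frame of (reactor, day, granular,
#'   effluent) sample pairs; \code{unpairedSamples}: data.frame of samples
#'   without a contemporaneous mate.
#' @name pairedindex-accessors
#' @export
samplePairs <- function(x) {
  stopifnot(is(x, "PairedIndex"))
  x@pairs
}

#' @rdname pairedindex-accessors
#' @export
unpairedSamples <- function(x) {
  stopifnot(is(x, "PairedIndex"))
  x@unpaired
}
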
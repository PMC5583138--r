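#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' WashoutExperiment: paired granular/effluent amplicon counts
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding a taxa x
#' samples matrix of 16S read counts (assay \code{"counts"}) with per-sample
#' metadata describing the paired sampling design of a granular sludge
#' sequencing batch reactor study: reactor label, compartment
#' (\code{"granular"} biomass withdrawn from the reactor, or \code{"effluent"}
#' suspended solids leaving with the treated water), day since seeding, and
#' the derived operational phase (\code{"startup"} or \code{"steady"}).
#'
#' Validity requires non-negative integral counts, unique taxon labels,
#' positive library sizes, compartments restricted to granular/effluent and a
#' unique (reactor, compartment, day) key per sample.
#'
#' @aliases WashoutExperiment-class
#' @exportClass WashoutExperiment
setClass("WashoutExperiment", contains = "SummarizedExperiment")

.validWashoutExperiment <- function(object) {
  msg <- character()
  if (!("counts" %in% assayNames(object))) {
    msg <- c(msg, "assay 'counts' is required")
  } else {
    cnt <- assay(object, "counts")
    if (anyNA(cnt)) msg <- c(msg, "counts contain NA")
    else {
      if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
      if (any(cnt != round(cnt))) msg <- c(msg, "counts must be integral")
      if (any(colSums(cnt) <= 0)) {
        bad <- colnames(cnt)[colSums(cnt) <= 0]
        msg <- c(msg, paste0("zero-sum sample column(s): ",
                             paste(bad, collapse = ", ")))
      }
    }
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "taxon labels (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  cd <- colData(object)
  need <- c("reactor", "compartment", "day", "phase")
  miss <- setdiff(need, colnames(cd))
  if (length(miss)) {
    msg <- c(msg, paste0("colData lacks column(s): ",
                         paste(miss, collapse = ", ")))
  } else {
    if (!all(cd$compartment %in% c("granular", "effluent")))
      msg <- c(msg, "compartment must be 'granular' or 'effluent'")
    if (any(cd$day < 0)) msg <- c(msg, "day must be >= 0")
    if (!all(cd$phase %in% c("startup", "steady")))
      msg <- c(msg, "phase must be 'startup' or 'steady'")
    key <- paste(cd$reactor, cd$compartment, cd$day)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (reactor, compartment, day) combination")
  }
  if (length(msg)) msg else TRUE
}
setValidity("WashoutExperiment", .validWashoutExperiment)

#' Contemporaneous granular/effluent sample pairs
#'
#' Pairing of samples taken from the same reactor on the same day, one from
#' each compartment. Samples lacking a contemporaneous mate in the other
#' compartment are listed in \code{unpaired}; they are retained for
#' whole-community analyses (diversity, ordination) but cannot contribute
#' retention ratios. Nothing is silently dropped.
#'
#' @slot pairs data.frame with columns reactor, day, granular, effluent
#'   (the two sample ids).
#' @slot unpaired data.frame with columns sample_id, reactor, compartment,
#'   day for samples without a mate.
#' @aliases PairedIndex-class
#' @exportClass PairedIndex
setClass("PairedIndex",
         representation(pairs = "data.frame", unpaired = "data.frame"))

setValidity("PairedIndex", function(object) {
  msg <- character()
  need <- c("reactor", "day", "granular", "effluent")
  if (!all(need %in% colnames(object@pairs)))
    msg <- c(msg, paste0("pairs needs columns: ", paste(need, collapse = ", ")))
  else if (nrow(object@pairs) &&
           anyDuplicated(paste(object@pairs$reactor, object@pairs$day)))
    msg <- c(msg, "one pair per (reactor, day) allowed")
  if (length(msg)) msg else TRUE
})

#' Configuration of the two-compartment wash-out simulator
#'
#' @slot taxa data.frame with columns \code{label}, \code{initialFraction}
#'   (fractions summing to 1), \code{growthRate} (net growth, per day) and
#'   \code{surfaceAffinity} (0 = granule core, 1 = granule surface /
#'   planktonic).
#' @slot days integer-valued vector of sampled days since seeding.
#' @slot granulationStart,granulationEnd days bounding the linear granulation
#'   ramp G(t) (0 before start, 1 after end).
#' @slot beta erosion enrichment strength (dimensionless, >= 0).
#' @slot delta selective biomass loss rate (per day, >= 0).
#' @slot depth sequencing depth, reads per sample.
#' @slot label reactor label used for emitted sample ids.
#' @aliases SimConfig-class
#' @exportClass SimConfig
setClass("SimConfig",
         representation(taxa = "data.frame", days = "numeric",
                        granulationStart = "numeric",
                        granulationEnd = "numeric",
                        beta = "numeric", delta = "numeric",
                        depth = "numeric", label = "character"))

setValidity("SimConfig", function(object) {
  msg <- character()
  tx <- object@taxa
  need <- c("label", "initialFraction", "growthRate", "surfaceAffinity")
  if (!all(need %in% colnames(tx))) {
    msg <- c(msg, paste0("taxa needs columns: ", paste(need, collapse = ", ")))
  } else {
    if (anyDuplicated(tx$label)) msg <- c(msg, "duplicate taxon labels")
    if (any(tx$initialFraction <= 0))
      msg <- c(msg, "initial fractions must be > 0")
    if (abs(sum(tx$initialFraction) - 1) > 1e-8)
      msg <- c(msg, "initial fractions must sum to 1")
    if (any(tx$surfaceAffinity < 0 | tx$surfaceAffinity > 1))
      msg <- c(msg, "surfaceAffinity must lie in [0, 1]")
  }
  if (any(object@days < 0) || anyDuplicated(object@days) ||
      is.unsorted(object@days))
    msg <- c(msg, "days must be sorted, unique and non-negative")
  if (object@granulationStart >= object@granulationEnd)
    msg <- c(msg, "granulationStart must be < granulationEnd")
  if (object@beta < 0 || object@delta < 0 || object@depth <= 0)
    msg <- c(msg, "beta, delta must be >= 0 and depth > 0")
  if (length(msg)) msg else TRUE
})

#' Noiseless ground truth of a wash-out simulation
#'
#' Deterministic (noise-free) compartment compositions recorded at the
#' sampled days: reactor fractions p, effluent fractions q, erosion
#' enrichment factors e, and expected retention ratios rho = p / q.
#'
#' @slot taxa taxon labels (rows of all matrices).
#' @slot days sampled days (columns).
#' @slot p,q,e,rho taxa x days matrices.
#' @aliases SimTruth-class
#' @exportClass SimTruth
setClass("SimTruth",
         representation(taxa = "character", days = "numeric",
                        p = "matrix", q = "matrix",
                        e = "matrix", rho = "matrix"))

setValidity("SimTruth", function(object) {
  msg <- character()
  dims <- vapply(list(object@p, object@q, object@e, object@rho),
                 function(m) all(dim(m) == c(length(object@taxa),
                                             length(object@days))),
                 logical(1))
  if (!all(dims)) msg <- c(msg, "matrix dims must be taxa x days")
  else {
    if (any(abs(colSums(object@p) - 1) > 1e-9) ||
        any(abs(colSums(object@q) - 1) > 1e-9))
      msg <- c(msg, "p and q columns must each sum to 1")
  }
  if (length(msg)) msg else TRUE
})

#' Non-metric multidimensional scaling result
#'
#' @slot points samples x k matrix of centred ordination coordinates.
#' @slot stress final Kruskal stress-1 of the best restart.
#' @slot trace per-iteration stress of the best restart (non-increasing).
#' @slot stressPerStart final stress of every restart.
#' @slot classicalInitStress stress of the classical-scaling (metric MDS)
#'   initial configuration before any iteration.
#' @slot bestStart index of the winning restart (1 = classical scaling).
#' @slot converged whether the winning run met the relative stress tolerance.
#' @slot degenerate TRUE when all input dissimilarities are equal.
#' @aliases OrdinationResult-class
#' @exportClass OrdinationResult
setClass("OrdinationResult",
         representation(points = "matrix", stress = "numeric",
                        trace = "numeric", stressPerStart = "numeric",
                        classicalInitStress = "numeric",
                        bestStart = "integer", converged = "logical",
                        degenerate = "logical"))

setMethod("show", "WashoutExperiment", function(object) {
  cd <- colData(object)
  cat("WashoutExperiment:", nrow(object), "taxa x", ncol(object), "samples\n")
  cat("  reactors:   ", paste(sort(unique(cd$reactor)), collapse = ", "), "\n")
  cat("  compartments:", paste(table(cd$compartment)[c("granular", "effluent")],
                               c("granular,", "effluent"), collapse = " "), "\n")
  cat("  days:       ", min(cd$day), "-", max(cd$day),
      " (", length(unique(cd$day)), " distinct)\n", sep = "")
  cat("  phase split: startup<=day ", metadata(object)$startupEndDay %||% 42,
      "\n", sep = "")
  invisible(object)
})

setMethod("show", "PairedIndex", function(object) {
  cat("PairedIndex:", nrow(object@pairs), "contemporaneous pairs,",
      nrow(object@unpaired), "unpaired samples\n")
  if (nrow(object@pairs))
    cat("  per reactor:",
        paste(names(table(object@pairs$reactor)),
              table(object@pairs$reactor), sep = "=", collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig '", object@label, "': ", nrow(object@taxa), " taxa, ",
      length(object@days), " sampled days (", min(object@days), "-",
      max(object@days), ")\n", sep = "")
  cat("  granulation ramp ", object@granulationStart, "->",
      object@granulationEnd, " d; beta=", object@beta, ", delta=",
      object@delta, ", depth=", object@depth, "\n", sep = "")
  invisible(object)
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", length(object@taxa), "taxa x", length(object@days),
      "days; expected retention ratios in [",
      signif(min(object@rho), 3), ",", signif(max(object@rho), 3), "]\n")
  invisible(object)
})

setMethod("show", "OrdinationResult", function(object) {
  cat("OrdinationResult: ", nrow(object@points), " samples in ",
      ncol(object@points), " dimensions\n", sep = "")
  cat("  stress-1 = ", signif(object@stress, 6), " (best of ",
      length(object@stressPerStart), " starts, start #", object@bestStart,
      if (object@converged) ", converged" else ", not converged",
      if (object@degenerate) ", DEGENERATE input" else "", ")\n", sep = "")
  invisible(object)
})

`%||%` <- function(a, b) if (is.null(a)) b else a
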
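#' Margalef species richness
#'
#' D = (S - 1) / ln N: observed richness corrected for sequencing depth.
#'
#' @param S number of observed taxa (>= 1).
#' @param N total number of reads (>= 2, since ln 1 = 0).
#' @return numeric, >= 0. Vectorized.
#' @examples
#' margalefRichness(10, 100) # 9 / ln(100)
#' @export
margalefRichness <- function(S, N) {
  if (any(S < 1)) stop("S must be >= 1")
  if (any(N < 2)) stop("N must be >= 2")
  (S - 1) / log(N)
}

#' Shannon diversity index
#'
#' H' = -sum p_i ln p_i over the nonzero entries of a relative-abundance
#' vector.
#'
#' @param p relative abundances summing to 1 (tolerance 1e-6).
#' @return H' in nats.
#' @export
shannonIndex <- function(p) {
  if (any(p < 0)) stop("abundances must be non-negative")
  if (abs(sum(p) - 1) > 1e-6) stop("abundances must sum to 1")
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Pielou evenness
#'
#' J = H' / ln S over the S nonzero entries; 1 for a perfectly even
#' community. Undefined (NA) for single-taxon samples (ln 1 = 0).
#'
#' @param p relative abundances summing to 1 (tolerance 1e-6).
#' @return J in [0, 1], or NA when only one taxon is present.
#' @examples
#' pielouEvenness(c(0.5, 0.25, 0.25))
#' @export
pielouEvenness <- function(p) {
  if (any(p < 0)) stop("abundances must be non-negative")
  if (abs(sum(p) - 1) > 1e-6) stop("abundances must sum to 1")
  S <- sum(p > 0)
  if (S == 1) return(NA_real_)
  shannonIndex(p) / log(S)
}

#' Per-sample diversity records
#'
#' Observed richness S, library size N, Margalef richness, Shannon index and
#' Pielou evenness for every sample.
#'
#' @param x count matrix (taxa x samples) or
#'   \linkS4class{WashoutExperiment}.
#' @param ... unused.
#' @return data.frame with one row per sample: sample_id, richness_S,
#'   reads_N, margalef, shannon, pielou.
#' @rdname diversityTable
#' @export
setMethod("diversityTable", "matrix", function(x, ...) {
  ra <- relativeAbundance(x)
  out <- data.frame(
    sample_id = colnames(x),
    richness_S = colSums(x > 0),
    reads_N = colSums(x),
    stringsAsFactors = FALSE)
  out$margalef <- margalefRichness(out$richness_S, out$reads_N)
  out$shannon <- apply(ra, 2L, shannonIndex)
  out$pielou <- apply(ra, 2L, pielouEvenness)
  rownames(out) <- NULL
  out
})

#' @rdname diversityTable
#' @export
setMethod("diversityTable", "WashoutExperiment",
          function(x, ...) diversityTable(counts(x)))
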
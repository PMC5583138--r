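#' @importFrom vegan vegdist
NULL

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i): 0 for identical
#' communities, 1 for disjoint supports. Invariant to joint scaling of both
#' vectors and symmetric in its arguments; it is a semi-metric (the triangle
#' inequality may fail). Note BC on raw count vectors equals BC on the
#' matching relative-abundance vectors only when the two totals are equal;
#' the pipeline therefore computes it on per-sample relative abundances.
#'
#' @param x,y non-negative numeric vectors of equal length, not both
#'   all-zero.
#' @return dissimilarity in [0, 1].
#' @examples
#' brayCurtis(c(1, 2, 3), c(3, 2, 1)) # 1/3
#' @export
brayCurtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (anyNA(x) || anyNA(y) || any(x < 0) || any(y < 0))
    stop("entries must be non-negative and finite")
  s <- sum(x + y)
  if (s == 0) stop("both vectors are all-zero")
  sum(abs(x - y)) / s
}

#' Bray-Curtis dissimilarity matrix over all samples
#'
#' Computed on per-sample relative abundances by default (library sizes
#' differ between compartments), via \code{vegan::vegdist}.
#'
#' @param x count matrix (taxa x samples) or
#'   \linkS4class{WashoutExperiment}.
#' @param relative scale each sample to sum 1 first (default TRUE).
#' @param ... unused.
#' @return symmetric samples x samples matrix, zero diagonal, entries in
#'   [0, 1], with sample-id dimnames.
#' @rdname brayCurtisMatrix
#' @export
setMethod("brayCurtisMatrix", "matrix", function(x, relative = TRUE, ...) {
  m <- if (relative) relativeAbundance(x) else x
  d <- as.matrix(vegan::vegdist(t(m), method = "bray"))
  diag(d) <- 0
  d
})

#' @rdname brayCurtisMatrix
#' @export
setMethod("brayCurtisMatrix", "WashoutExperiment",
          function(x, relative = TRUE, ...)
            brayCurtisMatrix(counts(x), relative = relative))

#' Paired granular/effluent community similarity per reactor
#'
#' For every contemporaneous sample pair the Bray-Curtis similarity
#' (1 - BC) x 100 is computed; the per-reactor mean and sample standard
#' deviation summarize how closely the effluent community tracks the
#' granular community.
#'
#' @param dm dissimilarity matrix from [brayCurtisMatrix()].
#' @param pairs a \linkS4class{PairedIndex}.
#' @return data.frame with columns reactor, n_pairs, mean_similarity,
#'   sd_similarity (percent).
#' @export
pairedSimilaritySummary <- function(dm, pairs) {
  stopifnot(is(pairs, "PairedIndex"))
  pr <- samplePairs(pairs)
  if (!nrow(pr)) stop("no pairs to summarize")
  missing <- setdiff(c(pr$granular, pr$effluent), rownames(dm))
  if (length(missing))
    stop("paired sample(s) missing from dissimilarity matrix: ",
         paste(missing, collapse = ", "))
  sim <- (1 - dm[cbind(pr$granular, pr$effluent)]) * 100
  agg <- split(sim, pr$reactor)
  out <- data.frame(reactor = names(agg),
                    n_pairs = vapply(agg, length, integer(1)),
                    mean_similarity = vapply(agg, mean, numeric(1)),
                    sd_similarity = vapply(agg, stats::sd, numeric(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Mean cross-reactor community similarity within a day window
#'
#' Mean Bray-Curtis similarity (1 - BC) x 100 over all cross-group sample
#' pairs within the window, for every unordered pair of groups — e.g. how
#' similar the three reactor set-ups are to each other by the end of the
#' experiment.
#'
#' @param dm dissimilarity matrix.
#' @param meta data.frame with columns sample_id, reactor, day, or a
#'   \linkS4class{WashoutExperiment}.
#' @param window numeric length-2 day range (inclusive); default all days.
#' @return data.frame with columns group1, group2, n_pairs,
#'   mean_similarity.
#' @export
betweenGroupSimilarity <- function(dm, meta, window = c(-Inf, Inf)) {
  if (is(meta, "WashoutExperiment")) {
    meta <- data.frame(sample_id = colnames(meta),
                       reactor = reactor(meta), day = sampleDay(meta),
                       stringsAsFactors = FALSE)
  }
  sub <- meta[meta$day >= window[1] & meta$day <= window[2], , drop = FALSE]
  groups <- split(sub$sample_id, sub$reactor)
  if (length(groups) < 2) stop("need at least two groups in the window")
  if (any(!lengths(groups))) stop("empty group in the window")
  gn <- names(groups)
  combs <- utils::combn(gn, 2)
  rows <- apply(combs, 2L, function(gg) {
    a <- groups[[gg[1]]]
    b <- groups[[gg[2]]]
    vals <- dm[a, b, drop = FALSE]
    data.frame(group1 = gg[1], group2 = gg[2], n_pairs = length(vals),
               mean_similarity = mean((1 - vals) * 100),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
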
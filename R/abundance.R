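#' Per-sample relative read abundance
#'
#' Scales every sample (column) to sum to 1. Relative abundances are always
#' computed per sample, never from pooled counts, because library sizes
#' differ between compartments.
#'
#' @param x count matrix (taxa x samples) or \linkS4class{WashoutExperiment}.
#' @param ... unused.
#' @return numeric matrix of fractions with the same dimnames; every column
#'   sums to 1 within 1e-9.
#' @examples
#' relativeAbundance(matrix(c(2, 3, 5), 3, 1,
#'                          dimnames = list(c("a", "b", "c"), "S1")))
#' @rdname relativeAbundance
#' @export
setMethod("relativeAbundance", "matrix", function(x, ...) {
  if (any(x < 0)) stop("negative entries in count matrix")
  cs <- colSums(x)
  if (any(cs == 0)) {
    bad <- if (is.null(colnames(x))) which(cs == 0) else colnames(x)[cs == 0]
    stop("zero-sum sample column(s): ", paste(bad, collapse = ", "))
  }
  sweep(x, 2L, cs, "/")
})

#' @rdname relativeAbundance
#' @export
setMethod("relativeAbundance", "WashoutExperiment", function(x, ...) {
  relativeAbundance(counts(x))
})

.genusOf <- function(labels, prefix = "g__") {
  vapply(labels, function(lab) {
    parts <- if (grepl(";", lab, fixed = TRUE))
      trimws(strsplit(lab, ";", fixed = TRUE)[[1]]) else lab
    hit <- parts[startsWith(parts, prefix)]
    hit <- hit[nchar(hit) > nchar(prefix)]
    if (length(hit)) hit[[1]] else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Collapse OTU-level counts to genus level
#'
#' Sums counts over taxa sharing a genus label. Labels are parsed with
#' Greengenes-style rank prefixes, either bare (\code{"g__Zoogloea"}) or as a
#' semicolon-delimited lineage (\code{"k__...;p__...;g__Zoogloea"}). Taxa
#' without a genus assignment (empty or missing \code{g__} field) keep their
#' own label, so unclassified OTUs such as \code{OTU_6} survive as their own
#' rows. Total counts per sample are conserved.
#'
#' @param x count matrix with taxon rownames, or
#'   \linkS4class{WashoutExperiment}.
#' @param rank taxonomic rank to collapse to; currently genus (prefix
#'   \code{g__}) and the other standard prefixes (\code{k__ p__ c__ o__ f__
#'   s__}) are understood.
#' @param ... unused.
#' @return same type as \code{x} with one row per genus (or retained OTU),
#'   in order of first appearance.
#' @rdname collapseToGenus
#' @export
setMethod("collapseToGenus", "matrix", function(x, rank = "genus", ...) {
  prefixes <- c(kingdom = "k__", phylum = "p__", class = "c__",
                order = "o__", family = "f__", genus = "g__",
                species = "s__")
  if (!rank %in% names(prefixes)) stop("unknown rank: ", rank)
  pre <- prefixes[[rank]]
  lab <- .genusOf(rownames(x), pre)
  if (all(is.na(lab)))
    stop("rank '", rank, "' (prefix '", pre,
         "') not present in any taxon label")
  lab[is.na(lab)] <- rownames(x)[is.na(lab)]
  groups <- factor(lab, levels = unique(lab))
  out <- rowsum(x, groups, reorder = FALSE)
  storage.mode(out) <- storage.mode(x)
  out
})

#' @rdname collapseToGenus
#' @export
setMethod("collapseToGenus", "WashoutExperiment",
          function(x, rank = "genus", ...) {
  m <- collapseToGenus(counts(x), rank = rank)
  cd <- colData(x)
  sd <- data.frame(sample_id = colnames(x), reactor = cd$reactor,
                   compartment = cd$compartment, day = cd$day,
                   stringsAsFactors = FALSE)
  WashoutExperiment(m, sd,
                    startupEndDay = metadata(x)$startupEndDay %||% 42)
})

.categoryOf <- function(reactor, compartment) {
  paste0(reactor, ifelse(compartment == "granular", "R", "E"))
}

#' Mean relative abundance per sample category
#'
#' Categories are reactor x compartment combinations, labelled in the
#' conventional short form (\code{R1R} = reactor content of R1, \code{R1E} =
#' effluent of R1). The mean is the arithmetic mean of per-sample relative
#' abundances; per-category sample counts are attached as attribute
#' \code{"n"}.
#'
#' @param x a \linkS4class{WashoutExperiment}.
#' @return taxa x category matrix of mean relative abundances; every column
#'   sums to 1 within 1e-9.
#' @export
categoryMeans <- function(x) {
  stopifnot(is(x, "WashoutExperiment"))
  ra <- relativeAbundance(x)
  cat <- .categoryOf(reactor(x), compartment(x))
  f <- factor(cat, levels = unique(cat[order(reactor(x),
                                             compartment(x) == "granular")]))
  n <- as.integer(table(f))
  m <- t(rowsum(t(ra), f, reorder = FALSE)) / rep(n, each = nrow(ra))
  names(n) <- colnames(m)
  structure(m, n = n)
}

#' Select dominant genera common to all sample categories
#'
#' Restricts to taxa whose mean relative abundance exceeds \code{minMean}
#' (default 0, i.e. presence) in every reactor x compartment category, ranks
#' them by grand mean relative abundance over all samples (ties broken
#' lexicographically) and returns the top \code{n}. The cumulative share of
#' the selection (mean and sd over samples of the summed relative abundance)
#' is attached as attribute \code{"share"}.
#'
#' @param x a \linkS4class{WashoutExperiment}.
#' @param n number of taxa to return; if fewer taxa are common to all
#'   categories, all of them are returned with a warning.
#' @param minMean minimum per-category mean relative abundance for a taxon to
#'   count as "common" (default 0: any nonzero mean).
#' @param rankBy \code{"grand_mean"} (default) or \code{"category_min"}
#'   (rank by the worst-category mean instead).
#' @return character vector of taxon labels, most abundant first, with
#'   attribute \code{"share"} = c(mean, sd) in percent.
#' @export
selectCommonTop <- function(x, n = 19, minMean = 0,
                            rankBy = c("grand_mean", "category_min")) {
  stopifnot(is(x, "WashoutExperiment"))
  rankBy <- match.arg(rankBy)
  cm <- categoryMeans(x)
  common <- rownames(cm)[apply(cm, 1L, function(z) all(z > minMean))]
  if (!length(common)) stop("no taxon is present in every category")
  ra <- relativeAbundance(x)
  score <- switch(rankBy,
                  grand_mean = rowMeans(ra[common, , drop = FALSE]),
                  category_min = apply(cm[common, , drop = FALSE], 1L, min))
  ord <- order(-score, common)
  sel <- common[ord]
  if (length(sel) < n) {
    warning("only ", length(sel), " taxa are common to all categories ",
            "(n = ", n, " requested); returning all of them")
  } else {
    sel <- sel[seq_len(n)]
  }
  shares <- colSums(ra[sel, , drop = FALSE]) * 100
  structure(sel, share = c(mean = mean(shares), sd = stats::sd(shares)))
}
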
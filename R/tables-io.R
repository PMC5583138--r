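#' @importFrom utils read.delim write.table
NULL

.compartmentAliases <- c(granular = "granular", granule = "granular",
                         granules = "granular", reactor = "granular",
                         biomass = "granular", r = "granular",
                         effluent = "effluent", suspended = "effluent",
                         e = "effluent")

.normalizeCompartment <- function(x, aliases = .compartmentAliases) {
  key <- tolower(trimws(x))
  out <- unname(aliases[key])
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown compartment label(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(names(aliases), collapse = ", "), ")")
  }
  out
}

.validateCounts <- function(m, taxa, samples, strict = TRUE, what = "table") {
  if (anyDuplicated(taxa))
    stop("duplicate taxon label(s): ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  if (anyDuplicated(samples))
    stop("duplicate sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0)
    stop("malformed (non-numeric) value(s) in ", what, " at data line(s): ",
         paste(bad + 1L, collapse = ", "))
  }
  if (any(m < 0)) stop("negative count(s) found; counts must be >= 0")
  off <- abs(m - round(m)) > 1e-8
  if (any(off)) {
    if (strict) stop("non-integral count(s) found; read counts must be ",
                     "integers (set strict = FALSE to round)")
    warning("rounding ", sum(off), " non-integral count(s) to integers")
  }
  m <- round(m)
  cs <- colSums(m)
  if (any(cs <= 0))
    stop("zero-sum sample column(s): ",
         paste(samples[cs <= 0], collapse = ", "))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(taxa, samples)
  m
}

#' Read a taxa-by-sample count table
#'
#' Reads a tab-separated count table (first column = taxon labels, header row
#' = sample ids) or a BIOM format 1.0 dense-matrix JSON table, validates it
#' (non-negative integral counts, unique labels, positive library sizes) and
#' returns an integer matrix.
#'
#' @param path file path.
#' @param format \code{"tsv"} (default) or \code{"biom_dense"} (requires the
#'   biomformat package).
#' @param strict abort on non-integral numeric counts (default); when FALSE
#'   they are rounded with a warning.
#' @return integer matrix, taxa x samples, with dimnames.
#' @seealso [writeCountTable()], [WashoutExperiment()]
#' @export
readCountTable <- function(path, format = c("tsv", "biom_dense"),
                           strict = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    raw <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                      check.names = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character")
    if (ncol(raw) < 2) stop("count table needs a taxon column plus >= 1 sample")
    taxa <- raw[[1]]
    samples <- colnames(raw)[-1]
    m <- suppressWarnings(
      vapply(raw[-1], as.numeric, numeric(nrow(raw))))
    if (nrow(raw) == 1L) m <- matrix(m, nrow = 1L)
    .validateCounts(m, taxa, samples, strict = strict, what = basename(path))
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("format 'biom_dense' requires the biomformat package")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    .validateCounts(m, rownames(m), colnames(m), strict = strict,
                    what = basename(path))
  }
}

#' Write a count table as TSV
#'
#' Inverse of [readCountTable()] for the TSV format: header row
#' \code{taxon<TAB>sample ids...}, one taxon per line. Reading a written
#' table reproduces counts, taxon order and sample order exactly.
#'
#' @param counts integer matrix with taxon rownames and sample colnames.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeCountTable <- function(counts, path) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  df <- data.frame(taxon = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Reads a CSV or TSV metadata table (separator sniffed from the header line)
#' with mandatory columns \code{sample_id}, \code{reactor},
#' \code{compartment}, \code{day}. Compartment labels are normalized to
#' \code{granular}/\code{effluent} via an alias map; days must parse as
#' non-negative integers; the (reactor, compartment, day) key must be unique.
#' The operational phase is deliberately left unassigned here (see
#' [assignPhase()]).
#'
#' @param path file path.
#' @param compartmentAliases named character vector mapping accepted labels
#'   (lower-cased) to \code{"granular"} or \code{"effluent"}.
#' @return data.frame with columns sample_id, reactor, compartment, day.
#' @export
readSampleMetadata <- function(path,
                               compartmentAliases = .compartmentAliases) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.delim(path, header = TRUE, sep = sep, quote = "",
                   check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "reactor", "compartment", "day")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  day <- suppressWarnings(as.numeric(df$day))
  if (anyNA(day) || any(day != round(day)) || any(day < 0))
    stop("day must be a non-negative integer for every sample")
  out <- data.frame(sample_id = as.character(df$sample_id),
                    reactor = as.character(df$reactor),
                    compartment = .normalizeCompartment(df$compartment,
                                                        compartmentAliases),
                    day = as.integer(round(day)),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$sample_id))
    stop("duplicate sample_id(s): ",
         paste(unique(out$sample_id[duplicated(out$sample_id)]),
               collapse = ", "))
  key <- paste(out$reactor, out$compartment, out$day)
  if (anyDuplicated(key))
    stop("duplicate (reactor, compartment, day): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  out
}

#' Construct a WashoutExperiment
#'
#' Combines a validated count matrix and sample metadata into the central
#' container. Samples present in the metadata are matched to count-table
#' columns by \code{sample_id}; the operational phase is derived from the day
#' since seeding with [assignPhase()].
#'
#' @param counts integer matrix, taxa x samples (see [readCountTable()]).
#' @param sampleData data.frame with columns sample_id, reactor, compartment,
#'   day (see [readSampleMetadata()]).
#' @param startupEndDay last day (inclusive) of the start-up phase; the
#'   default 42 encodes start-up = weeks 1-6, steady state = weeks 7-12.
#' @return a \linkS4class{WashoutExperiment}.
#' @examples
#' cnt <- matrix(c(5L, 3L, 2L, 8L), 2, dimnames = list(c("g__A", "g__B"),
#'                                                     c("S1", "S2")))
#' md <- data.frame(sample_id = c("S1", "S2"), reactor = "R1",
#'                  compartment = c("granular", "effluent"), day = 55L)
#' WashoutExperiment(cnt, md)
#' @export
WashoutExperiment <- function(counts, sampleData, startupEndDay = 42) {
  stopifnot(is.matrix(counts))
  sd <- as.data.frame(sampleData, stringsAsFactors = FALSE)
  if (!all(sd$sample_id %in% colnames(counts)))
    stop("metadata sample_id(s) missing from count table: ",
         paste(setdiff(sd$sample_id, colnames(counts)), collapse = ", "))
  counts <- counts[, sd$sample_id, drop = FALSE]
  sd$compartment <- .normalizeCompartment(sd$compartment)
  cd <- DataFrame(reactor = sd$reactor, compartment = sd$compartment,
                  day = as.integer(sd$day),
                  phase = as.character(assignPhase(sd$day, startupEndDay)),
                  row.names = sd$sample_id)
  se <- SummarizedExperiment(assays = list(counts = counts), colData = cd)
  obj <- new("WashoutExperiment", se)
  metadata(obj)$startupEndDay <- startupEndDay
  obj
}

#' Build the contemporaneous granular/effluent pairing
#'
#' For every (reactor, day) with both a granular and an effluent sample, one
#' pair is formed; samples without a mate are reported as unpaired (kept for
#' ordination and diversity, excluded from retention ratios).
#'
#' @param x a \linkS4class{WashoutExperiment}, or a data.frame with columns
#'   sample_id, reactor, compartment, day.
#' @return a \linkS4class{PairedIndex}.
#' @rdname pairedIndex
#' @export
setMethod("pairedIndex", "WashoutExperiment", function(x, ...) {
  cd <- colData(x)
  meta <- data.frame(sample_id = colnames(x), reactor = cd$reactor,
                     compartment = cd$compartment, day = cd$day,
                     stringsAsFactors = FALSE)
  pairedIndex(meta)
})

#' @rdname pairedIndex
#' @export
setMethod("pairedIndex", "data.frame", function(x, ...) {
  empty_pairs <- data.frame(reactor = character(), day = integer(),
                            granular = character(), effluent = character(),
                            stringsAsFactors = FALSE)
  empty_un <- data.frame(sample_id = character(), reactor = character(),
                         compartment = character(), day = integer(),
                         stringsAsFactors = FALSE)
  if (!nrow(x)) return(new("PairedIndex", pairs = empty_pairs,
                           unpaired = empty_un))
  key <- paste(x$reactor, x$day, sep = "\r")
  paired <- lapply(split(seq_len(nrow(x)), key), function(idx) {
    g <- idx[x$compartment[idx] == "granular"]
    e <- idx[x$compartment[idx] == "effluent"]
    if (length(g) == 1L && length(e) == 1L) list(pair = c(g, e))
    else list(un = idx)
  })
  pr <- do.call(rbind, lapply(paired, function(z) z$pair))
  un <- unlist(lapply(paired, function(z) z$un), use.names = FALSE)
  pairs <- if (is.null(pr)) empty_pairs else {
    df <- data.frame(reactor = x$reactor[pr[, 1]], day = x$day[pr[, 1]],
                     granular = x$sample_id[pr[, 1]],
                     effluent = x$sample_id[pr[, 2]],
                     stringsAsFactors = FALSE)
    df[order(df$reactor, df$day), , drop = FALSE]
  }
  unp <- if (is.null(un) || !length(un)) empty_un else {
    df <- x[un, c("sample_id", "reactor", "compartment", "day")]
    df[order(df$reactor, df$day), , drop = FALSE]
  }
  rownames(pairs) <- NULL
  rownames(unp) <- NULL
  new("PairedIndex", pairs = pairs, unpaired = unp)
})
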
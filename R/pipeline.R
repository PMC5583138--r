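#' Hydraulic residence time of a sequencing batch reactor
#'
#' HRT = cycle length / volume exchange ratio, reported to one decimal. A
#' 4 h cycle with 43% exchange gives 9.3 h.
#'
#' @param cycleLengthH cycle length in hours (> 0).
#' @param exchangeRatio volume exchange ratio in (0, 1].
#' @return hours, rounded to 1 decimal.
#' @examples
#' hydraulicResidenceTime(4, 0.43) # 9.3
#' @export
hydraulicResidenceTime <- function(cycleLengthH, exchangeRatio) {
  if (any(cycleLengthH <= 0)) stop("cycle length must be positive")
  if (any(exchangeRatio <= 0 | exchangeRatio > 1))
    stop("exchange ratio must lie in (0, 1]")
  round(cycleLengthH / exchangeRatio, 1)
}

#' COD:N ratio of the influent
#'
#' Nitrogen parts per 100 parts chemical oxygen demand,
#' round(100 * N / COD), as conventionally reported "100:x".
#'
#' @param influentCOD influent COD, mg/L (> 0).
#' @param influentNH4N influent NH4-N, mg/L (> 0).
#' @return integer x in "100:x". See [codNLabel()] for the formatted string.
#' @examples
#' codNRatio(1416, 85) # 6
#' codNRatio(712, 85)  # 12
#' @export
codNRatio <- function(influentCOD, influentNH4N) {
  if (any(influentCOD <= 0)) stop("influent COD must be positive")
  if (any(influentNH4N <= 0)) stop("influent NH4-N must be positive")
  as.integer(round(100 * influentNH4N / influentCOD))
}

#' @rdname codNRatio
#' @param ... passed to [codNRatio()].
#' @export
codNLabel <- function(...) sprintf("100:%d", codNRatio(...))

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full paired-compartment analysis
#'
#' End-to-end orchestration: relative abundances, category means and
#' common-dominant-genus selection, retention-ratio series with trend
#' correlations and steady-state Wilcoxon tests, Bray-Curtis dissimilarity
#' with paired and cross-reactor similarity summaries, NMDS ordination,
#' per-sample diversity indices, and a machine-readable run manifest. All
#' outputs are numeric TSV/JSON files; counts of undefined ratios, unpaired
#' samples and not-computable tests are recorded in the manifest so nothing
#' is silently dropped.
#'
#' @param outDir output directory (created if needed).
#' @param experiment a \linkS4class{WashoutExperiment}; alternatively give
#'   \code{countsPath}/\code{metaPath} to read tables from disk, or neither
#'   to simulate the bundled [scenarioPaperLike()] scenario.
#' @param countsPath,metaPath input files for [readCountTable()] /
#'   [readSampleMetadata()].
#' @param seed integer seed governing simulation noise and NMDS restarts.
#' @param topN number of dominant common genera to select (default 19).
#' @param startupEndDay phase boundary day (default 42).
#' @param zeroPolicy \code{"exclude"} or \code{"pseudocount"} (see
#'   [retentionSeries()]).
#' @param nmdsK,nmdsRestarts NMDS dimensions and restarts.
#' @return invisibly, a list with the output paths and the key result
#'   objects.
#' @export
runPipeline <- function(outDir, experiment = NULL, countsPath = NULL,
                        metaPath = NULL, seed = 1, topN = 19,
                        startupEndDay = 42,
                        zeroPolicy = c("exclude", "pseudocount"),
                        nmdsK = 2, nmdsRestarts = 20) {
  zeroPolicy <- match.arg(zeroPolicy)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- "input"
  res <- tryCatch({
    we <- if (!is.null(experiment)) {
      experiment
    } else if (!is.null(countsPath)) {
      if (is.null(metaPath)) stop("metaPath required with countsPath")
      WashoutExperiment(readCountTable(countsPath),
                        readSampleMetadata(metaPath),
                        startupEndDay = startupEndDay)
    } else {
      simulateScenario(scenarioPaperLike(), seed = seed)$experiment
    }

    stage <- "abundance"
    ra <- relativeAbundance(we)
    .writeTsv(data.frame(taxon = rownames(ra), ra, check.names = FALSE),
              file.path(outDir, "relative_abundance.tsv"))
    cm <- categoryMeans(we)
    .writeTsv(data.frame(taxon = rownames(cm), cm, check.names = FALSE),
              file.path(outDir, "category_means.tsv"))
    top <- selectCommonTop(we, n = topN)
    writeLines(top, file.path(outDir, "top_genera.txt"))

    stage <- "retention"
    pi <- pairedIndex(we)
    series <- retentionSeries(we, taxa = top, zeroPolicy = zeroPolicy)
    .writeTsv(series, file.path(outDir, "retention_series.tsv"))
    trend <- pearsonTrend(series)
    .writeTsv(trend, file.path(outDir, "trend_table.tsv"))
    phase <- wilcoxonVsOne(series, phase = "steady")
    .writeTsv(phase, file.path(outDir, "phase_tests.tsv"))

    stage <- "community"
    dm <- brayCurtisMatrix(we)
    .writeTsv(data.frame(sample_id = rownames(dm), dm, check.names = FALSE),
              file.path(outDir, "dissimilarity.tsv"))
    pss <- pairedSimilaritySummary(dm, pi)
    .writeTsv(pss, file.path(outDir, "paired_similarity.tsv"))
    maxDay <- max(sampleDay(we))
    bgs <- NULL
    if (length(unique(reactor(we))) >= 2) {
      bgs <- betweenGroupSimilarity(dm, we, window = c(startupEndDay + 1,
                                                       maxDay))
      .writeTsv(bgs, file.path(outDir, "between_reactor_similarity.tsv"))
    }
    ord <- nmdsOrdination(dm, k = nmdsK, nRestarts = nmdsRestarts,
                          seed = seed)
    pts <- ordinationPoints(ord)
    .writeTsv(data.frame(sample_id = rownames(pts), pts,
                         stress = ordinationStress(ord),
                         check.names = FALSE),
              file.path(outDir, "nmds_coordinates.tsv"))
    div <- diversityTable(we)
    .writeTsv(div, file.path(outDir, "diversity.tsv"))

    stage <- "manifest"
    manifest <- list(
      seed = seed,
      parameters = list(topN = topN, startupEndDay = startupEndDay,
                        zeroPolicy = zeroPolicy, nmdsK = nmdsK,
                        nmdsRestarts = nmdsRestarts),
      n_samples = ncol(we), n_taxa = nrow(we),
      n_pairs = nrow(samplePairs(pi)),
      n_unpaired_samples = nrow(unpairedSamples(pi)),
      n_undefined_ratios = sum(is.na(series$ratio)),
      n_not_computable_trends = sum(trend$status != "ok"),
      n_not_computable_phase_tests = sum(phase$status != "ok"),
      nmds_stress = ordinationStress(ord),
      r_version = as.character(getRversion()),
      package_version = as.character(utils::packageVersion("washoutR")))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(experiment = we, top = top, series = series, trend = trend,
         phase = phase, pairedSimilarity = pss, betweenGroup = bgs,
         ordination = ord, diversity = div, manifest = manifest,
         outDir = outDir)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
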
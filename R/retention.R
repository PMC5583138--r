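#' Assign the operational phase from the day since seeding
#'
#' Start-up covers weeks 1-6 (days 0-42, seeding day included), steady-state
#' operation weeks 7-12 (day 43 onwards), following the process-performance
#' definition of the phases (ammonium and total-nitrogen removal stabilising
#' after about six weeks).
#'
#' @param day integer vector of days since seeding (>= 0).
#' @param startupEndDay last day (inclusive) of start-up; default 42.
#' @return factor with levels \code{startup}, \code{steady}.
#' @examples
#' assignPhase(c(42, 43)) # startup, steady
#' @export
assignPhase <- function(day, startupEndDay = 42) {
  if (anyNA(day) || any(day < 0)) stop("day must be non-negative")
  factor(ifelse(day <= startupEndDay, "startup", "steady"),
         levels = c("startup", "steady"))
}

#' Per-taxon retention ratio
#'
#' The retention ratio of a taxon at one contemporaneous sample pair is its
#' relative read abundance in the granular (reactor) sample divided by its
#' relative read abundance in the effluent sample. A value above 1 means the
#' taxon is better represented in the reactor than in the effluent (good
#' retention); below 1, preferential wash-out. The ratio is undefined when
#' the effluent abundance is zero; undefined values carry a reason
#' (\code{zero_effluent} or \code{zero_both}) in attribute \code{"reason"}
#' and are never interpolated.
#'
#' @param granular,effluent relative abundances in [0, 1] (vectorized).
#' @return numeric vector of ratios, NA where undefined, with character
#'   attribute \code{"reason"} ("" where defined).
#' @examples
#' retentionRatio(0.10, 0.05) # 2
#' retentionRatio(0.02, 0)    # NA, reason "zero_effluent"
#' @export
retentionRatio <- function(granular, effluent) {
  if (length(granular) != length(effluent))
    stop("granular and effluent must have equal length")
  if (anyNA(granular) || anyNA(effluent) ||
      any(granular < 0 | granular > 1) || any(effluent < 0 | effluent > 1))
    stop("relative abundances must lie in [0, 1]")
  ratio <- ifelse(effluent > 0, granular / effluent, NA_real_)
  reason <- ifelse(effluent > 0, "",
                   ifelse(granular > 0, "zero_effluent", "zero_both"))
  structure(ratio, reason = reason)
}

#' Retention-ratio time series for paired samples
#'
#' Computes, for each requested taxon and each contemporaneous
#' granular/effluent sample pair, the retention ratio of per-sample relative
#' abundances. Undefined ratios (zero effluent abundance) are flagged with a
#' reason and excluded from downstream tests under the default
#' \code{zeroPolicy = "exclude"}; \code{"pseudocount"} instead adds 0.5 reads
#' to every cell of the count table before closure, so every ratio is
#' defined (all ratios shift slightly as a consequence).
#'
#' @param x a \linkS4class{WashoutExperiment}.
#' @param taxa taxon labels to evaluate (default: all).
#' @param zeroPolicy \code{"exclude"} (default) or \code{"pseudocount"}.
#' @param pseudocount reads added per cell under the pseudocount policy.
#' @return data.frame with columns taxon, reactor, day, phase, granular,
#'   effluent (relative abundances), ratio, reason — one row per taxon x
#'   pair. Unpaired samples never contribute rows.
#' @export
retentionSeries <- function(x, taxa = NULL,
                            zeroPolicy = c("exclude", "pseudocount"),
                            pseudocount = 0.5) {
  stopifnot(is(x, "WashoutExperiment"))
  zeroPolicy <- match.arg(zeroPolicy)
  if (is.null(taxa)) taxa <- rownames(x)
  missing <- setdiff(taxa, rownames(x))
  if (length(missing))
    stop("taxa not in table: ", paste(missing, collapse = ", "))
  pi <- pairedIndex(x)
  pairs <- samplePairs(pi)
  if (!nrow(pairs)) stop("no contemporaneous granular/effluent pairs found")
  cnt <- counts(x)
  if (zeroPolicy == "pseudocount") cnt <- cnt + pseudocount
  ra <- relativeAbundance(cnt)
  g <- ra[taxa, pairs$granular, drop = FALSE]
  e <- ra[taxa, pairs$effluent, drop = FALSE]
  rr <- retentionRatio(as.vector(g), as.vector(e))
  np <- nrow(pairs)
  nt <- length(taxa)
  boundary <- metadata(x)$startupEndDay %||% 42
  data.frame(taxon = rep(taxa, times = np),
             reactor = rep(pairs$reactor, each = nt),
             day = rep(pairs$day, each = nt),
             phase = as.character(assignPhase(rep(pairs$day, each = nt),
                                              boundary)),
             granular = as.vector(g), effluent = as.vector(e),
             ratio = as.vector(rr),
             reason = attr(rr, "reason"),
             stringsAsFactors = FALSE)
}

#' Significance stars for p-values
#'
#' Strict-inequality cutoffs as conventionally printed in correlation
#' tables: \code{***} p < 0.001, \code{**} p < 0.01, \code{*} p < 0.05,
#' \code{•} p < 0.1, otherwise "". Exactly p = 0.05 therefore earns
#' \code{•}, not \code{*}.
#'
#' @param p numeric vector of p-values in (0, 1]; NA passes through.
#' @return character vector of star markers.
#' @export
significanceStars <- function(p) {
  ok <- is.na(p) | (p > 0 & p <= 1)
  if (!all(ok)) stop("p-values must lie in (0, 1]")
  out <- ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*",
         ifelse(p < 0.1, "•", ""))))
  out[is.na(p)] <- NA_character_
  out
}

#' Temporal trend of retention ratios
#'
#' For each (taxon, reactor) series, the Pearson correlation between the day
#' since seeding and the retention ratio over all defined points, with the
#' usual two-sided t-test p-value (t = r sqrt((n-2)/(1-r^2)) on n-2 df) and
#' significance stars. Series with fewer than 3 defined points, or with zero
#' variance in either coordinate, are flagged rather than dropped. A
#' Benjamini-Hochberg adjusted column \code{p_bh} is emitted as a
#' convenience; the star markers are based on the raw p-values.
#'
#' @param series data.frame from [retentionSeries()].
#' @return data.frame with columns taxon, reactor, n, r, p, stars, p_bh,
#'   status (\code{ok}, \code{not_computable}, or
#'   \code{not_computable_constant}).
#' @export
pearsonTrend <- function(series) {
  stopifnot(all(c("taxon", "reactor", "day", "ratio") %in% colnames(series)))
  groups <- split(series, list(series$taxon, series$reactor), drop = TRUE)
  rows <- lapply(groups, function(df) {
    ok <- !is.na(df$ratio)
    n <- sum(ok)
    out <- data.frame(taxon = df$taxon[1], reactor = df$reactor[1],
                      n = n, r = NA_real_, p = NA_real_,
                      stars = NA_character_, status = "ok",
                      stringsAsFactors = FALSE)
    if (n < 3) {
      out$status <- "not_computable"
    } else if (stats::var(df$day[ok]) == 0 || stats::var(df$ratio[ok]) == 0) {
      out$status <- "not_computable_constant"
    } else {
      ct <- stats::cor.test(df$day[ok], df$ratio[ok], method = "pearson")
      out$r <- unname(ct$estimate)
      # p underflows to 0 for |r| = 1; keep it in (0, 1] for the star rule
      out$p <- max(ct$p.value, .Machine$double.xmin)
      out$stars <- significanceStars(out$p)
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res <- res[order(res$taxon, res$reactor), , drop = FALSE]
  res$p_bh <- stats::p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res[, c("taxon", "reactor", "n", "r", "p", "stars", "p_bh", "status")]
}

#' Phase-wise Wilcoxon test of retention ratios against 1
#'
#' For each (taxon, reactor) series, the defined retention ratios of the
#' requested phase are tested against the hypothesized value 1 with a
#' two-sided one-sample Wilcoxon signed-rank test ([signedRankTest()]): zero
#' differences are dropped, the null is enumerated exactly for n <= 25 and a
#' tie-corrected normal approximation is used beyond. The test runs on the
#' raw ratio scale by default (note the raw scale is asymmetric around 1;
#' \code{logScale = TRUE} tests log-ratios against 0 instead). The direction
#' call requires both significance at \code{alpha} and the median on the
#' corresponding side of 1.
#'
#' @param series data.frame from [retentionSeries()].
#' @param phase \code{"steady"} (default) or \code{"startup"}.
#' @param alpha significance level for the direction call (0.05).
#' @param exact,exactMax passed to [signedRankTest()].
#' @param logScale test log(ratio) against 0 instead of ratio against 1.
#' @return data.frame with columns taxon, reactor, phase, n (defined,
#'   nonzero-difference points), median (of defined ratios), statistic (V,
#'   positive-rank sum), p, direction (\code{above_1}, \code{below_1},
#'   \code{none}), status.
#' @export
wilcoxonVsOne <- function(series, phase = c("steady", "startup"),
                          alpha = 0.05, exact = NULL, exactMax = 25,
                          logScale = FALSE) {
  phase <- match.arg(phase)
  stopifnot(all(c("taxon", "reactor", "phase", "ratio") %in% colnames(series)))
  sub <- series[series$phase == phase, , drop = FALSE]
  groups <- split(sub, list(sub$taxon, sub$reactor), drop = TRUE)
  rows <- lapply(groups, function(df) {
    x <- df$ratio[!is.na(df$ratio)]
    med <- if (length(x)) stats::median(x) else NA_real_
    if (!length(x)) {
      tst <- list(statistic = NA_real_, p.value = NA_real_, n = 0L,
                  status = "not_computable")
    } else if (logScale) {
      tst <- signedRankTest(log(x), mu = 0, exact = exact,
                            exactMax = exactMax)
    } else {
      tst <- signedRankTest(x, mu = 1, exact = exact, exactMax = exactMax)
    }
    dir <- "none"
    if (tst$status == "ok" && !is.na(tst$p.value) && tst$p.value < alpha) {
      if (med > 1) dir <- "above_1" else if (med < 1) dir <- "below_1"
    }
    data.frame(taxon = df$taxon[1], reactor = df$reactor[1], phase = phase,
               n = tst$n, median = med, statistic = tst$statistic,
               p = tst$p.value, direction = dir, status = tst$status,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$taxon, res$reactor), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Tukey five-number boxplot summary
#'
#' Median and quartiles by the linear-interpolation quantile rule
#' (\code{type = 7}), whiskers at the most extreme observations within 1.5
#' IQR of the quartiles, everything beyond reported as outliers.
#'
#' @param x numeric vector (NAs dropped).
#' @return list with \code{stats} = c(lower whisker, Q1, median, Q3, upper
#'   whisker) and \code{outliers}.
#' @examples
#' summarizeBoxplot(c(1, 2, 3, 4, 100)) # upper whisker 4, outlier 100
#' @export
summarizeBoxplot <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("no defined values to summarize")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  list(stats = c(min(x[x >= lo]), q[1], q[2], q[3], max(x[x <= hi])),
       outliers = sort(x[x < lo | x > hi]))
}
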
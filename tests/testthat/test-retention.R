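test_that("phase assignment splits start-up (weeks 1-6) from steady state", {
  expect_identical(as.character(assignPhase(42)), "startup")
  expect_identical(as.character(assignPhase(43)), "steady")
  expect_identical(as.character(assignPhase(0)), "startup")
  expect_error(assignPhase(-1), "non-negative")
  expect_identical(as.character(assignPhase(30, startupEndDay = 28)),
                   "steady")
})

test_that("retention ratio arithmetic and undefined-value policy", {
  expect_equal(as.vector(retentionRatio(0.10, 0.05)), 2.0)
  for (x in c(0.01, 0.3, 1)) expect_equal(as.vector(retentionRatio(x, x)), 1)
  r <- retentionRatio(c(0.02, 0, 0.5), c(0, 0, 0.25))
  expect_identical(attr(r, "reason"), c("zero_effluent", "zero_both", ""))
  expect_true(is.na(r[1]) && is.na(r[2]) && r[3] == 2)
  expect_error(retentionRatio(1.2, 0.5), "\\[0, 1\\]")
  expect_error(retentionRatio(0.5, -0.1), "\\[0, 1\\]")
})

test_that("retention series bookkeeping flags undefined points, never drops them", {
  we <- makeToyExperiment(nTaxa = 3, days = c(10, 20, 30, 50, 60))
  cnt <- counts(we)
  eff <- colnames(we)[compartment(we) == "effluent"]
  cnt["g__T2", eff[c(1, 3)]] <- 0L   # absent from effluent on 2 of 5 days
  we2 <- WashoutExperiment(cnt, data.frame(
    sample_id = colnames(we), reactor = reactor(we),
    compartment = compartment(we), day = sampleDay(we)))
  sr <- retentionSeries(we2)
  t2 <- sr[sr$taxon == "g__T2", ]
  expect_identical(nrow(t2), 5L)
  expect_identical(sum(is.na(t2$ratio)), 2L)
  expect_identical(sort(unique(t2$reason[is.na(t2$ratio)])), "zero_effluent")
  expect_error(retentionSeries(we2, taxa = "g__missing"), "g__missing")
})

test_that("two-taxon closure: one ratio above 1 forces the other below", {
  set.seed(11)
  for (rep in 1:20) {
    cnt <- matrix(sample(1:200, 4, replace = TRUE), 2, 2,
                  dimnames = list(c("A", "B"), c("g1", "e1")))
    storage.mode(cnt) <- "integer"
    we <- WashoutExperiment(cnt, data.frame(
      sample_id = c("g1", "e1"), reactor = "R1",
      compartment = c("granular", "effluent"), day = 10L))
    sr <- retentionSeries(we)
    rA <- sr$ratio[sr$taxon == "A"]
    rB <- sr$ratio[sr$taxon == "B"]
    if (rA == 1) expect_equal(rB, 1)
    else expect_true(xor(rA > 1, rB > 1))
  }
})

test_that("ratios are composition-based: scaling effluent counts changes nothing", {
  we <- makeToyExperiment(nTaxa = 6, days = c(10, 50))
  sr <- retentionSeries(we)
  cnt <- counts(we)
  eff <- compartment(we) == "effluent"
  cnt[, eff] <- cnt[, eff] * 7L
  we2 <- WashoutExperiment(cnt, data.frame(
    sample_id = colnames(we), reactor = reactor(we),
    compartment = compartment(we), day = sampleDay(we)))
  expect_equal(retentionSeries(we2)$ratio, sr$ratio, tolerance = 1e-12)
})

test_that("effluent-weighted ratios conserve unity over the full table", {
  we <- makeToyExperiment(nTaxa = 7, days = c(10, 30, 50))
  sr <- retentionSeries(we)   # no zero cells in this fixture
  for (d in unique(sr$day)) {
    sub <- sr[sr$day == d, ]
    expect_equal(sum(sub$effluent * sub$ratio), 1, tolerance = 1e-12)
    expect_equal(sum(sub$granular), 1, tolerance = 1e-12)
  }
})

test_that("significance stars use strict cutoffs", {
  expect_identical(significanceStars(c(0.0007, 0.009, 0.049, 0.05, 0.09, 0.5)),
                   c("***", "**", "*", "•", "•", ""))
  expect_error(significanceStars(0), "\\(0, 1\\]")
  expect_error(significanceStars(1.5), "\\(0, 1\\]")
  expect_identical(significanceStars(NA_real_), NA_character_)
})

test_that("pearson trend matches the definitional oracle and flags degeneracy", {
  mk <- function(day, ratio) data.frame(
    taxon = "t", reactor = "R1", day = day,
    phase = as.character(assignPhase(day)), granular = NA, effluent = NA,
    ratio = ratio, reason = "", stringsAsFactors = FALSE)

  perfect <- pearsonTrend(mk(1:3, 1:3))
  expect_equal(perfect$r, 1)

  const <- pearsonTrend(mk(1:3, rep(2, 3)))
  expect_identical(const$status, "not_computable_constant")
  expect_true(is.na(const$r))

  short <- pearsonTrend(mk(1:2, c(1, 2)))
  expect_identical(short$status, "not_computable")

  set.seed(5)
  day <- c(3, 17, 31, 52, 80)
  ratio <- exp(rnorm(5, 0, 0.4))
  got <- pearsonTrend(mk(day, ratio))
  want <- pearsonOracle(day, ratio)
  expect_equal(got$r, want$r, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  expect_identical(got$stars, significanceStars(want$p))
})

test_that("wilcoxon against 1: exact p-values, degenerate input, raw-scale ranks", {
  res <- signedRankTest(c(2.1, 1.8, 2.5, 1.9, 2.2, 2.0), mu = 1)
  expect_equal(res$p.value, 2 * (1 / 2^6))
  expect_equal(res$statistic, 21)       # all six positive ranks

  allone <- signedRankTest(rep(1, 5), mu = 1)
  expect_identical(allone$status, "degenerate")

  # raw scale: (0.5, 2.0) vs 1 has |−0.5| < |1.0|, hence V = 2, p = 1
  recip <- signedRankTest(c(0.5, 2.0), mu = 1)
  expect_equal(recip$statistic, 2)
  expect_equal(recip$p.value, 1)
})

test_that("exact signed-rank p agrees with full 2^n enumeration for n <= 10", {
  set.seed(77)
  for (rep in 1:60) {
    n <- sample(2:10, 1)
    # rounding induces ties and occasional zero differences
    x <- round(rnorm(n, mean = 0.3, sd = 1), sample(0:1, 1))
    if (all(x == 0)) next
    got <- signedRankTest(x, mu = 0)
    want <- wilcoxonEnumOracle(x, mu = 0)
    expect_equal(got$statistic, want$statistic)
    expect_equal(got$p.value, want$p.value, tolerance = 1e-12)
  }
})

test_that("wilcoxonVsOne calls direction from median and significance", {
  we <- makeToyExperiment(nTaxa = 4, days = c(45, 52, 59, 66, 73, 80, 84))
  cnt <- counts(we)
  gr <- compartment(we) == "granular"
  cnt["g__T1", gr] <- cnt["g__T1", !gr] * 4L   # strongly retained
  we2 <- WashoutExperiment(cnt, data.frame(
    sample_id = colnames(we), reactor = reactor(we),
    compartment = compartment(we), day = sampleDay(we)))
  ph <- wilcoxonVsOne(retentionSeries(we2), phase = "steady")
  row <- ph[ph$taxon == "g__T1", ]
  expect_identical(row$direction, "above_1")
  expect_true(row$median > 1 && row$p < 0.05)
})

test_that("boxplot summary follows the 1.5 IQR whisker rule", {
  b <- summarizeBoxplot(c(1, 2, 3, 4, 100))
  expect_equal(b$stats, c(1, 2, 3, 4, 4))
  expect_equal(b$outliers, 100)

  b1 <- summarizeBoxplot(7)
  expect_true(all(b1$stats == 7) && !length(b1$outliers))

  sym <- summarizeBoxplot(c(1, 2, 3, 4, 5))
  expect_equal(sym$stats[3] - sym$stats[2], sym$stats[4] - sym$stats[3])
})
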
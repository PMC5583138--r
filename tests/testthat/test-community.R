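test_that("Bray-Curtis limits, hand arithmetic, and double-loop oracle", {
  expect_equal(brayCurtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(brayCurtis(c(1, 0), c(0, 1)), 1)
  expect_equal(brayCurtis(c(1, 2, 3), c(3, 2, 1)), 4 / 12)
  expect_error(brayCurtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(brayCurtis(c(-1, 2), c(1, 2)), "non-negative")

  set.seed(8)
  for (rep in 1:40) {
    x <- runif(12) * sample(c(1, 100), 1)
    y <- runif(12)
    expect_equal(brayCurtis(x, y), bcOracle(x, y), tolerance = 1e-12)
    # symmetry and joint-scale invariance
    expect_equal(brayCurtis(x, y), brayCurtis(y, x), tolerance = 1e-15)
    expect_equal(brayCurtis(3.7 * x, 3.7 * y), brayCurtis(x, y),
                 tolerance = 1e-12)
  }
})

test_that("count-scale and relative-scale Bray-Curtis agree only at equal totals", {
  x <- c(10, 20, 30); y <- c(30, 20, 10)          # equal totals
  expect_equal(brayCurtis(x, y), brayCurtis(x / sum(x), y / sum(y)),
               tolerance = 1e-12)
  y2 <- 2 * y                                      # unequal totals
  expect_gt(abs(brayCurtis(x, y2) - brayCurtis(x / sum(x), y2 / sum(y2))),
            1e-3)
})

test_that("dissimilarity matrix is symmetric, bounded, zero-diagonal, matches scalar op", {
  we <- makeToyExperiment(nTaxa = 6, days = c(5, 20, 50, 70))
  dm <- brayCurtisMatrix(we)
  expect_equal(dm, t(dm), tolerance = 1e-12)
  expect_true(all(diag(dm) == 0))
  expect_true(all(dm >= 0 & dm <= 1))
  ra <- relativeAbundance(we)
  expect_equal(dm[1, 2], brayCurtis(ra[, 1], ra[, 2]), tolerance = 1e-12)
})

test_that("paired similarity summary: identical pairs and hand-computed means", {
  pairs <- new("PairedIndex",
               pairs = data.frame(reactor = "R1", day = c(1L, 2L),
                                  granular = c("g1", "g2"),
                                  effluent = c("e1", "e2"),
                                  stringsAsFactors = FALSE),
               unpaired = data.frame(sample_id = character(),
                                     reactor = character(),
                                     compartment = character(),
                                     day = integer()))
  ids <- c("g1", "g2", "e1", "e2")
  dm0 <- matrix(0, 4, 4, dimnames = list(ids, ids))
  s0 <- pairedSimilaritySummary(dm0, pairs)
  expect_equal(s0$mean_similarity, 100)
  expect_equal(s0$sd_similarity, 0)

  dm <- dm0
  dm["g1", "e1"] <- dm["e1", "g1"] <- 0.3
  dm["g2", "e2"] <- dm["e2", "g2"] <- 0.4
  s <- pairedSimilaritySummary(dm, pairs)
  expect_equal(s$mean_similarity, 65)
  expect_equal(s$sd_similarity, sd(c(70, 60)), tolerance = 1e-12)

  expect_error(pairedSimilaritySummary(dm0[1:3, 1:3], pairs), "missing")
})

test_that("paired similarity decreases as erosion enrichment grows (noiseless)", {
  tx <- makeTaxa(12)
  sims <- sapply(c(0, 0.5, 1, 2, 3), function(b) {
    tr <- simulateWashout(simConfig(tx, beta = b, delta = 0))$truth
    j <- length(tr@days)             # final steady-state day
    (1 - brayCurtis(tr@p[, j], tr@q[, j])) * 100
  })
  expect_equal(sims[1], 100)
  expect_true(all(diff(sims) < 0))
})

test_that("between-group similarity: identical, disjoint, and simulated reactors", {
  ids <- c("a1", "a2", "b1", "b2")
  meta <- data.frame(sample_id = ids, reactor = rep(c("A", "B"), each = 2),
                     day = c(50L, 60L, 50L, 60L), stringsAsFactors = FALSE)
  dm0 <- matrix(0, 4, 4, dimnames = list(ids, ids))
  expect_equal(betweenGroupSimilarity(dm0, meta)$mean_similarity, 100)
  dm1 <- matrix(1, 4, 4, dimnames = list(ids, ids)); diag(dm1) <- 0
  expect_equal(betweenGroupSimilarity(dm1, meta)$mean_similarity, 0)
  expect_error(betweenGroupSimilarity(dm0, meta, window = c(70, 80)),
               "group")

  # three simulated reactors with different erosion regimes: cross-reactor
  # similarity stays below the within-reactor paired similarity
  sim <- simulateScenario(scenarioPaperLike(), seed = 5)
  dm <- brayCurtisMatrix(sim$experiment)
  pss <- pairedSimilaritySummary(dm, pairedIndex(sim$experiment))
  bgs <- betweenGroupSimilarity(dm, sim$experiment, window = c(43, 84))
  expect_true(max(bgs$mean_similarity) < min(pss$mean_similarity))
})

test_that("diversity indices: closed forms, hand arithmetic, vegan cross-check", {
  expect_equal(margalefRichness(1, 50), 0)
  expect_equal(margalefRichness(10, 100), 9 / log(100))
  expect_error(margalefRichness(5, 1), ">= 2")
  expect_true(margalefRichness(11, 100) > margalefRichness(10, 100))

  expect_equal(pielouEvenness(rep(1 / 5, 5)), 1)
  expect_true(is.na(pielouEvenness(1)))
  p <- c(0.5, 0.25, 0.25)
  expect_equal(shannonIndex(p), 1.0397, tolerance = 1e-4)
  expect_equal(pielouEvenness(p), 1.0397208 / log(3), tolerance = 1e-6)
  expect_error(pielouEvenness(c(0.5, 0.2)), "sum to 1")

  set.seed(3)
  for (rep in 1:10) {
    v <- rmultinom(1, 500, runif(8) + 0.05)[, 1]
    v <- v[v >= 0]
    pv <- v / sum(v)
    expect_equal(shannonIndex(pv), vegan::diversity(v, index = "shannon"),
                 tolerance = 1e-12)
    expect_lte(pielouEvenness(pv), 1)
  }

  we <- makeToyExperiment(nTaxa = 5, days = c(10, 50))
  dt <- diversityTable(we)
  expect_identical(nrow(dt), 4L)
  expect_equal(dt$margalef,
               margalefRichness(dt$richness_S, dt$reads_N))
})
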
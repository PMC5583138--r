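test_that("TSV count tables round-trip exactly, including simulator output", {
  f <- tempfile(fileext = ".tsv")
  m <- matrix(c(5L, 3L, 2L, 8L, 1L, 4L), 3, 2,
              dimnames = list(c("g__A", "g__B", "OTU_6"), c("S1", "S2")))
  writeCountTable(m, f)
  expect_identical(readCountTable(f), m)

  sim <- simulateWashout(simConfig(makeTaxa(8), depth = 5000), seed = 7)
  cnt <- counts(sim$experiment)
  writeCountTable(cnt, f)
  back <- readCountTable(f)
  expect_identical(back, cnt)
  expect_identical(rownames(back), rownames(cnt))
  expect_identical(colnames(back), colnames(cnt))
})

test_that("count table validation rejects bad input", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("taxon\tS1\tS2", "g__A\t-1\t2", "g__B\t3\t4"), f)
  expect_error(readCountTable(f), "negative")

  writeLines(c("taxon\tS1", "g__A\t1.5"), f)
  expect_error(readCountTable(f), "non-integral")
  expect_warning(m <- readCountTable(f, strict = FALSE), "rounding")
  expect_identical(m[1, 1], 2L)

  writeLines(c("taxon\tS1", "g__A\t2", "g__A\t3"), f)
  expect_error(readCountTable(f), "duplicate taxon")

  writeLines(c("taxon\tS1\tS2", "g__A\tx\t2", "g__B\t3\t4"), f)
  expect_error(readCountTable(f), "line")

  writeLines(c("taxon\tS1\tS2", "g__A\t0\t2", "g__B\t0\t4"), f)
  expect_error(readCountTable(f), "zero-sum.*S1")
})

test_that("BIOM dense tables are read when biomformat is present", {
  skip_if_not_installed("biomformat")
  m <- matrix(c(5L, 3L, 2L, 8L, 0L, 4L), 3, 2,
              dimnames = list(c("t1", "t2", "t3"), c("S1", "S2")))
  f <- tempfile(fileext = ".biom")
  biomformat::write_biom(biomformat::make_biom(m), f)
  expect_identical(readCountTable(f, format = "biom_dense"), m)
})

test_that("metadata parsing normalizes compartments and enforces uniqueness", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,reactor,compartment,day", "S1,R1,effluent,55"), f)
  md <- readSampleMetadata(f)
  expect_identical(md$reactor, "R1")
  expect_identical(md$compartment, "effluent")
  expect_identical(md$day, 55L)

  writeLines(c("sample_id,reactor,compartment,day", "S1,R1,granule,10"), f)
  expect_identical(readSampleMetadata(f)$compartment, "granular")

  writeLines(c("sample_id,reactor,compartment,day",
               "S1,R1,sludge,10"), f)
  expect_error(readSampleMetadata(f), "sludge")

  writeLines(c("sample_id,reactor,compartment,day",
               "S1,R1,granular,10", "S2,R1,granular,10"), f)
  expect_error(readSampleMetadata(f), "duplicate")

  # TSV dialect is sniffed from the header
  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\treactor\tcompartment\tday",
               "S1\tR2\tsuspended\t7"), f2)
  md2 <- readSampleMetadata(f2)
  expect_identical(md2$compartment, "effluent")
})

test_that("paired index matches the 13+13-per-reactor design and reports unpaired", {
  sim <- simulateScenario(scenarioPaperLike(), seed = 3)
  pi <- pairedIndex(sim$experiment)
  expect_identical(nrow(samplePairs(pi)), 39L)
  expect_identical(as.vector(table(samplePairs(pi)$reactor)), rep(13L, 3))
  expect_identical(nrow(unpairedSamples(pi)), 0L)

  meta <- data.frame(sample_id = c("a", "b"), reactor = "R1",
                     compartment = c("granular", "effluent"),
                     day = c(5L, 6L), stringsAsFactors = FALSE)
  pi2 <- pairedIndex(meta)
  expect_identical(nrow(samplePairs(pi2)), 0L)
  expect_identical(nrow(unpairedSamples(pi2)), 2L)

  pi3 <- pairedIndex(meta[0, ])
  expect_identical(nrow(samplePairs(pi3)), 0L)
  expect_identical(nrow(unpairedSamples(pi3)), 0L)
})

test_that("paired index size never exceeds the smaller compartment", {
  set.seed(42)
  for (rep in 1:10) {
    ng <- sample(0:8, 1); ne <- sample(0:8, 1)
    meta <- rbind(
      if (ng) data.frame(sample_id = paste0("g", 1:ng), reactor = "R1",
                         compartment = "granular",
                         day = sample(1:10, ng), stringsAsFactors = FALSE),
      if (ne) data.frame(sample_id = paste0("e", 1:ne), reactor = "R1",
                         compartment = "effluent",
                         day = sample(1:10, ne), stringsAsFactors = FALSE))
    if (is.null(meta)) next
    pi <- pairedIndex(meta)
    expect_lte(nrow(samplePairs(pi)), min(ng, ne))
    expect_identical(2L * nrow(samplePairs(pi)) + nrow(unpairedSamples(pi)),
                     nrow(meta))
  }
})

test_that("WashoutExperiment validity catches malformed objects", {
  we <- makeToyExperiment()
  expect_s4_class(we, "WashoutExperiment")
  bad <- counts(we); bad[1, 1] <- -1L
  expect_error(WashoutExperiment(bad, data.frame(
    sample_id = colnames(we), reactor = reactor(we),
    compartment = compartment(we), day = sampleDay(we))),
    "non-negative")
})
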
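test_that("the full pipeline reproduces the reference example under both methods", {
  repo <- workedExampleRepository()
  crm <- rankingEntries(recommend(workedExampleText(), repo,
                                  runConfig(method = "CR_M")))
  expect_equal(crm$ontologyId, c("NCI", "FMA", "40465"))
  expect_equal(crm$score, c(35, 25, 10))
  expect_equal(crm$rank, 1:3)
  cr <- rankingEntries(recommend(workedExampleText(), repo,
                                 runConfig(method = "CR")))
  expect_equal(stats::setNames(cr$score, cr$ontologyId),
               c("NCI" = 28, "FMA" = 18, "40465" = 10))
})

test_that("switching the output value reorders but never rescores", {
  repo <- workedExampleRepository()
  byScore <- rankingEntries(recommend(workedExampleText(), repo,
                                      runConfig(method = "CR_M", outputValue = "score")))
  byNorm <- rankingEntries(recommend(workedExampleText(), repo,
                                     runConfig(method = "CR_M", outputValue = "normalized")))
  expect_setequal(byScore$ontologyId, byNorm$ontologyId)
  m <- match(byScore$ontologyId, byNorm$ontologyId)
  expect_equal(byNorm$score[m], byScore$score)
  expect_equal(byNorm$normalizedScore[m], byScore$normalizedScore)
  # the one-concept ontology wins on the size-normalized value
  expect_equal(byNorm$ontologyId[1], "40465")
})

test_that("keyword scenario matches each line independently, longest-only", {
  repo <- breastCancerRepo()
  rk <- recommend("breast cancer\ncancer", repo, runConfig(scenario = "keyword"))
  e <- rankingEntries(rk)
  # line 1 keeps only the full phrase (HD); line 2 credits BIRN
  expect_setequal(e$ontologyId, c("HD", "BIRN"))
  expect_equal(e$score[e$ontologyId == "HD"], 10)
  expect_equal(e$score[e$ontologyId == "BIRN"], 10)
  # corpus scenario over the same text does not suppress by default
  rc <- rankingEntries(recommend("breast cancer\ncancer", repo,
                                 runConfig(scenario = "corpus")))
  expect_setequal(rc$ontologyId, c("HD", "VO", "BIRN"))
})

test_that("no dictionary hit yields an empty ranking with a warning", {
  repo <- workedExampleRepository()
  expect_warning(rk <- recommend("zzz qqq", repo, runConfig()),
                 "no annotations")
  expect_equal(nrow(rankingEntries(rk)), 0L)
  expect_error(recommend("", repo, runConfig()), "empty")
})

test_that("ties share the smaller rank and break by ontology id", {
  a <- ontology("AAA", data.frame(localId = "1", preferredName = "melanoma",
                                  stringsAsFactors = FALSE))
  b <- ontology("BBB", data.frame(localId = "1", preferredName = "melanoma",
                                  stringsAsFactors = FALSE))
  d <- ontology("CCC", data.frame(localId = "1", preferredName = "tumor",
                                  stringsAsFactors = FALSE),
                isaEdges = NULL)
  repo <- ontologyRepository(list(b, a, d))
  e <- rankingEntries(recommend("melanoma melanoma tumor", repo, runConfig()))
  expect_equal(e$ontologyId, c("AAA", "BBB", "CCC"))
  expect_equal(e$score, c(20, 20, 10))
  expect_equal(e$rank, c(1L, 1L, 3L))
})

test_that("topK truncates the ranking", {
  repo <- workedExampleRepository()
  e <- rankingEntries(recommend(workedExampleText(), repo,
                                runConfig(method = "CR_M", topK = 2L)))
  expect_equal(nrow(e), 2L)
  expect_equal(e$ontologyId, c("NCI", "FMA"))
})

test_that("repository group filter restricts the run", {
  repo <- workedExampleRepository()
  e <- rankingEntries(recommend(workedExampleText(), repo,
                                runConfig(method = "CR_M",
                                          repositoryFilter = "bioportal")))
  expect_equal(e$ontologyId, "40465")
  expect_equal(e$score, 10)
})

test_that("renderings: text table, XML element order, cloud scaling", {
  repo <- workedExampleRepository()
  rk <- recommend(workedExampleText(), repo, runConfig(method = "CR_M"))
  txt <- renderRanking(rk, "text")
  expect_match(txt, "NCI Thesaurus")
  expect_match(txt, "8\\.7500")
  doc <- xml2::read_xml(renderRanking(rk, "xml"))
  onts <- xml2::xml_find_all(doc, "//ontology")
  expect_equal(length(onts), 3L)
  expect_equal(xml2::xml_attr(onts, "id"), c("NCI", "FMA", "40465"))
  expect_equal(vapply(xml2::xml_children(onts[[1]]), xml2::xml_name, ""),
               c("score", "normalizedScore", "rank", "annotations"))
  cloud <- strsplit(renderRanking(rk, "cloud"), "\n")[[1]]
  w <- as.numeric(sub(".*\t", "", cloud))
  expect_equal(w[1], 10)  # the top score gets the top bucket
  expect_equal(w[3], 1)
  expect_equal(w[2], 1 + 9 * (25 - 10) / (35 - 10))
  expect_error(renderRanking(rk, "pdf"), "unknown format")
})

test_that("an all-equal ranking renders every cloud weight as 10", {
  a <- ontology("A", data.frame(localId = "1", preferredName = "melanoma",
                                stringsAsFactors = FALSE))
  b <- ontology("B", data.frame(localId = "1", preferredName = "melanoma",
                                stringsAsFactors = FALSE))
  rk <- recommend("melanoma", ontologyRepository(list(a, b)), runConfig())
  w <- as.numeric(sub(".*\t", "", strsplit(renderRanking(rk, "cloud"), "\n")[[1]]))
  expect_equal(w, c(10, 10))
})

test_that("JSON rendering round-trips the ranking exactly", {
  repo <- workedExampleRepository()
  for (value in c("score", "normalized")) {
    rk <- recommend(workedExampleText(), repo,
                    runConfig(method = "CR_M", outputValue = value))
    back <- parseRankingJSON(renderRanking(rk, "json"))
    expect_equal(rankingEntries(back), rankingEntries(rk))
    expect_equal(outputValue(back), outputValue(rk))
  }
  # empty ranking renders to a valid, parseable document
  empty <- suppressWarnings(recommend("zzz", repo, runConfig()))
  expect_equal(nrow(rankingEntries(parseRankingJSON(renderRanking(empty, "json")))), 0L)
  expect_equal(length(xml2::xml_children(xml2::read_xml(renderRanking(empty, "xml")))), 0L)
  expect_equal(renderRanking(empty, "cloud"), "")
})

test_that("identical input, repository and config give byte-identical JSON", {
  repo <- workedExampleRepository()
  cfg <- runConfig(method = "CR_M")
  j1 <- renderRanking(recommend(workedExampleText(), repo, cfg), "json")
  j2 <- renderRanking(recommend(workedExampleText(), repo, cfg), "json")
  expect_identical(as.character(j1), as.character(j2))
})

test_that("a planted source ontology is recovered at rank 1", {
  withr::local_seed(1357)
  wins <- 0L
  for (trial in 1:100) {
    repo <- generateRepository(fixtureSpec(
      nOntologies = 5L,
      sizeRanges = list(small = c(5L, 10L), medium = c(10L, 20L),
                        large = c(20L, 40L)),
      mappingDensity = 0.05, seed = sample.int(2^30, 1)))
    src <- sample(names(ontologies(repo)), 1)
    txt <- generateCorpus(repo, src, nTerms = 30, noiseFraction = 0.3,
                          seed = sample.int(2^30, 1))
    e <- rankingEntries(suppressWarnings(recommend(txt, repo, runConfig(method = "CR"))))
    if (nrow(e) && e$ontologyId[1] == src) wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})

test_that("a run configuration file in the service's parameter dialect loads", {
  cfgFile <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("longestOnly = true", "withDefaultStopWords = true",
               "minTermSize = 4", "activateMapping = true",
               "scenario = keyword"), cfgFile)
  cfg <- readRunConfig(cfgFile)
  expect_equal(cfg$method, "CR_M")
  expect_equal(cfg$scenario, "keyword")
  expect_true(cfg$match$longestOnly)
  expect_equal(cfg$match$minTermSize, 4L)
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("activateMapping: false", "outputValue: normalized",
               "preferred: 12"), yml)
  cfg2 <- readRunConfig(yml)
  expect_equal(cfg2$method, "CR")
  expect_equal(cfg2$outputValue, "normalized")
  expect_equal(cfg2$weights$preferred, 12)
})
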
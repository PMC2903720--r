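test_that("OBO subset parsing extracts ids, names, synonyms and is_a edges", {
  path <- writeTempOBO(c(
    "format-version: 1.2", "",
    "[Term]", "id: T:1", "name: Neoplasm",
    'synonym: "tumor" EXACT []', "",
    "[Term]", "id: T:2", "name: Melanoma", "is_a: T:1"))
  ont <- readOBO(path, "TOY")
  expect_s4_class(ont, "Ontology")
  expect_equal(ontologySize(ont), 2L)
  expect_equal(nrow(isaEdges(ont)), 1L)
  cc <- concepts(ont)
  expect_equal(cc$preferredName[cc$localId == "T:1"], "Neoplasm")
  expect_equal(cc$synonyms[[which(cc$localId == "T:1")]], "tumor")
  expect_equal(cc$synonyms[[which(cc$localId == "T:2")]], character())
})

test_that("obsolete terms are dropped and size reflects it", {
  path <- writeTempOBO(c(
    "[Term]", "id: T:1", "name: alpha", "",
    "[Term]", "id: T:2", "name: beta", "is_obsolete: true", "",
    "[Term]", "id: T:3", "name: gamma"))
  ont <- readOBO(path, "TOY")
  expect_equal(ontologySize(ont), 2L)
  expect_setequal(concepts(ont)$localId, c("T:1", "T:3"))
})

test_that("malformed stanzas, duplicate ids and is_a cycles are errors", {
  noName <- writeTempOBO(c("[Term]", "id: T:1", 'synonym: "x" EXACT []'))
  expect_error(readOBO(noName, "TOY"), "lacks a name")
  dup <- writeTempOBO(c("[Term]", "id: T:1", "name: a", "",
                        "[Term]", "id: T:1", "name: b"))
  expect_error(readOBO(dup, "TOY"), "duplicate term id")
  cyc <- writeTempOBO(c("[Term]", "id: T:1", "name: a", "is_a: T:2", "",
                        "[Term]", "id: T:2", "name: b", "is_a: T:1"))
  expect_error(readOBO(cyc, "TOY"), "cycle")
  unq <- writeTempOBO(c("[Term]", "id: T:1", "name: a", "synonym: no quotes"))
  expect_error(readOBO(unq, "TOY"), "unquoted synonym")
})

test_that("OBO round-trip preserves ids, names, synonyms and edges", {
  for (ont in ontologies(workedExampleRepository())) {
    path <- withr::local_tempfile(fileext = ".obo")
    writeOBO(ont, path)
    back <- readOBO(path, ontologyId(ont), displayName = displayName(ont),
                    groupTag = groupTag(ont))
    expect_equal(concepts(back), concepts(ont))
    expect_equal(isaEdges(back), isaEdges(ont))
  }
  # synthetic round-trip, incl. a hierarchy and multi-synonym concepts
  repo <- generateRepository(fixtureSpec(nOntologies = 2L, seed = 7L))
  for (ont in ontologies(repo)) {
    path <- withr::local_tempfile(fileext = ".obo")
    writeOBO(ont, path)
    back <- readOBO(path, ontologyId(ont))
    expect_equal(concepts(back), concepts(ont))
    expect_equal(isaEdges(back)[order(isaEdges(back)$child), ],
                 isaEdges(ont)[order(isaEdges(ont)$child), ],
                 ignore_attr = TRUE)
  }
})

test_that("an independent OBO parser agrees with readOBO on a written file", {
  ont <- ontologies(workedExampleRepository())[["NCI"]]
  path <- withr::local_tempfile(fileext = ".obo")
  writeOBO(ont, path)
  out <- suppressWarnings(system2("python", c("-c", shQuote(paste0(
    "import obonet; g = obonet.read_obo('", path, "'); ",
    "print(len(g.nodes)); ",
    "print(sorted(g.nodes)); ",
    "print(sorted(d['name'] for _, d in g.nodes(data=True)))"))),
    stdout = TRUE, stderr = FALSE))
  expect_equal(as.integer(out[1]), ontologySize(ont))
  expect_equal(out[2], paste0("['", paste(sort(concepts(ont)$localId),
                                          collapse = "', '"), "']"))
})

test_that("mappings TSV loading indexes resolvable rows and skips the rest", {
  repo <- treatmentRepo()
  repo0 <- ontologyRepository(ontologies(repo))   # strip the mapping
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment",
               "MSH\tC0087111\tSNOMEDCT\tC0087111",
               "MSH\tC0087111\tNOSUCH\tX1"), tsv)
  expect_warning(loaded <- readMappings(tsv, repo0), "1 mapping row")
  expect_equal(nrow(mappings(loaded)), 1L)
  expect_equal(mappingTargets(loaded, "MSH", "C0087111"),
               data.frame(targetOntology = "SNOMEDCT", targetId = "C0087111",
                          stringsAsFactors = FALSE))
  # wrong column count is an error
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("MSH\tC0087111\tSNOMEDCT", bad)
  expect_error(readMappings(bad, repo0), "expected 4")
  # empty file leaves the repository unchanged
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), empty)
  expect_equal(readMappings(empty, repo0), repo0)
})

test_that("mapping index agrees with a linear scan of the mapping table", {
  repo <- generateRepository(fixtureSpec(nOntologies = 8L,
                                         mappingDensity = 0.2, seed = 11L))
  mp <- mappings(repo)
  expect_gt(nrow(mp), 0L)
  for (ont in ontologies(repo)) {
    for (id in concepts(ont)$localId) {
      scan <- mp[mp$sourceOntology == ontologyId(ont) & mp$sourceId == id,
                 c("targetOntology", "targetId"), drop = FALSE]
      rownames(scan) <- NULL
      expect_equal(mappingTargets(repo, ontologyId(ont), id), scan)
    }
  }
})

test_that("repository content does not depend on load order", {
  repo <- workedExampleRepository()
  dir <- withr::local_tempdir()
  writeRepository(repo, dir)
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  man$ontologies <- rev(man$ontologies)
  yaml::write_yaml(man, file.path(dir, "manifest.yaml"))
  reloaded <- loadRepository(file.path(dir, "manifest.yaml"))
  expect_setequal(names(ontologies(reloaded)), names(ontologies(repo)))
  expect_equal(reloaded@mappingIndex, repo@mappingIndex)
  for (id in names(ontologies(repo)))
    expect_equal(concepts(ontologies(reloaded)[[id]]),
                 concepts(ontologies(repo)[[id]]))
})

test_that("validity catches broken ontologies and inconsistent repositories", {
  expect_error(ontology("X", data.frame(localId = c("a", "a"),
                                        preferredName = c("x", "y"))),
               "duplicate")
  expect_error(ontology("X", data.frame(localId = "a", preferredName = "x"),
                        isaEdges = data.frame(child = "a", parent = "zz")),
               "unknown localId")
  repo <- workedExampleRepository()
  broken <- repo
  broken@mappingIndex <- list()
  expect_error(validObject(broken), "forward index")
  selfMap <- data.frame(sourceOntology = "NCI", sourceId = "C0025201",
                        targetOntology = "NCI", targetId = "C0025202",
                        stringsAsFactors = FALSE)
  expect_error(ontologyRepository(ontologies(repo), selfMap),
               "different ontologies")
})

test_that("group-tag filtering keeps only the selected sub-repository", {
  repo <- workedExampleRepository()
  umls <- filterRepository(repo, "umls")
  expect_setequal(names(ontologies(umls)), c("NCI", "FMA"))
  expect_equal(nrow(mappings(umls)), 2L)
  bp <- filterRepository(repo, "bioportal")
  expect_equal(names(ontologies(bp)), "40465")
  expect_equal(nrow(mappings(bp)), 0L)
  expect_error(filterRepository(repo, "nosuch"), "every ontology")
})
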
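#' Recommendation run configuration
#'
#' Bundles the method (`"CR"` = concept recognition only, `"CR_M"` =
#' concept recognition plus mapping expansion), the input scenario, the
#' ranking value and the matching/weighting parameters. Unless
#' `match` is supplied explicitly, `longestOnly` follows the scenario:
#' `TRUE` for keyword inputs (a keyword should be credited as a whole
#' phrase), `FALSE` for corpus inputs.
#'
#' @param method `"CR"` or `"CR_M"`.
#' @param scenario `"corpus"` (free text) or `"keyword"` (one phrase per
#'   line, matched independently).
#' @param outputValue `"score"` or `"normalized"` — the ranking key.
#' @param repositoryFilter group tags to keep (see [groupTag()]);
#'   default keeps every ontology.
#' @param match a [matchConfig()]; default derived from `scenario`.
#' @param weights a [weightTable()].
#' @param topK number of entries kept in the ranking.
#' @return a `RunConfig` list.
#' @export
runConfig <- function(method = c("CR", "CR_M"),
                      scenario = c("corpus", "keyword"),
                      outputValue = c("score", "normalized"),
                      repositoryFilter = c("umls", "bioportal", "other"),
                      match = NULL, weights = weightTable(), topK = 15L) {
  method <- match.arg(method)
  scenario <- match.arg(scenario)
  outputValue <- match.arg(outputValue)
  if (is.null(match))
    match <- matchConfig(longestOnly = scenario == "keyword")
  stopifnot(topK >= 1L)
  structure(list(method = method, scenario = scenario,
                 outputValue = outputValue,
                 repositoryFilter = repositoryFilter,
                 match = match, weights = weights, topK = as.integer(topK)),
            class = "RunConfig")
}

#' Read a run configuration file
#'
#' Accepts either YAML or flat `key = value` lines using the annotation
#' service's parameter names: `longestOnly`, `withDefaultStopWords`,
#' `minTermSize`, `activateMapping` (true selects the CR+M method),
#' plus optional `scenario`, `outputValue`, `topK` and weight overrides
#' `preferred`, `synonym`, `mapped`, `ancestor_a`, `ancestor_b`,
#' `ancestor_k`.
#'
#' @param path path to the configuration file.
#' @return a [runConfig()].
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vals <- tryCatch(yaml::read_yaml(path), error = function(e) NULL)
  if (!is.list(vals)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[grepl("=", lines, fixed = TRUE)]
    kv <- strsplit(lines, "=", fixed = TRUE)
    coerce <- function(v) {
      if (tolower(v) %in% c("true", "false")) return(tolower(v) == "true")
      utils::type.convert(v, as.is = TRUE)
    }
    vals <- stats::setNames(lapply(kv, function(x) coerce(trimws(x[2]))),
                            trimws(vapply(kv, `[`, "", 1)))
  }
  pick <- function(key, default) if (is.null(vals[[key]])) default else vals[[key]]
  scenario <- pick("scenario", "corpus")
  wt <- weightTable(preferred = pick("preferred", 10), synonym = pick("synonym", 8),
                    mapped = pick("mapped", 7), ancestorA = pick("ancestor_a", 1),
                    ancestorB = pick("ancestor_b", 10), ancestorK = pick("ancestor_k", 0.2))
  mc <- matchConfig(
    longestOnly = pick("longestOnly", scenario == "keyword"),
    minTermSize = pick("minTermSize", 3L),
    useDefaultStopwords = pick("withDefaultStopWords", TRUE))
  runConfig(method = if (isTRUE(pick("activateMapping", FALSE))) "CR_M" else "CR",
            scenario = scenario, outputValue = pick("outputValue", "score"),
            match = mc, weights = wt, topK = pick("topK", 15L))
}

#' Recommend ontologies for a text or keyword list
#'
#' The full pipeline: compile the dictionary from the (filtered)
#' repository, recognize direct annotations (whole text for the corpus
#' scenario; each non-empty line independently for the keyword
#' scenario), expand through mappings when the method is CR+M, weight
#' every annotation by its context, aggregate per ontology, and rank by
#' the selected output value (descending; ties broken by ascending
#' ontology id and sharing the smaller rank).
#'
#' @param inputText the corpus text or newline-separated keywords.
#' @param repo an [OntologyRepository].
#' @param config a [runConfig()].
#' @return an [OntologyRanking]. If nothing in the input matches the
#'   dictionary, a warning is raised and the ranking is empty.
#' @examples
#' repo <- workedExampleRepository()
#' recommend("Melanoma is a malignant tumor of melanocytes.", repo,
#'           runConfig(method = "CR_M"))
#' @export
recommend <- function(inputText, repo, config = runConfig()) {
  if (!is.character(inputText) || length(inputText) != 1L ||
      !nzchar(trimws(inputText)))
    stop("input is empty")
  if (!length(ontologies(repo))) stop("repository is empty")
  if (!setequal(config$repositoryFilter, c("umls", "bioportal", "other")))
    repo <- filterRepository(repo, config$repositoryFilter)
  dict <- compileDictionary(repo, config$match)
  if (config$scenario == "keyword") {
    lines <- strsplit(inputText, "\n", fixed = TRUE)[[1]]
    keep <- which(nzchar(trimws(lines)))
    pieces <- lapply(keep, function(i)
      recognize(lines[i], dict, config$match, line = i))
    direct <- if (length(pieces)) do.call(rbind, pieces) else annotationFrame()
  } else {
    direct <- recognize(inputText, dict, config$match)
  }
  ann <- direct
  if (config$method == "CR_M")
    ann <- rbind(ann, expandMappings(direct, repo))
  ann <- addWeights(ann, config$weights)
  scores <- aggregateScores(ann, repo)
  if (nrow(scores) == 0L)
    warning("no annotations found; returning an empty ranking")
  key <- if (config$outputValue == "score") scores$score else scores$normalizedScore
  ord <- order(-key, scores$ontologyId)
  scores <- scores[ord, , drop = FALSE]
  key <- key[ord]
  # ties share the smaller (best) rank
  scores$rank <- if (nrow(scores)) match(key, key) else integer()
  scores <- utils::head(scores, config$topK)
  rownames(scores) <- NULL
  new("OntologyRanking", entries = scores, outputValue = config$outputValue,
      configEcho = list(method = config$method, scenario = config$scenario,
                        outputValue = config$outputValue,
                        longestOnly = config$match$longestOnly,
                        minTermSize = config$match$minTermSize,
                        topK = config$topK))
}

#' @rdname OntologyRanking-class
#' @export
setMethod("rankingEntries", "OntologyRanking", function(x) x@entries)
#' @rdname OntologyRanking-class
#' @export
setMethod("outputValue", "OntologyRanking", function(x) x@outputValue)

setMethod("show", "OntologyRanking", function(object) {
  cat("OntologyRanking (", nrow(object@entries), " ontologies, by ",
      object@outputValue, ")\n", sep = "")
  if (nrow(object@entries)) cat(renderRanking(object, "text"), "\n")
})

#' Render a ranking as text, XML, JSON or tag-cloud weights
#'
#' * `text`: an aligned, human-readable table.
#' * `xml`: one `<ontology>` element per entry in rank order, with child
#'   elements `score`, `normalizedScore`, `rank`, `annotations`.
#' * `json`: a schema-versioned object that round-trips through
#'   [parseRankingJSON()] without loss.
#' * `cloud`: `displayName<TAB>fontWeight` lines, the font weight
#'   scaled linearly to \[1, 10\] between the smallest and largest
#'   selected value (all-equal case: every weight is 10).
#'
#' Normalized scores are printed at 4 decimal places in the text, xml
#' and cloud renderings; the json rendering keeps full precision so the
#' round-trip is exact.
#'
#' @param ranking an [OntologyRanking].
#' @param format `"text"`, `"xml"`, `"json"` or `"cloud"`.
#' @return a single string.
#' @export
renderRanking <- function(ranking, format = c("text", "xml", "json", "cloud")) {
  if (!is.character(format) || length(format) != 1L ||
      !format %in% c("text", "xml", "json", "cloud"))
    stop("unknown format: ", paste(format, collapse = ", "))
  e <- rankingEntries(ranking)
  switch(format,
    text = {
      tab <- data.frame(rank = e$rank, ontology = e$ontologyId,
                        name = e$displayName, score = e$score,
                        normalized = sprintf("%.4f", e$normalizedScore),
                        annotations = e$annotationCount)
      paste(utils::capture.output(print(tab, row.names = FALSE)), collapse = "\n")
    },
    xml = {
      doc <- xml2::xml_new_root("ranking")
      xml2::xml_set_attr(doc, "value", outputValue(ranking))
      for (i in seq_len(nrow(e))) {
        node <- xml2::xml_add_child(doc, "ontology", id = e$ontologyId[i],
                                    name = e$displayName[i])
        xml2::xml_add_child(node, "score", format(e$score[i]))
        xml2::xml_add_child(node, "normalizedScore", sprintf("%.4f", e$normalizedScore[i]))
        xml2::xml_add_child(node, "rank", as.character(e$rank[i]))
        xml2::xml_add_child(node, "annotations", as.character(e$annotationCount[i]))
      }
      as.character(doc)
    },
    json = {
      obj <- list(schema = "ontology-ranking/1", outputValue = outputValue(ranking),
                  config = ranking@configEcho, entries = e)
      jsonlite::toJSON(obj, dataframe = "columns", auto_unbox = TRUE, digits = NA)
    },
    cloud = {
      if (nrow(e) == 0L) return("")
      v <- if (outputValue(ranking) == "score") e$score else e$normalizedScore
      fw <- if (max(v) == min(v)) rep(10, length(v)) else
        1 + 9 * (v - min(v)) / (max(v) - min(v))
      paste(sprintf("%s\t%.4f", e$displayName, fw), collapse = "\n")
    })
}

#' Reconstruct a ranking from its JSON rendering
#'
#' @param json string produced by `renderRanking(x, "json")`.
#' @return an [OntologyRanking] equal to the one rendered.
#' @export
parseRankingJSON <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  if (!identical(obj$schema, "ontology-ranking/1"))
    stop("not an ontology-ranking/1 document")
  e <- as.data.frame(obj$entries, stringsAsFactors = FALSE)
  if (nrow(e) == 0L)
    e <- data.frame(ontologyId = character(), displayName = character(),
                    score = numeric(), normalizedScore = numeric(),
                    annotationCount = integer(), rank = integer(),
                    stringsAsFactors = FALSE)
  e$annotationCount <- as.integer(e$annotationCount)
  e$rank <- as.integer(e$rank)
  e$score <- as.numeric(e$score)
  e$normalizedScore <- as.numeric(e$normalizedScore)
  new("OntologyRanking", entries = e, outputValue = obj$outputValue,
      configEcho = obj$config)
}
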
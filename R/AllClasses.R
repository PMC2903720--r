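#' @import methods
NULL

## Central containers. Concepts live inside an Ontology as a data.frame with a
## list-column of synonyms; annotations are plain data.frames (see
## annotationFrame()) so that the matching/expansion/scoring pipeline composes
## with ordinary data-frame tooling.

#' Ontology: a named collection of concepts plus an is_a hierarchy
#'
#' A single ontology as the recommender sees it: an identifier, a display
#' name, one row per concept (local id, preferred name, synonyms), the
#' is_a edges between local ids, and a repository group tag used to
#' restrict runs to a sub-repository (e.g. UMLS-derived vs community
#' ontologies).
#'
#' @slot ontologyId single string, unique within a repository.
#' @slot displayName human-readable name.
#' @slot concepts data.frame with columns `localId` (character, unique),
#'   `preferredName` (character, non-empty) and `synonyms` (list of
#'   character vectors, possibly empty; never containing the preferred
#'   name case-insensitively).
#' @slot isaEdges data.frame with columns `child`, `parent` (local ids);
#'   the graph must be acyclic.
#' @slot groupTag one of `"umls"`, `"bioportal"`, `"other"`.
#'
#' @seealso [ontology()], [readOBO()], [ontologySize()]
#' @export
setClass("Ontology",
  representation(
    ontologyId = "character",
    displayName = "character",
    concepts = "data.frame",
    isaEdges = "data.frame",
    groupTag = "character"
  )
)

setValidity("Ontology", function(object) {
  msg <- character()
  if (length(object@ontologyId) != 1L || !nzchar(object@ontologyId))
    msg <- c(msg, "ontologyId must be a single non-empty string")
  cc <- object@concepts
  if (!all(c("localId", "preferredName", "synonyms") %in% names(cc)))
    msg <- c(msg, "concepts needs columns localId, preferredName, synonyms")
  else {
    if (nrow(cc) < 1L)
      msg <- c(msg, "an ontology must contain at least one concept")
    if (anyDuplicated(cc$localId))
      msg <- c(msg, "duplicate concept localId")
    if (any(!nzchar(trimws(cc$preferredName))))
      msg <- c(msg, "empty preferredName")
    if (!is.list(cc$synonyms))
      msg <- c(msg, "synonyms must be a list column")
    else {
      clash <- mapply(function(p, s) any(tolower(s) == tolower(p)),
                      cc$preferredName, cc$synonyms)
      if (any(unlist(clash)))
        msg <- c(msg, "a synonym duplicates its preferred name")
    }
  }
  ee <- object@isaEdges
  if (!all(c("child", "parent") %in% names(ee)))
    msg <- c(msg, "isaEdges needs columns child, parent")
  else if (all(c("localId") %in% names(cc))) {
    unknown <- setdiff(c(ee$child, ee$parent), cc$localId)
    if (length(unknown))
      msg <- c(msg, paste0("isaEdges reference unknown localId: ",
                           paste(unknown, collapse = ", ")))
    else if (nrow(ee) && .hasCycle(ee))
      msg <- c(msg, "is_a graph contains a cycle")
  }
  if (!(length(object@groupTag) == 1L &&
        object@groupTag %in% c("umls", "bioportal", "other")))
    msg <- c(msg, "groupTag must be one of umls, bioportal, other")
  if (length(msg)) msg else TRUE
})

#' OntologyRepository: ontologies plus cross-ontology mappings
#'
#' The loaded repository the recommender runs against: a named list of
#' [Ontology] objects, a table of directed point-to-point mappings
#' between concepts of different ontologies, and a forward index from
#' `(ontologyId, localId)` to mapping rows for constant-time expansion.
#'
#' @slot ontologies named list of [Ontology]; names equal the ontology ids.
#' @slot mappings data.frame with columns `sourceOntology`, `sourceId`,
#'   `targetOntology`, `targetId`; one row is one directed mapping.
#' @slot mappingIndex named list: key `"<ontologyId>\t<localId>"`, value
#'   integer row indices into `mappings`.
#'
#' @seealso [ontologyRepository()], [readMappings()], [recommend()]
#' @export
setClass("OntologyRepository",
  representation(
    ontologies = "list",
    mappings = "data.frame",
    mappingIndex = "list"
  )
)

setValidity("OntologyRepository", function(object) {
  msg <- character()
  ids <- vapply(object@ontologies, function(o) o@ontologyId, character(1))
  if (length(ids) && !identical(unname(names(object@ontologies)), unname(ids)))
    msg <- c(msg, "ontologies list names must equal the ontology ids")
  if (anyDuplicated(ids))
    msg <- c(msg, "duplicate ontology id in repository")
  mp <- object@mappings
  need <- c("sourceOntology", "sourceId", "targetOntology", "targetId")
  if (!all(need %in% names(mp)))
    msg <- c(msg, "mappings needs columns sourceOntology, sourceId, targetOntology, targetId")
  else if (nrow(mp)) {
    if (any(mp$sourceOntology == mp$targetOntology))
      msg <- c(msg, "a mapping must link two different ontologies")
    ok <- function(ont, id) {
      ont %in% ids &&
        id %in% object@ontologies[[ont]]@concepts$localId
    }
    bad <- !mapply(ok, mp$sourceOntology, mp$sourceId) |
           !mapply(ok, mp$targetOntology, mp$targetId)
    if (any(bad))
      msg <- c(msg, "mapping endpoint does not resolve to a loaded concept")
  }
  # index must be exactly the forward index of mappings
  if (!identical(object@mappingIndex, .buildMappingIndex(mp)))
    msg <- c(msg, "mappingIndex is not the forward index of mappings")
  if (length(msg)) msg else TRUE
})

#' OntologyRanking: an ordered per-ontology recommendation
#'
#' The result of [recommend()]: one row per ontology that received at
#' least one annotation, ordered by the selected output value (raw score
#' or size-normalized score), plus an echo of the run configuration.
#'
#' @slot entries data.frame with columns `ontologyId`, `displayName`,
#'   `score`, `normalizedScore`, `annotationCount`, `rank`; ordered by
#'   the selected value descending, ties broken by ontology id, tied
#'   values sharing the smaller rank.
#' @slot outputValue `"score"` or `"normalized"` (the ordering key).
#' @slot configEcho list digest of the [runConfig()] used.
#'
#' @seealso [recommend()], [renderRanking()], [rankingEntries()]
#' @export
setClass("OntologyRanking",
  representation(
    entries = "data.frame",
    outputValue = "character",
    configEcho = "list"
  )
)

setValidity("OntologyRanking", function(object) {
  msg <- character()
  need <- c("ontologyId", "displayName", "score", "normalizedScore",
            "annotationCount", "rank")
  if (!all(need %in% names(object@entries)))
    msg <- c(msg, paste("entries needs columns:", paste(need, collapse = ", ")))
  if (!(length(object@outputValue) == 1L &&
        object@outputValue %in% c("score", "normalized")))
    msg <- c(msg, "outputValue must be 'score' or 'normalized'")
  if (length(msg)) msg else TRUE
})
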
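#' Construct an Ontology
#'
#' @param ontologyId single string identifying the ontology.
#' @param concepts data.frame with columns `localId`, `preferredName` and
#'   optionally `synonyms` (a list of character vectors). Synonyms equal to
#'   the preferred name (case-insensitively) are dropped, and duplicate
#'   synonyms are de-duplicated.
#' @param isaEdges data.frame with columns `child`, `parent` (local ids),
#'   or `NULL` for a flat ontology.
#' @param displayName human-readable name; defaults to `ontologyId`.
#' @param groupTag repository group: `"umls"`, `"bioportal"` or `"other"`.
#' @return a validated [Ontology].
#' @examples
#' ont <- ontology("TOY", data.frame(localId = "T1", preferredName = "melanoma"))
#' ontologySize(ont)
#' @export
ontology <- function(ontologyId, concepts, isaEdges = NULL,
                     displayName = ontologyId, groupTag = "other") {
  if (is.null(concepts$synonyms)) concepts$synonyms <- replicate(nrow(concepts), character(), simplify = FALSE)
  concepts$preferredName <- trimws(concepts$preferredName)
  concepts$synonyms <- mapply(function(p, s) {
    s <- trimws(s)
    s <- s[nzchar(s)]
    s <- s[!duplicated(tolower(s))]
    s[tolower(s) != tolower(p)]
  }, concepts$preferredName, concepts$synonyms, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  if (is.null(isaEdges))
    isaEdges <- data.frame(child = character(), parent = character(),
                           stringsAsFactors = FALSE)
  new("Ontology", ontologyId = ontologyId, displayName = displayName,
      concepts = .conceptFrame(concepts$localId, concepts$preferredName,
                               concepts$synonyms),
      isaEdges = isaEdges[, c("child", "parent"), drop = FALSE],
      groupTag = groupTag)
}

#' @rdname Ontology-class
#' @export
setMethod("ontologyId", "Ontology", function(x) x@ontologyId)
#' @rdname Ontology-class
#' @export
setMethod("displayName", "Ontology", function(x) x@displayName)
#' @rdname Ontology-class
#' @export
setMethod("concepts", "Ontology", function(x) x@concepts)
#' @rdname Ontology-class
#' @export
setMethod("isaEdges", "Ontology", function(x) x@isaEdges)
#' @rdname Ontology-class
#' @export
setMethod("groupTag", "Ontology", function(x) x@groupTag)
#' @rdname ontologySize
#' @export
setMethod("ontologySize", "Ontology", function(x) nrow(x@concepts))

setMethod("show", "Ontology", function(object) {
  cat("Ontology '", object@ontologyId, "' (", object@displayName, ")\n",
      "  concepts: ", nrow(object@concepts),
      ", is_a edges: ", nrow(object@isaEdges),
      ", group: ", object@groupTag, "\n", sep = "")
})

#' Construct an OntologyRepository
#'
#' Bundles ontologies and directed cross-ontology mappings; the forward
#' mapping index is (re)built here, so the index is always consistent with
#' the mapping table.
#'
#' @param ontologies list of [Ontology] objects.
#' @param mappings data.frame with columns `sourceOntology`, `sourceId`,
#'   `targetOntology`, `targetId`, or `NULL` for none.
#' @return a validated [OntologyRepository].
#' @seealso [readMappings()] to append mappings from a TSV file.
#' @export
ontologyRepository <- function(ontologies, mappings = NULL) {
  ids <- vapply(ontologies, ontologyId, character(1))
  names(ontologies) <- ids
  if (is.null(mappings)) mappings <- .emptyMappings()
  rownames(mappings) <- NULL
  new("OntologyRepository", ontologies = ontologies, mappings = mappings,
      mappingIndex = .buildMappingIndex(mappings))
}

#' @rdname OntologyRepository-class
#' @export
setMethod("ontologies", "OntologyRepository", function(x) x@ontologies)
#' @rdname OntologyRepository-class
#' @export
setMethod("mappings", "OntologyRepository", function(x) x@mappings)

setMethod("show", "OntologyRepository", function(object) {
  sizes <- vapply(object@ontologies, ontologySize, integer(1))
  cat("OntologyRepository with ", length(object@ontologies), " ontologies (",
      sum(sizes), " concepts) and ", nrow(object@mappings), " mappings\n",
      sep = "")
  if (length(object@ontologies)) {
    head <- utils::head(names(object@ontologies), 6L)
    cat("  ", paste(head, collapse = ", "),
        if (length(object@ontologies) > 6L) ", ..." else "", "\n", sep = "")
  }
})

#' Mapping targets of a concept
#'
#' Looks up the directed mappings leaving `(ontologyId, localId)` through
#' the repository's forward index.
#'
#' @param repo an [OntologyRepository].
#' @param ontologyId,localId the source concept.
#' @return a data.frame with columns `targetOntology`, `targetId`
#'   (zero rows if the concept maps nowhere).
#' @export
mappingTargets <- function(repo, ontologyId, localId) {
  rows <- repo@mappingIndex[[.mappingKey(ontologyId, localId)]]
  if (is.null(rows))
    return(data.frame(targetOntology = character(), targetId = character(),
                      stringsAsFactors = FALSE))
  out <- repo@mappings[rows, c("targetOntology", "targetId"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict a repository to group tags
#'
#' Keeps only ontologies whose [groupTag()] is in `tags`; mappings with an
#' endpoint in a dropped ontology are removed and the index rebuilt.
#'
#' @param repo an [OntologyRepository].
#' @param tags character vector of group tags to keep.
#' @return a filtered [OntologyRepository].
#' @export
filterRepository <- function(repo, tags) {
  keep <- vapply(repo@ontologies, function(o) o@groupTag %in% tags, logical(1))
  onts <- repo@ontologies[keep]
  if (!length(onts))
    stop("repository filter removed every ontology")
  ids <- names(onts)
  mp <- repo@mappings
  mp <- mp[mp$sourceOntology %in% ids & mp$targetOntology %in% ids, , drop = FALSE]
  ontologyRepository(onts, mp)
}
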
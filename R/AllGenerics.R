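#' @rdname Ontology-class
#' @param object,x an object.
#' @export
setGeneric("ontologyId", function(x) standardGeneric("ontologyId"))

#' @rdname Ontology-class
#' @export
setGeneric("displayName", function(x) standardGeneric("displayName"))

#' @rdname Ontology-class
#' @export
setGeneric("concepts", function(x) standardGeneric("concepts"))

#' @rdname Ontology-class
#' @export
setGeneric("isaEdges", function(x) standardGeneric("isaEdges"))

#' @rdname Ontology-class
#' @export
setGeneric("groupTag", function(x) standardGeneric("groupTag"))

#' Number of concepts in an ontology
#'
#' The ontology size used by the normalized score: the number of concepts
#' (not the number of terms; synonyms do not count).
#'
#' @param x an [Ontology].
#' @return a positive integer.
#' @examples
#' repo <- workedExampleRepository()
#' ontologySize(ontologies(repo)[["NCI"]])  # 4
#' @export
setGeneric("ontologySize", function(x) standardGeneric("ontologySize"))

#' @rdname OntologyRepository-class
#' @param x an object.
#' @export
setGeneric("ontologies", function(x) standardGeneric("ontologies"))

#' @rdname OntologyRepository-class
#' @export
setGeneric("mappings", function(x) standardGeneric("mappings"))

#' @rdname OntologyRanking-class
#' @param x an object.
#' @export
setGeneric("rankingEntries", function(x) standardGeneric("rankingEntries"))

#' @rdname OntologyRanking-class
#' @export
setGeneric("outputValue", function(x) standardGeneric("outputValue"))
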
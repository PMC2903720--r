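#' Annotation context weights
#'
#' The weight table used by the scoring step. Defaults: a direct
#' annotation matched on a concept's preferred name weighs 10, on a
#' synonym 8, a mapping expansion 7, and an ancestor expansion at level n
#' weighs `floor(a + b * exp(-k * n))` with a = 1, b = 10, k = 0.2 —
#' i.e. 9 at n = 1, 7 at n = 2, 4 at n = 5, 3 at n = 8 and 1 for
#' n > 12. The floor is applied per annotation, before summation.
#'
#' @param preferred,synonym,mapped weights for the three flat contexts.
#' @param ancestorA,ancestorB,ancestorK parameters of the exponential
#'   ancestor decay.
#' @return a `WeightTable` list.
#' @export
weightTable <- function(preferred = 10, synonym = 8, mapped = 7,
                        ancestorA = 1, ancestorB = 10, ancestorK = 0.2) {
  w <- list(preferred = preferred, synonym = synonym, mapped = mapped,
            ancestorA = ancestorA, ancestorB = ancestorB, ancestorK = ancestorK)
  if (any(unlist(w[c("preferred", "synonym", "mapped")]) <= 0))
    stop("context weights must be positive")
  structure(w, class = "WeightTable")
}

#' Weight of a single annotation context
#'
#' @param context one of `"direct_preferred"`, `"direct_synonym"`,
#'   `"mapped"`, `"ancestor"` (vectorized).
#' @param ancestorLevel integer level n >= 1; required (and used) only
#'   where `context == "ancestor"`.
#' @param table a [weightTable()].
#' @return numeric weights, one per context.
#' @examples
#' annotationWeight("direct_preferred")      # 10
#' annotationWeight("ancestor", 5)           # 4
#' @export
annotationWeight <- function(context, ancestorLevel = NA_integer_,
                             table = weightTable()) {
  if (length(ancestorLevel) == 1L)
    ancestorLevel <- rep(ancestorLevel, length(context))
  stopifnot(length(ancestorLevel) == length(context))
  isAnc <- context == "ancestor"
  if (any(isAnc & (is.na(ancestorLevel) | ancestorLevel < 1)))
    stop("ancestor context requires ancestorLevel >= 1")
  w <- numeric(length(context))
  w[context == "direct_preferred"] <- table$preferred
  w[context == "direct_synonym"] <- table$synonym
  w[context == "mapped"] <- table$mapped
  w[isAnc] <- floor(table$ancestorA +
                    table$ancestorB * exp(-table$ancestorK * ancestorLevel[isAnc]))
  unknown <- !context %in% c("direct_preferred", "direct_synonym", "mapped", "ancestor")
  if (any(unknown)) stop("unknown annotation context: ", context[unknown][1])
  w
}

#' Attach weights to an annotation table
#'
#' @param annotations annotation data.frame (direct and/or expanded).
#' @param table a [weightTable()].
#' @return the annotations with a numeric `weight` column appended.
#' @export
addWeights <- function(annotations, table = weightTable()) {
  annotations$weight <- if (nrow(annotations) == 0L) numeric() else
    annotationWeight(annotations$context, annotations$ancestorLevel, table)
  annotations
}

#' Aggregate annotation weights per ontology
#'
#' Sums the weights of each ontology's annotations into a raw score and
#' divides by the ontology size (concept count) for the normalized
#' score. Ontologies with no annotation are omitted.
#'
#' @param annotations a weighted annotation data.frame ([addWeights()]).
#' @param repo the [OntologyRepository] the annotations refer to.
#' @return a data.frame with columns `ontologyId`, `displayName`,
#'   `score`, `normalizedScore`, `annotationCount`, one row per
#'   annotated ontology, in ontology-id order.
#' @export
aggregateScores <- function(annotations, repo) {
  empty <- data.frame(ontologyId = character(), displayName = character(),
                      score = numeric(), normalizedScore = numeric(),
                      annotationCount = integer(), stringsAsFactors = FALSE)
  if (nrow(annotations) == 0L) return(empty)
  if (is.null(annotations$weight))
    stop("annotations carry no weights; call addWeights() first")
  unknown <- setdiff(unique(annotations$ontologyId), names(ontologies(repo)))
  if (length(unknown))
    stop("annotation references ontology not in repository: ", unknown[1])
  score <- tapply(annotations$weight, annotations$ontologyId, sum)
  count <- tapply(annotations$weight, annotations$ontologyId, length)
  ids <- sort(names(score))
  sizes <- vapply(ontologies(repo)[ids], ontologySize, integer(1))
  disp <- vapply(ontologies(repo)[ids], displayName, character(1))
  data.frame(ontologyId = ids, displayName = unname(disp),
             score = unname(as.numeric(score[ids])),
             normalizedScore = unname(as.numeric(score[ids]) / sizes),
             annotationCount = unname(as.integer(count[ids])),
             stringsAsFactors = FALSE)
}
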
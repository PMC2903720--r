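# internal helpers shared across modules

# cycle test on an edge list (child -> parent) by iterative leaf pruning;
# avoids recursion so deep chains are safe
.hasCycle <- function(edges) {
  ch <- edges$child
  pa <- edges$parent
  repeat {
    nodes <- unique(c(ch, pa))
    if (!length(nodes)) return(FALSE)
    # nodes that are never a parent can be removed together with their edges
    leaves <- setdiff(nodes, pa)
    if (!length(leaves)) return(TRUE)
    keep <- !(ch %in% leaves)
    if (!any(keep)) return(FALSE)
    ch <- ch[keep]
    pa <- pa[keep]
  }
}

.mappingKey <- function(ontologyId, localId) paste(ontologyId, localId, sep = "\t")

# forward index: key "<ont>\t<id>" -> integer row numbers into the mapping table
.buildMappingIndex <- function(mappings) {
  if (is.null(mappings) || nrow(mappings) == 0L) return(structure(list(), names = character()))
  keys <- .mappingKey(mappings$sourceOntology, mappings$sourceId)
  idx <- split(seq_len(nrow(mappings)), keys)
  idx[order(names(idx))]
}

.emptyMappings <- function() {
  data.frame(sourceOntology = character(), sourceId = character(),
             targetOntology = character(), targetId = character(),
             stringsAsFactors = FALSE)
}

.conceptFrame <- function(localId = character(), preferredName = character(),
                          synonyms = list()) {
  data.frame(localId = localId, preferredName = preferredName,
             synonyms = I(as.list(synonyms)), stringsAsFactors = FALSE)
}

#' Empty annotation table
#'
#' Annotations flow through the pipeline as a data.frame with one row per
#' annotation. Columns: `ontologyId`, `localId` (the annotated concept),
#' `start`, `end` (0-based half-open character offsets into the input
#' phrase), `line` (1-based input line, for keyword inputs), `surface`
#' (the matched slice of the input), `context` (one of
#' `"direct_preferred"`, `"direct_synonym"`, `"mapped"`, `"ancestor"`)
#' and `ancestorLevel` (`NA` unless `context == "ancestor"`).
#'
#' @return a zero-row annotation data.frame with the pipeline's columns.
#' @export
annotationFrame <- function() {
  data.frame(ontologyId = character(), localId = character(),
             start = integer(), end = integer(), line = integer(),
             surface = character(), context = character(),
             ancestorLevel = integer(), stringsAsFactors = FALSE)
}

.sortAnnotations <- function(ann) {
  if (nrow(ann) == 0L) return(ann)
  ord <- order(ann$line, ann$start, ann$end, ann$ontologyId, ann$localId)
  rownames(ann) <- NULL
  ann <- ann[ord, , drop = FALSE]
  rownames(ann) <- NULL
  ann
}
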
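#' Expand direct annotations through cross-ontology mappings
#'
#' For each direct annotation on concept c and each directed mapping
#' c -> c', emits one expanded annotation on c' with the seed's span and
#' context `"mapped"`. Expansion is single-hop: mappings of mapped
#' concepts are not followed, and mapped annotations never re-seed is_a
#' expansion. A mapped expansion is not emitted when the same
#' (concept, span) already exists among the direct annotations — the
#' direct annotation carries the higher weight — and identical
#' expansions are emitted once.
#'
#' @param direct annotation data.frame from [recognize()].
#' @param repo an [OntologyRepository] with its mapping index built.
#' @return an annotation data.frame of `"mapped"` expansions only
#'   (possibly zero rows); combine with the direct annotations before
#'   scoring.
#' @examples
#' repo <- workedExampleRepository()
#' d <- recognize("melanocytes", compileDictionary(repo), matchConfig())
#' expandMappings(d, repo)  # the FMA melanocyte expansion
#' @export
expandMappings <- function(direct, repo) {
  out <- annotationFrame()
  if (nrow(direct) == 0L || nrow(mappings(repo)) == 0L) return(out)
  rows <- list()
  for (i in seq_len(nrow(direct))) {
    tg <- mappingTargets(repo, direct$ontologyId[i], direct$localId[i])
    if (!nrow(tg)) next
    rows[[length(rows) + 1L]] <- data.frame(
      ontologyId = tg$targetOntology, localId = tg$targetId,
      start = direct$start[i], end = direct$end[i], line = direct$line[i],
      surface = direct$surface[i], context = "mapped",
      ancestorLevel = NA_integer_, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(out)
  exp <- do.call(rbind, rows)
  key <- function(a) paste(a$ontologyId, a$localId, a$line, a$start, a$end, sep = "\r")
  exp <- exp[!duplicated(key(exp)) & !(key(exp) %in% key(direct)), , drop = FALSE]
  .sortAnnotations(exp)
}

#' Expand direct annotations through the is_a hierarchy
#'
#' For each direct annotation, emits one expanded annotation per distinct
#' ancestor of the annotated concept within `maxLevel` is_a edges, in the
#' same ontology, with `ancestorLevel` set to the minimal edge distance
#' (breadth-first). Each (ancestor, span) is emitted at most once per
#' input. This expansion is available for annotation workflows but is off
#' by default in recommendation runs, where only mapping expansion feeds
#' the ranking.
#'
#' @param direct annotation data.frame from [recognize()].
#' @param repo an [OntologyRepository].
#' @param maxLevel maximum ancestor distance, or `Inf` for the full
#'   transitive closure.
#' @return an annotation data.frame of `"ancestor"` expansions.
#' @export
expandIsa <- function(direct, repo, maxLevel = Inf) {
  out <- annotationFrame()
  if (nrow(direct) == 0L) return(out)
  rows <- list()
  for (i in seq_len(nrow(direct))) {
    ont <- ontologies(repo)[[direct$ontologyId[i]]]
    anc <- .ancestorLevels(isaEdges(ont), direct$localId[i], maxLevel)
    if (!nrow(anc)) next
    rows[[length(rows) + 1L]] <- data.frame(
      ontologyId = direct$ontologyId[i], localId = anc$localId,
      start = direct$start[i], end = direct$end[i], line = direct$line[i],
      surface = direct$surface[i], context = "ancestor",
      ancestorLevel = anc$level, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(out)
  exp <- do.call(rbind, rows)
  key <- paste(exp$ontologyId, exp$localId, exp$line, exp$start, exp$end, sep = "\r")
  # same (ancestor, span) reachable from several seeds: keep the minimal level
  ord <- order(key, exp$ancestorLevel)
  exp <- exp[ord, , drop = FALSE]
  exp <- exp[!duplicated(key[ord]), , drop = FALSE]
  .sortAnnotations(exp)
}

# breadth-first levels over child->parent edges; returns minimal edge
# distance per reachable ancestor
.ancestorLevels <- function(edges, localId, maxLevel) {
  level <- integer(); names(level) <- character()
  frontier <- localId
  n <- 0L
  seen <- localId
  while (length(frontier) && n < maxLevel) {
    n <- n + 1L
    parents <- unique(edges$parent[edges$child %in% frontier])
    parents <- setdiff(parents, seen)
    if (!length(parents)) break
    level[parents] <- n
    seen <- c(seen, parents)
    frontier <- parents
  }
  data.frame(localId = names(level), level = unname(level),
             stringsAsFactors = FALSE)
}
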
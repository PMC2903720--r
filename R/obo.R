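#' Read an OBO 1.2 flat file (subset) into an Ontology
#'
#' Parses the subset of OBO that the recommender needs: the header is
#' skipped, each `[Term]` stanza contributes one concept via its `id:`,
#' `name:`, `synonym:` and `is_a:` lines, and stanzas with
#' `is_obsolete: true` are dropped (including their is_a edges). Synonym
#' scope qualifiers (EXACT, BROAD, ...) and trailing xref lists are
#' ignored; only the quoted synonym text is kept. Any other tag, and any
#' non-`[Term]` stanza (e.g. `[Typedef]`), is ignored silently.
#'
#' @param path path to the OBO file.
#' @param ontologyId identifier to assign to the loaded ontology.
#' @param displayName human-readable name; defaults to `ontologyId`.
#' @param groupTag `"umls"`, `"bioportal"` or `"other"`.
#' @return an [Ontology].
#' @section Errors: malformed stanzas (missing `id:` or `name:`),
#'   duplicate term ids and is_a cycles are errors; messages carry the
#'   line number of the offending stanza.
#' @seealso [writeOBO()] for the inverse.
#' @export
readOBO <- function(path, ontologyId, displayName = ontologyId,
                    groupTag = "other") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  # strip OBO trailing comments (unescaped "!")
  lines <- sub("[[:space:]]*!.*$", "", lines)

  starts <- grep("^\\[", lines)
  termStarts <- which(lines == "[Term]")
  ids <- character(); names_ <- character(); syns <- list()
  children <- character(); parents <- character()
  for (s in termStarts) {
    nxt <- starts[starts > s]
    e <- if (length(nxt)) min(nxt) - 1L else length(lines)
    block <- lines[(s + 1L):e]
    tag <- sub(":.*$", "", block)
    val <- trimws(sub("^[^:]*:", "", block))
    id <- val[tag == "id"]
    nm <- val[tag == "name"]
    if (length(id) != 1L || !nzchar(id))
      stop("OBO parse error at line ", s, ": [Term] stanza without a single id:")
    if (any(tag == "is_obsolete") && tolower(val[tag == "is_obsolete"][1]) == "true")
      next
    if (length(nm) != 1L || !nzchar(nm))
      stop("OBO parse error at line ", s, ": term '", id, "' lacks a name:")
    if (id %in% ids)
      stop("OBO parse error at line ", s, ": duplicate term id '", id, "'")
    sv <- val[tag == "synonym"]
    stext <- character()
    if (length(sv)) {
      m <- regexpr('^"(\\\\.|[^"\\\\])*"', sv)
      if (any(m == -1L))
        stop("OBO parse error at line ", s, ": unquoted synonym in term '", id, "'")
      mt <- regmatches(sv, m)
      stext <- gsub('\\\\(.)', "\\1", substr(mt, 2L, nchar(mt) - 1L))
    }
    pv <- val[tag == "is_a"]
    ids <- c(ids, id); names_ <- c(names_, nm); syns <- c(syns, list(stext))
    if (length(pv)) {
      children <- c(children, rep(id, length(pv)))
      parents <- c(parents, pv)
    }
  }
  if (!length(ids)) stop("OBO parse error: no non-obsolete [Term] stanza in ", path)
  edges <- data.frame(child = children, parent = parents, stringsAsFactors = FALSE)
  # drop edges pointing at obsolete/unknown parents only if they point at a
  # term that was present but obsolete; unknown ids remain an error (validity)
  edges <- edges[edges$parent %in% ids | !.knownElsewhere(edges$parent, lines), , drop = FALSE]
  ontology(ontologyId,
           data.frame(localId = ids, preferredName = names_,
                      synonyms = I(syns), stringsAsFactors = FALSE),
           isaEdges = edges, displayName = displayName, groupTag = groupTag)
}

# is_a targets that appear as an id: of some stanza in the file (possibly an
# obsolete one); edges to those are silently dropped rather than an error
.knownElsewhere <- function(targets, lines) {
  allIds <- trimws(sub("^id:", "", lines[startsWith(lines, "id:")]))
  !(targets %in% allIds)
}

#' Write an Ontology back to the OBO subset
#'
#' Emits a minimal header plus one `[Term]` stanza per concept with `id:`,
#' `name:`, `synonym: "..." EXACT []` and `is_a:` lines, in concept order.
#' `readOBO(writeOBO(x))` reproduces `x` up to display name and group tag
#' (which live in the repository manifest, not the OBO file).
#'
#' @param ont an [Ontology].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeOBO <- function(ont, path) {
  cc <- concepts(ont)
  ee <- isaEdges(ont)
  out <- c("format-version: 1.2", paste0("ontology: ", ontologyId(ont)))
  esc <- function(x) gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", x))
  for (i in seq_len(nrow(cc))) {
    out <- c(out, "", "[Term]",
             paste0("id: ", cc$localId[i]),
             paste0("name: ", cc$preferredName[i]))
    for (s in cc$synonyms[[i]])
      out <- c(out, paste0('synonym: "', esc(s), '" EXACT []'))
    for (p in ee$parent[ee$child == cc$localId[i]])
      out <- c(out, paste0("is_a: ", p))
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Read a 4-column mappings TSV into a repository
#'
#' Appends directed point-to-point mappings from a tab-separated file with
#' columns `source_ontology`, `source_id`, `target_ontology`, `target_id`
#' (no header; `#` lines are comments). Rows whose endpoints do not
#' resolve to loaded concepts are skipped with one warning carrying the
#' skip count; a row with the wrong column count is an error.
#'
#' @param path path to the TSV file.
#' @param repo an [OntologyRepository].
#' @return the repository with the resolvable mappings appended and the
#'   mapping index rebuilt.
#' @export
readMappings <- function(path, repo) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[!grepl("^[[:space:]]*(#|$)", lines)]
  if (!length(lines)) return(repo)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad))
    stop("malformed mappings file ", path, ": row ", bad[1],
         " has ", lengths(parts)[bad[1]], " columns (expected 4)")
  mp <- data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(mp) <- c("sourceOntology", "sourceId", "targetOntology", "targetId")
  resolves <- function(ont, id) {
    !is.null(repo@ontologies[[ont]]) && id %in% repo@ontologies[[ont]]@concepts$localId
  }
  ok <- mapply(resolves, mp$sourceOntology, mp$sourceId) &
        mapply(resolves, mp$targetOntology, mp$targetId)
  if (any(!ok))
    warning(sum(!ok), " mapping row(s) skipped: endpoint not loaded")
  ontologyRepository(repo@ontologies, rbind(repo@mappings, mp[ok, , drop = FALSE]))
}

#' Load a repository from a manifest file
#'
#' The manifest is a YAML file listing the OBO files to load and,
#' optionally, a mappings TSV, with paths relative to the manifest:
#'
#' ```yaml
#' ontologies:
#'   - path: nci.obo
#'     ontology_id: NCI
#'     display_name: NCI Thesaurus
#'     group_tag: umls
#' mappings: mappings.tsv
#' ```
#'
#' @param path path to the manifest YAML.
#' @return an [OntologyRepository].
#' @seealso [writeRepository()] for the inverse.
#' @export
loadRepository <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  man <- yaml::read_yaml(path)
  if (is.null(man$ontologies) || !length(man$ontologies))
    stop("manifest lists no ontologies: ", path)
  base <- dirname(path)
  onts <- lapply(man$ontologies, function(o) {
    readOBO(file.path(base, o$path), o$ontology_id,
            displayName = if (is.null(o$display_name)) o$ontology_id else o$display_name,
            groupTag = if (is.null(o$group_tag)) "other" else o$group_tag)
  })
  repo <- ontologyRepository(onts)
  if (!is.null(man$mappings))
    repo <- readMappings(file.path(base, man$mappings), repo)
  repo
}

#' Write a repository as OBO files + mappings TSV + manifest
#'
#' @param repo an [OntologyRepository].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeRepository <- function(repo, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(ontologies(repo), function(o) {
    fn <- paste0(gsub("[^A-Za-z0-9_.-]", "_", ontologyId(o)), ".obo")
    writeOBO(o, file.path(dir, fn))
    list(path = fn, ontology_id = ontologyId(o),
         display_name = displayName(o), group_tag = groupTag(o))
  })
  man <- list(ontologies = unname(entries))
  mp <- mappings(repo)
  if (nrow(mp)) {
    utils::write.table(mp, file.path(dir, "mappings.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    man$mappings <- "mappings.tsv"
  }
  manPath <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(man, manPath)
  invisible(manPath)
}
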
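#' Matching configuration
#'
#' Controls dictionary compilation and concept recognition. The defaults
#' mirror the annotation service's standard settings: minimum term size 3
#' and the built-in English stopword list enabled. `longestOnly` defaults
#' to `FALSE` here; [runConfig()] flips it per scenario (keyword inputs
#' default to longest-only matching, corpus inputs do not).
#'
#' @param longestOnly if `TRUE`, annotations whose span is strictly
#'   contained in another annotation's span are suppressed.
#' @param minTermSize terms whose normalized form is shorter than this
#'   many characters are excluded from the dictionary.
#' @param useDefaultStopwords include the built-in stopword list.
#' @param stopwords extra stopwords (character vector). Stopwords block
#'   single-token dictionary entries only; multi-word terms containing a
#'   stopword are kept.
#' @return a `MatchConfig` list.
#' @export
matchConfig <- function(longestOnly = FALSE, minTermSize = 3L,
                        useDefaultStopwords = TRUE, stopwords = character()) {
  stopifnot(minTermSize >= 1L)
  sw <- tolower(stopwords)
  if (useDefaultStopwords) sw <- union(sw, defaultStopwords())
  structure(list(longestOnly = isTRUE(longestOnly),
                 minTermSize = as.integer(minTermSize),
                 useDefaultStopwords = isTRUE(useDefaultStopwords),
                 stopwords = sort(sw)),
            class = "MatchConfig")
}

#' Built-in English stopword list
#'
#' A fixed, version-controlled list of common English function words,
#' shipped as a plain-text resource (one word per line). Stopwords only
#' block single-token dictionary entries.
#'
#' @return a character vector of lower-case words.
#' @export
defaultStopwords <- function() {
  path <- system.file("extdata", "stopwords.txt", package = "OntoRecommender")
  tolower(readLines(path, warn = FALSE))
}

# case-fold and collapse whitespace; the canonical form used for both
# dictionary terms and text windows
.normalizeTerm <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(x)))
}

# token runs of Unicode letters/digits with 0-based half-open offsets
.tokenize <- function(text) {
  m <- gregexpr("[\\p{L}\\p{N}]+", text, perl = TRUE)[[1]]
  if (m[1] == -1L)
    return(data.frame(token = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  start <- as.integer(m) - 1L
  end <- start + attr(m, "match.length")
  data.frame(token = regmatches(text, list(m))[[1]], start = start, end = end,
             stringsAsFactors = FALSE)
}

# naive English plural folding: strip a trailing "s" unless the token is
# short or ends in "ss" ("mass" stays "mass")
.depluralize <- function(tokens) {
  strip <- nchar(tokens) > 3L & endsWith(tokens, "s") & !endsWith(tokens, "ss")
  tokens[strip] <- substr(tokens[strip], 1L, nchar(tokens[strip]) - 1L)
  tokens
}

#' Compile the term dictionary from a repository
#'
#' One entry per concept preferred name and per synonym, normalized by
#' case-folding and whitespace collapsing. Entries shorter than
#' `minTermSize` characters, and single-token entries equal to a
#' stopword, are excluded (exclusion counts are reported as a message).
#'
#' @param repo an [OntologyRepository].
#' @param config a [matchConfig()].
#' @return a data.frame with columns `term` (normalized), `ontologyId`,
#'   `localId`, `kind` (`"preferred"` or `"synonym"`) and `nTokens`,
#'   de-duplicated on (`term`, concept, `kind`).
#' @examples
#' dict <- compileDictionary(workedExampleRepository(), matchConfig())
#' nrow(dict)  # 8 concepts + 2 synonyms = 10 entries
#' @export
compileDictionary <- function(repo, config = matchConfig()) {
  pieces <- lapply(ontologies(repo), function(ont) {
    cc <- concepts(ont)
    n <- lengths(cc$synonyms)
    data.frame(
      term = c(cc$preferredName, unlist(cc$synonyms, use.names = FALSE)),
      ontologyId = ontologyId(ont),
      localId = c(cc$localId, rep(cc$localId, n)),
      kind = c(rep("preferred", nrow(cc)), rep("synonym", sum(n))),
      stringsAsFactors = FALSE)
  })
  dict <- do.call(rbind, unname(pieces))
  dict$term <- .normalizeTerm(dict$term)
  dict <- dict[!duplicated(dict[c("term", "ontologyId", "localId", "kind")]), , drop = FALSE]
  tooShort <- nchar(dict$term) < config$minTermSize
  stop_ <- !grepl(" ", dict$term, fixed = TRUE) & dict$term %in% config$stopwords
  excluded <- tooShort | stop_
  if (any(excluded))
    message("dictionary: excluded ", sum(tooShort), " term(s) below minTermSize and ",
            sum(stop_ & !tooShort), " stopword term(s)")
  dict <- dict[!excluded, , drop = FALSE]
  dict$nTokens <- lengths(strsplit(dict$term, " ", fixed = TRUE))
  rownames(dict) <- NULL
  dict
}

#' Recognize dictionary terms in text (direct annotations)
#'
#' Scans the text for token-boundary-aligned occurrences of dictionary
#' terms (matching is case-insensitive, with naive plural folding: a
#' window that has no exact dictionary match is retried with trailing
#' "s" stripped from its tokens). Every occurrence yields one annotation
#' per matching dictionary entry; with `longestOnly`, annotations whose
#' span is strictly contained in another annotation's span are
#' suppressed, regardless of ontology.
#'
#' @param text a non-empty string.
#' @param dictionary output of [compileDictionary()].
#' @param config a [matchConfig()].
#' @param line line number recorded on the annotations (used by the
#'   keyword scenario, where each line is matched independently).
#' @return an annotation data.frame (see [annotationFrame()]) with
#'   contexts `"direct_preferred"`/`"direct_synonym"`, sorted by
#'   (`start`, `end`, `ontologyId`, `localId`).
#' @examples
#' repo <- workedExampleRepository()
#' recognize("the melanoma tumor", compileDictionary(repo), matchConfig())
#' @export
recognize <- function(text, dictionary, config = matchConfig(), line = 1L) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("input text is empty")
  toks <- .tokenize(text)
  out <- annotationFrame()
  if (nrow(toks) && nrow(dictionary)) {
    env <- new.env(hash = TRUE, parent = emptyenv())
    for (i in seq_len(nrow(dictionary))) {
      k <- dictionary$term[i]
      env[[k]] <- c(env[[k]], i)
    }
    low <- tolower(toks$token)
    stripped <- .depluralize(low)
    rows <- list()
    for (n in sort(unique(dictionary$nTokens))) {
      if (n > nrow(toks)) break
      for (w in seq_len(nrow(toks) - n + 1L)) {
        idx <- w:(w + n - 1L)
        hit <- env[[paste(low[idx], collapse = " ")]]
        if (is.null(hit))
          hit <- env[[paste(stripped[idx], collapse = " ")]]
        if (is.null(hit)) next
        hit <- hit[dictionary$nTokens[hit] == n]
        if (!length(hit)) next
        s <- toks$start[w]; e <- toks$end[w + n - 1L]
        rows[[length(rows) + 1L]] <- data.frame(
          ontologyId = dictionary$ontologyId[hit],
          localId = dictionary$localId[hit],
          start = s, end = e, line = as.integer(line),
          surface = substr(text, s + 1L, e),
          context = ifelse(dictionary$kind[hit] == "preferred",
                           "direct_preferred", "direct_synonym"),
          ancestorLevel = NA_integer_, stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) out <- do.call(rbind, rows)
  }
  out <- .sortAnnotations(out)
  if (config$longestOnly) out <- suppressSubsumed(out)
  out
}

#' Suppress annotations strictly contained in a longer span
#'
#' The longest-only semantics: an annotation survives unless its span is
#' a strict sub-interval of some other annotation's span on the same
#' input line (containment across ontologies counts; equal spans never
#' suppress each other). Idempotent.
#'
#' @param annotations an annotation data.frame from one input.
#' @return the surviving annotations, order preserved.
#' @export
suppressSubsumed <- function(annotations) {
  if (nrow(annotations) < 2L) return(annotations)
  spans <- unique(annotations[c("line", "start", "end")])
  keep <- rep(TRUE, nrow(annotations))
  for (i in seq_len(nrow(spans))) {
    contained <- annotations$line == spans$line[i] &
      annotations$start >= spans$start[i] & annotations$end <= spans$end[i] &
      (annotations$end - annotations$start) < (spans$end[i] - spans$start[i])
    keep <- keep & !contained
  }
  out <- annotations[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
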
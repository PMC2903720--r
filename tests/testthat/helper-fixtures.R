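# shared fixtures and independent oracles, built in code at test time

writeTempOBO <- function(lines) {
  path <- withr::local_tempfile(fileext = ".obo", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# a toy repository holding the longest-only example terms
breastCancerRepo <- function() {
  a <- ontology("HD", data.frame(
    localId = "DOID:1612", preferredName = "breast cancer",
    stringsAsFactors = FALSE), displayName = "Human Disease")
  b <- ontology("VO", data.frame(
    localId = "VO:1", preferredName = "breast", stringsAsFactors = FALSE),
    displayName = "Vaccine Ontology")
  d <- ontology("BIRN", data.frame(
    localId = "B:1", preferredName = "cancer", stringsAsFactors = FALSE),
    displayName = "BIRNLex")
  ontologyRepository(list(a, b, d))
}

# the mapping-expansion example: "treatment" exists in MSH only, and a
# point-to-point mapping carries it into SNOMEDCT
treatmentRepo <- function() {
  msh <- ontology("MSH", data.frame(
    localId = "C0087111", preferredName = "treatment",
    stringsAsFactors = FALSE), groupTag = "umls")
  sct <- ontology("SNOMEDCT", data.frame(
    localId = "C0087111", preferredName = "therapeutic procedure",
    stringsAsFactors = FALSE), groupTag = "umls")
  mp <- data.frame(sourceOntology = "MSH", sourceId = "C0087111",
                   targetOntology = "SNOMEDCT", targetId = "C0087111",
                   stringsAsFactors = FALSE)
  ontologyRepository(list(msh, sct), mp)
}

# --- independent matcher oracle -------------------------------------------
# tries every dictionary term at every token-aligned window of the text,
# via substring comparison; written independently of recognize()'s
# hash-lookup scan

oracleDepluralize <- function(tok) {
  ifelse(nchar(tok) > 3 & grepl("s$", tok) & !grepl("ss$", tok),
         sub("s$", "", tok), tok)
}

oracleRecognize <- function(text, dictionary) {
  m <- gregexpr("[[:alnum:]]+", text)[[1]]
  if (m[1] == -1L) return(annotationFrame())
  tokStart <- as.integer(m) - 1L
  tokEnd <- tokStart + attr(m, "match.length")
  n <- length(tokStart)
  hits <- list()
  for (a in seq_len(n)) for (b in a:n) {
    slice <- substr(text, tokStart[a] + 1L, tokEnd[b])
    toks <- tolower(strsplit(gsub("[^[:alnum:]]+", " ", slice), " ")[[1]])
    exact <- paste(toks, collapse = " ")
    folded <- paste(oracleDepluralize(toks), collapse = " ")
    hitExact <- which(dictionary$term == exact & dictionary$nTokens == b - a + 1L)
    hit <- if (length(hitExact)) hitExact else
      which(dictionary$term == folded & dictionary$nTokens == b - a + 1L)
    for (h in hit)
      hits[[length(hits) + 1L]] <- data.frame(
        ontologyId = dictionary$ontologyId[h], localId = dictionary$localId[h],
        start = tokStart[a], end = tokEnd[b], line = 1L, surface = slice,
        context = ifelse(dictionary$kind[h] == "preferred",
                         "direct_preferred", "direct_synonym"),
        ancestorLevel = NA_integer_, stringsAsFactors = FALSE)
  }
  out <- if (length(hits)) do.call(rbind, hits) else annotationFrame()
  out <- out[order(out$start, out$end, out$ontologyId, out$localId), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# random single-ontology repositories over a tiny ASCII vocabulary, for the
# matcher property tests
randomMatchCase <- function() {
  pool <- c("alpha", "beta", "gamma", "delta", "cell", "tumor", "gene",
            "acid", "bone", "brain", "cells", "mass")
  nTerm <- sample(3:8, 1)
  terms <- vapply(seq_len(nTerm), function(i)
    paste(sample(pool, sample(1:3, 1)), collapse = " "), character(1))
  terms <- unique(terms)
  ont <- ontology("RND", data.frame(
    localId = sprintf("R%02d", seq_along(terms)), preferredName = terms,
    stringsAsFactors = FALSE))
  textToks <- sample(pool, sample(5:25, 1), replace = TRUE)
  seps <- sample(c(" ", ", ", " ", "; ", " "), length(textToks) - 1, replace = TRUE)
  text <- paste0(paste0(textToks[-length(textToks)], seps, collapse = ""),
                 textToks[length(textToks)])
  list(repo = ontologyRepository(list(ont)), text = text)
}
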
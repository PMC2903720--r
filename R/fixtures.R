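#' The pinned worked-example repository
#'
#' A three-ontology miniature repository used throughout the
#' documentation and tests: an NCI Thesaurus excerpt (Melanocyte,
#' Melanoma, Neoplasm with synonym "tumor", and Eye structure), an FMA
#' excerpt (Eye, Intestine with synonym "bowel", Melanocyte) and the
#' one-concept Human Disease excerpt (Melanoma, DOID:1909), linked by
#' two directed mappings: NCI Melanocyte -> FMA Melanocyte and FMA Eye
#' -> NCI Eye structure. Annotating the sentence about melanoma of
#' melanocytes in skin, bowel and eye with CR+M over this repository
#' yields the per-ontology scores NCI 35, FMA 25, Human Disease 10.
#'
#' Two concepts are deliberately given preferred names that do not occur
#' in the example sentence — NCI "Eye structure" and FMA "Epidermal
#' melanocyte" — so each is credited only through its mapping, never by
#' a direct match; that is what makes the CR+M totals come out as the
#' reference annotation list requires.
#'
#' @return an [OntologyRepository] with 3 ontologies and 2 mappings.
#' @examples
#' repo <- workedExampleRepository()
#' vapply(ontologies(repo), ontologySize, integer(1))  # NCI 4, FMA 3, 40465 1
#' @export
workedExampleRepository <- function() {
  nci <- ontology("NCI", data.frame(
    localId = c("C0025201", "C0025202", "C0027651", "C0015392"),
    preferredName = c("Melanocyte", "Melanoma", "Neoplasm", "Eye structure"),
    synonyms = I(list(character(), character(), "tumor", character())),
    stringsAsFactors = FALSE),
    displayName = "NCI Thesaurus", groupTag = "umls")
  fma <- ontology("FMA", data.frame(
    localId = c("C0015392", "C0021853", "C0025201"),
    preferredName = c("Eye", "Intestine", "Epidermal melanocyte"),
    synonyms = I(list(character(), "bowel", character())),
    stringsAsFactors = FALSE),
    displayName = "Foundational Model of Anatomy", groupTag = "umls")
  hd <- ontology("40465", data.frame(
    localId = "DOID:1909", preferredName = "Melanoma",
    stringsAsFactors = FALSE),
    displayName = "Human Disease", groupTag = "bioportal")
  mp <- data.frame(
    sourceOntology = c("NCI", "FMA"), sourceId = c("C0025201", "C0015392"),
    targetOntology = c("FMA", "NCI"), targetId = c("C0025201", "C0015392"),
    stringsAsFactors = FALSE)
  ontologyRepository(list(nci, fma, hd), mp)
}

#' The worked-example input sentence
#'
#' @return the melanoma sentence annotated in the package documentation.
#' @export
workedExampleText <- function() {
  paste("Melanoma is a malignant tumor of melanocytes which are found",
        "predominantly in skin but also in the bowel and the eye.")
}

#' Synthetic repository specification
#'
#' Parameters for [generateRepository()]. The default size mix follows
#' the composition of public biomedical ontology repositories, where
#' roughly half the ontologies are small, a third medium and the rest
#' large, scaled down to desk sizes: small 5–15, medium 20–50, large
#' 60–120 concepts. A fraction of ontologies are designated hubs and
#' receive mappings from other ontologies at `mappingDensity` per
#' (concept, hub) pair; non-hub pairs get a quarter of that density, so
#' hub in-degree is elevated the way reference terminologies are in real
#' mapping networks.
#'
#' @param nOntologies number of ontologies to generate.
#' @param sizeMix named probabilities for the small/medium/large classes
#'   (default c(small = .47, medium = .36, large = .17)).
#' @param sizeRanges named list of c(min, max) concept counts per class.
#' @param mappingDensity probability that a concept maps into a given
#'   hub ontology.
#' @param hubFraction fraction of ontologies designated as hubs.
#' @param maxSynonyms each concept gets 0..maxSynonyms synonyms.
#' @param isaDensity probability that a concept (after the first) gets
#'   an is_a parent among earlier concepts (acyclic by construction).
#' @param vocabulary optional character vector used as the token pool;
#'   by default a deterministic pronounceable pool disjoint from the
#'   noise alphabet used by [generateCorpus()].
#' @param seed integer; fully determines the generated repository.
#' @return a `FixtureSpec` list.
#' @export
fixtureSpec <- function(nOntologies = 10L,
                        sizeMix = c(small = 0.47, medium = 0.36, large = 0.17),
                        sizeRanges = list(small = c(5L, 15L),
                                          medium = c(20L, 50L),
                                          large = c(60L, 120L)),
                        mappingDensity = 0.02, hubFraction = 0.1,
                        maxSynonyms = 2L, isaDensity = 0.7,
                        vocabulary = NULL, seed = 1L) {
  stopifnot(nOntologies >= 1L, mappingDensity >= 0, mappingDensity <= 1,
            hubFraction >= 0, hubFraction <= 1)
  structure(list(nOntologies = as.integer(nOntologies), sizeMix = sizeMix,
                 sizeRanges = sizeRanges, mappingDensity = mappingDensity,
                 hubFraction = hubFraction, maxSynonyms = as.integer(maxSynonyms),
                 isaDensity = isaDensity, vocabulary = vocabulary,
                 seed = as.integer(seed)),
            class = "FixtureSpec")
}

# deterministic pronounceable token pool; letters restricted to b-o so the
# noise alphabet (q-z) used by generateCorpus stays disjoint
.defaultVocabulary <- function() {
  cons <- c("b", "d", "f", "g", "h", "k", "l", "m", "n")
  vow <- c("a", "e", "i", "o")
  syl <- as.vector(outer(cons, vow, paste0))
  as.vector(outer(as.vector(outer(syl, syl, paste0)), syl, paste0))
}

#' Generate a synthetic ontology repository
#'
#' Deterministic for a given spec (the spec's seed drives every draw).
#' Every preferred name and synonym is a unique token from the
#' vocabulary, so distinct concepts never collide lexically; is_a
#' parents are drawn only among earlier-generated concepts, which makes
#' the hierarchy acyclic by construction; mappings are sampled toward
#' designated hub ontologies at the spec's density (plus a weaker
#' non-hub baseline).
#'
#' @param spec a [fixtureSpec()].
#' @return an [OntologyRepository].
#' @export
generateRepository <- function(spec = fixtureSpec()) {
  vocab <- if (is.null(spec$vocabulary)) .defaultVocabulary() else spec$vocabulary
  withr::local_seed(spec$seed)
  classes <- sample(names(spec$sizeMix), spec$nOntologies, replace = TRUE,
                    prob = spec$sizeMix)
  sizes <- vapply(classes, function(cl) {
    r <- spec$sizeRanges[[cl]]
    sample(seq.int(r[1], r[2]), 1L)
  }, integer(1))
  nHubs <- ceiling(spec$hubFraction * spec$nOntologies)
  nSyn <- lapply(sizes, function(s) sample(0:spec$maxSynonyms, s, replace = TRUE))
  need <- sum(sizes) + sum(unlist(nSyn))
  if (need > length(vocab))
    stop("vocabulary too small: need ", need, " tokens, have ", length(vocab))
  tokens <- sample(vocab, need)
  cursor <- 0L
  takeTokens <- function(k) {
    if (k == 0L) return(character())
    out <- tokens[(cursor + 1L):(cursor + k)]
    cursor <<- cursor + k
    out
  }
  onts <- vector("list", spec$nOntologies)
  for (i in seq_len(spec$nOntologies)) {
    s <- sizes[i]
    ids <- sprintf("C%04d", seq_len(s))
    prefs <- takeTokens(s)
    syns <- lapply(nSyn[[i]], takeTokens)
    child <- character(); parent <- character()
    for (j in seq_len(s)[-1]) {
      if (stats::runif(1) < spec$isaDensity) {
        child <- c(child, ids[j])
        parent <- c(parent, ids[sample.int(j - 1L, 1L)])
      }
    }
    onts[[i]] <- ontology(sprintf("ONT%03d", i),
      data.frame(localId = ids, preferredName = prefs, synonyms = I(syns),
                 stringsAsFactors = FALSE),
      isaEdges = data.frame(child = child, parent = parent,
                            stringsAsFactors = FALSE),
      displayName = sprintf("Synthetic ontology %03d (%s)", i, classes[i]),
      groupTag = if (i <= nHubs) "umls" else "bioportal")
  }
  ids <- vapply(onts, ontologyId, character(1))
  hubs <- ids[seq_len(nHubs)]
  rows <- list()
  for (i in seq_len(spec$nOntologies)) {
    src <- onts[[i]]
    for (tgt in ids[ids != ids[i]]) {
      dens <- if (tgt %in% hubs) spec$mappingDensity else spec$mappingDensity / 4
      if (dens <= 0) next
      hitIdx <- which(stats::runif(ontologySize(src)) < dens)
      if (!length(hitIdx)) next
      tgtConcepts <- concepts(onts[[match(tgt, ids)]])$localId
      rows[[length(rows) + 1L]] <- data.frame(
        sourceOntology = ids[i],
        sourceId = concepts(src)$localId[hitIdx],
        targetOntology = tgt,
        targetId = sample(tgtConcepts, length(hitIdx), replace = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  mp <- if (length(rows)) do.call(rbind, rows) else NULL
  ontologyRepository(onts, mp)
}

#' Generate a synthetic corpus from one ontology
#'
#' Samples `nTerms` terms (preferred names and synonyms) of the source
#' ontology, with replacement, and interleaves noise tokens built from a
#' character alphabet disjoint from the default vocabulary, so noise can
#' never hit the dictionary. The number of noise tokens is chosen so
#' that they make up `noiseFraction` of the corpus. One phrase per
#' line; deterministic per seed.
#'
#' @param repo an [OntologyRepository].
#' @param sourceOntology id of the ontology the corpus is drawn from.
#' @param nTerms number of real term occurrences.
#' @param noiseFraction fraction of corpus tokens that are noise, in
#'   \[0, 1).
#' @param seed integer seed.
#' @return a single string, phrases separated by newlines.
#' @export
generateCorpus <- function(repo, sourceOntology, nTerms, noiseFraction = 0,
                           seed = 1L) {
  ont <- ontologies(repo)[[sourceOntology]]
  if (is.null(ont)) stop("no such ontology: ", sourceOntology)
  cc <- concepts(ont)
  terms <- c(cc$preferredName, unlist(cc$synonyms, use.names = FALSE))
  if (!length(terms)) stop("source ontology has no terms")
  stopifnot(noiseFraction >= 0, noiseFraction < 1, nTerms >= 1L)
  withr::local_seed(seed)
  real <- sample(terms, nTerms, replace = TRUE)
  nNoise <- round(nTerms * noiseFraction / (1 - noiseFraction))
  noise <- if (nNoise > 0)
    vapply(seq_len(nNoise), function(i)
      paste(sample(c("q", "r", "s", "t", "u", "v", "w", "x", "y", "z"),
                   sample(4:8, 1L), replace = TRUE), collapse = ""),
      character(1))
  else character()
  paste(sample(c(real, noise)), collapse = "\n")
}
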
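#' Classify a co-sentential bioentity pair
#'
#' Given the entity and interaction mentions of one sentence, assigns a
#' confidence type to a pair of entity keys:
#'
#' * **type 1** — some interaction-term mention lies strictly between a
#'   mention of one pair member and a mention of the other (any witnessing
#'   combination of mentions suffices);
#' * **type 2** — the sentence contains an interaction-term mention, but
#'   none between the names;
#' * **type 3** — the pair co-occurs in the sentence without any
#'   interaction term.
#'
#' Types are ordered from most to least confident; abstract-level
#' co-occurrence (type 4) is handled by [extract_abstract_pairs()].
#' Classification is symmetric in the pair order. Negated statements are
#' deliberately not treated specially: "A does not bind B" classifies as
#' type 1 like its affirmative counterpart.
#'
#' @param entities Entity-mention tibble (as from [tag_entities()]) restricted
#'   to one sentence.
#' @param interactions Interaction-mention tibble for the same sentence.
#' @param key1,key2 The two (distinct) normalized entity keys.
#' @return Integer 1, 2 or 3.
#' @export
classify_pair <- function(entities, interactions, key1, key2) {
  if (identical(key1, key2)) {
    stop("classify_pair requires two distinct entity keys", call. = FALSE)
  }
  a <- entities[entities$key == key1, , drop = FALSE]
  b <- entities[entities$key == key2, , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0) {
    stop("both pair members must be mentioned in the sentence", call. = FALSE)
  }
  res <- classify_pair_impl(a, b, interactions)
  res$type
}

# Internal classifier that also reports the supporting interaction terms:
# for type 1 the witnessing between-the-names terms, for type 2 all terms in
# the sentence, for type 3 none.
classify_pair_impl <- function(a, b, interactions) {
  if (nrow(interactions) == 0) {
    return(list(type = 3L, terms = character(0)))
  }
  witness <- logical(nrow(interactions))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      lo <- min(a$end[i], b$end[j])
      hi <- max(a$start[i], b$start[j])
      if (lo > hi) next   # mentions overlap or touch; no gap to test
      witness <- witness |
        (interactions$start >= lo & interactions$end <= hi)
    }
  }
  if (any(witness)) {
    list(type = 1L, terms = unique(interactions$term[witness]))
  } else {
    list(type = 2L, terms = unique(interactions$term))
  }
}

#' Extract sentence-level co-occurrences (types 1-3)
#'
#' For every sentence, takes the set of distinct entity keys present.
#' Sentences with four or more distinct bioentities are excluded outright:
#' they tend to be too complex for reliable pair extraction. Otherwise each
#' unordered pair of distinct keys yields exactly one co-occurrence, typed
#' by [classify_pair()] (a sentence instance gets its single best reading:
#' 1 beats 2 beats 3). A key mentioned twice never pairs with itself.
#'
#' @param tagged A `tagged_abstract`.
#' @param max_entities Exclusion threshold: sentences with at least this
#'   many distinct entity keys yield nothing (default 4).
#' @return Co-occurrence tibble with columns `pmid`, `term1`, `term2`
#'   (normalized keys, `term1 < term2`), `type`, `sentence_index`,
#'   `interaction_terms` (list), `concepts` (list, filled by
#'   [associate_concepts()]), `evidence` (sentence text).
#' @export
extract_sentence_pairs <- function(tagged, max_entities = 4) {
  stopifnot(inherits(tagged, "tagged_abstract"))
  ents <- tagged$entities
  out <- list()
  for (s in unique(ents$sentence_index)) {
    es <- ents[ents$sentence_index == s, , drop = FALSE]
    keys <- sort(unique(es$key))
    if (length(keys) < 2 || length(keys) >= max_entities) next
    is_ <- tagged$interactions[tagged$interactions$sentence_index == s, ,
                               drop = FALSE]
    evidence <- tagged$record$sentences$text[tagged$record$sentences$index == s]
    pairs <- utils::combn(keys, 2, simplify = FALSE)
    for (p in pairs) {
      cls <- classify_pair_impl(es[es$key == p[1], , drop = FALSE],
                                es[es$key == p[2], , drop = FALSE], is_)
      out[[length(out) + 1L]] <- tibble::tibble(
        pmid = tagged$record$pmid, term1 = p[1], term2 = p[2],
        type = cls$type, sentence_index = s,
        interaction_terms = list(cls$terms), concepts = list(character(0)),
        evidence = evidence
      )
    }
  }
  if (length(out) == 0) return(cooc_empty())
  dplyr::bind_rows(out)
}

#' Extract abstract-level co-occurrences (type 4)
#'
#' Every unordered pair of distinct entity keys occurring anywhere in the
#' abstract that has no sentence-level co-occurrence in this abstract is
#' emitted once as a type-4 instance. Pairs whose only shared sentences were
#' excluded by the complexity rule are therefore still captured at abstract
#' level. Type-4 rows carry no evidence sentence and no interaction terms.
#'
#' @param tagged A `tagged_abstract`.
#' @param sentence_pairs The tibble from [extract_sentence_pairs()] for the
#'   same abstract.
#' @return Co-occurrence tibble (possibly empty) of type-4 rows.
#' @export
extract_abstract_pairs <- function(tagged, sentence_pairs) {
  stopifnot(inherits(tagged, "tagged_abstract"))
  keys <- sort(unique(tagged$entities$key))
  if (length(keys) < 2) return(cooc_empty())
  pairs <- utils::combn(keys, 2, simplify = FALSE)
  seen <- paste(sentence_pairs$term1, sentence_pairs$term2, sep = "\r")
  out <- list()
  for (p in pairs) {
    if (paste(p[1], p[2], sep = "\r") %in% seen) next
    out[[length(out) + 1L]] <- tibble::tibble(
      pmid = tagged$record$pmid, term1 = p[1], term2 = p[2],
      type = 4L, sentence_index = NA_integer_,
      interaction_terms = list(character(0)), concepts = list(character(0)),
      evidence = ""
    )
  }
  if (length(out) == 0) return(cooc_empty())
  dplyr::bind_rows(out)
}

#' Attach concepts to co-occurrences
#'
#' Sentence-level co-occurrences (types 1-3) receive exactly the concept
#' phrases mentioned in their own evidence sentence; abstract-level
#' co-occurrences (type 4) receive all concept phrases mentioned anywhere in
#' the abstract.
#'
#' @param cooc Co-occurrence tibble for one abstract.
#' @param concept_mentions Concept-mention tibble from [tag_concepts()] for
#'   the same abstract.
#' @return The co-occurrence tibble with the `concepts` list-column filled.
#' @export
associate_concepts <- function(cooc, concept_mentions) {
  if (nrow(cooc) == 0) return(cooc)
  all_phrases <- unique(concept_mentions$phrase)
  cooc$concepts <- lapply(seq_len(nrow(cooc)), function(i) {
    if (cooc$type[i] == 4L) {
      all_phrases
    } else {
      unique(concept_mentions$phrase[
        concept_mentions$sentence_index == cooc$sentence_index[i]
      ])
    }
  })
  cooc
}

#' Run the full extraction pipeline over a corpus
#'
#' Tags every abstract and extracts typed, concept-annotated co-occurrences:
#' sentence-level pairs (types 1-3, with the four-entity complexity
#' exclusion), then abstract-level pairs (type 4) for pairs never
#' co-sentential, then concept association.
#'
#' @param corpus List of [abstract_record()]s (e.g. from [read_corpus()]).
#' @param gene_lexicon A [gene_lexicon()].
#' @param interaction_lexicon An [interaction_lexicon()] or `NULL`.
#' @param concept_lexicon A [load_concepts()] lexicon or `NULL`.
#' @param max_entities Complexity-exclusion threshold (default 4).
#' @return Co-occurrence tibble across the corpus (see
#'   [extract_sentence_pairs()] for columns).
#' @export
extract_cooccurrences <- function(corpus, gene_lexicon,
                                  interaction_lexicon = NULL,
                                  concept_lexicon = NULL,
                                  max_entities = 4) {
  res <- lapply(corpus, function(rec) {
    tg <- tag_abstract(rec, gene_lexicon, interaction_lexicon, concept_lexicon)
    sp <- extract_sentence_pairs(tg, max_entities = max_entities)
    ap <- extract_abstract_pairs(tg, sp)
    associate_concepts(dplyr::bind_rows(sp, ap), tg$concepts)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) cooc_empty() else out
}

#' Summarize co-occurrence instances per pair
#'
#' Groups instances by unordered pair across the corpus. `best_type` is the
#' minimum (most confident) type observed; `support` counts instances;
#' PMIDs, concepts and interaction terms are unioned.
#'
#' @param cooc Co-occurrence tibble.
#' @return Tibble with columns `term1`, `term2`, `best_type`, `support`,
#'   `pmids`, `concepts`, `interaction_terms` (the last three list-columns).
#' @export
summarize_pairs <- function(cooc) {
  if (nrow(cooc) == 0) {
    return(tibble::tibble(
      term1 = character(), term2 = character(), best_type = integer(),
      support = integer(), pmids = list(), concepts = list(),
      interaction_terms = list()
    ))
  }
  cooc |>
    dplyr::group_by(.data$term1, .data$term2) |>
    dplyr::summarise(
      best_type = min(.data$type),
      support = dplyr::n(),
      pmids = list(unique(.data$pmid)),
      concepts = list(unique(unlist(.data$concepts))),
      interaction_terms = list(unique(unlist(.data$interaction_terms))),
      .groups = "drop"
    )
}

#' Write / read the co-occurrence table as TSV
#'
#' List-columns (`interaction_terms`, `concepts`) are pipe-collapsed on
#' write and split again on read, so a write/read round trip preserves the
#' table.
#'
#' @param cooc Co-occurrence tibble.
#' @param path Output path.
#' @return `write_cooccurrences()` returns `path` invisibly;
#'   `read_cooccurrences()` returns the tibble.
#' @export
write_cooccurrences <- function(cooc, path) {
  flat <- tibble::tibble(
    pmid = cooc$pmid, term1 = cooc$term1, term2 = cooc$term2,
    type = cooc$type, sentence_index = cooc$sentence_index,
    interaction_terms = collapse_field(cooc$interaction_terms),
    concepts = collapse_field(cooc$concepts),
    evidence = cooc$evidence
  )
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_cooccurrences
#' @export
read_cooccurrences <- function(path) {
  flat <- utils::read.delim(path, sep = "\t", quote = "",
                            colClasses = "character")
  if (nrow(flat) == 0) return(cooc_empty())
  tibble::tibble(
    pmid = flat$pmid, term1 = flat$term1, term2 = flat$term2,
    type = as.integer(flat$type),
    sentence_index = suppressWarnings(as.integer(flat$sentence_index)),
    interaction_terms = split_field(flat$interaction_terms),
    concepts = split_field(flat$concepts),
    evidence = flat$evidence
  )
}
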
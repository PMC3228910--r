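# Dictionary matching helpers ------------------------------------------------

# Locate all occurrences of each surface form in `text`, case-insensitively
# and respecting token boundaries: a match may not begin or end inside an
# alphanumeric run. `suffix` optionally allows the match to be extended by a
# short inflectional suffix ("s"/"es"), used for concept phrases.
# Returns a tibble with 0-based half-open offsets.
locate_terms <- function(text, surfaces, suffix = FALSE) {
  out <- tibble::tibble(start = integer(), end = integer(),
                        surface = character(), key = character())
  if (length(surfaces) == 0 || !nzchar(text)) return(out)
  # cheap pre-filter: fixed substring presence in the case-folded text
  lower <- stringi::stri_trans_tolower(text)
  present <- stringi::stri_detect_fixed(lower, surfaces)
  surfaces <- surfaces[present]
  if (length(surfaces) == 0) return(out)
  hits <- vector("list", length(surfaces))
  for (i in seq_along(surfaces)) {
    esc <- regex_escape(surfaces[i])
    # multi-word phrases tolerate any internal whitespace
    esc <- stringi::stri_replace_all_fixed(esc, " ", "\\s+")
    pat <- paste0(
      "(?<![a-zA-Z0-9])", esc,
      if (suffix) "(?:es|s)?" else "",
      "(?![a-zA-Z0-9])"
    )
    loc <- stringi::stri_locate_all_regex(
      text, pat, opts_regex = stringi::stri_opts_regex(case_insensitive = TRUE)
    )[[1]]
    if (is.na(loc[1, 1])) next
    hits[[i]] <- tibble::tibble(
      start = unname(loc[, 1]) - 1L,   # to 0-based half-open
      end = unname(loc[, 2]),
      surface = stringi::stri_sub(text, loc[, 1], loc[, 2]),
      key = surfaces[i]
    )
  }
  res <- dplyr::bind_rows(hits)
  if (nrow(res) == 0) return(out)
  dplyr::arrange(res, .data$start, .data$end)
}

# Leftmost-longest resolution: scan candidates ordered by start (then by
# decreasing length) and greedily keep non-overlapping matches.
resolve_leftmost_longest <- function(matches) {
  if (nrow(matches) == 0) return(matches)
  m <- matches[order(matches$start, -matches$end), ]
  keep <- logical(nrow(m))
  last_end <- -1L
  for (i in seq_len(nrow(m))) {
    if (m$start[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- m$end[i]
    }
  }
  m[keep, ]
}

# Map mention offsets to sentence indices; mentions spanning a sentence
# boundary (possible for multi-word forms) are dropped.
assign_sentences <- function(mentions, sentences) {
  if (nrow(mentions) == 0) {
    mentions$sentence_index <- integer(0)
    return(mentions)
  }
  idx <- findInterval(mentions$start, sentences$start)
  ok <- idx >= 1 & mentions$start >= sentences$start[idx] &
    mentions$end <= sentences$end[pmax(idx, 1)]
  mentions <- mentions[ok, , drop = FALSE]
  mentions$sentence_index <- sentences$index[idx[ok]]
  mentions
}

# Tagging operations ---------------------------------------------------------

#' Tag gene/protein entity mentions in an abstract
#'
#' Dictionary-based entity recognition: every indexed surface form of the
#' gene lexicon is matched case-insensitively against the abstract body,
#' with token-boundary checks (a match may not begin or end inside an
#' alphanumeric run) and leftmost-longest resolution of overlapping
#' candidates. Each mention carries the full set of candidate gene ids —
#' ambiguous surface forms are flagged, not resolved.
#'
#' This dictionary tagger is one implementation of the package's pluggable
#' tagging contract: any function producing a mention tibble with the same
#' columns and invariants (spans inside their sentence, non-overlapping,
#' non-empty `gene_ids`) can be substituted upstream of the co-occurrence
#' stage.
#'
#' @param record An [abstract_record()].
#' @param lexicon A [gene_lexicon()].
#' @return Tibble with columns `sentence_index`, `start`, `end` (0-based
#'   half-open offsets into the body), `surface`, `key` (normalized surface),
#'   `gene_ids` (list of character vectors), `display_symbol` (official
#'   symbol of the first candidate) and `ambiguous`.
#' @export
tag_entities <- function(record, lexicon) {
  stopifnot(inherits(record, "abstract_record"),
            inherits(lexicon, "gene_lexicon"))
  cand <- locate_terms(record$body, names(lexicon$index))
  m <- resolve_leftmost_longest(cand)
  m <- assign_sentences(m, record$sentences)
  ids <- lexicon$index[m$key]
  tibble::tibble(
    sentence_index = m$sentence_index,
    start = m$start, end = m$end, surface = m$surface, key = m$key,
    gene_ids = unname(ids),
    display_symbol = unname(vapply(ids, function(g)
      unname(lexicon$symbols[g[1]]), character(1))),
    ambiguous = lengths(ids) > 1
  )
}

#' Tag biointeraction-term mentions
#'
#' Matches the interaction-term dictionary against the abstract body with
#' the same token-boundary, case-insensitive rules as [tag_entities()].
#' Mentions overlapping an entity mention are discarded: an entity surface
#' cannot double as an interaction trigger.
#'
#' @param record An [abstract_record()].
#' @param lexicon An [interaction_lexicon()].
#' @param entities Entity mentions from [tag_entities()] (used to suppress
#'   overlaps); may be `NULL`.
#' @return Tibble with columns `sentence_index`, `start`, `end`, `surface`,
#'   `term` (normalized).
#' @export
tag_interactions <- function(record, lexicon, entities = NULL) {
  stopifnot(inherits(record, "abstract_record"),
            inherits(lexicon, "interaction_lexicon"))
  cand <- locate_terms(record$body, lexicon$terms)
  m <- resolve_leftmost_longest(cand)
  if (!is.null(entities) && nrow(entities) > 0 && nrow(m) > 0) {
    overlaps <- vapply(seq_len(nrow(m)), function(i) {
      any(m$start[i] < entities$end & entities$start < m$end[i])
    }, logical(1))
    m <- m[!overlaps, , drop = FALSE]
  }
  m <- assign_sentences(m, record$sentences)
  tibble::tibble(
    sentence_index = m$sentence_index,
    start = m$start, end = m$end, surface = m$surface, term = m$key
  )
}

#' Tag concept mentions
#'
#' Matches the user's concept phrases case-insensitively, one mention per
#' occurrence. A phrase also matches when its final token is extended by a
#' short inflectional suffix ("s" or "es"), so "brain" matches "brains";
#' fuller stemming is deliberately not attempted, to keep matches
#' auditable. Concept mentions may overlap entity mentions (a word can name
#' both a process and a protein).
#'
#' @param record An [abstract_record()].
#' @param lexicon A [load_concepts()] lexicon.
#' @return Tibble with columns `sentence_index`, `start`, `end`, `surface`,
#'   `phrase` (the lexicon phrase).
#' @export
tag_concepts <- function(record, lexicon) {
  stopifnot(inherits(record, "abstract_record"),
            inherits(lexicon, "concept_lexicon"))
  m <- locate_terms(record$body, lexicon$phrases, suffix = TRUE)
  m <- resolve_leftmost_longest(m)
  m <- assign_sentences(m, record$sentences)
  tibble::tibble(
    sentence_index = m$sentence_index,
    start = m$start, end = m$end, surface = m$surface, phrase = m$key
  )
}

#' Tag one abstract with all three dictionaries
#'
#' Applies entity, interaction-term and concept tagging in that order
#' (entities suppress overlapping interaction terms; concepts are
#' independent).
#'
#' @param record An [abstract_record()].
#' @param gene_lexicon A [gene_lexicon()] (mandatory).
#' @param interaction_lexicon An [interaction_lexicon()], or `NULL` to skip
#'   (all sentence pairs then classify as type 3).
#' @param concept_lexicon A [load_concepts()] lexicon, or `NULL` to skip.
#' @return Object of class `tagged_abstract`: list with `record`,
#'   `entities`, `interactions`, `concepts`.
#' @export
tag_abstract <- function(record, gene_lexicon,
                         interaction_lexicon = NULL, concept_lexicon = NULL) {
  if (is.null(interaction_lexicon)) {
    interaction_lexicon <- structure(list(terms = character(0)),
                                     class = "interaction_lexicon")
  }
  if (is.null(concept_lexicon)) {
    concept_lexicon <- structure(list(phrases = character(0)),
                                 class = "concept_lexicon")
  }
  entities <- tag_entities(record, gene_lexicon)
  interactions <- tag_interactions(record, interaction_lexicon, entities)
  concepts <- tag_concepts(record, concept_lexicon)
  structure(
    list(record = record, entities = entities,
         interactions = interactions, concepts = concepts),
    class = "tagged_abstract"
  )
}

#' @export
print.tagged_abstract <- function(x, ...) {
  cat(sprintf(
    "<tagged_abstract> PMID %s: %d entity, %d interaction, %d concept mentions\n",
    x$record$pmid, nrow(x$entities), nrow(x$interactions), nrow(x$concepts)
  ))
  invisible(x)
}

#' Flatten tagged mentions to a single table
#'
#' One row per mention of any kind, suitable for inspection or TSV export.
#'
#' @param tagged A `tagged_abstract` or a list of them.
#' @return Tibble with columns `pmid`, `kind` (`entity`, `interaction`,
#'   `concept`), `sentence_index`, `start`, `end`, `surface`, `ids`
#'   (pipe-separated gene ids, empty for non-entities).
#' @export
mentions_table <- function(tagged) {
  if (inherits(tagged, "tagged_abstract")) tagged <- list(tagged)
  dplyr::bind_rows(lapply(tagged, function(t) {
    pmid <- t$record$pmid
    dplyr::bind_rows(
      if (nrow(t$entities)) tibble::tibble(
        pmid = pmid, kind = "entity",
        sentence_index = t$entities$sentence_index,
        start = t$entities$start, end = t$entities$end,
        surface = t$entities$surface,
        ids = collapse_field(t$entities$gene_ids)
      ),
      if (nrow(t$interactions)) tibble::tibble(
        pmid = pmid, kind = "interaction",
        sentence_index = t$interactions$sentence_index,
        start = t$interactions$start, end = t$interactions$end,
        surface = t$interactions$surface, ids = ""
      ),
      if (nrow(t$concepts)) tibble::tibble(
        pmid = pmid, kind = "concept",
        sentence_index = t$concepts$sentence_index,
        start = t$concepts$start, end = t$concepts$end,
        surface = t$concepts$surface, ids = ""
      )
    )
  }))
}
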
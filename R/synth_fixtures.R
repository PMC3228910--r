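# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Invent a pool of synthetic entity names
#'
#' Names are alphanumeric tokens (`GX001P`, `GX002P`, ...) absent from
#' English text, so fixture corpora cannot produce accidental dictionary
#' matches.
#'
#' @param n Number of entities.
#' @param prefix Name prefix.
#' @return Tibble with columns `gene_id`, `symbol`, `synonyms` (list).
#' @export
make_entity_pool <- function(n, prefix = "GX") {
  tibble::tibble(
    gene_id = as.character(9000L + seq_len(n)),
    symbol = sprintf("%s%03dP", prefix, seq_len(n)),
    synonyms = rep(list(character(0)), n)
  )
}

#' Configuration for the synthetic corpus generator
#'
#' Describes a corpus with known, planted interaction structure: which
#' entity pairs appear, at which co-occurrence type, with which concept.
#' Each planted pair gets its own abstract so that planted counts are exact
#' by construction; additional dedicated abstracts hold deliberately complex
#' sentences (four distinct entities, excluded by the complexity rule) and
#' negated interaction sentences ("X does not bind Y", which the method
#' still reads as type 1 — negation blindness is a documented property, and
#' the generator plants it so tests assert it intentionally).
#'
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param planted_pairs Tibble with columns `term1`, `term2` (entity
#'   symbols), `target_type` (1-4) and optionally `concept` (phrase or
#'   `NA`).
#' @param entity_pool Tibble as from [make_entity_pool()]; defaults to a
#'   pool covering all planted symbols. Every planted symbol must be in the
#'   pool.
#' @param n_abstracts Total abstracts; must be at least the number of
#'   planted pairs plus `complex_sentence_count` plus `negation_count`
#'   (the remainder are entity-free distractor abstracts). Default: exactly
#'   the needed number.
#' @param distractor_sentences_per_abstract Neutral sentences (no entities,
#'   no triggers) added to each abstract (default 1).
#' @param complex_sentence_count Abstracts whose single content sentence
#'   names four distinct entities (default 0).
#' @param negation_count Abstracts with one "does not <verb>" sentence
#'   (default 0).
#' @param verbs Interaction verbs used by the templates; each must be in
#'   the shipped default interaction-term dictionary.
#' @return Object of class `fixture_config`.
#' @export
fixture_config <- function(seed, planted_pairs,
                           entity_pool = NULL, n_abstracts = NULL,
                           distractor_sentences_per_abstract = 1,
                           complex_sentence_count = 0,
                           negation_count = 0,
                           verbs = c("binds", "inhibits", "activates",
                                     "phosphorylates")) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  planted_pairs <- tibble::as_tibble(planted_pairs)
  stopifnot(all(c("term1", "term2", "target_type") %in% names(planted_pairs)))
  if (!"concept" %in% names(planted_pairs)) {
    planted_pairs$concept <- NA_character_
  }
  planted_pairs$target_type <- as.integer(planted_pairs$target_type)
  if (nrow(planted_pairs) > 0) {
    stopifnot(all(planted_pairs$target_type %in% 1:4),
              all(planted_pairs$term1 != planted_pairs$term2))
  }
  default_terms <- load_interaction_terms()$terms
  if (any(planted_pairs$target_type %in% 1:2) || negation_count > 0 ||
      complex_sentence_count > 0) {
    if (length(verbs) == 0) {
      stop("planting type 1/2 requires a non-empty verb pool", call. = FALSE)
    }
    missing <- setdiff(normalize_key(verbs), default_terms)
    if (length(missing) > 0) {
      stop("verb(s) not in the default interaction-term dictionary: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  need_extra <- 4L * complex_sentence_count + 2L * negation_count
  symbols <- unique(c(planted_pairs$term1, planted_pairs$term2))
  if (is.null(entity_pool)) {
    entity_pool <- tibble::tibble(
      gene_id = as.character(9000L + seq_along(symbols)),
      symbol = symbols, synonyms = rep(list(character(0)), length(symbols))
    )
  }
  entity_pool <- tibble::as_tibble(entity_pool)
  absent <- setdiff(symbols, entity_pool$symbol)
  if (length(absent) > 0) {
    stop("planted symbol(s) missing from the entity pool: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  # dedicated entities for complex / negation abstracts
  if (need_extra > 0) {
    extra <- make_entity_pool(need_extra, prefix = "QZ")
    extra$gene_id <- as.character(8000L + seq_len(need_extra))
    entity_pool <- dplyr::bind_rows(entity_pool, extra)
  }
  n_needed <- nrow(planted_pairs) + complex_sentence_count + negation_count
  if (is.null(n_abstracts)) n_abstracts <- n_needed
  if (n_abstracts < n_needed) {
    stop(sprintf("n_abstracts (%d) is below the %d needed for the plants",
                 n_abstracts, n_needed), call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), planted_pairs = planted_pairs,
         entity_pool = entity_pool, n_abstracts = as.integer(n_abstracts),
         distractor_sentences_per_abstract =
           as.integer(distractor_sentences_per_abstract),
         complex_sentence_count = as.integer(complex_sentence_count),
         negation_count = as.integer(negation_count),
         verbs = verbs),
    class = "fixture_config"
  )
}

#' @export
print.fixture_config <- function(x, ...) {
  cat(sprintf(
    "<fixture_config> seed %d: %d planted pairs, %d abstracts (%d complex, %d negated)\n",
    x$seed, nrow(x$planted_pairs), x$n_abstracts,
    x$complex_sentence_count, x$negation_count
  ))
  invisible(x)
}

distractors <- c(
  "The clinical cohort was followed for two years.",
  "Samples were collected at the reference hospital.",
  "Imaging was performed at baseline and at follow-up.",
  "The findings were consistent across replicate experiments.",
  "Patient consent was obtained before enrolment."
)

#' Render one planted sentence
#'
#' Produces a sentence that, when tagged with the fixture lexicons,
#' classifies to exactly the requested co-occurrence type for the pair, and
#' mentions the concept iff one is given. Type 4 is not a single sentence
#' (its members never share one) and is assembled by [generate_corpus()].
#'
#' @param term1,term2 Entity symbols.
#' @param target_type 1, 2 or 3.
#' @param verb Interaction verb (used by types 1 and 2).
#' @param concept Concept phrase or `NA`.
#' @return Character scalar.
#' @export
plant_sentence <- function(term1, term2, target_type, verb = "binds",
                           concept = NA_character_) {
  stopifnot(target_type %in% 1:3)
  tail <- if (!is.na(concept)) paste0(" during ", concept) else ""
  switch(as.character(target_type),
    "1" = sprintf("%s %s %s%s.", term1, verb, term2, tail),
    "2" = sprintf("%s and %s accumulate together when the complex %s with membranes%s.",
                  term1, term2, verb, tail),
    "3" = sprintf("%s and %s coexist in patient tissue%s.",
                  term1, term2, tail)
  )
}

#' Generate a synthetic corpus bundle with planted truth
#'
#' Writes, under `dir`: `corpus.txt` (MEDLINE tagged-field format),
#' `gene_lexicon.tsv`, `interaction_terms.txt` (the shipped default
#' dictionary), `concepts.txt` and `gold.tsv` (planted type-1/2/3 pairs plus
#' the designated pair of each complex sentence, with truthful stratum
#' flags). Output is a pure function of the configuration: the same seed
#' gives byte-identical files.
#'
#' @param config A [fixture_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths), `planted`
#'   (tibble of planted pairs with `pmid`), and `config`.
#' @export
generate_corpus <- function(config, dir) {
  stopifnot(inherits(config, "fixture_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(config$seed, generate_corpus_impl(config, dir))
}

generate_corpus_impl <- function(config, dir) {
  pp <- config$planted_pairs
  n_plant <- nrow(pp)
  pool <- config$entity_pool
  verbs <- config$verbs
  ndist <- config$distractor_sentences_per_abstract
  pick_distractors <- function() {
    if (ndist == 0) return(character(0))
    distractors[sample.int(length(distractors), ndist, replace = TRUE)]
  }
  abstracts <- list()
  planted <- list()
  gold <- list()
  pmid_counter <- 900000L
  next_pmid <- function() {
    pmid_counter <<- pmid_counter + 1L
    as.character(pmid_counter)
  }
  extra_i <- 0L
  extra_symbol <- function() {
    extra_i <<- extra_i + 1L
    pool$symbol[pool$gene_id == as.character(8000L + extra_i)]
  }
  for (i in seq_len(n_plant)) {
    pmid <- next_pmid()
    verb <- verbs[sample.int(length(verbs), 1)]
    concept <- pp$concept[i]
    sents <- if (pp$target_type[i] <= 3) {
      plant_sentence(pp$term1[i], pp$term2[i], pp$target_type[i], verb,
                     concept)
    } else {
      c(sprintf("%s was observed in cortical samples.", pp$term1[i]),
        pick_distractors(),
        sprintf("%s was observed in hippocampal samples.", pp$term2[i]),
        if (!is.na(concept)) sprintf("These findings relate to %s.", concept))
    }
    body <- paste(c(sents, pick_distractors()), collapse = " ")
    abstracts[[length(abstracts) + 1L]] <- list(
      pmid = pmid, title = sprintf("Observational study %d.", i), body = body
    )
    planted[[length(planted) + 1L]] <- tibble::tibble(
      pmid = pmid, term1 = pp$term1[i], term2 = pp$term2[i],
      target_type = pp$target_type[i], concept = concept
    )
    if (pp$target_type[i] <= 3) {
      gold[[length(gold) + 1L]] <- tibble::tibble(
        pmid = pmid, term1 = pp$term1[i], term2 = pp$term2[i],
        is_self = FALSE, non_gene_symbol = FALSE, both_in_dictionary = TRUE,
        both_detected = TRUE, complex_sentence = FALSE
      )
    }
  }
  for (i in seq_len(config$complex_sentence_count)) {
    pmid <- next_pmid()
    ents <- c(extra_symbol(), extra_symbol(), extra_symbol(), extra_symbol())
    verb <- verbs[sample.int(length(verbs), 1)]
    sent <- sprintf("%s, %s, %s and %s %s in cultured cells.",
                    ents[1], ents[2], ents[3], ents[4], verb)
    abstracts[[length(abstracts) + 1L]] <- list(
      pmid = pmid, title = sprintf("Complex-sentence study %d.", i),
      body = paste(c(sent, pick_distractors()), collapse = " ")
    )
    gold[[length(gold) + 1L]] <- tibble::tibble(
      pmid = pmid, term1 = ents[1], term2 = ents[2],
      is_self = FALSE, non_gene_symbol = FALSE, both_in_dictionary = TRUE,
      both_detected = TRUE, complex_sentence = TRUE
    )
  }
  for (i in seq_len(config$negation_count)) {
    pmid <- next_pmid()
    a <- extra_symbol()
    b <- extra_symbol()
    base <- c("bind", "inhibit", "activate", "phosphorylate")
    verb <- base[sample.int(length(base), 1)]
    sent <- sprintf("%s does not %s %s.", a, verb, b)
    abstracts[[length(abstracts) + 1L]] <- list(
      pmid = pmid, title = sprintf("Negative-finding study %d.", i),
      body = paste(c(sent, pick_distractors()), collapse = " ")
    )
    planted[[length(planted) + 1L]] <- tibble::tibble(
      pmid = pmid, term1 = a, term2 = b, target_type = 1L,
      concept = NA_character_
    )
  }
  n_pad <- config$n_abstracts - length(abstracts)
  for (i in seq_len(n_pad)) {
    pmid <- next_pmid()
    abstracts[[length(abstracts) + 1L]] <- list(
      pmid = pmid, title = sprintf("Background study %d.", i),
      body = paste(c(pick_distractors(), distractors[1]), collapse = " ")
    )
  }
  # write files -------------------------------------------------------------
  paths <- list(
    corpus = file.path(dir, "corpus.txt"),
    gene_lexicon = file.path(dir, "gene_lexicon.tsv"),
    interaction_terms = file.path(dir, "interaction_terms.txt"),
    concepts = file.path(dir, "concepts.txt"),
    gold = file.path(dir, "gold.tsv")
  )
  med <- as.character(unlist(lapply(abstracts, function(a) {
    c(sprintf("PMID- %s", a$pmid),
      sprintf("TI  - %s", a$title),
      sprintf("AB  - %s", a$body),
      "")
  })))
  writeLines(med, paths$corpus)
  writeLines(c("gene_id\tsymbol\tsynonyms",
               sprintf("%s\t%s\t%s", pool$gene_id, pool$symbol,
                       collapse_field(pool$synonyms))),
             paths$gene_lexicon)
  file.copy(system.file("extdata", "interaction_terms.txt",
                        package = "litcooc"),
            paths$interaction_terms, overwrite = TRUE)
  concepts <- unique(stats::na.omit(pp$concept))
  writeLines(as.character(concepts), paths$concepts)
  gold_df <- if (length(gold) > 0) dplyr::bind_rows(gold) else
    tibble::tibble(pmid = character(), term1 = character(),
                   term2 = character(), is_self = logical(),
                   non_gene_symbol = logical(), both_in_dictionary = logical(),
                   both_detected = logical(), complex_sentence = logical())
  utils::write.table(gold_df, paths$gold, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  planted_df <- if (length(planted) > 0) dplyr::bind_rows(planted) else
    tibble::tibble(pmid = character(), term1 = character(),
                   term2 = character(), target_type = integer(),
                   concept = character())
  invisible(list(paths = paths, planted = planted_df, config = config))
}

#' Two-hub fixture preset
#'
#' A corpus emulating the shape of a thematic neurodegeneration literature
#' set: two hub proteins with 48 and 11 planted type-1 partners
#' respectively, one extra type-1 pair between two non-hub proteins, and a
#' type-2 bridge pair between the hubs, with an "aggregation" concept on a
#' subset of sentences. Running the pipeline on it recovers hub degrees 48
#' and 11 at the type-1 threshold by construction.
#'
#' @param seed Integer seed.
#' @param concept_every Attach the concept to every k-th planted pair
#'   (default 5).
#' @return A [fixture_config()].
#' @export
two_hub_config <- function(seed, concept_every = 5) {
  hub1 <- "HUBAP"
  hub2 <- "HUBSN"
  partners1 <- sprintf("PA%03dP", seq_len(48))
  partners2 <- sprintf("PB%03dP", seq_len(11))
  others <- c("OTHAP", "OTHBP")
  pp <- tibble::tibble(
    term1 = c(rep(hub1, 48), rep(hub2, 11), others[1], hub1),
    term2 = c(partners1, partners2, others[2], hub2),
    target_type = c(rep(1L, 48 + 11 + 1), 2L)
  )
  pp$concept <- ifelse(seq_len(nrow(pp)) %% concept_every == 0,
                       "aggregation", NA_character_)
  symbols <- unique(c(pp$term1, pp$term2))
  pool <- tibble::tibble(
    gene_id = as.character(9000L + seq_along(symbols)),
    symbol = symbols,
    synonyms = rep(list(character(0)), length(symbols))
  )
  fixture_config(seed, pp, entity_pool = pool)
}
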
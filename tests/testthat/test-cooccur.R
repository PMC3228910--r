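tag_neuro <- function(body, terms = c("binds", "inhibits", "interacts")) {
  tag_abstract(mk_record(body), neuro_lexicon(), interaction_lexicon(terms))
}

test_that("trigger between the names gives type 1", {
  tg <- tag_neuro(paste("Neuroserpin binds Abeta and is a neuroprotective",
                        "component of amyloid plaques in Alzheimer disease."))
  sp <- extract_sentence_pairs(tg)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$type, 1L)
  expect_setequal(c(sp$term1, sp$term2), c("abeta", "neuroserpin"))
  expect_equal(sp$interaction_terms[[1]], "binds")
})

test_that("trigger elsewhere in the sentence gives type 2", {
  tg <- tag_neuro(deposits_sentence)
  sp <- extract_sentence_pairs(tg)
  row <- sp[sp$term1 == "abeta" & sp$term2 == "alpha-synuclein", ]
  expect_equal(row$type, 2L)
  # and the pairs with tau, where "interacts" lies between, are type 1
  expect_equal(sp$type[sp$term2 == "tau"], c(1L, 1L))
})

test_that("no trigger gives type 3", {
  tg <- tag_neuro("Abeta and tau colocalize")
  sp <- extract_sentence_pairs(tg)
  expect_equal(sp$type, 3L)
  expect_equal(sp$interaction_terms[[1]], character(0))
})

test_that("classification is symmetric and matches the brute-force oracle", {
  bodies <- c(
    "Neuroserpin binds Abeta in plaques.",
    deposits_sentence,
    "Abeta and tau colocalize",
    "BRI2 inhibits Abeta aggregation",
    "Abeta interacts with tau and binds Neuroserpin.",
    "tau, Abeta and BRI2 were measured; BRI2 binds tau."
  )
  for (b in bodies) {
    tg <- tag_neuro(b)
    for (s in unique(tg$entities$sentence_index)) {
      ents <- tg$entities[tg$entities$sentence_index == s, ]
      ints <- tg$interactions[tg$interactions$sentence_index == s, ]
      keys <- unique(ents$key)
      if (length(keys) < 2) next
      for (p in utils::combn(keys, 2, simplify = FALSE)) {
        got <- classify_pair(ents, ints, p[1], p[2])
        expect_equal(got, oracle_classify(ents, ints, p[1], p[2]),
                     info = paste(b, "|", p[1], p[2]))
        expect_equal(got, classify_pair(ents, ints, p[2], p[1]))
      }
    }
  }
})

test_that("classify_pair enforces its preconditions", {
  tg <- tag_neuro("Abeta binds tau.")
  ents <- tg$entities
  ints <- tg$interactions
  expect_error(classify_pair(ents, ints, "abeta", "abeta"), "distinct")
  expect_error(classify_pair(ents, ints, "abeta", "notthere"), "mentioned")
})

test_that("sentences with four or more distinct bioentities are excluded", {
  lex <- gene_lexicon(as.character(1:5), c("AAP", "BBP", "CCP", "DDP", "EEP"),
                      NULL)
  mk <- function(n) {
    syms <- c("AAP", "BBP", "CCP", "DDP", "EEP")[seq_len(n)]
    body <- paste0(paste(syms, collapse = ", "), " and the complex binds X.")
    tag_abstract(mk_record(body), lex, interaction_lexicon("binds"))
  }
  expect_equal(nrow(extract_sentence_pairs(mk(2))), 1L)
  expect_equal(nrow(extract_sentence_pairs(mk(3))), 3L)
  expect_equal(nrow(extract_sentence_pairs(mk(4))), 0L)
  expect_equal(nrow(extract_sentence_pairs(mk(5))), 0L)
  # threshold counts distinct keys, not mentions
  tg <- tag_abstract(mk_record("AAP binds AAP, AAP, BBP and CCP."), lex,
                     interaction_lexicon("binds"))
  expect_equal(nrow(extract_sentence_pairs(tg)), 3L)
})

test_that("self-pairs are never emitted", {
  lex <- gene_lexicon("1", "AAP", NULL)
  tg <- tag_abstract(mk_record("AAP binds AAP strongly."), lex,
                     interaction_lexicon("binds"))
  expect_equal(nrow(extract_sentence_pairs(tg)), 0L)
  expect_equal(nrow(extract_abstract_pairs(tg, extract_sentence_pairs(tg))), 0L)
})

test_that("type 4 captures abstract-only pairs without duplicating", {
  lex <- gene_lexicon(as.character(1:2), c("AAP", "SNCP"), NULL)
  tg <- tag_abstract(
    mk_record("AAP was seen in cortex. Controls were used. SNCP was seen."),
    lex, interaction_lexicon("binds"))
  sp <- extract_sentence_pairs(tg)
  ap <- extract_abstract_pairs(tg, sp)
  expect_equal(nrow(sp), 0L)
  expect_equal(nrow(ap), 1L)
  expect_equal(ap$type, 4L)
  expect_true(is.na(ap$sentence_index))
  # pair already co-sentential -> no extra type-4 record
  tg2 <- tag_abstract(mk_record("AAP binds SNCP. AAP was also seen."), lex,
                      interaction_lexicon("binds"))
  sp2 <- extract_sentence_pairs(tg2)
  expect_equal(nrow(extract_abstract_pairs(tg2, sp2)), 0L)
  # pairs whose only shared sentence was excluded remain type-4 eligible
  lex4 <- gene_lexicon(as.character(1:4), c("AAP", "BBP", "CCP", "DDP"), NULL)
  tg3 <- tag_abstract(mk_record("AAP, BBP, CCP and DDP form a complex."),
                      lex4, interaction_lexicon("binds"))
  sp3 <- extract_sentence_pairs(tg3)
  expect_equal(nrow(sp3), 0L)
  expect_equal(nrow(extract_abstract_pairs(tg3, sp3)), 6L)
})

test_that("concepts attach at sentence scope for types 1-3, abstract scope for type 4", {
  lex <- gene_lexicon(as.character(1:4), c("AAP", "BBP", "CCP", "DDP"), NULL)
  body <- paste("AAP binds BBP.",
                "Aggregation was studied in controls.",
                "CCP was measured separately.")
  tg <- tag_abstract(mk_record(body), lex, interaction_lexicon("binds"),
                     load_concepts("aggregation"))
  sp <- extract_sentence_pairs(tg)
  ap <- extract_abstract_pairs(tg, sp)
  cooc <- associate_concepts(dplyr::bind_rows(sp, ap), tg$concepts)
  # type-1 pair's own sentence has no concept mention -> none attached
  expect_equal(cooc$concepts[[which(cooc$type == 1L)]], character(0))
  # type-4 pairs receive all concepts found anywhere in the abstract
  for (i in which(cooc$type == 4L)) {
    expect_equal(cooc$concepts[[i]], "aggregation")
  }
  # concept in the evidence sentence is attached to the sentence-level pair
  tg2 <- tag_abstract(mk_record("AAP binds BBP during aggregation."), lex,
                      interaction_lexicon("binds"),
                      load_concepts("aggregation"))
  sp2 <- associate_concepts(extract_sentence_pairs(tg2), tg2$concepts)
  expect_equal(sp2$concepts[[1]], "aggregation")
})

test_that("negated statements still classify as type 1 by design", {
  tg <- tag_neuro("Abeta does not bind tau.", terms = c("bind", "binds"))
  sp <- extract_sentence_pairs(tg)
  expect_equal(sp$type, 1L)
})

cooc_empty_for_tests <- function() {
  tibble::tibble(pmid = character(), term1 = character(), term2 = character(),
                 type = integer(), sentence_index = integer(),
                 interaction_terms = list(), concepts = list(),
                 evidence = character())
}

test_that("pair summaries take the best type and aggregate evidence", {
  cooc <- dplyr::bind_rows(
    tibble::tibble(pmid = "1", term1 = "a", term2 = "b", type = 3L,
                   sentence_index = 0L, interaction_terms = list(character(0)),
                   concepts = list("x"), evidence = "s1"),
    tibble::tibble(pmid = "2", term1 = "a", term2 = "b", type = 1L,
                   sentence_index = 1L, interaction_terms = list("binds"),
                   concepts = list("y"), evidence = "s2")
  )
  s <- summarize_pairs(cooc)
  expect_equal(nrow(s), 1L)
  expect_equal(s$best_type, 1L)
  expect_equal(s$support, 2L)
  expect_setequal(s$pmids[[1]], c("1", "2"))
  expect_setequal(s$concepts[[1]], c("x", "y"))
  expect_equal(nrow(summarize_pairs(cooc_empty_for_tests())), 0L)
})

test_that("type-threshold sets are nested for any corpus", {
  for (seed in 1:5) {
    res <- generate_corpus(random_fixture_config(seed), withr::local_tempdir())
    cooc <- run_pipeline_on_fixture(res)
    s <- summarize_pairs(cooc)
    sets <- lapply(1:4, function(t) {
      paste(s$term1[s$best_type <= t], s$term2[s$best_type <= t])
    })
    for (t in 1:3) expect_true(all(sets[[t]] %in% sets[[t + 1]]))
  }
})

test_that("no co-occurrence comes from a sentence with four or more entities", {
  res <- generate_corpus(
    random_fixture_config(11), withr::local_tempdir())
  corp <- read_corpus(res$paths$corpus)
  glex <- load_gene_dictionary(res$paths$gene_lexicon)
  ilex <- load_interaction_terms(res$paths$interaction_terms)
  cooc <- extract_cooccurrences(corp, glex, ilex)
  sent_level <- cooc[!is.na(cooc$sentence_index), ]
  for (i in seq_len(nrow(sent_level))) {
    rec <- corp[[sent_level$pmid[i]]]
    ents <- tag_entities(rec, glex)
    n_keys <- length(unique(
      ents$key[ents$sentence_index == sent_level$sentence_index[i]]))
    expect_lt(n_keys, 4)
  }
})

test_that("co-occurrence tables round-trip through TSV", {
  tg <- tag_neuro("BRI2 inhibits Abeta aggregation")
  cooc <- associate_concepts(extract_sentence_pairs(tg), tg$concepts)
  path <- withr::local_tempfile()
  write_cooccurrences(cooc, path)
  back <- read_cooccurrences(path)
  expect_equal(back$term1, cooc$term1)
  expect_equal(back$type, cooc$type)
  expect_equal(back$evidence, cooc$evidence)
  expect_equal(back$interaction_terms, cooc$interaction_terms)
})
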
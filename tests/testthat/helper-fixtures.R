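# Shared in-code fixtures and independent oracles.

neuro_lexicon <- function() {
  gene_lexicon(
    gene_id = c("351", "6622", "4137", "5764", "627"),
    symbol = c("APP", "SNCA", "MAPT", "NRSN", "BRI2"),
    synonyms = list(
      c("Abeta", "amyloid beta precursor protein"),
      c("alpha-synuclein"),
      c("tau"),
      c("Neuroserpin"),
      character(0)
    )
  )
}

mk_record <- function(body, pmid = "1") abstract_record(pmid, "", body)

deposits_sentence <- paste(
  "Deposits of AMYLOID proteins, including Abeta and alpha-synuclein",
  "coexist in the brains of patients with dementia with Lewy bodies;",
  "however, it is not known how either of them interacts with tau to",
  "provoke neurofibrillary tangle formation across the tauopathies."
)

# Independent brute-force classifier: enumerates every combination of one
# mention of each pair member and every interaction mention, testing
# betweenness by direct offset comparison, with no shared code with
# classify_pair().
oracle_classify <- function(entities, interactions, key1, key2) {
  a_rows <- which(entities$key == key1)
  b_rows <- which(entities$key == key2)
  between <- FALSE
  for (i in a_rows) {
    for (j in b_rows) {
      for (m in seq_len(nrow(interactions))) {
        s1 <- entities$start[i]; e1 <- entities$end[i]
        s2 <- entities$start[j]; e2 <- entities$end[j]
        ms <- interactions$start[m]; me <- interactions$end[m]
        if (e1 <= s2 && ms >= e1 && me <= s2) between <- TRUE
        if (e2 <= s1 && ms >= e2 && me <= s1) between <- TRUE
      }
    }
  }
  if (between) return(1L)
  if (nrow(interactions) > 0) return(2L)
  3L
}

# A small random fixture configuration for property tests: a handful of
# planted pairs over disjoint invented entities, random types and concepts.
random_fixture_config <- function(seed) {
  set.seed(seed)
  n <- sample(2:5, 1)
  pool <- make_entity_pool(2 * n, prefix = sprintf("R%02d", seed %% 90))
  pp <- tibble::tibble(
    term1 = pool$symbol[seq_len(n) * 2 - 1],
    term2 = pool$symbol[seq_len(n) * 2],
    target_type = sample(1:4, n, replace = TRUE),
    concept = ifelse(stats::runif(n) < 0.4, "aggregation", NA_character_)
  )
  fixture_config(seed, pp, entity_pool = pool,
                 complex_sentence_count = sample(0:1, 1),
                 negation_count = sample(0:1, 1))
}

# Run the full pipeline on a generated fixture bundle, reading everything
# back through the package's file readers.
run_pipeline_on_fixture <- function(res) {
  corp <- read_corpus(res$paths$corpus)
  glex <- load_gene_dictionary(res$paths$gene_lexicon)
  ilex <- load_interaction_terms(res$paths$interaction_terms)
  clex <- if (file.size(res$paths$concepts) > 0) {
    load_concepts(res$paths$concepts)
  } else NULL
  extract_cooccurrences(corp, glex, ilex, clex)
}
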
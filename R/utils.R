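#' Normalize a surface form into a matching key
#'
#' Case-folds, collapses internal whitespace and trims. This single
#' normalization is used everywhere two pieces of text are compared: lexicon
#' index keys, entity pair identity, gold-standard matching. Keeping it in one
#' place guarantees that a pair predicted by the tagger and a pair listed in a
#' gold file agree on identity whenever their raw spellings differ only in
#' case or spacing.
#'
#' @param x Character vector.
#' @return Character vector of normalized keys.
#' @examples
#' normalize_key(c("  Alpha-Synuclein ", "COLORECTAL   CANCER"))
#' @export
normalize_key <- function(x) {
  x <- stringi::stri_trans_tolower(x)
  x <- stringi::stri_replace_all_regex(x, "\\s+", " ")
  stringi::stri_trim_both(x)
}

# Escape regex metacharacters so a lexicon surface can be embedded verbatim
# in a pattern.
regex_escape <- function(x) {
  stringi::stri_replace_all_regex(x, "([\\[\\]{}()+*^$|\\\\?.\\-])", "\\\\$1")
}

# Canonical ordering of an unordered pair of keys: term1 <= term2
# lexicographically (C collation so ordering is locale-independent).
order_pair <- function(a, b) {
  swap <- stringi::stri_cmp_lt(b, a)
  tibble::tibble(
    term1 = ifelse(swap, b, a),
    term2 = ifelse(swap, a, b)
  )
}

# Collapse a list-column of character vectors to a delimited string (used by
# the TSV and GraphML writers); inverse of split_field().
collapse_field <- function(x, sep = "|") {
  vapply(x, function(v) paste(sort(unique(v)), collapse = sep), character(1))
}

split_field <- function(x, sep = "|") {
  lapply(stringi::stri_split_fixed(x, sep), function(v) v[nzchar(v)])
}

cooc_empty <- function() {
  tibble::tibble(
    pmid = character(), term1 = character(), term2 = character(),
    type = integer(), sentence_index = integer(),
    interaction_terms = list(), concepts = list(), evidence = character()
  )
}
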
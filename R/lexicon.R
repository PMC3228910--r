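#' Build a gene/protein lexicon
#'
#' The gene lexicon maps surface forms (official symbols and synonyms) to
#' gene identifiers. Matching keys are case-folded with
#' [normalize_key()]; a surface form may map to several gene ids —
#' ambiguity is preserved in the index and surfaced downstream, never
#' silently resolved. Surface forms shorter than `min_length` characters are
#' dropped (and counted in `n_dropped`) because very short synonyms produce
#' pathological false matches.
#'
#' @param gene_id Character vector of gene identifiers.
#' @param symbol Character vector of official symbols (same length).
#' @param synonyms List of character vectors of synonyms (same length), or
#'   `NULL` for none.
#' @param min_length Minimum surface-form length kept in the index
#'   (default 2).
#' @return Object of class `gene_lexicon`: list with `entries` (tibble),
#'   `index` (named list: normalized surface -> character vector of gene
#'   ids), `symbols` (named vector: gene id -> official symbol) and
#'   `n_dropped`.
#' @examples
#' lex <- gene_lexicon(c("351", "6622"), c("APP", "SNCA"),
#'                     list(c("Abeta"), c("alpha-synuclein")))
#' lexicon_lookup(lex, "abeta")
#' @export
gene_lexicon <- function(gene_id, symbol, synonyms = NULL, min_length = 2) {
  stopifnot(length(gene_id) == length(symbol))
  if (is.null(synonyms)) synonyms <- rep(list(character(0)), length(gene_id))
  stopifnot(length(synonyms) == length(gene_id))
  gene_id <- as.character(gene_id)
  if (length(gene_id) == 0) {
    stop("gene lexicon is mandatory and may not be empty", call. = FALSE)
  }
  entries <- tibble::tibble(
    gene_id = gene_id, symbol = as.character(symbol),
    synonyms = lapply(synonyms, as.character)
  )
  # index: every symbol and synonym, case-folded
  surf <- c(entries$symbol, unlist(entries$synonyms, use.names = FALSE))
  ids <- c(entries$gene_id,
           rep(entries$gene_id, lengths(entries$synonyms)))
  key <- normalize_key(surf)
  keep <- nchar(key) >= min_length
  n_dropped <- sum(!keep)
  df <- unique(data.frame(key = key[keep], gene_id = ids[keep],
                          stringsAsFactors = FALSE))
  index <- split(df$gene_id, df$key)
  structure(
    list(entries = entries, index = index,
         symbols = stats::setNames(entries$symbol, entries$gene_id),
         n_dropped = n_dropped),
    class = "gene_lexicon"
  )
}

#' @export
print.gene_lexicon <- function(x, ...) {
  cat(sprintf("<gene_lexicon> %d genes, %d indexed surface forms (%d dropped as too short)\n",
              nrow(x$entries), length(x$index), x$n_dropped))
  invisible(x)
}

#' Load a gene/protein dictionary from TSV
#'
#' The file must have three tab-separated columns: gene id, official symbol,
#' and pipe-separated synonyms (third column may be empty). A header line
#' starting with `gene_id` is allowed and skipped.
#'
#' @param path Path to the TSV file.
#' @inheritParams gene_lexicon
#' @return A `gene_lexicon`.
#' @export
load_gene_dictionary <- function(path, min_length = 2) {
  if (!file.exists(path)) stop("gene dictionary not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(stringi::stri_trim_both(lines))]
  if (length(lines) > 0 &&
      stringi::stri_startswith_fixed(tolower(lines[1]), "gene_id")) {
    lines <- lines[-1]
  }
  if (length(lines) == 0) {
    stop("gene dictionary is empty: ", path, call. = FALSE)
  }
  parts <- stringi::stri_split_fixed(lines, "\t")
  nfield <- lengths(parts)
  if (any(nfield < 2)) {
    stop(sprintf("gene dictionary line %d has fewer than 2 columns: %s",
                 which(nfield < 2)[1], shQuote(lines[which(nfield < 2)[1]])),
         call. = FALSE)
  }
  gene_id <- vapply(parts, `[`, character(1), 1)
  symbol <- vapply(parts, `[`, character(1), 2)
  syn_raw <- vapply(parts, function(p) if (length(p) >= 3) p[3] else "",
                    character(1))
  synonyms <- split_field(syn_raw)
  gene_lexicon(gene_id, symbol, synonyms, min_length = min_length)
}

#' Look up a surface form in a gene lexicon
#'
#' Lookup is total: any query returns a (possibly empty) character vector of
#' gene ids, never an error.
#'
#' @param lexicon A `gene_lexicon`.
#' @param query Character scalar (normalized internally).
#' @return Character vector of matching gene ids (possibly empty).
#' @export
lexicon_lookup <- function(lexicon, query) {
  stopifnot(inherits(lexicon, "gene_lexicon"))
  hit <- lexicon$index[[normalize_key(query)]]
  if (is.null(hit)) character(0) else hit
}

#' Build or load the biointeraction-term lexicon
#'
#' Biointeraction terms are trigger words such as "binds", "inhibits" or
#' "activates" that signal a molecular interaction in a sentence. Terms are
#' case-folded and deduplicated. A default dictionary of ~30 common
#' interaction verb lemmas in several inflections ships with the package and
#' is used when `path` is `NULL`; it is a plain one-term-per-line text file
#' meant to be copied and edited.
#'
#' @param path Path to a one-term-per-line file, or `NULL` for the shipped
#'   default. Lines starting with `#` are ignored.
#' @return Object of class `interaction_lexicon`: list with `terms`
#'   (character vector of normalized terms).
#' @export
load_interaction_terms <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "interaction_terms.txt", package = "litcooc")
  }
  if (!file.exists(path)) {
    stop("interaction-term file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- stringi::stri_trim_both(lines)
  lines <- lines[nzchar(lines) & !stringi::stri_startswith_fixed(lines, "#")]
  interaction_lexicon(lines)
}

#' @rdname load_interaction_terms
#' @param terms Character vector of terms (any case; deduplicated).
#' @export
interaction_lexicon <- function(terms) {
  terms <- unique(normalize_key(terms))
  terms <- terms[nzchar(terms)]
  structure(list(terms = terms), class = "interaction_lexicon")
}

#' @export
print.interaction_lexicon <- function(x, ...) {
  cat(sprintf("<interaction_lexicon> %d terms\n", length(x$terms)))
  invisible(x)
}

#' Build or load the concept list
#'
#' Concepts are user-supplied phrases of one or more words (for example
#' "aggregation" or "colorectal cancer") that are matched
#' case-insensitively in abstracts and attached to co-occurrences.
#' Normalization is case-folding plus whitespace collapse; input order is
#' preserved; duplicates (after normalization) are removed. An empty concept
#' list is valid — concept analysis is then skipped.
#'
#' @param source Path to a one-phrase-per-line file, or a character vector
#'   of phrases.
#' @return Object of class `concept_lexicon`: list with `phrases`.
#' @export
load_concepts <- function(source) {
  lines <- if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    unlist(stringi::stri_split_lines(source), use.names = FALSE)
  }
  phrases <- normalize_key(lines)
  phrases <- phrases[nzchar(phrases)]
  structure(list(phrases = phrases[!duplicated(phrases)]),
            class = "concept_lexicon")
}

#' @export
print.concept_lexicon <- function(x, ...) {
  cat(sprintf("<concept_lexicon> %d phrases\n", length(x$phrases)))
  invisible(x)
}
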
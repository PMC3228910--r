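#' Construct an abstract record
#'
#' An abstract record holds one article: its PMID, title, body text and the
#' sentence segmentation of the body. The title is prepended to the abstract
#' text (separated by a single space) so that entity names occurring only in
#' the title are still taggable; the first sentence of the body is therefore
#' usually the title.
#'
#' All character offsets in this package are 0-based and half-open
#' (`[start, end)`), the standoff-annotation convention, so `start` of the
#' first character is 0 and `end` equals the offset one past the last
#' character.
#'
#' @param pmid Character scalar, the PubMed identifier (digits).
#' @param title Character scalar, may be empty.
#' @param abstract Character scalar, the abstract text.
#' @return An object of class `abstract_record`: a list with elements
#'   `pmid`, `title`, `body` and `sentences` (a tibble as returned by
#'   [segment_sentences()]).
#' @examples
#' rec <- abstract_record("123", "A binds B.", "C inhibits D.")
#' rec$sentences
#' @export
abstract_record <- function(pmid, title = "", abstract = "") {
  stopifnot(is.character(pmid), length(pmid) == 1, nzchar(pmid))
  title <- if (is.na(title)) "" else title
  body <- if (nzchar(title)) {
    paste(stringi::stri_trim_both(title), abstract, sep = " ")
  } else {
    abstract
  }
  structure(
    list(
      pmid = pmid,
      title = title,
      body = body,
      sentences = segment_sentences(body)
    ),
    class = "abstract_record"
  )
}

#' @export
print.abstract_record <- function(x, ...) {
  cat(sprintf(
    "<abstract_record> PMID %s: %d sentences, %d characters\n",
    x$pmid, nrow(x$sentences), nchar(x$body)
  ))
  invisible(x)
}

#' Parse a PMID list
#'
#' Reads a plain-text PMID list, one identifier per line. Blank lines are
#' ignored, duplicates are removed keeping the first occurrence, and input
#' order is otherwise preserved. Any non-numeric token is an error reported
#' with its line number.
#'
#' @param source Either a path to an existing file or a character vector of
#'   lines (a single string containing newlines is split).
#' @return Character vector of unique PMIDs in first-seen order.
#' @examples
#' parse_pmid_list(c("123", "456", "123"))
#' @export
parse_pmid_list <- function(source) {
  lines <- if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    unlist(stringi::stri_split_lines(source), use.names = FALSE)
  }
  lines <- stringi::stri_trim_both(lines)
  keep <- nzchar(lines)
  toks <- lines[keep]
  lineno <- seq_along(lines)[keep]
  bad <- !stringi::stri_detect_regex(toks, "^[0-9]+$")
  if (any(bad)) {
    stop(sprintf(
      "non-numeric PMID token(s) at line %s: %s",
      paste(lineno[bad], collapse = ", "),
      paste(shQuote(toks[bad]), collapse = ", ")
    ), call. = FALSE)
  }
  toks[!duplicated(toks)]
}

#' Read an abstract corpus
#'
#' Reads a corpus of abstracts from either MEDLINE tagged-field plain text
#' (`PMID- `, `TI  - `, `AB  - ` fields, continuation lines indented) or
#' PubMed efetch XML. One [abstract_record()] is produced per article that
#' has an abstract; articles without one are skipped and counted in the
#' `n_skipped` attribute of the result.
#'
#' @param path Path to the corpus file.
#' @param format `"medline"` or `"pubmed-xml"`.
#' @return Named list of `abstract_record` objects (names are PMIDs), with
#'   attribute `n_skipped` giving the number of abstract-less records.
#' @export
read_corpus <- function(path, format = c("medline", "pubmed-xml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("corpus file not found: ", path, call. = FALSE)
  recs <- switch(format,
    "medline" = read_medline(path),
    "pubmed-xml" = read_pubmed_xml(path)
  )
  if (length(recs$records) == 0) {
    warning("empty corpus: no records with an abstract in ", path, call. = FALSE)
  }
  pmids <- vapply(recs$records, `[[`, character(1), "pmid")
  if (anyDuplicated(pmids)) {
    stop("duplicate PMID(s) in corpus: ",
         paste(unique(pmids[duplicated(pmids)]), collapse = ", "),
         call. = FALSE)
  }
  structure(stats::setNames(recs$records, pmids), n_skipped = recs$n_skipped)
}

# MEDLINE tagged-field reader. A field line is "TAG - value" with the tag
# left-justified in the first four columns; indented lines continue the
# previous field; a new record starts at each PMID field.
read_medline <- function(path) {
  lines <- readLines(path, warn = FALSE)
  field_re <- "^([A-Z]{1,4})\\s{0,3}- (.*)$"
  tags <- character(0)
  vals <- character(0)
  for (ln in lines) {
    m <- stringi::stri_match_first_regex(ln, field_re)
    if (!is.na(m[1, 1])) {
      tags <- c(tags, m[1, 2])
      vals <- c(vals, m[1, 3])
    } else if (stringi::stri_detect_regex(ln, "^\\s+\\S") && length(vals) > 0) {
      vals[length(vals)] <- paste(vals[length(vals)],
                                  stringi::stri_trim_both(ln))
    }
    # other lines (blank, malformed) are record separators / ignored
  }
  if (length(tags) == 0) {
    return(list(records = list(), n_skipped = 0L))
  }
  if (tags[1] != "PMID") {
    stop("not a MEDLINE tagged-field file: first field is ", tags[1],
         ", expected PMID", call. = FALSE)
  }
  rec_id <- cumsum(tags == "PMID")
  records <- list()
  n_skipped <- 0L
  for (i in unique(rec_id)) {
    t <- tags[rec_id == i]
    v <- vals[rec_id == i]
    pmid <- v[t == "PMID"][1]
    ab <- paste(v[t == "AB"], collapse = " ")
    ti <- paste(v[t == "TI"], collapse = " ")
    if (!nzchar(ab)) {
      n_skipped <- n_skipped + 1L
      next
    }
    records[[length(records) + 1L]] <- abstract_record(pmid, ti, ab)
  }
  list(records = records, n_skipped = n_skipped)
}

read_pubmed_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
    error = function(e) stop("cannot parse PubMed XML: ", conditionMessage(e),
                             call. = FALSE))
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
  records <- list()
  n_skipped <- 0L
  for (a in arts) {
    pmid <- xml2::xml_text(xml2::xml_find_first(a, ".//MedlineCitation/PMID"))
    title <- xml2::xml_text(xml2::xml_find_first(a, ".//ArticleTitle"))
    ab_nodes <- xml2::xml_find_all(a, ".//Abstract/AbstractText")
    ab <- paste(xml2::xml_text(ab_nodes), collapse = " ")
    if (is.na(pmid) || !nzchar(pmid)) next
    if (!nzchar(ab)) {
      n_skipped <- n_skipped + 1L
      next
    }
    records[[length(records) + 1L]] <-
      abstract_record(pmid, if (is.na(title)) "" else title, ab)
  }
  list(records = records, n_skipped = n_skipped)
}

#' Default abbreviation guard list for sentence segmentation
#'
#' Returns the shipped list of abbreviations after which a period never ends
#' a sentence. Users can extend it by passing their own vector to
#' [segment_sentences()].
#'
#' @return Character vector of abbreviations (each ending in a period).
#' @export
default_abbreviations <- function() {
  path <- system.file("extdata", "abbreviations.txt", package = "litcooc")
  readLines(path, warn = FALSE)
}

#' Segment text into sentences
#'
#' Rule-based sentence splitting: a sentence break is placed after a run of
#' `.`, `!` or `?` that is followed by whitespace and an uppercase letter or
#' digit, unless the token ending at the punctuation is on the abbreviation
#' guard list (for example `e.g.`, `Fig.`, `et al.`). Each sentence span is
#' trimmed of surrounding whitespace, so joining the sentence texts with the
#' skipped whitespace reconstructs the input exactly.
#'
#' @param body Character scalar.
#' @param abbreviations Character vector of abbreviation tokens that suppress
#'   a split; defaults to [default_abbreviations()].
#' @return Tibble with columns `index` (0-based ordinal), `start`, `end`
#'   (0-based half-open character offsets into `body`) and `text`.
#' @examples
#' segment_sentences("A binds B. C inhibits D.")
#' @export
segment_sentences <- function(body, abbreviations = default_abbreviations()) {
  empty <- tibble::tibble(
    index = integer(), start = integer(), end = integer(), text = character()
  )
  if (is.null(body) || is.na(body) || !nzchar(stringi::stri_trim_both(body))) {
    return(empty)
  }
  abbr <- tolower(abbreviations)
  cand <- stringi::stri_locate_all_regex(body, "[.!?]+(?=\\s+[A-Z0-9])")[[1]]
  cuts <- integer(0)
  if (!is.na(cand[1, 1])) {
    for (i in seq_len(nrow(cand))) {
      e <- cand[i, 2]  # 1-based inclusive end of the punctuation run
      # token ending at the punctuation, including it ("Fig." / "al.")
      pre <- stringi::stri_sub(body, 1, e)
      tok <- stringi::stri_extract_last_regex(pre, "\\S+$")
      if (!is.na(tok) && tolower(tok) %in% abbr) next
      cuts <- c(cuts, unname(e))
    }
  }
  bounds1 <- c(1L, cuts + 1L)          # 1-based slice starts
  ends1 <- c(cuts, nchar(body))        # 1-based inclusive slice ends
  out <- vector("list", length(bounds1))
  for (i in seq_along(bounds1)) {
    s1 <- bounds1[i]
    e1 <- ends1[i]
    slice <- stringi::stri_sub(body, s1, e1)
    lead <- stringi::stri_locate_first_regex(slice, "\\S")[1]
    if (is.na(lead)) next
    trail <- stringi::stri_locate_last_regex(slice, "\\S")[1]
    start1 <- s1 + lead - 1L
    end1 <- s1 + trail - 1L
    out[[i]] <- tibble::tibble(
      start = start1 - 1L,             # 0-based half-open
      end = end1,
      text = stringi::stri_sub(body, start1, end1)
    )
  }
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) return(empty)
  out$index <- seq_len(nrow(out)) - 1L
  out[, c("index", "start", "end", "text")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
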
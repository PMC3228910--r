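#' Load a gold-standard interaction set
#'
#' Reads a TSV of curated interactions with columns `pmid`, `term1`,
#' `term2` and optional three-state flag columns (`TRUE`/`FALSE`/empty =
#' unknown): `is_self`, `non_gene_symbol`, `both_in_dictionary`,
#' `both_detected`, `complex_sentence`. Term keys are normalized exactly as
#' the tagger normalizes entity keys, so matching against predictions is
#' literal, never fuzzy. Duplicate `(pmid, pair)` rows are collapsed to one
#' and counted in the `n_duplicates` attribute.
#'
#' @param path Path to the gold TSV (header row required).
#' @return Tibble of gold interactions with attribute `n_duplicates`.
#' @export
load_gold <- function(path) {
  if (!file.exists(path)) stop("gold file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", quote = "",
                          colClasses = "character")
  need <- c("pmid", "term1", "term2")
  if (!all(need %in% names(df))) {
    stop("gold file must have columns pmid, term1, term2; found: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  }
  bad <- !nzchar(df$pmid) | !nzchar(df$term1) | !nzchar(df$term2)
  if (any(bad)) {
    stop("malformed gold row(s) at line(s): ",
         paste(which(bad) + 1L, collapse = ", "), call. = FALSE)
  }
  flags <- c("is_self", "non_gene_symbol", "both_in_dictionary",
             "both_detected", "complex_sentence")
  parse_flag <- function(x) {
    if (is.null(x)) return(rep(NA, nrow(df)))
    ifelse(toupper(x) %in% c("TRUE", "T", "1"), TRUE,
           ifelse(toupper(x) %in% c("FALSE", "F", "0"), FALSE, NA))
  }
  pair <- order_pair(normalize_key(df$term1), normalize_key(df$term2))
  out <- tibble::tibble(pmid = df$pmid, term1 = pair$term1,
                        term2 = pair$term2)
  for (f in flags) out[[f]] <- parse_flag(df[[f]])
  # a self-pair is a self-interaction regardless of the flag column
  out$is_self <- out$is_self | (out$term1 == out$term2)
  out$is_self[is.na(out$is_self) & out$term1 == out$term2] <- TRUE
  dup <- duplicated(out[, c("pmid", "term1", "term2")])
  structure(out[!dup, , drop = FALSE], n_duplicates = sum(dup))
}

#' Filter a gold set to interactions the method can detect by definition
#'
#' Removes self-interactions (homo-dimers) and interactions where a partner
#' is not the symbol of a gene or protein (complexes, mutants, fragments),
#' which a pair-level co-occurrence method cannot detect by definition.
#'
#' @param gold Tibble from [load_gold()].
#' @return List with `retained` (tibble) and `report` (tibble of exclusion
#'   counts per reason; an unknown flag counts as not excluded).
#' @export
filter_gold <- function(gold) {
  self <- !is.na(gold$is_self) & gold$is_self
  nongene <- !is.na(gold$non_gene_symbol) & gold$non_gene_symbol
  list(
    retained = gold[!(self | nongene), , drop = FALSE],
    report = tibble::tibble(
      reason = c("self_interaction", "non_gene_symbol", "retained"),
      n = c(sum(self), sum(nongene & !self), sum(!(self | nongene)))
    )
  )
}

pair_keys <- function(pmid, term1, term2) {
  p <- order_pair(normalize_key(term1), normalize_key(term2))
  paste(pmid, p$term1, p$term2, sep = "\r")
}

#' Pool gold truths with manually confirmed predictions
#'
#' The pooled-truth protocol: the reference set for scoring is the union of
#' the filtered gold interactions and a curated set of predictions confirmed
#' true by manual reading of the abstracts. The union is on `(pmid, pair)`
#' keys, so a confirmed prediction already present in gold counts once.
#' This package ingests the curation (e.g. validation records with status
#' `validated`); it does not automate it.
#'
#' @param filtered_gold Tibble with columns `pmid`, `term1`, `term2`.
#' @param confirmed Tibble with columns `pmid`, `term1`, `term2` of
#'   confirmed novel predictions (may be empty or `NULL`).
#' @return Tibble of the pooled truth set (`pmid`, `term1`, `term2`).
#' @export
pool_truth <- function(filtered_gold, confirmed = NULL) {
  g <- tibble::tibble(
    pmid = filtered_gold$pmid,
    term1 = normalize_key(filtered_gold$term1),
    term2 = normalize_key(filtered_gold$term2)
  )
  if (!is.null(confirmed) && nrow(confirmed) > 0) {
    c2 <- order_pair(normalize_key(confirmed$term1),
                     normalize_key(confirmed$term2))
    g <- dplyr::bind_rows(g, tibble::tibble(pmid = confirmed$pmid,
                                            term1 = c2$term1,
                                            term2 = c2$term2))
  }
  g[!duplicated(pair_keys(g$pmid, g$term1, g$term2)), , drop = FALSE]
}

#' Score predictions against a pooled truth set
#'
#' Predictions are co-occurrence pairs with a best type; the scored set at
#' threshold `t` is the cumulative set of pairs with best type at most `t`
#' (so threshold 3 includes the type-1 and type-2 pairs). True positives
#' are predictions whose `(pmid, pair)` key is in the pooled truth; recall
#' is TP over the truth size, precision TP over the prediction count, both
#' in percent. With zero predictions precision is undefined and reported as
#' `NA`, never as 0 or 100.
#'
#' @param pooled_truth Tibble from [pool_truth()]; must be non-empty.
#' @param predictions Pair tibble with columns `pmid`, `term1`, `term2` and
#'   `best_type` (e.g. per-PMID summaries; [per_pmid_pairs()] builds one
#'   from a co-occurrence table).
#' @param threshold Maximum type pooled into the prediction set (1, 2 or 3).
#' @return One-row tibble: `threshold`, `n_predictions`, `tp`, `fp`,
#'   `truth_size`, `recall`, `precision` (exact percentages) and
#'   `recall_pct`, `precision_pct` (rounded to integers for display, as
#'   benchmark tables conventionally print them).
#' @export
score_predictions <- function(pooled_truth, predictions, threshold) {
  stopifnot(threshold %in% 1:3)
  if (is.null(pooled_truth) || nrow(pooled_truth) == 0) {
    stop("pooled truth set is empty: recall is undefined", call. = FALSE)
  }
  truth_keys <- unique(pair_keys(pooled_truth$pmid, pooled_truth$term1,
                                 pooled_truth$term2))
  pred <- predictions[predictions$best_type <= threshold, , drop = FALSE]
  pred_keys <- unique(pair_keys(pred$pmid, pred$term1, pred$term2))
  tp <- sum(pred_keys %in% truth_keys)
  fp <- length(pred_keys) - tp
  n <- length(pred_keys)
  tibble::tibble(
    threshold = as.integer(threshold), n_predictions = n, tp = tp, fp = fp,
    truth_size = length(truth_keys),
    recall = 100 * tp / length(truth_keys),
    precision = if (n == 0) NA_real_ else 100 * tp / n,
    recall_pct = round(100 * tp / length(truth_keys)),
    precision_pct = if (n == 0) NA_integer_ else as.integer(round(100 * tp / n))
  )
}

#' Per-(pmid, pair) prediction table from a co-occurrence table
#'
#' Collapses co-occurrence instances to one row per abstract and pair with
#' the best (minimum) type, the unit at which instance-level evaluation
#' matches predictions to gold interactions.
#'
#' @param cooc Co-occurrence tibble.
#' @return Tibble with columns `pmid`, `term1`, `term2`, `best_type`.
#' @export
per_pmid_pairs <- function(cooc) {
  if (nrow(cooc) == 0) {
    return(tibble::tibble(pmid = character(), term1 = character(),
                          term2 = character(), best_type = integer()))
  }
  cooc |>
    dplyr::group_by(.data$pmid, .data$term1, .data$term2) |>
    dplyr::summarise(best_type = min(.data$type), .groups = "drop")
}

#' Stratified recall by entity-recognition failure mode
#'
#' Recomputes recall restricting the truth denominator to nested strata:
#' all truths; truths whose both names are in the dictionary; truths whose
#' both names were actually detected by the tagger; truths whose evidence
#' sentence was not excluded as complex. Truths with the stratum flag
#' unknown are excluded from restricted strata (and counted in
#' `n_unknown`). This decomposes recall losses into name-coverage,
#' tagging and sentence-complexity components.
#'
#' @param gold Flagged gold tibble (the stratum flags live here).
#' @param pooled_truth Pooled truth set; stratum membership is looked up in
#'   `gold` by `(pmid, pair)` key (pooled truths absent from `gold`, i.e.
#'   confirmed novel predictions, count as detected in every stratum since
#'   the method found them).
#' @param predictions Prediction tibble as for [score_predictions()].
#' @param threshold Maximum type pooled (1, 2 or 3).
#' @param stratum One of `"all"`, `"both_in_dictionary"`, `"both_detected"`,
#'   `"not_complex"`.
#' @return One-row tibble like [score_predictions()] plus `stratum` and
#'   `n_unknown`.
#' @export
stratify_recall <- function(gold, pooled_truth, predictions, threshold,
                            stratum = c("all", "both_in_dictionary",
                                        "both_detected", "not_complex")) {
  stratum <- match.arg(stratum)
  if (stratum == "all") {
    res <- score_predictions(pooled_truth, predictions, threshold)
    res$stratum <- stratum
    res$n_unknown <- 0L
    return(res)
  }
  gk <- pair_keys(gold$pmid, gold$term1, gold$term2)
  # strata nest: in-dictionary >= detected >= not-complex
  flag <- switch(stratum,
    "both_in_dictionary" = gold$both_in_dictionary,
    "both_detected" = gold$both_in_dictionary & gold$both_detected,
    "not_complex" = gold$both_in_dictionary & gold$both_detected &
      !gold$complex_sentence
  )
  tk <- pair_keys(pooled_truth$pmid, pooled_truth$term1, pooled_truth$term2)
  pos <- match(tk, gk)
  in_gold <- !is.na(pos)
  fl <- rep(TRUE, length(tk))          # novel confirmed truths: detected
  fl[in_gold] <- flag[pos[in_gold]]
  unknown <- is.na(fl)
  keep <- !unknown & fl
  truth <- pooled_truth[keep, , drop = FALSE]
  if (nrow(truth) == 0) {
    stop("stratum '", stratum, "' is empty: recall is undefined",
         call. = FALSE)
  }
  # numerator: tp within the stratum
  res <- score_predictions(truth, predictions, threshold)
  res$stratum <- stratum
  res$n_unknown <- sum(unknown)
  # precision is not meaningful on a restricted denominator; drop it
  res$precision <- NA_real_
  res$precision_pct <- NA_integer_
  res
}

#' Format an evaluation table
#'
#' Human-readable lines shaped like a benchmark table: each cell
#' `tp/denominator (pct%)`.
#'
#' @param results Tibble of rows from [score_predictions()] /
#'   [stratify_recall()].
#' @return Character vector of report lines.
#' @export
format_eval_table <- function(results) {
  vapply(seq_len(nrow(results)), function(i) {
    r <- results[i, ]
    rec <- sprintf("%d/%d (%d%%)", r$tp, r$truth_size, r$recall_pct)
    prec <- if (is.na(r$precision_pct)) "-" else
      sprintf("%d/%d (%d%%)", r$tp, r$n_predictions, r$precision_pct)
    sprintf("Type %d\trecall %s\tprecision %s%s", r$threshold, rec, prec,
            if ("stratum" %in% names(r) && !is.na(r$stratum[1]))
              paste0("\t[", r$stratum, "]") else "")
  }, character(1))
}

# Validation records ---------------------------------------------------------

#' Save / load user validation records
#'
#' A validation record is a user's confirm/reject annotation of one
#' extracted pair in one abstract: columns `pmid`, `term1`, `term2`,
#' `status` (`validated` or `rejected`) and `timestamp` (any sortable
#' string, e.g. ISO-8601). Persistence is TSV so tables can be shared
#' between projects and users. On load, records for the same `(pmid, pair)`
#' are superseded by the latest timestamp; two conflicting records with the
#' same timestamp are an error.
#'
#' @param records Tibble of validation records.
#' @param path TSV path.
#' @return `save_validations()` returns `path` invisibly;
#'   `load_validations()` the effective (superseded-resolved) tibble.
#' @export
save_validations <- function(records, path) {
  stopifnot(all(c("pmid", "term1", "term2", "status", "timestamp") %in%
                  names(records)))
  bad <- !records$status %in% c("validated", "rejected")
  if (any(bad)) {
    stop("invalid validation status: ",
         paste(unique(records$status[bad]), collapse = ", "), call. = FALSE)
  }
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname save_validations
#' @export
load_validations <- function(path) {
  empty <- tibble::tibble(pmid = character(), term1 = character(),
                          term2 = character(), status = character(),
                          timestamp = character())
  if (!file.exists(path)) stop("validation file not found: ", path,
                               call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", quote = "",
                          colClasses = "character")
  if (nrow(df) == 0) return(empty)
  pair <- order_pair(normalize_key(df$term1), normalize_key(df$term2))
  df$term1 <- pair$term1
  df$term2 <- pair$term2
  key <- paste(df$pmid, df$term1, df$term2, sep = "\r")
  out <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    d <- df[idx, , drop = FALSE]
    latest <- d[d$timestamp == max(d$timestamp), , drop = FALSE]
    if (nrow(latest) > 1 && length(unique(latest$status)) > 1) {
      stop("conflicting validation records with identical timestamp for ",
           latest$pmid[1], " (", latest$term1[1], ", ", latest$term2[1], ")",
           call. = FALSE)
    }
    latest[1, , drop = FALSE]
  })
  tibble::as_tibble(dplyr::bind_rows(out))
}
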
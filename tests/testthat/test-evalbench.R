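write_gold <- function(df) {
  path <- withr::local_tempfile(.local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("gold files load with normalization, self detection and dedup", {
  path <- write_gold(tibble::tibble(
    pmid = c("1", "2", "3", "1", "4"),
    term1 = c("Abeta", "TAU", "SNCA", "abeta", "P53"),
    term2 = c("Tau", "tau", "APP", "TAU", "P53")
  ))
  g <- load_gold(path)
  expect_equal(nrow(g), 4L)                 # one duplicate collapsed
  expect_equal(attr(g, "n_duplicates"), 1L)
  expect_true(all(g$term1 == tolower(g$term1)))
  expect_true(g$is_self[g$pmid == "2"])     # term1 == term2 after folding
  expect_true(g$is_self[g$pmid == "4"])
  expect_true(is.na(g$both_in_dictionary[1]))  # missing flags are unknown
})

test_that("gold filtering removes self and non-gene pairs with a report", {
  df <- tibble::tibble(
    pmid = as.character(1:10),
    term1 = letters[1:10], term2 = LETTERS[11:20],
    is_self = c(TRUE, TRUE, rep(FALSE, 8)),
    non_gene_symbol = c(FALSE, FALSE, TRUE, rep(FALSE, 7))
  )
  g <- load_gold(write_gold(df))
  fg <- filter_gold(g)
  expect_equal(nrow(fg$retained), 7L)
  expect_equal(fg$report$n[fg$report$reason == "self_interaction"], 2L)
  expect_equal(fg$report$n[fg$report$reason == "non_gene_symbol"], 1L)
  # no flags set -> all retained
  g2 <- load_gold(write_gold(df[, 1:3]))
  expect_equal(nrow(filter_gold(g2)$retained), 10L)
})

test_that("pooled truth is a set union on (pmid, pair) keys", {
  gold <- tibble::tibble(pmid = as.character(1:201),
                         term1 = sprintf("g%03da", 1:201),
                         term2 = sprintf("g%03db", 1:201))
  novel <- tibble::tibble(pmid = as.character(1001:1024),
                          term1 = sprintf("n%03da", 1:24),
                          term2 = sprintf("n%03db", 1:24))
  pooled <- pool_truth(gold, novel)
  expect_equal(nrow(pooled), 225L)
  # overlap counted once
  pooled2 <- pool_truth(gold, gold[1:5, ])
  expect_equal(nrow(pooled2), 201L)
  expect_equal(nrow(pool_truth(gold, NULL)), 201L)
})

# Builds a truth/prediction pair whose counts mirror a published-style
# nested benchmark: 225 truths; 70 type-1 predictions (56 true), 109
# cumulative type-2 (76 true), 136 cumulative type-3 (90 true).
nested_benchmark <- function() {
  truth <- tibble::tibble(pmid = sprintf("t%03d", 1:225),
                          term1 = "geneA", term2 = "geneB")
  pred_block <- function(idx_true, n_total, type, tag) {
    tibble::tibble(
      pmid = c(truth$pmid[idx_true],
               sprintf("%s%03d", tag, seq_len(n_total - length(idx_true)))),
      term1 = "geneA", term2 = "geneB",
      best_type = type
    )
  }
  preds <- dplyr::bind_rows(
    pred_block(1:56, 70, 1L, "f1"),     # 56 TP + 14 FP at type 1
    pred_block(57:76, 39, 2L, "f2"),    # +20 TP + 19 FP at type 2
    pred_block(77:90, 27, 3L, "f3")     # +14 TP + 13 FP at type 3
  )
  list(truth = truth, preds = preds)
}

test_that("scoring reproduces the nested benchmark arithmetic", {
  nb <- nested_benchmark()
  r1 <- score_predictions(nb$truth, nb$preds, 1)
  expect_equal(r1$tp, 56L)
  expect_equal(r1$n_predictions, 70L)
  expect_equal(r1$precision_pct, 80L)
  expect_equal(r1$recall_pct, 25L)
  r2 <- score_predictions(nb$truth, nb$preds, 2)
  expect_equal(c(r2$tp, r2$n_predictions, r2$recall_pct, r2$precision_pct),
               c(76L, 109L, 34L, 70L))
  r3 <- score_predictions(nb$truth, nb$preds, 3)
  expect_equal(c(r3$tp, r3$n_predictions, r3$recall_pct, r3$precision_pct),
               c(90L, 136L, 40L, 66L))
  # cumulative monotonicity
  expect_true(r1$tp <= r2$tp && r2$tp <= r3$tp)
  expect_true(r1$n_predictions <= r2$n_predictions &&
                r2$n_predictions <= r3$n_predictions)
})

test_that("empty truth errors; zero predictions give missing precision", {
  nb <- nested_benchmark()
  expect_error(score_predictions(nb$truth[0, ], nb$preds, 1), "undefined")
  none <- score_predictions(nb$truth, nb$preds[0, ], 1)
  expect_equal(none$recall, 0)
  expect_true(is.na(none$precision))
  expect_true(is.na(none$precision_pct))
})

test_that("stratified recall narrows the denominator over nested strata", {
  nb <- nested_benchmark()
  # flags: 169 in dictionary, 137 of those detected, 95 of those not complex;
  # the 90 true positives sit inside every stratum
  gold <- nb$truth
  gold$is_self <- FALSE
  gold$non_gene_symbol <- FALSE
  gold$both_in_dictionary <- c(rep(TRUE, 169), rep(FALSE, 56))
  gold$both_detected <- c(rep(TRUE, 137), rep(FALSE, 88))
  gold$complex_sentence <- c(rep(FALSE, 95), rep(TRUE, 42), rep(FALSE, 88))
  r_all <- stratify_recall(gold, nb$truth, nb$preds, 3, "all")
  r_dict <- stratify_recall(gold, nb$truth, nb$preds, 3, "both_in_dictionary")
  r_det <- stratify_recall(gold, nb$truth, nb$preds, 3, "both_detected")
  r_nc <- stratify_recall(gold, nb$truth, nb$preds, 3, "not_complex")
  expect_equal(r_all$truth_size, 225L)
  expect_equal(r_dict$truth_size, 169L)
  expect_equal(r_det$truth_size, 137L)
  expect_equal(r_nc$truth_size, 95L)
  expect_equal(r_all$recall_pct, 40L)
  expect_equal(r_dict$recall_pct, 53L)
  expect_equal(r_det$recall_pct, 66L)
  expect_equal(r_nc$recall_pct, 95L)
  # recall non-decreasing as the stratum narrows
  expect_true(r_all$recall <= r_dict$recall &&
                r_dict$recall <= r_det$recall && r_det$recall <= r_nc$recall)
  # stratum "all" equals the plain score
  plain <- score_predictions(nb$truth, nb$preds, 3)
  expect_equal(r_all$recall, plain$recall)
  # empty stratum errors
  gold$both_in_dictionary <- FALSE
  expect_error(stratify_recall(gold, nb$truth, nb$preds, 3,
                               "both_in_dictionary"), "empty")
})

test_that("unknown stratum flags are excluded and counted", {
  nb <- nested_benchmark()
  gold <- nb$truth
  gold$both_in_dictionary <- c(rep(TRUE, 200), rep(NA, 25))
  gold$both_detected <- NA
  gold$complex_sentence <- NA
  r <- stratify_recall(gold, nb$truth, nb$preds, 3, "both_in_dictionary")
  expect_equal(r$truth_size, 200L)
  expect_equal(r$n_unknown, 25L)
})

test_that("validation tables round-trip with timestamp superseding", {
  recs <- tibble::tibble(
    pmid = c("1", "1", "2"),
    term1 = c("abeta", "abeta", "tau"),
    term2 = c("tau", "tau", "snca"),
    status = c("validated", "rejected", "validated"),
    timestamp = c("2024-01-01T10:00:00", "2024-02-01T10:00:00",
                  "2024-01-01T10:00:00")
  )
  path <- withr::local_tempfile()
  save_validations(recs, path)
  eff <- load_validations(path)
  expect_equal(nrow(eff), 2L)
  expect_equal(eff$status[eff$pmid == "1"], "rejected")
  # exact round trip for non-conflicting records
  save_validations(recs[3, ], path)
  expect_equal(load_validations(path)$pmid, "2")
  # conflicting same-timestamp records error
  bad <- recs
  bad$timestamp <- "2024-01-01T10:00:00"
  save_validations(bad, path)
  expect_error(load_validations(path), "conflicting")
  expect_error(save_validations(dplyr::mutate(recs, status = "maybe"), path),
               "invalid validation status")
})

test_that("evaluation tables format like a benchmark report", {
  nb <- nested_benchmark()
  r <- score_predictions(nb$truth, nb$preds, 1)
  line <- format_eval_table(r)
  expect_match(line, "56/225 \\(25%\\)")
  expect_match(line, "56/70 \\(80%\\)")
})
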
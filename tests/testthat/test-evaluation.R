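# Results table shaped like the curated benchmark: 166 truth-A / 50 truth-B,
# with 162 true positives, 4 false negatives, 24 false positives.
curated_results <- function() {
  pmid <- as.character(1:216)
  truth <- setNames(rep(c("A", "B"), c(166, 50)), pmid)
  score <- c(rep(0.9, 162), rep(0.1, 4),    # truth A: 162 above, 4 below
             rep(0.9, 24), rep(0.1, 26))    # truth B: 24 above, 26 below
  list(results = data.frame(pmid = pmid, score = score,
                            stringsAsFactors = FALSE),
       truth = truth)
}

test_that("confusion counts reproduce the curated benchmark arithmetic", {
  cr <- curated_results()
  cc <- confusion(cr$results, cr$truth, 0.5)
  expect_equal(cc$TP, 162)
  expect_equal(cc$FP, 24)
  expect_equal(cc$TN, 26)
  expect_equal(cc$FN, 4)
  expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, 216)

  m <- precision_recall_fpr(cc)
  expect_equal(m$precision, 162 / 186, tolerance = 1e-12)
  # both readings of the 87% figure: positive predictive value and the
  # fraction of correct assignments (188/216)
  expect_equal(round(m$precision, 2), 0.87)
  expect_equal(round((cc$TP + cc$TN) / 216, 2), 0.87)
  expect_equal(mcc(cc), 0.6048104, tolerance = 1e-6)

  expect_error(confusion(cr$results, cr$truth[-1], 0.5), "no truth label")
})

test_that("confusion matches brute-force enumeration on random instances", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(5:100, 1)
    pmid <- as.character(seq_len(n))
    results <- data.frame(pmid = pmid,
                          score = round(runif(n), 2),
                          stringsAsFactors = FALSE)
    truth <- setNames(sample(c("A", "B"), n, TRUE), pmid)
    th <- sample(c(0, 0.3, 0.5, 0.9, 1), 1)
    got <- confusion(results, truth, th)
    want <- oracle_confusion(results, truth, th)
    expect_equal(unclass(got)[c("TP", "FP", "TN", "FN")], want,
                 ignore_attr = TRUE)
  }
})

test_that("undefined ratios are reported as NA, never zero", {
  m <- precision_recall_fpr(confusion_counts(TP = 0, FP = 0, TN = 10, FN = 0))
  expect_true(is.na(m$precision))
  expect_true(is.na(m$recall))
  expect_equal(m$fpr, 0)

  m <- precision_recall_fpr(confusion_counts(TP = 5, FP = 5, TN = 0, FN = 0))
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 1)
})

test_that("MCC has its fixed points and symmetry", {
  expect_equal(mcc(confusion_counts(TP = 7, FP = 0, TN = 9, FN = 0)), 1)
  expect_equal(mcc(confusion_counts(TP = 0, FP = 9, TN = 0, FN = 7)), -1)
  expect_equal(mcc(confusion_counts(TP = 0, FP = 0, TN = 0, FN = 0)), 0)
  expect_equal(mcc(confusion_counts(TP = 3, FP = 0, TN = 0, FN = 2)), 0)
  # swapping labels and predictions together leaves MCC unchanged
  set.seed(5)
  for (i in 1:10) {
    v <- as.list(sample(0:30, 4, TRUE))
    names(v) <- c("TP", "FP", "TN", "FN")
    swapped <- list(TP = v$TN, FP = v$FN, TN = v$TP, FN = v$FP)
    expect_equal(mcc(do.call(confusion_counts, v)),
                 mcc(do.call(confusion_counts, swapped)))
  }
})

test_that("threshold sweeps are monotone and hit the known anchor points", {
  cr <- curated_results()
  curve <- sweep_thresholds(cr$results, cr$truth, c(0, 0.5, 1))
  expect_equal(nrow(curve), 3)
  row <- curve[curve$threshold == 0.5, ]
  expect_equal(row$precision, 162 / 186, tolerance = 1e-12)
  expect_equal(row$mcc_x100, 60.48104, tolerance = 1e-4)
  # threshold above every score: nothing assigned A
  expect_equal(curve$recall[curve$threshold == 1], 0)

  # balanced truth at an admit-everything threshold: precision is the base
  # rate, exactly one half
  n <- 40
  res <- data.frame(pmid = as.character(1:n), score = runif(n, 0.1, 0.9))
  truth <- setNames(rep(c("A", "B"), n / 2), res$pmid)
  cc0 <- confusion(res, truth, 0)
  expect_equal(precision_recall_fpr(cc0)$precision, 0.5)
  expect_equal(precision_recall_fpr(cc0)$recall, 1)

  # recall and FPR never increase as the threshold rises (random sweeps)
  set.seed(31)
  for (i in 1:5) {
    n <- sample(20:80, 1)
    res <- data.frame(pmid = as.character(1:n), score = round(runif(n), 2))
    truth <- setNames(sample(c("A", "B"), n, TRUE), res$pmid)
    curve <- sweep_thresholds(res, truth)
    expect_true(all(diff(curve$recall) <= 1e-12))
    expect_true(all(diff(curve$fpr) <= 1e-12))
  }
})

test_that("majority vote resolves curator panels and flags disagreement", {
  ann <- data.frame(pmid = c("1", "2", "3"),
                    c1 = c("A", "A", "B"),
                    c2 = c("A", "A", "B"),
                    c3 = c("B", "A", "B"),
                    stringsAsFactors = FALSE)
  mv <- majority_vote(ann)
  expect_equal(mv$label, c("A", "A", "B"))
  expect_equal(mv$ambiguous, c(TRUE, FALSE, FALSE))

  expect_error(majority_vote(ann[, 1:3]), "odd")

  # panel arithmetic: 122 unanimous A + 30 unanimous B + 64 split (44 to A,
  # 20 to B) gives the 166/50 majority split
  lab <- function(n, a, b, c) data.frame(pmid = seq_len(n), c1 = a, c2 = b,
                                         c3 = c, stringsAsFactors = FALSE)
  panel <- rbind(lab(122, "A", "A", "A"), lab(30, "B", "B", "B"),
                 lab(44, "A", "A", "B"), lab(20, "B", "B", "A"))
  panel$pmid <- as.character(seq_len(216))
  mv <- majority_vote(panel)
  expect_equal(sum(mv$label == "A"), 166)
  expect_equal(sum(mv$label == "B"), 50)
  expect_equal(sum(mv$ambiguous), 64)
})

test_that("truth tables read in plain and curation form", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1\tA", "2\tB"), f)
  expect_equal(read_truth(f), c(`1` = "A", `2` = "B"))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1\tA\tA\tB", "2\tB\tB\tB"), f2)
  expect_equal(read_truth(f2), c(`1` = "A", `2` = "B"))
})
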
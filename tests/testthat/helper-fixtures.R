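# Shared fixtures and independent oracles, all built in code.

tiny_dictionary <- function() {
  keyword_dictionary(data.frame(
    surface_form = c("cyclin E", "cyclin", "phosphorylation", "p53",
                     "cancer", "kinase", "aurora"),
    term_id = c("t1", "t2", "a1", "g1", "d1", "g2", "g3"),
    term_type = c("gene_protein", "gene_protein", "bio_action",
                  "gene_protein", "disease", "gene_protein",
                  "gene_protein"),
    stringsAsFactors = FALSE))
}

# Independent longest-match oracle: normalizes text per the documented
# matching policy (lower-case, split on non-alphanumeric-hyphen), then walks
# the word sequence comparing against every dictionary key by prefix,
# taking the longest match at each position, non-overlapping.
oracle_tag <- function(text, dict) {
  words <- strsplit(gsub("[^a-z0-9-]+", " ", tolower(text)), " +")[[1]]
  words <- words[nzchar(words)]
  keys <- lapply(dict$surface_form, function(s) {
    w <- strsplit(gsub("[^a-z0-9-]+", " ", tolower(s)), " +")[[1]]
    w[nzchar(w)]
  })
  hits <- character(0)
  i <- 1
  while (i <= length(words)) {
    best_len <- 0
    best_terms <- character(0)
    for (k in seq_along(keys)) {
      kw <- keys[[k]]
      if (length(kw) >= best_len && i + length(kw) - 1 <= length(words) &&
          all(words[i:(i + length(kw) - 1)] == kw)) {
        if (length(kw) > best_len) {
          best_len <- length(kw)
          best_terms <- dict$term_id[k]
        } else {
          best_terms <- c(best_terms, dict$term_id[k])
        }
      }
    }
    if (best_len > 0) {
      hits <- c(hits, best_terms)
      i <- i + best_len
    } else {
      i <- i + 1
    }
  }
  if (length(hits) == 0) return(integer(0))
  tab <- table(hits)
  setNames(as.integer(tab), names(tab))
}

# Brute-force confusion oracle: one explicit loop over abstracts.
oracle_confusion <- function(results, truth, threshold) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(nrow(results))) {
    is_a <- truth[[results$pmid[i]]] == "A"
    pos <- results$score[i] > threshold
    if (pos && is_a) tp <- tp + 1L
    if (pos && !is_a) fp <- fp + 1L
    if (!pos && is_a) fn <- fn + 1L
    if (!pos && !is_a) tn <- tn + 1L
  }
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}

# Perfectly separable toy profiles: A abstracts mention only "aaa",
# B abstracts only "bbb".
separable_profiles <- function(n = 20) {
  a <- lapply(seq_len(n), function(i) {
    keyword_profile(c(aaa = 1L + i %% 3), pmid = i)
  })
  b <- lapply(seq_len(n), function(i) {
    keyword_profile(c(bbb = 1L + i %% 2), pmid = n + i)
  })
  list(a = setNames(a, seq_len(n)), b = setNames(b, n + seq_len(n)))
}

# A hand-built model with known weights, for exercising ranking contracts
# without fitting.
fake_model <- function(terms = c("x1", "x2"),
                       weights = setNames(c(1, -1), terms),
                       intercept = 0) {
  structure(list(
    weights = weights, intercept = intercept, chosen_C = 1,
    cv_accuracy = NA_real_, trace = NULL, refined = NA,
    test_set_accuracy = NA_real_,
    space = structure(list(terms = terms, V = length(terms)),
                      class = "feature_space"),
    cfg = solver_config(), seed = 1L, n_a = 0L, n_b = 0L,
    labels = NULL, pmids = NULL, fitted = NULL, call = NULL
  ), class = "litrank")
}
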
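test_that("dictionary compilation validates entries and preserves ambiguity", {
  expect_error(compile_dictionary(data.frame(surface_form = character(),
                                             term_id = character(),
                                             term_type = character())),
               "empty")

  dict <- tiny_dictionary()
  m <- compile_dictionary(dict)
  expect_s3_class(m, "keyword_matcher")
  expect_equal(m$max_len, 2)  # "cyclin E" is two tokens

  # duplicate (surface, term) pairs collapse with a warning
  expect_warning(compile_dictionary(rbind(dict, dict[1, ])), "duplicate")

  # one surface form, two term ids: both credited per occurrence
  amb <- keyword_dictionary(data.frame(
    surface_form = c("raf", "raf"), term_id = c("g_raf", "o_raf"),
    term_type = c("gene_protein", "organism"), stringsAsFactors = FALSE))
  prof <- tag_text(list(pmid = 1, body = "raf signalling and raf again"),
                   compile_dictionary(amb))
  expect_equal(prof[["g_raf"]], 2L)
  expect_equal(prof[["o_raf"]], 2L)

  # one term id, one type only
  expect_error(keyword_dictionary(data.frame(
    surface_form = c("x", "y"), term_id = c("t", "t"),
    term_type = c("disease", "drug"))), "more than one type")
})

test_that("tagging counts non-overlapping longest matches per term", {
  m <- compile_dictionary(tiny_dictionary())
  prof <- tag_text(list(pmid = 5, body = "p53 binds p53"), m)
  expect_equal(prof[["g1"]], 2L)

  # longest match wins: "cyclin E" suppresses the nested "cyclin"
  prof <- tag_text(list(pmid = 6, body = "cyclin E phosphorylation"), m)
  expect_equal(sort(names(prof)), c("a1", "t1"))
  expect_equal(unname(prof[c("t1", "a1")]), c(1L, 1L))

  # case-insensitive, title and body concatenated, punctuation split
  prof <- tag_text(list(pmid = 7, title = "P53 in CANCER:",
                        body = "the p53 axis? Cancer."), m)
  expect_equal(prof[["g1"]], 2L)
  expect_equal(prof[["d1"]], 2L)
  # hyphens stay inside tokens: "p53-cancer" is one token, matching nothing
  prof <- tag_text(list(pmid = 7, body = "the p53-cancer axis"), m)
  expect_length(prof, 0)

  # no text: legal empty profile
  prof <- tag_text(list(pmid = 8, title = "", body = ""), m)
  expect_length(prof, 0)
})

test_that("tagging matches the brute-force longest-match oracle", {
  dict <- tiny_dictionary()
  m <- compile_dictionary(dict)
  vocab <- c(dict$surface_form, "binds", "via", "the", "during", "mitosis")
  set.seed(7)
  for (i in 1:25) {
    text <- paste(sample(vocab, sample(3:30, 1), replace = TRUE),
                  collapse = " ")
    got <- tag_text(list(pmid = i, body = text), m)
    want <- oracle_tag(text, dict)
    expect_equal(unclass(got)[order(names(got))],
                 want[order(names(want))], ignore_attr = TRUE,
                 label = text)
  }
})

test_that("type selection filters after matching and protects core types", {
  m <- compile_dictionary(tiny_dictionary())
  rec <- list(pmid = 9, body = "p53 phosphorylation in cancer")
  full <- tag_text(rec, m)
  no_gene <- tag_text(rec, m, type_selection(disable = "gene_protein"))
  expect_false("g1" %in% names(no_gene))
  # disabling one type never changes the remaining counts
  shared <- intersect(names(full), names(no_gene))
  expect_equal(unclass(full)[shared], unclass(no_gene)[shared],
               ignore_attr = TRUE)

  expect_error(type_selection(disable = "bio_term"), "always used")
  expect_error(type_selection(disable = c("disease", "bio_action")),
               "always used")
  expect_setequal(type_selection(), KEYWORD_TYPES)
})

test_that("tagging is deterministic", {
  m <- compile_dictionary(tiny_dictionary())
  rec <- list(pmid = 1, body = "cyclin E and cyclin and p53 phosphorylation")
  expect_identical(tag_text(rec, m), tag_text(rec, m))
})

test_that("pre-tagged profiles load with type filtering and row validation", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1\tg1\tgene_protein\t2",
               "1\ta1\tbio_action\t1",
               "2\tg1\tgene_protein\t0",
               "2\td1\tdisease\t3"), f)
  expect_warning(profs <- load_pretagged(f), "non-positive")
  expect_length(profs, 2)
  expect_equal(unclass(profs[["1"]])[c("a1", "g1")], c(a1 = 1L, g1 = 2L),
               ignore_attr = TRUE)
  expect_equal(names(profs[["2"]]), "d1")

  profs <- suppressWarnings(
    load_pretagged(f, type_selection(disable = "disease")))
  expect_length(profs[["2"]], 0)

  # loaded profiles are interchangeable with tag_text output
  m <- compile_dictionary(tiny_dictionary())
  tagged <- tag_text(list(pmid = "1", body = "p53 phosphorylation p53"), m)
  expect_equal(unclass(tagged)[order(names(tagged))],
               unclass(profs[["1"]])[order(names(profs[["1"]]))],
               ignore_attr = TRUE)
})

test_that("pre-tagged round-trip preserves profiles and mean keyword load", {
  w <- generate_world(delta = 0.5, n_per_topic = c(10, 10), vocab_size = 60,
                      mean_keywords = 32, seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  type_of <- setNames(w$dictionary$term_type, w$dictionary$term_id)
  write_pretagged(w$profiles, type_of, f)
  back <- load_pretagged(f)
  nonempty <- names(w$profiles)[lengths(w$profiles) > 0]
  expect_setequal(names(back), nonempty)
  for (p in nonempty) {
    expect_equal(unclass(back[[p]])[order(names(back[[p]]))],
                 unclass(w$profiles[[p]])[order(names(w$profiles[[p]]))],
                 ignore_attr = TRUE)
  }
  mean_kw <- mean(vapply(back, sum, 0))
  expect_gt(mean_kw, 25)  # Poisson(32) over 20 abstracts
})
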
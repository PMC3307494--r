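#' Keyword types of the dictionary
#'
#' Every canonical term carries exactly one of these types.  The two
#' "general biological" types, \code{bio_term} and \code{bio_action}, are
#' always enabled and cannot be disabled; the remaining types are
#' user-selectable.
#'
#' @format Character vector of the nine recognized keyword types.
#' @export
KEYWORD_TYPES <- c("gene_protein", "chemical", "disease", "drug", "symptom",
                   "organism", "bio_term", "bio_action", "other_bio")

#' Always-enabled keyword types
#' @format Character vector of the two types that cannot be disabled.
#' @export
ALWAYS_ENABLED_TYPES <- c("bio_term", "bio_action")

#' Select which keyword types are used
#'
#' @param disable character vector of types to switch off.  Disabling
#'   \code{bio_term} or \code{bio_action} is refused.
#' @return Character vector of enabled types, class \code{"type_selection"}.
#' @export
type_selection <- function(disable = character()) {
  if (length(disable)) {
    disable <- match.arg(disable, KEYWORD_TYPES, several.ok = TRUE)
    bad <- intersect(disable, ALWAYS_ENABLED_TYPES)
    if (length(bad)) {
      lr_stop("keyword type(s) %s are always used and cannot be disabled",
              paste(bad, collapse = ", "))
    }
  }
  structure(setdiff(KEYWORD_TYPES, disable), class = "type_selection")
}

#' Read a typed keyword dictionary
#'
#' @param path headerless TSV \code{surface_form<TAB>term_id<TAB>term_type}.
#' @return Data frame with those three columns, class
#'   \code{"keyword_dictionary"}.
#' @export
read_dictionary <- function(path) {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  if (ncol(df) < 3) lr_stop("dictionary %s needs three columns", path)
  names(df)[1:3] <- c("surface_form", "term_id", "term_type")
  keyword_dictionary(df[, 1:3])
}

#' Construct a keyword dictionary
#'
#' @param entries data frame with columns \code{surface_form},
#'   \code{term_id}, \code{term_type}.
#' @return The validated data frame, class \code{"keyword_dictionary"}.
#' @export
keyword_dictionary <- function(entries) {
  stopifnot(all(c("surface_form", "term_id", "term_type") %in%
                  names(entries)))
  if (any(!nzchar(entries$surface_form))) {
    lr_stop("dictionary surface forms must be non-empty")
  }
  bad <- setdiff(unique(entries$term_type), KEYWORD_TYPES)
  if (length(bad)) {
    lr_stop("unknown keyword type(s): %s", paste(bad, collapse = ", "))
  }
  # each canonical term has exactly one type
  tt <- unique(entries[, c("term_id", "term_type")])
  if (anyDuplicated(tt$term_id)) {
    lr_stop("term_id(s) mapped to more than one type: %s",
            paste(unique(tt$term_id[duplicated(tt$term_id)]), collapse = ", "))
  }
  structure(as.data.frame(entries[, c("surface_form", "term_id", "term_type")],
                          stringsAsFactors = FALSE),
            class = c("keyword_dictionary", "data.frame"))
}

# Tokenization used on both dictionary surface forms and abstract text:
# lower-case, split on anything that is not a letter, digit or hyphen, so
# hyphens stay inside tokens ("G1-phase" is one token).
lr_tokenize <- function(text) {
  text <- tolower(text)
  toks <- strsplit(gsub("[^a-z0-9-]+", " ", text), " +")[[1]]
  toks[nzchar(toks)]
}

#' Compile a dictionary into a matcher
#'
#' Surface forms are tokenized; the matcher recognizes multi-word forms by
#' token sequence.  Compilation is deterministic given entry order.
#' Duplicate (surface form, term ID) pairs are collapsed with a warning; a
#' surface form mapped to several term IDs keeps all of them, so ambiguity
#' is preserved and every mapped term is credited per occurrence.
#'
#' @param entries a [keyword_dictionary()] (or coercible data frame).
#' @return An object of class \code{"keyword_matcher"}.
#' @export
compile_dictionary <- function(entries) {
  if (NROW(entries) == 0) lr_stop("cannot compile an empty dictionary")
  entries <- keyword_dictionary(entries)
  dup <- duplicated(entries[, c("surface_form", "term_id")])
  if (any(dup)) {
    lr_warn("collapsed %d duplicate (surface form, term) pair(s)", sum(dup))
    entries <- entries[!dup, , drop = FALSE]
  }
  keys <- vapply(entries$surface_form,
                 function(s) paste(lr_tokenize(s), collapse = " "), "")
  if (any(!nzchar(keys))) {
    lr_stop("surface form(s) tokenize to nothing: %s",
            paste(entries$surface_form[!nzchar(keys)], collapse = ", "))
  }
  map <- new.env(parent = emptyenv(), size = nrow(entries))
  for (i in seq_len(nrow(entries))) {
    map[[keys[i]]] <- c(map[[keys[i]]], entries$term_id[i])
  }
  type_of <- entries$term_type[!duplicated(entries$term_id)]
  names(type_of) <- entries$term_id[!duplicated(entries$term_id)]
  max_len <- max(lengths(strsplit(keys, " ", fixed = TRUE)))
  structure(list(map = map, max_len = max_len, type_of = type_of,
                 n_forms = length(unique(keys))),
            class = "keyword_matcher")
}

#' @export
print.keyword_matcher <- function(x, ...) {
  cat(sprintf("Keyword matcher: %d surface form(s), %d term(s), max %d token(s)\n",
              x$n_forms, length(x$type_of), x$max_len))
  invisible(x)
}

#' Tag abstract text into a keyword profile
#'
#' Title and body are concatenated and scanned left to right with
#' case-insensitive, token-boundary-anchored, longest-match, non-overlapping
#' matching.  Counts are per canonical term ID (surface variants pooled);
#' each occurrence of an ambiguous surface form credits all mapped term IDs.
#' Terms whose type is not enabled are removed after matching, so disabling
#' a type never changes the counts of the remaining types.
#'
#' @param record a list or one-row data frame with \code{title} and/or
#'   \code{body} fields (missing or empty text yields an empty profile).
#' @param matcher a compiled [compile_dictionary()] matcher.
#' @param selection a [type_selection()].
#' @return Named integer vector of occurrence counts by term ID, with the
#'   record's \code{pmid} kept in attribute \code{"pmid"}; class
#'   \code{"keyword_profile"}.
#' @export
tag_text <- function(record, matcher, selection = type_selection()) {
  stopifnot(inherits(matcher, "keyword_matcher"))
  title <- if (!is.null(record$title)) record$title else ""
  body <- if (!is.null(record$body)) record$body else ""
  toks <- lr_tokenize(paste(title, body))
  hits <- character(0)
  i <- 1L
  n <- length(toks)
  while (i <= n) {
    matched <- 0L
    for (len in seq(min(matcher$max_len, n - i + 1L), 1L)) {
      key <- paste(toks[i:(i + len - 1L)], collapse = " ")
      ids <- matcher$map[[key]]
      if (!is.null(ids)) {
        hits <- c(hits, ids)
        matched <- len
        break
      }
    }
    i <- i + max(matched, 1L)
  }
  counts <- if (length(hits)) {
    tab <- table(hits)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(integer(0), character(0))
  }
  keep <- matcher$type_of[names(counts)] %in% selection
  counts <- counts[keep]
  keyword_profile(counts, pmid = record$pmid)
}

#' Construct a keyword profile
#'
#' @param counts named vector of strictly positive occurrence counts by
#'   term ID (an empty profile is legal).
#' @param pmid the abstract's PubMed ID.
#' @return Named integer vector of class \code{"keyword_profile"}.
#' @export
keyword_profile <- function(counts, pmid) {
  counts <- stats::setNames(as.integer(counts), names(counts))
  if (any(counts <= 0)) lr_stop("profile counts must be strictly positive")
  structure(counts, pmid = as.character(pmid), class = "keyword_profile")
}

#' Tag every record of a corpus
#'
#' @param corpus an \code{abstract_corpus} data frame.
#' @inheritParams tag_text
#' @return Named list of [keyword_profile()]s, names are PMIDs.
#' @export
tag_corpus <- function(corpus, matcher, selection = type_selection()) {
  out <- lapply(seq_len(nrow(corpus)), function(i) {
    tag_text(corpus[i, , drop = FALSE], matcher, selection)
  })
  names(out) <- corpus$pmid
  out
}

#' Load pre-tagged keyword profiles
#'
#' Reads a headerless TSV \code{pmid<TAB>term_id<TAB>term_type<TAB>count}.
#' The type filter is applied at load time, so loaded profiles are usable
#' interchangeably with [tag_text()] output.  Rows with non-positive counts
#' are rejected with a warning.
#'
#' @param path file path.
#' @param selection a [type_selection()].
#' @return Named list of [keyword_profile()]s, names are PMIDs.
#' @export
load_pretagged <- function(path, selection = type_selection()) {
  if (file.size(path) == 0) {
    lr_warn("empty pre-tagged file %s", path)
    return(stats::setNames(list(), character(0)))
  }
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  if (ncol(df) < 4) lr_stop("pre-tagged file %s needs four columns", path)
  names(df)[1:4] <- c("pmid", "term_id", "term_type", "count")
  df$count <- suppressWarnings(as.integer(df$count))
  bad <- is.na(df$count) | df$count <= 0
  if (any(bad)) {
    lr_warn("rejected %d pre-tagged row(s) with non-positive count", sum(bad))
    df <- df[!bad, , drop = FALSE]
  }
  df <- df[df$term_type %in% selection, , drop = FALSE]
  pmids <- unique(df$pmid)
  out <- lapply(pmids, function(p) {
    sub <- df[df$pmid == p, , drop = FALSE]
    counts <- tapply(sub$count, sub$term_id, sum)
    keyword_profile(stats::setNames(as.integer(counts), names(counts)),
                    pmid = p)
  })
  stats::setNames(out, pmids)
}

#' Write keyword profiles as a pre-tagged TSV
#'
#' @param profiles named list of [keyword_profile()]s.
#' @param type_of named character vector mapping term IDs to keyword types.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_pretagged <- function(profiles, type_of, path) {
  rows <- unlist(lapply(names(profiles), function(p) {
    prof <- profiles[[p]]
    if (length(prof) == 0) return(character(0))
    paste(p, names(prof), type_of[names(prof)], as.integer(prof), sep = "\t")
  }))
  writeLines(rows, path)
  invisible(path)
}
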
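#' Identifier kinds accepted in input lists
#'
#' Input lists are declared to contain one of these kinds.  Numeric tokens are
#' never auto-classified: an Entrez gene ID is indistinguishable from a PubMed
#' ID by its digits alone, so the kind must be stated per list.
#'
#' @format A character vector of the four recognized kinds.
#' @export
ID_KINDS <- c("ensembl_gene", "entrez_gene", "pubmed_id", "pubmed_query")

#' Parse and clean an identifier list
#'
#' Validates each token against the declared identifier kind.  Ensembl gene
#' IDs must match the \code{ENSG}-prefixed pattern; Entrez gene and PubMed IDs
#' must be positive integers; PubMed queries need only be non-empty text.
#' Malformed tokens are dropped with a warning; order is preserved.
#'
#' @param tokens character vector of raw input tokens.
#' @param declared_kind one of [ID_KINDS]; never inferred from token shape.
#' @return A data frame with columns \code{raw_token} and \code{id_kind},
#'   class \code{"identifier_list"}.
#' @export
parse_identifier_list <- function(tokens, declared_kind) {
  declared_kind <- match.arg(declared_kind, ID_KINDS)
  if (length(tokens) == 0) lr_stop("empty identifier list")
  tokens <- trimws(as.character(tokens))
  ok <- switch(declared_kind,
    ensembl_gene = grepl("^ENSG[0-9]+$", tokens),
    entrez_gene  = grepl("^[0-9]+$", tokens) & tokens != "0",
    pubmed_id    = grepl("^[0-9]+$", tokens) & tokens != "0",
    pubmed_query = nzchar(tokens)
  )
  if (any(!ok)) {
    lr_warn("dropped %d malformed %s token(s): %s", sum(!ok), declared_kind,
            paste(utils::head(tokens[!ok], 5), collapse = ", "))
  }
  kept <- tokens[ok]
  if (length(kept) == 0) {
    lr_stop("no usable %s identifiers after clean-up", declared_kind,
            class = "litrank_unusable_set")
  }
  structure(
    data.frame(raw_token = kept, id_kind = declared_kind,
               stringsAsFactors = FALSE),
    class = c("identifier_list", "data.frame")
  )
}

#' Construct a document set
#'
#' A document set is an ordered list of PMIDs labelled A (interesting
#' training set), B (background training set) or C (query set).  Duplicates
#' and overlaps with other sets are deliberately preserved: repeated entries
#' are a user-level device for weighting imbalanced inputs.
#'
#' @param pmids character or integer vector of PubMed IDs.
#' @param label one of \code{"A"}, \code{"B"}, \code{"C"}.
#' @return An object of class \code{"document_set"}.
#' @export
document_set <- function(pmids, label = c("A", "B", "C")) {
  label <- match.arg(label)
  structure(list(label = label, pmids = as.character(pmids)),
            class = "document_set")
}

#' @export
print.document_set <- function(x, ...) {
  cat(sprintf("Document set %s: %d abstract(s)\n", x$label, length(x$pmids)))
  invisible(x)
}

#' @export
length.document_set <- function(x) length(x$pmids)

#' Gene-to-literature link tables
#'
#' Holds the mapping tables used to expand gene identifiers into abstracts:
#' Entrez gene to PMIDs (GeneRIF- and interaction-derived links included),
#' Ensembl gene to Entrez gene (one-to-many mappings retained in full), and
#' an optional PubMed-query to PMID-list resolution table for query inputs.
#'
#' @param entrez_to_pmids named list: Entrez gene ID -> character vector of
#'   PMIDs (a gene may map to zero abstracts).
#' @param ensembl_to_entrez named list: ENSG ID -> character vector of Entrez
#'   gene IDs.
#' @param query_to_pmids named list: query string -> character vector of
#'   PMIDs (fixture-resolved; no live retrieval is performed).
#' @return An object of class \code{"gene_link_table"}.
#' @export
gene_link_table <- function(entrez_to_pmids = list(),
                            ensembl_to_entrez = list(),
                            query_to_pmids = list()) {
  structure(list(entrez_to_pmids = entrez_to_pmids,
                 ensembl_to_entrez = ensembl_to_entrez,
                 query_to_pmids = query_to_pmids),
            class = "gene_link_table")
}

#' Read gene link tables from TSV files
#'
#' @param entrez_pmid_path two-column TSV \code{entrez<TAB>pmid}, one link
#'   per row, no header.
#' @param ensg_entrez_path optional two-column TSV \code{ensg<TAB>entrez}.
#' @return A [gene_link_table()].
#' @export
read_gene_links <- function(entrez_pmid_path, ensg_entrez_path = NULL) {
  read_pairs <- function(path) {
    df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                            quote = "", comment.char = "")
    if (ncol(df) < 2) lr_stop("link table %s needs two columns", path)
    split(df[[2]], factor(df[[1]], levels = unique(df[[1]])))
  }
  e2p <- if (file.size(entrez_pmid_path) > 0) read_pairs(entrez_pmid_path) else list()
  g2e <- if (!is.null(ensg_entrez_path) && file.size(ensg_entrez_path) > 0) {
    read_pairs(ensg_entrez_path)
  } else {
    list()
  }
  gene_link_table(entrez_to_pmids = e2p, ensembl_to_entrez = g2e)
}

#' Expand identifiers to a document set of abstracts
#'
#' Ensembl gene IDs are first translated to all matching Entrez gene IDs (a
#' one-to-many mapping contributes every target), then each Entrez gene
#' contributes every PMID linked in the table.  PubMed IDs pass through
#' unchanged; PubMed queries are resolved through the fixture table.  Output
#' order follows input order, then link-table order; duplicates are retained.
#' Genes without mappings or abstracts contribute nothing, with a warning.
#'
#' @param ids an \code{identifier_list} from [parse_identifier_list()].
#' @param links a [gene_link_table()].
#' @param label label for the resulting [document_set()].
#' @return A [document_set()].
#' @export
expand_to_abstracts <- function(ids, links = gene_link_table(),
                                label = c("A", "B", "C")) {
  label <- match.arg(label)
  stopifnot(inherits(links, "gene_link_table"))
  entrez_pmids <- function(eid) {
    pm <- links$entrez_to_pmids[[eid]]
    if (is.null(pm) || length(pm) == 0) {
      lr_warn("Entrez gene %s has no linked abstracts", eid)
      character(0)
    } else {
      as.character(pm)
    }
  }
  out <- vector("list", nrow(ids))
  for (i in seq_len(nrow(ids))) {
    tok <- ids$raw_token[i]
    out[[i]] <- switch(ids$id_kind[i],
      pubmed_id = tok,
      entrez_gene = entrez_pmids(tok),
      ensembl_gene = {
        eids <- links$ensembl_to_entrez[[tok]]
        if (is.null(eids) || length(eids) == 0) {
          lr_warn("Ensembl gene %s has no Entrez mapping", tok)
          character(0)
        } else {
          unlist(lapply(as.character(eids), entrez_pmids), use.names = FALSE)
        }
      },
      pubmed_query = {
        pm <- links$query_to_pmids[[tok]]
        if (is.null(pm)) {
          lr_warn("query '%s' has no fixture resolution", tok)
          character(0)
        } else {
          as.character(pm)
        }
      }
    )
  }
  pmids <- unlist(out, use.names = FALSE)
  if (length(pmids) == 0) {
    lr_stop("set %s expanded to zero abstracts", label,
            class = "litrank_unusable_set")
  }
  document_set(pmids, label)
}

#' Enforce the per-input size cap
#'
#' Every input field is limited to a maximum number of entries (genes or
#' abstracts); a larger list is refused outright and the user is asked to
#' reduce it.  The default cap is 25,000.
#'
#' @param x a [document_set()], an \code{identifier_list}, or a plain vector.
#' @param cap maximum number of entries allowed.
#' @return \code{x}, unchanged, if within the cap.
#' @export
enforce_input_cap <- function(x, cap = 25000L) {
  stopifnot(cap > 0)
  n <- if (inherits(x, "document_set")) {
    length(x$pmids)
  } else if (is.data.frame(x)) {
    nrow(x)
  } else {
    length(x)
  }
  if (n > cap) {
    lr_stop(paste0("input has %d entries, above the maximum of %d; ",
                   "please reduce the corresponding list's size"),
            n, cap, class = "litrank_cap_exceeded")
  }
  x
}

#' Read an abstract corpus
#'
#' Supported formats: \code{fixture_tsv} (headerless
#' \code{pmid<TAB>title<TAB>body}), \code{fixture_json} (array of objects
#' with fields \code{pmid}, \code{title}, \code{body}), and
#' \code{medline_text} (records with \code{PMID-}, \code{TI  -} and
#' \code{AB  -} tags, continuation lines indented).  Title-only records are
#' retained with an empty body, as some PubMed entries contain only titles.
#' Duplicate PMIDs within one file: last occurrence wins, with a warning.
#'
#' @param path file path.
#' @param format one of \code{"fixture_tsv"}, \code{"fixture_json"},
#'   \code{"medline_text"}.
#' @return A data frame with character columns \code{pmid}, \code{title},
#'   \code{body}, class \code{"abstract_corpus"}.
#' @export
read_corpus <- function(path,
                        format = c("fixture_tsv", "fixture_json",
                                   "medline_text")) {
  format <- match.arg(format)
  df <- switch(format,
    fixture_tsv = {
      if (file.size(path) == 0) {
        lr_warn("empty corpus file %s", path)
        data.frame(pmid = character(), title = character(),
                   body = character(), stringsAsFactors = FALSE)
      } else {
        raw <- readLines(path, warn = FALSE)
        parts <- strsplit(raw, "\t", fixed = TRUE)
        bad <- vapply(parts, length, 0L) < 1
        if (any(bad)) lr_warn("skipped %d unparseable corpus row(s)", sum(bad))
        parts <- parts[!bad]
        data.frame(
          pmid  = vapply(parts, `[`, "", 1),
          title = vapply(parts, function(p) if (length(p) >= 2) p[2] else "", ""),
          body  = vapply(parts, function(p) if (length(p) >= 3) p[3] else "", ""),
          stringsAsFactors = FALSE
        )
      }
    },
    fixture_json = {
      recs <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
      if (length(recs) == 0 || NROW(recs) == 0) {
        lr_warn("empty corpus file %s", path)
        data.frame(pmid = character(), title = character(),
                   body = character(), stringsAsFactors = FALSE)
      } else {
        data.frame(
          pmid  = as.character(recs$pmid),
          title = if (!is.null(recs$title)) ifelse(is.na(recs$title), "", recs$title) else "",
          body  = if (!is.null(recs$body)) ifelse(is.na(recs$body), "", recs$body) else "",
          stringsAsFactors = FALSE
        )
      }
    },
    medline_text = read_medline(path)
  )
  dup <- duplicated(df$pmid, fromLast = TRUE)
  if (any(dup)) {
    lr_warn("duplicate PMID(s) in %s; last record wins: %s", path,
            paste(unique(df$pmid[dup]), collapse = ", "))
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  structure(df, class = c("abstract_corpus", "data.frame"))
}

# Minimal Medline text reader: PMID- / TI  - / AB  - tags, continuation lines
# indented with spaces.  Records lacking an abstract keep an empty body.
read_medline <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  cur <- NULL
  field <- NULL
  flush <- function(cur) {
    if (is.null(cur) || is.null(cur$pmid) || !nzchar(cur$pmid)) return(NULL)
    data.frame(pmid = cur$pmid,
               title = trimws(paste(cur$ti, collapse = " ")),
               body = trimws(paste(cur$ab, collapse = " ")),
               stringsAsFactors = FALSE)
  }
  for (ln in lines) {
    if (grepl("^PMID-", ln)) {
      r <- flush(cur)
      if (!is.null(r)) recs[[length(recs) + 1L]] <- r
      cur <- list(pmid = trimws(sub("^PMID-", "", ln)),
                  ti = character(), ab = character())
      field <- NULL
    } else if (is.null(cur)) {
      next
    } else if (grepl("^TI  -", ln)) {
      cur$ti <- c(cur$ti, trimws(sub("^TI  -", "", ln)))
      field <- "ti"
    } else if (grepl("^AB  -", ln)) {
      cur$ab <- c(cur$ab, trimws(sub("^AB  -", "", ln)))
      field <- "ab"
    } else if (grepl("^ {4,}", ln) && !is.null(field)) {
      cur[[field]] <- c(cur[[field]], trimws(ln))
    } else {
      field <- NULL
    }
  }
  r <- flush(cur)
  if (!is.null(r)) recs[[length(recs) + 1L]] <- r
  if (length(recs) == 0) {
    lr_warn("no parseable Medline records in %s", path)
    return(data.frame(pmid = character(), title = character(),
                      body = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, recs)
}

#' Write an abstract corpus
#'
#' Inverse of [read_corpus()] for the fixture formats; round-tripping
#' reproduces record content exactly.
#'
#' @param corpus an \code{abstract_corpus} data frame.
#' @param path output file path.
#' @param format \code{"fixture_tsv"} or \code{"fixture_json"}.
#' @return \code{path}, invisibly.
#' @export
write_corpus <- function(corpus, path,
                         format = c("fixture_tsv", "fixture_json")) {
  format <- match.arg(format)
  if (format == "fixture_tsv") {
    writeLines(paste(corpus$pmid, corpus$title, corpus$body, sep = "\t"),
               path)
  } else {
    jsonlite::write_json(
      data.frame(pmid = corpus$pmid, title = corpus$title,
                 body = corpus$body, stringsAsFactors = FALSE),
      path, auto_unbox = TRUE)
  }
  invisible(path)
}
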
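#' Sample a random background set B
#'
#' When only an interesting set A is given, set B is filled automatically
#' with the same number of abstracts as expanded from A, sampled without
#' replacement from the indexed corpus excluding A's abstracts.  Seeded and
#' deterministic.
#'
#' @param set_a a [document_set()] of A's expanded abstracts.
#' @param universe character vector of all indexed PMIDs.
#' @param seed integer seed.
#' @return A [document_set()] labelled B, disjoint from A.
#' @export
sample_random_background <- function(set_a, universe, seed = 1L) {
  stopifnot(inherits(set_a, "document_set"))
  pool <- setdiff(unique(as.character(universe)), set_a$pmids)
  n <- length(set_a$pmids)
  if (length(pool) < n) {
    lr_stop("universe has only %d abstracts outside set A; %d needed",
            length(pool), n)
  }
  pmids <- with_seed(seed, sample(pool, n))
  document_set(pmids, "B")
}

#' Default query set C: the whole indexed corpus
#'
#' When the user gives no set C, every abstract indexed with keywords is
#' ranked — including the abstracts of sets A and B.  The report then shows
#' only abstracts above the high-score cutoff instead of the full listing.
#'
#' @param indexed named list of keyword profiles (or an
#'   \code{abstract_corpus}); its PMIDs define the index.
#' @return A [document_set()] labelled C.
#' @export
default_setC <- function(indexed) {
  pmids <- if (inherits(indexed, "abstract_corpus")) {
    indexed$pmid
  } else {
    names(indexed)
  }
  if (length(pmids) == 0) lr_stop("indexed corpus is empty")
  document_set(pmids, "C")
}

#' Classify and rank the query set
#'
#' Scores every vector with the model's probability of set A.  An abstract
#' is assigned to A iff its score is strictly greater than the threshold
#' (a score exactly at the threshold goes to B); the A list is sorted by
#' descending score so the most A-like abstracts lead, the B list by
#' ascending score so the most confident B abstracts lead, with ascending
#' PMID as the deterministic tie-break.  Ranks are 1-based within each
#' assignment list.
#'
#' @param model a fitted [litrank()] model.
#' @param profiles_c named list of [keyword_profile()]s (or a matrix over
#'   the model's feature space) for set C.
#' @param threshold assignment threshold, default 0.5.
#' @return Data frame of class \code{"ranked_results"} with columns
#'   \code{pmid}, \code{score}, \code{assignment}, \code{rank}; A block
#'   first, then B block.
#' @export
classify_and_rank <- function(model, profiles_c, threshold = 0.5) {
  score <- predict(model, profiles_c, type = "response")
  pmid <- names(score)
  assignment <- ifelse(score > threshold, "A", "B")
  df <- data.frame(pmid = pmid, score = unname(score),
                   assignment = assignment, stringsAsFactors = FALSE)
  a <- df[df$assignment == "A", , drop = FALSE]
  b <- df[df$assignment == "B", , drop = FALSE]
  a <- a[order(-a$score, a$pmid, method = "radix"), , drop = FALSE]
  b <- b[order(b$score, b$pmid, method = "radix"), , drop = FALSE]
  a$rank <- seq_len(nrow(a))
  b$rank <- seq_len(nrow(b))
  out <- rbind(a, b)
  rownames(out) <- NULL
  structure(out, class = c("ranked_results", "data.frame"))
}

#' Job configuration
#'
#' Bundles the inputs and settings of one ranking job.  Set inputs are
#' token vectors with a declared identifier kind each; data inputs may be
#' in-memory objects or file paths (resolved by [run_job()]).
#'
#' @param set_a,set_b,set_c character vectors of input tokens (\code{set_b}
#'   and \code{set_c} may be \code{NULL}: B is then sampled at random from
#'   the index and C defaults to the whole index).
#' @param kind_a,kind_b,kind_c identifier kinds, see [ID_KINDS].
#' @param corpus an \code{abstract_corpus}, a path to one, or \code{NULL}
#'   when \code{pretagged} is given.
#' @param dictionary a [keyword_dictionary()] or path; required with
#'   \code{corpus}.
#' @param pretagged named list of keyword profiles or path to a pre-tagged
#'   TSV; alternative to tagging \code{corpus} text.
#' @param links a [gene_link_table()] (or \code{NULL} for abstract-only
#'   inputs).
#' @param disable_types keyword types to disable (see [type_selection()]).
#' @param threshold assignment threshold, default 0.5 (strict).
#' @param cutoff high-score report cutoff for whole-index mode, default
#'   0.85.
#' @param input_cap per-input size cap, default 25000.
#' @param seed integer seed for background sampling and fold assignment.
#' @param cfg a [solver_config()].
#' @param exclude_training_from_c drop training PMIDs from set C before
#'   classification (the evaluation variant).
#' @return Object of class \code{"job_config"}.
#' @export
job_config <- function(set_a, kind_a = "pubmed_id",
                       set_b = NULL, kind_b = "pubmed_id",
                       set_c = NULL, kind_c = "pubmed_id",
                       corpus = NULL, dictionary = NULL, pretagged = NULL,
                       links = NULL, disable_types = character(),
                       threshold = 0.5, cutoff = 0.85, input_cap = 25000L,
                       seed = 1L, cfg = solver_config(),
                       exclude_training_from_c = FALSE) {
  stopifnot(threshold > 0, threshold < 1, cutoff > 0, cutoff < 1,
            input_cap > 0)
  structure(list(set_a = set_a, kind_a = kind_a, set_b = set_b,
                 kind_b = kind_b, set_c = set_c, kind_c = kind_c,
                 corpus = corpus, dictionary = dictionary,
                 pretagged = pretagged, links = links,
                 disable_types = disable_types, threshold = threshold,
                 cutoff = cutoff, input_cap = as.integer(input_cap),
                 seed = as.integer(seed), cfg = cfg,
                 exclude_training_from_c = exclude_training_from_c),
            class = "job_config")
}

#' Read a job configuration from YAML
#'
#' All [job_config()] fields may be given; \code{corpus}, \code{dictionary},
#' \code{pretagged} and link-table entries are file paths.
#'
#' @param path YAML file.
#' @return A [job_config()] (data fields still as paths).
#' @export
read_job_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    lr_stop("the yaml package is required to read YAML job configs")
  }
  y <- yaml::read_yaml(path)
  links <- if (!is.null(y$entrez_pmid) || !is.null(y$ensg_entrez)) {
    read_gene_links(y$entrez_pmid, y$ensg_entrez)
  } else {
    NULL
  }
  job_config(
    set_a = as.character(y$set_a),
    kind_a = y$kind_a %||% "pubmed_id",
    set_b = if (!is.null(y$set_b)) as.character(y$set_b),
    kind_b = y$kind_b %||% "pubmed_id",
    set_c = if (!is.null(y$set_c)) as.character(y$set_c),
    kind_c = y$kind_c %||% "pubmed_id",
    corpus = y$corpus, dictionary = y$dictionary, pretagged = y$pretagged,
    links = links,
    disable_types = as.character(y$disable_types %||% character()),
    threshold = y$threshold %||% 0.5,
    cutoff = y$cutoff %||% 0.85,
    input_cap = y$input_cap %||% 25000L,
    seed = y$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage: %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run a full ranking job
#'
#' Executes the workflow end to end: (0) input parsing and size caps, (1)
#' identifier expansion and set assembly (with random-background B and
#' whole-index C defaults), (2) tagging and vectorization, (3) penalty
#' tuning and training, (4) classification and ranking, (5) report
#' assembly.  Any stage error aborts with a stage-labelled message.  The
#' run is deterministic under a fixed seed and configuration.
#'
#' @param cfg a [job_config()].
#' @return Object of class \code{"job_report"}: set sizes, CV accuracy,
#'   test-set accuracy, chosen C with trace, the full ranked table, the top
#'   A and top B lists, the fitted model, and a config echo.
#' @export
run_job <- function(cfg) {
  stopifnot(inherits(cfg, "job_config"))
  selection <- type_selection(disable = cfg$disable_types)

  # stage 0: input
  ids_a <- stage("input", {
    enforce_input_cap(parse_identifier_list(cfg$set_a, cfg$kind_a),
                      cfg$input_cap)
  })
  ids_b <- if (!is.null(cfg$set_b)) {
    stage("input", enforce_input_cap(
      parse_identifier_list(cfg$set_b, cfg$kind_b), cfg$input_cap))
  }
  ids_c <- if (!is.null(cfg$set_c)) {
    stage("input", enforce_input_cap(
      parse_identifier_list(cfg$set_c, cfg$kind_c), cfg$input_cap))
  }

  # stage 2 resources are needed for set-assembly defaults, so load first
  res <- stage("processing", {
    profiles <- if (!is.null(cfg$pretagged)) {
      if (is.character(cfg$pretagged)) {
        load_pretagged(cfg$pretagged, selection)
      } else {
        cfg$pretagged
      }
    } else {
      corpus <- if (is.character(cfg$corpus)) read_corpus(cfg$corpus) else cfg$corpus
      dict <- if (is.character(cfg$dictionary)) {
        read_dictionary(cfg$dictionary)
      } else {
        cfg$dictionary
      }
      if (is.null(corpus) || is.null(dict)) {
        lr_stop("either pretagged profiles or corpus + dictionary required")
      }
      tag_corpus(corpus, compile_dictionary(dict), selection)
    }
    profiles
  })
  links <- cfg$links %||% gene_link_table()

  # stage 1: collection
  sets <- stage("collection", {
    set_a <- enforce_input_cap(expand_to_abstracts(ids_a, links, "A"),
                               cfg$input_cap)
    set_b <- if (!is.null(ids_b)) {
      enforce_input_cap(expand_to_abstracts(ids_b, links, "B"),
                        cfg$input_cap)
    } else {
      sample_random_background(set_a, names(res), cfg$seed)
    }
    whole_index <- is.null(ids_c)
    set_c <- if (!whole_index) {
      enforce_input_cap(expand_to_abstracts(ids_c, links, "C"),
                        cfg$input_cap)
    } else {
      default_setC(res)
    }
    if (cfg$exclude_training_from_c) {
      keep <- !(set_c$pmids %in% c(set_a$pmids, set_b$pmids))
      set_c <- document_set(set_c$pmids[keep], "C")
    }
    list(a = set_a, b = set_b, c = set_c, whole_index = whole_index)
  })

  pick <- function(ds) {
    miss <- setdiff(ds$pmids, names(res))
    if (length(miss)) {
      lr_warn("set %s: %d PMID(s) not in the keyword index, dropped",
              ds$label, length(miss))
    }
    res[ds$pmids[ds$pmids %in% names(res)]]
  }
  prof_a <- stage("processing", pick(sets$a))
  prof_b <- stage("processing", pick(sets$b))
  prof_c <- stage("processing", pick(sets$c))
  if (length(prof_a) == 0 || length(prof_b) == 0) {
    stop("[stage: processing] a training set has no indexed abstracts",
         call. = FALSE)
  }

  # stages 3-4: training, classification
  model <- stage("training", litrank(prof_a, prof_b, cfg$cfg, cfg$seed))
  ranked <- stage("classification",
                  classify_and_rank(model, prof_c, cfg$threshold))

  # stage 5: results
  stage("results", {
    if (sets$whole_index) {
      top_a <- ranked[ranked$score > cfg$cutoff, , drop = FALSE]
      top_b <- ranked[ranked$score < 1 - cfg$cutoff, , drop = FALSE]
    } else {
      top_a <- ranked[ranked$assignment == "A", , drop = FALSE]
      top_b <- ranked[ranked$assignment == "B", , drop = FALSE]
    }
    structure(list(
      sizes = c(A = length(sets$a$pmids), B = length(sets$b$pmids),
                C = length(sets$c$pmids)),
      cv_accuracy = model$cv_accuracy,
      test_set_accuracy = model$test_set_accuracy,
      chosen_C = model$chosen_C,
      trace = model$trace,
      top_a = top_a,
      top_b = top_b,
      ranked = ranked,
      whole_index = sets$whole_index,
      model = model,
      config = cfg
    ), class = "job_report")
  })
}

#' @export
print.job_report <- function(x, ...) {
  cat("Literature ranking job report\n")
  cat(sprintf("  sets: |A| = %d, |B| = %d, |C| = %d abstract(s)\n",
              x$sizes["A"], x$sizes["B"], x$sizes["C"]))
  cat(sprintf("  chosen C = %g; CV accuracy %.3f; test-set accuracy %.3f\n",
              x$chosen_C, x$cv_accuracy, x$test_set_accuracy))
  cat(sprintf("  top set A results: %d; top set B results: %d (of %d ranked)\n",
              nrow(x$top_a), nrow(x$top_b), nrow(x$ranked)))
  invisible(x)
}

#' Write a job report to disk
#'
#' Emits the ranked table as TSV (\code{pmid<TAB>score<TAB>assignment<TAB>}
#' \code{rank}), the report (sizes, accuracies, trace, top lists) as JSON,
#' and a config echo.
#'
#' @param report a [run_job()] result.
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$ranked, file.path(dir, "ranked.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- report$config
  doc <- list(
    sizes = as.list(report$sizes),
    cv_accuracy = report$cv_accuracy,
    test_set_accuracy = report$test_set_accuracy,
    chosen_C = report$chosen_C,
    trace = report$trace,
    whole_index = report$whole_index,
    top_a = report$top_a,
    top_b = report$top_b,
    config = list(threshold = cfg$threshold, cutoff = cfg$cutoff,
                  input_cap = cfg$input_cap, seed = cfg$seed,
                  disable_types = cfg$disable_types,
                  solver = unclass(cfg$cfg))
  )
  jsonlite::write_json(doc, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
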
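#' Topic specification for the synthetic corpus generator
#'
#' A topic is a sampling distribution over dictionary terms plus the mean
#' number of keywords per abstract.  The default of 32 keywords per abstract
#' matches the average keyword yield of dictionary-tagged Medline abstracts
#' that the generator emulates.
#'
#' @param id topic identifier (\code{"A"} or \code{"B"}).
#' @param weights named non-negative numeric vector of sampling weights by
#'   term ID; at least one must be positive.
#' @param mean_keywords positive real, mean keywords per abstract.
#' @param n_abstracts number of abstracts to generate for the topic.
#' @return Object of class \code{"topic_spec"}.
#' @export
topic_spec <- function(id, weights, mean_keywords = 32, n_abstracts = 50) {
  if (!any(weights > 0)) {
    lr_stop("topic %s has no positive sampling weight", id)
  }
  stopifnot(all(weights >= 0), mean_keywords > 0, n_abstracts >= 1)
  structure(list(id = id, weights = weights,
                 mean_keywords = mean_keywords,
                 n_abstracts = as.integer(n_abstracts)),
            class = "topic_spec")
}

#' Generate a synthetic two-topic world
#'
#' Builds a typed keyword dictionary, two topic-conditioned abstract sets,
#' gene-to-abstract link tables and ground-truth labels, so every pipeline
#' stage can be exercised without external data.  The separability
#' parameter \code{delta} is the fraction of topic-exclusive vocabulary:
#' \code{delta = 0} gives both topics one identical term distribution
#' (unlearnable), \code{delta = 1} disjoint vocabularies (perfectly
#' separable).  Per abstract, the keyword count is Poisson with the topic's
#' mean and terms are drawn with replacement from the topic distribution;
#' term weights are Gamma-sampled (a Dirichlet draw up to normalization)
#' with a concentration knob.  Abstracts exist both as raw text (sampled
#' surface forms, space-joined) and as exact pre-tagged profiles.
#' Deterministic given the seed.
#'
#' @param spec_a,spec_b optional [topic_spec()]s; when omitted they are
#'   constructed from \code{delta} and the sizing arguments below.
#' @param delta separability in [0, 1].
#' @param n_per_topic integer vector of length 2: abstracts per topic.
#' @param vocab_size total dictionary size.
#' @param mean_keywords mean keywords per abstract (default 32).
#' @param n_genes number of synthetic genes per topic (0 for none).
#' @param link_purity probability that a gene's links stay within its own
#'   topic's abstracts (default 1).
#' @param concentration Dirichlet concentration for the term weights.
#' @param seed integer seed.
#' @return Object of class \code{"synthetic_world"} with elements
#'   \code{dictionary}, \code{corpus}, \code{profiles}, \code{links},
#'   \code{genes}, \code{truth} (named PMID -> topic vector), \code{delta},
#'   \code{seed}.
#' @export
generate_world <- function(spec_a = NULL, spec_b = NULL, delta = 1,
                           n_per_topic = c(50, 50), vocab_size = 120,
                           mean_keywords = 32, n_genes = 0,
                           link_purity = 1, concentration = 1, seed = 1L) {
  stopifnot(delta >= 0, delta <= 1, vocab_size >= 2,
            link_purity >= 0, link_purity <= 1)
  term_ids <- sprintf("t%05d", seq_len(vocab_size))
  surfaces <- sprintf("kw%05d", seq_len(vocab_size))
  types <- rep_len(KEYWORD_TYPES, vocab_size)
  dictionary <- keyword_dictionary(data.frame(
    surface_form = surfaces, term_id = term_ids, term_type = types,
    stringsAsFactors = FALSE))
  surface_of <- stats::setNames(surfaces, term_ids)

  world <- with_seed(seed, {
    if (is.null(spec_a) || is.null(spec_b)) {
      n_shared <- round((1 - delta) * vocab_size)
      n_excl <- vocab_size - n_shared
      shared <- seq_len(n_shared)
      excl_a <- n_shared + seq_len(ceiling(n_excl / 2))
      excl_b <- setdiff(n_shared + seq_len(n_excl), excl_a)
      shared_w <- stats::rgamma(length(shared), concentration) + 1e-9
      w_a <- stats::setNames(numeric(vocab_size), term_ids)
      w_b <- w_a
      w_a[shared] <- shared_w
      w_b[shared] <- shared_w
      w_a[excl_a] <- stats::rgamma(length(excl_a), concentration) + 1e-9
      w_b[excl_b] <- stats::rgamma(length(excl_b), concentration) + 1e-9
      spec_a <- topic_spec("A", w_a / sum(w_a), mean_keywords,
                           n_per_topic[1])
      spec_b <- topic_spec("B", w_b / sum(w_b), mean_keywords,
                           n_per_topic[2])
    }

    gen_topic <- function(spec, base) {
      n <- spec$n_abstracts
      pmids <- as.character(base + seq_len(n))
      terms <- names(spec$weights)
      profs <- vector("list", n)
      bodies <- character(n)
      for (i in seq_len(n)) {
        k <- stats::rpois(1, spec$mean_keywords)
        if (k > 0) {
          draw <- sample(terms, k, replace = TRUE, prob = spec$weights)
          tab <- table(draw)
          profs[[i]] <- keyword_profile(
            stats::setNames(as.integer(tab), names(tab)), pmids[i])
          bodies[i] <- paste(surface_of[draw], collapse = " ")
        } else {
          profs[[i]] <- keyword_profile(integer(0), pmids[i])
          bodies[i] <- ""
        }
      }
      list(pmids = pmids, profiles = stats::setNames(profs, pmids),
           bodies = bodies)
    }
    top_a <- gen_topic(spec_a, 100000L)
    top_b <- gen_topic(spec_b, 200000L)

    genes <- NULL
    links <- gene_link_table()
    if (n_genes > 0) {
      g_topic <- rep(c("A", "B"), each = n_genes)
      entrez <- as.character(300000L + seq_along(g_topic))
      ensg <- sprintf("ENSG%011d", seq_along(g_topic))
      e2p <- lapply(seq_along(g_topic), function(g) {
        own <- if (g_topic[g] == "A") top_a$pmids else top_b$pmids
        other <- if (g_topic[g] == "A") top_b$pmids else top_a$pmids
        k <- sample.int(min(8L, length(own)), 1)
        pm <- sample(own, k)
        flip <- stats::rbinom(k, 1, 1 - link_purity) == 1
        pm[flip] <- sample(other, sum(flip), replace = TRUE)
        pm
      })
      links <- gene_link_table(
        entrez_to_pmids = stats::setNames(e2p, entrez),
        ensembl_to_entrez = stats::setNames(as.list(entrez), ensg))
      genes <- data.frame(entrez = entrez, ensg = ensg, topic = g_topic,
                          stringsAsFactors = FALSE)
    }

    pmids <- c(top_a$pmids, top_b$pmids)
    corpus <- structure(data.frame(
      pmid = pmids,
      title = sprintf("synthetic abstract %s", pmids),
      body = c(top_a$bodies, top_b$bodies),
      stringsAsFactors = FALSE), class = c("abstract_corpus", "data.frame"))
    list(corpus = corpus,
         profiles = c(top_a$profiles, top_b$profiles),
         truth = stats::setNames(rep(c("A", "B"),
                                     c(length(top_a$pmids),
                                       length(top_b$pmids))), pmids),
         links = links, genes = genes,
         spec_a = spec_a, spec_b = spec_b)
  })

  structure(c(list(dictionary = dictionary), world,
              list(delta = delta, seed = as.integer(seed))),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(paste0("Synthetic two-topic world: %d abstract(s), %d term(s),",
                     " delta = %g, seed = %d\n"),
              nrow(x$corpus), nrow(x$dictionary), x$delta, x$seed))
  invisible(x)
}

#' Write a synthetic world as fixture files
#'
#' Emits the flat-file formats the other modules consume: dictionary TSV,
#' corpus TSV, pre-tagged profile TSV, gene link tables and a truth TSV.
#'
#' @param world a [generate_world()] result.
#' @param outdir output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
emit_fixtures <- function(world, outdir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(dictionary = file.path(outdir, "dictionary.tsv"),
             corpus = file.path(outdir, "corpus.tsv"),
             pretagged = file.path(outdir, "pretagged.tsv"),
             entrez_pmid = file.path(outdir, "entrez_pmid.tsv"),
             ensg_entrez = file.path(outdir, "ensg_entrez.tsv"),
             truth = file.path(outdir, "truth.tsv"))
  writeLines(paste(world$dictionary$surface_form, world$dictionary$term_id,
                   world$dictionary$term_type, sep = "\t"),
             paths["dictionary"])
  write_corpus(world$corpus, paths["corpus"])
  type_of <- stats::setNames(world$dictionary$term_type,
                             world$dictionary$term_id)
  write_pretagged(world$profiles, type_of, paths["pretagged"])
  pairs_tsv <- function(tab) {
    as.character(unlist(lapply(names(tab), function(k) {
      paste(k, tab[[k]], sep = "\t")
    })))
  }
  writeLines(pairs_tsv(world$links$entrez_to_pmids), paths["entrez_pmid"])
  writeLines(pairs_tsv(world$links$ensembl_to_entrez), paths["ensg_entrez"])
  writeLines(paste(names(world$truth), world$truth, sep = "\t"),
             paths["truth"])
  invisible(paths)
}
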
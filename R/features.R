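#' Build the training feature space
#'
#' The vocabulary is the union of term IDs across every profile of sets A
#' and B; its size V is the number of unique keywords found in all training
#' abstracts.  Dimensions are assigned lexicographically by term ID so the
#' mapping is a stable bijection onto 1..V.
#'
#' @param profiles_a,profiles_b named lists of [keyword_profile()]s for the
#'   two training sets (at least one profile each).
#' @return Object of class \code{"feature_space"} with elements
#'   \code{terms} (sorted term IDs; the dimension of a term is its position)
#'   and \code{V}.
#' @export
build_feature_space <- function(profiles_a, profiles_b) {
  if (length(profiles_a) == 0 || length(profiles_b) == 0) {
    lr_stop("both training sets need at least one profile")
  }
  terms <- unique(c(
    unlist(lapply(profiles_a, names), use.names = FALSE),
    unlist(lapply(profiles_b, names), use.names = FALSE)
  ))
  if (length(terms) == 0) {
    lr_stop("training sets tag to zero keywords: untrainable input",
            class = "litrank_untrainable")
  }
  terms <- sort(terms, method = "radix")
  structure(list(terms = terms, V = length(terms)), class = "feature_space")
}

#' @export
print.feature_space <- function(x, ...) {
  cat(sprintf("Feature space: V = %d keyword dimension(s)\n", x$V))
  invisible(x)
}

#' Vectorize one keyword profile
#'
#' Copies the profile's raw occurrence counts onto the feature-space
#' dimensions.  Terms absent from the space are silently dropped — this is
#' how the query set is restricted to the training vocabulary.  A profile
#' with no in-space terms yields a legal zero vector, which is still scored
#' later (at the model's intercept-only probability).
#'
#' @param profile a [keyword_profile()].
#' @param space a [build_feature_space()] result.
#' @param label \code{"A"}, \code{"B"} or \code{"unlabeled"}.
#' @return Object of class \code{"sparse_vector"}: \code{pmid},
#'   \code{label}, and \code{entries} (counts named by dimension index,
#'   ascending).
#' @export
vectorize <- function(profile, space, label = c("unlabeled", "A", "B")) {
  label <- match.arg(label)
  stopifnot(inherits(space, "feature_space"))
  dims <- match(names(profile), space$terms)
  keep <- !is.na(dims)
  ord <- order(dims[keep])
  entries <- stats::setNames(as.integer(profile[keep][ord]),
                             dims[keep][ord])
  structure(list(pmid = attr(profile, "pmid"), label = label,
                 entries = entries),
            class = "sparse_vector")
}

#' Vectorize a collection of profiles into a sparse matrix
#'
#' Rows follow the input order (duplicated abstracts become repeated rows);
#' columns are the feature-space dimensions.
#'
#' @param profiles named list of [keyword_profile()]s.
#' @param space a [build_feature_space()] result.
#' @return A \code{dgCMatrix} with one row per profile, V columns, row names
#'   the PMIDs and column names the term IDs.
#' @export
profile_matrix <- function(profiles, space) {
  stopifnot(inherits(space, "feature_space"))
  ii <- integer(0); jj <- integer(0); xx <- integer(0)
  for (r in seq_along(profiles)) {
    prof <- profiles[[r]]
    dims <- match(names(prof), space$terms)
    keep <- !is.na(dims)
    ii <- c(ii, rep.int(r, sum(keep)))
    jj <- c(jj, dims[keep])
    xx <- c(xx, as.integer(prof[keep]))
  }
  pmids <- vapply(profiles, function(p) attr(p, "pmid"), "")
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(profiles), space$V),
                       dimnames = list(pmids, space$terms))
}

#' Export labelled vectors in sparse text format
#'
#' One vector per line in the conventional \code{label dim:count} format of
#' linear-classifier tools, dimensions ascending and 1-based.  Labels are
#' written as \code{+1} (A), \code{-1} (B) and \code{0} (unlabeled).
#'
#' @param vectors list of [vectorize()] results.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
export_sparse <- function(vectors, path) {
  lab_code <- c(A = "+1", B = "-1", unlabeled = "0")
  lines <- vapply(vectors, function(v) {
    if (length(v$entries) == 0) return(lab_code[[v$label]])
    feats <- paste0(names(v$entries), ":", v$entries, collapse = " ")
    paste(lab_code[[v$label]], feats)
  }, "")
  writeLines(lines, path)
  invisible(path)
}
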
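#' Solver configuration
#'
#' The classifier is an L2-regularized logistic regression over raw keyword
#' counts; its probability output is the ranking score.  \code{tolerance_e}
#' is the solver termination criterion recorded with the model (default
#' 0.1); \code{folds} is the number of cross-validation folds used during
#' penalty tuning (default 5).
#'
#' @param tolerance_e positive real, solver tolerance.
#' @param folds integer >= 2, cross-validation folds.
#' @return Object of class \code{"solver_config"}.
#' @export
solver_config <- function(tolerance_e = 0.1, folds = 5L) {
  stopifnot(tolerance_e > 0, folds >= 2)
  structure(list(solver = "L2-regularized logistic regression (dual)",
                 tolerance_e = tolerance_e, folds = as.integer(folds)),
            class = "solver_config")
}

#' First-stage penalty grid
#'
#' The first stage of the penalty search evaluates cross-validated accuracy
#' at exactly eight points, C = 2^x for integer x from -3 to 4.
#'
#' @return Numeric vector \code{c(0.125, 0.25, 0.5, 1, 2, 4, 8, 16)}.
#' @export
first_stage_grid <- function() 2^(-3:4)

#' Neighborhood refinement values for a first-stage exponent
#'
#' The second search stage tests additional C values in the neighborhood of
#' the best first-stage point; each exponent has its fixed refinement row.
#'
#' @param x_best integer exponent in \code{[-3, 4]} of the best first-stage
#'   point.
#' @return Numeric vector of refinement C values.
#' @export
refinement_values <- function(x_best) {
  rows <- list(
    `-3` = c(0.05, 0.1, 0.15),
    `-2` = c(0.15, 0.2, 0.3, 0.35),
    `-1` = c(0.3, 0.4, 0.6, 0.7),
    `0`  = c(0.75, 1.25, 1.5),
    `1`  = c(1.5, 2.5, 3.0),
    `2`  = c(3.0, 3.5, 4.5, 5.0, 6.0),
    `3`  = c(6.0, 7.0, 9.0, 10.0, 11.0),
    `4`  = c(11.0, 12.0, 13.0, 14.0, 15.0)
  )
  key <- as.character(as.integer(x_best))
  if (!key %in% names(rows) || x_best != as.integer(x_best)) {
    lr_stop("x_best must be an integer in [-3, 4], got %s", x_best)
  }
  rows[[key]]
}

#' Decide whether the refinement stage runs
#'
#' Refinement is triggered for small training sets (fewer than 5,000
#' vectors) or moderate ones (fewer than 10,000 vectors) whose best
#' first-stage cross-validated accuracy is below 80%.
#'
#' @param n_training_vectors number of training vectors.
#' @param best_first_stage_accuracy best first-stage CV accuracy in [0, 1].
#' @return Logical.
#' @export
should_refine <- function(n_training_vectors, best_first_stage_accuracy) {
  stopifnot(n_training_vectors >= 1,
            best_first_stage_accuracy >= 0, best_first_stage_accuracy <= 1)
  n_training_vectors < 5000 ||
    (n_training_vectors < 10000 && best_first_stage_accuracy < 0.80)
}

# Ridge logistic fit for one penalty value.  The penalty C multiplies the
# loss term, so on glmnet's per-observation scale lambda = 1/(n * C); the
# intercept is unpenalized and counts are used raw (no standardization).
# glmnet needs >= 2 columns, so a one-dimensional space is padded with an
# all-zero column whose coefficient is dropped afterwards.
fit_l2lr <- function(x, labels, C) {
  n <- nrow(x)
  v <- ncol(x)
  if (length(unique(labels)) < 2) {
    p <- if (labels[1] == "A") 1 else 0
    return(list(weights = numeric(v), intercept = if (p == 1) Inf else -Inf,
                constant = p, C = C))
  }
  xfit <- if (v < 2) cbind(x, Matrix::Matrix(0, n, 2 - v, sparse = TRUE)) else x
  y <- factor(labels, levels = c("B", "A"))
  fit <- glmnet::glmnet(xfit, y, family = "binomial", alpha = 0,
                        lambda = 1 / (n * C), standardize = FALSE,
                        thresh = 1e-10)
  beta <- as.numeric(fit$beta[, 1L])[seq_len(v)]
  list(weights = beta, intercept = as.numeric(fit$a0[1L]), constant = NULL,
       C = C)
}

predict_prob <- function(fit, x) {
  if (!is.null(fit$constant)) return(rep(fit$constant, nrow(x)))
  stats::plogis(fit$intercept + as.numeric(x %*% fit$weights))
}

# Seeded, label-stratified fold assignment: within each class the rows are
# shuffled and dealt round-robin over the folds.
assign_folds <- function(labels, folds, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (lab in unique(labels)) {
      idx <- which(labels == lab)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

#' Cross-validated accuracy at one penalty value
#'
#' K-fold (default five-fold) cross-validation on the labelled training
#' vectors: folds are assigned by a seeded, label-stratified shuffle; the
#' returned value is the fraction of held-out vectors classified correctly
#' (assignment to A requires probability strictly above 0.5).  Deterministic
#' given the seed.
#'
#' @param x sparse or dense numeric matrix of training vectors (rows).
#' @param labels character vector of \code{"A"}/\code{"B"} row labels.
#' @param C positive penalty value.
#' @param cfg a [solver_config()].
#' @param seed integer seed for the fold assignment.
#' @return Accuracy as a fraction in [0, 1].
#' @export
cross_validate <- function(x, labels, C, cfg = solver_config(), seed = 1L) {
  n <- nrow(x)
  if (n < cfg$folds) {
    lr_stop("cannot run %d-fold cross-validation on %d vectors", cfg$folds, n)
  }
  if (length(unique(labels)) < 2) {
    lr_stop("cross-validation needs both labels present")
  }
  fold <- assign_folds(labels, cfg$folds, seed)
  correct <- 0L
  for (k in seq_len(cfg$folds)) {
    test <- fold == k
    if (!any(test)) next
    fit <- fit_l2lr(x[!test, , drop = FALSE], labels[!test], C)
    p <- predict_prob(fit, x[test, , drop = FALSE])
    pred <- ifelse(p > 0.5, "A", "B")
    correct <- correct + sum(pred == labels[test])
  }
  correct / n
}

#' Two-stage penalty grid search
#'
#' Evaluates the eight first-stage points C = 2^x, x = -3..4, by
#' cross-validation; if [should_refine()] holds for the training size and
#' best first-stage accuracy, additionally evaluates the fixed refinement
#' row of the best exponent (once, no recursion).  The chosen C attains the
#' maximal cross-validated accuracy over all evaluated points, ties broken
#' toward the smallest C (strongest regularization).  The same seed drives
#' the fold assignment at every grid point so accuracies are comparable.
#'
#' @inheritParams cross_validate
#' @return List with \code{chosen_C}, \code{cv_accuracy}, \code{x_best}
#'   (best first-stage exponent), \code{refined} (logical) and \code{trace}
#'   (data frame of stage, C and CV accuracy for every evaluated point).
#' @export
select_C <- function(x, labels, cfg = solver_config(), seed = 1L) {
  grid <- first_stage_grid()
  acc1 <- vapply(grid, function(C) cross_validate(x, labels, C, cfg, seed),
                 0)
  trace <- data.frame(stage = "first", C = grid, cv_accuracy = acc1,
                      stringsAsFactors = FALSE)
  best1 <- which(acc1 == max(acc1))[1L]  # grid ascending: first max = smallest C
  x_best <- (-3:4)[best1]
  refined <- should_refine(nrow(x), max(acc1))
  if (refined) {
    vals <- refinement_values(x_best)
    acc2 <- vapply(vals, function(C) cross_validate(x, labels, C, cfg, seed),
                   0)
    trace <- rbind(trace,
                   data.frame(stage = "refine", C = vals, cv_accuracy = acc2,
                              stringsAsFactors = FALSE))
  }
  best <- which(trace$cv_accuracy == max(trace$cv_accuracy))
  chosen <- min(trace$C[best])
  list(chosen_C = chosen, cv_accuracy = max(trace$cv_accuracy),
       x_best = x_best, refined = refined, trace = trace)
}

#' Train the final model at a chosen penalty
#'
#' Fits the L2-regularized logistic regression on all labelled training
#' vectors with the chosen C and reports the test-set accuracy obtained by
#' re-classifying the training vectors themselves (the A and B vectors serve
#' as both training set and default test set).
#'
#' @param x sparse or dense numeric matrix of training vectors.
#' @param labels character vector of \code{"A"}/\code{"B"} row labels.
#' @param chosen_C positive penalty, typically from [select_C()].
#' @param cfg a [solver_config()].
#' @param space optional [build_feature_space()] the columns of \code{x}
#'   correspond to; enables prediction from keyword profiles.
#' @param tuning optional [select_C()] result to record with the model.
#' @param seed integer seed recorded with the model.
#' @return Object of class \code{"litrank"}; see [litrank()].
#' @export
train_final <- function(x, labels, chosen_C, cfg = solver_config(),
                        space = NULL, tuning = NULL, seed = NA_integer_) {
  if (length(unique(labels)) < 2) {
    lr_stop("training requires both classes; got a single-class input")
  }
  fit <- fit_l2lr(x, labels, chosen_C)
  fitted <- predict_prob(fit, x)
  test_acc <- mean(ifelse(fitted > 0.5, "A", "B") == labels)
  terms <- colnames(x)
  model <- structure(list(
    weights = stats::setNames(fit$weights, terms),
    intercept = fit$intercept,
    chosen_C = chosen_C,
    cv_accuracy = if (!is.null(tuning)) tuning$cv_accuracy else NA_real_,
    trace = if (!is.null(tuning)) tuning$trace else NULL,
    refined = if (!is.null(tuning)) tuning$refined else NA,
    test_set_accuracy = test_acc,
    space = space,
    cfg = cfg,
    seed = seed,
    n_a = sum(labels == "A"),
    n_b = sum(labels == "B"),
    labels = labels,
    pmids = rownames(x),
    fitted = fitted,
    call = sys.call(-1)
  ), class = "litrank")
  model
}

#' Fit a two-set literature ranking model
#'
#' The main fitting function.  Builds the feature space from the keyword
#' profiles of the interesting set (A) and the background set (B),
#' vectorizes both sets as raw occurrence counts, tunes the penalty C by the
#' two-stage grid search under k-fold cross-validation ([select_C()]), and
#' trains the final L2-regularized logistic regression on all training
#' vectors.  The fitted object scores any abstract with the probability that
#' it belongs to set A.
#'
#' @param profiles_a,profiles_b named lists of [keyword_profile()]s for the
#'   two training sets (duplicated abstracts are kept as repeated vectors).
#' @param cfg a [solver_config()].
#' @param seed integer seed for the cross-validation fold assignment.
#' @param C optional fixed penalty; skips tuning when supplied.
#' @return Object of class \code{"litrank"} with components including
#'   \code{weights} (named by term ID), \code{intercept}, \code{chosen_C},
#'   \code{cv_accuracy}, \code{trace}, \code{test_set_accuracy} and
#'   \code{space}.  Supports \code{print}, \code{summary}, \code{coef},
#'   \code{predict}, \code{plot}, \code{residuals} and \code{simulate}.
#' @examples
#' a <- list(keyword_profile(c(cycle = 2, kinase = 1), 1),
#'           keyword_profile(c(cycle = 1), 2),
#'           keyword_profile(c(cycle = 3, kinase = 2), 3),
#'           keyword_profile(c(kinase = 1, cycle = 1), 4),
#'           keyword_profile(c(cycle = 2), 5))
#' b <- list(keyword_profile(c(soil = 1), 6),
#'           keyword_profile(c(soil = 2, drought = 1), 7),
#'           keyword_profile(c(drought = 2), 8),
#'           keyword_profile(c(soil = 1, drought = 1), 9),
#'           keyword_profile(c(drought = 1), 10))
#' fit <- litrank(a, b, seed = 1)
#' predict(fit, list(keyword_profile(c(cycle = 1), 11)))
#' @export
litrank <- function(profiles_a, profiles_b, cfg = solver_config(),
                    seed = 1L, C = NULL) {
  space <- build_feature_space(profiles_a, profiles_b)
  x <- profile_matrix(c(profiles_a, profiles_b), space)
  labels <- c(rep("A", length(profiles_a)), rep("B", length(profiles_b)))
  tuning <- if (is.null(C)) select_C(x, labels, cfg, seed) else NULL
  chosen <- if (is.null(C)) tuning$chosen_C else C
  model <- train_final(x, labels, chosen, cfg, space = space,
                       tuning = tuning, seed = as.integer(seed))
  model$call <- match.call()
  model
}

#' @export
print.litrank <- function(x, ...) {
  cat("Two-set literature ranking model\n")
  cat(sprintf("  training vectors: %d (A) + %d (B), %d keyword dimension(s)\n",
              x$n_a, x$n_b, length(x$weights)))
  cat(sprintf("  chosen C: %g", x$chosen_C))
  if (!is.na(x$cv_accuracy)) {
    cat(sprintf("  (CV accuracy %.3f over %d grid point(s))",
                x$cv_accuracy, NROW(x$trace)))
  }
  cat(sprintf("\n  test-set accuracy (re-classified training set): %.3f\n",
              x$test_set_accuracy))
  invisible(x)
}

#' @export
summary.litrank <- function(object, ...) {
  w <- sort(object$weights, decreasing = TRUE)
  structure(list(model = object,
                 top_a_terms = utils::head(w, 10),
                 top_b_terms = utils::head(sort(object$weights), 10)),
            class = "summary.litrank")
}

#' @export
print.summary.litrank <- function(x, ...) {
  print(x$model)
  if (!is.null(x$model$trace)) {
    cat("\nPenalty grid search:\n")
    print(x$model$trace, row.names = FALSE)
  }
  cat("\nMost A-indicative terms:\n")
  print(round(x$top_a_terms, 4))
  cat("\nMost B-indicative terms:\n")
  print(round(x$top_b_terms, 4))
  invisible(x)
}

#' @export
coef.litrank <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$weights)
}

# Coerce prediction inputs (profile list, single profile, or matrix) onto
# the model's feature space.
as_model_matrix <- function(object, newdata) {
  if (inherits(newdata, "keyword_profile")) newdata <- list(newdata)
  if (is.list(newdata) && !is.data.frame(newdata)) {
    return(profile_matrix(newdata, object$space))
  }
  if (ncol(newdata) != length(object$weights)) {
    lr_stop("newdata has %d columns; model expects %d", ncol(newdata),
            length(object$weights))
  }
  newdata
}

#' Score abstracts with a fitted ranking model
#'
#' @param object a fitted [litrank()] model.
#' @param newdata named list of [keyword_profile()]s (terms outside the
#'   training vocabulary are dropped), or a matrix over the model's feature
#'   space.  Omitted: the training vectors are scored.
#' @param type \code{"response"} (probability of set A), \code{"class"}
#'   (\code{"A"} iff score strictly above \code{threshold}, else
#'   \code{"B"}), or \code{"link"} (linear decision value).
#' @param threshold assignment threshold for \code{type = "class"}.
#' @param ... unused.
#' @return Named numeric or character vector, names are PMIDs.
#' @export
predict.litrank <- function(object, newdata = NULL,
                            type = c("response", "class", "link"),
                            threshold = 0.5, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    p <- stats::setNames(object$fitted, object$pmids)
  } else {
    x <- as_model_matrix(object, newdata)
    eta <- object$intercept + as.numeric(x %*% object$weights)
    if (type == "link") return(stats::setNames(eta, rownames(x)))
    p <- stats::setNames(stats::plogis(eta), rownames(x))
  }
  switch(type,
         response = p,
         class = stats::setNames(ifelse(p > threshold, "A", "B"), names(p)),
         link = stats::setNames(stats::qlogis(p), names(p)))
}

#' @export
residuals.litrank <- function(object, ...) {
  y <- as.numeric(object$labels == "A")
  stats::setNames(y - object$fitted, object$pmids)
}

#' @export
simulate.litrank <- function(object, nsim = 1, seed = NULL, ...) {
  n <- length(object$fitted)
  draw <- function() ifelse(stats::rbinom(n, 1, object$fitted) == 1, "A", "B")
  sims <- if (is.null(seed)) {
    replicate(nsim, draw(), simplify = FALSE)
  } else {
    with_seed(seed, replicate(nsim, draw(), simplify = FALSE))
  }
  out <- as.data.frame(stats::setNames(sims, paste0("sim_", seq_len(nsim))),
                       stringsAsFactors = FALSE)
  rownames(out) <- object$pmids
  out
}

#' Plot the penalty grid-search trace
#'
#' Cross-validated accuracy against the penalty C (log scale); first-stage
#' points are filled, refinement points open, the chosen C marked by a
#' vertical line.
#'
#' @param x a fitted [litrank()] model with a tuning trace.
#' @param ... passed to \code{plot}.
#' @export
plot.litrank <- function(x, ...) {
  if (is.null(x$trace)) lr_stop("model has no grid-search trace to plot")
  tr <- x$trace
  plot(tr$C, tr$cv_accuracy, log = "x",
       pch = ifelse(tr$stage == "first", 19, 1),
       xlab = "penalty C (log scale)", ylab = "CV accuracy",
       main = "Penalty grid search", ...)
  abline(v = x$chosen_C, lty = 2)
  legend("bottomright", pch = c(19, 1), bty = "n",
         legend = c("first stage", "refinement"))
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' Writes the sparse weight vector (non-zero terms), intercept, chosen C,
#' grid-search trace, accuracies, seed and a config echo, plus the full
#' feature-space term list so profiles can be re-vectorized at load time.
#'
#' @param object a fitted [litrank()] model.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_litrank <- function(object, path) {
  nz <- object$weights != 0
  doc <- list(
    terms = object$space$terms,
    weight_terms = names(object$weights)[nz],
    weights = unname(object$weights[nz]),
    intercept = object$intercept,
    chosen_C = object$chosen_C,
    cv_accuracy = object$cv_accuracy,
    test_set_accuracy = object$test_set_accuracy,
    refined = object$refined,
    trace = object$trace,
    seed = object$seed,
    n_a = object$n_a,
    n_b = object$n_b,
    config = unclass(object$cfg)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Load a serialized model
#'
#' @param path a JSON file written by [write_litrank()].
#' @return A \code{"litrank"} model usable for prediction.
#' @export
read_litrank <- function(path) {
  doc <- jsonlite::fromJSON(path)
  terms <- doc$terms
  w <- stats::setNames(numeric(length(terms)), terms)
  w[doc$weight_terms] <- doc$weights
  structure(list(
    weights = w,
    intercept = doc$intercept,
    chosen_C = doc$chosen_C,
    cv_accuracy = doc$cv_accuracy,
    trace = doc$trace,
    refined = doc$refined,
    test_set_accuracy = doc$test_set_accuracy,
    space = structure(list(terms = terms, V = length(terms)),
                      class = "feature_space"),
    cfg = solver_config(doc$config$tolerance_e, doc$config$folds),
    seed = doc$seed,
    n_a = doc$n_a,
    n_b = doc$n_b,
    labels = NULL, pmids = NULL, fitted = NULL,
    call = NULL
  ), class = "litrank")
}
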
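# One-vs-rest linear max-margin classification
# --------------------------------------------
# L2-regularised squared-hinge-loss ("L2-SVM") binary classifiers, one per
# class value, with class-biased regularisation: the cost of each positive
# example is multiplied by the negative:positive ratio of its class, while
# negative examples keep cost C = 1.  The bias term is an appended constant
# feature (and is therefore regularised like any other weight).  The solver
# is deterministic (L-BFGS on the smooth squared-hinge objective, restricted
# to the active hashed columns of the training data).

#' Training configuration for the one-vs-rest classifiers
#'
#' @param C base regularisation cost, applied to negative examples
#'   (default 1).
#' @param use_bias_factors multiply the positive-example cost of each class
#'   by its negative:positive ratio (default `TRUE`).
#' @param bias append a constant feature as the bias/intercept term
#'   (default `TRUE`).
#' @param tol solver gradient tolerance (default `1e-4`).
#' @param maxit maximum solver iterations per binary model.
#' @return A `training_config` list.
#' @export
training_config <- function(C = 1, use_bias_factors = TRUE, bias = TRUE,
                            tol = 1e-4, maxit = 300L) {
  stopifnot(C > 0, tol > 0, maxit >= 1L)
  structure(list(C = C, use_bias_factors = use_bias_factors, bias = bias,
                 tol = tol, maxit = as.integer(maxit)),
            class = "training_config")
}

#' Class-biased regularisation factors
#'
#' For each class, the positive-example cost factor is the ratio of negative
#' to positive examples of that class; negative examples keep factor 1.
#'
#' @param labels character/factor vector of gold labels.
#' @param values class values to compute factors for (default: the observed
#'   labels).
#' @return Named numeric vector of factors; `NA` for a class with zero
#'   positive examples (such classes are skipped at training time with a
#'   warning).
#' @export
#' @examples
#' # A: 10 positives vs 90 negatives -> factor 9; B: 90 vs 10 -> 1/9
#' compute_bias_factors(rep(c("A", "B"), c(10, 90)))
compute_bias_factors <- function(labels, values = sort(unique(as.character(labels)))) {
  labels <- as.character(labels)
  n <- length(labels)
  pos <- vapply(values, function(v) sum(labels == v), numeric(1))
  out <- (n - pos) / pos
  out[pos == 0] <- NA_real_
  setNames(out, values)
}

# squared-hinge binary fit on a dgCMatrix (bias column already appended)
.fit_l2svm <- function(X, y, cost, tol = 1e-4, maxit = 300L) {
  d <- ncol(X)
  fn <- function(w) {
    s <- as.numeric(X %*% w)
    h <- pmax(0, 1 - y * s)
    0.5 * sum(w^2) + sum(cost * h^2)
  }
  gr <- function(w) {
    s <- as.numeric(X %*% w)
    h <- pmax(0, 1 - y * s)
    w - 2 * as.numeric(Matrix::crossprod(X, cost * y * h))
  }
  res <- optim(numeric(d), fn, gr, method = "L-BFGS-B",
               control = list(maxit = maxit, factr = 1e7, pgtol = tol))
  res$par
}

#' Train one-vs-rest classifiers for one label set
#'
#' @param X instance matrix (`dgCMatrix`, rows = instances, columns = hashed
#'   feature space), e.g. from stacking [normalise_typewise()] vectors.
#' @param labels gold label per row (exactly one per instance).
#' @param values class values in their fixed (default-first) order; defaults
#'   to the sorted observed labels.
#' @param config a [training_config()].
#' @param dimension name recorded on the model set.
#' @param lexicon_checksum checksum of the cue lexicon the features were
#'   built with; prediction against a different lexicon is refused.
#' @return An `mk_model_set`: per-value weight vectors over the active
#'   columns of the hashed space plus bias.  A value with zero positive
#'   examples is skipped with a warning and always predicted negative.
#' @export
train_ovr <- function(X, labels, values = sort(unique(as.character(labels))),
                      config = training_config(), dimension = "label",
                      lexicon_checksum = NA_integer_) {
  labels <- as.character(labels)
  if (nrow(X) == 0L) stop("empty training set")
  stopifnot(nrow(X) == length(labels))
  active <- which(Matrix::colSums(X != 0) > 0)
  Xa <- X[, active, drop = FALSE]
  if (config$bias) Xa <- cbind(Xa, 1)
  factors <- compute_bias_factors(labels, values)
  W <- matrix(NA_real_, nrow = ncol(Xa), ncol = length(values),
              dimnames = list(NULL, values))
  for (v in values) {
    y <- ifelse(labels == v, 1, -1)
    if (!any(y > 0)) {
      warning(sprintf("class '%s' of %s has no positive examples; model skipped",
                      v, dimension))
      next
    }
    fac <- if (config$use_bias_factors) factors[[v]] else 1
    cost <- ifelse(y > 0, config$C * fac, config$C)
    W[, v] <- .fit_l2svm(Xa, y, cost, tol = config$tol, maxit = config$maxit)
  }
  structure(list(dimension = dimension, values = values, active = active,
                 W = W, config = config, dim = ncol(X),
                 lexicon_checksum = lexicon_checksum),
            class = "mk_model_set")
}

#' @exportS3Method base::print
print.mk_model_set <- function(x, ...) {
  cat(sprintf("<mk_model_set %s: values [%s], %d active features>\n",
              x$dimension, paste(x$values, collapse = ", "), length(x$active)))
  invisible(x)
}

#' Decision scores of a model set
#'
#' @param models an `mk_model_set`.
#' @param X instance matrix over the same hashed space used at training.
#' @return Numeric matrix (rows = instances, columns = class values);
#'   `-Inf` for skipped classes.
#' @export
predict_scores <- function(models, X) {
  stopifnot(ncol(X) == models$dim)
  Xa <- X[, models$active, drop = FALSE]
  if (models$config$bias) Xa <- cbind(Xa, 1)
  S <- matrix(-Inf, nrow = nrow(X), ncol = length(models$values),
              dimnames = list(NULL, models$values))
  for (v in models$values) {
    w <- models$W[, v]
    if (!anyNA(w)) S[, v] <- as.numeric(Xa %*% w)
  }
  S
}

#' Single-label prediction with highest-score fallback
#'
#' Returns the argmax-scoring value for each instance; a value is always
#' returned even when every score is negative.  Exact ties break towards the
#' earlier value in the model's fixed value order (defaults first).
#'
#' @inheritParams predict_scores
#' @return Character vector of predicted values, one per row of `X`.
#' @export
predict_single_label <- function(models, X) {
  S <- predict_scores(models, X)
  models$values[apply(S, 1L, which.max)]
}

#' Multi-label prediction (positive scores plus the argmax)
#'
#' Assigns every value with a positive decision score, plus the value with
#' the highest score, so the result is never empty — unless the designated
#' `none_class` is the argmax, which encodes "no label" for token-level cue
#' detection.
#'
#' @inheritParams predict_scores
#' @param none_class optional class name meaning "no label"; when it wins
#'   the argmax the instance gets an empty label set.
#' @return List of character vectors, one per row of `X`.
#' @export
predict_multi_label <- function(models, X, none_class = NULL) {
  S <- predict_scores(models, X)
  lapply(seq_len(nrow(S)), function(r) {
    s <- S[r, ]
    top <- models$values[which.max(s)]
    labs <- union(models$values[s > 0 & is.finite(s)], top)
    labs <- labs[order(match(labs, models$values))]
    if (!is.null(none_class) && identical(top, none_class)) return(character())
    setdiff(labs, none_class %||% character())
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
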
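## Identification layer: dichotomous pre-filters on qualitative
## characters, pooled-covariance linear discriminant classification,
## resubstitution error, and the multi-specimen probability rule.

#' Dichotomous pre-filter on qualitative characters
#'
#' Two calliphorid species are diagnosable from a single qualitative
#' character, before any measurement: a partially closed (folded)
#' spiracular labellum is exclusive to *Cochliomyia hominivorax*, and
#' large perispiracular papillae (score 2) are exclusive to
#' *Protophormia terraenovae*.  Specimens matching either rule are
#' identified immediately and excluded from the morphometric analysis;
#' all others pass through (`NA`).
#'
#' The labellum rule is checked first; the two rules are mutually
#' exclusive on valid material.
#'
#' @param labellum Logical vector: folded spiracular labellum present?
#' @param papillae Integer vector of papillae scores in \{0, 1, 2\}.
#' @return Character vector: species label or `NA` (no decision).
#' @export
#' @examples
#' dichotomous_prefilter(c(TRUE, FALSE, FALSE), c(0, 2, 1))
dichotomous_prefilter <- function(labellum, papillae) {
  stopifnot(length(labellum) == length(papillae),
            all(papillae %in% c(0, 1, 2)))
  labellum <- as.logical(labellum)
  out <- rep(NA_character_, length(labellum))
  out[labellum] <- "Cochliomyia hominivorax"
  out[!labellum & papillae == 2] <- "Protophormia terraenovae"
  out
}

#' Fit a pooled-covariance linear discriminant classifier
#'
#' Linear discriminant functions with a common (pooled within-class)
#' covariance matrix and, by default, equal priors.  Classification
#' assigns the label maximizing the linear discriminant score
#' \eqn{d_k(x) = x' \Sigma^{-1} \mu_k - \frac12 \mu_k' \Sigma^{-1}
#' \mu_k + \log \pi_k}; with equal priors this is the nearest class
#' centroid in the whitened (canonical) space.  Ties are broken by the
#' lexicographically smallest class label.
#'
#' @param x Numeric matrix/data frame of training observations.
#' @param groups Class labels, one per row; at least 2 classes.
#' @param priors Prior probabilities, named by class or in level order;
#'   default equal.  Must sum to 1.
#' @return Object of class `discriminant_classifier`: class `means`,
#'   `pooled_cov`, `priors`, `labels`, and the retained training set
#'   for resubstitution.
#' @export
fit_classifier <- function(x, groups, priors = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  groups <- factor(groups)
  ok <- stats::complete.cases(x) & !is.na(groups)
  x <- x[ok, , drop = FALSE]
  groups <- droplevels(groups[ok])
  sc <- scatter_matrices(x, groups)
  Sigma <- sc$W / sc$df_within
  ch <- tryCatch(chol(Sigma), error = function(e) {
    stop("singular pooled covariance", call. = FALSE)
  })
  labels <- levels(groups)
  if (is.null(priors)) {
    priors <- setNames(rep(1 / length(labels), length(labels)), labels)
  } else {
    if (is.null(names(priors))) names(priors) <- labels
    priors <- priors[labels]
    if (abs(sum(priors) - 1) > 1e-8) stop("priors must sum to 1",
                                          call. = FALSE)
  }
  structure(list(means = sc$group_means, pooled_cov = Sigma,
                 chol = ch, priors = priors, labels = labels,
                 training = list(x = x, groups = groups)),
            class = "discriminant_classifier")
}

discriminant_scores <- function(object, x) {
  x <- as.matrix(x[, colnames(object$means), drop = FALSE])
  # whiten via the Cholesky factor of the pooled covariance
  zi <- function(m) t(backsolve(object$chol, t(m), transpose = TRUE))
  xz <- zi(x)
  mz <- zi(object$means)
  lin <- xz %*% t(mz)
  const <- -0.5 * rowSums(mz^2) + log(object$priors)
  sweep(lin, 2L, const, "+")
}

#' Predict classes and posteriors from a discriminant classifier
#'
#' @param object A `discriminant_classifier`.
#' @param newdata Matrix/data frame with the training variables; the
#'   training set is used when omitted.
#' @param ... Unused.
#' @return List with `class` (factor) and `posterior` (matrix, rows
#'   summing to 1; equal-covariance Gaussian posteriors).
#' @export
predict.discriminant_classifier <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$training$x
  d <- discriminant_scores(object, newdata)
  # softmax of the linear scores = Gaussian posterior under equal cov
  dmax <- apply(d, 1L, max)
  ed <- exp(d - dmax)
  post <- ed / rowSums(ed)
  colnames(post) <- object$labels
  # which.max takes the first maximum; labels are in sorted (level)
  # order, so ties resolve to the lexicographically smallest label
  cls <- factor(object$labels[apply(d, 1L, which.max)],
                levels = object$labels)
  list(class = cls, posterior = post)
}

#' Resubstitution misclassification rates
#'
#' Reclassifies the training specimens with the fitted classifier and
#' reports the fraction of each class assigned elsewhere, the overall
#' rate, and the confusion matrix.
#'
#' @param classifier A fitted `discriminant_classifier`.
#' @return List with `per_class` (named rates), `overall`, `confusion`
#'   (true class x assigned class counts).
#' @export
resubstitution_error <- function(classifier) {
  stopifnot(inherits(classifier, "discriminant_classifier"))
  truth <- classifier$training$groups
  pred <- predict(classifier)$class
  confusion <- table(truth = truth, assigned = pred)
  wrong <- pred != truth
  per_class <- vapply(classifier$labels, function(lv) {
    mean(wrong[truth == lv])
  }, numeric(1L))
  list(per_class = per_class, overall = mean(wrong), confusion = confusion)
}

#' Probability that a group identification is wrong
#'
#' If a single specimen is misidentified with probability `rate` and
#' `k` specimens are identified independently, the probability that
#' every one of them is wrong — i.e. that the group identification
#' fails — is `rate^k`.  Independence across specimens is an
#' assumption of this simple-probability argument, not a biological
#' claim.
#'
#' @param rate Per-specimen misidentification probability in \[0, 1\].
#' @param k Number of specimens identified (integer >= 1); may be a
#'   vector.
#' @return `rate^k`.
#' @export
#' @examples
#' group_misid_probability(12 / 106, c(1, 4))
group_misid_probability <- function(rate, k) {
  stopifnot(is.numeric(rate), rate >= 0, rate <= 1)
  if (any(k < 1) || any(k != as.integer(k))) {
    stop("k must be an integer >= 1", call. = FALSE)
  }
  rate^k
}
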
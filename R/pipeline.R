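## End-to-end pipeline: landmarks in, identification tables out.
## Stages: dichotomous pre-filter -> feature extraction -> stepwise
## variable selection -> canonical discriminant analysis -> linear
## discriminant classification -> probability report.  Every specimen
## is accounted for exactly once across the pre-filter report, the
## analysis set, and the exclusion log.

#' Run the full puparium-identification pipeline
#'
#' Executes, in order: the dichotomous pre-filter on qualitative
#' characters (pre-filtered specimens are identified immediately and
#' bypass all measurement stages); extraction of the 27 morphometric
#' variables; stepwise canonical discriminant variable selection among
#' `candidates`; canonical discriminant analysis on the selected set
#' (descriptive, univariate, multivariate and raw-coefficient tables,
#' plus canonical scores for plotting); pooled-covariance linear
#' discriminant classification with per-class resubstitution error;
#' and per-class multi-specimen misidentification probabilities.
#'
#' Specimens without landmarks that are not caught by the pre-filter,
#' and specimens with incomplete candidate variables, are logged as
#' exclusions with their `specimen_id`.
#'
#' @param specimens A `specimen_table`, or a path passed to
#'   [read_specimens()].
#' @param level Grouping column: `"species"`, `"genus"`,
#'   `"subfamily"`, `"sex"`, `"location"` or `"diet"`.
#' @param candidates Candidate variables for stepwise selection
#'   (default the three established discriminators: `length2`,
#'   `angle4`, `narrow`).
#' @param entry_alpha,stay_alpha Stepwise significance levels
#'   (default 0.15).
#' @param group_k Specimen counts for the group-probability table
#'   (default `1:4`).
#' @param axis,scale Passed to [extract_features()].
#' @param outdir Optional directory; when given, every table is also
#'   written as a CSV (`prefilter.csv`, `exclusions.csv`,
#'   `descriptives.csv`, `stepwise.csv`, `univariate.csv`,
#'   `multivariate.csv`, `coefficients.csv`, `scores.csv`,
#'   `identification.csv`, `error_rates.csv`, `group_probability.csv`).
#' @return Invisibly, a list with elements `prefilter`, `exclusions`,
#'   `features`, `descriptives`, `stepwise`, `selected`, `univariate`,
#'   `multivariate`, `coefficients`, `scores`, `identification`,
#'   `error_rates`, `group_probability`, and the fitted `model` and
#'   `classifier`.
#' @export
run_pipeline <- function(specimens, level = "species",
                         candidates = c("length2", "angle4", "narrow"),
                         entry_alpha = 0.15, stay_alpha = 0.15,
                         group_k = 1:4, axis = 0, scale = 1,
                         outdir = NULL) {
  if (is.character(specimens) && length(specimens) == 1L) {
    specimens <- read_specimens(specimens)
  }
  specimens <- as_specimen_table(as.data.frame(specimens))
  level <- match.arg(level, c("species", "genus", "subfamily", "sex",
                              "location", "diet"))

  ## stage 1: dichotomous pre-filter
  pre <- dichotomous_prefilter(specimens$labellum, specimens$papillae)
  prefilter <- data.frame(specimen_id = specimens$specimen_id[!is.na(pre)],
                          identified_as = pre[!is.na(pre)],
                          stringsAsFactors = FALSE)
  rest <- specimens[is.na(pre), , drop = FALSE]

  ## stage 2: feature extraction (specimens without landmarks are logged)
  has_lm <- !is.na(rest$x1)
  exclusions <- data.frame(
    specimen_id = rest$specimen_id[!has_lm],
    reason = if (any(!has_lm)) "no landmark block" else character(0),
    stringsAsFactors = FALSE)
  measured <- rest[has_lm, , drop = FALSE]
  if (nrow(measured) < 4L) {
    stop("pipeline: too few measurable specimens after pre-filtering",
         call. = FALSE)
  }
  features <- extract_features(measured, axis = axis, scale = scale)
  grp <- features[[level]]
  if (is.null(grp) || all(is.na(grp))) {
    stop("pipeline: grouping column '", level, "' is empty",
         call. = FALSE)
  }
  usable <- !is.na(grp) &
    stats::complete.cases(features[, candidates, drop = FALSE])
  if (any(!usable)) {
    exclusions <- rbind(exclusions, data.frame(
      specimen_id = features$specimen_id[!usable],
      reason = "incomplete candidate variables or missing group",
      stringsAsFactors = FALSE))
  }
  features <- features[usable, , drop = FALSE]
  grp <- factor(grp[usable])
  xmat <- as.matrix(features[, candidates, drop = FALSE])

  ## stage 3: descriptive statistics
  sc_all <- scatter_matrices(xmat, grp)
  descriptives <- do.call(rbind, lapply(levels(grp), function(lv) {
    xi <- xmat[grp == lv, , drop = FALSE]
    data.frame(group = lv, variable = colnames(xmat),
               n = nrow(xi), mean = colMeans(xi),
               stderr = apply(xi, 2L, stats::sd) / sqrt(nrow(xi)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))

  ## stage 4: stepwise selection, then canonical analysis on selection
  trace <- stepwise_select(xmat, grp, candidates,
                           entry_alpha = entry_alpha,
                           stay_alpha = stay_alpha)
  selected <- attr(trace, "selected")
  if (length(selected) == 0L) {
    stop("pipeline: stepwise selection entered no variables",
         call. = FALSE)
  }
  xsel <- xmat[, selected, drop = FALSE]
  scatter <- scatter_matrices(xsel, grp)
  model <- canonical_solve(scatter)
  univariate <- univariate_stats(xsel, grp)
  tests <- multivariate_tests(model)
  coefficients <- data.frame(variable = rownames(model$coefficients),
                             model$coefficients, row.names = NULL,
                             stringsAsFactors = FALSE)
  scores <- canonical_scores(model, xsel)
  scores_tab <- data.frame(specimen_id = features$specimen_id,
                           group = as.character(grp), scores,
                           stringsAsFactors = FALSE)

  ## stage 5: classification + resubstitution + probability layer
  classifier <- fit_classifier(xsel, grp)
  pred <- predict(classifier)
  err <- resubstitution_error(classifier)
  identification <- data.frame(
    specimen_id = features$specimen_id,
    true_group = as.character(grp),
    assigned = as.character(pred$class),
    posterior = pred$posterior[cbind(seq_len(nrow(xsel)),
                                     as.integer(pred$class))],
    stringsAsFactors = FALSE)
  error_rates <- data.frame(group = names(err$per_class),
                            resubstitution_error = unname(err$per_class),
                            stringsAsFactors = FALSE)
  group_probability <- do.call(rbind, lapply(names(err$per_class),
    function(lv) {
      data.frame(group = lv, k = group_k,
                 misid_probability =
                   group_misid_probability(err$per_class[[lv]], group_k),
                 stringsAsFactors = FALSE)
    }))

  result <- list(prefilter = prefilter, exclusions = exclusions,
                 features = features, descriptives = descriptives,
                 stepwise = as.data.frame(trace), selected = selected,
                 univariate = univariate, multivariate = tests,
                 coefficients = coefficients, scores = scores_tab,
                 identification = identification,
                 error_rates = error_rates,
                 group_probability = group_probability,
                 model = model, classifier = classifier)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    tables <- c("prefilter", "exclusions", "descriptives", "stepwise",
                "univariate", "multivariate", "coefficients", "scores",
                "identification", "error_rates", "group_probability")
    for (tb in tables) {
      utils::write.csv(result[[tb]], file.path(outdir, paste0(tb, ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(result)
}
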
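## Canonical discriminant analysis, written from first principles.
##
## For g groups on p variables, the between-class (B), pooled
## within-class (W) and total (T = B + W) cross-product matrices drive
## everything: univariate test rows, the canonical eigenproblem of
## W^{-1}B, the four multivariate test statistics with their F
## approximations, and stepwise variable selection on partial R-square.

#' Between/within/total scatter decomposition
#'
#' Computes the MANOVA cross-product matrices for grouped multivariate
#' data: \eqn{B = \sum_i n_i (m_i - \bar m)(m_i - \bar m)'},
#' \eqn{W = \sum_i \sum_{x \in i} (x - m_i)(x - m_i)'}, and
#' \eqn{T = B + W}.
#'
#' @param x Numeric matrix or data frame of observations (rows) by
#'   variables (columns).  No missing values (complete-case rule).
#' @param groups Factor (or coercible) of group labels, one per row;
#'   at least 2 groups, each with at least 2 observations.
#' @return An object of class `scatter_decomposition`: list with
#'   matrices `B`, `W`, `T`, degrees of freedom `df_between` (g-1) and
#'   `df_within` (N-g), counts `n`, `g`, `p`, per-group `group_n` and
#'   `group_means`, and the `grand_mean`.
#' @export
#' @examples
#' x <- c(1, 2, 3, 4)
#' g <- c("A", "A", "B", "B")
#' scatter_matrices(x, g)$B  # SSB = 4
scatter_matrices <- function(x, groups) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("x must be numeric", call. = FALSE)
  if (anyNA(x)) stop("x contains missing values; apply the ",
                     "complete-case rule first", call. = FALSE)
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nrow(x) != length(groups)) stop("length mismatch", call. = FALSE)
  g <- nlevels(groups)
  if (g < 2L) stop("need at least 2 groups", call. = FALSE)
  n_i <- tabulate(groups)
  if (any(n_i < 2L)) {
    stop("degenerate group '", levels(groups)[which(n_i < 2L)[1L]],
         "' has fewer than 2 observations", call. = FALSE)
  }
  N <- nrow(x)
  p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(p))
  means <- rowsum(x, groups)[levels(groups), , drop = FALSE] / n_i
  grand <- colSums(x) / N
  dm <- sweep(means, 2L, grand)
  B <- crossprod(dm * sqrt(n_i))
  W <- matrix(0, p, p, dimnames = list(colnames(x), colnames(x)))
  for (lv in levels(groups)) {
    xi <- x[groups == lv, , drop = FALSE]
    ci <- sweep(xi, 2L, means[lv, ])
    W <- W + crossprod(ci)
  }
  dimnames(B) <- dimnames(W)
  structure(list(B = B, W = W, T = B + W,
                 df_between = g - 1L, df_within = N - g,
                 n = N, g = g, p = p,
                 group_n = setNames(n_i, levels(groups)),
                 group_means = means, grand_mean = grand,
                 variables = colnames(x)),
            class = "scatter_decomposition")
}

## ---- univariate rows ------------------------------------------------

univariate_row <- function(variable, SSB, SSW, N, g) {
  SST <- SSB + SSW
  r2 <- if (SST > 0) SSB / SST else 0
  Fv <- if (SSW > 0) (SSB / (g - 1)) / (SSW / (N - g)) else Inf
  data.frame(
    variable = variable,
    total_sd = sqrt(SST / (N - 1)),
    pooled_sd = sqrt(SSW / (N - g)),
    between_sd = sqrt(SSB * g / (N * (g - 1))),
    r_square = r2,
    rsq_ratio = if (r2 < 1) r2 / (1 - r2) else Inf,
    F = Fv,
    df1 = g - 1,
    df2 = N - g,
    p_value = stats::pf(Fv, g - 1, N - g, lower.tail = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Univariate one-way test rows from raw data
#'
#' One row per variable: total, pooled within-class, and between-class
#' standard deviations, R-square, R-square/(1 - R-square), and the
#' one-way F with its p-value.  Each variable is analyzed on its own
#' complete cases, so the effective N may differ across variables.
#'
#' The between-class SD follows the convention
#' \eqn{\sqrt{SSB \cdot g / (N (g - 1))}} (not SSB/(g-1)).
#'
#' @inheritParams scatter_matrices
#' @return Data frame, one row per column of `x`.
#' @export
univariate_stats <- function(x, groups) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  groups <- factor(groups)
  rows <- lapply(colnames(x), function(v) {
    ok <- is.finite(x[, v])
    sc <- scatter_matrices(x[ok, v, drop = FALSE], groups[ok])
    univariate_row(v, sc$B[1L, 1L], sc$W[1L, 1L], sc$n, sc$g)
  })
  do.call(rbind, rows)
}

#' Univariate test row reconstructed from published group summaries
#'
#' Rebuilds a full univariate test row from per-group counts and means
#' plus the pooled within-class standard deviation — the quantities a
#' descriptive-statistics table prints — without raw observations:
#' \eqn{SSB = \sum n_i (m_i - \bar m)^2} with
#' \eqn{\bar m = \sum n_i m_i / N}, and
#' \eqn{SSW = s_p^2 (N - g)}.
#'
#' @param ns Integer vector of per-group counts (at least 2 groups).
#' @param means Numeric vector of per-group means, same length.
#' @param pooled_sd Pooled within-class standard deviation (> 0).
#' @param variable Variable name for the output row.
#' @return One-row data frame with the [univariate_stats()] columns.
#' @export
#' @examples
#' # groups {1,2} and {3,4}: SSB = 4, SSW = 1
#' univariate_stats_from_summaries(c(2, 2), c(1.5, 3.5), sqrt(0.5))
univariate_stats_from_summaries <- function(ns, means, pooled_sd,
                                            variable = "x") {
  stopifnot(length(ns) == length(means), all(ns >= 1),
            is.finite(pooled_sd), pooled_sd > 0)
  g <- length(ns)
  if (g < 2L) stop("need at least 2 groups", call. = FALSE)
  N <- sum(ns)
  grand <- sum(ns * means) / N
  SSB <- sum(ns * (means - grand)^2)
  SSW <- pooled_sd^2 * (N - g)
  univariate_row(variable, SSB, SSW, N, g)
}

## ---- canonical eigenproblem ----------------------------------------

#' Solve the canonical discriminant eigenproblem
#'
#' Computes the eigenvalues and raw canonical coefficients of
#' \eqn{W^{-1}B} via Cholesky whitening of W (numerically stable and
#' guaranteed-real for positive definite W).  Raw coefficients are
#' scaled so each canonical variate has pooled within-class variance 1
#' (\eqn{c' (W/(N-g)) c = 1}), and signed so the largest-magnitude
#' coefficient of each variate is positive.
#'
#' @param scatter A `scatter_decomposition` from [scatter_matrices()];
#'   W must be positive definite.
#' @return Object of class `canonical_model`: `eigenvalues` (length
#'   `rank`, descending), `canonical_correlations`
#'   (\eqn{\sqrt{\lambda/(1+\lambda)}}), `coefficients` (p x rank, raw),
#'   `centroids` (group means in canonical space, centered at the grand
#'   mean), `rank` = min(p, g-1), plus `n`, `p`, `g`, `grand_mean`.
#' @export
canonical_solve <- function(scatter) {
  stopifnot(inherits(scatter, "scatter_decomposition"))
  W <- scatter$W
  B <- scatter$B
  p <- scatter$p
  R <- tryCatch(chol(W), error = function(e) {
    stop("pooled within-class scatter is singular (collinear or ",
         "constant variables among: ",
         paste(scatter$variables, collapse = ", "), ")", call. = FALSE)
  })
  # W^{-1}B eigenproblem via the symmetric form R^{-T} B R^{-1}
  Rinv <- backsolve(R, diag(p))
  M <- crossprod(Rinv, B %*% Rinv)
  M <- (M + t(M)) / 2
  es <- eigen(M, symmetric = TRUE)
  s <- min(p, scatter$g - 1L)
  lambda <- pmax(es$values, 0)[seq_len(s)]
  coefs <- Rinv %*% es$vectors[, seq_len(s), drop = FALSE]
  # unit pooled within-class variance: c' (W / df_within) c = 1
  coefs <- coefs * sqrt(scatter$df_within)
  for (j in seq_len(s)) {
    if (coefs[which.max(abs(coefs[, j])), j] < 0) coefs[, j] <- -coefs[, j]
  }
  dimnames(coefs) <- list(scatter$variables, paste0("Can", seq_len(s)))
  centroids <- sweep(scatter$group_means, 2L, scatter$grand_mean) %*% coefs
  structure(list(eigenvalues = lambda,
                 canonical_correlations = sqrt(lambda / (1 + lambda)),
                 coefficients = coefs,
                 centroids = centroids,
                 rank = s,
                 n = scatter$n, p = p, g = scatter$g,
                 grand_mean = scatter$grand_mean),
            class = "canonical_model")
}

#' Canonical scores for observations
#'
#' Projects observations onto the canonical variates of a fitted model
#' (centering at the training grand mean).
#'
#' @param model A `canonical_model`.
#' @param x Matrix/data frame with the model's variables as columns.
#' @return Matrix of scores, columns `Can1`, `Can2`, ...
#' @export
canonical_scores <- function(model, x) {
  stopifnot(inherits(model, "canonical_model"))
  x <- as.matrix(x[, rownames(model$coefficients), drop = FALSE])
  sweep(x, 2L, model$grand_mean) %*% model$coefficients
}

## ---- multivariate tests --------------------------------------------

#' The four multivariate test statistics with F approximations
#'
#' From the eigenvalues \eqn{\lambda_i} of \eqn{W^{-1}B}: Wilks'
#' \eqn{\Lambda = \prod 1/(1+\lambda_i)} (Rao's F), Pillai's trace
#' \eqn{V = \sum \lambda_i/(1+\lambda_i)}, the Hotelling-Lawley trace
#' \eqn{U = \sum \lambda_i} (two-regime F approximation), and Roy's
#' greatest root \eqn{\lambda_1} (upper-bound F).  The classical
#' parameters are \eqn{s = \min(p, g-1)}, \eqn{m = (|p-g+1|-1)/2},
#' \eqn{n = (N-g-p-1)/2}; when \eqn{s = 1} all four F approximations
#' coincide exactly.
#'
#' @param model A `canonical_model`, or a numeric vector of
#'   eigenvalues.
#' @param N,p,g Observation, variable and group counts; taken from the
#'   model when it is a `canonical_model`.
#' @return Data frame with rows `Wilks' Lambda`, `Pillai's Trace`,
#'   `Hotelling-Lawley Trace`, `Roy's Greatest Root` and columns
#'   `statistic`, `value`, `F`, `df1`, `df2`, `p_value`; the parameters
#'   `s`, `m`, `n` are attached as attributes.
#' @export
#' @examples
#' multivariate_tests(c(3, 1), N = 30, p = 2, g = 3)
multivariate_tests <- function(model, N = NULL, p = NULL, g = NULL) {
  if (inherits(model, "canonical_model")) {
    lambda <- model$eigenvalues
    if (is.null(N)) N <- model$n
    if (is.null(p)) p <- model$p
    if (is.null(g)) g <- model$g
  } else {
    lambda <- as.numeric(model)
    if (is.null(N) || is.null(p) || is.null(g)) {
      stop("N, p and g are required when eigenvalues are ",
           "supplied directly", call. = FALSE)
    }
  }
  q <- g - 1
  s <- min(p, q)
  m <- (abs(p - q) - 1) / 2
  nn <- (N - g - p - 1) / 2
  if (N - g <= 0 || q < 1 || p < 1) {
    stop("non-positive degrees of freedom (N = ", N, ", p = ", p,
         ", g = ", g, ")", call. = FALSE)
  }
  lambda <- lambda[seq_len(min(length(lambda), s))]

  L <- prod(1 / (1 + lambda))
  V <- sum(lambda / (1 + lambda))
  U <- sum(lambda)
  l1 <- if (length(lambda)) lambda[1L] else 0

  # Wilks: Rao's F
  tt <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  w_df1 <- p * q
  w_df2 <- ((N - 1) - (p + q + 1) / 2) * tt - (p * q - 2) / 2
  Lt <- L^(1 / tt)
  w_F <- if (Lt > 0) ((1 - Lt) / Lt) * (w_df2 / w_df1) else Inf

  # Pillai
  p_df1 <- s * (2 * m + s + 1)
  p_df2 <- s * (2 * nn + s + 1)
  p_F <- if (V < s) ((2 * nn + s + 1) / (2 * m + s + 1)) *
    (V / s) / (1 - V / s) else Inf

  # Hotelling-Lawley (two-regime approximation)
  if (nn > 0) {
    b <- (p + 2 * nn) * (q + 2 * nn) / (2 * (2 * nn + 1) * (nn - 1))
    h_df1 <- p * q
    h_df2 <- 4 + (p * q + 2) / (b - 1)
    cc <- (h_df2 - 2) / (2 * nn)
    h_F <- (U / cc) * (h_df2 / h_df1)
  } else {
    h_df1 <- s * (2 * m + s + 1)
    h_df2 <- 2 * (s * nn + 1)
    h_F <- 2 * (s * nn + 1) * U / (s^2 * (2 * m + s + 1))
  }

  # Roy: upper-bound F
  r <- max(p, q)
  r_df1 <- r
  r_df2 <- N - g - r + q
  r_F <- l1 * r_df2 / r

  out <- data.frame(
    statistic = c("Wilks' Lambda", "Pillai's Trace",
                  "Hotelling-Lawley Trace", "Roy's Greatest Root"),
    value = c(L, V, U, l1),
    F = c(w_F, p_F, h_F, r_F),
    df1 = c(w_df1, p_df1, h_df1, r_df1),
    df2 = c(w_df2, p_df2, h_df2, r_df2),
    stringsAsFactors = FALSE
  )
  out$p_value <- stats::pf(out$F, out$df1, out$df2, lower.tail = FALSE)
  attr(out, "s") <- s
  attr(out, "m") <- m
  attr(out, "n") <- nn
  out
}

## ---- stepwise selection --------------------------------------------

wilks_of_set <- function(x, groups, vars) {
  if (length(vars) == 0L) return(1)
  sc <- scatter_matrices(x[, vars, drop = FALSE], groups)
  dT <- det(sc$T)
  dW <- det(sc$W)
  if (!is.finite(dT) || dT <= 0) return(NA_real_)
  dW / dT
}

#' Stepwise canonical discriminant variable selection
#'
#' Forward selection with a backward look after every entry, on the
#' partial R-square scale.  For a candidate \eqn{v} given the entered
#' set \eqn{S}, partial \eqn{R^2 = 1 - \Lambda(S \cup v)/\Lambda(S)}
#' where \eqn{\Lambda} is Wilks' Lambda of a variable set, and the
#' F-to-enter with \eqn{k = |S|} already entered is
#' \eqn{F = \frac{N - g - k}{g - 1}\cdot\frac{R^2}{1 - R^2}} on
#' \eqn{(g-1,\; N-g-k)} degrees of freedom.  The candidate with the
#' largest partial R-square enters if its p-value is below
#' `entry_alpha`; after each entry, any entered variable whose removal
#' F has p-value above `stay_alpha` is removed (worst first).  Each
#' step also records Wilks' Lambda of the current set (with Rao-F
#' p-value) and the average squared canonical correlation
#' ASCC = Pillai's trace / (g - 1) (with Pillai-F p-value).
#'
#' @inheritParams scatter_matrices
#' @param candidates Variable names to consider (default: all columns).
#' @param entry_alpha,stay_alpha Significance levels for entry and
#'   retention; both default to 0.15.
#' @return Object of class `stepwise_trace`: a data frame with columns
#'   `step`, `action` ("entered"/"removed"), `variable`,
#'   `partial_rsq`, `F`, `p_value`, `wilks`, `p_wilks`, `ascc`,
#'   `p_ascc`; the final selection is in `attr(, "selected")`.
#' @export
stepwise_select <- function(x, groups, candidates = NULL,
                            entry_alpha = 0.15, stay_alpha = 0.15) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (is.null(candidates)) candidates <- colnames(x)
  if (length(candidates) == 0L) stop("empty candidate set", call. = FALSE)
  bad <- setdiff(candidates, colnames(x))
  if (length(bad)) stop("unknown candidate(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  stopifnot(entry_alpha > 0, entry_alpha < 1, stay_alpha > 0, stay_alpha < 1)
  groups <- factor(groups)
  ok <- stats::complete.cases(x[, candidates, drop = FALSE]) & !is.na(groups)
  x <- x[ok, , drop = FALSE]
  groups <- droplevels(groups[ok])
  N <- nrow(x)
  g <- nlevels(groups)
  if (g < 2L) stop("need at least 2 groups", call. = FALSE)

  entered <- character(0)
  lambda_cur <- 1
  trace <- list()
  step <- 0L

  model_row <- function(action, variable, pr2, Fv, df2v) {
    # Wilks + ASCC of the current entered set
    k <- length(entered)
    wl <- wilks_of_set(x, groups, entered)
    mt <- if (k > 0L) {
      sc <- scatter_matrices(x[, entered, drop = FALSE], groups)
      multivariate_tests(canonical_solve(sc), N = N, p = k, g = g)
    } else NULL
    data.frame(
      step = step, action = action, variable = variable,
      partial_rsq = pr2, F = Fv,
      p_value = stats::pf(Fv, g - 1, df2v, lower.tail = FALSE),
      wilks = wl,
      p_wilks = if (!is.null(mt)) mt$p_value[1L] else NA_real_,
      ascc = if (!is.null(mt)) mt$value[2L] / (g - 1) else NA_real_,
      p_ascc = if (!is.null(mt)) mt$p_value[2L] else NA_real_,
      stringsAsFactors = FALSE
    )
  }

  repeat {
    pool <- setdiff(candidates, entered)
    if (length(pool) == 0L) break
    k <- length(entered)
    df2 <- N - g - k
    if (df2 <= 0) break
    pr2 <- vapply(pool, function(v) {
      wl_new <- wilks_of_set(x, groups, c(entered, v))
      if (is.na(wl_new) || is.na(lambda_cur) || lambda_cur <= 0) {
        return(NA_real_)  # degenerate (constant/collinear) candidate
      }
      max(0, min(1, 1 - wl_new / lambda_cur))
    }, numeric(1L))
    pr2 <- pr2[!is.na(pr2)]
    if (length(pr2) == 0L) break
    best <- names(pr2)[which.max(pr2)]
    r2 <- pr2[[best]]
    if (r2 >= 1) r2 <- 1 - 1e-12
    Fv <- (df2 / (g - 1)) * r2 / (1 - r2)
    pv <- stats::pf(Fv, g - 1, df2, lower.tail = FALSE)
    if (pv > entry_alpha) break
    entered <- c(entered, best)
    lambda_cur <- wilks_of_set(x, groups, entered)
    step <- step + 1L
    trace[[length(trace) + 1L]] <- model_row("entered", best, r2, Fv, df2)

    # backward look: drop any entered variable that no longer earns its keep
    repeat {
      k <- length(entered)
      if (k < 2L) break
      df2r <- N - g - (k - 1L)
      rem <- vapply(entered, function(v) {
        wl_without <- wilks_of_set(x, groups, setdiff(entered, v))
        max(0, min(1, 1 - lambda_cur / wl_without))
      }, numeric(1L))
      Fr <- (df2r / (g - 1)) * rem / (1 - pmin(rem, 1 - 1e-12))
      pr <- stats::pf(Fr, g - 1, df2r, lower.tail = FALSE)
      worst <- names(pr)[which.max(pr)]
      if (pr[[worst]] <= stay_alpha) break
      entered <- setdiff(entered, worst)
      lambda_cur <- wilks_of_set(x, groups, entered)
      step <- step + 1L
      trace[[length(trace) + 1L]] <-
        model_row("removed", worst, rem[[worst]], Fr[[worst]], df2r)
    }
  }

  out <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(0), action = character(0),
               variable = character(0), partial_rsq = numeric(0),
               F = numeric(0), p_value = numeric(0), wilks = numeric(0),
               p_wilks = numeric(0), ascc = numeric(0),
               p_ascc = numeric(0), stringsAsFactors = FALSE)
  attr(out, "selected") <- entered
  attr(out, "N") <- N
  attr(out, "g") <- g
  class(out) <- c("stepwise_trace", class(out))
  out
}

## ---- one-stop fit ---------------------------------------------------

#' Fit a full canonical discriminant analysis
#'
#' Convenience wrapper: scatter decomposition, univariate rows,
#' canonical eigenproblem, and the four multivariate tests in one call.
#'
#' @inheritParams scatter_matrices
#' @return Object of class `candisc_fit`: list with `scatter`,
#'   `univariate`, `model` (the `canonical_model`) and `tests`.
#' @export
candisc_fit <- function(x, groups) {
  x <- as.matrix(x)
  groups <- factor(groups)
  ok <- stats::complete.cases(x) & !is.na(groups)
  x <- x[ok, , drop = FALSE]
  groups <- droplevels(groups[ok])
  scatter <- scatter_matrices(x, groups)
  model <- canonical_solve(scatter)
  structure(list(scatter = scatter,
                 univariate = univariate_stats(x, groups),
                 model = model,
                 tests = multivariate_tests(model)),
            class = "candisc_fit")
}

format_p <- function(p) ifelse(p < 1e-4, "<0.0001", sprintf("%.4f", p))

#' @export
print.candisc_fit <- function(x, ...) {
  cat("Canonical discriminant analysis:", x$scatter$g, "groups,",
      x$scatter$p, "variables, N =", x$scatter$n, "\n\n")
  u <- x$univariate
  u$p_value <- format_p(u$p_value)
  cat("Univariate one-way tests:\n")
  print(u, digits = 6, row.names = FALSE)
  tt <- x$tests
  tt$p_value <- format_p(tt$p_value)
  cat(sprintf("\nMultivariate tests (S = %g, M = %g, N = %g):\n",
              attr(x$tests, "s"), attr(x$tests, "m"), attr(x$tests, "n")))
  print(tt, digits = 6, row.names = FALSE)
  cat("\nRaw canonical coefficients:\n")
  print(x$model$coefficients, digits = 6)
  invisible(x)
}

#' @export
print.stepwise_trace <- function(x, ...) {
  cat("Stepwise canonical discriminant selection (N =", attr(x, "N"),
      ", groups =", attr(x, "g"), ")\n")
  y <- as.data.frame(x)
  y$p_value <- format_p(y$p_value)
  y$p_wilks <- format_p(y$p_wilks)
  y$p_ascc <- format_p(y$p_ascc)
  print(y, digits = 6, row.names = FALSE)
  cat("Selected:", paste(attr(x, "selected"), collapse = ", "), "\n")
  invisible(x)
}
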
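test_that("scatter decomposition matches hand computations and T = B + W", {
  # 1-D: groups {1,2} and {3,4} -> SSB 4, SSW 1, SST 5
  sc <- scatter_matrices(c(1, 2, 3, 4), c("A", "A", "B", "B"))
  expect_equal(sc$B[1, 1], 4)
  expect_equal(sc$W[1, 1], 1)
  expect_equal(sc$T[1, 1], 5)
  expect_equal(sc$df_between, 1L)
  expect_equal(sc$df_within, 2L)

  # identical group means -> zero between-class scatter
  sc0 <- scatter_matrices(c(1, 3, 1, 3), c("A", "A", "B", "B"))
  expect_equal(sc0$B[1, 1], 0)

  # random grouped data: the decomposition identity holds elementwise
  set.seed(31)
  for (i in 1:5) {
    d <- random_grouped_sample(n_per = 7, g = 3, p = 4)
    sc <- scatter_matrices(d$x, d$groups)
    expect_equal(sc$T, sc$B + sc$W, tolerance = 1e-8)
    # and T equals the direct total cross-product about the grand mean
    Tdirect <- crossprod(sweep(d$x, 2, colMeans(d$x)))
    expect_equal(unname(sc$T), unname(Tdirect), tolerance = 1e-8)
  }

  expect_error(scatter_matrices(c(1, 2, 3), c("A", "A", "B")),
               "fewer than 2")
  xs <- cbind(a = rnorm(10), b = 0)
  expect_error(canonical_solve(scatter_matrices(xs, rep(c("A", "B"), 5))),
               "singular")
})

test_that("univariate rows from summaries match hand values and the raw path", {
  # groups {1,2} and {3,4} via their summaries
  r <- univariate_stats_from_summaries(c(2, 2), c(1.5, 3.5), sqrt(0.5))
  expect_equal(r$r_square, 0.8)
  expect_equal(r$F, 8)

  # equal means: no between-group signal
  r0 <- univariate_stats_from_summaries(c(5, 5), c(2, 2), 1)
  expect_equal(r0$r_square, 0)
  expect_equal(r0$F, 0)

  expect_error(univariate_stats_from_summaries(4, 2, 1), "2 groups")

  # summary path equals the raw-data path to 1e-10
  set.seed(32)
  for (i in 1:5) {
    d <- random_grouped_sample(n_per = 9, g = 3, p = 1)
    raw <- univariate_stats(d$x, d$groups)
    ns <- tabulate(d$groups)
    means <- tapply(d$x[, 1], d$groups, mean)
    via <- univariate_stats_from_summaries(ns, means, raw$pooled_sd, "V1")
    for (col in c("total_sd", "pooled_sd", "between_sd", "r_square",
                  "rsq_ratio", "F", "p_value")) {
      expect_equal(via[[col]], raw[[col]], tolerance = 1e-10)
    }
  }
})

test_that("canonical eigenproblem matches closed forms and an independent solver", {
  # p = 1: the single eigenvalue is SSB/SSW
  sc <- scatter_matrices(c(1, 2, 3, 4), c("A", "A", "B", "B"))
  m <- canonical_solve(sc)
  expect_equal(m$eigenvalues, 4)

  # g = 2 with several variables: exactly one positive eigenvalue
  set.seed(33)
  d2 <- random_grouped_sample(n_per = 10, g = 2, p = 3)
  m2 <- canonical_solve(scatter_matrices(d2$x, d2$groups))
  expect_equal(m2$rank, 1L)
  expect_gt(m2$eigenvalues[1], 0)

  # random small instances: eigenvalues match eigen(solve(W) %*% B)
  for (i in 1:10) {
    g <- sample(2:4, 1); p <- sample(1:3, 1)
    d <- random_grouped_sample(n_per = sample(5:10, 1), g = g, p = p)
    sc <- scatter_matrices(d$x, d$groups)
    m <- canonical_solve(sc)
    oracle <- sort(Re(eigen(solve(sc$W) %*% sc$B)$values),
                   decreasing = TRUE)[seq_len(m$rank)]
    expect_equal(m$eigenvalues, pmax(oracle, 0), tolerance = 1e-8)
  }
})

test_that("raw coefficients give unit pooled within-class variance, are
           uncorrelated within classes, and carry a positive lead sign", {
  set.seed(34)
  for (i in 1:5) {
    d <- random_grouped_sample(n_per = 12, g = 4, p = 3)
    sc <- scatter_matrices(d$x, d$groups)
    m <- canonical_solve(sc)
    Wn <- sc$W / sc$df_within
    for (j in seq_len(m$rank)) {
      cj <- m$coefficients[, j]
      expect_equal(drop(t(cj) %*% Wn %*% cj), 1, tolerance = 1e-8)
      expect_gt(cj[which.max(abs(cj))], 0)
      for (k in seq_len(j - 1)) {
        ck <- m$coefficients[, k]
        expect_equal(drop(t(cj) %*% Wn %*% ck), 0, tolerance = 1e-8)
      }
    }
  }
})

test_that("the four multivariate statistics follow their defining formulas", {
  mt <- multivariate_tests(c(3, 1), N = 30, p = 2, g = 3)
  expect_equal(mt$value, c(0.125, 1.25, 4, 3))

  mt0 <- multivariate_tests(c(0, 0), N = 30, p = 2, g = 3)
  expect_equal(mt0$value, c(1, 0, 0, 0))

  # classical parameters for p = 3, g = 6, N = 465
  mtp <- multivariate_tests(c(2, 1, 0.5), N = 465, p = 3, g = 6)
  expect_equal(attr(mtp, "s"), 3)
  expect_equal(attr(mtp, "m"), 0.5)
  expect_equal(attr(mtp, "n"), 227.5)

  # recomputation from eigenvalues agrees with the table to 1e-10
  set.seed(35)
  for (i in 1:5) {
    lam <- sort(rexp(3, 1 / 2), decreasing = TRUE)
    mt <- multivariate_tests(lam, N = 100, p = 3, g = 4)
    expect_equal(mt$value[1], prod(1 / (1 + lam)), tolerance = 1e-10)
    expect_equal(mt$value[2], sum(lam / (1 + lam)), tolerance = 1e-10)
    expect_equal(mt$value[3], sum(lam), tolerance = 1e-10)
    expect_equal(mt$value[4], lam[1], tolerance = 1e-10)
    expect_true(all(mt$value[1] > 0, mt$value[1] <= 1))
    expect_true(mt$value[2] >= 0 && mt$value[2] <= 3)
  }

  expect_error(multivariate_tests(c(1), N = 3, p = 2, g = 3),
               "degrees of freedom")
})

test_that("all four F approximations coincide when s = 1", {
  set.seed(36)
  # p = 1 (any g) and g = 2 (any p) both give s = 1
  cases <- list(list(g = 3, p = 1), list(g = 2, p = 3), list(g = 2, p = 1))
  for (cs in cases) {
    d <- random_grouped_sample(n_per = 15, g = cs$g, p = cs$p)
    sc <- scatter_matrices(d$x, d$groups)
    mt <- multivariate_tests(canonical_solve(sc))
    expect_equal(diff(range(mt$F)), 0, tolerance = 1e-8 * max(mt$F))
    if (cs$p == 1) {
      uni <- univariate_stats(d$x, d$groups)
      expect_equal(mt$F[1], uni$F[1], tolerance = 1e-8)
    }
  }
})

test_that("stepwise selection enters informative variables and respects
           the Wilks monotonicity invariant", {
  set.seed(37)
  n <- 30
  groups <- factor(rep(c("A", "B", "C"), each = n))
  signal <- rep(c(0, 4, 8), each = n)
  x <- cbind(inform = signal + rnorm(3 * n),
             noise = rnorm(3 * n),
             constant = 1)
  tr <- stepwise_select(x, groups, entry_alpha = 0.05, stay_alpha = 0.05)
  expect_equal(tr$variable[1], "inform")
  expect_false("constant" %in% attr(tr, "selected"))

  # step-1 partial R-square equals the univariate r_square
  uni <- univariate_stats(x[, "inform", drop = FALSE], groups)
  expect_equal(tr$partial_rsq[1], uni$r_square[1], tolerance = 1e-10)
  # and its F is the univariate one-way F
  expect_equal(tr$F[1], uni$F[1], tolerance = 1e-10)

  # Wilks' Lambda never increases as variables enter
  set.seed(38)
  for (i in 1:3) {
    d <- random_grouped_sample(n_per = 15, g = 3, p = 4)
    tr <- stepwise_select(d$x, d$groups, entry_alpha = 0.9, stay_alpha = 0.95)
    ent <- tr[tr$action == "entered", ]
    if (nrow(ent) > 1) expect_true(all(diff(ent$wilks) <= 1e-12))
    # ASCC is Pillai / (g - 1), recomputed independently on the final set
    sel <- attr(tr, "selected")
    mt <- multivariate_tests(
      canonical_solve(scatter_matrices(d$x[, sel, drop = FALSE], d$groups)))
    expect_equal(tr$ascc[nrow(tr)], mt$value[2] / 2, tolerance = 1e-10)
  }

  expect_error(stepwise_select(x, groups, candidates = character(0)),
               "empty")
  # all-constant candidates produce an empty trace
  xc <- cbind(c1 = rep(1, 90), c2 = rep(2, 90))
  trc <- stepwise_select(xc, groups)
  expect_equal(nrow(trc), 0L)
})
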
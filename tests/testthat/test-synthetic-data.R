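test_that("built-in population specs carry the published group structure", {
  sub <- builtin_population_specs("subfamily")
  expect_equal(length(sub$labels), 3L)
  expect_equal(unname(sub$n), c(174, 178, 113))
  expect_equal(unname(sub$pooled_sd),
               c(6.0799, 5.0221, 13.7813))

  gen <- builtin_population_specs("genus")
  expect_equal(length(gen$labels), 6L)
  expect_equal(sum(gen$n), 465)

  sp <- builtin_population_specs("species")
  expect_equal(length(sp$labels), 8L)
  expect_equal(sum(sp$n), 465)
  expect_equal(sp$means["Phormia regina", "length2"], 78.0362)

  for (lv in c("subfamily", "genus", "species")) {
    s <- builtin_population_specs(lv)
    expect_s3_class(s, "population_spec")
    expect_true(all(s$n >= 2))
    expect_equal(diag(s$correlation), rep(1, 3), ignore_attr = TRUE)
    expect_equal(dim(s$group_sds), dim(s$means))
    expect_true(all(s$group_sds > 0))
  }
  expect_error(builtin_population_specs("order"))
})

test_that("per-group SDs recover from the printed standard errors", {
  sp <- builtin_population_specs("species")
  # SD = StdErr * sqrt(N): Phormia regina length2 StdErr 0.439375, N 108
  expect_equal(sp$group_sds["Phormia regina", "length2"],
               0.439375 * sqrt(108), ignore_attr = TRUE)
})

test_that("simulate_features is seed-deterministic and respects the spec", {
  sp <- builtin_population_specs("species")
  a <- simulate_features(sp, seed = 99)
  b <- simulate_features(sp, seed = 99)
  expect_identical(a, b)
  expect_equal(nrow(a), 465L)
  expect_equal(as.integer(table(a$group)), unname(sp$n))

  # zero-variance spec: draws equal group means exactly
  z <- population_spec(c("A", "B"), c(3, 3),
                       rbind(c(1, 2), c(5, 9)), c(0, 0))
  fz <- simulate_features(z, seed = 1)
  expect_equal(fz[[2]], rep(c(1, 5), each = 3))
  expect_equal(fz[[3]], rep(c(2, 9), each = 3))
})

test_that("large-n simulated means concentrate on the spec means", {
  sp <- builtin_population_specs("species")
  f <- simulate_features(sp, seed = 7, n_per_group = 1e4)
  for (v in sp$variables) {
    sm <- tapply(f[[v]], f$group, mean)
    bound <- 4 * sp$pooled_sd[[v]] / sqrt(1e4)
    expect_true(all(abs(sm - sp$means[, v]) < bound))
  }
})

test_that("simulated data recovers the analytic univariate R-square", {
  sp <- builtin_population_specs("species")
  f <- simulate_features(sp, seed = 13)
  uni <- univariate_stats(f$length2, f$group)
  analytic <- univariate_stats_from_summaries(
    sp$n, sp$means[, "length2"], sp$pooled_sd[["length2"]])
  expect_equal(uni$r_square, analytic$r_square, tolerance = 0.05)
})

test_that("synthesize_landmarks realizes length and angle targets exactly", {
  lm <- synthesize_landmarks(rep(50, 6), rep(90, 6))
  tab <- as_specimen_table(specimen_row("s", lm = lm))
  f <- extract_features(tab)
  expect_equal(as.numeric(f[paste0("length", 1:6)]), rep(50, 6),
               tolerance = 1e-9)
  expect_equal(as.numeric(f[paste0("angle", 1:6)]), rep(90, 6),
               tolerance = 1e-9)

  expect_error(synthesize_landmarks(c(0, rep(50, 5)), rep(90, 6)),
               "positive")
  expect_error(synthesize_landmarks(rep(50, 6), c(rep(90, 5), 180)),
               "angles")
})

test_that("randomized feasible targets roundtrip through the geometry", {
  set.seed(51)
  for (i in 1:10) {
    # harvest targets from an actual configuration so widths are feasible
    src <- random_landmarks()
    ftab <- extract_features(as_specimen_table(specimen_row("x", lm = src)))
    lengths <- as.numeric(ftab[paste0("length", 1:6)])
    angles <- as.numeric(ftab[paste0("angle", 1:6)])
    widths <- unlist(ftab[c("wideL", "narrowL", "wideR", "narrowR",
                            "wide", "narrow")])
    lm <- synthesize_landmarks(lengths, angles, widths = widths)
    back <- extract_features(as_specimen_table(specimen_row("y", lm = lm)))
    expect_equal(as.numeric(back[paste0("length", 1:6)]), lengths,
                 tolerance = 1e-9)
    expect_equal(as.numeric(back[paste0("angle", 1:6)]), angles,
                 tolerance = 1e-9)
    expect_equal(unlist(back[names(widths)]), widths, tolerance = 1e-9)
  }
})

test_that("geometrically impossible width targets raise infeasibility", {
  expect_error(
    synthesize_landmarks(rep(50, 6), rep(90, 6),
                         widths = c(wideL = 40, narrowL = 35, wideR = 40,
                                    narrowR = 35, wide = 1000, narrow = 1)),
    "infeasible")
})

test_that("simulate_specimens realizes the drawn discriminators as landmarks", {
  sp <- builtin_population_specs("species")
  st <- simulate_specimens("species", seed = 77, n_per_group = 4)
  f <- extract_features(st)
  draws <- simulate_features(sp, seed = 77, n_per_group = 4)
  expect_equal(f$length2, draws$length2, tolerance = 1e-9)
  expect_equal(f$angle4, draws$angle4, tolerance = 1e-9)
  expect_equal(f$narrow, draws$narrow, tolerance = 1e-9)
  expect_equal(f$species, as.character(draws$group))
})

test_that("the shipped specimen background table is internally consistent", {
  counts <- specimen_counts()
  expect_equal(sum(counts$n), 505)
  expect_equal(length(unique(counts$species)), 10L)
  # batch sums agree with the per-species analysis Ns (Calliphora
  # vicina 77, Lucilia sericata 99)
  per_species <- tapply(counts$n, counts$species, sum)
  expect_equal(unname(per_species[["Calliphora vicina"]]), 77)
  expect_equal(unname(per_species[["Lucilia sericata"]]), 99)
})
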
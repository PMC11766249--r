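## Synthetic data with the statistical structure the analysis assumes:
## per-taxon multivariate-normal feature draws parameterized by
## published group sizes, means and pooled within-class SDs, and an
## inverse-geometry constructor that places 12 landmarks realizing
## prescribed lengths, angles and widths.

# Published per-taxon summary statistics for the three discriminators
# (length2, angle4, narrow) at each taxonomic level.  StdErr converts
# to a per-group SD via SD = StdErr * sqrt(N).  The pooled
# within-class SD is a single per-variable value.  Chrysomyinae group
# sizes differ by variable at the subfamily level (complete-case
# analysis per variable); simulation uses the length2 sizes.
builtin_tables <- function() {
  list(
    subfamily = list(
      groups = c("Calliphorinae", "Chrysomyinae", "Luciliinae"),
      n = cbind(length2 = c(174, 178, 113),
                angle4 = c(174, 207, 113),
                narrow = c(174, 207, 113)),
      means = cbind(length2 = c(42.42563, 77.45124, 45.28814),
                    angle4 = c(36.81741, 65.80676, 49.99319),
                    narrow = c(109.8691, 98.11097, 75.27035)),
      stderr = cbind(length2 = c(0.603716, 0.359465, 0.401046),
                     angle4 = c(0.396177, 0.372499, 0.452896),
                     narrow = c(1.018223, 1.251904, 0.868647)),
      pooled_sd = c(length2 = 6.0799, angle4 = 5.0221, narrow = 13.7813)
    ),
    genus = list(
      groups = c("Calliphora", "Chrysomya", "Cochliomyia", "Cynomya",
                 "Lucilia", "Phormia"),
      n = cbind(length2 = c(98, 30, 40, 76, 113, 108),
                angle4 = c(98, 30, 40, 76, 113, 108),
                narrow = c(98, 30, 40, 76, 113, 108)),
      means = cbind(
        length2 = c(37.07776, 77.118, 76.12175, 49.32158, 45.28814, 78.0362),
        angle4 = c(38.56643, 65.11933, 71.294, 34.56211, 49.99319, 65.23676),
        narrow = c(111.8896, 96.118, 115.1433, 107.2638, 75.27035, 86.01204)),
      stderr = cbind(
        length2 = c(0.53704, 0.716633, 0.90666, 0.563951, 0.401046, 0.439375),
        angle4 = c(0.51058, 0.935825, 0.639532, 0.523184, 0.452896, 0.392917),
        narrow = c(1.326149, 1.731377, 1.992577, 1.543251, 0.868647, 1.072371)),
      pooled_sd = c(length2 = 4.7943, angle4 = 4.6250, narrow = 11.6160)
    ),
    species = list(
      groups = c("Calliphora livida", "Calliphora vicina",
                 "Chrysomya megacephala", "Cochliomyia macellaria",
                 "Cynomya cadaverina", "Lucilia coeruleiviridis",
                 "Lucilia sericata", "Phormia regina"),
      n = cbind(length2 = c(21, 77, 30, 40, 76, 14, 99, 108),
                angle4 = c(21, 77, 30, 40, 76, 14, 99, 108),
                narrow = c(21, 77, 30, 40, 76, 14, 99, 108)),
      means = cbind(
        length2 = c(33.41, 38.07805, 77.118, 76.12175, 49.32158,
                    46.20071, 45.15909, 78.0362),
        angle4 = c(37.37238, 38.89208, 65.11933, 71.294, 34.56211,
                   46.13857, 50.53828, 65.23676),
        narrow = c(98.51238, 115.5379, 96.118, 115.1433, 107.2638,
                   85.63643, 73.80444, 86.01204)),
      stderr = cbind(
        length2 = c(0.671428, 0.612128, 0.716633, 0.90666, 0.563951,
                    1.409753, 0.413709, 0.439375),
        angle4 = c(0.867152, 0.602485, 0.935825, 0.639532, 0.523184,
                   1.914886, 0.417504, 0.392917),
        narrow = c(1.663625, 1.35678, 1.731377, 1.992577, 1.543251,
                   3.311618, 0.775613, 1.072371)),
      pooled_sd = c(length2 = 4.7191, angle4 = 4.5696, narrow = 11.0136)
    )
  )
}

#' Construct a population specification for simulation
#'
#' A `population_spec` carries everything [simulate_features()] needs:
#' per-taxon labels, sizes and mean vectors over a variable set, a
#' pooled within-class SD per variable, and a within-class correlation
#' matrix (identity by default; the published tables print no
#' covariances, and the three final discriminators are reported as
#' uncorrelated).
#'
#' @param labels Character vector of group labels.
#' @param n Integer vector of per-group sizes (>= 2).
#' @param means Numeric matrix, groups x variables, with column names.
#' @param pooled_sd Named per-variable pooled within-class SDs (>= 0).
#' @param correlation Within-class correlation matrix (symmetric
#'   positive definite, unit diagonal); default identity.
#' @param level Optional tag ("subfamily", "genus", "species", ...).
#' @param group_sds Optional groups x variables matrix of per-group
#'   SDs (used when `use_group_sds = TRUE` in [simulate_features()]).
#' @return Object of class `population_spec`.
#' @export
population_spec <- function(labels, n, means, pooled_sd,
                            correlation = NULL, level = NA_character_,
                            group_sds = NULL) {
  means <- as.matrix(means)
  stopifnot(length(labels) == nrow(means), length(n) == nrow(means),
            all(n >= 2), length(pooled_sd) == ncol(means),
            all(pooled_sd >= 0))
  p <- ncol(means)
  if (is.null(correlation)) correlation <- diag(p)
  correlation <- as.matrix(correlation)
  if (!isTRUE(all.equal(correlation, t(correlation))) ||
      any(abs(diag(correlation) - 1) > 1e-12)) {
    stop("correlation must be symmetric with unit diagonal", call. = FALSE)
  }
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("correlation matrix is not positive definite",
                         call. = FALSE)
  if (is.null(colnames(means))) colnames(means) <- names(pooled_sd)
  if (is.null(colnames(means))) colnames(means) <- paste0("V", seq_len(p))
  rownames(means) <- labels
  if (!is.null(group_sds)) {
    group_sds <- as.matrix(group_sds)
    dimnames(group_sds) <- dimnames(means)
  }
  structure(list(labels = labels, n = as.integer(n), means = means,
                 pooled_sd = setNames(as.numeric(pooled_sd),
                                      colnames(means)),
                 correlation = correlation, level = level,
                 group_sds = group_sds,
                 variables = colnames(means)),
            class = "population_spec")
}

#' Built-in population specifications from the published tables
#'
#' Returns the generative parameters for the three discriminators
#' (`length2`, `angle4`, `narrow`) at a taxonomic level, as published:
#' per-group Ns and means, per-variable pooled within-class SDs, and
#' per-group SDs recovered from the printed standard errors
#' (SD = StdErr * sqrt(N)).  The within-class correlation defaults to
#' identity.  Group sizes for simulation are the `length2` ones; the
#' full per-variable N matrix is attached as `attr(, "n_by_variable")`
#' (at the subfamily level, angle4/narrow have N = 207 rather than 178
#' for Chrysomyinae).
#'
#' @param level `"subfamily"` (3 groups), `"genus"` (6 groups) or
#'   `"species"` (8 groups; the two pre-filter species are excluded
#'   from measured analyses).
#' @return A `population_spec`.
#' @export
#' @examples
#' sp <- builtin_population_specs("species")
#' sum(sp$n)  # 465
builtin_population_specs <- function(level = c("subfamily", "genus",
                                               "species")) {
  level <- match.arg(level)
  tb <- builtin_tables()[[level]]
  spec <- population_spec(
    labels = tb$groups,
    n = tb$n[, "length2"],
    means = tb$means,
    pooled_sd = tb$pooled_sd,
    level = level,
    group_sds = tb$stderr * sqrt(tb$n)
  )
  attr(spec, "n_by_variable") <- tb$n
  spec
}

#' Simulate a grouped feature table from a population specification
#'
#' Draws, for each taxon, `n` observations from a multivariate normal
#' with the spec's mean vector and covariance (SD diagonal times the
#' correlation matrix).  With all-zero SDs the draws equal the group
#' means exactly.
#'
#' @param spec A `population_spec`.
#' @param seed Optional integer seed for reproducibility.
#' @param n_per_group Optional single size or per-group vector
#'   overriding the spec's sizes.
#' @param use_group_sds Use per-group SDs instead of the pooled SDs
#'   (requires `spec$group_sds`); only the pooled-SD path reproduces
#'   published pooled-SD-based test rows exactly.
#' @return Data frame: `group` factor plus one column per variable.
#' @export
simulate_features <- function(spec, seed = NULL, n_per_group = NULL,
                              use_group_sds = FALSE) {
  stopifnot(inherits(spec, "population_spec"))
  if (!is.null(seed)) set.seed(seed)
  ns <- if (is.null(n_per_group)) spec$n else
    rep_len(as.integer(n_per_group), length(spec$labels))
  p <- ncol(spec$means)
  out <- vector("list", length(spec$labels))
  for (i in seq_along(spec$labels)) {
    sds <- if (use_group_sds) {
      if (is.null(spec$group_sds)) stop("spec has no per-group SDs",
                                        call. = FALSE)
      spec$group_sds[i, ]
    } else spec$pooled_sd
    D <- diag(as.numeric(sds), p)
    Sigma <- D %*% spec$correlation %*% D
    draws <- if (all(sds == 0)) {
      matrix(rep(spec$means[i, ], each = ns[i]), ns[i], p)
    } else {
      MASS::mvrnorm(ns[i], mu = spec$means[i, ], Sigma = Sigma)
    }
    colnames(draws) <- spec$variables
    out[[i]] <- data.frame(group = spec$labels[i], draws,
                           stringsAsFactors = FALSE,
                           check.names = FALSE)
  }
  res <- do.call(rbind, out)
  res$group <- factor(res$group, levels = spec$labels)
  rownames(res) <- NULL
  res
}

## ---- inverse geometry ----------------------------------------------

#' Layout parameters for landmark synthesis
#'
#' Controls where [synthesize_landmarks()] places slit anchors when
#' width targets leave freedom: spacing between within-plate slit
#' anchors and the separation between the plates, both in image units.
#'
#' @param slit_spacing Distance between consecutive slit anchors
#'   within a plate (default 20).
#' @param plate_separation Gap between the left and right plates
#'   (default 60).
#' @return Object of class `landmark_layout`.
#' @export
landmark_layout <- function(slit_spacing = 20, plate_separation = 60) {
  stopifnot(slit_spacing > 0, plate_separation > 0)
  structure(list(slit_spacing = slit_spacing,
                 plate_separation = plate_separation),
            class = "landmark_layout")
}

# Intersection of circles |z - c1| = r1 and |z - c2| = r2; returns both
# solutions as rows (identical rows at tangency), or NULL if the
# circles do not intersect.
circle_intersect <- function(c1, r1, c2, r2) {
  d <- sqrt(sum((c2 - c1)^2))
  if (d < 1e-12) {
    if (abs(r1 - r2) > 1e-9 * max(1, r1)) return(NULL)
    p <- c1 + c(r1, 0)
    return(rbind(p, p, deparse.level = 0))
  }
  if (d > r1 + r2 + 1e-9 * max(1, d) ||
      d < abs(r1 - r2) - 1e-9 * max(1, d)) {
    return(NULL)
  }
  a <- (d^2 + r1^2 - r2^2) / (2 * d)
  h <- sqrt(max(r1^2 - a^2, 0))
  e <- (c2 - c1) / d
  perp <- h * c(-e[2L], e[1L])
  foot <- c1 + a * e
  rbind(foot + perp, foot - perp, deparse.level = 0)
}

#' Synthesize a landmark configuration realizing target features
#'
#' Places 12 points such that [extract_features()] recovers the six
#' requested slit lengths and adjusted angles to numerical precision,
#' and — when `widths` are supplied — the six plate widths as well.
#' Slit start points act as anchors; each end point is the start plus
#' the slit vector (length and raw angle; right-plate raw angles are
#' generated as 180 minus the adjusted target so the adjustment
#' convention round-trips).  Width constraints are solved in closed
#' form by circle intersection; geometrically inconsistent targets
#' (e.g. a narrow width no placement can achieve) raise an
#' infeasibility error.  The construction is deterministic.
#'
#' @param lengths Numeric vector of 6 positive slit lengths.
#' @param angles Numeric vector of 6 adjusted angles in (0, 180).
#' @param widths Optional named vector with `wideL`, `narrowL`,
#'   `wideR`, `narrowR`, `wide`, `narrow` (all positive).  When
#'   omitted, anchors fall on a default grid set by `layout`.
#' @param layout A [landmark_layout()].
#' @return 12 x 2 landmark matrix (row k = point k).
#' @export
#' @examples
#' lm <- synthesize_landmarks(rep(50, 6), rep(90, 6))
#' plate_widths(lm)
synthesize_landmarks <- function(lengths, angles, widths = NULL,
                                 layout = landmark_layout()) {
  stopifnot(length(lengths) == 6L, length(angles) == 6L,
            inherits(layout, "landmark_layout"))
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("infeasible targets: slit lengths must be positive",
         call. = FALSE)
  }
  if (any(!is.finite(angles)) || any(angles <= 0) || any(angles >= 180)) {
    stop("infeasible targets: adjusted angles must lie in (0, 180)",
         call. = FALSE)
  }
  raw <- ifelse(seq_len(6L) <= 3L, angles, 180 - angles)
  th <- raw * pi / 180
  v <- cbind(lengths * cos(th), lengths * sin(th))  # slit vectors

  ss <- layout$slit_spacing
  if (is.null(widths)) {
    x0 <- 2 * ss + layout$plate_separation
    anchors <- rbind(c(0, 0), c(ss, 0), c(2 * ss, 0),
                     c(x0, 0), c(x0 + ss, 0), c(x0 + 2 * ss, 0))
  } else {
    need <- c("wideL", "narrowL", "wideR", "narrowR", "wide", "narrow")
    if (!all(need %in% names(widths))) {
      stop("widths must name: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    wd <- widths[need]
    if (any(!is.finite(wd)) || any(wd <= 0)) {
      stop("infeasible targets: widths must be positive", call. = FALSE)
    }
    s1 <- c(0, 0)
    # left plate: |s3| = wideL and |(v1 - v3) - s3| = narrowL
    s3_sol <- circle_intersect(c(0, 0), wd[["wideL"]],
                               v[1L, ] - v[3L, ], wd[["narrowL"]])
    # right plate internal geometry: w' = s6 - s4 with |w'| = wideR
    # and |(v4 - v6) - w'| = narrowR
    wp_sol <- circle_intersect(c(0, 0), wd[["wideR"]],
                               v[4L, ] - v[6L, ], wd[["narrowR"]])
    if (is.null(s3_sol) || is.null(wp_sol)) {
      stop("infeasible width targets: requested within-plate widths ",
           "cannot be realized with these slit vectors", call. = FALSE)
    }
    # between plates: s4 = c0 + t with |t| = narrow (the point-6 to
    # point-8 offset) and |s6 - s1| = |c0 + t + w'| = wide.  Each
    # within-plate solution has a mirror twin; take the first
    # combination that admits a between-plate solution (deterministic
    # search order).
    anchors <- NULL
    for (i in 1:2) {
      for (j in 1:2) {
        s3 <- s3_sol[i, ]
        wprime <- wp_sol[j, ]
        c0 <- s3 + v[3L, ] - v[4L, ]
        z <- c0 + wprime
        t_sol <- circle_intersect(c(0, 0), wd[["narrow"]], -z,
                                  wd[["wide"]])
        if (is.null(t_sol)) next
        s4 <- c0 + t_sol[1L, ]
        s6 <- s4 + wprime
        anchors <- rbind(s1, (s1 + s3) / 2, s3,
                         s4, (s4 + s6) / 2, s6)
        break
      }
      if (!is.null(anchors)) break
    }
    if (is.null(anchors)) {
      stop("infeasible width targets: requested distances cannot be ",
           "realized simultaneously", call. = FALSE)
    }
  }
  pts <- matrix(NA_real_, 12L, 2L)
  for (k in 1:6) {
    pts[2L * k - 1L, ] <- anchors[k, ]
    pts[2L * k, ] <- anchors[k, ] + v[k, ]
  }
  colnames(pts) <- c("x", "y")
  pts
}

#' Simulate a full specimen table with synthesized landmarks
#'
#' Draws discriminator values (`length2`, `angle4`, `narrow`) from a
#' built-in or user population spec and realizes each draw as a
#' 12-point landmark configuration via [synthesize_landmarks()], so
#' the landmark-to-identification pipeline can run end to end.
#' Non-target slits get fixed nominal lengths/angles; the remaining
#' widths are set relative to the drawn `narrow`.  Optionally appends
#' the two pre-filter taxa (folded-labellum *Cochliomyia hominivorax*
#' and large-papillae *Protophormia terraenovae*) as qualitative-only
#' records without landmarks, in their published sample sizes.
#'
#' @param level Taxonomic level for [builtin_population_specs()], or a
#'   `population_spec` with variables `length2`, `angle4`, `narrow`.
#' @param seed Optional integer seed.
#' @param n_per_group Optional override of per-group sizes.
#' @param include_prefilter_taxa Append the two diagnosable species?
#'   (Default `FALSE`.)
#' @param layout A [landmark_layout()].
#' @return A `specimen_table`.
#' @export
simulate_specimens <- function(level = "species", seed = NULL,
                               n_per_group = NULL,
                               include_prefilter_taxa = FALSE,
                               layout = landmark_layout()) {
  spec <- if (inherits(level, "population_spec")) level else
    builtin_population_specs(level)
  stopifnot(all(c("length2", "angle4", "narrow") %in% spec$variables))
  feats <- simulate_features(spec, seed = seed, n_per_group = n_per_group)
  n <- nrow(feats)
  coords <- matrix(NA_real_, n, 24L,
                   dimnames = list(NULL, coordinate_names()))
  for (i in seq_len(n)) {
    nr <- max(feats$narrow[i], 10)
    # non-target slits get fixed, deliberately non-parallel geometry so
    # the within-plate width targets below are always self-consistent
    lengths <- c(48, feats$length2[i], 52, 50, 46, 54)
    angles <- c(40, 45, 50, min(max(feats$angle4[i], 1), 179), 48, 42)
    lm <- synthesize_landmarks(
      lengths = lengths, angles = angles,
      widths = implied_widths(lengths, angles, nr, layout),
      layout = layout)
    coords[i, paste0("x", 1:12)] <- lm[, 1L]
    coords[i, paste0("y", 1:12)] <- lm[, 2L]
  }
  tab <- data.frame(specimen_id = sprintf("sim%04d", seq_len(n)),
                    as.data.frame(coords),
                    papillae = 0, operculum = 1, labellum = FALSE,
                    stringsAsFactors = FALSE)
  lvl <- if (is.na(spec$level)) "species" else spec$level
  grp <- as.character(feats$group)
  if (lvl == "species") {
    tab$species <- grp
    tab$genus <- vapply(strsplit(grp, " "), `[`, "", 1L)
    tab$subfamily <- genus_subfamily(tab$genus)
  } else if (lvl == "genus") {
    tab$genus <- grp
    tab$subfamily <- genus_subfamily(grp)
  } else {
    tab[[lvl]] <- grp
  }
  if (isTRUE(include_prefilter_taxa)) {
    extra <- data.frame(
      specimen_id = c(sprintf("chom%02d", 1:11), sprintf("pter%02d", 1:31)),
      species = rep(c("Cochliomyia hominivorax",
                      "Protophormia terraenovae"), c(11L, 31L)),
      papillae = rep(c(0, 2), c(11L, 31L)),
      operculum = 1,
      labellum = rep(c(TRUE, FALSE), c(11L, 31L)),
      stringsAsFactors = FALSE)
    for (cc in coordinate_names()) extra[[cc]] <- NA_real_
    extra$genus <- vapply(strsplit(extra$species, " "), `[`, "", 1L)
    extra$subfamily <- genus_subfamily(extra$genus)
    tab <- rbind(tab[names(tab)], extra[names(tab)])
  }
  as_specimen_table(tab)
}

# Width targets consistent with the given slit geometry: anchor the
# plates on the default grid, read off the within-plate widths that
# placement implies, and set the between-plate widths from the target
# narrowest distance (the wide distance follows the same placement).
implied_widths <- function(lengths, angles, narrow, layout) {
  raw <- ifelse(seq_len(6L) <= 3L, angles, 180 - angles)
  th <- raw * pi / 180
  v <- cbind(lengths * cos(th), lengths * sin(th))
  s3 <- c(2 * layout$slit_spacing, 0)
  wprime <- c(2 * layout$slit_spacing, 0)
  c0 <- s3 + v[3L, ] - v[4L, ]
  z <- c0 + wprime
  c(wideL = sqrt(sum(s3^2)),
    narrowL = sqrt(sum((v[1L, ] - v[3L, ] - s3)^2)),
    wideR = sqrt(sum(wprime^2)),
    narrowR = sqrt(sum((v[4L, ] - v[6L, ] - wprime)^2)),
    wide = sqrt(sum(z^2)) + 0.8 * narrow,
    narrow = narrow)
}

genus_subfamily <- function(genus) {
  map <- c(Calliphora = "Calliphorinae", Cynomya = "Calliphorinae",
           Chrysomya = "Chrysomyinae", Cochliomyia = "Chrysomyinae",
           Phormia = "Chrysomyinae", Protophormia = "Chrysomyinae",
           Lucilia = "Luciliinae")
  unname(map[genus])
}

#' Specimen background counts shipped with the package
#'
#' Reads the background specimen table (taxon, count, location, source
#' and diet for every collection batch; 505 specimens in total across
#' 10 species).
#'
#' @return Data frame with columns `subfamily`, `genus`, `species`,
#'   `n`, `location`, `source`, `diet`.
#' @export
specimen_counts <- function() {
  path <- system.file("extdata", "specimen_counts.csv",
                      package = "puparia", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
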
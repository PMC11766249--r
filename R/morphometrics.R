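## Geometry of the spiracular plates.  Slit k runs from point 2k-1 to
## point 2k; slits 1-3 sit on the left plate, slits 4-6 on the right.
## Angles are measured against a user-set horizontal (the digitization
## reference line); right-plate angles are folded to a common positive
## basis by subtracting from 180 degrees.

#' Euclidean length of a spiracular slit
#'
#' @param start,end Numeric length-2 vectors `c(x, y)`.
#' @return Non-negative distance, symmetric in its arguments.
#' @export
#' @examples
#' slit_length(c(0, 0), c(3, 4))  # 5
slit_length <- function(start, end) {
  stopifnot(length(start) == 2L, length(end) == 2L,
            all(is.finite(start)), all(is.finite(end)))
  sqrt(sum((end - start)^2))
}

#' Raw and adjusted angle of a spiracular slit
#'
#' The raw angle is the undirected angle between the slit segment and
#' the reference horizontal, mapped to \[0, 180); it is invariant to
#' swapping the two endpoints.  Right-plate slits (indices 4-6) are
#' adjusted to the common positive basis by subtracting from 180
#' degrees; left-plate slits (1-3) keep the raw angle.
#'
#' @param start,end Numeric length-2 points; must be distinct.
#' @param slit_index Integer 1..6.
#' @param axis Orientation of the reference horizontal in degrees
#'   (default 0: the x-axis is the user-set 180-degree line).
#' @return Named numeric vector `c(raw = , adjusted = )`, degrees.
#' @export
#' @examples
#' slit_angle(c(0, 0), c(1, 1), slit_index = 5)  # raw 45, adjusted 135
slit_angle <- function(start, end, slit_index, axis = 0) {
  stopifnot(length(start) == 2L, length(end) == 2L,
            all(is.finite(start)), all(is.finite(end)),
            slit_index %in% 1:6, is.finite(axis))
  v <- end - start
  if (all(v == 0)) {
    stop("degenerate geometry: slit ", slit_index,
         " has coincident endpoints", call. = FALSE)
  }
  raw <- unname((atan2(v[2L], v[1L]) * 180 / pi - axis) %% 180)
  adjusted <- if (slit_index <= 3L) raw else 180 - raw
  c(raw = raw, adjusted = adjusted)
}

#' Plate widths from a landmark configuration
#'
#' The six width measures are distances between fixed 1-based point
#' pairs: widest within the left plate (points 1-5), narrowest within
#' the left plate (2-6), widest right (7-11), narrowest right (8-12),
#' widest between plates (1-11), narrowest between plates (6-8).
#'
#' @param landmarks A 12 x 2 numeric matrix, row `k` = point `k`.
#' @return Named numeric vector `wideL`, `narrowL`, `wideR`, `narrowR`,
#'   `wide`, `narrow`.
#' @export
plate_widths <- function(landmarks) {
  landmarks <- as.matrix(landmarks)
  stopifnot(nrow(landmarks) == 12L, ncol(landmarks) == 2L,
            all(is.finite(landmarks)))
  d <- function(i, j) sqrt(sum((landmarks[i, ] - landmarks[j, ])^2))
  c(wideL = d(1, 5), narrowL = d(2, 6),
    wideR = d(7, 11), narrowR = d(8, 12),
    wide = d(1, 11), narrow = d(6, 8))
}

#' Landmark matrix from a specimen-table row
#'
#' @param row One row of a `specimen_table`.
#' @return 12 x 2 matrix of coordinates, or `NULL` if the landmark
#'   block is absent.
#' @keywords internal
landmarks_matrix <- function(row) {
  xs <- as.numeric(row[paste0("x", 1:12)])
  ys <- as.numeric(row[paste0("y", 1:12)])
  if (anyNA(xs) || anyNA(ys)) return(NULL)
  cbind(x = xs, y = ys)
}

features_from_landmarks <- function(lm, papillae, operculum,
                                    axis = 0, scale = 1) {
  lengths <- numeric(6L)
  angles <- numeric(6L)
  for (k in 1:6) {
    s <- lm[2L * k - 1L, ]
    e <- lm[2L * k, ]
    lengths[k] <- slit_length(s, e) * scale
    angles[k] <- slit_angle(s, e, k, axis = axis)[["adjusted"]]
  }
  w <- plate_widths(lm) * scale
  mean_wide_within <- (w[["wideL"]] + w[["wideR"]]) / 2
  mean_narrow_within <- (w[["narrowL"]] + w[["narrowR"]]) / 2
  out <- c(
    setNames(lengths, paste0("length", 1:6)),
    setNames(angles, paste0("angle", 1:6)),
    w,
    total_within = w[["wideL"]] + w[["narrowL"]] + w[["wideR"]] + w[["narrowR"]],
    total_between = w[["wide"]] + w[["narrow"]],
    ratio_within = if (mean_narrow_within > 0)
      mean_wide_within / mean_narrow_within else NA_real_,
    ratio_between = if (w[["narrow"]] > 0)
      w[["wide"]] / w[["narrow"]] else NA_real_,
    meanWideWithin = mean_wide_within,
    meanNarrowWithin = mean_narrow_within,
    meanWideAll = (w[["wideL"]] + w[["wideR"]] + w[["wide"]]) / 3,
    meanNarrowAll = (w[["narrowL"]] + w[["narrowR"]] + w[["narrow"]]) / 3,
    totalSlitLength = sum(lengths),
    papillae = as.numeric(papillae),
    operculum = as.numeric(operculum)
  )
  out[feature_names()]
}

#' Extract the 27 morphometric variables from digitized landmarks
#'
#' Converts every specimen's 12-point landmark configuration into the
#' canonical feature set (see [feature_names()]): slit lengths and
#' adjusted angles for slits 1-6, the six plate widths, width totals
#' within and between plates, wide/narrow ratios, four width means, the
#' total slit length, and the copied qualitative scores.  Degenerate
#' zero-width denominators yield `NA` ratios rather than infinities.
#'
#' @param specimens A `specimen_table` (every row must carry a complete
#'   landmark block; pre-filter qualitative-only specimens out first,
#'   see [dichotomous_prefilter()]).
#' @param axis Reference-horizontal orientation in degrees (default 0).
#' @param scale Optional units-per-pixel factor multiplying all
#'   distances (angles are unaffected).  Default 1 (image units).
#' @return Data frame: metadata columns followed by the 27 variables in
#'   canonical order, one row per specimen, input order preserved.
#' @export
extract_features <- function(specimens, axis = 0, scale = 1) {
  specimens <- as_specimen_table(as.data.frame(specimens))
  stopifnot(is.finite(axis), is.finite(scale), scale > 0)
  n <- nrow(specimens)
  feats <- matrix(NA_real_, n, length(feature_names()),
                  dimnames = list(NULL, feature_names()))
  for (i in seq_len(n)) {
    lm <- landmarks_matrix(specimens[i, ])
    if (is.null(lm)) {
      stop("specimen '", specimens$specimen_id[i],
           "' has no landmark block; it can only pass through the ",
           "dichotomous pre-filter", call. = FALSE)
    }
    feats[i, ] <- features_from_landmarks(
      lm, specimens$papillae[i], specimens$operculum[i],
      axis = axis, scale = scale)
  }
  meta <- specimens[intersect(meta_names(), names(specimens))]
  cbind(as.data.frame(meta, stringsAsFactors = FALSE),
        as.data.frame(feats))
}
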
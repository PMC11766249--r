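## Specimen tables: one row per puparium, 12 digitized landmarks
## (x1,y1 .. x12,y12; points 1-12 are the start/end points of the six
## spiracular slits, left plate = slits 1-3 = points 1-6, right plate =
## slits 4-6 = points 7-12), two scored qualitative characters and the
## folded-labellum flag, plus taxonomic / collection metadata.

#' Canonical names of the morphometric feature columns
#'
#' Returns the canonical column order used throughout the package for
#' feature tables: six slit lengths, six adjusted slit angles, four
#' within-plate widths (`wideL`, `narrowL`, `wideR`, `narrowR`), two
#' between-plate widths (`wide`, `narrow`), the within- and between-plate
#' width totals, the two wide/narrow ratios, four width means, the total
#' slit length, and the two scored characters (`papillae`, `operculum`).
#'
#' This is the 27-variable candidate set of the screening analysis
#' (scores, lengths, angles, the six widths, two ratios, four means and
#' the total slit length) plus the two auxiliary width totals, 29
#' columns in all.
#'
#' @return Character vector of length 29.
#' @export
#' @examples
#' feature_names()
feature_names <- function() {
  c(paste0("length", 1:6), paste0("angle", 1:6),
    "wideL", "narrowL", "wideR", "narrowR", "wide", "narrow",
    "total_within", "total_between", "ratio_within", "ratio_between",
    "meanWideWithin", "meanNarrowWithin", "meanWideAll", "meanNarrowAll",
    "totalSlitLength", "papillae", "operculum")
}

coordinate_names <- function() {
  as.vector(rbind(paste0("x", 1:12), paste0("y", 1:12)))
}

meta_names <- function() {
  c("specimen_id", "subfamily", "genus", "species",
    "sex", "location", "diet", "source")
}

#' Validate a specimen table
#'
#' Checks the structural invariants of a specimen table: the 24
#' coordinate columns are present and numeric, each row's landmark block
#' is either complete (all 24 coordinates finite) or entirely absent
#' (all `NA`, for specimens recorded by qualitative characters only),
#' the two endpoints of every slit are distinct, `papillae` is in
#' \{0, 1, 2\}, `operculum` in \{0, 1\}, `labellum` is logical, and
#' `specimen_id` values are unique.
#'
#' @param x A data frame with the columns of [read_specimens()].
#' @return `x` invisibly, with class `specimen_table` prepended.
#' @export
as_specimen_table <- function(x) {
  stopifnot(is.data.frame(x))
  cn <- coordinate_names()
  missing_cols <- setdiff(c("specimen_id", cn, "papillae", "operculum",
                            "labellum"), names(x))
  if (length(missing_cols) > 0L) {
    stop("specimen table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (cc in cn) {
    if (!is.numeric(x[[cc]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(x[[cc]])))) &
                   !is.na(x[[cc]]) & as.character(x[[cc]]) != "")
      stop("non-numeric coordinate in column '", cc, "' at row ",
           if (length(bad)) bad[1L] else "?", call. = FALSE)
    }
  }
  coords <- as.matrix(x[cn])
  n_na <- rowSums(is.na(coords))
  mixed <- which(n_na > 0L & n_na < 24L)
  if (length(mixed) > 0L) {
    stop("row ", mixed[1L], ": landmark block must be complete (24 ",
         "coordinates) or entirely empty", call. = FALSE)
  }
  inf <- which(n_na == 0L & rowSums(!is.finite(coords)) > 0L)
  if (length(inf) > 0L) {
    stop("row ", inf[1L], ": non-finite landmark coordinate", call. = FALSE)
  }
  has_lm <- n_na == 0L
  for (k in 1:6) {
    # endpoints of slit k are points 2k-1 and 2k
    sx <- coords[has_lm, 2L * (2L * k - 1L) - 1L]
    sy <- coords[has_lm, 2L * (2L * k - 1L)]
    ex <- coords[has_lm, 2L * (2L * k) - 1L]
    ey <- coords[has_lm, 2L * (2L * k)]
    same <- which(sx == ex & sy == ey)
    if (length(same) > 0L) {
      stop("slit ", k, " has coincident endpoints in row ",
           which(has_lm)[same[1L]], call. = FALSE)
    }
  }
  if (!all(x$papillae %in% c(0, 1, 2))) {
    stop("papillae score must be 0, 1 or 2 (row ",
         which(!x$papillae %in% c(0, 1, 2))[1L], ")", call. = FALSE)
  }
  if (!all(x$operculum %in% c(0, 1))) {
    stop("operculum score must be 0 or 1 (row ",
         which(!x$operculum %in% c(0, 1))[1L], ")", call. = FALSE)
  }
  if (!is.logical(x$labellum)) {
    if (all(x$labellum %in% c(0, 1, NA))) {
      x$labellum <- as.logical(x$labellum)
    } else {
      stop("labellum must be logical (TRUE/FALSE or 0/1)", call. = FALSE)
    }
  }
  if (anyDuplicated(x$specimen_id)) {
    stop("duplicate specimen_id: ",
         x$specimen_id[anyDuplicated(x$specimen_id)], call. = FALSE)
  }
  for (mc in setdiff(meta_names(), names(x))) x[[mc]] <- NA_character_
  class(x) <- unique(c("specimen_table", class(x)))
  invisible(x)
}

#' Read a specimen landmark table
#'
#' Reads a CSV (or tab-separated) table with one row per specimen.  The
#' header must declare the 24 coordinate columns `x1,y1 .. x12,y12`
#' (point indices are 1-based, matching the digitization scheme: points
#' \eqn{2k-1} and \eqn{2k} are the start and end of slit \eqn{k}), the
#' scored characters `papillae` (0/1/2), `operculum` (0/1) and
#' `labellum` (logical: folded spiracular labellum), and any of the
#' metadata columns `specimen_id`, `subfamily`, `genus`, `species`,
#' `sex`, `location`, `diet`, `source`.  An entirely empty landmark
#' block is allowed and marks a specimen recorded by qualitative
#' characters only (such specimens can pass through the dichotomous
#' pre-filter but not the measurement pipeline).
#'
#' @param path Path to the file.
#' @param sep Field separator; `","` (default) or `"\t"` for
#'   tab-separated exports.
#' @return A `specimen_table` data frame, rows in file order.
#' @seealso [write_specimens()], [extract_features()]
#' @export
read_specimens <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         check.names = FALSE)
  cn <- coordinate_names()
  missing_cols <- setdiff(cn, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing coordinate column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- grep("^[xy][0-9]+$", names(raw), value = TRUE)
  extra <- setdiff(extra, cn)
  if (length(extra) > 0L) {
    stop("unexpected coordinate column(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  for (cc in cn) {
    v <- raw[[cc]]
    if (!is.numeric(v)) {
      chr <- trimws(as.character(v))
      num <- suppressWarnings(as.numeric(chr))
      bad <- which(is.na(num) & !is.na(chr) & chr != "")
      if (length(bad) > 0L) {
        stop("non-numeric coordinate '", chr[bad[1L]], "' in column '",
             cc, "', row ", bad[1L], call. = FALSE)
      }
      raw[[cc]] <- num
    }
  }
  if (is.null(raw$specimen_id)) raw$specimen_id <- as.character(seq_len(nrow(raw)))
  raw$specimen_id <- as.character(raw$specimen_id)
  as_specimen_table(raw)
}

fmt_num <- function(v) {
  # full double precision so that write -> read is the identity
  out <- vapply(v, function(z) {
    if (is.na(z)) "" else sprintf("%.17g", z)
  }, character(1L))
  out
}

#' Write a specimen landmark table
#'
#' Writes a `specimen_table` as CSV with numeric fields at full double
#' precision, so [read_specimens()] recovers the values bit-for-bit.
#'
#' @param x A `specimen_table` (see [as_specimen_table()]).
#' @param path Output file path.
#' @param sep Field separator, default `","`.
#' @return `path`, invisibly.
#' @export
write_specimens <- function(x, path, sep = ",") {
  x <- as_specimen_table(as.data.frame(x))
  cols <- c(intersect(meta_names(), names(x)), coordinate_names(),
            "papillae", "operculum", "labellum")
  out <- x[cols]
  for (cc in coordinate_names()) out[[cc]] <- fmt_num(out[[cc]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a feature table
#'
#' Writes the output of [extract_features()] (metadata columns plus the
#' 27 morphometric variables in the canonical [feature_names()] order)
#' as CSV at full float precision.  All rows must carry the same
#' variable set.
#'
#' @param x Data frame with metadata columns and the 27 feature columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  x <- as.data.frame(x)
  fn <- feature_names()
  missing_cols <- setdiff(fn, names(x))
  if (length(missing_cols) > 0L) {
    stop("feature table is missing variable(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cols <- c(intersect(meta_names(), names(x)), fn)
  out <- x[cols]
  for (cc in fn) out[[cc]] <- fmt_num(as.numeric(out[[cc]]))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path Path to the CSV.
#' @return Data frame with metadata and the 27 feature columns.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(feature_names(), names(x))
  if (length(missing_cols) > 0L) {
    stop("feature table is missing variable(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (v in feature_names()) x[[v]] <- as.numeric(x[[v]])
  x
}
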
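#' Construct a sample table of shoot radiocesium measurements
#'
#' A sample table holds one row per measured individual: the stand it was
#' collected in, its species, the origin of the stem (0 = coppice sprout,
#' 1 = plantation), the measured radiocesium activity concentration in
#' Bq kg^-1, and whether the measurement was left-censored (below the
#' detection limit and therefore unusable in the likelihood).
#'
#' @param stand_id character or factor, stand labels (non-empty).
#' @param species character or factor, species labels (non-empty).
#' @param origin integer 0/1 per record (0 = sprout, 1 = plantation).
#' @param activity numeric, activity concentration in Bq kg^-1. May be `NA`
#'   for censored records; must be strictly positive when `censored` is FALSE.
#' @param censored logical per record; defaults to marking records with
#'   missing or non-positive activity as censored.
#' @param provenance free-text note recording where the data came from.
#'
#' @return A `sample_table`: a `data.frame` with columns `stand_id`,
#'   `species`, `origin`, `activity`, `censored` and a `provenance`
#'   attribute. Stand and species grouping uses order of first appearance,
#'   so groupings are stable under row duplication.
#' @export
sample_table <- function(stand_id, species, origin, activity,
                         censored = NULL, provenance = "constructed in R") {
  stand_id <- as.character(stand_id)
  species <- as.character(species)
  n <- length(stand_id)
  stopifnot(length(species) == n, length(origin) == n, length(activity) == n)
  if (any(!nzchar(stand_id)) || anyNA(stand_id)) {
    stop("stand_id values must be non-empty strings")
  }
  if (any(!nzchar(species)) || anyNA(species)) {
    stop("species values must be non-empty strings")
  }
  origin <- as.integer(origin)
  if (anyNA(origin) || !all(origin %in% c(0L, 1L))) {
    stop("origin must be 0 (sprout) or 1 (plantation) for every record")
  }
  activity <- as.numeric(activity)
  if (is.null(censored)) {
    censored <- is.na(activity) | activity <= 0
  }
  censored <- as.logical(censored)
  if (length(censored) != n || anyNA(censored)) {
    stop("censored must be a logical vector with one value per record")
  }
  bad <- !censored & (is.na(activity) | activity <= 0)
  if (any(bad)) {
    stop("activity must be strictly positive for non-censored records (rows ",
         paste(which(bad), collapse = ", "), ")")
  }
  out <- data.frame(stand_id = stand_id, species = species, origin = origin,
                    activity = activity, censored = censored,
                    stringsAsFactors = FALSE)
  structure(out, provenance = provenance,
            class = c("sample_table", "data.frame"))
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("<sample_table> %d records, %d stands, %d species (%d censored)\n",
              nrow(x), length(unique(x$stand_id)), length(unique(x$species)),
              sum(x$censored)))
  cat("provenance:", attr(x, "provenance"), "\n")
  NextMethod()
}

# default CSV column names; remappable because field data headers vary
.default_columns <- c(stand_id = "stand", species = "species",
                      origin = "origin", activity = "activity",
                      censored = "censored")

#' Read a sample table from CSV
#'
#' Reads a flat CSV with one row per sampled individual. Default column names
#' are `stand`, `species`, `origin`, `activity` and (optionally) `censored`;
#' pass `column_map` to adapt other headers. Rows whose activity cell is
#' missing, non-positive, or flagged in the censored column are marked
#' censored (below-detection conventions differ between labs, so all three
#' encodings are honoured). `origin` may be coded 0/1 or as the strings
#' `"sprout"`/`"plantation"`.
#'
#' @param path path to a CSV file (RFC 4180, UTF-8).
#' @param column_map optional named character vector mapping the canonical
#'   names `stand_id`, `species`, `origin`, `activity`, `censored` to the
#'   file's column names, e.g. `c(activity = "cs137_bq_kg")`.
#' @return A [sample_table] preserving the file's row order.
#' @export
read_samples <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  cols <- .default_columns
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), names(cols))
    if (length(unknown)) stop("unknown column_map entries: ",
                              paste(unknown, collapse = ", "))
    cols[names(column_map)] <- column_map
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  required <- c("stand_id", "species", "origin", "activity")
  for (field in required) {
    if (!cols[[field]] %in% names(raw)) {
      stop("missing required column '", cols[[field]], "' (", field,
           ") in ", path)
    }
  }
  act_raw <- trimws(raw[[cols[["activity"]]]])
  act_raw[act_raw %in% c("", "NA", "ND", "n.d.", "<DL")] <- NA
  activity <- suppressWarnings(as.numeric(act_raw))
  parse_fail <- !is.na(act_raw) & is.na(activity)

  flagged <- rep(FALSE, nrow(raw))
  if (cols[["censored"]] %in% names(raw)) {
    flag_raw <- tolower(trimws(raw[[cols[["censored"]]]]))
    flagged <- flag_raw %in% c("true", "t", "1", "yes", "y")
  }
  bad_parse <- which(parse_fail & !flagged)
  if (length(bad_parse)) {
    stop("non-numeric activity value on non-censored row(s): ",
         paste(bad_parse, collapse = ", "))
  }
  censored <- is.na(activity) | flagged | (!is.na(activity) & activity <= 0)
  origin_raw <- tolower(trimws(raw[[cols[["origin"]]]]))
  origin <- ifelse(origin_raw %in% c("1", "plantation", "planted"), 1L,
            ifelse(origin_raw %in% c("0", "sprout", "coppice"), 0L, NA_integer_))
  if (anyNA(origin)) {
    stop("unrecognised origin value on row(s): ",
         paste(which(is.na(origin)), collapse = ", "),
         " (expected 0/1 or sprout/plantation)")
  }
  sample_table(stand_id = raw[[cols[["stand_id"]]]],
               species = raw[[cols[["species"]]]],
               origin = origin, activity = activity, censored = censored,
               provenance = paste0("read from ", path))
}

#' Write a sample table to CSV
#'
#' Writes the same dialect [read_samples] reads: columns `stand`, `species`,
#' `origin` (0/1), `activity` (empty cell for censored records with no
#' recorded value), `censored` (true/false). A read/write/read round trip is
#' lossless.
#'
#' @param table a [sample_table].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(table, path) {
  stopifnot(inherits(table, "sample_table"))
  out <- data.frame(stand = table$stand_id, species = table$species,
                    origin = table$origin, activity = table$activity,
                    censored = tolower(as.character(table$censored)),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Drop left-censored records before likelihood-based analysis
#'
#' Detection limits for below-detection samples vary with counting time, so
#' censored records carry no usable concentration and are excluded from all
#' model fitting. Returns the filtered table together with the excluded
#' fraction so the accounting (e.g. 453 collected, 35 excluded, 7.7%) can be
#' reported alongside any fit.
#'
#' @param table a [sample_table].
#' @return A list with elements `table` (non-censored records only) and
#'   `excluded_fraction` (excluded count / total count).
#' @export
exclude_censored <- function(table) {
  stopifnot(inherits(table, "sample_table"))
  if (nrow(table) == 0L) stop("sample table is empty")
  keep <- !table$censored
  if (!any(keep)) stop("all records are censored; nothing to analyse")
  kept <- table[keep, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "provenance") <- attr(table, "provenance")
  class(kept) <- c("sample_table", "data.frame")
  list(table = kept, excluded_fraction = sum(!keep) / nrow(table))
}

#' Flag outliers by the 1.5 x IQR rule
#'
#' A value is flagged when it lies above Q3 + 1.5*IQR or below Q1 - 1.5*IQR.
#' Quartiles use linear-interpolation (type 7) quantiles; the rule is applied
#' to stand-level summaries when drawing box-plot style figures.
#'
#' @param values numeric vector (at least 4 values for a meaningful IQR;
#'   fewer give all-FALSE flags with a warning). `NA`s are never flagged.
#' @return logical vector of the same length.
#' @export
flag_outliers <- function(values) {
  values <- as.numeric(values)
  ok <- !is.na(values)
  if (sum(ok) < 4L) {
    warning("fewer than 4 non-missing values; no outliers flagged")
    return(rep(FALSE, length(values)))
  }
  q <- stats::quantile(values[ok], probs = c(0.25, 0.75), type = 7,
                       names = FALSE)
  iqr <- q[2] - q[1]
  flags <- ok & (values > q[2] + 1.5 * iqr | values < q[1] - 1.5 * iqr)
  flags
}

#' Locate the field-survey data file, if the user has supplied it
#'
#' The measured survey data (one CSV row per sampled shoot) are distributed
#' as supplementary material of the originating survey and have no public
#' accession, so they are not bundled. To run the integration checks
#' against them, either place the file at `inst/extdata/s1_table.csv`
#' before installing, or point `options(radshoots.s1_table = "/path.csv")`
#' at a copy.
#'
#' @return The path, or `NA_character_` when the file is unavailable.
#' @export
survey_data_path <- function() {
  opt <- getOption("radshoots.s1_table", NULL)
  if (!is.null(opt) && file.exists(opt)) return(opt)
  bundled <- system.file("extdata", "s1_table.csv", package = "radshoots")
  if (nzchar(bundled) && file.exists(bundled)) return(bundled)
  NA_character_
}

#' Stand-level summaries of log-transformed activity
#'
#' For each stand: the number of (non-censored) records, the mean and sample
#' standard deviation (n - 1 denominator) of the natural-log activity, and
#' outlier flags for the stand means and stand SDs under the 1.5 x IQR rule
#' (computed across stands, as in box-plot displays of stand summaries).
#'
#' @param table a [sample_table]; censored records must already have been
#'   removed with [exclude_censored].
#' @return A `data.frame` with columns `stand_id`, `n`, `mean_log`, `sd_log`
#'   (`NA` for single-record stands), `outlier_mean`, `outlier_sd`, ordered
#'   by first appearance of the stand.
#' @export
stand_summaries <- function(table) {
  stopifnot(inherits(table, "sample_table"))
  if (any(table$censored)) {
    stop("censored records present; call exclude_censored() first")
  }
  f <- factor(table$stand_id, levels = unique(table$stand_id))
  logs <- log(table$activity)
  n <- as.integer(tapply(logs, f, length))
  mean_log <- as.numeric(tapply(logs, f, mean))
  sd_log <- as.numeric(tapply(logs, f, function(v) {
    if (length(v) >= 2L) stats::sd(v) else NA_real_
  }))
  out <- data.frame(stand_id = levels(f), n = n, mean_log = mean_log,
                    sd_log = sd_log, stringsAsFactors = FALSE)
  out$outlier_mean <- if (nrow(out) >= 4L) flag_outliers(out$mean_log) else
    rep(FALSE, nrow(out))
  out$outlier_sd <- if (sum(!is.na(out$sd_log)) >= 4L)
    flag_outliers(out$sd_log) else rep(FALSE, nrow(out))
  out
}
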
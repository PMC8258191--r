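## Readers/writers for the delimited survey tables. Layouts are documented in
## inst/extdata/data_dictionary.md; all validation failures name the offending
## column or row so malformed field data fail loudly.

.required_cols <- list(
  weighings = c("sample_id", "taxon_name", "n_individuals", "raw_gain",
                "split_denominator", "n_subsamples", "is_control"),
  lengths   = c("sample_id", "taxon_name", "length"),
  stations  = c("station_id", "depth_m"),
  events    = c("event_id", "calendar_date")
)

.check_schema <- function(df, what) {
  missing <- setdiff(.required_cols[[what]], names(df))
  if (length(missing))
    stop(sprintf("%s table is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

.check_numeric <- function(x, col, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & is.na(v))
  if (length(bad))
    stop(sprintf("%s: non-numeric value in column '%s' at row(s) %s",
                 what, col, paste(utils::head(bad, 5), collapse = ", ")),
         call. = FALSE)
  v
}

#' Load a survey bundle from delimited text tables
#'
#' Reads the four survey tables (weighing records, length measurements,
#' stations, sampling events) from a directory or explicit file paths,
#' validates their schema and basic invariants, and returns a typed bundle.
#'
#' @details Validation rejects: missing required columns (named in the
#'   error), non-numeric masses or lengths (with row index), Motoda splits
#'   outside \{4, 8, 16\}, non-control records with zero individuals,
#'   non-positive lengths, and subsample volumes exceeding the dilution.
#'   Taxa not found in the reference table are kept but reported via a
#'   warning so they can be mapped or dropped explicitly; their conversion
#'   factors are left undefined downstream.
#'
#' @param dir directory containing `weighings.csv`, `lengths.csv`,
#'   `stations.csv`, `events.csv`; ignored if `paths` is given.
#' @param paths optional named list/vector with entries `weighings`,
#'   `lengths`, `stations`, `events`.
#' @param taxa reference taxon table used to flag unknown taxa; defaults to
#'   the packaged table.
#' @param quiet suppress the row-count message.
#' @return A list of class `"zoo_survey"` with elements `weighings`,
#'   `lengths`, `stations`, `events`.
#' @export
read_survey <- function(dir = NULL, paths = NULL,
                        taxa = load_reference_tables()$taxa, quiet = FALSE) {
  if (is.null(paths)) {
    if (is.null(dir)) stop("either 'dir' or 'paths' must be given")
    paths <- file.path(dir, c(weighings = "weighings.csv", lengths = "lengths.csv",
                              stations = "stations.csv", events = "events.csv"))
    names(paths) <- c("weighings", "lengths", "stations", "events")
  }
  for (p in paths) if (!file.exists(p)) stop("survey file not found: ", p)

  w <- .check_schema(utils::read.csv(paths[["weighings"]], stringsAsFactors = FALSE,
                                     colClasses = "character"), "weighings")
  l <- .check_schema(utils::read.csv(paths[["lengths"]], stringsAsFactors = FALSE,
                                     colClasses = "character"), "lengths")
  s <- .check_schema(utils::read.csv(paths[["stations"]], stringsAsFactors = FALSE),
                     "stations")
  e <- .check_schema(utils::read.csv(paths[["events"]], stringsAsFactors = FALSE),
                     "events")

  w$n_individuals     <- as.integer(.check_numeric(w$n_individuals, "n_individuals", "weighings"))
  w$raw_gain          <- .check_numeric(w$raw_gain, "raw_gain", "weighings")
  w$split_denominator <- as.integer(.check_numeric(w$split_denominator, "split_denominator", "weighings"))
  w$n_subsamples      <- as.integer(.check_numeric(w$n_subsamples, "n_subsamples", "weighings"))
  w$is_control        <- as.logical(w$is_control)
  if (is.null(w$stage_tag)) w$stage_tag <- NA_character_
  w$taxon_name <- normalize_taxon(w$taxon_name)

  l$length <- .check_numeric(l$length, "length", "lengths")
  if (is.null(l$stage_tag)) l$stage_tag <- NA_character_
  l$taxon_name <- normalize_taxon(l$taxon_name)

  e$calendar_date <- as.Date(e$calendar_date)
  if (is.null(e$day_of_year)) e$day_of_year <- as.integer(format(e$calendar_date, "%j"))

  validate_weighings(w)
  if (any(l$length <= 0)) stop("lengths: non-positive length values present")
  if (any(s$depth_m <= 0)) stop("stations: depths must be positive")

  known <- normalize_taxon(taxa$taxon_name)
  unknown <- setdiff(unique(w$taxon_name[!w$is_control]), known)
  if (length(unknown))
    warning("taxa not in the reference table (carried through unmapped): ",
            paste(unknown, collapse = ", "))
  if (!quiet)
    message(sprintf("survey loaded: %d weighings (%d controls), %d lengths, %d stations, %d events",
                    nrow(w), sum(w$is_control), nrow(l), nrow(s), nrow(e)))

  structure(list(weighings = w, lengths = l, stations = s, events = e),
            class = "zoo_survey")
}

validate_weighings <- function(w) {
  if (any(!w$is_control & (is.na(w$n_individuals) | w$n_individuals < 1)))
    stop("weighings: non-control records must have n_individuals >= 1")
  # control boats may lose mass (error is signed); plankton boats cannot
  if (any(!w$is_control & w$raw_gain < 0))
    stop("weighings: negative raw_gain on non-control records")
  if (any(w$is_control & w$n_individuals != 0))
    stop("weighings: control records must have n_individuals = 0")
  if (any(!w$split_denominator %in% c(4L, 8L, 16L)))
    stop("weighings: split_denominator must be one of 4, 8, 16")
  if (any(w$n_subsamples < 1 | w$n_subsamples > 100))
    stop("weighings: n_subsamples must be in 1..100 (2 ml each of 200 ml)")
  invisible(w)
}

#' @rdname read_survey
#' @param survey a `"zoo_survey"` bundle.
#' @export
write_survey <- function(survey, dir) {
  stopifnot(inherits(survey, "zoo_survey"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("weighings", "lengths", "stations", "events"))
    write_table_csv(survey[[nm]], file.path(dir, paste0(nm, ".csv")))
  invisible(dir)
}

#' Write a result table as CSV
#'
#' Thin wrapper around [utils::write.csv()] that warns on empty tables
#' (a header-only file is still written) and errors on unwritable paths.
#' Numeric round-trips through `read_table_csv()` are lossless to the
#' precision of `format()`'s 15 significant digits.
#'
#' @param x a data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  stopifnot(is.data.frame(x))
  if (nrow(x) == 0L) warning("writing empty table to ", path)
  ok <- tryCatch({
    utils::write.csv(x, path, row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ", conditionMessage(e)))
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Case-insensitive, whitespace-normalized taxon matching key; the canonical
# capitalization of the reference table is restored downstream by joining on
# this key.
normalize_taxon <- function(x) {
  x <- gsub("\\s+", " ", trimws(x))
  x
}

taxon_key <- function(x) tolower(normalize_taxon(x))
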
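#' Read gosling capture records
#'
#' Reads a CSV of gosling captures (columns `id`, `year`, `age_days`,
#' `mass_g`) and applies the capture-window filter: records with ages
#' outside `[capture_age_min, capture_age_max]` or non-positive mass are
#' dropped, with the dropped count reported via `message()` and attached as
#' the `"n_rejected"` attribute.
#'
#' @param path CSV file path.
#' @param config A [study_config()]; supplies the capture-age window.
#' @return A data frame with columns `id`, `year`, `age_days`, `mass_g`.
#' @export
read_gosling_records <- function(path, config = study_config()) {
  d <- read_checked_csv(path, c("id", "year", "age_days", "mass_g"))
  if (nrow(d) == 0) stop("no gosling records in ", path)
  ok <- !is.na(d$age_days) & !is.na(d$mass_g) & !is.na(d$year) &
    d$age_days >= config$capture_age_min &
    d$age_days <= config$capture_age_max &
    d$mass_g > 0
  n_rej <- sum(!ok)
  if (n_rej > 0)
    message("read_gosling_records: dropped ", n_rej,
            " record(s) outside the capture window or with invalid mass")
  out <- d[ok, c("id", "year", "age_days", "mass_g")]
  rownames(out) <- NULL
  if (nrow(out) == 0) stop("all gosling records were filtered out")
  out$year <- as.integer(out$year)
  out$age_days <- as.integer(out$age_days)
  attr(out, "n_rejected") <- n_rej
  out
}

#' Read aerial photo point-count samples
#'
#' Reads a CSV with columns `year`, `points_total`, `points_lawn`, one row
#' per photographic sample. Each row is a binomial trial: `points_total`
#' grid points overlaid on the photo, of which `points_lawn` fell on
#' *Carex subspathacea* grazing lawn.
#'
#' Rows violating `0 <= points_lawn <= points_total` (or with non-positive
#' `points_total`) are a data-corruption signal; by default the reader
#' errors naming the offending row. With `on_invalid = "drop"` such rows
#' are instead dropped, with their indices reported.
#'
#' @param path CSV file path.
#' @param on_invalid `"error"` (default) or `"drop"`.
#' @return Data frame with columns `year`, `points_total`, `points_lawn`
#'   and attribute `"n_rejected"`.
#' @export
read_photo_samples <- function(path, on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  d <- read_checked_csv(path, c("year", "points_total", "points_lawn"))
  if (nrow(d) == 0) stop("no photo samples in ", path)
  bad <- is.na(d$year) | is.na(d$points_total) | is.na(d$points_lawn) |
    d$points_total <= 0 | d$points_lawn < 0 | d$points_lawn > d$points_total
  if (any(bad)) {
    rows <- which(bad)
    if (on_invalid == "error")
      stop("invalid photo sample at row ", paste(rows, collapse = ", "),
           ": need 0 <= points_lawn <= points_total and points_total > 0")
    message("read_photo_samples: dropped ", length(rows), " invalid row(s): ",
            paste(rows, collapse = ", "))
  }
  out <- d[!bad, c("year", "points_total", "points_lawn")]
  rownames(out) <- NULL
  if (nrow(out) == 0) stop("all photo samples were filtered out")
  out$year <- as.integer(out$year)
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Read behavior observation bouts
#'
#' Reads a wide CSV of scan-sampling bouts: columns `year`, `group` (one of
#' `gosling`, `female`, `male`), `duration_min`, `total_scans`, plus one
#' count column per behavior category. Count columns not in
#' `config$behavior_categories` are a format error (the valid labels are
#' listed). Bouts shorter than `config$min_bout_minutes` are excluded with
#' a reported count; scan counts may sum to less than `total_scans`
#' (unclassified scans) but never more.
#'
#' @param path CSV file path.
#' @param config A [study_config()].
#' @return Data frame with columns `year`, `group`, `duration_min`,
#'   `total_scans` and one column per behavior; attribute `"n_rejected"`
#'   counts excluded short bouts.
#' @export
read_behavior_bouts <- function(path, config = study_config()) {
  fixed <- c("year", "group", "duration_min", "total_scans")
  d <- read_checked_csv(path, fixed)
  if (nrow(d) == 0) stop("no behavior bouts in ", path)
  count_cols <- setdiff(names(d), fixed)
  unknown <- setdiff(count_cols, config$behavior_categories)
  if (length(unknown) > 0)
    stop("unknown behavior label(s): ", paste(unknown, collapse = ", "),
         "; valid labels are: ",
         paste(config$behavior_categories, collapse = ", "))
  if (length(count_cols) == 0) stop("no behavior count columns found")
  bad_group <- !d$group %in% c("gosling", "female", "male")
  if (any(bad_group))
    stop("unknown group at row ", paste(which(bad_group), collapse = ", "),
         "; valid groups are: gosling, female, male")
  counts <- as.matrix(d[, count_cols, drop = FALSE])
  if (any(is.na(counts)) || any(counts < 0))
    stop("behavior counts must be non-negative and complete")
  if (any(d$total_scans <= 0) || any(d$duration_min <= 0))
    stop("total_scans and duration_min must be positive")
  over <- rowSums(counts) > d$total_scans
  if (any(over))
    stop("behavior counts exceed total_scans at row ",
         paste(which(over), collapse = ", "))
  short <- d$duration_min < config$min_bout_minutes
  if (any(short))
    message("read_behavior_bouts: excluded ", sum(short),
            " bout(s) shorter than ", config$min_bout_minutes, " min")
  out <- d[!short, c(fixed, count_cols)]
  rownames(out) <- NULL
  if (nrow(out) == 0) stop("all behavior bouts were filtered out")
  out$year <- as.integer(out$year)
  attr(out, "n_rejected") <- sum(short)
  out
}

#' Write a posterior trend-summary table
#'
#' Writes the long-format table used for all reported parameter summaries:
#' one row per (label, parameter) with posterior mean, sd, 2.5% and 97.5%
#' credible bounds, and the f statistic. Values are written at full
#' precision, so the table round-trips losslessly.
#'
#' @param summaries Data frame with columns `label`, `parameter`, `mean`,
#'   `sd`, `cri_2.5`, `cri_97.5`, `f`. Label/parameter pairs must be unique.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @seealso [read_trend_table()]
#' @export
write_trend_table <- function(summaries, path) {
  cols <- c("label", "parameter", "mean", "sd", "cri_2.5", "cri_97.5", "f")
  if (nrow(summaries) > 0) {
    missing <- setdiff(cols, names(summaries))
    if (length(missing) > 0)
      stop("summaries is missing column(s): ", paste(missing, collapse = ", "))
    key <- paste(summaries$label, summaries$parameter)
    if (anyDuplicated(key)) stop("duplicate (label, parameter) rows")
    summaries <- summaries[, cols]
  } else {
    summaries <- as.data.frame(setNames(replicate(length(cols), numeric(0),
                                                  simplify = FALSE), cols))
  }
  utils::write.csv(summaries, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a trend-summary table written by [write_trend_table()]
#' @param path CSV path.
#' @return Data frame with the trend-table columns.
#' @export
read_trend_table <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  expected <- c("label", "parameter", "mean", "sd", "cri_2.5", "cri_97.5", "f")
  if (!identical(names(d), expected))
    stop("not a trend table: ", path)
  d
}

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing) > 0)
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  d
}
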
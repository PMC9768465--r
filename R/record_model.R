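#' @importFrom rlang .data %||%
NULL

na_of <- function(type) {
  switch(type, character = NA_character_, double = NA_real_,
         integer = NA_integer_, logical = NA)
}

# canonical column order and types of a record set
record_schema <- function() {
  c(record_id = "character", r = "double", abs_r = "double",
    n = "integer", df = "integer",
    p_comparator = "character", p_value = "double",
    sig_label = "character", location = "character",
    study_id = "character", journal = "character",
    subfield = "character", year = "integer")
}

sig_levels <- c("significant", "non_significant", "unspecified")
loc_levels <- c("text", "table", "unknown")
cmp_levels <- c("=", "<", ">")

#' Assemble and validate a record set
#'
#' A record set is a tibble with one row per reported correlation and the
#' columns `record_id`, `r`, `abs_r`, `n`, `df`, `p_comparator` (`=`, `<`
#' or `>`), `p_value`, `sig_label` (`significant`, `non_significant`,
#' `unspecified`), `location` (`text`, `table`, `unknown`), `study_id`,
#' `journal`, `subfield`, `year`. Missing columns are added as all-absent;
#' `abs_r` is filled from `r`; `record_id` is generated when absent. Rows
#' whose `n` and `df` disagree with `df = n - 2` are flagged in the logical
#' column `df_inconsistent` (flagged, never corrected). Duplicate
#' `record_id`s are an error.
#'
#' @param x A data frame with at least an `r` column.
#' @param provenance Free-text provenance attached as an attribute.
#' @return A validated tibble (the record set).
#' @export
as_record_set <- function(x, provenance = NULL) {
  x <- tibble::as_tibble(x)
  if (!"r" %in% names(x)) stop("record set needs an `r` column")
  sch <- record_schema()
  for (col in names(sch)) {
    if (!col %in% names(x)) x[[col]] <- rep(na_of(sch[[col]]), nrow(x))
  }
  x$r <- as.double(x$r)
  x$abs_r <- ifelse(is.na(x$abs_r), abs(x$r), as.double(x$abs_r))
  x$n <- as.integer(x$n)
  x$df <- as.integer(x$df)
  x$p_value <- as.double(x$p_value)
  x$year <- as.integer(x$year)
  for (col in c("record_id", "p_comparator", "sig_label", "location",
                "study_id", "journal", "subfield")) {
    x[[col]] <- as.character(x[[col]])
  }
  if (all(is.na(x$record_id))) x$record_id <- sprintf("rec%05d", seq_len(nrow(x)))
  if (anyDuplicated(stats::na.omit(x$record_id))) stop("record_id values must be unique")
  bad_sig <- !is.na(x$sig_label) & !x$sig_label %in% sig_levels
  if (any(bad_sig)) stop("invalid sig_label: ", x$sig_label[which(bad_sig)[1]])
  bad_loc <- !is.na(x$location) & !x$location %in% loc_levels
  if (any(bad_loc)) stop("invalid location: ", x$location[which(bad_loc)[1]])
  bad_cmp <- !is.na(x$p_comparator) & !x$p_comparator %in% cmp_levels
  if (any(bad_cmp)) stop("invalid p_comparator: ", x$p_comparator[which(bad_cmp)[1]])
  x$df_inconsistent <- !is.na(x$n) & !is.na(x$df) & x$df != x$n - 2L
  x <- x[, c(names(sch), "df_inconsistent", setdiff(names(x), c(names(sch), "df_inconsistent")))]
  attr(x, "provenance") <- provenance
  x
}

#' Degrees of freedom of each record
#'
#' Uses the reported `df` when present, otherwise derives `n - 2` on demand
#' (never written back to the record set).
#'
#' @param rs A record set.
#' @return Integer vector of degrees of freedom (NA when neither `n` nor
#'   `df` is available).
#' @export
record_df <- function(rs) {
  ifelse(!is.na(rs$df), rs$df, rs$n - 2L)
}

#' Read a record-set CSV
#'
#' Reads a comma-separated, UTF-8, `.`-decimal file with a header naming at
#' least `r` among the record-set columns. Blank cells become absent fields
#' (an empty cell is distinct from 0). Rows violating the range invariants
#' (`r` outside `[-1, 1]`, `n < 3`, missing `r`) or with unparseable numeric
#' cells are rejected with a logged reason, never silently dropped: the
#' returned record set carries a `rejected` attribute (row index + reason),
#' also available via [rejected_records()].
#'
#' @param path File to read.
#' @param col_map Optional named character vector mapping the file's actual
#'   header names to the canonical schema names, e.g.
#'   `c(correlation = "r", N = "n")` — an adapter for externally deposited
#'   tables whose headers differ.
#' @return A record set tibble (see [as_record_set()]).
#' @export
read_records_csv <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "NA"), progress = FALSE)
  if (!is.null(col_map)) {
    hit <- names(raw) %in% names(col_map)
    names(raw)[hit] <- unname(col_map[names(raw)[hit]])
  }
  if (!"r" %in% names(raw)) stop("schema error: mandatory column `r` missing")
  raw <- raw[, intersect(c(names(record_schema())), names(raw)), drop = FALSE]

  n_rows <- nrow(raw)
  reason <- rep(NA_character_, n_rows)
  num_cols <- c("r", "abs_r", "n", "df", "p_value", "year")
  parsed <- raw
  for (col in intersect(num_cols, names(raw))) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- !is.na(raw[[col]]) & is.na(v)
    reason[bad & is.na(reason)] <- paste0("unparseable_", col)
    parsed[[col]] <- v
  }
  r <- parsed$r
  reason[is.na(reason) & is.na(r)] <- "missing_r"
  reason[is.na(reason) & !is.na(r) & abs(r) > 1] <- "r_out_of_range"
  if ("n" %in% names(parsed)) {
    reason[is.na(reason) & !is.na(parsed$n) & parsed$n < 3] <- "n_too_small"
  }
  keep <- is.na(reason)
  rejected <- tibble::tibble(row = which(!keep), reason = reason[!keep])
  if (nrow(rejected) > 0) {
    message(nrow(rejected), " row(s) rejected while reading ", path, ": ",
            paste(unique(rejected$reason), collapse = ", "))
  }
  rs <- as_record_set(parsed[keep, , drop = FALSE], provenance = path)
  attr(rs, "rejected") <- rejected
  rs
}

#' Rejected rows of the last read
#'
#' @param rs A record set returned by [read_records_csv()].
#' @return A tibble of row indices and rejection reasons (empty when all
#'   rows were accepted).
#' @export
rejected_records <- function(rs) {
  attr(rs, "rejected") %||% tibble::tibble(row = integer(), reason = character())
}

#' Write a record set to CSV
#'
#' Writes the canonical schema columns; absent fields are written as empty
#' cells so that [read_records_csv()] round-trips the set exactly.
#'
#' @param rs A record set.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(rs, path) {
  rs <- as_record_set(rs)
  readr::write_csv(rs[, names(record_schema())], path, na = "", progress = FALSE)
  invisible(path)
}

#' Default journal-to-subfield mapping
#'
#' The ten social and developmental psychology journals of the mined corpus,
#' keyed by the short names used in record tables.
#'
#' @return Named character vector, journal -> subfield.
#' @export
default_subfield_map <- function() {
  c(ChildDev = "developmental", DevPsy = "developmental",
    JAppDevPsy = "developmental", JCPP = "developmental",
    JExpChildPsy = "developmental",
    EJP = "social", JExpSocPsy = "social", JPSP = "social",
    JResInPer = "social", SPPS = "social")
}

#' Populate the subfield stratum from journal names
#'
#' @param rs A record set.
#' @param mapping Named character vector journal -> subfield
#'   (default [default_subfield_map()]).
#' @param default Fallback subfield for unmapped journals; with no default,
#'   an unmapped journal is a configuration error. Idempotent: applying the
#'   same mapping twice is a no-op.
#' @return The record set with `subfield` filled; record count unchanged.
#' @export
merge_strata <- function(rs, mapping = default_subfield_map(), default = NULL) {
  rs <- as_record_set(rs)
  j <- rs$journal
  known <- is.na(j) | j %in% names(mapping)
  if (any(!known) && is.null(default)) {
    stop("configuration error: unmapped journal(s) with no default: ",
         paste(unique(j[!known]), collapse = ", "))
  }
  sub <- ifelse(is.na(j), rs$subfield,
                ifelse(j %in% names(mapping), unname(mapping[j]), default))
  rs$subfield <- sub
  rs
}

#' Analysis configuration
#'
#' Bundles the significance level, sidedness, bootstrap replication count
#' and seed shared by the audit and summary functions.
#'
#' @param alpha Significance level in (0, 1); default 0.05.
#' @param sides `"two.sided"` or `"one.sided"`.
#' @param bootstrap_reps Bootstrap replications (default 10000).
#' @param seed Optional integer seed.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(alpha = 0.05, sides = c("two.sided", "one.sided"),
                            bootstrap_reps = 10000L, seed = NULL) {
  sides <- match.arg(sides)
  stopifnot(alpha > 0, alpha < 1, bootstrap_reps >= 1)
  structure(list(alpha = alpha, sides = sides,
                 bootstrap_reps = as.integer(bootstrap_reps), seed = seed),
            class = "analysis_config")
}

#' Write an analysis report as JSON
#'
#' Thin serialiser for audit reports and summary tables.
#'
#' @param x A list or data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}
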
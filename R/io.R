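# Flock-record CSV input/output.
#
# Schema (comma-delimited, UTF-8, decimal point, header mandatory; fixed
# units): house_id, duck_id, day, weight_kg, bgw_g_per_d, et_c,
# humidity_pct?, breed, lysine_pct?, methionine_pct?, observed_me_kj?,
# observed_cp_g? ('?' marks optional columns).

FLOCK_REQUIRED_COLS <- c("house_id", "duck_id", "day", "weight_kg",
                         "bgw_g_per_d", "et_c", "breed")
FLOCK_NUMERIC_COLS <- c("day", "weight_kg", "bgw_g_per_d", "et_c",
                        "humidity_pct", "lysine_pct", "methionine_pct",
                        "observed_me_kj", "observed_cp_g", "cold_days",
                        "true_me_kj", "true_cp_g")

#' Read a flock record CSV
#'
#' Validates the header (a missing required column is a schema error naming
#' the column) and each row: `weight_kg` positive, `bgw_g_per_d`
#' non-negative, `et_c` finite, `day` non-decreasing within each duck. In
#' strict mode (default) any violation raises a row-level error with the
#' 1-based data line number; lenient mode drops offending rows and reports
#' the count via a message. Consecutive-cold-day counts are derived from the
#' per-duck temperature series when not supplied as a `cold_days` column.
#'
#' @param path Path to the CSV file.
#' @param strict Reject any invalid row (default `TRUE`).
#' @param t_low Lower thermoneutral limit used for the cold-day scan, °C.
#' @return An [as_observation_set()] data frame, provenance `"file"`.
#' @export
read_flock_csv <- function(path, strict = TRUE, t_low = 15) {
  if (!file.exists(path)) abort_invalid("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(FLOCK_REQUIRED_COLS, names(df))
  if (length(missing_cols))
    abort_schema("flock CSV missing required column(s): ",
                 paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0) abort_invalid("no records in ", path)
  for (col in intersect(FLOCK_NUMERIC_COLS, names(df)))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))

  bad <- !is.finite(df$weight_kg) | df$weight_kg <= 0 |
    !is.finite(df$bgw_g_per_d) | df$bgw_g_per_d < 0 |
    !is.finite(df$et_c) | !is.finite(df$day)
  if (any(bad)) {
    lines <- which(bad)
    if (strict)
      abort_invalid("invalid value(s) in row(s) (data line ",
                    paste(lines, collapse = ", "),
                    "): weight_kg must be > 0, bgw_g_per_d >= 0, ",
                    "day and et_c finite")
    message("read_flock_csv: dropped ", length(lines),
            " invalid row(s) (data line ",
            paste(lines, collapse = ", "), ")")
    df <- df[!bad, , drop = FALSE]
    if (nrow(df) == 0) abort_invalid("no valid records in ", path)
  }

  key <- paste(df$house_id, df$duck_id)
  for (k in unique(key)) {
    d <- df$day[key == k]
    if (is.unsorted(d)) {
      if (strict)
        abort_invalid("day not non-decreasing within duck '", k, "'")
      message("read_flock_csv: reordered rows of duck '", k, "' by day")
      idx <- which(key == k)
      df[idx, ] <- df[idx[order(d)], ]
    }
  }
  df <- ensure_cold_days(df, t_low)
  rownames(df) <- NULL
  as_observation_set(df, "file")
}

#' Write a flock record CSV
#'
#' Numeric columns are formatted at 12 significant digits, so a write/read
#' round trip is lossless at that precision and byte-identical for a fixed
#' input.
#'
#' @param df Flock record data frame (e.g. from [generate_observations()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flock_csv <- function(df, path) {
  out <- as.data.frame(df)
  for (col in names(out)) {
    if (is.numeric(out[[col]]))
      out[[col]] <- vapply(out[[col]], function(v) {
        if (is.na(v)) "" else sprintf("%.12g", v)
      }, character(1))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
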
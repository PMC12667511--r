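#' Read a person registry from a delimited file
#'
#' Loads a registry into the raw record form the package works with: one row
#' per person with an id, full name, mother's name and date of birth. Column
#' names in the file are mapped to those fields through `column_map`.
#'
#' @param path file path.
#' @param column_map named character vector mapping field names
#'   (`record_id`, `full_name`, `mother_name`, `birth_date`, optionally
#'   `truth_ref`) to column names in the file. Defaults to identity.
#' @param delim field delimiter, default comma.
#' @param date_format `"ymd"` for ISO-8601 (default) or `"dmy"` for the
#'   Brazilian DD/MM/YYYY convention.
#' @param latin1 set `TRUE` for Latin-1 encoded files (common in legacy
#'   Brazilian extracts); default UTF-8.
#' @return `data.table` with columns `record_id`, `full_name`, `mother_name`,
#'   `birth_date` (`Date`, `NA` when absent) and `truth_ref` when mapped.
#'   Empty strings become `NA` for `birth_date`/`truth_ref` and empty
#'   `mother_name` is kept as `""` (legal: such records are simply ineligible
#'   for steps that require it).
#' @export
read_registry <- function(path,
                          column_map = c(record_id = "record_id",
                                         full_name = "full_name",
                                         mother_name = "mother_name",
                                         birth_date = "birth_date"),
                          delim = ",", date_format = c("ymd", "dmy"),
                          latin1 = FALSE) {
  date_format <- match.arg(date_format)
  if (!file.exists(path)) stop_config("input file not found: ", path)
  req <- c("record_id", "full_name", "mother_name", "birth_date")
  miss <- setdiff(req, names(column_map))
  if (length(miss)) stop_config("column_map lacks fields: ", paste(miss, collapse = ", "))

  dt <- data.table::fread(path, sep = delim, colClasses = "character",
                          encoding = if (latin1) "Latin-1" else "UTF-8",
                          na.strings = NULL)
  absent <- setdiff(unname(column_map), names(dt))
  if (length(absent)) {
    stop_config("mapped column(s) not in file header: ", paste(absent, collapse = ", "))
  }
  out <- data.table::data.table(
    record_id = dt[[column_map[["record_id"]]]],
    full_name = dt[[column_map[["full_name"]]]],
    mother_name = dt[[column_map[["mother_name"]]]]
  )
  out[is.na(full_name), full_name := ""]
  out[is.na(mother_name), mother_name := ""]

  dup <- unique(out$record_id[duplicated(out$record_id)])
  if (length(dup)) {
    stop_validation("duplicate record_id value(s): ",
                    paste(utils::head(dup, 5), collapse = ", "))
  }

  raw_date <- dt[[column_map[["birth_date"]]]]
  raw_date[is.na(raw_date)] <- ""
  fmt <- if (date_format == "ymd") "%Y-%m-%d" else "%d/%m/%Y"
  parsed <- as.Date(rep(NA_character_, length(raw_date)))
  nonempty <- nzchar(raw_date)
  parsed[nonempty] <- as.Date(raw_date[nonempty], format = fmt)
  bad <- which(nonempty & is.na(parsed))
  if (length(bad)) {
    stop_validation("unparseable birth_date on row(s) ",
                    paste(utils::head(bad, 5), collapse = ", "),
                    " (e.g. \"", raw_date[bad[1]], "\")")
  }
  out[, birth_date := parsed]

  if ("truth_ref" %in% names(column_map) &&
      column_map[["truth_ref"]] %in% names(dt)) {
    tr <- dt[[column_map[["truth_ref"]]]]
    tr[is.na(tr) | !nzchar(tr)] <- NA_character_
    out[, truth_ref := tr]
  }
  out[]
}

#' Write a person registry to a delimited file
#'
#' Inverse of [read_registry()] with the identity column map: dates are
#' written ISO-8601, missing values as empty strings.
#'
#' @param registry raw registry (`record_id`, `full_name`, `mother_name`,
#'   `birth_date`, optional `truth_ref`).
#' @param path output path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path, delim = ",") {
  dt <- data.table::as.data.table(registry)
  out <- data.table::data.table(
    record_id = as.character(dt$record_id),
    full_name = as.character(dt$full_name),
    mother_name = as.character(dt$mother_name),
    birth_date = ifelse(is.na(dt$birth_date),
                        "", format(as.Date(dt$birth_date), "%Y-%m-%d"))
  )
  if ("truth_ref" %in% names(dt)) {
    out[, truth_ref := ifelse(is.na(dt$truth_ref), "", as.character(dt$truth_ref))]
  }
  data.table::fwrite(out, path, sep = delim, quote = TRUE)
  invisible(path)
}

#' Write accepted links to a delimited file
#'
#' One row per link with columns `left_id`, `right_id`, `step`, `score`
#' (score printed with six decimals), ordered by step then left id.
#'
#' @param result a `linkage_result` from [run_linkage()].
#' @param path output path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_matches <- function(result, path, delim = ",") {
  if (!inherits(result, "linkage_result")) stop_config("result must be a linkage_result")
  m <- data.table::copy(result$matches)
  data.table::setorder(m, step, left_id)
  m[, score := sprintf("%.6f", score)]
  data.table::fwrite(m, path, sep = delim, quote = FALSE)
  invisible(path)
}

#' Read a matches file written by [write_matches()]
#'
#' @param path file path.
#' @param delim field delimiter.
#' @return `data.table` with columns `left_id`, `right_id`, `step`, `score`.
#' @export
read_matches <- function(path, delim = ",") {
  if (!file.exists(path)) stop_config("input file not found: ", path)
  dt <- data.table::fread(path, sep = delim,
                          colClasses = list(character = c("left_id", "right_id")))
  need <- c("left_id", "right_id", "step", "score")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop_config("matches file lacks column(s): ", paste(miss, collapse = ", "))
  dt[, step := as.integer(step)][, score := as.numeric(score)][]
}
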
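#' Consultation record corpora
#'
#' A consultation corpus is a tibble with one row per patient question. The
#' required columns are `question_id`, `patient_code`, `physician_code`,
#' `question_text` and `response_status`; `department`,
#' `response_time_min`, `created_hour`, `patient_sex`, `patient_age` and
#' `physician_title` are optional and may be `NA`.
#'
#' Two invariants are enforced at ingest: a record can only carry a response
#' time when its response status is `TRUE` (unanswered requests have no
#' response), and question identifiers are unique within a corpus. Records
#' with empty question text are rejected as well, because every record must
#' remain embeddable downstream.
#'
#' @name consultation-records
#' @keywords internal
NULL

.record_required <- c(
  "question_id", "patient_code", "physician_code",
  "question_text", "response_status"
)

.record_optional <- c(
  "department", "response_time_min", "created_hour",
  "patient_sex", "patient_age", "physician_title"
)

#' Read consultation records from CSV or JSONL
#'
#' Parses a delimited or line-JSON export of consultation records,
#' validates the schema, and drops rows that violate the corpus invariants
#' with row-level diagnostics. Response times may be given as bare minutes
#' or as `"8 h 12 min"`-style strings.
#'
#' @param path Path to the file.
#' @param format `"csv"` (header row required) or `"jsonl"` (one JSON object
#'   per line). Guessed from the file extension when missing.
#' @param col_map Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(question_id = "qid", response_time_min = "response_time")`.
#' @return A tibble of validated records in file order. Rejected rows are
#'   attached as the `"rejected"` attribute (a tibble with `row`,
#'   `question_id`, `reason`) and reported via a warning.
#' @export
read_records <- function(path, format = c("csv", "jsonl"), col_map = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (missing(format)) {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  format <- match.arg(format)
  raw <- if (format == "csv") {
    utils::read.csv(path,
      stringsAsFactors = FALSE, colClasses = "character",
      check.names = FALSE, fileEncoding = "UTF-8"
    )
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(stringi::stri_trim_both(lines))]
    rows <- lapply(lines, function(l) {
      as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
    })
    dplyr::bind_rows(rows)
  }
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (col_map[[canon]] %in% names(raw)) {
        names(raw)[names(raw) == col_map[[canon]]] <- canon
      }
    }
  }
  missing_cols <- setdiff(.record_required, names(raw))
  if (length(missing_cols)) {
    stop(
      "missing required column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  as_records(raw, source = path)
}

#' Validate a data frame of consultation records
#'
#' Applies the corpus invariants to an already-loaded data frame. Used by
#' [read_records()] and by the synthetic generator; call it directly when
#' records arrive from another source.
#'
#' @param df Data frame with at least the required record columns.
#' @param source Label used in diagnostics.
#' @return Validated tibble with a `"rejected"` attribute (see
#'   [read_records()]).
#' @export
as_records <- function(df, source = "records") {
  df <- tibble::as_tibble(df)
  n <- nrow(df)
  for (col in setdiff(.record_optional, names(df))) {
    df[[col]] <- NA
  }
  rec <- tibble::tibble(
    question_id = as.character(df$question_id),
    patient_code = as.character(df$patient_code),
    physician_code = as.character(df$physician_code),
    department = as.character(df$department),
    question_text = as.character(df$question_text),
    response_status = parse_logical(df$response_status),
    response_time_min = parse_duration_min(df$response_time_min),
    created_hour = suppressWarnings(as.integer(df$created_hour)),
    patient_sex = as.character(df$patient_sex),
    patient_age = suppressWarnings(as.numeric(df$patient_age)),
    physician_title = as.character(df$physician_title)
  )

  reasons <- character(n)
  flag <- function(idx, why) {
    reasons[idx] <<- ifelse(nzchar(reasons[idx]),
      paste(reasons[idx], why, sep = "; "), why
    )
  }
  flag(
    which(is.na(rec$question_id) | !nzchar(rec$question_id)),
    "empty question_id"
  )
  flag(
    which(is.na(rec$question_text) |
      !nzchar(stringi::stri_trim_both(rec$question_text))),
    "empty question_text"
  )
  flag(which(is.na(rec$response_status)), "unparsable response_status")
  flag(which(is.nan(rec$response_time_min)), "unparsable response_time")
  flag(
    which(!is.na(rec$response_time_min) & rec$response_time_min < 0),
    "negative response_time"
  )
  flag(
    which(!is.na(rec$response_status) & !rec$response_status &
      !is.na(rec$response_time_min)),
    "response_time present on unanswered record"
  )
  dup <- duplicated(rec$question_id) & nzchar(rec$question_id)
  flag(which(dup), "duplicate question_id")

  bad <- which(nzchar(reasons))
  rejected <- tibble::tibble(
    row = bad,
    question_id = rec$question_id[bad],
    reason = reasons[bad]
  )
  if (length(bad)) {
    warning(
      sprintf(
        "%s: rejected %d of %d row(s); first: row %d (%s)",
        source, length(bad), n, bad[1], reasons[bad[1]]
      ),
      call. = FALSE
    )
    rec <- rec[-bad, ]
  }
  structure(rec, rejected = rejected)
}

#' Write consultation records to CSV or JSONL
#'
#' @param records Record tibble (see [read_records()]).
#' @param path Output path.
#' @param format `"csv"` or `"jsonl"`; guessed from the extension when
#'   missing.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, format = c("csv", "jsonl")) {
  if (missing(format)) {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  format <- match.arg(format)
  out <- records[intersect(
    c(.record_required, .record_optional),
    names(records)
  )]
  if (format == "csv") {
    utils::write.csv(out, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  } else {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(out))) {
      row <- as.list(out[i, ])
      row <- row[!vapply(row, function(v) is.na(v) || is.null(v), logical(1))]
      writeLines(
        jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA, null = "null"),
        con
      )
    }
  }
  invisible(path)
}

#' Partition a corpus into training and two test sets
#'
#' Test set 1 is label-driven: records whose `question_id` appears in
#' `test1_labels` are held out together with the physician code that tagged
#' the question as within expertise (`selected_physician`). Test set 2 is a
#' uniform random sample without replacement from the remaining records.
#' The training set is the remainder. The split is deterministic for a
#' fixed seed.
#'
#' @param records Record tibble.
#' @param test1_labels Named character vector, `question_id -> physician_code`.
#' @param test2_size Number of records to sample into test set 2.
#' @param seed Integer random seed (default 2023).
#' @return An object of class `corpus_split`: a list with `training`,
#'   `test1` (with a `selected_physician` column) and `test2` tibbles.
#' @export
split_corpus <- function(records, test1_labels = character(),
                         test2_size = 0, seed = 2023) {
  ids <- records$question_id
  unknown <- setdiff(names(test1_labels), ids)
  if (length(unknown)) {
    stop(
      "test1 label(s) not in corpus: ",
      paste(utils::head(unknown, 5), collapse = ", "),
      call. = FALSE
    )
  }
  in_t1 <- ids %in% names(test1_labels)
  rest <- which(!in_t1)
  if (test2_size > length(rest)) {
    stop(
      "test2_size (", test2_size, ") exceeds records available after ",
      "test1 removal (", length(rest), ")",
      call. = FALSE
    )
  }
  t2_idx <- withr::with_seed(seed, sort(sample(rest, test2_size)))
  test1 <- records[in_t1, ]
  test1$selected_physician <- unname(test1_labels[test1$question_id])
  split <- structure(
    list(
      training = records[setdiff(rest, t2_idx), ],
      test1 = test1,
      test2 = records[t2_idx, ]
    ),
    class = "corpus_split", seed = seed
  )
  split
}

#' @export
print.corpus_split <- function(x, ...) {
  cat(sprintf(
    "<corpus_split> training: %d  test1: %d  test2: %d (seed %s)\n",
    nrow(x$training), nrow(x$test1), nrow(x$test2), attr(x, "seed")
  ))
  invisible(x)
}

#' Write a corpus split as three JSONL files
#'
#' @param split A `corpus_split`.
#' @param dir Output directory (created if absent); files are
#'   `training.jsonl`, `test1.jsonl`, `test2.jsonl`.
#' @return `dir`, invisibly.
#' @export
write_split <- function(split, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (part in c("training", "test1", "test2")) {
    write_records(split[[part]], file.path(dir, paste0(part, ".jsonl")),
      format = "jsonl"
    )
  }
  invisible(dir)
}

# Table-2 style bins used for corpus summaries.
.bin_age <- function(age) {
  cut(age,
    breaks = c(-Inf, 20, 40, 60, Inf),
    labels = c("<20", "20-39", "40-59", ">60"), right = FALSE
  )
}

.bin_hour <- function(hour) {
  cut(hour,
    breaks = c(-1, 5, 11, 17, 23),
    labels = c("0-5", "6-11", "12-17", "18-23")
  )
}

#' Summarize a consultation corpus
#'
#' Record-level counts and percentages for each categorical characteristic:
#' patient sex, age group, physician title, consultation creation hour
#' block, and response status. Percentages are `100 * count / total`
#' reported to 2 decimals; within a characteristic they sum to 100 up to
#' rounding.
#'
#' @param records Record tibble.
#' @return A tibble with columns `field`, `level`, `n`, `pct`.
#' @export
summarize_corpus <- function(records) {
  if (nrow(records) == 0) {
    stop("cannot summarize an empty corpus", call. = FALSE)
  }
  total <- nrow(records)
  one <- function(field, values) {
    values <- values[!is.na(values)]
    if (!length(values)) {
      return(NULL)
    }
    tab <- table(values)
    tibble::tibble(
      field = field,
      level = names(tab),
      n = as.integer(tab),
      pct = round(100 * as.integer(tab) / total, 2)
    )
  }
  dplyr::bind_rows(
    one("patient_sex", records$patient_sex),
    one("age_group", .bin_age(records$patient_age)),
    one("physician_title", records$physician_title),
    one("created_hour", .bin_hour(records$created_hour)),
    one("response_status", ifelse(records$response_status, "True", "False"))
  )
}
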
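#' Read a participant cohort table from delimited text
#'
#' @param path CSV (or other delimited) file with a header row.
#' @param schema Named list mapping roles to column names:
#'   required roles `subject_id`, `age`, `sex`, `diagnosis`, `site`;
#'   optional `qc` (character vector of QC metric columns) and `regions`
#'   (named list, phenotype -> character vector of region columns).
#' @param sep Field separator, default `","`.
#' @return A list with `cohort` (a [cohort_table]) and `report`
#'   (rows read, rows dropped for unparseable required fields, reasons).
#'   Missing region values are retained as `NA`; analyses drop row-wise
#'   per region and report the n actually used.
#' @export
read_cohort_table <- function(path, schema = list(), sep = ",") {
  req_roles <- c("subject_id", "age", "sex", "diagnosis", "site")
  for (r in req_roles) if (is.null(schema[[r]])) schema[[r]] <- r
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  missing_roles <- req_roles[!vapply(req_roles, function(r)
    schema[[r]] %in% names(raw), logical(1))]
  if (length(missing_roles))
    stop("cohort schema roles not found in header: ",
         paste(missing_roles, collapse = ", "), call. = FALSE)
  df <- raw
  ren <- vapply(req_roles, function(r) schema[[r]], character(1))
  names(df)[match(ren, names(df))] <- req_roles
  n_in <- nrow(df)
  df$age <- suppressWarnings(as.numeric(df$age))
  df$sex <- suppressWarnings(as.numeric(df$sex))
  df$diagnosis <- suppressWarnings(as.numeric(df$diagnosis))
  keep <- !is.na(df$subject_id) & !is.na(df$age) & df$age > 0 &
    !is.na(df$sex) & !is.na(df$diagnosis) & !is.na(df$site)
  dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in ", path, ": ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "), call. = FALSE)
  qc_cols <- schema$qc %||% character()
  region_cols <- schema$regions %||% list()
  cohort <- cohort_table(df, qc_cols = qc_cols, region_cols = region_cols)
  list(cohort = cohort,
       report = list(n_read = n_in, n_retained = nrow(df),
                     n_dropped = dropped))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

RATING_CATEGORIES <- c(good = 1L, minor_error = 2L, visible_motion = 3L,
                       bad = 4L)

#' Read a ratings CSV
#'
#' Expects the five columns `image_hash`, `rater_id`, `category`,
#' `deliberation_ms`, `timestamp`. Categories are validated against the
#' four-level vocabulary (`good`, `minor_error`, `visible_motion`,
#' `bad`).
#'
#' @param path CSV path.
#' @return A data.frame of class `ratings_table`.
#' @export
read_ratings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ratings_table(df)
}

#' Validate a ratings data.frame
#' @param df Data frame with the five rating columns.
#' @export
ratings_table <- function(df) {
  need <- c("image_hash", "rater_id", "category", "deliberation_ms",
            "timestamp")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("ratings table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!df$category %in% names(RATING_CATEGORIES))
  if (length(bad))
    stop("unknown rating category ", sQuote(df$category[bad[1]]),
         " at row ", bad[1], call. = FALSE)
  dup <- duplicated(df[, c("image_hash", "rater_id")])
  if (any(dup))
    stop("duplicate (image_hash, rater_id) pair at row ", which(dup)[1],
         call. = FALSE)
  if (any(df$deliberation_ms < 0))
    stop("deliberation_ms must be >= 0", call. = FALSE)
  class(df) <- c("ratings_table", "data.frame")
  df
}

#' Write a ratings CSV
#' @param ratings A ratings table (validated with [ratings_table()]).
#' @param path Output CSV path.
#' @export
write_ratings <- function(ratings, path) {
  ratings <- ratings_table(as.data.frame(ratings))
  utils::write.csv(ratings, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
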
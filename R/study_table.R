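#' One study's event counts and exposures
#'
#' A `study_table` holds the data of a single study for rate-based signal
#' detection: one record per row (a drug group or an adverse-event term),
#' with an event count `n_i` and a positive exposure denominator `P_i`
#' (person-time, subject count, or -- in the report-counts dialect -- the
#' row's marginal report count).
#'
#' @param counts Non-negative integer event counts, one per row.
#' @param exposures Positive exposure denominators, one per row.
#' @param rows Optional character row labels (drugs or AE terms); defaults
#'   to `"row1"`, `"row2"`, ... Must be unique.
#' @param study Optional study identifier (a length-1 label).
#'
#' @return An object of class `"study_table"`: a list with elements
#'   `study`, `rows`, `counts`, `exposures`, and `total_events`
#'   (\eqn{n_. = \sum_i n_i}).
#'
#' @details Tables with a single row are accepted (some studies report only
#'   one arm or one AE term) but carry no comparative information; the test
#'   statistic for such a table is 0.
#'
#' @examples
#' study_table(counts = c(20, 77), exposures = c(181753, 1534190),
#'             rows = c("PLandPPI", "PL"), study = "s2")
#' @export
study_table <- function(counts, exposures, rows = NULL, study = NULL) {
  if (length(counts) != length(exposures))
    stop("'counts' and 'exposures' must have the same length", call. = FALSE)
  if (length(counts) < 1L)
    stop("a study table needs at least one row", call. = FALSE)
  if (anyNA(counts) || anyNA(exposures))
    stop("missing values in counts or exposures", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(exposures <= 0))
    stop("exposures must be strictly positive", call. = FALSE)
  if (is.null(rows)) rows <- paste0("row", seq_along(counts))
  rows <- as.character(rows)
  if (anyDuplicated(rows))
    stop("row labels must be unique within a study", call. = FALSE)
  if (is.null(study)) study <- "study1"
  structure(
    list(study = as.character(study)[1L], rows = rows,
         counts = as.numeric(counts), exposures = as.numeric(exposures),
         total_events = sum(counts)),
    class = "study_table")
}

#' @export
print.study_table <- function(x, ...) {
  cat("Study table: ", x$study, "  (", length(x$rows), " rows, ",
      x$total_events, " events)\n", sep = "")
  df <- data.frame(row = x$rows, count = x$counts, exposure = x$exposures,
                   rate = x$counts / x$exposures)
  print(df, row.names = FALSE, ...)
  invisible(x)
}

#' @export
as.data.frame.study_table <- function(x, ...) {
  data.frame(study = x$study, row = x$rows, count = x$counts,
             exposure = x$exposures, stringsAsFactors = FALSE)
}

#' An ordered collection of studies sharing a row vocabulary
#'
#' Bundles several [study_table()] objects for a joint multi-study
#' analysis.  Row labels form a shared vocabulary: a row may be absent
#' from some studies, but a label always denotes the same semantic row.
#' Studies analysed together must use the same denominator dialect --
#' either true exposures (person-time, subjects) or marginal report
#' counts; analyses mixing reporting-rate data with exposure-based data
#' are refused because their relative-rate estimates are not comparable.
#'
#' @param ... `study_table` objects, or a single list of them.
#' @param dialect Denominator dialect shared by all studies:
#'   `"exposure"` (risk comparison) or `"report_counts"` (relative
#'   reporting-rate comparison, exposures are marginal counts).
#'
#' @return An object of class `"multi_study"`: a list of `study_table`s
#'   with attributes `dialect` and `rows` (the union vocabulary, in order
#'   of first appearance).
#' @examples
#' ppi_fixture("first_occurrence")
#' @export
multi_study <- function(..., dialect = c("exposure", "report_counts")) {
  dialect <- match.arg(dialect)
  tabs <- list(...)
  if (length(tabs) == 1L && !inherits(tabs[[1L]], "study_table"))
    tabs <- tabs[[1L]]
  if (length(tabs) < 1L) stop("at least one study is required", call. = FALSE)
  ok <- vapply(tabs, inherits, logical(1), what = "study_table")
  if (!all(ok)) stop("all elements must be 'study_table' objects", call. = FALSE)
  ids <- vapply(tabs, `[[`, character(1), "study")
  if (anyDuplicated(ids)) stop("duplicate study ids", call. = FALSE)
  names(tabs) <- ids
  vocab <- unique(unlist(lapply(tabs, `[[`, "rows")))
  structure(tabs, dialect = dialect, rows = vocab, class = "multi_study")
}

#' @export
print.multi_study <- function(x, ...) {
  cat("Multi-study data: ", length(x), " studies, ",
      length(attr(x, "rows")), " rows (dialect: ", attr(x, "dialect"),
      ")\n", sep = "")
  df <- do.call(rbind, lapply(x, as.data.frame))
  print(df, row.names = FALSE, ...)
  invisible(x)
}

#' @export
as.data.frame.multi_study <- function(x, ...) {
  do.call(rbind, c(lapply(x, as.data.frame), make.row.names = FALSE))
}

#' Pool counts and exposures over studies
#'
#' Collapses a multi-study dataset to one table by summing, per row of the
#' shared vocabulary, the event counts and exposures over all studies.
#' Rows absent from a study contribute 0 to both sums.  This is the input
#' of the simple pooled analysis; note that pooling discards the
#' study-level structure (and with it the protection against
#' between-study confounding), which is why the pooled test's type-I
#' error is not guaranteed at nominal level.
#'
#' @param data A [multi_study()] object.
#' @return A [study_table()] with the union row vocabulary, study id
#'   `"pooled"`.
#' @examples
#' pool_studies(ppi_fixture("first_occurrence"))
#' @export
pool_studies <- function(data) {
  if (!inherits(data, "multi_study"))
    stop("'data' must be a 'multi_study' object", call. = FALSE)
  vocab <- attr(data, "rows")
  cnt <- stats::setNames(numeric(length(vocab)), vocab)
  exp <- cnt
  for (tab in data) {
    cnt[tab$rows] <- cnt[tab$rows] + tab$counts
    exp[tab$rows] <- exp[tab$rows] + tab$exposures
  }
  if (any(exp == 0))
    stop("pooled exposure is zero for some rows", call. = FALSE)
  study_table(counts = unname(cnt), exposures = unname(exp),
              rows = vocab, study = "pooled")
}
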
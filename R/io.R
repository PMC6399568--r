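# Long-format reader/writer.  Schema: header study,row,count,exposure
# (comma- or tab-separated, sniffed); one record per (study, row).

#' Read a long-format multi-study table
#'
#' Parses a CSV/TSV file with header `study,row,count,exposure` into a
#' [multi_study()] object, validating as it goes (non-numeric or
#' negative values and duplicate (study, row) pairs are reported with
#' their line numbers).  The field separator (comma or tab) is sniffed
#' from the header line.
#'
#' The `exposure` column may be omitted only in the `report_counts`
#' dialect; the denominator of each row is then its marginal report
#' count, computed as the row's total count over all studies in the
#' file.  Supplying the true marginals explicitly is preferred whenever
#' they are known.
#'
#' @param path File path.
#' @param dialect `"exposure"` or `"report_counts"`, see [multi_study()].
#' @return A [multi_study()] object; studies appear in file order.
#' @export
read_long_table <- function(path, dialect = c("exposure", "report_counts")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path, call. = FALSE)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE,
                          colClasses = "character")
  need <- c("study", "row", "count")
  if (!all(need %in% names(df)))
    stop("header must contain columns study,row,count[,exposure]",
         call. = FALSE)
  has_exp <- "exposure" %in% names(df)
  if (!has_exp && dialect == "exposure")
    stop("the exposure dialect requires an 'exposure' column",
         call. = FALSE)
  if (nrow(df) == 0L) stop("no data records in ", path, call. = FALSE)
  line_no <- seq_len(nrow(df)) + 1L
  .bad <- function(cond, what) {
    if (any(cond))
      stop(what, " at line", if (sum(cond) > 1) "s" else "", " ",
           paste(line_no[cond], collapse = ", "), call. = FALSE)
  }
  cnt <- suppressWarnings(as.numeric(df$count))
  .bad(is.na(cnt), "non-numeric count")
  .bad(cnt < 0 | cnt != round(cnt), "count not a non-negative integer")
  if (has_exp) {
    expo <- suppressWarnings(as.numeric(df$exposure))
    .bad(is.na(expo), "non-numeric exposure")
    .bad(expo <= 0, "non-positive exposure")
  } else {
    marg <- tapply(cnt, df$row, sum)
    expo <- as.numeric(marg[df$row])
    .bad(expo <= 0, "zero marginal report count")
  }
  .bad(duplicated(paste(df$study, df$row, sep = "\r")),
       "duplicate (study, row) pair")
  ids <- unique(df$study)
  tabs <- lapply(ids, function(id) {
    sel <- df$study == id
    study_table(counts = cnt[sel], exposures = expo[sel],
                rows = df$row[sel], study = id)
  })
  multi_study(tabs, dialect = dialect)
}

#' Write a multi-study dataset in the long format
#'
#' @param data A [multi_study()] object.
#' @param path Output file; `".tsv"` extension selects tab separation.
#' @return `path`, invisibly.
#' @export
write_long_table <- function(data, path) {
  stopifnot(inherits(data, "multi_study"))
  df <- as.data.frame(data)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Tidy result table of an analysis
#'
#' Converts a single-study [regular_lrt()] result, a list of them, or a
#' multi-study `"global_lrt_result"` into the tidy output layout used by
#' the writers: one line per analysis unit with the statistic, p-value,
#' threshold and signal flag from the step-down procedure.
#'
#' @param x A result object or list of `lrt_result`s.
#' @param alpha Significance level for the signal flags.
#' @return A data frame.
#' @export
report_table <- function(x, alpha = 0.05) {
  if (inherits(x, "lrt_result")) x <- list(x)
  if (inherits(x, "global_lrt_result")) {
    sd <- global_step_down(x, alpha = alpha)
    unit <- if ("study" %in% names(sd)) paste(sd$row, sd$study, sep = ":")
            else sd$row
    return(data.frame(method = x$method, unit = unit, stat = sd$stat,
                      p_value = sd$p_value, threshold_95 = x$threshold_95,
                      signal = sd$signal, signal_rank = sd$signal_rank,
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(x, function(r) {
    sd <- step_down_signals(r, alpha = alpha)
    data.frame(study = r$study, row = sd$row, loglr = sd$loglr,
               p_value = sd$p_value, threshold_95 = r$threshold_95,
               signal = sd$signal, stringsAsFactors = FALSE)
  }))
}

#' Write an analysis report
#'
#' Writes the tidy result table as CSV and, alongside it, a short
#' human-readable text summary listing the detected signals with their
#' statistic, p-value and threshold (and source study for the
#' maximum-over-studies method).
#'
#' @param x A result object accepted by [report_table()].
#' @param path Output CSV path; the text summary goes to the same name
#'   with extension `.txt` (or is skipped with `format = "csv"`).
#' @param alpha Significance level for the signal flags.
#' @param format `"both"` (default), `"csv"`, or `"txt"`.
#' @return The tidy data frame, invisibly.
#' @export
write_report <- function(x, path, alpha = 0.05,
                         format = c("both", "csv", "txt")) {
  format <- match.arg(format)
  tab <- report_table(x, alpha = alpha)
  if (format != "txt")
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  if (format != "csv") {
    txt <- sub("\\.[^.]*$", "", path)
    txt <- paste0(txt, ".txt")
    sig <- tab[tab$signal, , drop = FALSE]
    lines <- c(
      sprintf("Signal detection report (alpha = %g)", alpha),
      sprintf("%d analysis unit(s), %d signal(s) detected",
              nrow(tab), nrow(sig)),
      "")
    if (nrow(sig) > 0) {
      unit <- if ("unit" %in% names(sig)) sig$unit
              else paste(sig$row, sig$study, sep = " @ ")
      stat <- if ("stat" %in% names(sig)) sig$stat else sig$loglr
      lines <- c(lines, sprintf(
        "  %-30s stat %8.3f   p %7.4g   95%% thr %7.3f",
        unit, stat, sig$p_value, sig$threshold_95))
    } else lines <- c(lines, "  no signals at this level")
    writeLines(lines, txt)
  }
  invisible(tab)
}
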
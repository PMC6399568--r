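#' Log likelihood ratio for one row versus its complement
#'
#' The signal-detection statistic compares the Poisson event rate of one
#' row (count \eqn{n}, exposure \eqn{P}) against the pooled rate of all
#' other rows (count \eqn{N - n}, exposure \eqn{P_. - P}).  Writing
#' \eqn{E = P N / P_.} for the expected count under the common-rate null,
#' the statistic is
#' \deqn{\log LR = n \log(n/E) + (N - n) \log\{(N - n)/(N - E)\},}
#' the log of the ratio of the Poisson likelihood maximised under
#' \eqn{p \ne q} to the likelihood maximised under \eqn{p = q}, where
#' \eqn{p} and \eqn{q} are the row and complement rates.  Terms with a
#' zero count contribute 0 (the usual \eqn{0 \log 0 = 0} convention), so
#' the statistic is finite for any table.  The value is always
#' non-negative and is two-sided: no elevated-rate direction is imposed
#' here (see [study_loglr()] for the one-sided version used in testing).
#'
#' In the report-counts dialect the same formula applies with the row's
#' marginal report count standing in for its exposure.
#'
#' @param count Event count of the row, \eqn{0 \le n \le N}. Vectorised.
#' @param exposure Exposure of the row, \eqn{0 < P \le P_.}. Vectorised.
#' @param total_events Total events \eqn{N} over all rows.
#' @param total_exposure Total exposure \eqn{P_.} over all rows.
#'
#' @return Numeric vector of log likelihood ratios (\eqn{\ge 0}).
#'   A degenerate table with `total_events = 0` returns 0.
#' @examples
#' log_lr(67, 196698, 246, 1771756)   # 24.28
#' @export
log_lr <- function(count, exposure, total_events, total_exposure) {
  if (any(exposure <= 0)) stop("'exposure' must be positive", call. = FALSE)
  if (any(exposure > total_exposure))
    stop("'exposure' cannot exceed 'total_exposure'", call. = FALSE)
  if (any(count < 0) || any(count > total_events))
    stop("'count' must lie in [0, total_events]", call. = FALSE)
  if (total_events == 0) return(rep(0, length(count)))
  e <- exposure * total_events / total_exposure
  n <- count
  t1 <- ifelse(n == 0, 0, n * (log(n) - log(e)))
  m <- total_events - n
  t2 <- ifelse(m == 0, 0, m * (log(m) - log(total_events - e)))
  t1 + t2
}

#' Expected row counts under the common-rate null
#'
#' @param table A [study_table()].
#' @return A list with `e` (per-row expected counts
#'   \eqn{E_i = P_i n_. / P_.}, which sum to \eqn{n_.}) and `p_total`
#'   (\eqn{P_. = \sum_i P_i}).
#' @export
expected_counts <- function(table) {
  stopifnot(inherits(table, "study_table"))
  p_total <- sum(table$exposures)
  list(e = stats::setNames(table$exposures * table$total_events / p_total,
                           table$rows),
       p_total = p_total)
}

#' One-sided per-row log likelihood ratios of a study
#'
#' Computes [log_lr()] for every row of a study against the complement of
#' that row, and applies the one-sided alternative \eqn{p_i > q_i}: rows
#' whose observed rate does not exceed the complement's rate get 0, so
#' only rate elevations can score.  The maximum of this vector is the
#' study's MLLR statistic.
#'
#' @param table A [study_table()].
#' @return Named numeric vector of one-sided log likelihood ratios.
#' @examples
#' tab <- study_table(c(67, 179), c(196698, 1575058), c("PLandPPI", "PL"))
#' study_loglr(tab)   # 24.28 for PLandPPI, 0 for PL
#' @export
study_loglr <- function(table) {
  stopifnot(inherits(table, "study_table"))
  .loglr_onesided(table$counts, table$exposures, table$total_events,
                  sum(table$exposures), table$rows)
}

# vectorised one-sided logLR; counts may be a matrix (rows x draws) with
# fixed exposures and total (the conditional null holds N fixed)
.loglr_onesided <- function(counts, exposures, total_events, total_exposure,
                            rows = NULL) {
  if (length(exposures) == 1L) {
    v <- if (is.matrix(counts)) matrix(0, nrow(counts), ncol(counts))
         else rep(0, length(counts))
    return(v)  # single row: no comparison possible
  }
  e <- exposures * total_events / total_exposure
  n <- counts
  m <- total_events - n
  t1 <- n * (log(n) - log(e))
  t1[n == 0] <- 0
  t2 <- m * (log(m) - log(total_events - e))
  t2[m == 0] <- 0
  v <- t1 + t2
  # one-sided indicator: zero unless the row rate exceeds the complement rate
  elevated <- n / exposures > m / (total_exposure - exposures)
  v[!elevated] <- 0
  if (total_events == 0) v[] <- 0
  if (!is.null(rows) && !is.matrix(v)) names(v) <- rows
  v
}
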
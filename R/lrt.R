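# run code under a temporary RNG state when a seed is given; the caller's
# RNG stream is restored afterwards
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# conditional null draws for one study: I x n_draws matrix of multinomial
# counts given the observed total n_. and cell probabilities P_i / P_.
.study_null_draws <- function(table, n_draws) {
  probs <- table$exposures / sum(table$exposures)
  if (table$total_events == 0)
    return(matrix(0L, length(probs), n_draws))
  if (length(probs) == 1L)
    return(matrix(table$total_events, 1L, n_draws))
  stats::rmultinom(n_draws, size = table$total_events, prob = probs)
}

#' Monte-Carlo null sample of the MLLR statistic
#'
#' Draws `n_draws` datasets from the conditional null of the study --
#' multinomial cell counts given the observed total \eqn{n_.} with
#' probabilities \eqn{P_i / P_.} -- and returns the MLLR (maximum
#' one-sided per-row log likelihood ratio) of each draw.  This empirical
#' distribution replaces the intractable finite-sample null of the
#' maximum statistic.
#'
#' @param table A [study_table()].
#' @param n_draws Number of Monte-Carlo draws (default 10000).
#' @param seed Optional integer seed; given the same seed the sample is
#'   reproducible and the caller's RNG state is left untouched.
#' @return Numeric vector of `n_draws` MLLR values.
#' @export
mc_null_sample <- function(table, n_draws = 10000, seed = NULL) {
  stopifnot(inherits(table, "study_table"), n_draws >= 1)
  .with_seed(seed, {
    draws <- .study_null_draws(table, n_draws)
    v <- .loglr_onesided(draws, table$exposures, table$total_events,
                         sum(table$exposures))
    if (is.matrix(v)) apply(v, 2L, max) else rep(0, n_draws)
  })
}

#' Rank-based Monte-Carlo p-value
#'
#' The p-value of an observed statistic against an empirical null sample:
#' one minus the rank of the observed value among the observed value and
#' the null draws, divided by one plus the number of draws.  Ties are
#' ranked in favour of the observed value (it ranks above equal draws),
#' i.e. \eqn{p = \#\{null > obs\} / (1 + n_{draws})}; an observed value
#' exceeding every draw therefore has p-value exactly 0.
#'
#' @param observed Observed statistic (vectorised).
#' @param null_sample Numeric vector of null draws (non-empty).
#' @return p-values in \[0, 1\].
#' @export
mc_p_value <- function(observed, null_sample) {
  if (length(null_sample) < 1L) stop("empty null sample", call. = FALSE)
  m <- length(null_sample)
  srt <- sort(null_sample)
  (m - findInterval(observed, srt)) / (1 + m)
}

#' Regular likelihood ratio test for one study
#'
#' Runs the complete single-study analysis: one-sided per-row log
#' likelihood ratios, the MLLR statistic (their maximum), a Monte-Carlo
#' empirical null conditioned on the observed event total, the rank-based
#' p-value, and the empirical 95% rejection threshold.  The row attaining
#' the maximum is the most significant signal candidate.
#'
#' @param table A [study_table()].
#' @param n_draws Monte-Carlo draws for the empirical null.
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `"lrt_result"` with elements
#'   `per_row_loglr`, `mllr`, `signal_row`, `p_value`, `threshold_95`,
#'   `null_sample`, `mc_draws`, `seed`, `study`.
#' @examples
#' tab <- study_table(c(3, 17), c(2884, 87481), c("PLandPPI", "PL"), "s6")
#' regular_lrt(tab, n_draws = 2000, seed = 1)
#' @export
regular_lrt <- function(table, n_draws = 10000, seed = NULL) {
  stopifnot(inherits(table, "study_table"))
  if (length(table$rows) == 1L)
    warning("single-row table: statistic is 0 and no signal can be detected",
            call. = FALSE)
  v <- study_loglr(table)
  mllr <- max(v)
  null <- mc_null_sample(table, n_draws = n_draws, seed = seed)
  structure(
    list(per_row_loglr = v, mllr = mllr,
         signal_row = table$rows[which.max(v)],
         p_value = mc_p_value(mllr, null),
         threshold_95 = unname(stats::quantile(null, 0.95)),
         null_sample = null, mc_draws = n_draws, seed = seed,
         study = table$study),
    class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat("Regular LRT  (study ", x$study, ", ", x$mc_draws, " MC draws)\n",
      sep = "")
  cat(sprintf("  MLLR = %.4f  (row '%s'),  p = %.4g,  95%% threshold = %.4f\n",
              x$mllr, x$signal_row, x$p_value, x$threshold_95))
  invisible(x)
}

#' Step-down identification of secondary signals
#'
#' After the global test, rows are ranked by their log likelihood ratio
#' and each is tested in turn against the *same* Monte-Carlo null sample
#' of the maximum statistic.  Testing stops at the first row whose
#' p-value is not below `alpha`; rows before the stop are flagged as
#' signals (the first being the primary signal, the rest secondary).
#' Re-using the null of the maximum keeps the procedure conservative for
#' the lower-ranked rows.
#'
#' @param result An [regular_lrt()] result (or any object with
#'   `per_row_loglr` and `null_sample`).
#' @param alpha Significance level (default 0.05).
#' @return A data frame with one line per row: `row`, `loglr`, `p_value`,
#'   `signal` (logical), ordered by decreasing `loglr`.
#' @export
step_down_signals <- function(result, alpha = 0.05) {
  v <- sort(result$per_row_loglr, decreasing = TRUE)
  p <- mc_p_value(v, result$null_sample)
  sig <- p < alpha & v > 0  # a non-elevated row is never a signal
  if (any(!sig)) {
    stop_at <- which(!sig)[1L]
    if (stop_at <= length(sig)) sig[stop_at:length(sig)] <- FALSE
  }
  data.frame(row = names(v), loglr = unname(v), p_value = unname(p),
             signal = unname(sig), row.names = NULL,
             stringsAsFactors = FALSE)
}
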
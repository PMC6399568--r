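# --- shared multi-study Monte-Carlo machinery -------------------------------
#
# All multi-study nulls regenerate EVERY study from its own conditional
# multinomial (given that study's observed event total and exposures), never
# from the pooled margins.  One RNG stream covers all studies so a single
# seed fixes the whole draw.

# draw n_draws replicate datasets; eta (optional; vector over the row
# vocabulary, or a rows x studies matrix) multiplies the cell
# probabilities row-wise to plant signals.  Returns per-study count
# matrices (I_s x n_draws) and one-sided logLR matrices of the same shape.
.ms_draws <- function(data, n_draws, eta = NULL, keep_counts = TRUE) {
  vocab <- attr(data, "rows")
  counts <- vector("list", length(data))
  loglr <- vector("list", length(data))
  for (s in seq_along(data)) {
    tab <- data[[s]]
    w <- tab$exposures
    if (!is.null(eta)) {
      w <- w * if (is.matrix(eta)) eta[match(tab$rows, vocab), s]
               else eta[match(tab$rows, vocab)]
    }
    if (length(w) == 1L) {
      cm <- matrix(tab$total_events, 1L, n_draws)
    } else if (tab$total_events == 0) {
      cm <- matrix(0, length(w), n_draws)
    } else {
      cm <- stats::rmultinom(n_draws, tab$total_events, w / sum(w))
    }
    loglr[[s]] <- .loglr_onesided(cm, tab$exposures, tab$total_events,
                                  sum(tab$exposures))
    if (keep_counts) counts[[s]] <- cm
  }
  list(counts = if (keep_counts) counts else NULL, loglr = loglr)
}

# column maxima of a matrix (0 for a 1-row degenerate study)
.colmax <- function(m) if (nrow(m) == 0L) numeric(ncol(m)) else
  do.call(pmax, lapply(seq_len(nrow(m)), function(i) m[i, ]))

# MMLLR per draw: max over studies and rows
.mmllr_stat <- function(loglr_list) {
  mllr_s <- lapply(loglr_list, .colmax)
  do.call(pmax, mllr_s)
}

# per-study weights for the weighted combiner
.wlrn_weights <- function(data, weight_mode, weights) {
  switch(weight_mode,
    study_total_exposure = vapply(data, function(t) sum(t$exposures),
                                  numeric(1)),
    custom = {
      if (is.null(weights) || length(weights) != length(data) ||
          any(weights <= 0))
        stop("'weights' must be positive, one per study", call. = FALSE)
      as.numeric(weights)
    },
    NULL)  # row_exposure handled per row
}

# wLR_i per draw for every vocabulary row, then the maximum MwLR.
# study_w is NULL for row_exposure mode (weights are the row's exposures).
.mwlr_stat <- function(data, loglr_list, study_w) {
  vocab <- attr(data, "rows")
  n_draws <- ncol(loglr_list[[1L]])
  num <- matrix(0, length(vocab), n_draws)
  den <- numeric(length(vocab))
  for (s in seq_along(data)) {
    idx <- match(data[[s]]$rows, vocab)
    w <- if (is.null(study_w)) data[[s]]$exposures
         else rep(study_w[s], length(idx))
    num[idx, ] <- num[idx, ] + w * loglr_list[[s]]
    den[idx] <- den[idx] + w
  }
  keep <- den > 0
  if (!all(keep))
    warning("rows with zero total weight excluded: ",
            paste(vocab[!keep], collapse = ", "), call. = FALSE)
  wlr <- num[keep, , drop = FALSE] / den[keep]
  rownames(wlr) <- vocab[keep]
  list(wlr = wlr, mwlr = .colmax(wlr))
}

.new_global_result <- function(method, statistic, signal, p_value,
                               threshold_95, per_unit_stats, null_sample,
                               mc_draws, seed) {
  structure(list(method = method, statistic = statistic, signal = signal,
                 p_value = p_value, threshold_95 = threshold_95,
                 per_unit_stats = per_unit_stats, null_sample = null_sample,
                 mc_draws = mc_draws, seed = seed),
            class = "global_lrt_result")
}

#' @export
print.global_lrt_result <- function(x, ...) {
  cat("Multi-study LRT, method '", x$method, "'  (", x$mc_draws,
      " MC draws)\n", sep = "")
  cat(sprintf("  statistic = %.4f  (%s),  p = %.4g,  95%% threshold = %.4f\n",
              x$statistic, paste(x$signal, collapse = " in "),
              x$p_value, x$threshold_95))
  invisible(x)
}

# --- the three combiners ----------------------------------------------------

#' Simple pooled analysis with the regular LRT
#'
#' Sums counts and exposures over studies ([pool_studies()]) and applies
#' the regular LRT to the collapsed table.  The Monte-Carlo null is drawn
#' from the *pooled* table's conditional multinomial, not from the
#' study-level structure; when exposure composition differs across
#' studies this null understates the variance of the pooled counts, so
#' the pooled test need not control the type-I error (and is vulnerable
#' to aggregation paradoxes).  It is provided as the naive baseline.
#'
#' @param data A [multi_study()] object.
#' @param n_draws Monte-Carlo draws for the empirical null.
#' @param seed Optional integer seed.
#' @return A `"global_lrt_result"` (see [mmlr()]).
#' @examples
#' pooled_lrt(ppi_fixture("first_occurrence"), n_draws = 2000, seed = 1)
#' @export
pooled_lrt <- function(data, n_draws = 10000, seed = NULL) {
  stopifnot(inherits(data, "multi_study"))
  pooled <- pool_studies(data)
  res <- regular_lrt(pooled, n_draws = n_draws, seed = seed)
  .new_global_result("pooled", res$mllr, res$signal_row, res$p_value,
                     res$threshold_95, res$per_row_loglr, res$null_sample,
                     n_draws, seed)
}

#' Maximum over studies of the study-level MLLR (MMLR)
#'
#' Each study is analysed by the regular LRT; the global statistic is the
#' maximum of the per-study MLLR values,
#' \eqn{MMLLR = \max_s \max_i \log LR_{is}}, and the detected signal is a
#' (row, study) combination.  The empirical null regenerates every study
#' from its own conditional multinomial per draw and takes the same
#' double maximum, so study-level heterogeneity is respected and the
#' type-I error is controlled.
#'
#' @param data A [multi_study()] object.
#' @param n_draws Monte-Carlo draws for the empirical null.
#' @param seed Optional integer seed.
#' @return An object of class `"global_lrt_result"`: `method`,
#'   `statistic`, `signal` (here `c(row, study)`), `p_value`,
#'   `threshold_95`, `per_unit_stats` (all row-study log likelihood
#'   ratios, for step-down), `null_sample`, `mc_draws`, `seed`.
#' @examples
#' mmlr(ppi_fixture("all_occurrences"), n_draws = 2000, seed = 1)
#' @export
mmlr <- function(data, n_draws = 10000, seed = NULL) {
  stopifnot(inherits(data, "multi_study"))
  obs <- lapply(data, study_loglr)
  units <- data.frame(
    row = unlist(lapply(obs, names), use.names = FALSE),
    study = rep(names(data), lengths(obs)),
    loglr = unlist(obs, use.names = FALSE),
    stringsAsFactors = FALSE)
  k <- which.max(units$loglr)
  null <- .with_seed(seed, {
    d <- .ms_draws(data, n_draws, keep_counts = FALSE)
    .mmllr_stat(d$loglr)
  })
  .new_global_result("mmlr", units$loglr[k],
                     c(row = units$row[k], study = units$study[k]),
                     mc_p_value(units$loglr[k], null),
                     unname(stats::quantile(null, 0.95)),
                     units, null, n_draws, seed)
}

#' Exposure-weighted LRT over studies (wLRn)
#'
#' For each row \eqn{i}, the combined statistic is the weighted average
#' of its one-sided per-study log likelihood ratios over the \eqn{S_i}
#' studies containing the row,
#' \eqn{wLR_i = \sum_s w_{is} \log LR_{is} / \sum_s w_{is}}, and the
#' global statistic is \eqn{MwLR = \max_i wLR_i}.  Studies where the row
#' is not rate-elevated contribute 0 through the one-sided indicator.
#' The default weight is the study's total exposure (all rows of a study
#' share one weight), which reproduces the behaviour of weighting a
#' study's evidence by the information it carries; weighting by the
#' row's own exposure, or supplying custom per-study weights (e.g.
#' sample sizes), are alternatives.  The empirical null regenerates all
#' studies per draw, as in [mmlr()].
#'
#' @param data A [multi_study()] object.
#' @param n_draws Monte-Carlo draws for the empirical null.
#' @param seed Optional integer seed.
#' @param weight_mode `"study_total_exposure"` (default),
#'   `"row_exposure"`, or `"custom"`.
#' @param weights Positive per-study weights, required when
#'   `weight_mode = "custom"`.
#' @return A `"global_lrt_result"`; `per_unit_stats` holds the per-row
#'   `wlr` values used for step-down.
#' @examples
#' wlrn(ppi_fixture("all_occurrences"), n_draws = 2000, seed = 1)
#' @export
wlrn <- function(data, n_draws = 10000, seed = NULL,
                 weight_mode = c("study_total_exposure", "row_exposure",
                                 "custom"),
                 weights = NULL) {
  stopifnot(inherits(data, "multi_study"))
  weight_mode <- match.arg(weight_mode)
  study_w <- .wlrn_weights(data, weight_mode, weights)
  obs_ll <- lapply(data, function(t) matrix(study_loglr(t), ncol = 1L))
  obs <- .mwlr_stat(data, obs_ll, study_w)
  wlr <- stats::setNames(as.vector(obs$wlr[, 1L]), rownames(obs$wlr))
  k <- which.max(wlr)
  null <- .with_seed(seed, {
    d <- .ms_draws(data, n_draws, keep_counts = FALSE)
    .mwlr_stat(data, d$loglr, study_w)$mwlr
  })
  units <- data.frame(row = names(wlr), loglr = unname(wlr),
                      stringsAsFactors = FALSE)
  .new_global_result("wlrn", unname(wlr[k]), c(row = names(wlr)[k]),
                     mc_p_value(wlr[k], null),
                     unname(stats::quantile(null, 0.95)),
                     units, null, n_draws, seed)
}

#' Step-down secondary signals for a multi-study analysis
#'
#' Ranks the analysis units -- rows for the pooled and weighted methods,
#' (row, study) combinations for [mmlr()] -- by their statistic and tests
#' each against the stored global null sample with the rank-based
#' p-value, stopping at the first unit that is not significant.
#'
#' @param result A `"global_lrt_result"`.
#' @param alpha Significance level (default 0.05).
#' @return A data frame ordered by decreasing statistic with columns
#'   `row` (and `study` for mmlr), `stat`, `p_value`, `signal`,
#'   `signal_rank` (NA for non-signals).
#' @examples
#' res <- mmlr(ppi_fixture("all_occurrences"), n_draws = 2000, seed = 1)
#' global_step_down(res)   # studies 2, 4, 5 and 6 carry the signal
#' @export
global_step_down <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "global_lrt_result"))
  units <- result$per_unit_stats
  units <- units[order(units$loglr, decreasing = TRUE), , drop = FALSE]
  p <- mc_p_value(units$loglr, result$null_sample)
  sig <- p < alpha & units$loglr > 0
  if (any(!sig)) {
    stop_at <- which(!sig)[1L]
    sig[stop_at:length(sig)] <- FALSE
  }
  out <- data.frame(units, p_value = p, signal = sig,
                    signal_rank = ifelse(sig, cumsum(sig), NA_integer_),
                    row.names = NULL, stringsAsFactors = FALSE)
  names(out)[names(out) == "loglr"] <- "stat"
  out
}
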
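# Traditional meta-analysis of log relative risks (rate ratios), the
# comparator for the LRT combiners.  Pooling uses the closed-form
# inverse-variance and DerSimonian-Laird moment estimators so that the
# conventions (variance 1/n1 + 1/n2, z = 1.96) are explicit; metafor is
# used as an independent cross-check in the test suite.

#' Per-study relative risk on the log scale
#'
#' For two compared rows with event counts and exposures
#' \eqn{(n_1, P_1)} and \eqn{(n_2, P_2)}, the log rate ratio is
#' \eqn{\log\{(n_1/P_1)/(n_2/P_2)\}} with the usual person-time variance
#' \eqn{1/n_1 + 1/n_2}; the 95% interval is
#' \eqn{\exp(\log rr \pm 1.96\sqrt{var})}.
#'
#' @param n1,P1 Events and exposure of the index row (e.g. the treated
#'   group). Vectorised.
#' @param n2,P2 Events and exposure of the reference row.
#' @param study Optional study labels.
#' @return A data frame of class `"study_effects"` with columns `study`,
#'   `n1`, `P1`, `n2`, `P2`, `log_rr`, `variance`, `rr`, `ci_low`,
#'   `ci_high`.  Both counts must be positive (the variance is undefined
#'   otherwise); see [study_effects()] for the handling of zero-count
#'   studies.
#' @examples
#' study_effect(20, 181753, 77, 1534190)   # rr 2.19 (1.34, 3.58)
#' @export
study_effect <- function(n1, P1, n2, P2, study = NULL) {
  if (any(n1 <= 0) || any(n2 <= 0))
    stop("event counts must be positive for a log relative risk",
         call. = FALSE)
  if (is.null(study)) study <- paste0("s", seq_along(n1))
  log_rr <- log((n1 / P1) / (n2 / P2))
  variance <- 1 / n1 + 1 / n2
  half <- 1.96 * sqrt(variance)
  structure(
    data.frame(study = as.character(study), n1 = n1, P1 = P1, n2 = n2,
               P2 = P2, log_rr = log_rr, variance = variance,
               rr = exp(log_rr), ci_low = exp(log_rr - half),
               ci_high = exp(log_rr + half), stringsAsFactors = FALSE),
    class = c("study_effects", "data.frame"))
}

#' Per-study effects from a multi-study dataset
#'
#' Extracts, for every study containing both rows, the relative risk of
#' `rows[1]` versus `rows[2]`.  Studies with a zero count in either row
#' are excluded with a warning (their log-rate-ratio variance is
#' undefined); setting `zero_counts = "continuity"` instead adds 0.5 to
#' both counts of the affected studies.
#'
#' @param data A [multi_study()] object.
#' @param rows Character vector of the two row labels to compare
#'   (index first); defaults to the first two vocabulary rows.
#' @param zero_counts `"exclude"` (default) or `"continuity"`.
#' @return A `"study_effects"` data frame (see [study_effect()]).
#' @examples
#' study_effects(ppi_fixture("first_occurrence"))
#' @export
study_effects <- function(data, rows = NULL,
                          zero_counts = c("exclude", "continuity")) {
  stopifnot(inherits(data, "multi_study"))
  zero_counts <- match.arg(zero_counts)
  if (is.null(rows)) rows <- attr(data, "rows")[1:2]
  if (length(rows) != 2L) stop("'rows' must name two rows", call. = FALSE)
  rec <- lapply(data, function(tab) {
    i <- match(rows, tab$rows)
    if (anyNA(i)) return(NULL)
    c(tab$counts[i], tab$exposures[i])
  })
  rec <- rec[!vapply(rec, is.null, logical(1))]
  m <- do.call(rbind, rec)
  n1 <- m[, 1]; n2 <- m[, 2]; P1 <- m[, 3]; P2 <- m[, 4]
  zero <- n1 == 0 | n2 == 0
  if (any(zero)) {
    if (zero_counts == "exclude") {
      warning("excluding ", sum(zero), " zero-count stud",
              if (sum(zero) > 1) "ies" else "y", ": ",
              paste(rownames(m)[zero], collapse = ", "), call. = FALSE)
      n1 <- n1[!zero]; n2 <- n2[!zero]; P1 <- P1[!zero]; P2 <- P2[!zero]
      m <- m[!zero, , drop = FALSE]
    } else {
      n1 <- n1 + 0.5 * zero
      n2 <- n2 + 0.5 * zero
    }
  }
  if (length(n1) == 0L) stop("no studies with both rows observed",
                             call. = FALSE)
  study_effect(n1, P1, n2, P2, study = rownames(m))
}

.meta_pool <- function(effects, tau2, model) {
  w <- 1 / (effects$variance + tau2)
  mu <- sum(w * effects$log_rr) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- mu / se
  structure(
    list(model = model, pooled_rr = exp(mu), log_rr = mu, se = se,
         ci_low = exp(mu - 1.96 * se), ci_high = exp(mu + 1.96 * se),
         tau2 = tau2, z = z, p = 2 * stats::pnorm(-abs(z)),
         k = nrow(effects)),
    class = "meta_result")
}

#' Fixed-effect meta-analysis of log relative risks
#'
#' Inverse-variance pooling: weights \eqn{w_s = 1/var_s}, pooled effect
#' \eqn{\sum w_s \log rr_s / \sum w_s}, standard error
#' \eqn{1/\sqrt{\sum w_s}}, two-sided Z test of no effect.
#'
#' @param effects A `"study_effects"` data frame ([study_effects()]).
#' @return An object of class `"meta_result"`: `model`, `pooled_rr`,
#'   `log_rr`, `se`, `ci_low`, `ci_high`, `tau2` (0 here), `z`, `p`, `k`.
#' @examples
#' fixed_effect(study_effects(ppi_fixture("first_occurrence")))
#' @export
fixed_effect <- function(effects) {
  stopifnot(inherits(effects, "study_effects"))
  .meta_pool(effects, 0, "fixed")
}

#' Random-effects meta-analysis (DerSimonian-Laird)
#'
#' Between-study variance by the moment estimator: with fixed-effect
#' weights \eqn{w_s}, \eqn{Q = \sum w_s (\log rr_s - \hat\mu_{FE})^2}
#' and \eqn{\tau^2 = \max\{0, (Q - (S-1)) / (\sum w - \sum w^2/\sum w)\}};
#' pooling then uses weights \eqn{1/(var_s + \tau^2)}.  When \eqn{\tau^2}
#' truncates to 0 the result coincides with [fixed_effect()].
#'
#' @inheritParams fixed_effect
#' @return A `"meta_result"` (see [fixed_effect()]) with `model =
#'   "random"` and the estimated `tau2`.
#' @examples
#' random_effects_dl(study_effects(ppi_fixture("all_occurrences")))
#' @export
random_effects_dl <- function(effects) {
  stopifnot(inherits(effects, "study_effects"))
  w <- 1 / effects$variance
  mu_fe <- sum(w * effects$log_rr) / sum(w)
  q <- sum(w * (effects$log_rr - mu_fe)^2)
  k <- nrow(effects)
  tau2 <- if (k < 2L) 0 else
    max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  .meta_pool(effects, tau2, "random")
}

#' Z test of the pooled relative risk
#'
#' Rejects when \eqn{|\log \hat{rr}| / se} exceeds the two-sided normal
#' critical value, i.e. tests the null that the overall relative risk
#' is 1.
#'
#' @param result A `"meta_result"`.
#' @param alpha Two-sided level (default 0.05).
#' @return `TRUE` if the null of no overall effect is rejected.
#' @export
meta_z_test <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "meta_result"))
  abs(result$z) > stats::qnorm(1 - alpha / 2)
}

#' Forest-plot table
#'
#' Per-study relative risks with their intervals plus the pooled summary
#' row, in a tidy layout ready for plotting or reporting.
#'
#' @param effects A `"study_effects"` data frame.
#' @param result A `"meta_result"` pooled from it.
#' @return A data frame with columns `study`, `rr`, `ci_low`, `ci_high`,
#'   `weight` (normalised pooling weight, NA for the summary row),
#'   `summary` (logical).
#' @export
forest_table <- function(effects, result) {
  stopifnot(inherits(effects, "study_effects"),
            inherits(result, "meta_result"))
  w <- 1 / (effects$variance + result$tau2)
  rbind(
    data.frame(study = effects$study, rr = effects$rr,
               ci_low = effects$ci_low, ci_high = effects$ci_high,
               weight = w / sum(w), summary = FALSE,
               stringsAsFactors = FALSE),
    data.frame(study = paste0("pooled (", result$model, ")"),
               rr = result$pooled_rr, ci_low = result$ci_low,
               ci_high = result$ci_high, weight = NA_real_,
               summary = TRUE, stringsAsFactors = FALSE))
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "%s-effect meta-analysis of %d studies\n  rr = %.3f (%.3f, %.3f), tau2 = %.4f, z = %.3f, p = %.4g\n",
    x$model, x$k, x$pooled_rr, x$ci_low, x$ci_high, x$tau2, x$z, x$p))
  invisible(x)
}
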
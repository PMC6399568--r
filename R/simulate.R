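# Simulation harness: type-I error and power of the multi-study LRT
# combiners and of the traditional meta-analysis Z test, on conditioned
# multinomial study grids.
#
# A scenario fixes the per-study event totals n_.s and exposures P_is of
# an observed grid; replicates are drawn per study from
#   (n_1s, ..., n_Is) | n_.s ~ Mult(n_.s, eta_is P_is / sum_i eta_is P_is),
# the common-rate null when all eta within a study are equal.  Because
# every replicate shares the same (n_.s, P_is), each method's Monte-Carlo
# null distribution is computed once per scenario and reused across
# replicates; a per-replicate threshold mode exists but is redundant on
# fixed grids.

#' Define a simulation scenario
#'
#' @param grid A [multi_study()] object supplying the per-study event
#'   totals and exposures that every replicate conditions on (e.g.
#'   [ppi_fixture()] or [lipiodol_like()]).
#' @param eta Relative-risk multipliers planted on the rows: a vector
#'   over the row vocabulary (recycled across studies) or a rows-by-
#'   studies matrix for study-varying risks.  All 1 is the global null.
#' @param n_reps Number of simulated datasets (10000 for type-I error,
#'   1000 for power are the conventional sizes).
#' @param mc_draws Monte-Carlo draws for each method's empirical null.
#' @param alpha Nominal level of the tests.
#' @param seed Integer seed fixing thresholds and replicates.
#' @param name Scenario label used in reports.
#' @return An object of class `"scenario"`.
#' @examples
#' scenario(ppi_fixture("first_occurrence"), n_reps = 200, mc_draws = 500,
#'          seed = 1, name = "null-1occ")
#' @export
scenario <- function(grid, eta = 1, n_reps = 1000, mc_draws = 10000,
                     alpha = 0.05, seed = 1, name = "scenario") {
  stopifnot(inherits(grid, "multi_study"))
  vocab <- attr(grid, "rows")
  if (is.matrix(eta)) {
    if (nrow(eta) != length(vocab) || ncol(eta) != length(grid))
      stop("'eta' matrix must be rows x studies", call. = FALSE)
  } else {
    eta <- rep(eta, length.out = length(vocab))
  }
  if (any(eta <= 0)) stop("'eta' must be positive", call. = FALSE)
  structure(list(grid = grid, eta = eta, n_reps = n_reps,
                 mc_draws = mc_draws, alpha = alpha, seed = seed,
                 name = name),
            class = "scenario")
}

.is_null_scenario <- function(scn) {
  if (is.matrix(scn$eta))
    all(apply(scn$eta, 2L, function(col) length(unique(col)) == 1L))
  else length(unique(scn$eta)) == 1L
}

#' @export
print.scenario <- function(x, ...) {
  cat("Scenario '", x$name, "': ", length(x$grid), " studies, ",
      length(attr(x$grid, "rows")), " rows, ",
      if (.is_null_scenario(x)) "null" else "alternative",
      " (n_reps = ", x$n_reps, ", mc_draws = ", x$mc_draws,
      ", alpha = ", x$alpha, ", seed = ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Scenarios on the embedded PPI grids
#'
#' Convenience constructor for the standard simulation grids: the
#' six-study PPI dataset with a relative-risk multiplier `eta1` planted
#' on the `PLandPPI` row (a scalar for a common risk, or one value per
#' study for study-varying risks such as
#' `c(1.5, 1.2, 3, 1, 1.3, 2)`).
#'
#' @param endpoint Passed to [ppi_fixture()].
#' @param eta1 Relative risk(s) of the `PLandPPI` row; 1 is the null.
#' @inheritParams scenario
#' @return A [scenario()].
#' @export
ppi_scenario <- function(endpoint = c("first_occurrence",
                                      "all_occurrences"),
                         eta1 = 1, n_reps = 1000, mc_draws = 10000,
                         alpha = 0.05, seed = 1, name = NULL) {
  endpoint <- match.arg(endpoint)
  grid <- ppi_fixture(endpoint)
  if (is.null(name))
    name <- paste0(if (all(eta1 == 1)) "sim0" else "sima",
                   if (endpoint == "first_occurrence") "1occ" else "allocc")
  eta <- if (length(eta1) == 1L) c(eta1, 1) else
    rbind(rep(eta1, length.out = length(grid)), 1)
  scenario(grid, eta = eta, n_reps = n_reps, mc_draws = mc_draws,
           alpha = alpha, seed = seed, name = name)
}

#' Draw one study's table under a scenario
#'
#' Generates the counts of study `study_index` from the scenario's
#' conditional multinomial (using the current RNG stream; seed the
#' session or pass `seed` for reproducibility).
#'
#' @param scn A [scenario()].
#' @param study_index Which study to draw.
#' @param seed Optional integer seed.
#' @return A [study_table()] with the same rows and exposures as the
#'   grid study and freshly drawn counts.
#' @export
generate_study <- function(scn, study_index, seed = NULL) {
  stopifnot(inherits(scn, "scenario"))
  tab <- scn$grid[[study_index]]
  vocab <- attr(scn$grid, "rows")
  eta_s <- if (is.matrix(scn$eta)) scn$eta[match(tab$rows, vocab), study_index]
           else scn$eta[match(tab$rows, vocab)]
  w <- tab$exposures * eta_s
  cnt <- .with_seed(seed, {
    if (length(w) == 1L) tab$total_events
    else stats::rmultinom(1L, tab$total_events, w / sum(w))[, 1L]
  })
  study_table(counts = cnt, exposures = tab$exposures, rows = tab$rows,
              study = tab$study)
}

# --- core engine ------------------------------------------------------------

# null samples (length mc_draws) of each method's statistic on the grid
.method_nulls <- function(grid, mc_draws, methods, weight_mode, weights) {
  out <- list()
  if (any(c("mmlr", "wlrn") %in% methods)) {
    d <- .ms_draws(grid, mc_draws, keep_counts = FALSE)
    if ("mmlr" %in% methods) out$mmlr <- .mmllr_stat(d$loglr)
    if ("wlrn" %in% methods)
      out$wlrn <- .mwlr_stat(grid, d$loglr,
                             .wlrn_weights(grid, weight_mode, weights))$mwlr
  }
  if ("pooled" %in% methods) {
    # the pooled method's null is drawn from the pooled table itself --
    # the documented reason its type-I error can exceed nominal
    pooled <- pool_studies(grid)
    out$pooled <- mc_null_sample(pooled, mc_draws)
  }
  out
}

# replicate statistics for each method from one set of per-study draws
.method_stats <- function(grid, draws, methods, weight_mode, weights) {
  out <- list()
  if ("mmlr" %in% methods) out$mmlr <- .mmllr_stat(draws$loglr)
  if ("wlrn" %in% methods)
    out$wlrn <- .mwlr_stat(grid, draws$loglr,
                           .wlrn_weights(grid, weight_mode, weights))$mwlr
  if ("pooled" %in% methods) {
    vocab <- attr(grid, "rows")
    n_draws <- ncol(draws$counts[[1L]])
    pc <- matrix(0, length(vocab), n_draws)
    pe <- numeric(length(vocab))
    for (s in seq_along(grid)) {
      idx <- match(grid[[s]]$rows, vocab)
      pc[idx, ] <- pc[idx, ] + draws$counts[[s]]
      pe[idx] <- pe[idx] + grid[[s]]$exposures
    }
    out$pooled <- .colmax(.loglr_onesided(pc, pe, sum(pc[, 1L]), sum(pe)))
  }
  out
}

.power_row <- function(name, method, stats, null, alpha, n_reps) {
  # a replicate rejects when its statistic strictly exceeds the upper
  # alpha empirical quantile of the scenario's null sample -- the
  # threshold form of the test; for these discrete statistics this is
  # slightly more conservative than p < alpha under the reporting
  # p-value's tie convention
  thr <- if (alpha <= 0) Inf else stats::quantile(null, 1 - alpha,
                                                  names = FALSE)
  r <- mean(stats > thr)
  data.frame(scenario = name, method = method, rejection_rate = r,
             n_reps = n_reps, mc_se = sqrt(r * (1 - r) / n_reps),
             stringsAsFactors = FALSE)
}

.run_lrt_scenario <- function(scn, methods, weight_mode, weights) {
  .with_seed(scn$seed, {
    nulls <- .method_nulls(scn$grid, scn$mc_draws, methods, weight_mode,
                           weights)
    draws <- .ms_draws(scn$grid, scn$n_reps,
                       eta = if (.is_null_scenario(scn)) NULL else scn$eta,
                       keep_counts = "pooled" %in% methods)
    stats <- .method_stats(scn$grid, draws, methods, weight_mode, weights)
    do.call(rbind, lapply(methods, function(m)
      .power_row(scn$name, m, stats[[m]], nulls[[m]], scn$alpha,
                 scn$n_reps)))
  })
}

#' Type-I error of the LRT combiners on a null scenario
#'
#' Simulates `n_reps` null datasets (all relative risks equal within
#' each study), computes each method's statistic per replicate, and
#' reports the fraction rejected at level `alpha`.  Because every
#' replicate conditions on the same totals and exposures, each method's
#' empirical null (of `mc_draws` draws) is computed once and shared by
#' all replicates; a replicate is rejected when its rank-based p-value
#' against that null sample is below `alpha`.
#'
#' @param scn A null [scenario()] (all `eta` equal within study).
#' @param methods Any of `"pooled"`, `"wlrn"`, `"mmlr"`.
#' @param weight_mode,weights Passed to the weighted combiner, see
#'   [wlrn()].
#' @return A data frame with one line per method: `scenario`, `method`,
#'   `rejection_rate`, `n_reps`, `mc_se` (binomial standard error).
#' @examples
#' estimate_type1(ppi_scenario("first_occurrence", n_reps = 200,
#'                             mc_draws = 500, seed = 1))
#' @export
estimate_type1 <- function(scn, methods = c("pooled", "wlrn", "mmlr"),
                           weight_mode = "study_total_exposure",
                           weights = NULL) {
  stopifnot(inherits(scn, "scenario"))
  if (!.is_null_scenario(scn))
    stop("scenario plants a signal; use estimate_power()", call. = FALSE)
  methods <- match.arg(methods, several.ok = TRUE)
  .run_lrt_scenario(scn, methods, weight_mode, weights)
}

#' Power of the LRT combiners on an alternative scenario
#'
#' As [estimate_type1()], but replicates are generated with the
#' scenario's planted relative risks while each method's rejection
#' threshold is still calibrated on the null of the same grid.
#'
#' @inheritParams estimate_type1
#' @param scn An alternative [scenario()].
#' @return A data frame as in [estimate_type1()].
#' @examples
#' estimate_power(ppi_scenario("all_occurrences", eta1 = 3, n_reps = 100,
#'                             mc_draws = 500, seed = 1))
#' @export
estimate_power <- function(scn, methods = c("pooled", "wlrn", "mmlr"),
                           weight_mode = "study_total_exposure",
                           weights = NULL) {
  stopifnot(inherits(scn, "scenario"))
  if (.is_null_scenario(scn))
    warning("null scenario: the 'power' is the type-I error",
            call. = FALSE)
  methods <- match.arg(methods, several.ok = TRUE)
  .run_lrt_scenario(scn, methods, weight_mode, weights)
}

#' Rejection rate of the traditional meta-analysis Z test
#'
#' For two-row scenarios, each replicate is pooled by the fixed-effect
#' (or DerSimonian-Laird random-effects) model of the per-study log
#' relative risks and the two-sided Z test of no overall effect is run
#' at level `alpha`.  Studies with a zero count in either row carry an
#' undefined log-rate-ratio variance and are dropped from that
#' replicate; replicates with fewer than two usable studies are skipped
#' (both counts reported in the result).
#'
#' @param scn A two-row [scenario()].
#' @param model `"fixed"` or `"random"`.
#' @return A data frame: `scenario`, `method`, `rejection_rate`,
#'   `n_reps` (replicates used), `n_skipped`, `mc_se`.
#' @examples
#' estimate_meta_test(ppi_scenario("all_occurrences", n_reps = 500,
#'                                 seed = 1))
#' @export
estimate_meta_test <- function(scn, model = c("fixed", "random")) {
  stopifnot(inherits(scn, "scenario"))
  model <- match.arg(model)
  grid <- scn$grid
  if (length(attr(grid, "rows")) != 2L)
    stop("the meta-analysis benchmark needs a two-row scenario",
         call. = FALSE)
  S <- length(grid)
  Ns <- vapply(grid, `[[`, numeric(1), "total_events")
  P1 <- vapply(grid, function(t) t$exposures[1L], numeric(1))
  P2 <- vapply(grid, function(t) t$exposures[2L], numeric(1))
  .with_seed(scn$seed, {
    d <- .ms_draws(grid, scn$n_reps,
                   eta = if (.is_null_scenario(scn)) NULL else scn$eta,
                   keep_counts = TRUE)
    n1 <- do.call(rbind, lapply(d$counts, function(m) m[1L, ]))  # S x reps
    n2 <- Ns - n1
    ok <- n1 > 0 & n2 > 0
    lrr <- log((n1 / P1) / (n2 / P2))
    v <- 1 / n1 + 1 / n2
    w <- ifelse(ok, 1 / v, 0)
    lrr[!ok] <- 0
    k <- colSums(ok)
    sw <- colSums(w)
    mu <- colSums(w * lrr) / sw
    if (model == "random") {
      q <- colSums(w * (lrr - rep(mu, each = S))^2 * ok)
      tau2 <- pmax(0, (q - (k - 1)) / (sw - colSums(w^2) / sw))
      w <- ifelse(ok, 1 / (v + rep(tau2, each = S)), 0)
      sw <- colSums(w)
      mu <- colSums(w * lrr) / sw
    }
    z <- mu / (1 / sqrt(sw))
    usable <- k >= 2L
    rej <- abs(z[usable]) > stats::qnorm(1 - scn$alpha / 2)
    r <- mean(rej)
    data.frame(scenario = scn$name,
               method = paste0("meta_", model),
               rejection_rate = r, n_reps = sum(usable),
               n_skipped = sum(!usable),
               mc_se = sqrt(r * (1 - r) / sum(usable)),
               stringsAsFactors = FALSE)
  })
}

#' Run a grid of scenarios
#'
#' Executes each scenario with [estimate_type1()] or [estimate_power()]
#' as appropriate (and optionally the meta-analysis benchmark for
#' two-row grids), binding the results into one tidy table shaped like a
#' type-I-error / power report.
#'
#' @param scenarios A list of [scenario()] objects.
#' @param methods LRT methods to evaluate.
#' @param meta Also run [estimate_meta_test()] (fixed-effect) on two-row
#'   scenarios.
#' @return A data frame of rejection rates, one line per scenario and
#'   method.
#' @export
run_scenario_grid <- function(scenarios,
                              methods = c("pooled", "wlrn", "mmlr"),
                              meta = FALSE) {
  if (inherits(scenarios, "scenario")) scenarios <- list(scenarios)
  out <- lapply(scenarios, function(scn) {
    res <- if (.is_null_scenario(scn)) estimate_type1(scn, methods)
           else estimate_power(scn, methods)
    if (meta && length(attr(scn$grid, "rows")) == 2L) {
      mt <- estimate_meta_test(scn)
      res <- rbind(res, mt[names(mt) != "n_skipped"])
    }
    res
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}
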
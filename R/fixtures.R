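# Embedded PPI example: 6 randomised trials comparing the composite
# osteoporosis-related AE between patients on placebo plus concomitant
# proton pump inhibitors (PLandPPI) and placebo only (PL), with
# person-day exposures.  Two endpoints: first occurrence of the
# composite AE (1occ) and all repeated occurrences (allocc).
.ppi_data <- list(
  first_occurrence = list(
    PLandPPI = list(events = c(1, 20, 2, 30, 8, 3),
                    exposure = c(10225, 181753, 9822, 56845, 19575, 2884)),
    PL = list(events = c(14, 77, 11, 167, 144, 17),
              exposure = c(168947, 1534190, 133813, 470833, 713856, 87481))),
  all_occurrences = list(
    PLandPPI = list(events = c(4, 67, 3, 48, 14, 5),
                    exposure = c(10383, 196698, 10381, 64764, 24188, 4266)),
    PL = list(events = c(30, 179, 13, 228, 169, 21),
              exposure = c(173796, 1575058, 136128, 513109, 789274, 95959))))

#' The embedded PPI six-trial dataset
#'
#' Event counts and person-day exposures for the composite
#' osteoporosis-related adverse event in six trials, comparing patients
#' on placebo with concomitant proton pump inhibitors (`PLandPPI`)
#' against placebo only (`PL`).  Two event-counting endpoints are
#' available: the first occurrence per subject, or all repeated
#' occurrences.
#'
#' @param endpoint `"first_occurrence"` (default) or `"all_occurrences"`.
#' @return A [multi_study()] object with six two-row studies
#'   (`s1` ... `s6`), exposure dialect.
#' @examples
#' ppi <- ppi_fixture("all_occurrences")
#' pool_studies(ppi)   # events (141, 640), exposures (310680, 3283324)
#' @export
ppi_fixture <- function(endpoint = c("first_occurrence", "all_occurrences")) {
  endpoint <- match.arg(endpoint)
  d <- .ppi_data[[endpoint]]
  tabs <- lapply(1:6, function(s)
    study_table(counts = c(d$PLandPPI$events[s], d$PL$events[s]),
                exposures = c(d$PLandPPI$exposure[s], d$PL$exposure[s]),
                rows = c("PLandPPI", "PL"), study = paste0("s", s)))
  multi_study(tabs, dialect = "exposure")
}

#' Synthetic multi-study AE grid shaped like a contrast-agent safety review
#'
#' Generates a synthetic dataset with the shape of a one-drug /
#' many-adverse-events literature review: `n_studies` studies, each with
#' a subject count \eqn{P_s} drawn uniformly from 11--257 that serves as
#' the shared exposure of every AE row (one exposure unit per subject),
#' and `n_rows` AE terms whose baseline frequencies are drawn from a
#' skewed distribution so a few terms (fever-like) dominate while many
#' are rare.  Counts are drawn per study as a multinomial over AE terms
#' given a Poisson number of AE reports (about 1.5 per subject, capped
#' so single cells stay within 0--128).  `eta` plants elevated-risk
#' terms: the generated grid then carries true signals on those rows.
#'
#' The generator is deterministic given `seed` and is independent of the
#' analysis code paths it is used to exercise.
#'
#' @param seed Integer seed (required: the grid is a reproducible object).
#' @param n_rows Number of AE terms (default 27).
#' @param n_studies Number of studies (default 13).
#' @param eta Optional relative-risk multipliers, length `n_rows`
#'   (default all 1: no planted signal).
#' @return A [multi_study()] object, exposure dialect (subject counts),
#'   rows `AE01` ... .
#' @examples
#' lip <- lipiodol_like(seed = 1)
#' range(vapply(lip, function(t) sum(t$exposures[1]), numeric(1)))
#' @export
lipiodol_like <- function(seed, n_rows = 27, n_studies = 13, eta = NULL) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (is.null(eta)) eta <- rep(1, n_rows)
  if (length(eta) != n_rows || any(eta <= 0))
    stop("'eta' must be positive, one per row", call. = FALSE)
  .with_seed(seed, {
    rows <- sprintf("AE%02d", seq_len(n_rows))
    # skewed baseline AE frequencies, shared across studies
    base <- sort(stats::rgamma(n_rows, shape = 0.4, rate = 1) + 0.02,
                 decreasing = TRUE)
    tabs <- lapply(seq_len(n_studies), function(s) {
      p_s <- sample(11:257, 1L)
      n_tot <- stats::rpois(1L, 1.5 * p_s)
      prob <- base * eta / sum(base * eta)
      cnt <- stats::rmultinom(1L, n_tot, prob)[, 1L]
      # the printed shape caps single cells at 128 reports
      over <- cnt > 128
      if (any(over)) cnt[over] <- 128
      study_table(counts = cnt, exposures = rep(p_s, n_rows), rows = rows,
                  study = sprintf("s%02d", s))
    })
    multi_study(tabs, dialect = "exposure")
  })
}
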
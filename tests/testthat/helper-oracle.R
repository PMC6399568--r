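# Brute-force likelihood-maximisation oracle for the one-sided two-row
# statistic: log of sup_{p >= q} L(p, q) / sup_{p = q} L(p, q) for
# independent Poisson counts n1 ~ Pois(p P1), n2 ~ Pois(q P2), found by
# iterative grid refinement.  Independent of the closed form under test.
oracle_loglr_2row <- function(n1, P1, n2, P2) {
  ll <- function(p, q)
    stats::dpois(n1, p * P1, log = TRUE) + stats::dpois(n2, q * P2, log = TRUE)
  hi <- max((n1 + 5) / P1, (n2 + 5) / P2, 10 / (P1 + P2))

  # sup over the common-rate null by 1-D refinement
  lo_r <- 0; hi_r <- hi
  for (it in 1:40) {
    r <- seq(lo_r, hi_r, length.out = 41)
    v <- ll(r, r)
    i <- which.max(v)
    lo_r <- r[max(1L, i - 1L)]; hi_r <- r[min(41L, i + 1L)]
  }
  null_max <- max(v)

  # sup over p >= q by 2-D refinement with the constraint clamped
  lo_p <- 0; hi_p <- hi; lo_q <- 0; hi_q <- hi
  for (it in 1:40) {
    ps <- seq(lo_p, hi_p, length.out = 31)
    qs <- seq(lo_q, hi_q, length.out = 31)
    g <- expand.grid(p = ps, q = qs)
    g <- g[g$p >= g$q, ]
    v2 <- ll(g$p, g$q)
    k <- which.max(v2)
    dp <- (hi_p - lo_p) / 30; dq <- (hi_q - lo_q) / 30
    lo_p <- max(0, g$p[k] - dp); hi_p <- g$p[k] + dp
    lo_q <- max(0, g$q[k] - dq); hi_q <- g$q[k] + dq
  }
  alt_max <- max(v2)
  max(0, alt_max - null_max)
}
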
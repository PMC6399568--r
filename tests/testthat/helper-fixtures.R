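# printed per-study two-row data of the embedded PPI example, kept here
# in raw form so tests can rebuild tables without going through the
# fixture constructor under test
ppi_raw <- list(
  occ1 = list(n1 = c(1, 20, 2, 30, 8, 3),
              P1 = c(10225, 181753, 9822, 56845, 19575, 2884),
              n2 = c(14, 77, 11, 167, 144, 17),
              P2 = c(168947, 1534190, 133813, 470833, 713856, 87481)),
  allocc = list(n1 = c(4, 67, 3, 48, 14, 5),
                P1 = c(10383, 196698, 10381, 64764, 24188, 4266),
                n2 = c(30, 179, 13, 228, 169, 21),
                P2 = c(173796, 1575058, 136128, 513109, 789274, 95959)))

two_row_table <- function(n1, P1, n2, P2, study = "s") {
  study_table(c(n1, n2), c(P1, P2), rows = c("A", "B"), study = study)
}
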
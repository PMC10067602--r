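#' Deterministic worked micro-cohort
#'
#' A hand-set 8-gene, 12-sample cohort whose pair indicators can be
#' enumerated by inspection, used in documentation and exact-value tests.
#' Sample S01 carries a tied pair (G1 = G2 = 5.0) to exercise the tie rule
#' (ties fall in the 0 branch of the indicator), and S05 ties G3 = G4.
#' Survival times are in days with a mix of events and censorings.
#'
#' @return A `sim_cohort` object (without planted truth fields).
#' @export
make_worked_fixture <- function() {
  genes <- paste0("G", 1:8)
  samples <- sprintf("S%02d", 1:12)
  expr <- matrix(c(
    # S01   S02   S03   S04   S05   S06   S07   S08   S09   S10   S11   S12
     5.0,  2.1,  8.4,  1.0,  6.6,  3.2,  9.1,  0.5,  4.4,  7.2,  2.8,  5.5,  # G1
     5.0,  4.3,  2.2,  3.3,  1.1,  6.4,  2.0,  1.5,  8.8,  3.9,  6.1,  2.2,  # G2
     1.2,  6.5,  4.1,  7.7,  3.0,  2.1,  5.5,  9.9,  1.0,  2.2,  8.0,  4.8,  # G3
     3.4,  1.8,  6.0,  2.5,  3.0,  7.3,  1.4,  4.2,  6.6,  5.1,  0.9,  7.7,  # G4
     7.8,  3.6,  1.9,  5.8,  9.2,  0.8,  4.7,  2.7,  3.3,  8.5,  4.0,  1.1,  # G5
     2.6,  8.0,  3.7,  4.9,  2.4,  5.9,  7.0,  6.1,  2.0,  1.3,  5.2,  9.4,  # G6
     6.3,  0.7,  7.5,  8.2,  4.5,  1.6,  3.8,  7.9,  5.7,  4.6,  3.1,  0.6,  # G7
     0.9,  5.4,  5.0,  6.7,  7.1,  4.0,  8.6,  3.5,  9.5,  6.8,  7.4,  3.0   # G8
  ), nrow = 8, byrow = TRUE, dimnames = list(genes, samples))
  survival <- data.frame(
    sample = samples,
    time = c(250, 1480, 90, 760, 1100, 430, 1900, 310, 640, 2100, 520, 980),
    event = c(1L, 0L, 1L, 1L, 0L, 1L, 0L, 1L, 1L, 0L, 1L, 0L),
    stringsAsFactors = FALSE
  )
  structure(list(expression = expr,
                 survival = survival,
                 true_subtype = NULL,
                 true_eta = NULL,
                 true_pair_indicators = NULL,
                 signature_genes = genes,
                 realized_censoring = mean(survival$event == 0L),
                 config = NULL),
            class = "sim_cohort")
}
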
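# Small in-code study sets used across tests.

# Two hand-sized studies with no zero cells.
toy_set <- function() {
  df <- data.frame(
    study_id = c("toy1", "toy2"),
    author = c("A", "B"), year = c(2001L, 2002L),
    origin = c("x", "y"), variant = "rs1333049",
    phenotype = c("CAD", "MI"),
    ethnicity = c("East Asian", "Caucasian"),
    control_source = c("HB", "PB"),
    case_hom_effect = c(9, 30), case_het = c(22, 38), case_hom_other = c(19, 23),
    ctrl_hom_effect = c(4, 102), ctrl_het = c(23, 222), ctrl_hom_other = c(23, 112),
    method = "test", stringsAsFactors = FALSE
  )
  structure(df, class = c("study_set", "data.frame"))
}

# k identical copies of one balanced record (all contrasts give OR = 1).
balanced_set <- function(k = 3) {
  df <- data.frame(
    study_id = sprintf("bal%d", seq_len(k)),
    author = "Bal", year = 2000L, origin = "z", variant = "rs1333049",
    phenotype = "CAD", ethnicity = "Caucasian", control_source = "PB",
    case_hom_effect = 25, case_het = 50, case_hom_other = 25,
    ctrl_hom_effect = 25, ctrl_het = 50, ctrl_hom_other = 25,
    method = "test", stringsAsFactors = FALSE
  )
  structure(df, class = c("study_set", "data.frame"))
}

# Effects table from raw log ORs / SEs, bypassing genotype counts.
fake_effects <- function(log_or, se, id = seq_along(log_or)) {
  data.frame(study_id = paste0("s", id), log_or = log_or, se = se,
             or = exp(log_or), stringsAsFactors = FALSE)
}

expect_close <- function(actual, expected, tol) {
  expect_true(abs(actual - expected) <= tol,
              label = sprintf("|%.5f - %.5f| <= %g", actual, expected, tol))
}
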
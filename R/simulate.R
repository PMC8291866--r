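#' Define a simulation scenario for synthetic study sets
#'
#' The generator emulates the structure of the shipped study table:
#' control genotypes are multinomial at Hardy-Weinberg proportions for
#' a chosen effect-allele frequency (optionally distorted by an
#' inbreeding-type coefficient `hwe_fis`), each study draws a true
#' log OR from Normal(log(or_allelic), tau2), and case genotype
#' probabilities follow the multiplicative per-allele odds model: the
#' control probabilities tilted by exp(g * theta) for g = 2, 1, 0
#' copies of the effect allele, renormalized.  Defaults mirror the
#' rs1333049 panel: 33 studies, control effect-allele frequency 0.49,
#' allelic OR 1.13, between-study variance 0.03, per-arm sizes spanning
#' the observed 50-2950 range, and strata drawn with the observed
#' label proportions.
#'
#' @param k Number of studies.
#' @param maf_control Control effect-allele frequency in (0, 1).
#' @param or_allelic True per-allele odds ratio (> 0).
#' @param tau2 Between-study variance of the true log OR (>= 0).
#' @param n_case_range,n_ctrl_range Integer ranges (min, max) for
#'   per-study arm sizes (persons).
#' @param hwe_fis Inbreeding-type disequilibrium coefficient applied to
#'   control genotype proportions (0 = exact Hardy-Weinberg).
#' @param strata_probs Named list of probability vectors for
#'   `ethnicity`, `control_source` and `phenotype` labels.
#' @param variant Variant label stamped on the records.
#' @param seed Integer seed; fully determines the simulated set.
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(k = 33,
                         maf_control = 0.49,
                         or_allelic = 1.13,
                         tau2 = 0.03,
                         n_case_range = c(50, 2600),
                         n_ctrl_range = c(50, 2950),
                         hwe_fis = 0,
                         strata_probs = list(
                           ethnicity = c("West Asian" = 8, "Caucasian" = 10,
                                         "East Asian" = 14, "African" = 1) / 33,
                           control_source = c(HB = 14, PB = 17, "NA" = 2) / 33,
                           phenotype = c(CAD = 22, MI = 11) / 33),
                         variant = "rs1333049",
                         seed = 1L) {
  stopifnot(k >= 1, maf_control > 0, maf_control < 1, or_allelic > 0,
            tau2 >= 0, all(n_case_range >= 1), all(n_ctrl_range >= 1),
            n_case_range[1] <= n_case_range[2],
            n_ctrl_range[1] <= n_ctrl_range[2],
            hwe_fis > -1, hwe_fis < 1)
  for (nm in c("ethnicity", "control_source", "phenotype")) {
    pr <- strata_probs[[nm]]
    if (is.null(pr) || abs(sum(pr) - 1) > 1e-8 || any(pr < 0)) {
      stop("strata_probs$", nm, " must be non-negative and sum to 1")
    }
  }
  structure(list(k = as.integer(k), maf_control = maf_control,
                 or_allelic = or_allelic, tau2 = tau2,
                 n_case_range = as.integer(n_case_range),
                 n_ctrl_range = as.integer(n_ctrl_range),
                 hwe_fis = hwe_fis, strata_probs = strata_probs,
                 variant = variant, seed = as.integer(seed)),
            class = "sim_scenario")
}

# Genotype probability vectors (effect-hom, het, other-hom) for the
# control population and for cases under the multiplicative model.
genotype_probs <- function(scenario, true_log_or) {
  p <- scenario$maf_control
  q <- 1 - p
  f <- scenario$hwe_fis
  ctrl <- c(p^2 + f * p * q, 2 * p * q * (1 - f), q^2 + f * p * q)
  if (any(ctrl < 0) || any(ctrl > 1)) {
    stop("hwe_fis = ", f, " gives degenerate control genotype probabilities")
  }
  case <- ctrl * exp(c(2, 1, 0) * true_log_or)
  list(control = ctrl, case = case / sum(case))
}

#' Simulate one case-control study record
#'
#' Draws a single study with its own sub-stream: the random state is
#' seeded from `scenario$seed` offset by `draw_index`, so study i of a
#' set can be regenerated in isolation.
#'
#' @param scenario A [sim_scenario()].
#' @param draw_index Positive integer index of the study within the
#'   set.
#' @return A one-row `study_set` data frame (standard schema, plus the
#'   true per-study log OR in column `true_log_or`).
#' @export
simulate_study <- function(scenario, draw_index = 1L) {
  stopifnot(inherits(scenario, "sim_scenario"), draw_index >= 1)
  set.seed((scenario$seed + 7919L * as.integer(draw_index)) %% .Machine$integer.max)
  theta <- stats::rnorm(1, log(scenario$or_allelic), sqrt(scenario$tau2))
  pr <- genotype_probs(scenario, theta)
  n_case <- sample(scenario$n_case_range[1]:scenario$n_case_range[2], 1)
  n_ctrl <- sample(scenario$n_ctrl_range[1]:scenario$n_ctrl_range[2], 1)
  g_case <- as.vector(stats::rmultinom(1, n_case, pr$case))
  g_ctrl <- as.vector(stats::rmultinom(1, n_ctrl, pr$control))
  draw_label <- function(pr) sample(names(pr), 1, prob = pr)
  df <- data.frame(
    study_id = sprintf("sim%03d", draw_index),
    author = sprintf("Synthetic%03d", draw_index),
    year = 2020L,
    origin = "simulated",
    variant = scenario$variant,
    phenotype = draw_label(scenario$strata_probs$phenotype),
    ethnicity = draw_label(scenario$strata_probs$ethnicity),
    control_source = draw_label(scenario$strata_probs$control_source),
    case_hom_effect = g_case[1], case_het = g_case[2], case_hom_other = g_case[3],
    ctrl_hom_effect = g_ctrl[1], ctrl_het = g_ctrl[2], ctrl_hom_other = g_ctrl[3],
    method = "simulated",
    true_log_or = theta,
    stringsAsFactors = FALSE
  )
  as_study_set(df)
}

#' Simulate a whole study set
#'
#' k studies from [simulate_study()]; a fixed `scenario$seed` fully
#' determines the output.
#'
#' @param scenario A [sim_scenario()].
#' @return A `study_set` data frame with `scenario$k` rows.
#' @examples
#' s <- simulate_set(sim_scenario(k = 5, seed = 42))
#' pool_auto(s, "allele")
#' @export
simulate_set <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  rows <- lapply(seq_len(scenario$k), function(i) simulate_study(scenario, i))
  as_study_set(do.call(rbind, rows))
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(paste0("sim_scenario: k = %d, control EAF = %.3f, ",
                     "allelic OR = %.3f, tau2 = %.3f, seed = %d\n"),
              x$k, x$maf_control, x$or_allelic, x$tau2, x$seed))
  invisible(x)
}
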
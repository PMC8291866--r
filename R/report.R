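#' Run the full meta-analysis and write report tables
#'
#' End-to-end driver: for each variant in the input it writes per-study
#' effect tables (all five genetic models), a pooled-results CSV in the
#' layout of the source paper's stratified table (overall plus
#' ethnicity, control-source and phenotype strata, all models), the
#' per-study Hardy-Weinberg screen, a pooled allele-frequency summary,
#' Begg test results, leave-one-out tables, funnel and forest data
#' files, and a plain-text log of every fixed/random model-selection
#' decision.
#'
#' @param input Path to a study CSV, or a `study_set` data frame.
#'   Defaults to the packaged CDKN2B-AS1 table.
#' @param out_dir Output directory (created if needed).
#' @param variants Variants to analyse (default: all in the input).
#' @param models Genetic models to run (default all five).
#' @param strat_vars Stratification variables (always includes the
#'   overall pool).
#' @param alpha_het,fixed,exclude_hwe_violations Passed to
#'   [pool_auto()].
#' @param hwe_method Passed to [hwe_test()].
#' @return Invisibly, a list: `pooled` (the stratified results data
#'   frame), `hwe`, `maf`, `begg`, `loo`, and `files` (paths written).
#' @export
run_full_analysis <- function(input = NULL, out_dir = "gcmeta-report",
                              variants = NULL,
                              models = genetic_models(),
                              strat_vars = c("ethnicity", "control_source",
                                             "phenotype"),
                              alpha_het = 0.05, fixed = c("mh", "iv"),
                              hwe_method = c("chisq", "exact"),
                              exclude_hwe_violations = FALSE) {
  fixed <- match.arg(fixed)
  hwe_method <- match.arg(hwe_method)
  models <- match.arg(models, genetic_models(), several.ok = TRUE)
  set <- if (is.null(input)) {
    cdkn2b_studies()
  } else if (is.character(input)) {
    read_studies(input)
  } else {
    input
  }
  if (is.null(variants)) variants <- unique(set$variant)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  log_lines <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    files[[length(files) + 1]] <<- path
    path
  }

  pooled_all <- list(); hwe_all <- list(); maf_all <- list()
  begg_all <- list(); loo_all <- list()
  for (v in variants) {
    sub <- set[set$variant == v, , drop = FALSE]
    hwe_all[[v]] <- hwe_test(sub, method = hwe_method)
    for (arm in c("cases", "controls")) {
      af <- pooled_allele_freq(sub, arm)
      maf_all[[paste(v, arm)]] <- data.frame(
        variant = v, arm = arm, effect_count = af$effect_count,
        total_alleles = af$total_alleles, freq = af$freq)
    }
    for (m in models) {
      eff <- effect_estimates(sub, m)
      emit(eff, sprintf("effects_%s_%s.csv", v, m))
      for (sv in c("none", strat_vars)) {
        res <- stratify(sub, by = sv, model = m, alpha_het = alpha_het,
                        fixed = fixed,
                        exclude_hwe_violations = exclude_hwe_violations)
        res <- cbind(variant = v, res)
        pooled_all[[length(pooled_all) + 1]] <- res
        for (i in seq_len(nrow(res))) {
          log_lines[[length(log_lines) + 1]] <- sprintf(
            "%s %s [%s=%s] k=%d Q=%.3f p_het=%s -> %s",
            v, m, sv, res$stratum[i], res$k[i],
            ifelse(is.na(res$q[i]), NA, res$q[i]),
            format_p(res$p_het[i]), res$model_used[i])
        }
      }
      # forest data: per-study rows plus the pooled row
      overall <- pool_auto(sub, m, alpha_het = alpha_het, fixed = fixed,
                           exclude_hwe_violations = exclude_hwe_violations)
      forest <- rbind(
        data.frame(study_id = eff$study_id, or = eff$or,
                   ci_low = eff$ci_low, ci_high = eff$ci_high,
                   pooled = FALSE),
        data.frame(study_id = "POOLED", or = overall$or,
                   ci_low = overall$ci_low, ci_high = overall$ci_high,
                   pooled = TRUE))
      emit(forest, sprintf("forest_%s_%s.csv", v, m))
      if (m == "allele") {
        bg <- begg_test(eff)
        begg_all[[v]] <- data.frame(variant = v, contrast = m,
                                    kendall_tau = bg$kendall_tau,
                                    score = bg$score, z = bg$z, p = bg$p,
                                    k = bg$k)
        emit(funnel_data(eff), sprintf("funnel_%s_%s.csv", v, m))
        loo <- leave_one_out(sub, m, alpha_het = alpha_het, fixed = fixed)
        loo_all[[v]] <- cbind(variant = v, loo)
        emit(loo_all[[v]], sprintf("leave_one_out_%s_%s.csv", v, m))
      }
    }
  }
  pooled <- do.call(rbind, pooled_all)
  hwe <- do.call(rbind, c(hwe_all, list(make.row.names = FALSE)))
  maf <- do.call(rbind, c(maf_all, list(make.row.names = FALSE)))
  begg <- do.call(rbind, c(begg_all, list(make.row.names = FALSE)))
  loo <- do.call(rbind, c(loo_all, list(make.row.names = FALSE)))
  emit(pooled, "pooled_results.csv")
  emit(format_pooled_table(pooled), "pooled_results_printed.csv")
  emit(hwe, "hwe_per_study.csv")
  emit(maf, "allele_frequency_summary.csv")
  emit(begg, "begg_tests.csv")
  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(unlist(log_lines), log_path)
  files[[length(files) + 1]] <- log_path
  invisible(list(pooled = pooled, hwe = hwe, maf = maf, begg = begg,
                 loo = loo, files = unlist(files)))
}

# Two-decimal OR(CI) and "<0.001"-style p values, mirroring how the
# printed stratified table is formatted.
format_pooled_table <- function(pooled) {
  data.frame(
    variant = pooled$variant, stratum_var = pooled$stratum_var,
    stratum = pooled$stratum, contrast = pooled$contrast,
    k = pooled$k,
    case_control = sprintf("%d/%d", pooled$n_cases, pooled$n_controls),
    or_ci = sprintf("%.2f(%.2f-%.2f)", pooled$or, pooled$ci_low,
                    pooled$ci_high),
    p_het = ifelse(is.na(pooled$p_het), "-", format_p(pooled$p_het)),
    p = format_p(pooled$p),
    model_used = pooled$model_used,
    stringsAsFactors = FALSE
  )
}

#' Compare pooled results against a printed reference table
#'
#' Joins a pooled-results data frame (from [run_full_analysis()] or
#' [stratify()]) to a reference CSV of printed values on
#' variant/stratum/contrast keys and reports per-cell absolute
#' differences with pass/fail at the given tolerances.
#'
#' @param pooled Data frame with columns `variant`, `stratum_var`,
#'   `stratum`, `contrast`, `or`, `ci_low`, `ci_high`.
#' @param reference Path to a reference CSV with the same key columns
#'   plus printed `or`, `ci_low`, `ci_high`.  Defaults to the packaged
#'   transcription of the source paper's stratified-results table.
#' @param tol Absolute tolerance on OR and CI bounds (default 0.02,
#'   i.e. two-decimal printing plus estimator ambiguity).
#' @return A data frame with one row per reference cell: keys, printed
#'   and recomputed values, `diff_or`, `diff_ci_low`, `diff_ci_high`,
#'   `pass`, and `missing_in_result` for unmatched reference rows.
#' @export
compare_to_reference <- function(pooled, reference = NULL, tol = 0.02) {
  if (is.null(reference)) {
    reference <- system.file("extdata", "table2_reference.csv",
                             package = "gcmeta", mustWork = TRUE)
  }
  ref <- utils::read.csv(reference, colClasses = "character",
                         na.strings = character())
  for (col in c("or", "ci_low", "ci_high")) ref[[col]] <- as.numeric(ref[[col]])
  key <- function(d) paste(d$variant, d$stratum_var, d$stratum, d$contrast)
  idx <- match(key(ref), key(pooled))
  out <- data.frame(
    variant = ref$variant, stratum_var = ref$stratum_var,
    stratum = ref$stratum, contrast = ref$contrast,
    or_ref = ref$or, or_est = pooled$or[idx],
    ci_low_ref = ref$ci_low, ci_low_est = pooled$ci_low[idx],
    ci_high_ref = ref$ci_high, ci_high_est = pooled$ci_high[idx],
    stringsAsFactors = FALSE
  )
  out$diff_or <- abs(out$or_est - out$or_ref)
  out$diff_ci_low <- abs(out$ci_low_est - out$ci_low_ref)
  out$diff_ci_high <- abs(out$ci_high_est - out$ci_high_ref)
  out$missing_in_result <- is.na(idx)
  out$pass <- !out$missing_in_result &
    out$diff_or <= tol & out$diff_ci_low <= tol & out$diff_ci_high <= tol
  out
}
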
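#' Cochran's Q heterogeneity test with I2 and DerSimonian-Laird tau2
#'
#' Inverse-variance weights w_i = 1/se_i^2 around the fixed-effect mean
#' give Q = sum w_i (theta_i - theta_hat)^2, referred to chi-square on
#' k - 1 df.  I2 = max(0, (Q - df)/Q) * 100 and the DerSimonian-Laird
#' moment estimator tau2 = max(0, (Q - df) / (sum w - sum w^2 / sum w)).
#'
#' @param log_or Per-study log odds ratios.
#' @param se Their standard errors (same length, all positive).
#' @return A list of class `heterogeneity`: `q`, `df`, `p_q`, `i2`
#'   (percent), `tau2`.
#' @examples
#' cochran_q(c(0, log(2)), c(0.1, 0.1))$q  # ~24.02
#' @export
cochran_q <- function(log_or, se) {
  k <- length(log_or)
  if (k < 2) stop("heterogeneity test needs at least 2 studies")
  stopifnot(length(se) == k, all(se > 0))
  w <- 1 / se^2
  theta_iv <- sum(w * log_or) / sum(w)
  q <- sum(w * (log_or - theta_iv)^2)
  df <- k - 1
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  tau2 <- max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
  structure(list(q = q, df = df,
                 p_q = stats::pchisq(q, df, lower.tail = FALSE),
                 i2 = i2, tau2 = tau2),
            class = "heterogeneity")
}

#' @export
print.heterogeneity <- function(x, ...) {
  cat(sprintf("Q = %.2f (df = %d, p = %.4g), I2 = %.1f%%, tau2 = %.4f\n",
              x$q, x$df, x$p_q, x$i2, x$tau2))
  invisible(x)
}

new_pooled_result <- function(model_used, log_or, se, het, k,
                              n_cases = NA_integer_, n_controls = NA_integer_,
                              contrast = NA_character_, stratum = NA_character_) {
  z <- stats::qnorm(0.975)
  structure(list(
    model_used = model_used,
    or = exp(log_or), ci_low = exp(log_or - z * se),
    ci_high = exp(log_or + z * se),
    log_or = log_or, se = se,
    p_assoc = 2 * stats::pnorm(-abs(log_or / se)),
    het = het, k = k, n_cases = n_cases, n_controls = n_controls,
    contrast = contrast, stratum = stratum
  ), class = "pooled_result")
}

#' Mantel-Haenszel fixed-effects pooled odds ratio
#'
#' OR_MH = sum(a_i d_i / n_i) / sum(b_i c_i / n_i), with the
#' Robins-Breslow-Greenland variance for its log and a 95 percent Wald
#' interval.  Zero cells are handled natively (no correction); tables
#' with an all-zero margin are dropped with a warning.
#'
#' @param tables A data frame with columns `a`, `b`, `c`, `d` as from
#'   [build_table()].
#' @param het Optional `heterogeneity` result to attach.
#' @return A `pooled_result` with `model_used = "fixed_mh"`.
#' @export
pool_fixed_mh <- function(tables, het = NULL) {
  keep <- with(tables, !((a + c) == 0 | (b + d) == 0 | (a + b) == 0 | (c + d) == 0))
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " degenerate table(s) from MH pooling")
    tables <- tables[keep, , drop = FALSE]
  }
  if (nrow(tables) == 0) stop("no estimable tables to pool")
  a <- tables$a; b <- tables$b; c <- tables$c; d <- tables$d
  n <- a + b + c + d
  R <- a * d / n
  S <- b * c / n
  if (sum(S) == 0 || sum(R) == 0) stop("Mantel-Haenszel OR not estimable")
  log_or <- log(sum(R) / sum(S))
  P <- (a + d) / n
  Q <- (b + c) / n
  var_log <- sum(P * R) / (2 * sum(R)^2) +
    sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
    sum(Q * S) / (2 * sum(S)^2)
  new_pooled_result("fixed_mh", log_or, sqrt(var_log), het, nrow(tables))
}

#' Inverse-variance fixed-effects pooling
#'
#' theta_hat = sum(w_i theta_i) / sum(w_i) with w_i = 1/se_i^2 and
#' SE = 1/sqrt(sum w_i).
#'
#' @param effects A data frame with columns `log_or` and `se` as from
#'   [effect_estimates()].
#' @param het Optional `heterogeneity` result to attach.
#' @return A `pooled_result` with `model_used = "fixed_iv"`.
#' @export
pool_fixed_iv <- function(effects, het = NULL) {
  if (nrow(effects) == 0) stop("no effects to pool")
  w <- 1 / effects$se^2
  new_pooled_result("fixed_iv", sum(w * effects$log_or) / sum(w),
                    sqrt(1 / sum(w)), het, nrow(effects))
}

#' DerSimonian-Laird random-effects pooling
#'
#' Re-weights with w*_i = 1/(se_i^2 + tau2), where tau2 is the
#' DerSimonian-Laird moment estimate from [cochran_q()].  With a single
#' study (or tau2 = 0) this collapses to the inverse-variance fixed
#' effect.
#'
#' @inheritParams pool_fixed_iv
#' @param het Optional precomputed `heterogeneity`; computed from the
#'   effects when omitted (k >= 2).
#' @return A `pooled_result` with `model_used = "random_dl"`.
#' @export
pool_random_dl <- function(effects, het = NULL) {
  if (nrow(effects) == 0) stop("no effects to pool")
  if (is.null(het)) {
    het <- if (nrow(effects) >= 2) cochran_q(effects$log_or, effects$se) else NULL
  }
  tau2 <- if (is.null(het)) 0 else het$tau2
  w <- 1 / (effects$se^2 + tau2)
  new_pooled_result("random_dl", sum(w * effects$log_or) / sum(w),
                    sqrt(1 / sum(w)), het, nrow(effects))
}

#' Heterogeneity-driven pooled analysis of a study set
#'
#' The selection rule of the source analysis: compute per-study effects
#' and Cochran's Q; when the Q-test P value is below `alpha_het` the
#' DerSimonian-Laird random-effects model is used, otherwise a fixed
#' -effects model (Mantel-Haenszel by default, inverse-variance
#' selectable).
#'
#' @param set A `study_set` with at least 2 records.
#' @param model One of [genetic_models()].
#' @param alpha_het Heterogeneity significance threshold (default
#'   0.05).
#' @param fixed Fixed-effects estimator: `"mh"` (default) or `"iv"`.
#' @param exclude_hwe_violations If `TRUE`, records whose control arm
#'   fails the Hardy-Weinberg chi-square test at `hwe_alpha` are
#'   dropped before pooling.  Off by default: the source analysis
#'   retains them.
#' @param hwe_alpha Threshold for the exclusion flag (default 0.05).
#' @return A `pooled_result` carrying the heterogeneity result, the
#'   contrast name, and case/control person totals.
#' @examples
#' pool_auto(cdkn2b_studies("rs1333049"), "allele")
#' @export
pool_auto <- function(set, model = genetic_models(), alpha_het = 0.05,
                      fixed = c("mh", "iv"),
                      exclude_hwe_violations = FALSE, hwe_alpha = 0.05) {
  model <- match.arg(model)
  fixed <- match.arg(fixed)
  if (exclude_hwe_violations) {
    hw <- hwe_test(set, method = "chisq", arm = "controls")
    set <- set[hw$hwe_p >= hwe_alpha, , drop = FALSE]
  }
  if (nrow(set) < 2) stop("pool_auto needs at least 2 studies")
  eff <- effect_estimates(set, model)
  het <- cochran_q(eff$log_or, eff$se)
  res <- if (het$p_q < alpha_het) {
    pool_random_dl(eff, het)
  } else if (fixed == "mh") {
    pool_fixed_mh(eff[c("study_id", "a", "b", "c", "d")], het)
  } else {
    pool_fixed_iv(eff, het)
  }
  tot <- study_totals(set)
  res$n_cases <- tot$n_cases
  res$n_controls <- tot$n_controls
  res$contrast <- model
  res
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("pooled OR = %.3f (95%% CI %.3f-%.3f), p = %s [%s, k = %d]\n",
              x$or, x$ci_low, x$ci_high, format_p(x$p_assoc), x$model_used, x$k))
  if (!is.null(x$het)) print(x$het)
  invisible(x)
}

#' Flatten pooled results to a data frame row
#'
#' @param x A `pooled_result`.
#' @param row.names,optional,... Standard [as.data.frame()] arguments
#'   (ignored).
#' @return One-row data frame with estimate, CI, p, heterogeneity and
#'   bookkeeping columns.
#' @export
as.data.frame.pooled_result <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    contrast = x$contrast, stratum = x$stratum, k = x$k,
    n_cases = x$n_cases, n_controls = x$n_controls,
    model_used = x$model_used,
    or = x$or, ci_low = x$ci_low, ci_high = x$ci_high,
    p = x$p_assoc,
    q = if (is.null(x$het)) NA_real_ else x$het$q,
    p_het = if (is.null(x$het)) NA_real_ else x$het$p_q,
    i2 = if (is.null(x$het)) NA_real_ else x$het$i2,
    tau2 = if (is.null(x$het)) NA_real_ else x$het$tau2,
    stringsAsFactors = FALSE
  )
}

#' Stratified pooled analysis
#'
#' Partitions the set by one stratification variable and pools each
#' stratum with [pool_auto()].  Single-study strata are reported with
#' the study's own estimate and `model_used = "single_study"` rather
#' than dropped (the African stratum of the shipped table has k = 1).
#'
#' @param set A `study_set`.
#' @param by `"ethnicity"`, `"control_source"`, `"phenotype"`, or
#'   `"none"` for the unstratified pool.
#' @param model One of [genetic_models()].
#' @param ... Passed to [pool_auto()].
#' @return A data frame with one row per stratum (columns as
#'   [as.data.frame.pooled_result()]); zero rows for an empty set.
#' @export
stratify <- function(set, by = c("none", "ethnicity", "control_source", "phenotype"),
                     model = genetic_models(), ...) {
  by <- match.arg(by)
  model <- match.arg(model)
  if (nrow(set) == 0) {
    return(as.data.frame(list())[0, ])
  }
  groups <- if (by == "none") list(Total = set) else split(set, set[[by]])
  rows <- lapply(names(groups), function(lab) {
    g <- groups[[lab]]
    res <- if (nrow(g) >= 2) {
      pool_auto(g, model, ...)
    } else {
      eff <- effect_estimates(g, model)
      r <- new_pooled_result("single_study", eff$log_or, eff$se, NULL, 1L)
      tot <- study_totals(g)
      r$n_cases <- tot$n_cases; r$n_controls <- tot$n_controls
      r$contrast <- model
      r
    }
    res$stratum <- lab
    as.data.frame(res)
  })
  out <- do.call(rbind, rows)
  out <- cbind(stratum_var = by, out)
  rownames(out) <- NULL
  out
}

#' Leave-one-out sensitivity analysis
#'
#' Re-pools the set k times, omitting each study in turn, with
#' [pool_auto()].  The result's `significance_stable` attribute is TRUE
#' when every reduced pool agrees with the full pool on whether the 95
#' percent CI excludes OR = 1.
#'
#' @inheritParams pool_auto
#' @return A data frame with one row per omitted study (`omitted` plus
#'   the pooled-result columns) and attributes `full` (the full-set
#'   `pooled_result`) and `significance_stable`.
#' @export
leave_one_out <- function(set, model = genetic_models(), ...) {
  model <- match.arg(model)
  if (nrow(set) < 3) stop("leave-one-out needs at least 3 studies")
  full <- pool_auto(set, model, ...)
  rows <- lapply(seq_len(nrow(set)), function(i) {
    res <- pool_auto(set[-i, , drop = FALSE], model, ...)
    cbind(omitted = set$study_id[i], as.data.frame(res))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  excl1 <- function(lo, hi) lo > 1 | hi < 1
  attr(out, "full") <- full
  attr(out, "significance_stable") <-
    all(excl1(out$ci_low, out$ci_high) == excl1(full$ci_low, full$ci_high))
  out
}

#' Format a P value the way meta-analysis tables print it
#'
#' @param p Numeric vector of probabilities.
#' @param digits Decimals shown (default 3).
#' @return Character vector: `"<0.001"` below the printable threshold,
#'   otherwise fixed-decimal text.
#' @export
format_p <- function(p, digits = 3) {
  lo <- 10^(-digits)
  ifelse(p < lo, paste0("<", format(lo, scientific = FALSE)),
         formatC(p, digits = digits, format = "f"))
}
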
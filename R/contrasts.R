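#' The five genetic-model contrasts
#'
#' Each model reduces the two 3-category genotype margins to a 2x2
#' exposure table.  Writing M for the effect allele and W for the other
#' allele: allelic = M vs W allele counts (2n alleles per arm);
#' heterozygous = MW vs WW persons; homozygous = MM vs WW persons;
#' dominant = MM+MW vs WW persons; recessive = MM vs MW+WW persons.
#'
#' @return Character vector of the five model names.
#' @export
genetic_models <- function() {
  c("allele", "heterozygous", "homozygous", "dominant", "recessive")
}

#' Build the 2x2 exposure tables for a genetic model
#'
#' @param set A `study_set` data frame (one or more records).
#' @param model One of [genetic_models()].
#' @return A data frame with one row per study: `study_id`, `a`
#'   (exposed cases), `b` (unexposed cases), `c` (exposed controls),
#'   `d` (unexposed controls), and a `unit` attribute (`"alleles"` for
#'   the allelic model, `"persons"` otherwise).  Heterozygous and
#'   homozygous tables exclude the third genotype class, so their
#'   totals are below the person total.
#' @examples
#' s <- cdkn2b_studies("rs1333049")
#' head(build_table(s, "dominant"))
#' @export
build_table <- function(set, model = genetic_models()) {
  model <- match.arg(model)
  cs <- arm_counts(set, "cases")
  ct <- arm_counts(set, "controls")
  tab <- switch(model,
    allele = data.frame(
      a = 2 * cs$hom_effect + cs$het, b = 2 * cs$hom_other + cs$het,
      c = 2 * ct$hom_effect + ct$het, d = 2 * ct$hom_other + ct$het),
    heterozygous = data.frame(
      a = cs$het, b = cs$hom_other, c = ct$het, d = ct$hom_other),
    homozygous = data.frame(
      a = cs$hom_effect, b = cs$hom_other,
      c = ct$hom_effect, d = ct$hom_other),
    dominant = data.frame(
      a = cs$hom_effect + cs$het, b = cs$hom_other,
      c = ct$hom_effect + ct$het, d = ct$hom_other),
    recessive = data.frame(
      a = cs$hom_effect, b = cs$het + cs$hom_other,
      c = ct$hom_effect, d = ct$het + ct$hom_other))
  tab <- cbind(study_id = set$study_id, tab)
  attr(tab, "unit") <- if (model == "allele") "alleles" else "persons"
  attr(tab, "model") <- model
  tab
}

#' Odds ratio of a single 2x2 table
#'
#' Cross-product odds ratio with the Woolf standard error
#' sqrt(1/a + 1/b + 1/c + 1/d) and 95 percent Wald interval on the log
#' scale.  If any cell is zero, the Haldane-Anscombe correction adds
#' 0.5 to all four cells (flagged in `corrected`).  A table with an
#' all-zero margin is non-estimable and raises an error.
#'
#' @param a,b,c,d Exposed cases, unexposed cases, exposed controls,
#'   unexposed controls.
#' @param correction Value added to every cell when a zero cell is
#'   present (default 0.5; set 0 to disable).
#' @return A list of class `effect_estimate`: `log_or`, `se`, `or`,
#'   `ci_low`, `ci_high`, `corrected`.
#' @examples
#' odds_ratio(40, 60, 31, 69)$or  # ~1.484
#' @export
odds_ratio <- function(a, b, c, d, correction = 0.5) {
  cells <- c(a, b, c, d)
  stopifnot(length(cells) == 4, all(cells >= 0))
  if ((a + c) == 0 || (b + d) == 0 || (a + b) == 0 || (c + d) == 0) {
    stop("non-estimable 2x2 table: an entire margin is zero")
  }
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + correction
  log_or <- log(cells[1] * cells[4] / (cells[2] * cells[3]))
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(0.975)
  structure(list(log_or = log_or, se = se, or = exp(log_or),
                 ci_low = exp(log_or - z * se),
                 ci_high = exp(log_or + z * se),
                 corrected = corrected),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("OR = %.3f (95%% CI %.3f-%.3f)%s\n", x$or, x$ci_low, x$ci_high,
              if (x$corrected) " [0.5 continuity correction]" else ""))
  invisible(x)
}

#' Per-study effect estimates under a genetic model
#'
#' Builds the model's 2x2 table for every record and computes per-study
#' odds ratios.  Records whose table has an all-zero margin cannot
#' contribute to the contrast; they are dropped with a warning.
#'
#' @inheritParams build_table
#' @param correction Passed to [odds_ratio()].
#' @return A data frame: `study_id`, `a`, `b`, `c`, `d`, `log_or`,
#'   `se`, `or`, `ci_low`, `ci_high`, `corrected`, with the `model`
#'   and `unit` attributes of the table.
#' @export
effect_estimates <- function(set, model = genetic_models(), correction = 0.5) {
  model <- match.arg(model)
  tab <- build_table(set, model)
  degenerate <- with(tab, (a + c) == 0 | (b + d) == 0 | (a + b) == 0 | (c + d) == 0)
  if (any(degenerate)) {
    warning("dropping ", sum(degenerate), " record(s) with an all-zero ",
            "margin under the ", model, " model: ",
            paste(tab$study_id[degenerate], collapse = ", "))
    tab <- tab[!degenerate, , drop = FALSE]
  }
  est <- lapply(seq_len(nrow(tab)), function(i) {
    odds_ratio(tab$a[i], tab$b[i], tab$c[i], tab$d[i], correction)
  })
  out <- cbind(
    tab,
    log_or = vapply(est, `[[`, numeric(1), "log_or"),
    se = vapply(est, `[[`, numeric(1), "se"),
    or = vapply(est, `[[`, numeric(1), "or"),
    ci_low = vapply(est, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(est, `[[`, numeric(1), "ci_high"),
    corrected = vapply(est, `[[`, logical(1), "corrected")
  )
  attr(out, "model") <- model
  attr(out, "unit") <- attr(tab, "unit")
  rownames(out) <- NULL
  out
}
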
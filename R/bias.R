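#' Begg-Mazumdar rank-correlation test for publication bias
#'
#' Tests for correlation between standardized effect sizes and their
#' variances.  With v_i = se_i^2 and the inverse-variance pooled mean
#' theta_hat, the deviations are variance-stabilized as
#' t_i = (theta_i - theta_hat) / sqrt(v_i - 1/sum(1/v_j)), and the
#' Kendall score S (concordant minus discordant pairs, ties scoring 0)
#' between t_i and v_i is referred to the normal approximation with
#' variance k(k-1)(2k+5)/18 and continuity correction |S| - 1.
#'
#' @param effects A data frame with columns `log_or` and `se` as from
#'   [effect_estimates()].
#' @return A list of class `begg_result`: `kendall_tau`, `score`, `z`,
#'   `p` (two-sided), `k`.
#' @export
begg_test <- function(effects) {
  k <- nrow(effects)
  if (k < 3) stop("Begg test needs at least 3 studies")
  v <- effects$se^2
  w <- 1 / v
  theta_hat <- sum(w * effects$log_or) / sum(w)
  t_i <- (effects$log_or - theta_hat) / sqrt(v - 1 / sum(w))
  pairs <- utils::combn(k, 2)
  score <- sum(sign(t_i[pairs[2, ]] - t_i[pairs[1, ]]) *
               sign(v[pairs[2, ]] - v[pairs[1, ]]))
  var_s <- k * (k - 1) * (2 * k + 5) / 18
  z <- max(abs(score) - 1, 0) / sqrt(var_s)
  structure(list(kendall_tau = score / (k * (k - 1) / 2),
                 score = score, z = z,
                 p = 2 * stats::pnorm(-z), k = k),
            class = "begg_result")
}

#' @export
print.begg_result <- function(x, ...) {
  cat(sprintf("Begg rank correlation: tau = %.3f, z = %.3f, p = %.3f (k = %d)\n",
              x$kendall_tau, x$z, x$p, x$k))
  invisible(x)
}

#' Funnel-plot coordinates
#'
#' One point per study (x = log OR, y = its SE; funnel plots draw the
#' SE axis inverted).  The attributes carry the inverse-variance pooled
#' center line and the 95 percent pseudo-confidence guide limits
#' theta_hat +/- 1.96 * se evaluated over the observed SE range, ready
#' for plotting.
#'
#' @inheritParams begg_test
#' @return A data frame `study_id`, `log_or`, `se` with attributes
#'   `center` (pooled log OR) and `guides` (data frame `se`,
#'   `lower`, `upper`).
#' @export
funnel_data <- function(effects) {
  if (nrow(effects) == 0) {
    out <- data.frame(study_id = character(), log_or = numeric(),
                      se = numeric(), stringsAsFactors = FALSE)
    attr(out, "center") <- NA_real_
    attr(out, "guides") <- data.frame(se = numeric(), lower = numeric(),
                                      upper = numeric())
    return(out)
  }
  w <- 1 / effects$se^2
  center <- sum(w * effects$log_or) / sum(w)
  se_grid <- seq(0, max(effects$se), length.out = 50)
  z <- stats::qnorm(0.975)
  out <- data.frame(study_id = effects$study_id, log_or = effects$log_or,
                    se = effects$se, stringsAsFactors = FALSE)
  attr(out, "center") <- center
  attr(out, "guides") <- data.frame(se = se_grid,
                                    lower = center - z * se_grid,
                                    upper = center + z * se_grid)
  out
}
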
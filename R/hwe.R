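#' Hardy-Weinberg chi-square goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of genotype counts against the
#' Hardy-Weinberg proportions implied by the sample allele frequency
#' p-hat = (2*hom_effect + het) / 2n, i.e. expected counts
#' (p^2 n, 2pq n, q^2 n).  No continuity correction is applied.  A
#' monomorphic sample (p-hat 0 or 1) is returned with `chi2 = 0`,
#' `p = 1` and `monomorphic = TRUE` rather than as an error.
#'
#' @param hom_effect,het,hom_other Genotype counts (persons).
#' @return A list of class `hwe_result`: `chi2`, `df` (1), `p`,
#'   `expected` (length-3 vector), `method`, `monomorphic`.
#' @examples
#' hwe_chisq(4, 23, 23)$p   # ~0.595
#' @export
hwe_chisq <- function(hom_effect, het, hom_other) {
  obs <- c(hom_effect, het, hom_other)
  stopifnot(length(obs) == 3, all(obs >= 0))
  n <- sum(obs)
  if (n == 0) stop("empty genotype sample")
  p <- (2 * obs[1] + obs[2]) / (2 * n)
  if (p == 0 || p == 1) {
    return(structure(list(chi2 = 0, df = 1L, p = 1,
                          expected = obs, method = "chisq",
                          monomorphic = TRUE),
                     class = "hwe_result"))
  }
  expected <- c(p^2, 2 * p * (1 - p), (1 - p)^2) * n
  chi2 <- sum((obs - expected)^2 / expected)
  structure(list(chi2 = chi2, df = 1L,
                 p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 expected = expected, method = "chisq",
                 monomorphic = FALSE),
            class = "hwe_result")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: given the observed allele counts, the
#' heterozygote count is enumerated over all configurations of the same
#' parity, each assigned its conditional probability
#' \deqn{P(h) = \frac{n!\, n_A!\, n_a!\, 2^h}{(2n)!\, n_{AA}!\, h!\, n_{aa}!},}
#' and the P value is the sum of probabilities no larger than that of
#' the observed configuration.
#'
#' @inheritParams hwe_chisq
#' @return A list of class `hwe_result` with `p`, `method = "exact"`,
#'   and `prob_observed`, the conditional probability of the observed
#'   heterozygote count.
#' @examples
#' hwe_exact(25, 50, 25)$p  # modal configuration, p = 1
#' @export
hwe_exact <- function(hom_effect, het, hom_other) {
  obs <- c(hom_effect, het, hom_other)
  stopifnot(length(obs) == 3, all(obs >= 0))
  n <- sum(obs)
  if (n == 0) stop("empty genotype sample")
  na <- 2 * obs[1] + obs[2]
  nb <- 2 * n - na
  if (na == 0 || nb == 0) {
    return(structure(list(chi2 = NA_real_, df = 1L, p = 1,
                          expected = obs, method = "exact",
                          prob_observed = 1, monomorphic = TRUE),
                     class = "hwe_result"))
  }
  hs <- seq(na %% 2, min(na, nb), by = 2)
  log_prob <- lgamma(n + 1) - lgamma((na - hs) / 2 + 1) - lgamma(hs + 1) -
    lgamma((nb - hs) / 2 + 1) + hs * log(2) +
    lgamma(na + 1) + lgamma(nb + 1) - lgamma(2 * n + 1)
  prob <- exp(log_prob - max(log_prob))
  prob <- prob / sum(prob)
  p_obs <- prob[match(obs[2], hs)]
  p <- sum(prob[prob <= p_obs * (1 + 1e-7)])
  structure(list(chi2 = NA_real_, df = 1L, p = min(p, 1),
                 expected = obs, method = "exact",
                 prob_observed = p_obs, monomorphic = FALSE),
            class = "hwe_result")
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("HWE %s test: p = %.4g%s\n", x$method, x$p,
              if (isTRUE(x$monomorphic)) " (monomorphic)" else ""))
  invisible(x)
}

#' Per-study Hardy-Weinberg screen of a study set
#'
#' Applies [hwe_chisq()] or [hwe_exact()] to one arm (by convention the
#' controls, as a genotyping-quality check) of every record.
#'
#' @param set A `study_set` data frame.
#' @param method `"chisq"` (default) or `"exact"`.
#' @param arm `"controls"` (default) or `"cases"`.
#' @return A data frame with `study_id`, `variant`, `hwe_p`,
#'   `hwe_method` and, for the chi-square method, `hwe_chi2`.
#' @export
hwe_test <- function(set, method = c("chisq", "exact"),
                     arm = c("controls", "cases")) {
  method <- match.arg(method)
  arm <- match.arg(arm)
  g <- arm_counts(set, arm)
  fun <- if (method == "chisq") hwe_chisq else hwe_exact
  res <- lapply(seq_len(nrow(set)),
                function(i) fun(g$hom_effect[i], g$het[i], g$hom_other[i]))
  data.frame(
    study_id = set$study_id,
    variant = set$variant,
    hwe_p = vapply(res, `[[`, numeric(1), "p"),
    hwe_chi2 = vapply(res, `[[`, numeric(1), "chi2"),
    hwe_method = method,
    stringsAsFactors = FALSE
  )
}

arm_counts <- function(set, arm = c("cases", "controls")) {
  arm <- match.arg(arm)
  pre <- if (arm == "cases") "case_" else "ctrl_"
  list(hom_effect = set[[paste0(pre, "hom_effect")]],
       het = set[[paste0(pre, "het")]],
       hom_other = set[[paste0(pre, "hom_other")]])
}

#' Pooled effect-allele frequency
#'
#' Effect-allele frequency in one arm, pooled across studies from summed
#' allele counts (2 * hom_effect + het over 2n alleles), not as a mean
#' of per-study frequencies.
#'
#' @param set A non-empty single-variant `study_set`.
#' @param arm `"cases"` or `"controls"`.
#' @return A list: `effect_count`, `total_alleles`, `freq`.
#' @examples
#' pooled_allele_freq(cdkn2b_studies("rs1333049"), "cases")$freq  # ~0.521
#' @export
pooled_allele_freq <- function(set, arm = c("cases", "controls")) {
  arm <- match.arg(arm)
  if (nrow(set) == 0) stop("empty study set")
  if (length(unique(set$variant)) > 1) {
    stop("pooled_allele_freq needs a single-variant set; filter first")
  }
  g <- arm_counts(set, arm)
  eff <- sum(2 * g$hom_effect + g$het)
  tot <- 2 * sum(g$hom_effect + g$het + g$hom_other)
  list(effect_count = eff, total_alleles = tot, freq = eff / tot)
}
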
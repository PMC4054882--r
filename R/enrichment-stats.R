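#' Observed-versus-expected chi-square enrichment test
#'
#' The single-term goodness-of-fit form used to compare SNP counts between
#' territories: the count at locus orthologs is the observed value `O`,
#' the count at control orthologs is the expected value `E`, and
#' `chi_square = (O - E)^2 / E` is referred to the upper tail of the
#' chi-square distribution with one degree of freedom. No continuity
#' correction is applied.
#'
#' Note this form is calibrated when `E` is a model expectation; when `E`
#' is itself a sampled count of the same size as `O`, the statistic is
#' anticonservative (see the methods vignette).
#'
#' @param observed Non-negative count at locus-ortholog territory.
#' @param expected Positive count (or expectation) at control territory.
#' @return Object of class `oe_chisq`: list with `observed`, `expected`,
#'   `statistic`, `df` (always 1) and `p_value`.
#' @examples
#' chisq_obs_exp(66, 51)
#' @export
chisq_obs_exp <- function(observed, expected) {
  if (length(observed) != 1 || length(expected) != 1) {
    abort("`observed` and `expected` must be scalars.")
  }
  if (is.na(expected) || expected <= 0) {
    abort("`expected` must be > 0; the statistic is undefined at 0.")
  }
  if (is.na(observed) || observed < 0) abort("`observed` must be >= 0.")
  statistic <- (observed - expected)^2 / expected
  structure(
    list(
      observed = observed, expected = expected,
      statistic = statistic, df = 1L,
      p_value = pchisq(statistic, df = 1, lower.tail = FALSE)
    ),
    class = "oe_chisq"
  )
}

#' @export
print.oe_chisq <- function(x, ...) {
  cat(sprintf("O = %g vs E = %g: chi-square(1) = %.3f, p = %.4g\n",
              x$observed, x$expected, x$statistic, x$p_value))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.oe_chisq <- function(x, ...) {
  tibble(observed = x$observed, expected = x$expected,
         statistic = x$statistic, df = x$df, p_value = x$p_value)
}

#' @exportS3Method generics::glance
glance.oe_chisq <- function(x, ...) tidy(x)

#' Logistic regression on the 2x2 association-class by territory table
#'
#' Tests whether clearing the genome-wide-significance threshold predicts
#' landing at a locus ortholog rather than a control region: the territory
#' (loci = 1, control = 0) is regressed on the association class
#' (associated vs potentially associated) by binomial IRLS (convergence
#' tolerance 1e-14 on the relative deviance change). The slope is the log-odds difference for the
#' `associated` class relative to `potential`; for a 2x2 table it equals
#' `log(ad/bc)` with `a` = loci/associated, `b` = control/associated,
#' `c` = loci/potential, `d` = control/potential. The two-sided Wald
#' p-value is primary; the likelihood-ratio p-value is reported alongside.
#'
#' @param loci_associated,control_associated,loci_potential,control_potential
#'   The four cell counts; all must be positive (a zero cell leaves the
#'   log-odds undefined and is out of contract). Alternatively pass a
#'   one-row data frame with these columns as the first argument.
#' @return Object of class `assoc_logistic`: list with `slope`, `slope_se`,
#'   `wald_z`, `p_value`, `lrt_p_value`, `table` and the underlying `fit`.
#' @examples
#' logistic_2x2(19, 7, 160, 44)
#' @export
logistic_2x2 <- function(loci_associated, control_associated = NULL,
                         loci_potential = NULL, control_potential = NULL) {
  if (is.data.frame(loci_associated)) {
    t <- loci_associated
    control_associated <- t$control_associated
    loci_potential <- t$loci_potential
    control_potential <- t$control_potential
    loci_associated <- t$loci_associated
  }
  cells <- c(
    loci_associated = loci_associated, control_associated = control_associated,
    loci_potential = loci_potential, control_potential = control_potential
  )
  if (any(is.na(cells)) || any(cells < 0)) abort("Cell counts must be non-negative.")
  if (any(cells == 0)) {
    abort(paste(
      "Zero cell in the 2x2 table; the log-odds are undefined and",
      "continuity handling is outside this function's contract."
    ))
  }
  dat <- tibble(
    assoc_class = factor(rep(c("associated", "potential"), each = 2),
                         levels = c("potential", "associated")),
    at_locus = rep(c(1, 0), times = 2),
    w = as.numeric(cells)
  )
  fit <- glm(at_locus ~ assoc_class, family = binomial(), data = dat,
             weights = dat$w, control = list(epsilon = 1e-14, maxit = 200))
  est <- summary(fit)$coefficients["assoc_classassociated", ]
  null_fit <- glm(at_locus ~ 1, family = binomial(), data = dat,
                  weights = dat$w, control = list(epsilon = 1e-14, maxit = 200))
  lrt_stat <- null_fit$deviance - fit$deviance
  structure(
    list(
      slope = unname(est["Estimate"]),
      slope_se = unname(est["Std. Error"]),
      wald_z = unname(est["z value"]),
      p_value = unname(est["Pr(>|z|)"]),
      lrt_p_value = pchisq(lrt_stat, df = 1, lower.tail = FALSE),
      table = as.list(cells),
      fit = fit
    ),
    class = "assoc_logistic"
  )
}

#' @export
print.assoc_logistic <- function(x, ...) {
  cat(sprintf(
    "logistic 2x2: slope = %.4f (SE %.4f), Wald z = %.3f, p = %.3f (LRT p = %.3f)\n",
    x$slope, x$slope_se, x$wald_z, x$p_value, x$lrt_p_value
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.assoc_logistic <- function(x, ...) {
  tibble(
    term = "assoc_class_associated", estimate = x$slope,
    std_error = x$slope_se, statistic = x$wald_z, p_value = x$p_value
  )
}

#' @exportS3Method generics::glance
glance.assoc_logistic <- function(x, ...) {
  tibble(slope = x$slope, slope_se = x$slope_se, wald_z = x$wald_z,
         p_value = x$p_value, lrt_p_value = x$lrt_p_value)
}

#' SNP-count ratio normalised by territory size
#'
#' The loci territory is much larger than the control territory, so the
#' raw count ratio `O/E` is normalised by the base ratio: `snp_ratio =
#' O/E`, `base_ratio = loci_unique_bases / control_total_bases`, and
#' `normalized_ratio = snp_ratio / base_ratio` — the per-base enrichment
#' of SNPs at locus orthologs relative to controls.
#'
#' @param observed,expected SNP counts at loci/control territory;
#'   `expected` must be > 0.
#' @param loci_unique_bases Unique bases of the locus territory.
#' @param control_total_bases Total bases of the control territory (> 0).
#' @return One-row tibble with `snp_ratio`, `base_ratio`,
#'   `normalized_ratio`, at full precision (round for display: one decimal
#'   for the count/base ratios, two for the normalised ratio).
#' @examples
#' ratio_summary(179, 51, 905100793, 312517940)
#' @export
ratio_summary <- function(observed, expected, loci_unique_bases,
                          control_total_bases) {
  if (expected <= 0 || control_total_bases <= 0) {
    abort("`expected` and `control_total_bases` must be > 0.")
  }
  snp_ratio <- observed / expected
  base_ratio <- loci_unique_bases / control_total_bases
  tibble(
    snp_ratio = snp_ratio,
    base_ratio = base_ratio,
    normalized_ratio = snp_ratio / base_ratio
  )
}
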
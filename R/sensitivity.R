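#' Cochran's Q heterogeneity statistic
#'
#' The inverse-variance weighted sum of squared deviations of the per-SNP
#' Wald ratios from a pooled estimate, with first-order weights
#' `beta_exp^2 / se_out^2` (matching the IVW weighting). Under
#' homogeneity Q follows a chi-square distribution with k-1 degrees of
#' freedom; large Q signals variability in per-SNP causal estimates and
#' hence potential assumption violations.
#'
#' @param instruments A harmonised instrument table with at least two
#'   rows.
#' @param pooled_estimate Pooled causal estimate; defaults to the IVW
#'   estimate of `instruments`.
#' @return A one-row tibble with `q`, `q_df` and `q_pval`.
#' @export
mr_cochran_q <- function(instruments, pooled_estimate = NULL) {
  dat <- as_tibble(instruments)
  k <- nrow(dat)
  if (k < 2) stop("Cochran's Q requires at least 2 instruments",
                  call. = FALSE)
  if (is.null(pooled_estimate)) {
    pooled_estimate <- mr_ivw(dat, se_policy = "fe")$estimate
  }
  re <- ratio_estimates(dat)
  q <- sum(re$w * (re$theta - pooled_estimate)^2)
  tibble(q = q, q_df = k - 1L,
         q_pval = stats::pchisq(q, k - 1, lower.tail = FALSE))
}

#' Egger intercept test for directional pleiotropy
#'
#' Extracts the intercept, its standard error and its two-sided p-value
#' (t distribution with k-2 degrees of freedom) from an MR-Egger fit. An
#' intercept close to zero indicates no unbalanced directional
#' pleiotropy.
#'
#' @param egger_result A one-row `mr_result` with `method == "egger"`
#'   (from [mr_egger()]).
#' @return A one-row tibble with `intercept`, `se` and `pval`.
#' @export
egger_intercept_test <- function(egger_result) {
  if (!identical(egger_result$method, "egger")) {
    stop("egger_intercept_test requires an MR-Egger result", call. = FALSE)
  }
  tibble(intercept = egger_result$intercept,
         se = egger_result$intercept_se,
         pval = egger_result$intercept_pval)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the pooled causal effect after sequentially excluding one
#' instrument at a time, to check that no single variant drives the
#' result. Uses IVW (single remaining instruments reduce to the Wald
#' ratio). Rows are ordered by the excluded variant's genomic position.
#'
#' @param instruments A harmonised instrument table with at least two
#'   rows.
#' @param se_policy IVW standard-error policy.
#' @param level Confidence level.
#' @return A tibble with one row per excluded variant (`excluded_snp`,
#'   estimate, se, CI, p) plus a final `"(none)"` row holding the
#'   full-sample estimate.
#' @export
mr_leave_one_out <- function(instruments, se_policy = "mre", level = 0.95) {
  dat <- as_tibble(instruments)
  k <- nrow(dat)
  if (k < 2) stop("leave-one-out requires at least 2 instruments",
                  call. = FALSE)
  dat <- dat[order(dat$chrom, dat$pos), , drop = FALSE]
  rows <- purrr::map(seq_len(k), function(i) {
    fit <- mr_ivw(dat[-i, , drop = FALSE], se_policy, level)
    dplyr::mutate(
      tidy(fit)[, c("estimate", "se", "ci_low", "ci_high", "pval", "n_snp")],
      excluded_snp = dat$snp[i], .before = 1
    )
  })
  full <- mr_ivw(dat, se_policy, level)
  dplyr::bind_rows(
    rows,
    dplyr::mutate(
      tidy(full)[, c("estimate", "se", "ci_low", "ci_high", "pval", "n_snp")],
      excluded_snp = "(none)", .before = 1
    )
  )
}

#' Single-SNP (forest-plot) analysis
#'
#' The Wald ratio and confidence interval for each instrument
#' individually, ordered by genomic position, followed by the pooled IVW
#' estimate — the data behind a forest plot.
#'
#' @param instruments A harmonised instrument table with at least one
#'   row.
#' @param level Confidence level.
#' @return A tibble with columns `snp`, `estimate`, `se`, `ci_low`,
#'   `ci_high`, `pval`; the pooled row has `snp == "All (IVW)"`.
#' @export
mr_single_snp <- function(instruments, level = 0.95) {
  dat <- as_tibble(instruments)
  if (nrow(dat) < 1) stop("at least one instrument required", call. = FALSE)
  dat <- dat[order(dat$chrom, dat$pos), , drop = FALSE]
  rows <- purrr::map(seq_len(nrow(dat)), function(i) {
    fit <- mr_wald_ratio(dat[i, ], level)
    dplyr::mutate(
      tidy(fit)[, c("estimate", "se", "ci_low", "ci_high", "pval")],
      snp = dat$snp[i], .before = 1
    )
  })
  pooled <- mr_ivw(dat, level = level)
  dplyr::bind_rows(
    rows,
    dplyr::mutate(
      tidy(pooled)[, c("estimate", "se", "ci_low", "ci_high", "pval")],
      snp = "All (IVW)", .before = 1
    )
  )
}

#' Funnel-plot data
#'
#' Per-instrument Wald ratio against its precision (the reciprocal of its
#' delta-method standard error). Symmetry about the pooled estimate
#' suggests balanced pleiotropy; both the standard error and the
#' precision are exported so either axis convention can be plotted.
#'
#' @param instruments A harmonised instrument table.
#' @return A tibble with columns `snp`, `theta`, `se`, `precision`.
#' @export
mr_funnel_data <- function(instruments) {
  dat <- as_tibble(instruments)
  if (nrow(dat) < 1) stop("at least one instrument required", call. = FALSE)
  re <- ratio_estimates(dat)
  tibble(snp = re$snp, theta = re$theta, se = re$se, precision = 1 / re$se)
}

#' Full sensitivity report
#'
#' Bundles the heterogeneity and pleiotropy diagnostics for an instrument
#' set: Cochran's Q, the Egger intercept test, leave-one-out series,
#' single-SNP Wald ratios and funnel coordinates.
#'
#' @param instruments A harmonised instrument table (>= 2 rows; the Egger
#'   intercept requires >= 3).
#' @param level Confidence level.
#' @return A list of class `mr_sensitivity` with elements `q`,
#'   `egger_intercept`, `leave_one_out`, `single_snp`, `funnel`.
#' @export
mr_sensitivity <- function(instruments, level = 0.95) {
  dat <- as_tibble(instruments)
  egger_icpt <- if (nrow(dat) >= 3) {
    egger_intercept_test(mr_egger(dat, level))
  } else {
    tibble(intercept = NA_real_, se = NA_real_, pval = NA_real_)
  }
  structure(
    list(
      q = mr_cochran_q(dat),
      egger_intercept = egger_icpt,
      leave_one_out = mr_leave_one_out(dat, level = level),
      single_snp = mr_single_snp(dat, level),
      funnel = mr_funnel_data(dat)
    ),
    class = "mr_sensitivity"
  )
}

#' @export
print.mr_sensitivity <- function(x, ...) {
  cat("MR sensitivity report\n")
  cat(sprintf("  Cochran's Q: %.3f on %d df (p = %.3g)\n",
              x$q$q, x$q$q_df, x$q$q_pval))
  if (!is.na(x$egger_intercept$intercept)) {
    cat(sprintf("  Egger intercept: %.4g (SE %.3g, p = %.3g)\n",
                x$egger_intercept$intercept, x$egger_intercept$se,
                x$egger_intercept$pval))
  }
  cat(sprintf("  leave-one-out rows: %d; single-SNP rows: %d\n",
              nrow(x$leave_one_out), nrow(x$single_snp)))
  invisible(x)
}
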
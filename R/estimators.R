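ci_z <- function(level = 0.95) stats::qnorm(1 - (1 - level) / 2)

mr_result_row <- function(method, n_snp, estimate, se,
                          pval = NULL, df = NULL, level = 0.95,
                          intercept = NA_real_, intercept_se = NA_real_,
                          intercept_pval = NA_real_,
                          q = NA_real_, q_df = NA_real_, q_pval = NA_real_) {
  if (is.null(df)) {
    crit <- ci_z(level)
    if (is.null(pval)) pval <- 2 * stats::pnorm(-abs(estimate / se))
  } else {
    crit <- stats::qt(1 - (1 - level) / 2, df)
    if (is.null(pval)) pval <- 2 * stats::pt(-abs(estimate / se), df)
  }
  ci_low <- estimate - crit * se
  ci_high <- estimate + crit * se
  out <- tibble(
    method = method, n_snp = n_snp,
    estimate = estimate, se = se,
    ci_low = ci_low, ci_high = ci_high, pval = pval,
    or = exp(estimate), or_ci_low = exp(ci_low), or_ci_high = exp(ci_high),
    intercept = intercept, intercept_se = intercept_se,
    intercept_pval = intercept_pval,
    q = q, q_df = q_df, q_pval = q_pval
  )
  class(out) <- c("mr_result", class(out))
  out
}

# Per-variant Wald ratio estimates and first-order delta-method weights.
ratio_estimates <- function(dat) {
  if (any(dat$beta_exp == 0)) {
    stop("beta_exp must be nonzero for ratio estimates", call. = FALSE)
  }
  theta <- dat$beta_out / dat$beta_exp
  se <- dat$se_out / abs(dat$beta_exp)
  tibble(snp = dat$snp, theta = theta, se = se, w = 1 / se^2)
}

#' Wald ratio causal estimate for a single instrument
#'
#' The per-SNP causal estimate: the SNP-outcome effect divided by the
#' SNP-exposure effect, with first-order delta-method standard error
#' `se_out / |beta_exp|`, normal confidence interval and p-value.
#'
#' @param instrument A one-row harmonised instrument (columns `beta_exp`,
#'   `se_exp`, `beta_out`, `se_out`).
#' @param level Confidence level (default 0.95).
#' @return A one-row `mr_result` tibble.
#' @export
mr_wald_ratio <- function(instrument, level = 0.95) {
  dat <- as_tibble(instrument)
  if (nrow(dat) != 1) stop("mr_wald_ratio takes exactly one instrument",
                           call. = FALSE)
  if (dat$beta_exp == 0) stop("beta_exp must be nonzero", call. = FALSE)
  est <- dat$beta_out / dat$beta_exp
  se <- dat$se_out / abs(dat$beta_exp)
  mr_result_row("wald_ratio", 1L, est, se, level = level)
}

#' Inverse-variance weighted (IVW) causal estimate
#'
#' The main-effect two-sample MR estimator: a weighted regression of the
#' SNP-outcome associations on the SNP-exposure associations with the
#' intercept constrained to zero, weights `1/se_out^2`. Equivalently the
#' inverse-variance weighted mean of the per-SNP Wald ratios with
#' first-order weights `beta_exp^2 / se_out^2`. With one instrument it
#' reduces exactly to the Wald ratio.
#'
#' Under the default multiplicative random-effects policy the fixed-effect
#' standard error is inflated by `max(1, sqrt(Q/(k-1)))`, where Q is
#' Cochran's heterogeneity statistic; `se_policy = "fe"` keeps the
#' fixed-effect standard error.
#'
#' @param instruments A harmonised instrument table (kept rows).
#' @param se_policy `"mre"` (multiplicative random effects, default) or
#'   `"fe"` (fixed effect).
#' @param level Confidence level.
#' @return A one-row `mr_result` tibble with Cochran's Q attached
#'   (for k >= 2).
#' @export
mr_ivw <- function(instruments, se_policy = c("mre", "fe"), level = 0.95) {
  se_policy <- match.arg(se_policy)
  dat <- as_tibble(instruments)
  k <- nrow(dat)
  if (k < 1) stop("IVW requires at least one instrument", call. = FALSE)
  if (k == 1) {
    # exact reduction to the Wald ratio, free of round-off from the
    # weighted-sum formulation
    est <- dat$beta_out / dat$beta_exp
    se_fe <- dat$se_out / abs(dat$beta_exp)
  } else {
    w_num <- sum(dat$beta_exp * dat$beta_out / dat$se_out^2)
    w_den <- sum(dat$beta_exp^2 / dat$se_out^2)
    est <- w_num / w_den
    se_fe <- sqrt(1 / w_den)
  }
  q <- NA_real_; q_df <- NA_real_; q_pval <- NA_real_
  se <- se_fe
  if (k >= 2) {
    re <- ratio_estimates(dat)
    q <- sum(re$w * (re$theta - est)^2)
    q_df <- k - 1
    q_pval <- stats::pchisq(q, q_df, lower.tail = FALSE)
    if (se_policy == "mre") se <- se_fe * max(1, sqrt(q / (k - 1)))
  }
  mr_result_row("ivw", as.integer(k), est, se, level = level,
                q = q, q_df = q_df, q_pval = q_pval)
}

#' MR-Egger regression
#'
#' A weighted regression of SNP-outcome on SNP-exposure associations with
#' a free intercept, weights `1/se_out^2`, after orienting every
#' instrument so its exposure effect is non-negative. The slope estimates
#' the causal effect under the InSIDE assumption (pleiotropic effects
#' independent of instrument strength); the intercept estimates the
#' average directional pleiotropy. Coefficient standard errors use
#' multiplicative over-dispersion scaling bounded below by 1; inference
#' uses the t distribution with k-2 degrees of freedom.
#'
#' @param instruments A harmonised instrument table with at least three
#'   rows.
#' @param level Confidence level.
#' @return A one-row `mr_result` tibble with `intercept`, `intercept_se`
#'   and `intercept_pval` populated.
#' @export
mr_egger <- function(instruments, level = 0.95) {
  dat <- as_tibble(instruments)
  k <- nrow(dat)
  if (k < 3) stop("MR-Egger requires at least 3 instruments", call. = FALSE)
  flip <- sign(dat$beta_exp)
  flip[flip == 0] <- 1
  bx <- dat$beta_exp * flip
  by <- dat$beta_out * flip
  w <- 1 / dat$se_out^2
  fit <- stats::lm(by ~ bx, weights = w)
  smry <- summary(fit)
  sigma <- smry$sigma
  infl <- max(1, sigma)
  # unit-variance coefficient SEs times the floored dispersion scale
  se_unit <- smry$coefficients[, "Std. Error"] / sigma
  slope <- unname(stats::coef(fit)["bx"])
  slope_se <- unname(se_unit["bx"]) * infl
  icpt <- unname(stats::coef(fit)["(Intercept)"])
  icpt_se <- unname(se_unit["(Intercept)"]) * infl
  df <- k - 2
  mr_result_row("egger", as.integer(k), slope, slope_se, df = df,
                level = level,
                intercept = icpt, intercept_se = icpt_se,
                intercept_pval = 2 * stats::pt(-abs(icpt / icpt_se), df))
}

# Interpolated weighted median of theta under weights w.
weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]; w <- w[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (s[1] >= 0.5) return(theta[1])
  n <- length(theta)
  if (s[n] <= 0.5) return(theta[n])
  j <- max(which(s < 0.5))
  theta[j] + (theta[j + 1] - theta[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
}

# Parametric bootstrap over (beta_exp, beta_out) for median/mode SEs.
boot_se <- function(dat, n_boot, point_fun) {
  k <- nrow(dat)
  ests <- vapply(seq_len(n_boot), function(b) {
    bx <- stats::rnorm(k, dat$beta_exp, dat$se_exp)
    by <- stats::rnorm(k, dat$beta_out, dat$se_out)
    bx[bx == 0] <- .Machine$double.eps
    theta <- by / bx
    w <- bx^2 / dat$se_out^2
    point_fun(theta, w)
  }, numeric(1))
  stats::sd(ests)
}

#' Weighted median causal estimate
#'
#' The weighted median of the per-SNP Wald ratios, consistent when at
#' least half of the total weight comes from valid instruments. Ratio
#' estimates are sorted, weights accumulated to mid-interval fractions
#' `s_j = (cumsum(w) - w/2) / sum(w)`, and the estimate is the linear
#' interpolation of theta at `s = 0.5`. The standard error is a
#' parametric bootstrap: exposure and outcome effects are resampled from
#' normals centred at the observed values with the observed standard
#' errors and the estimate recomputed.
#'
#' @param instruments A harmonised instrument table with at least three
#'   rows.
#' @param n_boot Number of bootstrap replicates (default 1000); `0` skips
#'   the bootstrap and returns `NA` standard error (useful in simulation
#'   studies of the point estimate).
#' @param seed Optional integer seed for the bootstrap (the global RNG
#'   state is restored afterwards).
#' @param level Confidence level.
#' @return A one-row `mr_result` tibble.
#' @export
mr_weighted_median <- function(instruments, n_boot = 1000, seed = NULL,
                               level = 0.95) {
  dat <- as_tibble(instruments)
  if (nrow(dat) < 3) stop("weighted median requires at least 3 instruments",
                          call. = FALSE)
  re <- ratio_estimates(dat)
  est <- weighted_median_point(re$theta, re$w)
  se <- if (n_boot > 0) {
    local_seed(seed, boot_se(dat, n_boot, weighted_median_point))
  } else NA_real_
  mr_result_row("weighted_median", as.integer(nrow(dat)), est, se,
                level = level)
}

# Weighted-kernel-density mode of theta; h = 0 collapses to the common value.
weighted_mode_point <- function(theta, w, bandwidth_factor = 1,
                                n_grid = 10000) {
  k <- length(theta)
  h <- bandwidth_factor * 0.9 *
    min(stats::sd(theta), stats::IQR(theta) / 1.34) * k^(-1 / 5)
  if (!is.finite(h) || h <= 0) return(theta[1])
  grid <- seq(min(theta) - 3 * h, max(theta) + 3 * h, length.out = n_grid)
  wn <- w / sum(w)
  dens <- colSums(wn * stats::dnorm(outer(theta, grid, "-") / h)) / h
  grid[which.max(dens)]
}

#' Weighted mode causal estimate (mode-based estimate)
#'
#' The mode of the weighted kernel density of the per-SNP Wald ratios,
#' consistent when the largest group of instruments sharing the same
#' causal parameter is valid. Bandwidth follows the Silverman-type rule
#' `h = bandwidth_factor * 0.9 * min(sd, IQR/1.34) * k^(-1/5)`; the
#' density uses a normal kernel with normalised inverse-variance weights
#' and is maximised over a fixed 10,000-point grid spanning
#' `[min(theta) - 3h, max(theta) + 3h]`. Standard error by the same
#' parametric bootstrap as [mr_weighted_median()]. When all ratio
#' estimates coincide (zero bandwidth) the estimate is the common value.
#'
#' @inheritParams mr_weighted_median
#' @param bandwidth_factor Multiplier on the rule-of-thumb bandwidth
#'   (default 1).
#' @return A one-row `mr_result` tibble.
#' @export
mr_weighted_mode <- function(instruments, bandwidth_factor = 1,
                             n_boot = 1000, seed = NULL, level = 0.95) {
  dat <- as_tibble(instruments)
  if (nrow(dat) < 3) stop("weighted mode requires at least 3 instruments",
                          call. = FALSE)
  re <- ratio_estimates(dat)
  est <- weighted_mode_point(re$theta, re$w, bandwidth_factor)
  se <- if (n_boot > 0) {
    local_seed(seed, boot_se(dat, n_boot, function(theta, w) {
      weighted_mode_point(theta, w, bandwidth_factor)
    }))
  } else NA_real_
  mr_result_row("weighted_mode", as.integer(nrow(dat)), est, se,
                level = level)
}

#' Run every applicable MR estimator
#'
#' Applies IVW, MR-Egger, weighted median and weighted mode to the
#' instrument set, skipping (with a message) any method whose minimum
#' instrument count is not met. With fewer than three instruments the
#' per-SNP Wald ratios are reported alongside IVW.
#'
#' @param instruments A harmonised instrument table.
#' @param n_boot Bootstrap replicates for median/mode standard errors.
#' @param seed Integer seed shared by all bootstrap draws.
#' @param se_policy IVW standard-error policy, see [mr_ivw()].
#' @param bandwidth_factor Mode bandwidth multiplier.
#' @param level Confidence level.
#' @return An `mr_result` tibble, one row per method (plus one Wald row
#'   per instrument when k < 3).
#' @export
mr_all <- function(instruments, n_boot = 1000, seed = NULL,
                   se_policy = c("mre", "fe"), bandwidth_factor = 1,
                   level = 0.95) {
  se_policy <- match.arg(se_policy)
  dat <- as_tibble(instruments)
  k <- nrow(dat)
  if (k < 1) stop("no instruments supplied", call. = FALSE)
  out <- list(mr_ivw(dat, se_policy, level))
  if (k < 3) {
    message("fewer than 3 instruments: egger/weighted_median/weighted_mode ",
            "skipped; reporting per-SNP Wald ratios")
    out <- c(out, purrr::map(seq_len(k),
                             function(i) mr_wald_ratio(dat[i, ], level)))
  } else {
    out <- c(out, list(
      mr_egger(dat, level),
      mr_weighted_median(dat, n_boot, seed, level),
      mr_weighted_mode(dat, bandwidth_factor, n_boot, seed, level)
    ))
  }
  res <- dplyr::bind_rows(out)
  class(res) <- unique(c("mr_result", class(res)))
  res
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an MR result
#'
#' @param x An `mr_result` tibble.
#' @param ... Unused.
#' @return A plain tibble of the estimates (already one row per method).
#' @method tidy mr_result
#' @export
tidy.mr_result <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "mr_result")
  out
}

#' Glance at an MR result
#'
#' @param x An `mr_result` tibble.
#' @param ... Unused.
#' @return A one-row tibble summarising instrument count and
#'   heterogeneity of the IVW analysis (or the first row when no IVW row
#'   is present).
#' @method glance mr_result
#' @export
glance.mr_result <- function(x, ...) {
  row <- if ("ivw" %in% x$method) x[x$method == "ivw", ][1, ] else x[1, ]
  tibble(n_snp = row$n_snp, q = row$q, q_df = row$q_df, q_pval = row$q_pval,
         n_methods = length(unique(x$method)))
}

# Evaluate code under a temporary RNG state; NULL seed leaves RNG alone.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
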
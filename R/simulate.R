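#' Simulation configuration for synthetic two-sample GWAS data
#'
#' Collects the generative parameters for paired exposure/outcome summary
#' statistics with a known causal effect. Effect scales are per-SD
#' standardised (log-odds per SD for a binary outcome); standard errors
#' follow the usual `1/sqrt(2*maf*(1-maf)*n)` form, with an extra
#' `case_fraction*(1-case_fraction)` factor for case-control outcomes.
#'
#' @param n_snps Number of variants.
#' @param theta True causal effect of the exposure on the outcome (per SD
#'   of exposure; log-odds per SD for a binary outcome).
#' @param maf_range Minor-allele-frequency interval within (0, 0.5].
#' @param instrument_effect_sd Scale of true SNP-exposure effects; true
#'   effects are drawn as `|N(0, instrument_effect_sd^2)|`, i.e. oriented
#'   to the exposure-increasing allele.
#' @param min_instrument_f Expected-F floor for true effects: each
#'   `gamma_j` is drawn from the folded normal left-truncated at
#'   `sqrt(min_instrument_f) * se_exposure_j`, emulating instruments that
#'   were discovered at genome-wide significance (an observed F of ~30 is
#'   the strength implied by p < 5e-8). Set to 0 for an untruncated draw,
#'   as in the `weak_instruments` scenario.
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of direct (horizontal)
#'   pleiotropic effects on the outcome; a nonzero mean gives directional
#'   pleiotropy relative to the exposure-increasing orientation.
#' @param inside_violation If `TRUE`, pleiotropic effects are correlated
#'   with instrument strength at `inside_correlation`, violating the
#'   InSIDE assumption.
#' @param inside_correlation Correlation used when `inside_violation`.
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param outcome_scale `"continuous_sd"` or `"log_odds"`.
#' @param case_fraction Case fraction of the outcome GWAS (log-odds only).
#' @param ld_blocks Optional list of `c(size, r2)` pairs; each block is a
#'   run of consecutive variants sharing one true exposure effect, with
#'   observed effects correlated at the block's r-squared. Variants not
#'   covered by a block are independent.
#' @param palindrome_fraction Fraction of variants given strand-ambiguous
#'   (A/T or C/G) allele pairs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 100, theta = 0,
                       maf_range = c(0.05, 0.45),
                       instrument_effect_sd = 0.1,
                       pleiotropy_mean = 0, pleiotropy_sd = 0,
                       min_instrument_f = 30,
                       inside_violation = FALSE, inside_correlation = 0.5,
                       n_exposure = 400102, n_outcome = 79865,
                       outcome_scale = c("log_odds", "continuous_sd"),
                       case_fraction = 24807 / 79865,
                       ld_blocks = NULL, palindrome_fraction = 0) {
  outcome_scale <- match.arg(outcome_scale)
  stopifnot(
    n_snps >= 1, length(maf_range) == 2,
    maf_range[1] > 0, maf_range[2] <= 0.5, maf_range[1] <= maf_range[2],
    instrument_effect_sd > 0, min_instrument_f >= 0, pleiotropy_sd >= 0,
    n_exposure > 2, n_outcome > 2,
    case_fraction > 0, case_fraction < 1,
    palindrome_fraction >= 0, palindrome_fraction <= 1,
    abs(inside_correlation) <= 1
  )
  if (!is.null(ld_blocks)) {
    sizes <- vapply(ld_blocks, function(b) b[[1]], numeric(1))
    r2s <- vapply(ld_blocks, function(b) b[[2]], numeric(1))
    stopifnot(all(sizes >= 1), all(r2s >= 0), all(r2s <= 1),
              sum(sizes) <= n_snps)
  }
  structure(
    list(n_snps = as.integer(n_snps), theta = theta, maf_range = maf_range,
         instrument_effect_sd = instrument_effect_sd,
         min_instrument_f = min_instrument_f,
         pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
         inside_violation = inside_violation,
         inside_correlation = inside_correlation,
         n_exposure = n_exposure, n_outcome = n_outcome,
         outcome_scale = outcome_scale, case_fraction = case_fraction,
         ld_blocks = ld_blocks, palindrome_fraction = palindrome_fraction),
    class = "sim_config"
  )
}

#' Named simulation scenario presets
#'
#' Fully specified [sim_config()] objects for the standard validation
#' scenarios. All presets use 100 strong instruments (mean F well above
#' 100 except `weak_instruments`), an exposure GWAS of 400,102 and a
#' case-control outcome GWAS of 24,807 cases / 55,058 controls on the
#' log-odds scale, mirroring the scale of large lung-function and
#' Alzheimer's GWASs.
#'
#' * `null` — no causal effect, no pleiotropy.
#' * `causal` — true effect 0.3 (log-odds per SD).
#' * `balanced_pleiotropy` — effect 0.3 plus mean-zero direct effects.
#' * `directional_pleiotropy` — effect 0.3 plus direct effects averaging
#'   about a fifth of the typical per-SNP causal signal (InSIDE holds).
#'
#' The two pleiotropy presets use a ten-fold larger exposure GWAS so that
#' regression-dilution attenuation of the Egger fit — a separate,
#' well-understood weak-instrument phenomenon — does not confound what
#' these scenarios are built to probe, the behaviour of the intercept
#' under horizontal pleiotropy.
#' * `weak_instruments` — effect spread calibrated so the mean
#'   F-statistic is about 10.
#' * `binary_outcome` — as `causal`; kept as an explicit name for the
#'   log-odds outcome scale.
#' * `ld_structured` — 50 variants in ten 5-variant LD blocks
#'   (within-block r-squared 0.9) with 30% palindromic variants.
#'
#' @param name Scenario name.
#' @return A `sim_config` object.
#' @export
mr_scenario <- function(name = c("null", "causal", "balanced_pleiotropy",
                                 "directional_pleiotropy", "weak_instruments",
                                 "binary_outcome", "ld_structured")) {
  name <- match.arg(name)
  switch(
    name,
    null = sim_config(theta = 0),
    causal = sim_config(theta = 0.3),
    balanced_pleiotropy = sim_config(theta = 0.3, pleiotropy_sd = 0.005,
                                     n_exposure = 4000102),
    directional_pleiotropy = sim_config(theta = 0.3,
                                        pleiotropy_mean = 0.002,
                                        pleiotropy_sd = 0.002,
                                        n_exposure = 4000102),
    weak_instruments = sim_config(theta = 0.3, instrument_effect_sd = 0.008,
                                  min_instrument_f = 0),
    binary_outcome = sim_config(theta = 0.3),
    ld_structured = sim_config(theta = 0.3, n_snps = 50,
                               ld_blocks = rep(list(c(5, 0.9)), 10),
                               palindrome_fraction = 0.3)
  )
}

#' Simulate paired two-sample GWAS summary statistics
#'
#' Generates exposure and outcome summary-statistic tables with known
#' ground truth. Per variant j: `maf_j ~ U(maf_range)`;
#' `gamma_j = |N(0, instrument_effect_sd^2)|`; pleiotropic effect
#' `alpha_j ~ N(pleiotropy_mean, pleiotropy_sd^2)`, correlated with
#' `gamma_j` only under `inside_violation`; standard errors
#' `se = 1/sqrt(2*maf*(1-maf)*n)` (times the Bernoulli variance factor for
#' a case-control outcome); observed effects
#' `beta_x ~ N(gamma, se_x^2)` and `beta_y ~ N(theta*gamma + alpha,
#' se_y^2)` with noise independent between tables (the two-sample,
#' no-overlap setting). Within an LD block the true `gamma` is shared and
#' the noise of the observed effects is equicorrelated at
#' `sqrt(r2)` (the genotype correlation implied by the block's
#' r-squared). Two-sided normal p-values; allele pairs are palindromic
#' with probability `palindrome_fraction`. All randomness derives from
#' `seed` via a fixed draw order, so equal seeds give bit-identical
#' output.
#'
#' @param config A [sim_config()] or preset name for [mr_scenario()].
#' @param seed Integer seed (required, for reproducibility).
#' @return A list of class `mr_simulation`:
#'   `exposure` and `outcome` ([summary_stats()] tables), `truth` (tibble
#'   with `snp`, `gamma`, `alpha`, `big_gamma = theta*gamma + alpha` and
#'   attribute `theta`), and `ld` (an [ld_matrix()]).
#' @export
simulate_two_sample <- function(config, seed) {
  if (is.character(config)) config <- mr_scenario(config)
  stopifnot(inherits(config, "sim_config"))
  if (missing(seed) || is.null(seed)) {
    stop("an integer seed is required", call. = FALSE)
  }
  local_seed(as.integer(seed), {
    k <- config$n_snps
    maf <- stats::runif(k, config$maf_range[1], config$maf_range[2])
    se_x <- 1 / sqrt(2 * maf * (1 - maf) * config$n_exposure)
    # folded normal left-truncated at the expected-F floor, by inverse CDF
    # (keeps the draw order fixed regardless of the truncation point)
    g_min <- sqrt(config$min_instrument_f) * se_x
    p_lo <- 2 * stats::pnorm(g_min / config$instrument_effect_sd) - 1
    u <- stats::runif(k)
    gamma <- config$instrument_effect_sd *
      stats::qnorm((p_lo + u * (1 - p_lo) + 1) / 2)

    # LD block bookkeeping: block id 0 = independent
    block <- integer(k)
    r2_within <- numeric(0)
    if (!is.null(config$ld_blocks)) {
      at <- 1L
      for (b in seq_along(config$ld_blocks)) {
        sz <- as.integer(config$ld_blocks[[b]][[1]])
        block[at:(at + sz - 1L)] <- b
        r2_within[b] <- config$ld_blocks[[b]][[2]]
        at <- at + sz
      }
      # one shared true exposure effect per block
      for (b in seq_along(config$ld_blocks)) {
        idx <- which(block == b)
        gamma[idx] <- gamma[idx[1]]
      }
    }

    z_pleio <- stats::rnorm(k)
    if (config$inside_violation && config$pleiotropy_sd > 0) {
      g_std <- as.numeric(scale(gamma))
      rho <- config$inside_correlation
      z_pleio <- rho * g_std + sqrt(1 - rho^2) * z_pleio
    }
    alpha <- config$pleiotropy_mean + config$pleiotropy_sd * z_pleio
    big_gamma <- config$theta * gamma + alpha

    se_y <- if (config$outcome_scale == "log_odds") {
      cf <- config$case_fraction
      1 / sqrt(2 * maf * (1 - maf) * config$n_outcome * cf * (1 - cf))
    } else {
      1 / sqrt(2 * maf * (1 - maf) * config$n_outcome)
    }

    # equicorrelated noise within blocks at the genotype correlation sqrt(r2)
    correlated_noise <- function() {
      z <- stats::rnorm(k)
      if (any(block > 0)) {
        z0 <- stats::rnorm(max(block))
        for (b in unique(block[block > 0])) {
          idx <- which(block == b)
          r <- sqrt(r2_within[b])
          z[idx] <- sqrt(r) * z0[b] + sqrt(1 - r) * z[idx]
        }
      }
      z
    }
    beta_x <- gamma + se_x * correlated_noise()
    beta_y <- big_gamma + se_y * correlated_noise()

    pal <- stats::runif(k) < config$palindrome_fraction
    pal_pairs <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
    npal_pairs <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                       c("G", "A"), c("C", "A"))
    pair_idx_pal <- sample.int(4, k, replace = TRUE)
    pair_idx_np <- sample.int(6, k, replace = TRUE)
    ea <- oa <- character(k)
    for (j in seq_len(k)) {
      pr <- if (pal[j]) pal_pairs[[pair_idx_pal[j]]] else
        npal_pairs[[pair_idx_np[j]]]
      ea[j] <- pr[1]; oa[j] <- pr[2]
    }

    ids <- sprintf("rs%06d", seq_len(k))
    pos <- 1e6 + (seq_len(k) - 1) * 1e5
    two_sided_p <- function(beta, se) {
      pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin)
    }
    base <- tibble(
      snp = ids, chrom = "1", pos = pos,
      effect_allele = ea, other_allele = oa, eaf = maf
    )
    exposure <- summary_stats(
      dplyr::mutate(base, beta = beta_x, se = se_x,
                    pval = two_sided_p(beta_x, se_x), n = config$n_exposure),
      trait_label = "exposure", trait_scale = "continuous_sd"
    )
    outcome <- summary_stats(
      dplyr::mutate(base, beta = beta_y, se = se_y,
                    pval = two_sided_p(beta_y, se_y), n = config$n_outcome),
      trait_label = "outcome", trait_scale = config$outcome_scale
    )

    r2 <- diag(k)
    for (b in unique(block[block > 0])) {
      idx <- which(block == b)
      r2[idx, idx] <- r2_within[b]
    }
    diag(r2) <- 1
    dimnames(r2) <- list(ids, ids)

    truth <- tibble(snp = ids, gamma = gamma, alpha = alpha,
                    big_gamma = big_gamma, maf = maf,
                    block = block)
    attr(truth, "theta") <- config$theta

    structure(
      list(exposure = exposure, outcome = outcome, truth = truth,
           ld = ld_matrix(r2), config = config, seed = as.integer(seed)),
      class = "mr_simulation"
    )
  })
}

#' @export
print.mr_simulation <- function(x, ...) {
  cat(sprintf(
    "Synthetic two-sample GWAS: %d variants, theta = %g, outcome scale %s\n",
    x$config$n_snps, x$config$theta, x$config$outcome_scale))
  cat(sprintf("  n_exposure = %d, n_outcome = %d, seed = %d\n",
              x$config$n_exposure, x$config$n_outcome, x$seed))
  invisible(x)
}
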
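# Fixture builders and independent oracles shared across the suite.

# A minimal valid summary-statistics data frame; override fields as needed.
make_sumstats_df <- function(n = 3, snp = sprintf("rs%03d", seq_len(n)),
                             chrom = "1", pos = seq_len(n) * 1e5,
                             ea = "A", oa = "G", eaf = 0.3,
                             beta = 0.05, se = 0.01, pval = 1e-10,
                             nn = 1e5) {
  tibble::tibble(snp = snp, chrom = chrom, pos = pos,
                 effect_allele = ea, other_allele = oa, eaf = eaf,
                 beta = beta, se = se, pval = pval, n = nn)
}

make_sumstats <- function(...) summary_stats(make_sumstats_df(...))

# A harmonised-instrument table built directly (bypassing harmonise_tables)
# for estimator tests.
make_instruments <- function(beta_exp, beta_out, se_exp = 0.01,
                             se_out = 0.01, n_exp = 1e5, n_out = 1e5) {
  k <- length(beta_exp)
  tibble::tibble(
    snp = sprintf("rs%03d", seq_len(k)), chrom = "1", pos = seq_len(k) * 1e5,
    effect_allele = "A", other_allele = "G",
    beta_exp = beta_exp, se_exp = rep_len(se_exp, k), eaf_exp = 0.3,
    pval_exp = 1e-10, n_exp = rep_len(n_exp, k),
    beta_out = beta_out, se_out = rep_len(se_out, k), eaf_out = 0.3,
    pval_out = 0.5, n_out = rep_len(n_out, k),
    status = "kept", exclusion_reason = "",
    orientation_flipped = FALSE, strand_complemented = FALSE
  )
}

# --- independent oracles -------------------------------------------------

# Zero-intercept weighted least squares via explicit normal equations.
oracle_ivw <- function(bx, by, sy) {
  w <- 1 / sy^2
  xtwx <- sum(w * bx * bx)
  xtwy <- sum(w * bx * by)
  xtwy / xtwx
}

# Free-intercept weighted regression via explicit normal equations,
# with the same bx >= 0 orientation rule as the estimator under test.
oracle_egger <- function(bx, by, sy) {
  fl <- ifelse(bx < 0, -1, 1)
  bx <- bx * fl; by <- by * fl
  w <- 1 / sy^2
  X <- cbind(1, bx)
  xtwx <- t(X) %*% (w * X)
  xtwy <- t(X) %*% (w * by)
  beta <- solve(xtwx, xtwy)
  list(intercept = beta[1], slope = beta[2])
}

# Interpolated weighted median by root-finding on the piecewise-linear
# cumulative mid-weight function.
oracle_weighted_median <- function(theta, w) {
  ord <- order(theta)
  th <- theta[ord]; ww <- w[ord]
  s <- (cumsum(ww) - ww / 2) / sum(ww)
  if (s[1] >= 0.5) return(th[1])
  if (s[length(s)] <= 0.5) return(th[length(th)])
  stats::approx(s, th, xout = 0.5)$y
}

# Dense-grid weighted kernel density argmax, evaluated point by point.
oracle_weighted_mode <- function(theta, w, bandwidth_factor = 1,
                                 n_grid = 10000) {
  k <- length(theta)
  h <- bandwidth_factor * 0.9 *
    min(stats::sd(theta), stats::IQR(theta) / 1.34) * k^(-1 / 5)
  if (!is.finite(h) || h <= 0) return(theta[1])
  grid <- seq(min(theta) - 3 * h, max(theta) + 3 * h, length.out = n_grid)
  wn <- w / sum(w)
  dens <- vapply(grid, function(g) {
    sum(wn * stats::dnorm((theta - g) / h)) / h
  }, numeric(1))
  grid[which.max(dens)]
}

# Instruments straight from a simulation draw. The generator emits both
# tables on a shared allele orientation, so harmonisation is the identity;
# building the pairing directly keeps replicate loops cheap.
sim_instruments <- function(sim) {
  tibble::tibble(
    snp = sim$exposure$snp, chrom = sim$exposure$chrom,
    pos = sim$exposure$pos,
    effect_allele = sim$exposure$effect_allele,
    other_allele = sim$exposure$other_allele,
    beta_exp = sim$exposure$beta, se_exp = sim$exposure$se,
    eaf_exp = sim$exposure$eaf, pval_exp = sim$exposure$pval,
    n_exp = sim$exposure$n,
    beta_out = sim$outcome$beta, se_out = sim$outcome$se,
    eaf_out = sim$outcome$eaf, pval_out = sim$outcome$pval,
    n_out = sim$outcome$n,
    status = "kept", exclusion_reason = "",
    orientation_flipped = FALSE, strand_complemented = FALSE
  )
}
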
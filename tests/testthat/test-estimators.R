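test_that("the Wald ratio matches its closed form, including signs", {
  ins <- make_instruments(beta_exp = 0.1, beta_out = 0.02, se_out = 0.01)
  res <- mr_wald_ratio(ins)
  expect_equal(res$estimate, 0.2)
  expect_equal(res$se, 0.1)
  expect_equal(res$or, exp(0.2))

  neg <- make_instruments(beta_exp = -0.1, beta_out = 0.02, se_out = 0.01)
  res_neg <- mr_wald_ratio(neg)
  expect_equal(res_neg$estimate, -0.2)
  expect_equal(res_neg$se, 0.1)

  nul <- make_instruments(beta_exp = 0.1, beta_out = 0, se_out = 0.01)
  res_nul <- mr_wald_ratio(nul)
  expect_equal(res_nul$estimate, 0)
  expect_equal(res_nul$pval, 1)

  zero <- make_instruments(beta_exp = 0, beta_out = 0.02)
  expect_error(mr_wald_ratio(zero), "nonzero")
})

test_that("IVW with one instrument equals the Wald ratio exactly", {
  ins <- make_instruments(beta_exp = 0.13, beta_out = -0.041,
                          se_out = 0.017)
  ivw <- mr_ivw(ins)
  wald <- mr_wald_ratio(ins)
  expect_identical(ivw$estimate, wald$estimate)
  expect_identical(ivw$se, wald$se)
})

test_that("perfectly homogeneous ratios give Q = 0 and no inflation", {
  bx <- c(0.1, 0.2, 0.3, 0.15)
  ins <- make_instruments(beta_exp = bx, beta_out = 0.5 * bx,
                          se_out = 0.01)
  res <- mr_ivw(ins)
  expect_equal(res$estimate, 0.5)
  expect_equal(res$q, 0, tolerance = 1e-20)
  expect_equal(res$q_pval, 1)
  expect_equal(res$se, mr_ivw(ins, se_policy = "fe")$se)
})

test_that("IVW equals the zero-intercept WLS normal-equations oracle", {
  ins <- make_instruments(beta_exp = c(0.1, 0.2, 0.3),
                          beta_out = c(0.01, 0.04, 0.09),
                          se_out = 0.01)
  res <- mr_ivw(ins)
  expect_equal(res$estimate,
               oracle_ivw(ins$beta_exp, ins$beta_out, ins$se_out),
               tolerance = 1e-12)

  set.seed(11)
  for (rep in 1:5) {
    k <- sample(5:10, 1)
    ins <- make_instruments(beta_exp = rnorm(k, 0.1, 0.05),
                            beta_out = rnorm(k, 0.03, 0.02),
                            se_out = runif(k, 0.005, 0.05))
    expect_equal(mr_ivw(ins)$estimate,
                 oracle_ivw(ins$beta_exp, ins$beta_out, ins$se_out),
                 tolerance = 1e-12)
  }
})

test_that("MR-Egger recovers exact linear and affine data", {
  bx <- c(0.05, 0.1, 0.2, 0.3)
  lin <- make_instruments(beta_exp = bx, beta_out = 0.3 * bx, se_out = 0.01)
  res <- mr_egger(lin)
  expect_equal(res$estimate, 0.3, tolerance = 1e-10)
  expect_equal(res$intercept, 0, tolerance = 1e-10)

  # with residual dispersion floored at 1, exact data keeps the
  # unit-dispersion coefficient SEs, so significance needs tight se_out
  bx6 <- c(0.05, 0.1, 0.15, 0.2, 0.25, 0.3)
  aff <- make_instruments(beta_exp = bx6, beta_out = 0.05 + 0.3 * bx6,
                          se_out = 0.001)
  res2 <- mr_egger(aff)
  expect_equal(res2$estimate, 0.3, tolerance = 1e-10)
  expect_equal(res2$intercept, 0.05, tolerance = 1e-10)
  expect_lt(res2$intercept_pval, 1e-4)
})

test_that("MR-Egger matches the weighted-regression oracle on noisy data", {
  set.seed(21)
  k <- 10
  bx <- rnorm(k, 0.1, 0.08)  # mixed signs exercise the orientation rule
  by <- 0.02 + 0.25 * abs(bx) * sign(bx) + rnorm(k, 0, 0.01)
  sy <- runif(k, 0.005, 0.03)
  ins <- make_instruments(beta_exp = bx, beta_out = by, se_out = sy)
  res <- mr_egger(ins)
  ora <- oracle_egger(bx, by, sy)
  expect_equal(res$estimate, ora$slope, tolerance = 1e-10)
  expect_equal(res$intercept, ora$intercept, tolerance = 1e-10)
  expect_error(mr_egger(ins[1:2, ]), "at least 3")
})

test_that("the weighted median interpolates the cumulative weight function", {
  # degenerate: all ratios equal
  bx <- c(0.1, 0.2, 0.4)
  ins <- make_instruments(beta_exp = bx, beta_out = 0.7 * bx,
                          se_out = c(0.01, 0.03, 0.02))
  expect_equal(mr_weighted_median(ins, n_boot = 10, seed = 1)$estimate, 0.7)

  # symmetric equal weights: the middle ratio
  ins2 <- make_instruments(beta_exp = 1, beta_out = c(0.1, 0.5, 0.9),
                           se_out = 0.01)
  expect_equal(mr_weighted_median(ins2, n_boot = 10, seed = 1)$estimate, 0.5)

  # unequal weights: brute-force oracle
  set.seed(31)
  for (rep in 1:5) {
    k <- 5
    bx <- runif(k, 0.05, 0.3)
    by <- rnorm(k, 0.2 * bx, 0.02)
    sy <- runif(k, 0.005, 0.05)
    ins3 <- make_instruments(beta_exp = bx, beta_out = by, se_out = sy)
    theta <- by / bx
    w <- bx^2 / sy^2
    expect_equal(mr_weighted_median(ins3, n_boot = 0)$estimate,
                 oracle_weighted_median(theta, w), tolerance = 1e-10)
  }
})

test_that("the weighted mode finds the dominant cluster, not outliers", {
  bx <- c(0.1, 0.2, 0.3)
  ins <- make_instruments(beta_exp = bx, beta_out = 0.4 * bx, se_out = 0.01)
  expect_equal(mr_weighted_mode(ins, n_boot = 10, seed = 1)$estimate, 0.4)

  # a tight cluster and one wild, low-weight outlier
  bx2 <- c(1, 1, 1, 0.05)
  by2 <- c(0.50, 0.51, 0.49, 0.25)  # last ratio is 5.0
  sy2 <- c(0.01, 0.01, 0.01, 0.05)
  ins2 <- make_instruments(beta_exp = bx2, beta_out = by2, se_out = sy2)
  est <- mr_weighted_mode(ins2, n_boot = 0)$estimate
  expect_gt(est, 0.4)
  expect_lt(est, 0.6)
})

test_that("the weighted mode equals the dense-grid density oracle", {
  set.seed(41)
  k <- 7
  bx <- runif(k, 0.05, 0.3)
  by <- rnorm(k, 0.3 * bx, 0.01)
  sy <- runif(k, 0.005, 0.03)
  ins <- make_instruments(beta_exp = bx, beta_out = by, se_out = sy)
  theta <- by / bx
  w <- bx^2 / sy^2
  expect_equal(mr_weighted_mode(ins, n_boot = 0)$estimate,
               oracle_weighted_mode(theta, w), tolerance = 1e-10)
})

test_that("estimators are equivariant under joint sign flips of instruments", {
  set.seed(51)
  bx <- runif(8, 0.05, 0.3)
  by <- rnorm(8, 0.2 * bx, 0.01)
  ins <- make_instruments(beta_exp = bx, beta_out = by, se_out = 0.01)
  flip <- rep(c(1, -1), 4)
  flipped <- dplyr::mutate(ins, beta_exp = beta_exp * flip,
                           beta_out = beta_out * flip)
  expect_equal(mr_ivw(flipped)$estimate, mr_ivw(ins)$estimate)
  expect_equal(mr_egger(flipped)$estimate, mr_egger(ins)$estimate)
  expect_equal(mr_egger(flipped)$intercept, mr_egger(ins)$intercept)
  expect_equal(mr_weighted_median(flipped, n_boot = 0)$estimate,
               mr_weighted_median(ins, n_boot = 0)$estimate)
  expect_equal(mr_weighted_mode(flipped, n_boot = 0)$estimate,
               mr_weighted_mode(ins, n_boot = 0)$estimate)
})

test_that("scaling all outcome SEs leaves IVW and Egger point estimates fixed", {
  set.seed(61)
  bx <- runif(6, 0.05, 0.3)
  by <- rnorm(6, 0.2 * bx, 0.02)
  sy <- runif(6, 0.005, 0.05)
  ins <- make_instruments(beta_exp = bx, beta_out = by, se_out = sy)
  scaled <- dplyr::mutate(ins, se_out = se_out * 7)
  expect_equal(mr_ivw(scaled)$estimate, mr_ivw(ins)$estimate)
  expect_equal(mr_egger(scaled)$estimate, mr_egger(ins)$estimate)
})

test_that("mr_all gates methods on instrument counts and is deterministic", {
  two <- make_instruments(beta_exp = c(0.1, 0.2),
                          beta_out = c(0.02, 0.05), se_out = 0.01)
  expect_message(res2 <- mr_all(two, seed = 1), "skipped")
  expect_setequal(res2$method, c("ivw", "wald_ratio"))
  expect_equal(sum(res2$method == "wald_ratio"), 2)

  set.seed(71)
  bx <- runif(10, 0.05, 0.3)
  ins <- make_instruments(beta_exp = bx,
                          beta_out = rnorm(10, 0.3 * bx, 0.005),
                          se_out = 0.01)
  a <- mr_all(ins, n_boot = 50, seed = 99)
  b <- mr_all(ins, n_boot = 50, seed = 99)
  expect_identical(a, b)
  expect_setequal(a$method,
                  c("ivw", "egger", "weighted_median", "weighted_mode"))
  # homogeneous, pleiotropy-free data: methods agree closely
  ests <- a$estimate
  expect_lt(max(ests) - min(ests), 0.05)
  # OR columns are the exact exponentials
  expect_equal(a$or, exp(a$estimate))
  expect_equal(a$or_ci_low, exp(a$ci_low))
  expect_true(all(a$ci_low < a$estimate & a$estimate < a$ci_high))
})

test_that("tidy and glance return broom-style tibbles", {
  bx <- c(0.1, 0.2, 0.3)
  ins <- make_instruments(beta_exp = bx, beta_out = 0.3 * bx, se_out = 0.01)
  res <- mr_all(ins, n_boot = 10, seed = 1)
  td <- tidy(res)
  expect_false(inherits(td, "mr_result"))
  expect_true(all(c("method", "estimate", "se", "pval") %in% names(td)))
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_snp, 3L)
  expect_equal(gl$n_methods, 4L)
})
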
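test_that("allele complementation follows Watson-Crick pairing", {
  expect_equal(complement_alleles(c("A", "C", "G", "T")),
               c("T", "G", "C", "A"))
  expect_error(complement_alleles("N"), "A, C, G, T")
})

test_that("palindromic pairs are exactly A/T and C/G", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("C", "G"))
  expect_true(is_palindromic("T", "A"))
  expect_false(is_palindromic("A", "G"))
  expect_false(is_palindromic("C", "A"))
})

row_for <- function(ea, oa, beta = 0.1, eaf = 0.3, snp = "rs1") {
  make_sumstats_df(n = 1, snp = snp, ea = ea, oa = oa, beta = beta,
                   eaf = eaf)
}

test_that("swapped alleles flip the outcome beta and EAF", {
  h <- harmonise_pair(row_for("A", "G", beta = 0.10),
                      row_for("G", "A", beta = -0.05, eaf = 0.7))
  expect_equal(h$status, "kept")
  expect_equal(h$beta_out, 0.05)
  expect_equal(h$eaf_out, 0.3)
  expect_true(h$orientation_flipped)
})

test_that("strand-complemented alleles are recognised, same and swapped order", {
  h1 <- harmonise_pair(row_for("A", "G", beta = 0.1),
                       row_for("T", "C", beta = 0.02))
  expect_equal(h1$status, "kept")
  expect_equal(h1$beta_out, 0.02)
  expect_true(h1$strand_complemented)
  expect_false(h1$orientation_flipped)

  h2 <- harmonise_pair(row_for("A", "G", beta = 0.1),
                       row_for("C", "T", beta = 0.02, eaf = 0.8))
  expect_equal(h2$status, "kept")
  expect_equal(h2$beta_out, -0.02)
  expect_true(h2$strand_complemented)
  expect_true(h2$orientation_flipped)
})

test_that("intermediate-frequency palindromes are excluded as ambiguous", {
  h <- harmonise_pair(row_for("A", "T", eaf = 0.50),
                      row_for("A", "T", eaf = 0.50))
  expect_equal(h$status, "excluded")
  expect_equal(h$exclusion_reason, "palindromic-ambiguous")

  # missing EAF on either side cannot be disambiguated
  h2 <- harmonise_pair(row_for("A", "T", eaf = NA),
                       row_for("A", "T", eaf = 0.1))
  expect_equal(h2$exclusion_reason, "palindromic-ambiguous")
})

test_that("non-intermediate palindromes are aligned by frequency agreement", {
  # out's EA=T at 0.91 implies A at 0.09, the same side of 0.5 as the
  # exposure's A at 0.10: the label swap is real, so the beta flips sign
  h <- harmonise_pair(row_for("A", "T", beta = 0.1, eaf = 0.10),
                      row_for("T", "A", beta = 0.02, eaf = 0.91))
  expect_equal(h$status, "kept")
  expect_equal(h$beta_out, -0.02)
  expect_equal(h$eaf_out, 0.09)

  # same labels, frequencies on opposite sides: the outcome is reported on
  # the other strand and its effect allele is really the exposure's other
  # allele, so the beta flips
  h2 <- harmonise_pair(row_for("A", "T", beta = 0.1, eaf = 0.10),
                       row_for("A", "T", beta = 0.02, eaf = 0.88))
  expect_equal(h2$status, "kept")
  expect_equal(h2$beta_out, -0.02)
  expect_true(h2$strand_complemented)

  # same labels, same side: kept as-is
  h3 <- harmonise_pair(row_for("A", "T", beta = 0.1, eaf = 0.10),
                       row_for("A", "T", beta = 0.02, eaf = 0.12))
  expect_equal(h3$beta_out, 0.02)
  expect_false(h3$orientation_flipped)
})

test_that("irreconcilable alleles are excluded", {
  h <- harmonise_pair(row_for("A", "G"), row_for("A", "C"))
  expect_equal(h$status, "excluded")
  expect_equal(h$exclusion_reason, "allele-mismatch")
})

test_that("id mismatch is a usage error", {
  expect_error(harmonise_pair(row_for("A", "G", snp = "rs1"),
                              row_for("A", "G", snp = "rs2")),
               "different variants")
})

test_that("harmonising tables covers all resolution cases with audit counts", {
  exposure <- summary_stats(dplyr::bind_rows(
    row_for("A", "G", snp = "v1"),                 # same order
    row_for("A", "G", snp = "v2"),                 # swapped in outcome
    row_for("A", "G", snp = "v3"),                 # complemented in outcome
    row_for("A", "T", snp = "v4", eaf = 0.5),      # ambiguous palindrome
    row_for("A", "G", snp = "v5"),                 # allele mismatch
    row_for("A", "G", snp = "v6")                  # absent from outcome
  ))
  outcome <- summary_stats(dplyr::bind_rows(
    row_for("A", "G", snp = "v1"),
    row_for("G", "A", snp = "v2", eaf = 0.7),
    row_for("T", "C", snp = "v3"),
    row_for("A", "T", snp = "v4", eaf = 0.5),
    row_for("A", "C", snp = "v5")
  ))
  harm <- harmonise_tables(exposure, outcome)
  expect_equal(nrow(harm), 6)
  expect_equal(sum(harm$status == "kept"), 3)
  audit <- harmonisation_audit(harm)
  reasons <- setNames(audit$n_variants, audit$exclusion_reason)
  expect_equal(unname(reasons["palindromic-ambiguous"]), 1L)
  expect_equal(unname(reasons["allele-mismatch"]), 1L)
  expect_equal(unname(reasons["not-in-outcome"]), 1L)
})

test_that("disjoint variant sets exclude everything as not-in-outcome", {
  exposure <- make_sumstats(n = 3)
  outcome <- make_sumstats(n = 3, snp = c("x1", "x2", "x3"))
  harm <- harmonise_tables(exposure, outcome)
  expect_true(all(harm$status == "excluded"))
  expect_true(all(harm$exclusion_reason == "not-in-outcome"))
})

test_that("identical tables harmonise to themselves with no flips", {
  tab <- make_sumstats(n = 5, beta = rnorm(5))
  harm <- harmonise_tables(tab, tab)
  expect_true(all(harm$status == "kept"))
  expect_false(any(harm$orientation_flipped))
  expect_false(any(harm$strand_complemented))
  expect_equal(harm$beta_out, tab$beta)
})

test_that("harmonisation is idempotent on an already-harmonised pair", {
  exp_row <- row_for("A", "G", beta = 0.1)
  out_row <- row_for("G", "A", beta = -0.05, eaf = 0.7)
  h1 <- harmonise_pair(exp_row, out_row)
  # re-feed the harmonised orientation as a fresh outcome row
  out2 <- row_for(h1$effect_allele, h1$other_allele, beta = h1$beta_out,
                  eaf = h1$eaf_out)
  h2 <- harmonise_pair(exp_row, out2)
  expect_equal(h2$beta_out, h1$beta_out)
  expect_equal(h2$eaf_out, h1$eaf_out)
  expect_false(h2$orientation_flipped)
})

test_that("jointly flipping both tables' effect alleles leaves betas invariant", {
  set.seed(42)
  for (rep in 1:20) {
    ea <- sample(c("A", "C"), 1)
    oa <- if (ea == "A") "G" else "T"
    b_exp <- rnorm(1); b_out <- rnorm(1); eaf <- runif(1, 0.05, 0.95)
    e1 <- row_for(ea, oa, beta = b_exp, eaf = eaf)
    o1 <- row_for(ea, oa, beta = b_out, eaf = eaf)
    h1 <- harmonise_pair(e1, o1)
    # flip the labelled effect allele in BOTH tables
    e2 <- row_for(oa, ea, beta = -b_exp, eaf = 1 - eaf)
    o2 <- row_for(oa, ea, beta = -b_out, eaf = 1 - eaf)
    h2 <- harmonise_pair(e2, o2)
    expect_equal(h1$status, "kept")
    expect_equal(h2$status, "kept")
    # the (beta_exp, beta_out) pair is the same association up to joint sign
    expect_equal(h2$beta_exp * h2$beta_out, h1$beta_exp * h1$beta_out)
  }
})

test_that("widening the ambiguity window never rescues an excluded palindrome", {
  eafs <- seq(0.05, 0.95, by = 0.05)
  narrow <- c(0.45, 0.55)
  wide <- c(0.35, 0.65)
  for (f in eafs) {
    h_n <- harmonise_pair(row_for("A", "T", eaf = f),
                          row_for("A", "T", eaf = f),
                          ambiguity_window = narrow)
    h_w <- harmonise_pair(row_for("A", "T", eaf = f),
                          row_for("A", "T", eaf = f),
                          ambiguity_window = wide)
    if (h_n$status == "excluded") expect_equal(h_w$status, "excluded")
  }
})
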
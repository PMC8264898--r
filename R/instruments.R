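#' Construct an LD matrix object
#'
#' A small container for pairwise squared correlations (r-squared) between
#' variants, as used by [ld_clump()]. The matrix must be symmetric with a
#' unit diagonal and values in \[0, 1\].
#'
#' @param r2 Square numeric matrix of squared correlations.
#' @param variant_ids Character vector of variant identifiers; defaults to
#'   the matrix's row names.
#' @return An object of class `ld_matrix`.
#' @export
ld_matrix <- function(r2, variant_ids = rownames(r2)) {
  r2 <- as.matrix(r2)
  if (is.null(variant_ids)) stop("variant_ids required", call. = FALSE)
  variant_ids <- as.character(variant_ids)
  if (nrow(r2) != ncol(r2) || nrow(r2) != length(variant_ids)) {
    stop("r2 must be square with one row per variant id", call. = FALSE)
  }
  if (anyDuplicated(variant_ids)) stop("duplicate variant ids", call. = FALSE)
  if (any(r2 < 0 | r2 > 1)) stop("r2 values must lie in [0, 1]", call. = FALSE)
  if (max(abs(r2 - t(r2))) > 1e-8) stop("r2 must be symmetric", call. = FALSE)
  if (max(abs(diag(r2) - 1)) > 1e-8) stop("r2 diagonal must be 1", call. = FALSE)
  dimnames(r2) <- list(variant_ids, variant_ids)
  structure(list(variant_ids = variant_ids, r2 = r2), class = "ld_matrix")
}

#' Read / write an LD matrix
#'
#' File format: tab-separated, header row of variant identifiers, square
#' numeric body with one row per variant in header order.
#'
#' @param path File path.
#' @return `read_ld_matrix()` returns an `ld_matrix`;
#'   `write_ld_matrix()` returns `path` invisibly.
#' @export
read_ld_matrix <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "d"),
                         progress = FALSE)
  m <- as.matrix(raw)
  rownames(m) <- colnames(m)
  ld_matrix(m)
}

#' @rdname read_ld_matrix
#' @param ld An `ld_matrix` object.
#' @export
write_ld_matrix <- function(ld, path) {
  df <- as_tibble(as.data.frame(ld$r2))
  names(df) <- ld$variant_ids
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Filter to genome-wide significant variants
#'
#' Retains rows whose p-value is strictly below `threshold`, preserving
#' input order.
#'
#' @param table A `summary_stats` table.
#' @param threshold Significance threshold in (0, 1); conventionally
#'   5e-8, or 5e-9 for the stricter lung-function GWAS convention.
#' @return The filtered table (class preserved).
#' @export
select_significant <- function(table, threshold = 5e-8) {
  stopifnot(threshold > 0, threshold < 1)
  restore_sumstats(as_tibble(table)[table$pval < threshold, , drop = FALSE],
                   table)
}

#' Greedy LD clumping
#'
#' Standard index-variant clumping: variants are ranked by ascending
#' p-value; the best remaining variant is accepted and every other variant
#' on the same chromosome within `window_kb` kilobases *and* with squared
#' correlation at least `r2_threshold` against it is discarded; repeat
#' until no variants remain. Ties on p-value are broken by (chromosome,
#' position) for determinism. Variants absent from `ld` are treated as
#' independent (r-squared 0) with a warning.
#'
#' @param table A `summary_stats` table.
#' @param ld An [ld_matrix()], or `NULL` to treat all variants as
#'   independent.
#' @param window_kb Clumping window in kilobases (default 10000).
#' @param r2_threshold Squared-correlation threshold (default 0.001).
#' @return The clumped table, sorted by genomic position.
#' @export
ld_clump <- function(table, ld = NULL, window_kb = 10000,
                     r2_threshold = 0.001) {
  tab <- as_tibble(table)
  if (nrow(tab) == 0) return(restore_sumstats(tab, table))
  if (!is.null(ld)) {
    absent <- setdiff(tab$snp, ld$variant_ids)
    if (length(absent) > 0) {
      warning(length(absent),
              " variant(s) absent from the LD matrix treated as independent",
              call. = FALSE)
    }
  }
  r2_of <- function(a, b) {
    if (is.null(ld)) return(0)
    if (!(a %in% ld$variant_ids) || !(b %in% ld$variant_ids)) return(0)
    ld$r2[a, b]
  }
  ord <- order(tab$pval, tab$chrom, tab$pos)
  remaining <- ord
  keep <- integer(0)
  while (length(remaining) > 0) {
    i <- remaining[1]
    keep <- c(keep, i)
    remaining <- remaining[-1]
    if (length(remaining) == 0) break
    drop <- vapply(remaining, function(j) {
      tab$chrom[j] == tab$chrom[i] &&
        abs(tab$pos[j] - tab$pos[i]) <= window_kb * 1000 &&
        r2_of(tab$snp[j], tab$snp[i]) >= r2_threshold
    }, logical(1))
    remaining <- remaining[!drop]
  }
  out <- tab[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  restore_sumstats(out, table)
}

#' Instrument-strength F-statistic
#'
#' The per-variant F-statistic, beta^2 / SE^2. Values above 10 are the
#' conventional indication that weak-instrument bias is unlikely.
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s), strictly positive.
#' @return Numeric vector of F-statistics.
#' @export
f_statistic <- function(beta, se) {
  if (any(se <= 0)) stop("se must be positive", call. = FALSE)
  beta^2 / se^2
}

#' Steiger directionality filtering
#'
#' Removes instruments that explain more variance in the outcome than in
#' the exposure, which (if present) points to reverse causation, a
#' confounder path or a direct effect. Variance explained is computed from
#' the t-statistic as r^2 = t^2 / (t^2 + n - 2) on each trait's reported
#' scale; a variant is retained iff r^2(exposure) > r^2(outcome).
#'
#' @param instruments A `harmonised` table (kept rows) with `beta_exp`,
#'   `se_exp`, `beta_out`, `se_out` and per-variant `n_exp`, `n_out`
#'   columns (scalar overrides may be supplied).
#' @param n_exp,n_out Optional scalar sample sizes overriding the
#'   per-variant columns.
#' @param mode `"directional"` (strict comparison, the default) or
#'   `"ztest"`, which additionally requires the difference to be
#'   significant at `alpha` under a normal approximation to the difference
#'   of Fisher-transformed correlations.
#' @param alpha One-sided level for `mode = "ztest"`.
#' @return The input tibble with `r2_exp`, `r2_out` and `steiger_keep`
#'   columns; rows failing the filter are dropped. The full annotated
#'   table (including dropped rows) is in the `"steiger"` attribute.
#' @export
steiger_filter <- function(instruments, n_exp = NULL, n_out = NULL,
                           mode = c("directional", "ztest"), alpha = 0.05) {
  mode <- match.arg(mode)
  dat <- as_tibble(instruments)
  nx <- n_exp %||% dat$n_exp
  ny <- n_out %||% dat$n_out
  if (any(nx <= 2) || any(ny <= 2)) {
    stop("sample sizes must exceed 2", call. = FALSE)
  }
  tx <- dat$beta_exp / dat$se_exp
  ty <- dat$beta_out / dat$se_out
  r2x <- tx^2 / (tx^2 + nx - 2)
  r2y <- ty^2 / (ty^2 + ny - 2)
  keep <- r2x > r2y
  if (mode == "ztest") {
    # Fisher z on |r|; retain unless outcome r2 significantly exceeds
    # exposure r2 is NOT enough -- require exposure significantly larger.
    zx <- atanh(pmin(sqrt(r2x), 1 - 1e-12))
    zy <- atanh(pmin(sqrt(r2y), 1 - 1e-12))
    zstat <- (zx - zy) / sqrt(1 / (nx - 3) + 1 / (ny - 3))
    keep <- keep & (stats::pnorm(zstat, lower.tail = FALSE) < alpha)
  }
  annotated <- dplyr::mutate(dat, r2_exp = r2x, r2_out = r2y,
                             steiger_keep = keep)
  out <- annotated[keep, , drop = FALSE]
  attr(out, "steiger") <- annotated
  class(out) <- unique(c("harmonised", class(out)))
  out
}

#' Run the full instrument-selection pipeline
#'
#' Applies, in order: genome-wide significance filtering of the exposure
#' table, greedy LD clumping, harmonisation against the outcome table
#' (including palindrome exclusion), and Steiger directionality filtering;
#' then computes per-variant F-statistics of the survivors.
#'
#' @param exposure,outcome `summary_stats` tables.
#' @param ld Optional [ld_matrix()] for clumping.
#' @param sig_threshold Significance threshold (default 5e-8).
#' @param window_kb,r2_threshold Clumping parameters (defaults 10000 kb,
#'   0.001).
#' @param ambiguity_window Palindrome EAF ambiguity interval.
#' @param steiger Logical; apply Steiger filtering (default `TRUE`).
#' @return A list of class `instrument_pipeline`:
#'   * `instruments` — kept `harmonised` rows with `f_stat` column;
#'   * `report` — tibble of stage counts (`stage`, `n_variants`);
#'   * `mean_f` — arithmetic mean F-statistic of the survivors;
#'   * `harmonisation` — the full harmonised table with exclusions.
#' @export
run_instrument_pipeline <- function(exposure, outcome, ld = NULL,
                                    sig_threshold = 5e-8,
                                    window_kb = 10000, r2_threshold = 0.001,
                                    ambiguity_window = c(0.42, 0.58),
                                    steiger = TRUE) {
  n_input <- nrow(exposure)
  sig <- select_significant(exposure, sig_threshold)
  clumped <- ld_clump(sig, ld, window_kb, r2_threshold)
  harm <- harmonise_tables(clumped, outcome, ambiguity_window)
  kept <- kept_instruments(harm)
  n_harm <- nrow(kept)
  if (steiger && n_harm > 0) kept <- steiger_filter(kept)
  if (nrow(kept) == 0) {
    stop("no-instruments: no variants survived the selection pipeline",
         call. = FALSE)
  }
  kept$f_stat <- f_statistic(kept$beta_exp, kept$se_exp)
  report <- tibble(
    stage = c("input", "significance", "clump", "harmonise", "steiger"),
    n_variants = c(n_input, nrow(sig), nrow(clumped), n_harm, nrow(kept))
  )
  structure(
    list(instruments = kept, report = report,
         mean_f = mean(kept$f_stat), harmonisation = harm),
    class = "instrument_pipeline"
  )
}

#' @export
print.instrument_pipeline <- function(x, ...) {
  cat("Instrument selection pipeline\n")
  for (i in seq_len(nrow(x$report))) {
    cat(sprintf("  %-13s %d variants\n",
                x$report$stage[i], x$report$n_variants[i]))
  }
  cat(sprintf("  mean F-statistic of survivors: %.1f\n", x$mean_f))
  invisible(x)
}
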
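#' Format an MR results table for publication
#'
#' Renders pooled estimates the way MR papers print them: odds ratio per
#' SD and its 95% CI to two decimals (round half to even) with a
#' `"low to high"` CI string, plus p-value and heterogeneity Q p-value.
#' Full-precision values stay in the results TSV; this is presentation
#' only.
#'
#' @param results An `mr_result` table.
#' @param digits Decimal places for OR and CI (default 2).
#' @return A tibble with columns `method`, `n_snp`, `or_per_sd`, `ci_95`,
#'   `p_value`, `q_pval`.
#' @export
format_results_table <- function(results, digits = 2) {
  dat <- as_tibble(results)
  fmt <- function(x) {
    ifelse(is.na(x), "NA",
           formatC(round(x, digits), format = "f", digits = digits))
  }
  fmt_p <- function(p) ifelse(is.na(p), "NA", formatC(p, format = "g",
                                                      digits = 2))
  method_label <- c(
    ivw = "IVW", egger = "MR Egger", weighted_median = "Weighted median",
    weighted_mode = "Weighted mode", wald_ratio = "Wald ratio"
  )
  tibble(
    method = unname(method_label[dat$method]),
    n_snp = dat$n_snp,
    or_per_sd = fmt(dat$or),
    ci_95 = paste(fmt(dat$or_ci_low), "to", fmt(dat$or_ci_high)),
    p_value = fmt_p(dat$pval),
    q_pval = fmt_p(dat$q_pval)
  )
}

#' Run the complete MR analysis from files
#'
#' End-to-end driver: reads exposure/outcome summary statistics (and an
#' optional LD matrix), runs the instrument-selection pipeline
#' (significance, clumping, harmonisation, Steiger), fits every
#' applicable estimator and the sensitivity suite, and writes a results
#' bundle under `output_dir`:
#' `results.tsv` (full precision), `results_formatted.tsv`,
#' `instruments.tsv`, `harmonisation_audit.tsv`, `pipeline_report.tsv`,
#' `leave_one_out.tsv`, `single_snp.tsv`, `funnel.tsv` and
#' `manifest.json` (all parameters, seed, package version).
#'
#' @param exposure_path,outcome_path Summary-statistics TSV paths.
#' @param output_dir Directory for the results bundle (created).
#' @param ld_path Optional LD-matrix TSV path.
#' @param exposure_map,outcome_map Optional `column_map`s for
#'   [read_summary_stats()].
#' @param outcome_scale Trait scale of the outcome.
#' @param sig_threshold,window_kb,r2_threshold,ambiguity_window,steiger
#'   Pipeline parameters, see [run_instrument_pipeline()].
#' @param n_boot,seed Bootstrap replicates and seed, see [mr_all()].
#' @return Invisibly, a list with `results`, `pipeline`, `sensitivity`
#'   and the file paths written.
#' @export
run_mr_files <- function(exposure_path, outcome_path, output_dir,
                         ld_path = NULL,
                         exposure_map = NULL, outcome_map = NULL,
                         outcome_scale = "log_odds",
                         sig_threshold = 5e-8, window_kb = 10000,
                         r2_threshold = 0.001,
                         ambiguity_window = c(0.42, 0.58), steiger = TRUE,
                         n_boot = 1000, seed = NULL) {
  if (!is.null(ld_path) && !file.exists(ld_path)) {
    stop("LD matrix file not found: ", ld_path, call. = FALSE)
  }
  if (is.null(seed)) stop("a seed is required (bootstrap estimators)",
                          call. = FALSE)
  exposure <- read_summary_stats(exposure_path, exposure_map,
                                 trait_scale = "continuous_sd")
  outcome <- read_summary_stats(outcome_path, outcome_map,
                                trait_scale = outcome_scale)
  ld <- if (!is.null(ld_path)) read_ld_matrix(ld_path) else NULL

  pipe <- run_instrument_pipeline(
    exposure, outcome, ld, sig_threshold = sig_threshold,
    window_kb = window_kb, r2_threshold = r2_threshold,
    ambiguity_window = ambiguity_window, steiger = steiger
  )
  for (i in seq_len(nrow(pipe$report))) {
    message(sprintf("stage %-13s: %d variants", pipe$report$stage[i],
                    pipe$report$n_variants[i]))
  }
  results <- mr_all(pipe$instruments, n_boot = n_boot, seed = seed)
  sens <- if (nrow(pipe$instruments) >= 2) {
    mr_sensitivity(pipe$instruments)
  } else NULL

  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    results = file.path(output_dir, "results.tsv"),
    results_formatted = file.path(output_dir, "results_formatted.tsv"),
    instruments = file.path(output_dir, "instruments.tsv"),
    audit = file.path(output_dir, "harmonisation_audit.tsv"),
    report = file.path(output_dir, "pipeline_report.tsv"),
    manifest = file.path(output_dir, "manifest.json")
  )
  readr::write_tsv(tidy(results), paths$results, progress = FALSE)
  readr::write_tsv(format_results_table(results), paths$results_formatted,
                   progress = FALSE)
  readr::write_tsv(pipe$instruments, paths$instruments, progress = FALSE)
  readr::write_tsv(harmonisation_audit(pipe$harmonisation), paths$audit,
                   progress = FALSE)
  readr::write_tsv(pipe$report, paths$report, progress = FALSE)
  if (!is.null(sens)) {
    paths$leave_one_out <- file.path(output_dir, "leave_one_out.tsv")
    paths$single_snp <- file.path(output_dir, "single_snp.tsv")
    paths$funnel <- file.path(output_dir, "funnel.tsv")
    readr::write_tsv(sens$leave_one_out, paths$leave_one_out,
                     progress = FALSE)
    readr::write_tsv(sens$single_snp, paths$single_snp, progress = FALSE)
    readr::write_tsv(sens$funnel, paths$funnel, progress = FALSE)
  }
  manifest <- list(
    package = "tsmr",
    version = as.character(utils::packageVersion("tsmr")),
    exposure_path = exposure_path, outcome_path = outcome_path,
    ld_path = ld_path, outcome_scale = outcome_scale,
    sig_threshold = sig_threshold, window_kb = window_kb,
    r2_threshold = r2_threshold, ambiguity_window = ambiguity_window,
    steiger = steiger, n_boot = n_boot, seed = seed,
    stage_counts = stats::setNames(as.list(pipe$report$n_variants),
                                   pipe$report$stage),
    mean_f = pipe$mean_f
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(results = results, pipeline = pipe, sensitivity = sens,
                 paths = paths))
}

#' Write a simulated dataset bundle to disk
#'
#' Materialises a [simulate_two_sample()] draw as the canonical TSV
#' dialect: `exposure.tsv`, `outcome.tsv`, `ground_truth.tsv`,
#' `ld_matrix.tsv` and a `manifest.json` recording the scenario and seed.
#'
#' @param scenario Scenario name for [mr_scenario()] or a [sim_config()].
#' @param seed Integer seed.
#' @param output_dir Output directory (created).
#' @return Invisibly, the list of file paths written.
#' @export
simulate_to_dir <- function(scenario, seed, output_dir) {
  sim <- simulate_two_sample(scenario, seed)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    exposure = file.path(output_dir, "exposure.tsv"),
    outcome = file.path(output_dir, "outcome.tsv"),
    truth = file.path(output_dir, "ground_truth.tsv"),
    ld = file.path(output_dir, "ld_matrix.tsv"),
    manifest = file.path(output_dir, "manifest.json")
  )
  write_summary_stats(sim$exposure, paths$exposure)
  write_summary_stats(sim$outcome, paths$outcome)
  readr::write_tsv(sim$truth, paths$truth, progress = FALSE)
  write_ld_matrix(sim$ld, paths$ld)
  jsonlite::write_json(
    list(package = "tsmr",
         version = as.character(utils::packageVersion("tsmr")),
         scenario = if (is.character(scenario)) scenario else "custom",
         theta = sim$config$theta, n_snps = sim$config$n_snps,
         outcome_scale = sim$config$outcome_scale, seed = sim$seed),
    paths$manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(paths)
}
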
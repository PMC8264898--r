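#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# Canonical column set of a summary-statistics table, in file-dialect order.
# File headers are SNP/CHR/BP/EA/OA/EAF/BETA/SE/P/N; internal names are
# lower-case and descriptive.
sumstats_cols <- c(
  snp = "SNP", chrom = "CHR", pos = "BP", effect_allele = "EA",
  other_allele = "OA", eaf = "EAF", beta = "BETA", se = "SE",
  pval = "P", n = "N"
)

valid_alleles <- c("A", "C", "G", "T")

#' Construct a summary-statistics table
#'
#' Builds a validated per-variant association table for one trait. Each row
#' is one biallelic SNP's association: effect allele, other allele, effect
#' allele frequency, effect size (per SD of a continuous trait or log-odds
#' for a binary trait), standard error, p-value and sample size. Rows that
#' violate the field invariants are dropped and recorded with a reason in
#' the `"rejections"` attribute (see [rejected_rows()]).
#'
#' @param data A data frame with columns `snp`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#'   `eaf` is the only column allowed to be missing (`NA`).
#' @param trait_label Character label for the trait.
#' @param trait_scale `"continuous_sd"` (beta per SD) or `"log_odds"`.
#' @return A tibble of class `summary_stats` containing the accepted rows,
#'   with attributes `trait_label`, `trait_scale` and `rejections`.
#' @export
summary_stats <- function(data, trait_label = "trait",
                          trait_scale = c("continuous_sd", "log_odds")) {
  trait_scale <- match.arg(trait_scale)
  needed <- names(sumstats_cols)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dat <- as_tibble(data)[needed]
  dat$snp <- as.character(dat$snp)
  dat$chrom <- as.character(dat$chrom)
  dat$effect_allele <- toupper(as.character(dat$effect_allele))
  dat$other_allele <- toupper(as.character(dat$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    dat[[col]] <- suppressWarnings(as.numeric(dat[[col]]))
  }

  reason <- rep(NA_character_, nrow(dat))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- TRUE
    reason[is.na(reason) & bad] <<- why
  }
  flag(is.na(dat$snp) | dat$snp == "", "missing variant id")
  flag(duplicated(dat$snp), "duplicate variant id")
  flag(!(dat$effect_allele %in% valid_alleles), "non-SNP effect allele")
  flag(!(dat$other_allele %in% valid_alleles), "non-SNP other allele")
  flag(dat$effect_allele == dat$other_allele, "identical alleles")
  flag(is.na(dat$pos) | dat$pos < 1 | dat$pos != round(dat$pos),
       "invalid position")
  flag(is.na(dat$beta), "unparseable beta")
  flag(is.na(dat$se) | dat$se <= 0, "non-positive SE")
  flag(is.na(dat$pval) | dat$pval <= 0 | dat$pval > 1, "p-value outside (0,1]")
  flag(is.na(dat$n) | dat$n <= 0, "non-positive sample size")
  # eaf may be NA; if present it must be an interior proportion
  bad_eaf <- !is.na(dat$eaf) & (dat$eaf <= 0 | dat$eaf >= 1)
  reason[is.na(reason) & bad_eaf] <- "EAF outside (0,1)"

  rejections <- tibble(
    row = which(!is.na(reason)),
    snp = dat$snp[!is.na(reason)],
    reason = reason[!is.na(reason)]
  )
  kept <- dat[is.na(reason), , drop = FALSE]
  new_summary_stats(kept, trait_label, trait_scale, rejections)
}

new_summary_stats <- function(data, trait_label, trait_scale, rejections) {
  out <- as_tibble(data)
  attr(out, "trait_label") <- trait_label
  attr(out, "trait_scale") <- trait_scale
  attr(out, "rejections") <- rejections
  class(out) <- c("summary_stats", class(out))
  out
}

# Re-attach summary_stats attributes after dplyr verbs strip the class.
restore_sumstats <- function(data, template) {
  new_summary_stats(
    as_tibble(data),
    trait_label = attr(template, "trait_label") %||% "trait",
    trait_scale = attr(template, "trait_scale") %||% "continuous_sd",
    rejections = attr(template, "rejections") %||%
      tibble(row = integer(), snp = character(), reason = character())
  )
}

#' Rows rejected during table validation
#'
#' @param x A `summary_stats` object.
#' @return A tibble with columns `row` (position in the input), `snp` and
#'   `reason`; zero rows when every input row validated.
#' @export
rejected_rows <- function(x) {
  attr(x, "rejections") %||%
    tibble(row = integer(), snp = character(), reason = character())
}

#' Trait scale of a summary-statistics table
#' @param x A `summary_stats` object.
#' @return `"continuous_sd"` or `"log_odds"`.
#' @export
trait_scale <- function(x) attr(x, "trait_scale") %||% "continuous_sd"

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("# GWAS summary statistics: %s (%s), %d variants\n",
              attr(x, "trait_label") %||% "trait",
              trait_scale(x), nrow(x)))
  rej <- rejected_rows(x)
  if (nrow(rej) > 0) {
    cat(sprintf("# %d input rows rejected at validation\n", nrow(rej)))
  }
  NextMethod()
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-delimited summary-statistics file into a validated
#' [summary_stats()] table. The canonical dialect has a header row with
#' columns `SNP`, `CHR`, `BP`, `EA`, `OA`, `EAF`, `BETA`, `SE`, `P`, `N`;
#' other dialects are mapped via `column_map`. Missing values are written
#' as `NA`, and only `EAF` may be missing. Rows failing validation (e.g.
#' non-positive SE, indel alleles) are rejected with a per-row reason,
#' retrievable with [rejected_rows()].
#'
#' @param path Path to a tab-separated file with a header row.
#' @param column_map Named character vector mapping canonical dialect names
#'   to the file's actual headers, e.g.
#'   `c(SNP = "rsid", BETA = "effect")`. Unmapped canonical names are
#'   looked up verbatim.
#' @param trait_scale `"continuous_sd"` or `"log_odds"`.
#' @param trait_label Trait label; defaults to the file name.
#' @return A `summary_stats` tibble.
#' @export
read_summary_stats <- function(path, column_map = NULL,
                               trait_scale = c("continuous_sd", "log_odds"),
                               trait_label = NULL) {
  trait_scale <- match.arg(trait_scale)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = "NA", progress = FALSE)
  header <- sumstats_cols
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), unname(sumstats_cols))
    if (length(bad) > 0) {
      stop("unknown canonical column(s) in column_map: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    header[match(names(column_map), sumstats_cols)] <- unname(column_map)
  }
  absent <- setdiff(unname(header), names(raw))
  if (length(absent) > 0) {
    stop("column(s) not present in ", path, ": ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  dat <- raw[unname(header)]
  names(dat) <- names(header)
  summary_stats(dat, trait_label = trait_label %||% basename(path),
                trait_scale = trait_scale)
}

#' Write a GWAS summary-statistics table
#'
#' Serialises a [summary_stats()] table to the canonical tab-separated
#' dialect (`SNP CHR BP EA OA EAF BETA SE P N`) at full numeric precision,
#' so that `read_summary_stats(write_summary_stats(x))` reproduces `x`
#' field for field. Missing `EAF` is written as `NA`.
#'
#' @param table A `summary_stats` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(table, path) {
  out <- as_tibble(table)[names(sumstats_cols)]
  names(out) <- unname(sumstats_cols)
  num <- function(x) {
    y <- vapply(x, function(v) {
      if (is.na(v)) NA_character_ else format(v, digits = 17, scientific = NA)
    }, character(1))
    y
  }
  for (col in c("BP", "EAF", "BETA", "SE", "P", "N")) out[[col]] <- num(out[[col]])
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
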
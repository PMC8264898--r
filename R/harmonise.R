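#' Complement a nucleotide allele
#'
#' @param allele Character vector of single-base alleles (`A`, `C`, `G`, `T`).
#' @return The Watson-Crick complement of each allele.
#' @export
complement_alleles <- function(allele) {
  allele <- toupper(allele)
  if (!all(allele %in% valid_alleles)) {
    stop("allele must be one of A, C, G, T", call. = FALSE)
  }
  unname(c(A = "T", C = "G", G = "C", T = "A")[allele])
}

#' Is an allele pair palindromic?
#'
#' A palindromic (strand-ambiguous) SNP has alleles that are each other's
#' complement: A/T or C/G. For such variants the strand cannot be resolved
#' from the alleles alone.
#'
#' @param effect_allele,other_allele Character vectors of alleles.
#' @return Logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  toupper(other_allele) == complement_alleles(effect_allele)
}

# Vectorised harmonisation core. `e` and `o` are equal-length data frames
# (one matched outcome row per exposure row; missing matches as NA rows).
harmonise_matched <- function(e, o, ambiguity_window) {
  k <- nrow(e)
  ea_x <- e$effect_allele; oa_x <- e$other_allele
  ea_y <- o$effect_allele; oa_y <- o$other_allele
  in_outcome <- !is.na(ea_y)

  flip <- rep(FALSE, k)
  comp <- rep(FALSE, k)
  status <- rep("kept", k)
  reason <- rep("", k)

  cea_y <- ifelse(in_outcome, unname(c(A = "T", C = "G", G = "C",
                                       T = "A")[ea_y]), NA)
  coa_y <- ifelse(in_outcome, unname(c(A = "T", C = "G", G = "C",
                                       T = "A")[oa_y]), NA)
  pal <- is_palindromic(ea_x, oa_x)

  same <- in_outcome & ea_y == ea_x & oa_y == oa_x
  swapped <- in_outcome & ea_y == oa_x & oa_y == ea_x
  csame <- in_outcome & !pal & cea_y == ea_x & coa_y == oa_x
  cswapped <- in_outcome & !pal & cea_y == oa_x & coa_y == ea_x

  # non-palindromic resolution: label match, swap, complemented variants
  npal <- !pal
  flip[npal & swapped] <- TRUE
  comp[npal & (csame | cswapped)] <- TRUE
  flip[npal & cswapped] <- TRUE
  mismatch <- in_outcome & npal & !(same | swapped | csame | cswapped)

  # palindromic resolution: same-order and swapped labels both match, so
  # orientation must come from allele-frequency agreement
  pal_lbl <- pal & in_outcome & (same | swapped)
  mismatch <- mismatch | (pal & in_outcome & !(same | swapped))
  eaf_y_on_x <- ifelse(ea_y == ea_x, o$eaf, 1 - o$eaf)
  in_win <- function(f) !is.na(f) & f >= ambiguity_window[1] &
    f <= ambiguity_window[2]
  ambiguous <- pal_lbl & (is.na(e$eaf) | is.na(o$eaf) |
                            in_win(e$eaf) | in_win(eaf_y_on_x))
  consistent <- pal_lbl & !ambiguous &
    ((e$eaf < 0.5) == (eaf_y_on_x < 0.5))
  inconsistent <- pal_lbl & !ambiguous & !consistent
  # frequency-consistent: the labels mean what they say
  flip[consistent & ea_y != ea_x] <- TRUE
  # frequencies disagree: the outcome is reported on the other strand
  comp[inconsistent] <- TRUE
  flip[inconsistent & ea_y == ea_x] <- TRUE

  status[!in_outcome] <- "excluded"; reason[!in_outcome] <- "not-in-outcome"
  status[mismatch] <- "excluded"; reason[mismatch] <- "allele-mismatch"
  status[ambiguous] <- "excluded"; reason[ambiguous] <- "palindromic-ambiguous"
  excluded <- status == "excluded"
  flip[excluded] <- FALSE
  comp[excluded] <- FALSE

  beta_out <- ifelse(flip, -o$beta, o$beta)
  eaf_out <- ifelse(flip, 1 - o$eaf, o$eaf)
  out <- tibble(
    snp = e$snp, chrom = e$chrom, pos = e$pos,
    effect_allele = ea_x, other_allele = oa_x,
    beta_exp = e$beta, se_exp = e$se, eaf_exp = e$eaf,
    pval_exp = e$pval, n_exp = e$n,
    beta_out = beta_out, se_out = o$se, eaf_out = eaf_out,
    pval_out = o$pval, n_out = o$n,
    status = status, exclusion_reason = reason,
    orientation_flipped = flip, strand_complemented = comp
  )
  out[excluded & reason == "not-in-outcome",
      c("beta_out", "se_out", "eaf_out", "pval_out", "n_out")] <- NA_real_
  out
}

#' Harmonise one exposure/outcome variant pair
#'
#' Places the outcome association on the exposure's effect-allele
#' orientation. Resolution order: (1) alleles match as given — keep;
#' (2) alleles match swapped — negate the outcome beta and reflect its EAF;
#' (3) alleles match after strand complementation — complement, then apply
#' (1)/(2); (4) palindromic pair — excluded as `"palindromic-ambiguous"`
#' when either EAF is missing or falls inside `ambiguity_window`, otherwise
#' aligned by frequency agreement (both EAFs on the same side of 0.5 means
#' same orientation); (5) anything else — excluded as `"allele-mismatch"`.
#'
#' @param exp,out One-row data frames (or single rows of a
#'   [summary_stats()] table) for the same `snp`.
#' @param ambiguity_window Numeric length-2: EAF interval within which a
#'   palindromic SNP is considered unresolvable. Default `c(0.42, 0.58)`.
#' @return A one-row tibble with the harmonised pair, its `status`
#'   (`"kept"`/`"excluded"`), `exclusion_reason`, and the
#'   `orientation_flipped`/`strand_complemented` flags.
#' @export
harmonise_pair <- function(exp, out, ambiguity_window = c(0.42, 0.58)) {
  if (exp$snp != out$snp) {
    stop("exposure and outcome rows refer to different variants", call. = FALSE)
  }
  harmonise_matched(as_tibble(exp), as_tibble(out), ambiguity_window)
}

#' Harmonise exposure and outcome summary-statistics tables
#'
#' Matches variants by identifier and places every exposure/outcome pair
#' on the exposure's effect-allele orientation (see [harmonise_pair()]
#' for the resolution rules). Exposure variants absent from the outcome
#' table are excluded with reason `"not-in-outcome"`. The result carries
#' an audit of exclusion counts in its `"audit"` attribute (see
#' [harmonisation_audit()]).
#'
#' @param exposure,outcome `summary_stats` tables (or data frames with the
#'   same columns).
#' @param ambiguity_window Palindrome EAF ambiguity interval, see
#'   [harmonise_pair()].
#' @return A tibble of class `harmonised` with one row per exposure
#'   variant.
#' @export
harmonise_tables <- function(exposure, outcome,
                             ambiguity_window = c(0.42, 0.58)) {
  exposure <- as_tibble(exposure)
  outcome <- as_tibble(outcome)
  idx <- match(exposure$snp, outcome$snp)
  matched <- outcome[idx, , drop = FALSE]
  matched$snp <- exposure$snp  # NA rows keep the exposure id
  out <- harmonise_matched(exposure, matched, ambiguity_window)
  audit <- out |>
    dplyr::count(.data$status, .data$exclusion_reason, name = "n_variants") |>
    dplyr::arrange(dplyr::desc(.data$status == "kept"))
  attr(out, "audit") <- audit
  class(out) <- c("harmonised", class(out))
  out
}

#' Harmonisation audit counts
#'
#' @param x A `harmonised` table from [harmonise_tables()].
#' @return A tibble of counts per `status`/`exclusion_reason`.
#' @export
harmonisation_audit <- function(x) {
  attr(x, "audit") %||%
    dplyr::count(as_tibble(x), .data$status, .data$exclusion_reason,
                 name = "n_variants")
}

#' Kept instruments from a harmonised table
#'
#' @param x A `harmonised` table.
#' @return The kept rows, ordered by chromosome and position.
#' @export
kept_instruments <- function(x) {
  as_tibble(x) |>
    dplyr::filter(.data$status == "kept") |>
    dplyr::arrange(.data$chrom, .data$pos)
}
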
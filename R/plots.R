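#' Scatter plot of SNP-outcome against SNP-exposure effects
#'
#' Each point is one instrument (outcome association against exposure
#' association, with error bars); lines show each fitted estimator's
#' slope (and the Egger intercept).
#'
#' @param instruments A harmonised instrument table.
#' @param results An `mr_result` table from [mr_all()] (optional; fitted
#'   lines are drawn for the methods present).
#' @return A ggplot object.
#' @export
plot_mr_scatter <- function(instruments, results = NULL) {
  dat <- as_tibble(instruments)
  flip <- ifelse(dat$beta_exp < 0, -1, 1)
  dat <- dplyr::mutate(dat, bx = .data$beta_exp * flip,
                       by = .data$beta_out * flip)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$bx, y = .data$by)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$by - 1.96 * .data$se_out,
                   ymax = .data$by + 1.96 * .data$se_out),
      width = 0, colour = "grey70") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$bx - 1.96 * .data$se_exp,
                   xmax = .data$bx + 1.96 * .data$se_exp),
      height = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "SNP effect on exposure", y = "SNP effect on outcome")
  if (!is.null(results)) {
    lines <- as_tibble(results) |>
      dplyr::filter(.data$method %in%
                      c("ivw", "egger", "weighted_median", "weighted_mode")) |>
      dplyr::mutate(
        slope = .data$estimate,
        yintercept = ifelse(.data$method == "egger", .data$intercept, 0)
      )
    p <- p + ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(slope = .data$slope, intercept = .data$yintercept,
                   colour = .data$method)
    ) +
      ggplot2::labs(colour = "Method")
  }
  p
}

#' Forest plot of single-SNP causal estimates
#'
#' @param single_snp Output of [mr_single_snp()].
#' @param or_scale Plot odds ratios (exponentiated) instead of log effects.
#' @return A ggplot object.
#' @export
plot_mr_forest <- function(single_snp, or_scale = FALSE) {
  dat <- dplyr::mutate(
    as_tibble(single_snp),
    snp = factor(.data$snp, levels = rev(.data$snp)),
    pooled = .data$snp == "All (IVW)"
  )
  if (or_scale) {
    dat <- dplyr::mutate(dat, estimate = exp(.data$estimate),
                         ci_low = exp(.data$ci_low),
                         ci_high = exp(.data$ci_high))
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$estimate, y = .data$snp)) +
    ggplot2::geom_vline(xintercept = if (or_scale) 1 else 0,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$pooled)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 18),
                                guide = "none") +
    ggplot2::labs(x = if (or_scale) "OR per SD" else "Causal estimate",
                  y = NULL)
}

#' Funnel plot of per-SNP estimates against precision
#'
#' @param funnel Output of [mr_funnel_data()].
#' @param pooled Optional pooled estimate drawn as a vertical line.
#' @return A ggplot object.
#' @export
plot_mr_funnel <- function(funnel, pooled = NULL) {
  p <- ggplot2::ggplot(as_tibble(funnel),
                       ggplot2::aes(x = .data$theta, y = .data$precision)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Per-SNP causal estimate", y = "Precision (1/SE)")
  if (!is.null(pooled)) {
    p <- p + ggplot2::geom_vline(xintercept = pooled, linetype = "dashed")
  }
  p
}

#' Leave-one-out plot
#'
#' @param loo Output of [mr_leave_one_out()].
#' @return A ggplot object.
#' @export
plot_mr_leave_one_out <- function(loo) {
  dat <- dplyr::mutate(
    as_tibble(loo),
    excluded_snp = factor(.data$excluded_snp, levels = rev(.data$excluded_snp))
  )
  ggplot2::ggplot(dat,
                  ggplot2::aes(x = .data$estimate, y = .data$excluded_snp)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "IVW estimate excluding the named SNP", y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot methods
#'
#' `autoplot()` on an `mr_sensitivity` report draws the funnel plot; on an
#' `mr_result` table it draws a method-level forest of the pooled
#' estimates.
#'
#' @param object An `mr_sensitivity` or `mr_result` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mr_sensitivity
#' @export
autoplot.mr_sensitivity <- function(object, ...) {
  pooled <- object$single_snp$estimate[object$single_snp$snp == "All (IVW)"]
  plot_mr_funnel(object$funnel, pooled = pooled)
}

#' @rdname autoplot.mr_sensitivity
#' @method autoplot mr_result
#' @export
autoplot.mr_result <- function(object, ...) {
  dat <- dplyr::mutate(as_tibble(object),
                       method = factor(.data$method,
                                       levels = rev(unique(.data$method))))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$estimate, y = .data$method)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Causal estimate (log scale)", y = NULL)
}
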
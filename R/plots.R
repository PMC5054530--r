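#' Plot a selection scan
#'
#' Manhattan-style panels of per-SNP Fst and -log10 Fisher q along the
#' chromosome, outliers highlighted and cutoffs drawn.
#'
#' @param object A `scan_result`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.scan_result <- function(object, ...) {
  d <- object$snps
  long <- dplyr::bind_rows(
    tibble::tibble(pos = d$pos, value = d$fst, outlier = d$is_fst_outlier,
                   panel = "Fst"),
    tibble::tibble(pos = d$pos, value = -log10(d$fisher_q),
                   outlier = d$is_fisher_outlier,
                   panel = "-log10(q), Fisher"))
  long <- long[is.finite(long$value), , drop = FALSE]
  cuts <- tibble::tibble(
    panel = c("Fst", "-log10(q), Fisher"),
    cutoff = c(object$thresholds$fst_cutoff,
               object$thresholds$neg_log10_q_cutoff))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pos / 1e6, y = .data$value,
                                     colour = .data$outlier)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_hline(data = cuts[is.finite(cuts$cutoff), ],
                        ggplot2::aes(yintercept = .data$cutoff),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "position (Mb)", y = NULL)
}

#' Plot windowed nucleotide diversity
#'
#' @param object A `diversity_track` from [windowed_pi()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.diversity_track <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = (.data$window_start +
                                      .data$window_end) / 2e6,
                               y = .data$pi)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "position (Mb)", y = expression(pi))
}

#' Plot the haplotype-frequency altitude cline
#'
#' @param object An `altitude_test` or `altitude_cor`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.altitude_test <- function(object, ...) {
  autoplot(object$correlation, ...)
}

#' @rdname autoplot.altitude_test
#' @export
autoplot.altitude_cor <- function(object, ...) {
  d <- object$records
  ggplot2::ggplot(d, ggplot2::aes(x = .data$altitude, y = .data$frequency)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey60", linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_chromosomes),
                        alpha = 0.8) +
    ggplot2::scale_size_area(max_size = 5, name = "chromosomes") +
    ggplot2::labs(
      x = "altitude (m)", y = "major-haplotype frequency",
      subtitle = sprintf("%s r = %.3f, two-sided p = %.3g (n = %d)",
                         object$method, object$r, object$p_value, object$n))
}

#' Plot the drift-test null distribution
#'
#' Histogram of per-replicate mean simulated Fst with the observed mean
#' marked.
#'
#' @param object A `drift_test`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.drift_test <- function(object, ...) {
  d <- tibble::tibble(mean_fst = object$mean_fst)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_fst)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_mean_fst,
                        colour = "firebrick") +
    ggplot2::labs(
      x = "mean simulated Fst (neutral model)", y = "replicates",
      subtitle = sprintf("P(drift >= observed) = %.3g over %d replicates",
                         object$empirical_probability, object$n_reps))
}

#' Heatmap of pairwise linkage disequilibrium
#'
#' @param ld Output of [pairwise_ld()].
#' @param stat `"r2"` or `"dprime"`.
#' @return A ggplot object.
#' @export
plot_ld <- function(ld, stat = c("r2", "dprime")) {
  stat <- match.arg(stat)
  m <- ld[[stat]]
  d <- tidyr::expand_grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  d$value <- m[cbind(d$i, d$j)]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$i, y = .data$j,
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 na.value = "grey90",
                                 name = if (stat == "r2") expression(r^2)
                                        else "D'") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "locus", y = "locus")
}
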
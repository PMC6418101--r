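#' @import ggplot2
#' @importFrom rlang .data
NULL

#' Plot per-donor screen quality control
#'
#' Z'-factor and assay window per donor, with the pass gates drawn as
#' dashed lines.
#'
#' @param qc A [qc_screen()] report.
#' @param z_min,window_min Gates to draw.
#' @return A ggplot.
#' @export
plot_screen_qc <- function(qc, z_min = 0.3, window_min = 2) {
  long <- qc |>
    dplyr::select("donor", "z_prime", "window") |>
    tidyr::pivot_longer(c("z_prime", "window"),
                        names_to = "metric", values_to = "value")
  gates <- tibble::tibble(metric = c("z_prime", "window"),
                          gate = c(z_min, window_min))
  ggplot(long, aes(x = .data$donor, y = .data$value)) +
    geom_point(size = 2) +
    geom_hline(data = gates, aes(yintercept = .data$gate), linetype = 2) +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "donor", y = NULL, title = "Screen QC per donor") +
    theme_bw()
}

#' Waterfall plot of ranked shRNA inhibition
#'
#' Cross-donor mean percent inhibition per shRNA, ranked from strongest to
#' weakest, with tier thresholds drawn.
#'
#' @param agg An [aggregate_inhibition()] table.
#' @param rules A [tier_rules()] supplying threshold lines.
#' @return A ggplot.
#' @export
plot_inhibition_ranked <- function(agg, rules = tier_rules()) {
  ggplot(agg, aes(x = .data$rank, y = .data$mean_inhibition)) +
    geom_col(width = 1, fill = "grey35") +
    geom_hline(yintercept = c(rules$t_lo, rules$t_hi), linetype = 2,
               colour = "firebrick") +
    labs(x = "shRNA rank", y = "mean inhibition (%)",
         title = "Ranked cross-donor ASMA inhibition") +
    theme_bw()
}

#' Volcano plot of a moderated differential-expression result
#'
#' @param de A [moderated_de()] tibble.
#' @return A ggplot.
#' @export
plot_volcano <- function(de) {
  ggplot(de, aes(x = .data$log2fc, y = -log10(.data$p),
                 colour = .data$significant)) +
    geom_point(alpha = 0.5, size = 0.8) +
    scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    labs(x = "log2 fold change", y = "-log10 p", colour = "significant") +
    theme_bw()
}

#' Fold-change concordance plot for a signature comparison
#'
#' Scatter of baseline vs follow-up log2 fold changes over the union of the
#' two DEG sets, annotated with the Pearson correlation.
#'
#' @param object A [compare_signatures()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot signature_comparison
#' @export
autoplot.signature_comparison <- function(object, ...) {
  dat <- object$union[!is.na(object$union$log2fc_base) &
                        !is.na(object$union$log2fc_follow), ]
  ggplot(dat, aes(x = .data$log2fc_base, y = .data$log2fc_follow)) +
    geom_point(alpha = 0.5, size = 0.8) +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    labs(
      x = "baseline log2FC", y = "follow-up log2FC",
      title = sprintf("Signature retention: %d%% (r = %.2f)",
                      object$retention_pct_reported, object$pearson_r)
    ) +
    theme_bw()
}

#' Display a synthetic well image
#'
#' @param object A [render_well_image()] result.
#' @param ... Ignored.
#' @return A ggplot showing both channels.
#' @method autoplot well_image
#' @export
autoplot.well_image <- function(object, ...) {
  to_df <- function(m, ch) {
    tibble::tibble(
      x = rep(seq_len(ncol(m)), each = nrow(m)),
      y = rep(seq_len(nrow(m)), ncol(m)),
      intensity = as.vector(m), channel = ch
    )
  }
  dat <- dplyr::bind_rows(to_df(object$dapi, "DAPI"),
                          to_df(object$asma, "ASMA"))
  ggplot(dat, aes(.data$x, .data$y, fill = .data$intensity)) +
    geom_raster() +
    facet_wrap(~channel) +
    scale_fill_viridis_c() +
    coord_equal() +
    theme_void()
}
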
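#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a batch-correction fit
#'
#' One row per (probe, batch) with the raw and empirical-Bayes-shrunken
#' location (`gamma_hat`, `gamma_star`) and scale (`delta_hat`,
#' `delta_star`) estimates.
#'
#' @param x A [batch_correct()] result.
#' @param ... Ignored.
#' @return A tibble.
#' @method tidy batch_correction
#' @export
tidy.batch_correction <- function(x, ...) {
  x$params
}

#' @rdname tidy.batch_correction
#' @method glance batch_correction
#' @export
glance.batch_correction <- function(x, ...) {
  if (nrow(x$params) == 0) {
    return(tibble::tibble(n_batches = 1L, mean_abs_gamma = 0,
                          mean_delta = 1))
  }
  tibble::tibble(
    n_batches = length(unique(x$params$batch)),
    mean_abs_gamma = mean(abs(x$params$gamma_star)),
    mean_delta = mean(x$params$delta_star)
  )
}

#' One-row summary of a signature comparison
#'
#' @param x A [compare_signatures()] result.
#' @param ... Ignored.
#' @return A tibble with the DEG counts, retention percentage and the
#'   fold-change correlation.
#' @method glance signature_comparison
#' @export
glance.signature_comparison <- function(x, ...) {
  tibble::tibble(
    n_base = x$n_base, n_follow = x$n_follow, n_overlap = x$n_overlap,
    retention_pct = x$retention_pct,
    retention_pct_reported = x$retention_pct_reported,
    pearson_r = x$pearson_r
  )
}

#' Tidy a QC report or hit table
#'
#' These results are already tibbles; `tidy()` strips the result class so
#' they drop into further dplyr work.
#'
#' @param x A `qc_report` or `hit_table`.
#' @param ... Ignored.
#' @return A plain tibble.
#' @method tidy qc_report
#' @export
tidy.qc_report <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.qc_report
#' @method tidy hit_table
#' @export
tidy.hit_table <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
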
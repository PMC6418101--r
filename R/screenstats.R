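#' Z'-factor of a control pair
#'
#' The standard screening-assay quality statistic
#' `1 - 3 * (sd_neg + sd_pos) / |mean_neg - mean_pos|`, computed with sample
#' (n - 1) standard deviations. Values of 0.3-0.6 indicate a screen robust
#' enough for high-throughput use; the noiseless limit is 1.
#'
#' @param neg_scores,pos_scores Numeric vectors of negative- and
#'   positive-control well scores (each length >= 2, distinct means).
#' @return The Z'-factor (dimensionless, <= 1).
#' @export
#' @examples
#' zprime(rnorm(120, 1, 0.1), rnorm(120, 1 / 3, 1 / 30))
zprime <- function(neg_scores, pos_scores) {
  check_arm(neg_scores, "neg_scores")
  check_arm(pos_scores, "pos_scores")
  mu_n <- mean(neg_scores); mu_p <- mean(pos_scores)
  if (mu_n == mu_p) abort("control means are identical; Z' undefined")
  1 - 3 * (sd(neg_scores) + sd(pos_scores)) / abs(mu_n - mu_p)
}

#' Assay window of a control pair
#'
#' Fold ratio of the negative-control mean score to the positive-control
#' mean score — the dynamic range of the phenotypic readout.
#'
#' @inheritParams zprime
#' @return The window in fold (dimensionless, > 0 for a working assay).
#' @export
assay_window <- function(neg_scores, pos_scores) {
  check_arm(neg_scores, "neg_scores")
  check_arm(pos_scores, "pos_scores")
  mu_p <- mean(pos_scores)
  if (mu_p <= 0) abort("positive-control mean must be positive")
  mean(neg_scores) / mu_p
}

check_arm <- function(x, name) {
  if (!is.numeric(x) || length(x) < 2 || any(!is.finite(x))) {
    abort(sprintf("`%s` must be a finite numeric vector of length >= 2.", name))
  }
}

#' Percent inhibition relative to a control arm
#'
#' `100 * (1 - mean(test) / mean(ctrl))`; negative values indicate
#' enhancement of the readout.
#'
#' @param test_scores,ctrl_scores Numeric well-score vectors (nonempty).
#' @param use_median Compare medians instead of means.
#' @return Percent inhibition.
#' @export
#' @examples
#' pct_inhibition(c(0.6, 0.7), c(1.0, 1.0))
pct_inhibition <- function(test_scores, ctrl_scores, use_median = FALSE) {
  if (!length(test_scores) || !length(ctrl_scores)) {
    abort("score vectors must be nonempty")
  }
  loc <- if (use_median) median else mean
  ctrl <- loc(ctrl_scores)
  if (ctrl <= 0) abort("control location must be positive")
  100 * (1 - loc(test_scores) / ctrl)
}

#' Knockdown percentage from relative target expression
#'
#' `100 * (1 - relative_expression)`; values above 1 (over-expression)
#' yield negative knockdown and are allowed.
#'
#' @param relative_expression Target/control expression ratio(s), >= 0.
#' @return Knockdown percent, vectorised.
#' @export
knockdown_pct <- function(relative_expression) {
  if (any(!is.finite(relative_expression)) || any(relative_expression < 0)) {
    abort("`relative_expression` must be non-negative and finite.")
  }
  100 * (1 - relative_expression)
}

#' Summarise a knockdown panel against efficacy thresholds
#'
#' For each threshold t, the fraction of shRNAs with knockdown strictly
#' greater than t percent, per donor and pooled across donors.
#'
#' @param panel Tibble with `shrna_id`, `donor` and `knockdown` (percent)
#'   columns; see [simulate_knockdown_panel()] + [knockdown_pct()].
#' @param thresholds Numeric thresholds in \[0, 100\].
#' @return Tibble: donor (`"pooled"` for the overall row), threshold,
#'   n_shrnas, fraction.
#' @export
#' @examples
#' panel <- tibble::tibble(shrna_id = c("a", "b", "c"), donor = "D01",
#'                         knockdown = c(80, 70, 50))
#' summarize_knockdown(panel, thresholds = 60)
summarize_knockdown <- function(panel, thresholds = c(60, 75)) {
  require_columns(panel, c("shrna_id", "donor", "knockdown"), "panel")
  if (nrow(panel) == 0) abort("`panel` is empty.")
  if (any(thresholds < 0 | thresholds > 100)) {
    abort("`thresholds` must lie in [0, 100].")
  }
  pooled <- dplyr::mutate(panel, donor = "pooled")
  dplyr::bind_rows(panel, pooled) |>
    tidyr::expand_grid(threshold = thresholds) |>
    dplyr::group_by(.data$donor, .data$threshold) |>
    dplyr::summarise(
      n_shrnas = dplyr::n(),
      fraction = mean(.data$knockdown > .data$threshold),
      .groups = "drop"
    )
}

#' Endpoint group difference (Welch t-test)
#'
#' Difference of group means with a two-tailed unequal-variance t-test,
#' the endpoint comparison used for well-level readouts. Degenerate input
#' (zero variance in both groups, equal means) reports p = 1.
#'
#' @param scores_a,scores_b Numeric vectors (each length >= 2).
#' @return Tibble: mean_diff (a minus b), p_value.
#' @export
group_difference <- function(scores_a, scores_b) {
  check_arm(scores_a, "scores_a")
  check_arm(scores_b, "scores_b")
  d <- mean(scores_a) - mean(scores_b)
  if (sd(scores_a) == 0 && sd(scores_b) == 0) {
    p <- if (d == 0) 1 else 0
  } else {
    p <- t.test(scores_a, scores_b, var.equal = FALSE)$p.value
  }
  tibble::tibble(mean_diff = d, p_value = p)
}

#' Per-donor screen quality control
#'
#' Computes, for every donor in a well table, the negative/positive control
#' statistics, the Z'-factor and the assay window, and flags the donor
#' against configurable gates. Wells without nuclei (score undefined) are
#' excluded with a warning.
#'
#' @param wells Well table with `donor`, `role`
#'   (`"negative"`/`"positive"`/`"test"`), `score` and optionally `nuclei`.
#' @param z_min Z' pass gate (default 0.3).
#' @param window_min Window pass gate in fold (default 2).
#' @return Tibble of class `qc_report`: donor, mu_neg, sd_neg, n_neg,
#'   mu_pos, sd_pos, n_pos, z_prime, window, pass.
#' @export
#' @examples
#' sim <- simulate_screen(screen_config(n_donors = 2, wells_per_condition = 20))
#' qc_screen(sim$wells)
qc_screen <- function(wells, z_min = 0.3, window_min = 2) {
  require_columns(wells, c("donor", "role", "score"), "wells")
  if ("nuclei" %in% names(wells) && any(wells$nuclei == 0)) {
    warn(sprintf("excluding %d well(s) with zero nuclei",
                 sum(wells$nuclei == 0)))
    wells <- wells[wells$nuclei > 0, ]
  }
  out <- wells |>
    dplyr::filter(.data$role %in% c("negative", "positive")) |>
    dplyr::group_by(.data$donor) |>
    dplyr::summarise(
      mu_neg = mean(.data$score[.data$role == "negative"]),
      sd_neg = sd(.data$score[.data$role == "negative"]),
      n_neg = sum(.data$role == "negative"),
      mu_pos = mean(.data$score[.data$role == "positive"]),
      sd_pos = sd(.data$score[.data$role == "positive"]),
      n_pos = sum(.data$role == "positive"),
      z_prime = zprime(.data$score[.data$role == "negative"],
                       .data$score[.data$role == "positive"]),
      window = assay_window(.data$score[.data$role == "negative"],
                            .data$score[.data$role == "positive"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(pass = .data$z_prime >= z_min & .data$window >= window_min)
  class(out) <- c("qc_report", class(out))
  out
}

#' Per-shRNA percent inhibition against same-donor negative controls
#'
#' For each (shRNA, donor), compares the mean test-well score to the mean
#' negative-control score of the same donor.
#'
#' @inheritParams qc_screen
#' @param use_median Compare medians instead of means.
#' @return Tibble: shrna_id, gene, donor, pct_inhibition.
#' @export
screen_inhibition <- function(wells, use_median = FALSE) {
  require_columns(wells, c("donor", "role", "score", "shrna_id", "gene"),
                  "wells")
  if ("nuclei" %in% names(wells)) wells <- wells[wells$nuclei > 0, ]
  ctrl <- wells |>
    dplyr::filter(.data$role == "negative") |>
    dplyr::group_by(.data$donor) |>
    dplyr::summarise(ctrl_scores = list(.data$score), .groups = "drop")
  wells |>
    dplyr::filter(.data$role == "test") |>
    dplyr::inner_join(ctrl, by = "donor") |>
    dplyr::group_by(.data$shrna_id, .data$gene, .data$donor) |>
    dplyr::summarise(
      pct_inhibition = pct_inhibition(.data$score, .data$ctrl_scores[[1]],
                                      use_median = use_median),
      .groups = "drop"
    )
}
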
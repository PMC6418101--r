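#' Tier rules for gene-level hit classification
#'
#' Encodes the count-and-threshold rules used to grade genes from their
#' per-shRNA inhibition values, evaluated in precedence order
#' very_strong > strong > moderate > weak > none:
#' \itemize{
#'   \item very_strong: at least `n_very_strong` shRNAs with inhibition
#'     strictly above `t_hi`;
#'   \item strong: at least `n_strong` shRNAs above `t_hi`;
#'   \item moderate: at least one shRNA above `t_hi` and at least one in the
#'     open interval (`t_lo`, `t_mid`);
#'   \item weak: at least `n_weak` shRNAs in the open interval
#'     (`t_lo`, `t_hi`).
#' }
#' All comparisons are strict, reading "more than 35%" literally.
#'
#' @param t_hi,t_mid,t_lo Percent-inhibition thresholds (defaults 35/30/25;
#'   must satisfy t_lo < t_mid < t_hi).
#' @param n_strong,n_weak,n_very_strong Count requirements (defaults 2/3/8).
#' @return An object of class `tier_rules`.
#' @export
tier_rules <- function(t_hi = 35, t_mid = 30, t_lo = 25,
                       n_strong = 2L, n_weak = 3L, n_very_strong = 8L) {
  if (!(t_lo < t_mid && t_mid < t_hi)) abort("need t_lo < t_mid < t_hi")
  if (any(c(n_strong, n_weak, n_very_strong) < 1)) abort("counts must be >= 1")
  structure(list(t_hi = t_hi, t_mid = t_mid, t_lo = t_lo,
                 n_strong = as.integer(n_strong), n_weak = as.integer(n_weak),
                 n_very_strong = as.integer(n_very_strong)),
            class = "tier_rules")
}

hit_tiers <- c("very_strong", "strong", "moderate", "weak", "none")

#' Average per-shRNA inhibition across donors and rank
#'
#' Unweighted mean of each shRNA's percent inhibition over the donors it was
#' tested in, sorted from strongest to weakest inhibition; ties break by
#' `shrna_id` lexicographic order. shRNAs with no finite value in any donor
#' are dropped with a warning.
#'
#' @param records Tibble with `shrna_id`, `gene`, `donor`, `pct_inhibition`.
#' @return Tibble: shrna_id, gene, mean_inhibition, n_donors, rank.
#' @export
#' @examples
#' rec <- tibble::tibble(shrna_id = c("a", "a", "b"), gene = "G",
#'                       donor = c("D1", "D2", "D1"),
#'                       pct_inhibition = c(40, 30, 20))
#' aggregate_inhibition(rec)
aggregate_inhibition <- function(records) {
  require_columns(records, c("shrna_id", "gene", "donor", "pct_inhibition"),
                  "records")
  if (nrow(records) == 0) abort("`records` is empty.")
  out <- records |>
    dplyr::group_by(.data$shrna_id, .data$gene) |>
    dplyr::summarise(
      mean_inhibition = mean(.data$pct_inhibition[is.finite(.data$pct_inhibition)]),
      n_donors = sum(is.finite(.data$pct_inhibition)),
      .groups = "drop"
    )
  dropped <- out$n_donors == 0
  if (any(dropped)) {
    warn(sprintf("dropping %d shRNA(s) with no finite inhibition value",
                 sum(dropped)))
    out <- out[!dropped, ]
  }
  out |>
    dplyr::arrange(dplyr::desc(.data$mean_inhibition), .data$shrna_id) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' Classify one gene from its per-shRNA inhibition values
#'
#' Applies the [tier_rules()] predicates in precedence order so that a gene
#' receives its best-supported label.
#'
#' @param shrna_means Numeric vector of per-shRNA mean inhibition percents
#'   for one gene.
#' @param rules A [tier_rules()].
#' @return One-row tibble: tier (factor over very_strong/strong/moderate/
#'   weak/none), n_gt_hi, n_in_lo_mid, n_in_lo_hi, best_inhibition.
#' @export
#' @examples
#' classify_gene(c(40, 38, 10))$tier
classify_gene <- function(shrna_means, rules = tier_rules()) {
  if (!is.numeric(shrna_means) || !length(shrna_means) ||
      any(is.na(shrna_means))) {
    abort("`shrna_means` must be a nonempty numeric vector without NA.")
  }
  n_gt_hi <- sum(shrna_means > rules$t_hi)
  n_in_lo_mid <- sum(shrna_means > rules$t_lo & shrna_means < rules$t_mid)
  n_in_lo_hi <- sum(shrna_means > rules$t_lo & shrna_means < rules$t_hi)
  tier <- if (n_gt_hi >= rules$n_very_strong) "very_strong"
  else if (n_gt_hi >= rules$n_strong) "strong"
  else if (n_gt_hi >= 1 && n_in_lo_mid >= 1) "moderate"
  else if (n_in_lo_hi >= rules$n_weak) "weak"
  else "none"
  tibble::tibble(
    tier = factor(tier, levels = hit_tiers),
    n_gt_hi = n_gt_hi,
    n_in_lo_mid = n_in_lo_mid,
    n_in_lo_hi = n_in_lo_hi,
    best_inhibition = max(shrna_means)
  )
}

#' Call tiered hits from per-shRNA, per-donor inhibition records
#'
#' Composes [aggregate_inhibition()] (cross-donor averaging and ranking)
#' with [classify_gene()] per gene; output is sorted by tier and then by
#' the gene's best shRNA mean inhibition.
#'
#' @inheritParams aggregate_inhibition
#' @param rules A [tier_rules()].
#' @return Tibble of class `hit_table`: gene, tier, n_shrnas, n_gt_hi,
#'   n_in_lo_mid, n_in_lo_hi, best_inhibition.
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   shrna_id = c("x1", "x2", "y1"), gene = c("X", "X", "Y"),
#'   donor = "D1", pct_inhibition = c(42, 39, 12)
#' )
#' call_hits(rec)
call_hits <- function(records, rules = tier_rules()) {
  agg <- aggregate_inhibition(records)
  out <- agg |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_shrnas = dplyr::n(),
      res = list(classify_gene(.data$mean_inhibition, rules)),
      .groups = "drop"
    ) |>
    tidyr::unnest("res") |>
    dplyr::arrange(.data$tier, dplyr::desc(.data$best_inhibition))
  class(out) <- c("hit_table", class(out))
  out
}
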
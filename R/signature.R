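#' Empirical-Bayes location/scale batch correction
#'
#' Removes additive and multiplicative per-(probe, batch) array effects from
#' a log2 expression matrix while preserving the biological covariate of
#' interest, following the parametric empirical-Bayes location/scale model:
#' per-probe batch locations and residual scales are estimated on
#' standardized data, shrunk toward their across-probe priors (normal prior
#' on locations, inverse-gamma on squared scales, both moment-matched), and
#' the data are adjusted and restored to the original scale. With a single
#' batch the input is returned unchanged.
#'
#' @param exprs Numeric matrix, probes x samples (log2 intensities), with
#'   sample columns named.
#' @param meta Data frame with one row per sample: `sample_id`, `batch`, and
#'   the covariate column.
#' @param covariate Name of the biological covariate to protect (default
#'   `"disease"`); set `NULL` for none.
#' @return A list of class `batch_correction`: `exprs` (corrected matrix)
#'   and `params` (tibble of per-(probe, batch) raw and shrunken location
#'   `gamma_hat`/`gamma_star` and scale `delta_hat`/`delta_star` estimates).
#' @export
#' @examples
#' sim <- simulate_expression_study(study_config(n_probes = 150,
#'                                               n_signature = 15, seed = 5))
#' bc <- batch_correct(sim$exprs, sim$meta)
batch_correct <- function(exprs, meta, covariate = "disease") {
  if (!is.matrix(exprs)) abort("`exprs` must be a matrix (probes x samples).")
  require_columns(meta, c("sample_id", "batch"), "meta")
  if (!setequal(colnames(exprs), meta$sample_id) ||
      ncol(exprs) != nrow(meta)) {
    abort("`meta` must describe exactly the columns of `exprs`.")
  }
  meta <- meta[match(colnames(exprs), meta$sample_id), ]
  batch <- factor(meta$batch)
  n_batch <- nlevels(batch)
  if (n_batch < 2) {
    return(structure(list(exprs = exprs, params = tibble::tibble()),
                     class = "batch_correction"))
  }
  if (any(table(batch) < 2)) abort("each batch needs >= 2 samples")

  batch_design <- model.matrix(~ 0 + batch)
  design <- batch_design
  if (!is.null(covariate)) {
    require_columns(meta, covariate, "meta")
    cov <- factor(meta[[covariate]])
    if (nlevels(cov) > 1) {
      cov_design <- model.matrix(~cov)[, -1, drop = FALSE]
      design <- cbind(batch_design, cov_design)
      if (qr(design)$rank < ncol(design)) {
        abort("covariate is confounded with batch; cannot correct")
      }
    }
  }

  n <- ncol(exprs)
  n_batches <- colSums(batch_design)
  beta_hat <- solve(crossprod(design), crossprod(design, t(exprs)))
  grand_mean <- crossprod(n_batches / n, beta_hat[seq_len(n_batch), , drop = FALSE])
  var_pooled <- rowMeans((exprs - t(design %*% beta_hat))^2)
  var_pooled <- pmax(var_pooled, 1e-12)

  stand_mean <- matrix(grand_mean, nrow(exprs), n)
  if (ncol(design) > n_batch) {
    tmp <- design
    tmp[, seq_len(n_batch)] <- 0
    stand_mean <- stand_mean + t(tmp %*% beta_hat)
  }
  s_data <- (exprs - stand_mean) / sqrt(var_pooled)

  gamma_hat <- t(solve(crossprod(batch_design),
                       crossprod(batch_design, t(s_data))))
  delta_hat <- sapply(levels(batch), function(b) {
    apply(s_data[, batch == b, drop = FALSE], 1, stats::var)
  })

  # moment-matched priors across probes, per batch
  gamma_bar <- colMeans(gamma_hat)
  tau2 <- apply(gamma_hat, 2, stats::var)
  a_prior <- apply(delta_hat, 2, function(d) {
    m <- mean(d); s2 <- stats::var(d); (2 * s2 + m^2) / s2
  })
  b_prior <- apply(delta_hat, 2, function(d) {
    m <- mean(d); s2 <- stats::var(d); (m * s2 + m^3) / s2
  })

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  adjusted <- s_data
  for (i in seq_len(n_batch)) {
    idx <- batch == levels(batch)[i]
    ni <- sum(idx)
    g <- gamma_hat[, i]
    d <- delta_hat[, i]
    g_new <- g
    d_new <- d
    for (iter in 1:100) {
      g_old <- g_new; d_old <- d_new
      g_new <- (ni * tau2[i] * g + d_new * gamma_bar[i]) /
        (ni * tau2[i] + d_new)
      sum2 <- rowSums((s_data[, idx, drop = FALSE] - g_new)^2)
      d_new <- (0.5 * sum2 + b_prior[i]) / (ni / 2 + a_prior[i] - 1)
      if (max(abs(g_new - g_old) / pmax(abs(g_old), 1e-8)) < 1e-4 &&
          max(abs(d_new - d_old) / pmax(abs(d_old), 1e-8)) < 1e-4) break
    }
    gamma_star[, i] <- g_new
    delta_star[, i] <- d_new
    adjusted[, idx] <- (s_data[, idx, drop = FALSE] - g_new) / sqrt(d_new)
  }
  corrected <- adjusted * sqrt(var_pooled) + stand_mean

  params <- tibble::tibble(
    probe_id = rep(rownames(exprs) %||% as.character(seq_len(nrow(exprs))),
                   times = n_batch),
    batch = rep(levels(batch), each = nrow(exprs)),
    gamma_hat = as.vector(gamma_hat),
    gamma_star = as.vector(gamma_star),
    delta_hat = as.vector(delta_hat),
    delta_star = as.vector(delta_star)
  )
  structure(list(exprs = corrected, params = params),
            class = "batch_correction")
}

#' Significance thresholds of the composite differential-expression rule
#'
#' A probe is called significant when all four gates pass: absolute fold
#' change above `fold_change` (evaluated as |log2FC| > log2(fold_change)),
#' Benjamini-Hochberg adjusted p below `q_max`, log-odds of differential
#' expression (B statistic) above `lods_min`, and average normalized log2
#' intensity above `avg_expr_min`. All inequalities are strict.
#'
#' @param fold_change Fold-change gate (linear scale), default 1.5.
#' @param q_max BH-adjusted p-value gate, default 0.01.
#' @param lods_min Log-odds gate, default 0.
#' @param avg_expr_min Average log2-intensity gate, default 4.
#' @return An object of class `de_thresholds`.
#' @export
de_thresholds <- function(fold_change = 1.5, q_max = 0.01, lods_min = 0,
                          avg_expr_min = 4) {
  stopifnot_scalar_num(fold_change, "fold_change", positive = TRUE)
  stopifnot_scalar_num(q_max, "q_max", positive = TRUE)
  structure(list(fold_change = fold_change, q_max = q_max,
                 lods_min = lods_min, avg_expr_min = avg_expr_min),
            class = "de_thresholds")
}

#' Moderated differential expression between disease and healthy samples
#'
#' Fits per-probe linear models with empirical-Bayes variance moderation
#' (limma) for a two-group contrast, or a one-sample moderated test on
#' within-pair differences when `paired = TRUE`. Reports the moderated t,
#' two-sided p, Benjamini-Hochberg q, log-odds of differential expression
#' (B statistic with prior proportion `lods_prior`), the mean log2 intensity
#' over the analysed samples, and the composite significance flag of
#' [de_thresholds()]. Replicate hybridisations (`is_replicate` column in
#' `meta`) are excluded before fitting.
#'
#' @param exprs Probes x samples log2 matrix with named dimensions.
#' @param meta Sample metadata; needs `sample_id` and the `group_col`
#'   column, plus `pair_col` when `paired = TRUE`.
#' @param contrast Length-2 character: `c(case, reference)` levels of
#'   `group_col`; log2FC is case minus reference.
#' @param group_col Metadata column holding the group labels.
#' @param paired One-sample fit on per-pair (case - reference) differences.
#' @param pair_col Metadata column identifying pairs (default `"donor"`).
#' @param lods_prior Prior proportion of differentially expressed probes.
#' @param thresholds A [de_thresholds()].
#' @return A tibble of class `de_result`: probe_id, log2fc, t, p, q, lods,
#'   avg_expr, significant.
#' @export
#' @examples
#' sim <- simulate_expression_study(study_config(n_probes = 300,
#'                                               n_signature = 30, seed = 2))
#' base <- sim$meta$passage == "P0P1" & !sim$meta$is_replicate
#' de <- moderated_de(sim$exprs[, sim$meta$sample_id[base]],
#'                    sim$meta[base, ])
#' head(de)
moderated_de <- function(exprs, meta, contrast = c("SSc", "healthy"),
                         group_col = "disease", paired = FALSE,
                         pair_col = "donor", lods_prior = 0.01,
                         thresholds = de_thresholds()) {
  if (!is.matrix(exprs)) abort("`exprs` must be a matrix (probes x samples).")
  require_columns(meta, c("sample_id", group_col), "meta")
  meta <- meta[match(colnames(exprs), meta$sample_id), ]
  if (anyNA(meta$sample_id)) abort("`meta` must describe all columns of `exprs`.")
  if ("is_replicate" %in% names(meta) && any(meta$is_replicate)) {
    keep <- !meta$is_replicate
    exprs <- exprs[, keep, drop = FALSE]
    meta <- meta[keep, ]
  }
  keep <- meta[[group_col]] %in% contrast
  exprs <- exprs[, keep, drop = FALSE]
  meta <- meta[keep, ]
  if (any(!is.finite(exprs))) abort("`exprs` contains non-finite values.")
  group <- factor(meta[[group_col]], levels = rev(contrast))

  if (paired) {
    require_columns(meta, pair_col, "meta")
    pairs <- split(seq_len(nrow(meta)), meta[[pair_col]])
    pairs <- Filter(function(i) length(unique(group[i])) == 2, pairs)
    if (length(pairs) < 2) abort("paired fit needs >= 2 complete pairs")
    diffs <- sapply(pairs, function(i) {
      rowMeans(exprs[, i[group[i] == contrast[1]], drop = FALSE]) -
        rowMeans(exprs[, i[group[i] == contrast[2]], drop = FALSE])
    })
    fit <- limma::lmFit(diffs, design = matrix(1, ncol(diffs), 1))
    coef_idx <- 1L
  } else {
    if (any(table(group) < 2)) abort("each group needs >= 2 samples")
    design <- model.matrix(~group)
    fit <- limma::lmFit(exprs, design)
    coef_idx <- 2L
  }
  fit <- limma::eBayes(fit, proportion = lods_prior)
  tt <- limma::topTable(fit, coef = coef_idx, number = Inf, sort.by = "none")

  out <- tibble::tibble(
    probe_id = rownames(exprs) %||% as.character(seq_len(nrow(exprs))),
    log2fc = tt$logFC,
    t = tt$t,
    p = tt$P.Value,
    q = tt$adj.P.Val,
    lods = tt$B,
    avg_expr = rowMeans(exprs)
  )
  out$significant <- de_significant(out, thresholds)
  class(out) <- c("de_result", class(out))
  out
}

de_significant <- function(results, thresholds) {
  abs(results$log2fc) > log2(thresholds$fold_change) &
    results$q < thresholds$q_max &
    results$lods > thresholds$lods_min &
    results$avg_expr > thresholds$avg_expr_min
}

#' Select differentially expressed probes under the composite rule
#'
#' @param results A [moderated_de()] result tibble.
#' @param thresholds A [de_thresholds()]; `NULL` reuses the `significant`
#'   flag already present in `results`.
#' @return Tibble: probe_id, log2fc, direction (`"up"`/`"down"`).
#' @export
select_degs <- function(results, thresholds = NULL) {
  require_columns(results, c("probe_id", "log2fc"), "results")
  sel <- if (is.null(thresholds)) {
    require_columns(results, "significant", "results")
    results$significant
  } else {
    de_significant(results, thresholds)
  }
  out <- results[sel, c("probe_id", "log2fc")]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  tibble::as_tibble(out)
}

#' Compare a baseline and a follow-up differential-expression signature
#'
#' Measures how much of a baseline disease signature is retained at
#' follow-up: the overlap of the two DEG sets, the retention percentage
#' (overlap / baseline), and the Pearson correlation of the two log2
#' fold-change vectors over the union of the DEG sets.
#'
#' Inputs may be full [moderated_de()] result tables (DEGs are selected via
#' their `significant` flag, fold changes for the union are taken from the
#' full tables) or pre-selected DEG tables with `probe_id` (and optionally
#' `log2fc`) columns. Union probes without a fold change on both sides are
#' omitted from the correlation.
#'
#' @param de_base Baseline DE results or DEG set.
#' @param de_follow Follow-up DE results or DEG set.
#' @return A list of class `signature_comparison`: n_base, n_follow,
#'   n_overlap, retention_pct (exact), retention_pct_reported (integer
#'   percent), pearson_r, and `union` (tibble: probe_id, log2fc_base,
#'   log2fc_follow).
#' @export
#' @examples
#' base <- tibble::tibble(probe_id = sprintf("p%04d", 1:926))
#' follow <- base[1:717, ]
#' compare_signatures(base, follow)$retention_pct_reported
compare_signatures <- function(de_base, de_follow) {
  base <- as_deg_set(de_base)
  follow <- as_deg_set(de_follow)
  if (nrow(base$degs) == 0) abort("baseline DEG set is empty; retention undefined")

  ids_base <- base$degs$probe_id
  ids_follow <- follow$degs$probe_id
  n_overlap <- length(intersect(ids_base, ids_follow))
  retention <- 100 * n_overlap / length(ids_base)

  union_ids <- union(ids_base, ids_follow)
  fc_base <- base$fc[union_ids]
  fc_follow <- follow$fc[union_ids]
  ok <- !is.na(fc_base) & !is.na(fc_follow)
  r <- if (sum(ok) >= 3) cor(fc_base[ok], fc_follow[ok]) else NA_real_

  structure(
    list(
      n_base = length(ids_base),
      n_follow = length(ids_follow),
      n_overlap = n_overlap,
      retention_pct = retention,
      retention_pct_reported = round(retention),
      pearson_r = r,
      union = tibble::tibble(probe_id = union_ids,
                             log2fc_base = unname(fc_base),
                             log2fc_follow = unname(fc_follow))
    ),
    class = "signature_comparison"
  )
}

as_deg_set <- function(x) {
  require_columns(x, "probe_id", "DE input")
  degs <- if ("significant" %in% names(x)) x[x$significant, ] else x
  fc <- if ("log2fc" %in% names(x)) {
    setNames(x$log2fc, x$probe_id)
  } else {
    setNames(rep(NA_real_, 0), character())
  }
  list(degs = degs, fc = fc)
}

#' @export
print.signature_comparison <- function(x, ...) {
  cat(sprintf(
    "Signature comparison: %d baseline DEGs, %d follow-up DEGs, %d overlap\n",
    x$n_base, x$n_follow, x$n_overlap))
  cat(sprintf("  retention: %.1f%% (reported %d%%)\n",
              x$retention_pct, x$retention_pct_reported))
  if (!is.na(x$pearson_r)) {
    cat(sprintf("  log2FC correlation over union: r = %.3f\n", x$pearson_r))
  }
  invisible(x)
}

#' Collapse probe-level results to genes
#'
#' Keeps, per gene, the probe with the largest absolute log2 fold change —
#' the conventional reduction when a probe-to-gene map is available.
#'
#' @param results A [moderated_de()] tibble.
#' @param probe_map Data frame with `probe_id`, `gene` columns.
#' @return The filtered results tibble with a `gene` column.
#' @export
collapse_probes <- function(results, probe_map) {
  require_columns(probe_map, c("probe_id", "gene"), "probe_map")
  results |>
    dplyr::inner_join(probe_map, by = "probe_id") |>
    dplyr::group_by(.data$gene) |>
    dplyr::slice_max(abs(.data$log2fc), n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
}
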
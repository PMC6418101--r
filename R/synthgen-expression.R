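#' Simulate a two-batch passage-retention expression study
#'
#' Generates a log2 expression matrix (probes x samples) for disease (SSc)
#' and healthy fibroblast samples at a baseline passage group (P0P1) and a
#' follow-up passage (P4). Signature probes carry a signed disease effect
#' drawn from the config's `effect_range`; at P4 a fraction
#' `retention_fraction` of them keep the full effect and the rest are
#' attenuated to `attenuation` times baseline. Samples are split across two
#' array batches with per-(probe, batch) additive location shifts and
#' residual-scale distortions, and `n_replicates` samples are hybridised in
#' both batches (same biology, independent batch terms and noise) to anchor
#' batch-effect estimation. SSc and healthy donors are paired across
#' passages (same donor measured at P0P1 and P4).
#'
#' @param config A [study_config()].
#' @return A list of class `expression_sim`:
#' \describe{
#'   \item{exprs}{numeric matrix, probes x samples, log2 intensities.}
#'   \item{meta}{tibble: sample_id, donor, disease, site, passage, batch,
#'     is_replicate.}
#'   \item{truth}{list: `probes` tibble (probe_id, is_signature, retained,
#'     log2fc_base, log2fc_p4), `gamma`/`delta` matrices (probe x batch).}
#' }
#' @export
#' @examples
#' sim <- simulate_expression_study(study_config(n_probes = 200,
#'                                               n_signature = 20, seed = 3))
#' dim(sim$exprs)
simulate_expression_study <- function(config) {
  if (!inherits(config, "study_config")) abort("`config` must be a study_config().")

  local_seed(stage_seed(config$seed, "expression"), {
    p <- config$n_probes
    probe_id <- sprintf("P%05d", seq_len(p))
    baseline <- runif(p, config$baseline_mean_range[1], config$baseline_mean_range[2])

    is_sig <- seq_len(p) <= config$n_signature
    effect <- numeric(p)
    effect[is_sig] <- sample(c(-1, 1), config$n_signature, replace = TRUE) *
      runif(config$n_signature, config$effect_range[1], config$effect_range[2])
    n_keep <- round(config$retention_fraction * config$n_signature)
    retained <- rep(FALSE, p)
    retained[sample(which(is_sig), n_keep)] <- TRUE
    effect_p4 <- ifelse(retained, effect, effect * config$attenuation)

    # biological samples: donor x passage; batches balanced within cell
    grp <- tidyr::expand_grid(
      passage = c("P0P1", "P4"),
      tibble::tibble(
        donor = c(sprintf("SSc%02d", seq_len(config$n_ssc)),
                  sprintf("HS%02d", seq_len(config$n_healthy))),
        disease = rep(c("SSc", "healthy"), c(config$n_ssc, config$n_healthy))
      )
    )
    grp$site <- ifelse(grp$disease == "SSc",
                       rep_len(c("affected", "non-affected"), nrow(grp)),
                       NA_character_)
    grp$batch <- stats::ave(seq_len(nrow(grp)),
                            paste(grp$passage, grp$disease),
                            FUN = function(i) rep_len(1:2, length(i)))
    grp$sample_id <- paste(grp$donor, grp$passage, sep = "_")
    grp$is_replicate <- FALSE

    # replicate hybridisations: same biology, the other batch
    rep_idx <- sort(sample(nrow(grp), min(config$n_replicates, nrow(grp))))
    reps <- grp[rep_idx, ]
    reps$batch <- 3L - reps$batch
    reps$sample_id <- paste0(reps$sample_id, "_rep")
    reps$is_replicate <- TRUE
    meta <- dplyr::bind_rows(grp, reps)
    bio_of <- c(seq_len(nrow(grp)), rep_idx)   # biological identity per column

    gamma <- matrix(rnorm(2 * p, 0, config$batch_shift_sd), p, 2)
    delta <- matrix(runif(2 * p, config$batch_scale_range[1],
                          config$batch_scale_range[2]), p, 2)
    if (config$batch_shift_sd == 0) gamma[] <- 0

    bio_signal <- function(row) {
      e <- if (row$passage == "P4") effect_p4 else effect
      baseline + if (row$disease == "SSc") e else 0
    }
    exprs <- matrix(NA_real_, p, nrow(meta),
                    dimnames = list(probe_id, meta$sample_id))
    for (j in seq_len(nrow(meta))) {
      b <- meta$batch[j]
      exprs[, j] <- bio_signal(meta[j, ]) + gamma[, b] +
        delta[, b] * rnorm(p, 0, config$noise_sd)
    }

    structure(
      list(
        exprs = exprs,
        meta = meta,
        truth = list(
          probes = tibble::tibble(probe_id = probe_id, is_signature = is_sig,
                                  retained = retained, log2fc_base = effect,
                                  log2fc_p4 = effect_p4),
          gamma = gamma, delta = delta, bio_of = bio_of
        )
      ),
      class = "expression_sim"
    )
  })
}
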
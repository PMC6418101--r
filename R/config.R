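#' Efficacy mixture model for simulated shRNAs
#'
#' Knockdown efficacy of a simulated shRNA is drawn from a two-component
#' mixture: with probability `w_eff` the hairpin is efficacious and its
#' efficacy follows a normal distribution truncated to \[0, 1\]; otherwise it
#' is a poor hairpin with efficacy uniform on \[0, `ineff_max`\]. The defaults
#' are calibrated so that roughly 80% of hairpins knock their target down by
#' more than 60% and roughly 65% by more than 75%, the performance band
#' typical of adenoviral shRNA panels in primary fibroblasts.
#'
#' @param w_eff Mixture weight of the efficacious component, in (0, 1].
#' @param eff_mean,eff_sd Mean and sd of the efficacious component before
#'   truncation to \[0, 1\].
#' @param ineff_max Upper bound of the uniform inefficacious component.
#' @return An object of class `efficacy_mixture`.
#' @export
#' @examples
#' efficacy_mixture()
efficacy_mixture <- function(w_eff = 0.8, eff_mean = 0.84, eff_sd = 0.10,
                             ineff_max = 0.6) {
  stopifnot_scalar_num(w_eff, "w_eff")
  if (w_eff <= 0 || w_eff > 1) abort("`w_eff` must be in (0, 1].")
  stopifnot_scalar_num(eff_mean, "eff_mean")
  stopifnot_scalar_num(eff_sd, "eff_sd", min = 0)
  stopifnot_scalar_num(ineff_max, "ineff_max", min = 0)
  structure(
    list(w_eff = w_eff, eff_mean = eff_mean, eff_sd = eff_sd,
         ineff_max = ineff_max),
    class = "efficacy_mixture"
  )
}

# Closed-form upper-tail probability P(efficacy > t) of the mixture.
# Used by tests as an analytic reference and exported for power planning.

#' Tail probability of the efficacy mixture
#'
#' Probability that a simulated shRNA's true efficacy exceeds `t`, in closed
#' form (truncated-normal tail ratio plus the uniform component).
#'
#' @param model An [efficacy_mixture()].
#' @param t Efficacy threshold in \[0, 1\]; vectorised.
#' @return Numeric vector of tail probabilities.
#' @export
efficacy_tail <- function(model, t) {
  z <- pnorm(1, model$eff_mean, model$eff_sd) - pnorm(0, model$eff_mean, model$eff_sd)
  tail_eff <- (pnorm(1, model$eff_mean, model$eff_sd) -
                 pnorm(pmin(pmax(t, 0), 1), model$eff_mean, model$eff_sd)) / z
  tail_ineff <- pmax(0, pmin(1, (model$ineff_max - t) / model$ineff_max))
  tail_ineff[model$ineff_max == 0] <- 0
  model$w_eff * tail_eff + (1 - model$w_eff) * tail_ineff
}

#' Default shRNA panel layout
#'
#' A panel of 31 genes covered by 2-4 hairpins each (103 shRNAs in total),
#' the size of a typical knockdown-validation panel.
#'
#' @return A tibble with columns `gene` and `n_shrnas`.
#' @export
default_shrna_panel <- function() {
  tibble::tibble(
    gene = sprintf("GENE%02d", 1:31),
    n_shrnas = rep(c(4L, 3L, 2L), times = c(15L, 11L, 5L))
  )
}

#' Configuration of a simulated ASMA screen
#'
#' Describes a multi-donor phenotypic screen: per-donor plates carrying
#' negative-control wells (GFP shRNA; well score centred at 1), positive
#' control wells (ACTA2 shRNA; score centred at `1 / fold_separation`) and
#' test-shRNA wells whose score reduction is proportional to the hairpin's
#' true knockdown efficacy. Well scores carry multiplicative lognormal noise
#' with coefficient of variation `cv_noise`, and every donor carries a
#' lognormal random effect (sdlog `donor_sdlog`) shared by all of that
#' donor's wells.
#'
#' @param n_donors Number of donors (one plate per donor).
#' @param wells_per_condition Wells per control arm and per test shRNA
#'   (default 120).
#' @param fold_separation True ratio of negative-control to positive-control
#'   mean score; must exceed 1.
#' @param cv_noise Coefficient of variation of well-level noise (>= 0).
#' @param shrna_panel Tibble with columns `gene`, `n_shrnas`
#'   (see [default_shrna_panel()]), or `NULL` for a controls-only screen.
#' @param efficacy_model An [efficacy_mixture()].
#' @param donor_sdlog sdlog of the per-donor lognormal random effect.
#' @param transduction_offset Optional additive score offset applied to all
#'   transduced wells (viral transduction can itself raise ASMA); default 0.
#' @param seed Master seed; all stage streams derive from it.
#' @return An object of class `screen_config`.
#' @export
#' @examples
#' cfg <- screen_config(n_donors = 2, fold_separation = 3, cv_noise = 0.1)
screen_config <- function(n_donors = 2L,
                          wells_per_condition = 120L,
                          fold_separation = 3,
                          cv_noise = 0.10,
                          shrna_panel = NULL,
                          efficacy_model = efficacy_mixture(),
                          donor_sdlog = 0.1,
                          transduction_offset = 0,
                          seed = 1L) {
  stopifnot_scalar_num(n_donors, "n_donors", min = 1)
  stopifnot_scalar_num(wells_per_condition, "wells_per_condition", min = 2)
  stopifnot_scalar_num(fold_separation, "fold_separation")
  if (fold_separation <= 1) abort("`fold_separation` must be > 1.")
  stopifnot_scalar_num(cv_noise, "cv_noise", min = 0)
  stopifnot_scalar_num(donor_sdlog, "donor_sdlog", min = 0)
  if (!inherits(efficacy_model, "efficacy_mixture")) {
    abort("`efficacy_model` must be an efficacy_mixture().")
  }
  if (!is.null(shrna_panel)) {
    require_columns(shrna_panel, c("gene", "n_shrnas"), "shrna_panel")
    if (any(shrna_panel$n_shrnas < 1)) abort("each gene needs >= 1 shRNA")
  }
  structure(
    list(
      n_donors = as.integer(n_donors),
      wells_per_condition = as.integer(wells_per_condition),
      fold_separation = fold_separation,
      cv_noise = cv_noise,
      shrna_panel = shrna_panel,
      efficacy_model = efficacy_model,
      donor_sdlog = donor_sdlog,
      transduction_offset = transduction_offset,
      seed = as.integer(seed)
    ),
    class = "screen_config"
  )
}

#' Configuration of a simulated passage-retention expression study
#'
#' Describes a two-passage, two-batch microarray study of disease (SSc) and
#' healthy fibroblasts. A set of `n_signature` probes carries a true disease
#' effect with |log2FC| uniform on `effect_range` (random sign). At the
#' follow-up passage (P4) a fraction `retention_fraction` of signature probes
#' keep their full effect; the remainder are attenuated to
#' `attenuation` times the baseline effect, so they fail significance
#' thresholds while still correlating weakly with baseline fold changes.
#' Samples are split across two array batches with per-(probe, batch)
#' additive shifts and residual-scale distortions; `n_replicates` samples are
#' hybridised in both batches to support batch-effect estimation.
#'
#' @param n_probes Total probes on the array.
#' @param n_signature Number of true disease-signature probes.
#' @param effect_range Length-2 range of true |log2FC| at baseline.
#' @param retention_fraction Fraction of signature probes retaining their
#'   full effect at P4, in \[0, 1\].
#' @param attenuation Residual effect fraction for non-retained probes.
#' @param n_ssc,n_healthy Biological samples per group at each passage
#'   (each >= 3).
#' @param n_replicates Samples measured in both batches (>= 1).
#' @param batch_shift_sd sd of the additive per-(probe, batch) shift (log2).
#' @param batch_scale_range Length-2 range of the multiplicative residual
#'   scale per (probe, batch).
#' @param noise_sd Residual sd of log2 intensities.
#' @param baseline_mean_range Range of per-probe baseline mean log2 intensity.
#' @param seed Master seed.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_probes = 2000L,
                         n_signature = 200L,
                         effect_range = c(0.6, 2.0),
                         retention_fraction = 0.77,
                         attenuation = 0.25,
                         n_ssc = 8L,
                         n_healthy = 8L,
                         n_replicates = 9L,
                         batch_shift_sd = 0.4,
                         batch_scale_range = c(0.8, 1.25),
                         noise_sd = 0.25,
                         baseline_mean_range = c(5, 11),
                         seed = 1L) {
  stopifnot_scalar_num(n_probes, "n_probes", min = 1)
  stopifnot_scalar_num(n_signature, "n_signature", min = 0)
  if (n_signature > n_probes) abort("`n_signature` must be <= `n_probes`.")
  if (length(effect_range) != 2L || any(effect_range < 0) ||
      diff(effect_range) < 0) {
    abort("`effect_range` must be an increasing pair of non-negative reals.")
  }
  stopifnot_scalar_num(retention_fraction, "retention_fraction", min = 0)
  if (retention_fraction > 1) abort("`retention_fraction` must be <= 1.")
  stopifnot_scalar_num(attenuation, "attenuation", min = 0)
  stopifnot_scalar_num(n_ssc, "n_ssc", min = 3)
  stopifnot_scalar_num(n_healthy, "n_healthy", min = 3)
  stopifnot_scalar_num(n_replicates, "n_replicates", min = 1)
  stopifnot_scalar_num(batch_shift_sd, "batch_shift_sd", min = 0)
  if (length(batch_scale_range) != 2L || any(batch_scale_range <= 0)) {
    abort("`batch_scale_range` must be a pair of positive reals.")
  }
  stopifnot_scalar_num(noise_sd, "noise_sd", min = 0)
  structure(
    list(
      n_probes = as.integer(n_probes),
      n_signature = as.integer(n_signature),
      effect_range = effect_range,
      retention_fraction = retention_fraction,
      attenuation = attenuation,
      n_ssc = as.integer(n_ssc),
      n_healthy = as.integer(n_healthy),
      n_replicates = as.integer(n_replicates),
      batch_shift_sd = batch_shift_sd,
      batch_scale_range = sort(batch_scale_range),
      noise_sd = noise_sd,
      baseline_mean_range = baseline_mean_range,
      seed = as.integer(seed)
    ),
    class = "study_config"
  )
}
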
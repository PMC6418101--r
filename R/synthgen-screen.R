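#' Simulate a multi-donor ASMA knockdown screen
#'
#' Generates, for each donor, a plate of negative-control wells (GFP shRNA),
#' positive-control wells (ACTA2 shRNA) and, if the config carries an shRNA
#' panel, test wells for each hairpin. Well scores are on the screen's
#' natural scale (density x area per nucleus, normalised so that the
#' negative-control expectation is 1): the positive control is centred at
#' `1 / fold_separation` and a test hairpin with true efficacy e at
#' `1 - e * (1 - 1 / fold_separation)`. Every well score is multiplied by a
#' shared per-donor lognormal random effect and by lognormal well noise with
#' CV `cv_noise`. Density, area and nuclei are decomposed so that
#' `density * area / nuclei` reproduces the drawn score exactly, making
#' table-based and image-based pipelines interchangeable.
#'
#' @param config A [screen_config()].
#' @return A list with class `screen_sim`:
#' \describe{
#'   \item{plate_map}{tibble: plate, well, donor, shrna_id, gene, role.}
#'   \item{wells}{tibble: plate, well, donor, shrna_id, gene, role,
#'     density, area, nuclei, score.}
#'   \item{truth}{list of tibbles — `donors` (donor, donor_effect),
#'     `shrnas` (shrna_id, gene, efficacy), `wells` (plate, well, true_mean).}
#' }
#' @export
#' @examples
#' sim <- simulate_screen(screen_config(n_donors = 2, wells_per_condition = 8))
#' head(sim$wells)
simulate_screen <- function(config) {
  if (!inherits(config, "screen_config")) abort("`config` must be a screen_config().")

  shrnas <- screen_shrna_truth(config)

  conditions <- dplyr::bind_rows(
    tibble::tibble(shrna_id = "shGFP", gene = "GFP", role = "negative",
                   efficacy = 0),
    tibble::tibble(shrna_id = "shACTA2", gene = "ACTA2", role = "positive",
                   efficacy = NA_real_),
    if (nrow(shrnas)) {
      tibble::tibble(shrna_id = shrnas$shrna_id, gene = shrnas$gene,
                     role = "test", efficacy = shrnas$efficacy)
    }
  )
  # positive-control mean is pinned at 1/fold_separation rather than derived
  # from a drawn ACTA2 efficacy, so the assay window is governed directly
  inhib_depth <- 1 - 1 / config$fold_separation
  conditions$true_mean <- ifelse(
    conditions$role == "positive",
    1 / config$fold_separation,
    1 - conditions$efficacy * inhib_depth
  ) + config$transduction_offset

  donors <- tibble::tibble(
    donor = sprintf("D%02d", seq_len(config$n_donors)),
    donor_effect = local_seed(
      stage_seed(config$seed, "donor"),
      if (config$donor_sdlog == 0) rep(1, config$n_donors)
      else rlnorm(config$n_donors, meanlog = -config$donor_sdlog^2 / 2,
                  sdlog = config$donor_sdlog)
    )
  )

  n_cond <- nrow(conditions)
  w <- config$wells_per_condition
  grid <- tidyr::expand_grid(donors, conditions)   # donor-major order
  grid <- grid[rep(seq_len(nrow(grid)), each = w), ]

  wells <- local_seed(stage_seed(config$seed, "screen"), {
    n <- nrow(grid)
    score <- grid$true_mean * grid$donor_effect * rlnorm_cv(n, config$cv_noise)
    nuclei <- pmax(1L, rpois(n, lambda = 200))
    area <- pmax(1, round(50 * sqrt(pmax(score, 0) * nuclei)))
    density <- score * nuclei / area
    dplyr::tibble(
      plate = grid$donor,
      well = rep(well_labels(n_cond * w), times = config$n_donors),
      donor = grid$donor,
      shrna_id = grid$shrna_id,
      gene = grid$gene,
      role = grid$role,
      density = density,
      area = as.integer(area),
      nuclei = as.integer(nuclei),
      score = score,
      true_mean = grid$true_mean
    )
  })

  plate_map <- dplyr::select(wells, "plate", "well", "donor", "shrna_id",
                             "gene", "role")
  truth_wells <- dplyr::select(wells, "plate", "well", "true_mean")
  wells$true_mean <- NULL

  structure(
    list(
      plate_map = plate_map,
      wells = wells,
      truth = list(donors = donors, shrnas = shrnas, wells = truth_wells)
    ),
    class = "screen_sim"
  )
}

# Draw each panel hairpin's true efficacy once from the mixture.
screen_shrna_truth <- function(config, n_shrnas = NULL) {
  panel <- config$shrna_panel
  if (!is.null(n_shrnas)) {
    n_genes <- ceiling(n_shrnas / 4)
    panel <- tibble::tibble(
      gene = sprintf("GENE%03d", seq_len(n_genes)),
      n_shrnas = diff(floor(seq(0, n_shrnas, length.out = n_genes + 1)))
    )
  }
  if (is.null(panel) || nrow(panel) == 0) {
    return(tibble::tibble(shrna_id = character(), gene = character(),
                          efficacy = numeric()))
  }
  genes <- rep(panel$gene, times = panel$n_shrnas)
  ids <- sprintf("sh%s_%d", genes,
                 unlist(lapply(panel$n_shrnas, seq_len), use.names = FALSE))
  eff <- local_seed(stage_seed(config$seed, "efficacy"),
                    draw_efficacy(length(ids), config$efficacy_model))
  tibble::tibble(shrna_id = ids, gene = genes, efficacy = eff)
}

draw_efficacy <- function(n, model) {
  is_eff <- runif(n) < model$w_eff
  eff <- numeric(n)
  eff[is_eff] <- rtruncnorm(sum(is_eff), model$eff_mean, model$eff_sd, 0, 1)
  eff[!is_eff] <- runif(sum(!is_eff), 0, model$ineff_max)
  eff
}

# 384-well style labels A01..P24, spilling into plate-relative numeric tails
well_labels <- function(n) {
  rows <- LETTERS[1:16]
  base <- as.vector(t(outer(rows, sprintf("%02d", 1:24), paste0)))
  if (n <= length(base)) return(base[seq_len(n)])
  reps <- ceiling(n / length(base))
  paste0(rep(base, reps)[seq_len(n)], ".", rep(seq_len(reps), each = length(base))[seq_len(n)])
}

#' Simulate an shRNA knockdown-efficacy panel
#'
#' Draws each hairpin's true knockdown efficacy once from the config's
#' efficacy mixture and reports, per donor, the observed relative target
#' expression `(1 - efficacy)` under multiplicative lognormal measurement
#' noise with CV `config$cv_noise` (set `cv_noise = 0` for noise-free
#' measurements).
#'
#' @param config A [screen_config()]; its `shrna_panel` (or
#'   [default_shrna_panel()] if `NULL`) defines the panel.
#' @param n_shrnas Optional override: simulate this many hairpins (grouped
#'   four per synthetic gene) instead of the config panel.
#' @return A list with elements `panel` (tibble: shrna_id, gene, donor,
#'   rel_expr) and `truth` (tibble: shrna_id, gene, efficacy).
#' @export
#' @examples
#' kd <- simulate_knockdown_panel(screen_config(n_donors = 2))
#' head(kd$panel)
simulate_knockdown_panel <- function(config, n_shrnas = NULL) {
  if (!inherits(config, "screen_config")) abort("`config` must be a screen_config().")
  cfg <- config
  if (is.null(cfg$shrna_panel) && is.null(n_shrnas)) {
    cfg$shrna_panel <- default_shrna_panel()
  }
  truth <- screen_shrna_truth(cfg, n_shrnas = n_shrnas)
  if (nrow(truth) == 0) abort("knockdown panel is empty; supply a panel or n_shrnas")

  donors <- sprintf("D%02d", seq_len(cfg$n_donors))
  panel <- tidyr::expand_grid(truth, donor = donors)
  panel$rel_expr <- local_seed(
    stage_seed(cfg$seed, "panel"),
    (1 - panel$efficacy) * rlnorm_cv(nrow(panel), cfg$cv_noise)
  )
  list(
    panel = dplyr::select(panel, "shrna_id", "gene", "donor", "rel_expr"),
    truth = truth
  )
}
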
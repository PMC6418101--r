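# Shared fixtures: noise-free render spec, small configs, a vector factory
# with exact sample moments, and an independently coded tier oracle.

quiet_spec <- function(width = 192L, height = 192L, ...) {
  image_spec(width = width, height = height, poisson_noise = FALSE,
             read_noise_sd = 0, ...)
}

small_screen <- function(...) {
  screen_config(n_donors = 2, wells_per_condition = 12, ...)
}

# length-2 vector with exact sample mean m and sample sd s
make_arm <- function(m, s) {
  c(m - s / sqrt(2), m + s / sqrt(2))
}

# Brute-force tier predicate evaluator, coded independently of
# classify_gene(): counts each predicate explicitly and walks the
# precedence ladder.
oracle_tier <- function(v, rules = tier_rules()) {
  above_hi <- length(which(v > rules$t_hi))
  in_lo_mid <- length(which(v > rules$t_lo & v < rules$t_mid))
  in_lo_hi <- length(which(v > rules$t_lo & v < rules$t_hi))
  if (above_hi >= rules$n_very_strong) return("very_strong")
  if (above_hi >= rules$n_strong) return("strong")
  if (above_hi >= 1 && in_lo_mid >= 1) return("moderate")
  if (in_lo_hi >= rules$n_weak) return("weak")
  "none"
}

# One full retention pipeline run at the generator defaults.
run_retention <- function(seed, config = study_config(seed = seed)) {
  sim <- simulate_expression_study(config)
  bc <- batch_correct(sim$exprs, sim$meta)
  de <- lapply(c("P0P1", "P4"), function(pg) {
    keep <- sim$meta$passage == pg & !sim$meta$is_replicate
    moderated_de(bc$exprs[, sim$meta$sample_id[keep]], sim$meta[keep, ])
  })
  compare_signatures(de[[1]], de[[2]])
}
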
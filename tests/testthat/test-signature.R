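test_that("batch correction matches the reference empirical-Bayes adjuster", {
  skip_if_not_installed("sva")
  sim <- simulate_expression_study(study_config(n_probes = 300,
                                                n_signature = 30, seed = 11))
  bc <- batch_correct(sim$exprs, sim$meta)
  ref <- suppressMessages(sva::ComBat(
    sim$exprs, batch = sim$meta$batch,
    mod = model.matrix(~ factor(sim$meta$disease))))
  expect_equal(bc$exprs, ref, tolerance = 1e-8)
})

test_that("single-batch input is returned unchanged", {
  sim <- simulate_expression_study(study_config(n_probes = 100,
                                                n_signature = 10, seed = 4))
  meta <- sim$meta
  meta$batch <- 1L
  bc <- batch_correct(sim$exprs, meta)
  expect_identical(bc$exprs, sim$exprs)
  expect_equal(nrow(tidy(bc)), 0)
})

test_that("pure additive batch shift is removed", {
  cfg <- study_config(n_probes = 400, n_signature = 0, batch_shift_sd = 0.8,
                      batch_scale_range = c(1, 1), noise_sd = 0.15, seed = 9)
  sim <- simulate_expression_study(cfg)
  bc <- batch_correct(sim$exprs, sim$meta)
  b <- factor(sim$meta$batch)
  gap <- rowMeans(bc$exprs[, b == 1]) - rowMeans(bc$exprs[, b == 2])
  gap_before <- rowMeans(sim$exprs[, b == 1]) - rowMeans(sim$exprs[, b == 2])
  expect_lt(mean(abs(gap)), 0.1)
  expect_lt(mean(abs(gap)), mean(abs(gap_before)) / 3)
})

test_that("correction shrinks replicate cross-batch distances", {
  sim <- simulate_expression_study(study_config(seed = 14))
  bc <- batch_correct(sim$exprs, sim$meta)
  reps <- sim$meta$sample_id[sim$meta$is_replicate]
  prim <- sub("_rep$", "", reps)
  dist_of <- function(m) {
    mean(sqrt(colMeans((m[, reps, drop = FALSE] - m[, prim, drop = FALSE])^2)))
  }
  expect_lt(dist_of(bc$exprs), dist_of(sim$exprs))
})

test_that("correction leaves the disease contrast essentially unbiased", {
  sim <- simulate_expression_study(study_config(seed = 19))
  keep <- sim$meta$passage == "P0P1" & !sim$meta$is_replicate
  meta <- sim$meta[keep, ]
  raw_fc <- function(m) {
    rowMeans(m[, meta$sample_id[meta$disease == "SSc"]]) -
      rowMeans(m[, meta$sample_id[meta$disease == "healthy"]])
  }
  bc <- batch_correct(sim$exprs, sim$meta)
  sig <- sim$truth$probes$is_signature
  bias <- mean(raw_fc(bc$exprs[, meta$sample_id])[sig] -
                 raw_fc(sim$exprs[, meta$sample_id])[sig])
  expect_lt(abs(bias), 0.05)
})

test_that("confounded batch and covariate is refused", {
  sim <- simulate_expression_study(study_config(seed = 5))
  meta <- sim$meta[!sim$meta$is_replicate, ]
  meta$batch <- ifelse(meta$disease == "SSc", 1L, 2L)
  expect_error(batch_correct(sim$exprs[, meta$sample_id], meta), "confounded")
})

test_that("null data produce essentially no composite-rule calls", {
  set.seed(3)
  n <- 2000
  mat <- matrix(rnorm(n * 12, 0, 0.3) + runif(n, 5, 11), n, 12,
                dimnames = list(sprintf("P%05d", 1:n), sprintf("s%02d", 1:12)))
  meta <- tibble::tibble(sample_id = colnames(mat),
                         disease = rep(c("SSc", "healthy"), each = 6))
  de <- moderated_de(mat, meta)
  expect_lte(mean(de$significant), 0.002)
})

test_that("a strongly planted effect is called significant", {
  set.seed(8)
  n <- 500
  mat <- matrix(rnorm(n * 16, 0, 0.25) + 7, n, 16,
                dimnames = list(sprintf("P%05d", 1:n), sprintf("s%02d", 1:16)))
  mat[1, 1:8] <- mat[1, 1:8] + 2   # log2FC = 2 in the case group
  meta <- tibble::tibble(sample_id = colnames(mat),
                         disease = rep(c("SSc", "healthy"), each = 8))
  de <- moderated_de(mat, meta)
  expect_true(de$significant[1])
  expect_equal(de$log2fc[1], 2, tolerance = 0.3)
})

test_that("paired mode on identical pair members gives exactly zero log2FC", {
  n <- 100
  half <- matrix(rnorm(n * 4, 0, 1) + 6, n, 4)
  mat <- cbind(half, half)
  dimnames(mat) <- list(sprintf("P%05d", 1:n), sprintf("s%02d", 1:8))
  meta <- tibble::tibble(
    sample_id = colnames(mat),
    disease = rep(c("SSc", "healthy"), each = 4),
    donor = rep(sprintf("d%d", 1:4), 2)
  )
  # zero-variance differences make eBayes warn; the fit itself is exact
  de <- suppressWarnings(moderated_de(mat, meta, paired = TRUE))
  expect_equal(de$log2fc, rep(0, n))
})

test_that("BH q-values are monotone in p and selection grows with alpha", {
  set.seed(12)
  mat <- matrix(rnorm(500 * 10, 0, 0.3) + 6, 500, 10,
                dimnames = list(sprintf("P%05d", 1:500), sprintf("s%02d", 1:10)))
  mat[1:30, 1:5] <- mat[1:30, 1:5] + runif(30, 0.5, 2)
  meta <- tibble::tibble(sample_id = colnames(mat),
                         disease = rep(c("SSc", "healthy"), each = 5))
  de <- moderated_de(mat, meta)
  ord <- order(de$p)
  expect_true(all(diff(de$q[ord]) >= -1e-12))
  expect_equal(de$q, p.adjust(de$p, "BH"))
  n_sel <- vapply(c(0.001, 0.01, 0.05, 0.2),
                  function(a) sum(de$q < a), integer(1))
  expect_true(all(diff(n_sel) >= 0))
})

test_that("moderated t approaches the ordinary t as noise vanishes", {
  cfg <- study_config(n_probes = 400, n_signature = 40, noise_sd = 0.02,
                      batch_shift_sd = 0, batch_scale_range = c(1, 1),
                      seed = 6)
  sim <- simulate_expression_study(cfg)
  keep <- sim$meta$passage == "P0P1" & !sim$meta$is_replicate
  mat <- sim$exprs[, sim$meta$sample_id[keep]]
  meta <- sim$meta[keep, ]
  de <- moderated_de(mat, meta)
  # exact recovery of the planted signature
  expect_setequal(de$probe_id[de$significant],
                  sim$truth$probes$probe_id[sim$truth$probes$is_signature])
  ssc <- meta$sample_id[meta$disease == "SSc"]
  hs <- meta$sample_id[meta$disease == "healthy"]
  t_ord <- vapply(seq_len(nrow(mat)), function(i) {
    t.test(mat[i, ssc], mat[i, hs], var.equal = TRUE)$statistic
  }, numeric(1))
  # moderation rescales each probe's t by s_g / s~_g; with vanishing noise
  # the ordering and inference agree even though per-probe ratios jitter
  expect_gt(cor(de$t, t_ord, method = "spearman"), 0.95)
  expect_equal(sign(de$t), sign(t_ord))
})

test_that("select_degs applies the four strict gates", {
  res <- tibble::tibble(
    probe_id = c("a", "b", "c", "d", "e"),
    log2fc = c(1.0, 1.0, 0.5, 1.0, -1.0),
    t = 5, p = 1e-4,
    q = c(0.005, 0.005, 0.005, 0.005, 0.005),
    lods = c(2, 2, 2, -1, 2),
    avg_expr = c(6, 3.5, 6, 6, 6)
  )
  sel <- select_degs(res, de_thresholds())
  expect_setequal(sel$probe_id, c("a", "e"))   # b fails avg, c fails FC, d lods
  expect_equal(sel$direction, c("up", "down"))
  expect_equal(nrow(select_degs(res[0, ], de_thresholds())), 0)
})

test_that("compare_signatures reproduces the worked retention example", {
  base <- tibble::tibble(probe_id = sprintf("p%04d", 1:926))
  follow <- base[1:717, ]
  cmp <- compare_signatures(base, follow)
  expect_equal(cmp$n_overlap, 717)
  expect_equal(cmp$retention_pct_reported, 77)
  expect_equal(cmp$retention_pct, 100 * 717 / 926)
})

test_that("compare_signatures limit cases behave", {
  fc <- tibble::tibble(probe_id = letters[1:5], log2fc = c(1, -2, 0.5, 3, -1))
  same <- compare_signatures(fc, fc)
  expect_equal(same$retention_pct, 100)
  expect_equal(same$pearson_r, 1)
  disj <- compare_signatures(fc, tibble::tibble(probe_id = LETTERS[1:3]))
  expect_equal(disj$retention_pct, 0)
  expect_error(compare_signatures(fc[0, ], fc), "empty")
})

test_that("probe collapsing keeps the strongest probe per gene", {
  res <- tibble::tibble(probe_id = c("p1", "p2", "p3"),
                        log2fc = c(0.5, -1.4, 0.2))
  map <- tibble::tibble(probe_id = c("p1", "p2", "p3"),
                        gene = c("G1", "G1", "G2"))
  out <- collapse_probes(res, map)
  expect_equal(out$probe_id[out$gene == "G1"], "p2")
})
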
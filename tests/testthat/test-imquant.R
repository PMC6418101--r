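test_that("blank and constant images segment to zero nuclei", {
  blank <- matrix(400, 64, 64)
  seg <- segment_nuclei(blank)
  expect_equal(seg$count, 0)
  expect_true(all(seg$labels == 0))
  expect_error(segment_nuclei(matrix(numeric(0), 0, 0)), "nonempty")
})

test_that("touching spots merge into one component (under-segmentation)", {
  img <- matrix(0, 64, 64)
  xs <- seq_len(64)
  for (cx in c(30, 36)) {  # closer than two spot radii -> overlapping blobs
    img <- img + 10000 * exp(-(outer((xs - 32)^2, (xs - cx)^2, "+")) / (2 * 4^2))
  }
  seg <- segment_nuclei(img + 400)
  expect_equal(seg$count, 1)
})

test_that("diagonally adjacent pixels join one 8-connected component", {
  img <- matrix(0, 32, 32)
  img[10, 10] <- img[11, 11] <- img[12, 12] <- 60000
  seg <- segment_nuclei(img, quant_params(min_nucleus_area = 1))
  expect_equal(seg$count, 1)
})

test_that("small components are discarded by min_nucleus_area", {
  img <- matrix(0, 32, 32)
  img[5:8, 5:8] <- 60000        # 16 px
  img[20, 20] <- 60000          # 1 px speck
  seg <- segment_nuclei(img, quant_params(min_nucleus_area = 4))
  expect_equal(seg$count, 1)
})

test_that("painted uniform ASMA region recovers its density x area", {
  dapi <- matrix(0, 64, 64); dapi[30:34, 30:34] <- 50000
  asma <- matrix(100, 64, 64)
  asma[10:29, 10:29] <- 8000   # 400 px at 8000 AU
  q <- quantify_asma(list(dapi = dapi, asma = asma),
                     quant_params(asma_threshold = "fixed", asma_fixed = 4000))
  expect_equal(q$area, 400L)
  expect_equal(q$density * q$area, 8000 * 400, tolerance = 0.05)
})

test_that("empty stain gives zero area, density and score", {
  dapi <- matrix(0, 48, 48); dapi[20:24, 20:24] <- 50000
  asma <- matrix(100, 48, 48)
  q <- quantify_asma(list(dapi = dapi, asma = asma),
                     quant_params(asma_threshold = "fixed", asma_fixed = 4000))
  expect_equal(q$area, 0L)
  expect_equal(q$density, 0)
  expect_equal(q$score, 0)
})

test_that("score is undefined (NA) when no nuclei are detected", {
  asma <- matrix(0, 48, 48); asma[10:20, 10:20] <- 9000
  q <- quantify_asma(list(dapi = matrix(100, 48, 48), asma = asma),
                     quant_params(asma_threshold = "fixed", asma_fixed = 4000))
  expect_false(q$score_defined)
  expect_true(is.na(q$score))
  expect_gt(q$area, 0)
})

test_that("channel shape mismatch errors", {
  expect_error(
    quantify_asma(list(dapi = matrix(0, 10, 10), asma = matrix(0, 10, 12))),
    "mismatch")
})

test_that("score is invariant to sub-threshold background shifts and area is
           monotone under amplitude scaling", {
  spec <- quiet_spec()
  img <- render_well_image(6, 700, spec, seed = 11)
  fixed <- quant_params(dapi_threshold = "fixed", dapi_fixed = 3000,
                        asma_threshold = "fixed", asma_fixed = 1000)
  q0 <- quantify_asma(img, fixed)
  shifted <- list(dapi = img$dapi, asma = img$asma + 200)  # still < threshold?
  # shift background only where below threshold minus margin stays below
  shifted$asma <- ifelse(img$asma < 600, img$asma + 200, img$asma)
  qs <- quantify_asma(shifted, fixed)
  expect_equal(qs$score, q0$score)
  scaled <- list(dapi = img$dapi * 1.5, asma = img$asma * 1.5)
  qsc <- quantify_asma(scaled, fixed)
  expect_gte(qsc$area, q0$area)
})

test_that("quantifier recovers generator nuclei counts exactly (property)", {
  spec <- quiet_spec()
  for (seed in 1:12) {
    n <- 3 + (seed %% 8)
    img <- render_well_image(n, 400, spec, seed = seed)
    expect_equal(segment_nuclei(img$dapi)$count, n, label = paste("seed", seed))
  }
})

test_that("quantify_wells matches the simulated well-table schema", {
  spec <- quiet_spec(width = 96L, height = 96L)
  imgs <- list(A01 = render_well_image(4, 500, spec, seed = 1),
               A02 = render_well_image(6, 900, spec, seed = 2))
  wt <- quantify_wells(imgs)
  expect_equal(wt$well, c("A01", "A02"))
  expect_true(all(c("density", "area", "nuclei", "score") %in% names(wt)))
  expect_equal(wt$nuclei, c(4L, 6L))
})
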
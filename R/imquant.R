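#' Quantification parameters for two-channel well images
#'
#' @param dapi_threshold,asma_threshold Threshold method per channel:
#'   `"otsu"` (default) or `"fixed"`.
#' @param dapi_fixed,asma_fixed Fixed thresholds in AU (16-bit scale);
#'   required when the corresponding method is `"fixed"`.
#' @param min_nucleus_area Minimum connected-component size (px) kept as a
#'   nucleus.
#' @return An object of class `quant_params`.
#' @export
quant_params <- function(dapi_threshold = c("otsu", "fixed"),
                         asma_threshold = c("otsu", "fixed"),
                         dapi_fixed = NULL, asma_fixed = NULL,
                         min_nucleus_area = 9L) {
  dapi_threshold <- match.arg(dapi_threshold)
  asma_threshold <- match.arg(asma_threshold)
  stopifnot_scalar_num(min_nucleus_area, "min_nucleus_area", min = 1)
  check_fixed <- function(x, name, method) {
    if (method == "fixed") {
      if (is.null(x)) abort(sprintf("`%s` is required with a fixed threshold.", name))
      stopifnot_scalar_num(x, name, min = 0)
      if (x > 65535) abort(sprintf("`%s` exceeds the 16-bit range.", name))
    }
  }
  check_fixed(dapi_fixed, "dapi_fixed", dapi_threshold)
  check_fixed(asma_fixed, "asma_fixed", asma_threshold)
  structure(
    list(dapi_threshold = dapi_threshold, asma_threshold = asma_threshold,
         dapi_fixed = dapi_fixed, asma_fixed = asma_fixed,
         min_nucleus_area = as.integer(min_nucleus_area)),
    class = "quant_params"
  )
}

# Channel threshold in AU. Otsu runs on the [0,1]-normalised image; a
# constant image has no Otsu separation and maps everything to background.
channel_threshold <- function(img, method, fixed) {
  if (method == "fixed") return(fixed)
  rng <- range(img)
  if (!all(is.finite(rng))) abort("image contains non-finite pixels")
  if (rng[1] == rng[2]) return(Inf)
  EBImage::otsu(EBImage::Image(img / 65535), range = c(0, 1)) * 65535
}

#' Segment nuclei in a DAPI channel
#'
#' Thresholds the channel (Otsu by default), labels connected components
#' with 8-connectivity, and discards components smaller than
#' `min_nucleus_area` pixels. A constant image yields zero nuclei (no
#' threshold separation), which is a documented degenerate case rather than
#' an error. Touching nuclei merge into one component; under-segmentation
#' is accepted behaviour.
#'
#' @param dapi Numeric matrix (single channel, AU on the 16-bit scale).
#' @param params A [quant_params()].
#' @return List: `count` (integer) and `labels` (integer matrix, 0 =
#'   background).
#' @export
#' @examples
#' img <- render_well_image(6, 500,
#'                          image_spec(poisson_noise = FALSE, read_noise_sd = 0),
#'                          seed = 2)
#' segment_nuclei(img$dapi)$count
segment_nuclei <- function(dapi, params = quant_params()) {
  if (!is.matrix(dapi) || length(dapi) == 0) {
    abort("`dapi` must be a nonempty numeric matrix.")
  }
  thr <- channel_threshold(dapi, params$dapi_threshold, params$dapi_fixed)
  mask <- dapi > thr
  if (!any(mask)) {
    return(list(count = 0L, labels = matrix(0L, nrow(dapi), ncol(dapi))))
  }
  labels <- label_components8(mask)
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes >= params$min_nucleus_area)
  relabel <- integer(length(sizes))
  relabel[keep] <- seq_along(keep)
  labels[labels > 0] <- relabel[labels[labels > 0]]
  list(count = length(keep), labels = labels)
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that
# touch diagonally are merged with a union-find pass.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1]))    # up-right
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relabel <- match(roots, sort(unique(roots)))
  lab[lab > 0] <- relabel[lab[lab > 0]]
  lab
}

#' Quantify a two-channel well image into the ASMA score
#'
#' Computes the screen's per-well readout from a registered (DAPI, ASMA)
#' image pair: `area` is the count of ASMA pixels above threshold,
#' `density` the mean ASMA intensity over those pixels (0 when the stain is
#' empty), `nuclei` the DAPI nucleus count from [segment_nuclei()], and
#' `score = density * area / nuclei` — the integrated suprathreshold ASMA
#' intensity per nucleus. With zero nuclei the score is undefined (`NA`)
#' and the well should be excluded downstream.
#'
#' @param image A `well_image` from [render_well_image()] /
#'   [read_well_tiff()], or a list with `dapi` and `asma` matrices of equal
#'   dimensions.
#' @param params A [quant_params()].
#' @return One-row tibble: density, area, nuclei, score, score_defined.
#' @export
#' @examples
#' img <- render_well_image(8, 800,
#'                          image_spec(poisson_noise = FALSE, read_noise_sd = 0),
#'                          seed = 4)
#' quantify_asma(img)
quantify_asma <- function(image, params = quant_params()) {
  dapi <- image$dapi; asma <- image$asma
  if (is.null(dapi) || is.null(asma)) abort("`image` needs `dapi` and `asma`.")
  if (!identical(dim(dapi), dim(asma))) {
    abort("DAPI and ASMA channels have mismatched dimensions.")
  }
  seg <- segment_nuclei(dapi, params)
  thr <- channel_threshold(asma, params$asma_threshold, params$asma_fixed)
  stained <- asma > thr
  area <- sum(stained)
  density <- if (area > 0) mean(asma[stained]) else 0
  score <- if (seg$count > 0) density * area / seg$count else NA_real_
  tibble::tibble(
    density = density, area = as.integer(area), nuclei = seg$count,
    score = score, score_defined = seg$count > 0
  )
}

#' Quantify a set of well images into a well table
#'
#' Maps [quantify_asma()] over a named list of images (or TIFF paths) and
#' returns rows compatible with the simulated well-table schema.
#'
#' @param images Named list of `well_image` objects or TIFF file paths.
#' @param params A [quant_params()].
#' @return Tibble: well, density, area, nuclei, score, score_defined.
#' @export
quantify_wells <- function(images, params = quant_params()) {
  if (!length(images)) abort("`images` is empty.")
  wells <- names(images) %||% as.character(seq_along(images))
  purrr::map2_dfr(images, wells, function(img, w) {
    if (is.character(img)) img <- read_well_tiff(img)
    dplyr::bind_cols(tibble::tibble(well = w), quantify_asma(img, params))
  })
}
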
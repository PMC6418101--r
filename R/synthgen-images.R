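#' Rendering parameters for synthetic two-channel well images
#'
#' Describes the geometry, amplitudes and noise model of the synthetic
#' fluorescence renderer: nuclei are isotropic Gaussian spots in the DAPI
#' channel; ASMA signal is drawn as elongated stress-fibre-like strokes
#' (anisotropic Gaussians at random orientations) whose amplitude is
#' proportional to the requested per-cell ASMA level. Intensities are on a
#' 16-bit scale (0-65535).
#'
#' @param width,height Image size in pixels.
#' @param nucleus_radius Gaussian sigma of a nucleus spot (px).
#' @param nucleus_amplitude Peak DAPI amplitude of a nucleus (AU).
#' @param asma_length,asma_width Stroke sigmas along/across its axis (px).
#' @param asma_amplitude_scale Peak ASMA amplitude per unit `asma_level`.
#' @param background Constant background level added to both channels (AU).
#' @param poisson_noise Apply Poisson shot noise?
#' @param read_noise_sd Gaussian read-noise sd (AU); 0 disables.
#' @param min_separation Minimum distance between nucleus centres (px).
#' @param max_clip_fraction Maximum tolerated fraction of clipped pixels.
#' @return An object of class `image_spec`.
#' @export
image_spec <- function(width = 256L, height = 256L,
                       nucleus_radius = 4, nucleus_amplitude = 12000,
                       asma_length = 18, asma_width = 2.5,
                       asma_amplitude_scale = 8,
                       background = 400,
                       poisson_noise = TRUE, read_noise_sd = 30,
                       min_separation = 24,
                       max_clip_fraction = 0.01) {
  stopifnot_scalar_num(width, "width", min = 8)
  stopifnot_scalar_num(height, "height", min = 8)
  stopifnot_scalar_num(nucleus_radius, "nucleus_radius", positive = TRUE)
  stopifnot_scalar_num(min_separation, "min_separation", min = 0)
  stopifnot_scalar_num(background, "background", min = 0)
  stopifnot_scalar_num(read_noise_sd, "read_noise_sd", min = 0)
  structure(
    list(width = as.integer(width), height = as.integer(height),
         bit_depth = 16L,
         nucleus_radius = nucleus_radius,
         nucleus_amplitude = nucleus_amplitude,
         asma_length = asma_length, asma_width = asma_width,
         asma_amplitude_scale = asma_amplitude_scale,
         background = background,
         poisson_noise = poisson_noise, read_noise_sd = read_noise_sd,
         min_separation = min_separation,
         max_clip_fraction = max_clip_fraction),
    class = "image_spec"
  )
}

#' Render a synthetic two-channel well image
#'
#' Places `nuclei_count` nucleus spots at random centres honouring the
#' spec's minimum separation, draws one ASMA stroke per nucleus with peak
#' amplitude `asma_amplitude_scale * asma_level`, adds the constant
#' background, and (optionally) applies Poisson shot noise plus Gaussian
#' read noise. The ground truth (centres, orientations, noise-free masks)
#' is returned alongside the pixels.
#'
#' @param nuclei_count Number of nuclei to place (>= 0).
#' @param asma_level Per-cell ASMA level (>= 0); linear in rendered signal.
#' @param spec An [image_spec()].
#' @param seed Seed for placement and noise.
#' @return A list of class `well_image` with elements `dapi` and `asma`
#'   (numeric matrices, AU on the 16-bit scale), and `truth` (list with
#'   `centers` tibble, `nuclei_count`, `dapi_signal`, `asma_signal` —
#'   the noise-free signal fields without background).
#' @export
#' @examples
#' img <- render_well_image(5, asma_level = 800,
#'                          spec = image_spec(poisson_noise = FALSE,
#'                                            read_noise_sd = 0),
#'                          seed = 1)
#' range(img$dapi)
render_well_image <- function(nuclei_count, asma_level, spec = image_spec(),
                              seed = 1L) {
  if (!inherits(spec, "image_spec")) abort("`spec` must be an image_spec().")
  stopifnot_scalar_num(nuclei_count, "nuclei_count", min = 0)
  stopifnot_scalar_num(asma_level, "asma_level", min = 0)

  local_seed(stage_seed(seed, "image"), {
    centers <- place_nuclei(nuclei_count, spec)
    xs <- seq_len(spec$width)
    ys <- seq_len(spec$height)

    dapi_sig <- matrix(0, spec$height, spec$width)
    asma_sig <- matrix(0, spec$height, spec$width)
    if (nrow(centers)) {
      centers$theta <- runif(nrow(centers), 0, pi)
      for (i in seq_len(nrow(centers))) {
        dx <- outer(rep(1, spec$height), xs - centers$x[i])
        dy <- outer(ys - centers$y[i], rep(1, spec$width))
        dapi_sig <- dapi_sig + spec$nucleus_amplitude *
          exp(-(dx^2 + dy^2) / (2 * spec$nucleus_radius^2))
        th <- centers$theta[i]
        u <- dx * cos(th) + dy * sin(th)     # along stroke
        v <- -dx * sin(th) + dy * cos(th)    # across stroke
        asma_sig <- asma_sig + spec$asma_amplitude_scale * asma_level *
          exp(-(u^2 / (2 * spec$asma_length^2) +
                  v^2 / (2 * spec$asma_width^2)))
      }
    }

    max_au <- 2^spec$bit_depth - 1
    dapi <- add_camera_noise(dapi_sig + spec$background, spec)
    asma <- add_camera_noise(asma_sig + spec$background, spec)
    clip_frac <- mean(c(dapi, asma) > max_au)
    if (clip_frac > spec$max_clip_fraction) {
      warn(sprintf("%.1f%% of pixels clip at the 16-bit ceiling", 100 * clip_frac))
    }
    dapi <- pmin(dapi, max_au)
    asma <- pmin(asma, max_au)

    structure(
      list(dapi = dapi, asma = asma,
           truth = list(centers = centers, nuclei_count = nrow(centers),
                        dapi_signal = dapi_sig, asma_signal = asma_sig)),
      class = "well_image"
    )
  })
}

place_nuclei <- function(n, spec) {
  if (n == 0) {
    return(tibble::tibble(x = numeric(), y = numeric()))
  }
  margin <- 3 * spec$nucleus_radius
  if (spec$width - 2 * margin < 1 || spec$height - 2 * margin < 1) {
    abort("image too small for the nucleus radius")
  }
  xs <- numeric(0); ys <- numeric(0)
  attempts <- 0L
  while (length(xs) < n) {
    attempts <- attempts + 1L
    if (attempts > 200L * n) {
      abort(sprintf(
        "could not place %d nuclei with min separation %.1f px in a %dx%d field",
        n, spec$min_separation, spec$width, spec$height))
    }
    cx <- runif(1, margin, spec$width - margin)
    cy <- runif(1, margin, spec$height - margin)
    if (!length(xs) ||
        min(sqrt((xs - cx)^2 + (ys - cy)^2)) >= spec$min_separation) {
      xs <- c(xs, cx); ys <- c(ys, cy)
    }
  }
  tibble::tibble(x = xs, y = ys)
}

add_camera_noise <- function(img, spec) {
  out <- img
  if (isTRUE(spec$poisson_noise)) {
    out <- matrix(rpois(length(out), lambda = pmax(out, 0)),
                  nrow(out), ncol(out))
  }
  if (spec$read_noise_sd > 0) {
    out <- out + rnorm(length(out), 0, spec$read_noise_sd)
  }
  pmax(out, 0)
}

#' Write / read a two-channel well image as 16-bit TIFF
#'
#' The image is stored as a two-page 16-bit grayscale TIFF with the DAPI
#' channel first, the format produced by high-content imagers.
#'
#' @param image A `well_image` (or list with `dapi` and `asma` matrices).
#' @param path Output path.
#' @return `write_well_tiff()` returns `path` invisibly; `read_well_tiff()`
#'   returns a list with `dapi` and `asma` matrices on the 16-bit AU scale.
#' @export
write_well_tiff <- function(image, path) {
  max_au <- 65535
  pages <- list(image$dapi / max_au, image$asma / max_au)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_well_tiff
#' @export
read_well_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2) abort("expected a two-page (DAPI, ASMA) TIFF")
  list(dapi = pages[[1]] * 65535, asma = pages[[2]] * 65535)
}
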
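#' Configuration for one synthetic phantom center
#'
#' Describes a single simulated acquisition center: how many benign and
#' malignant lesion images to draw, the image size, and the knobs that
#' control how ultrasound-like and how separable the images are.
#'
#' Phantom images emulate B-mode breast ultrasound at small scale: a
#' speckle-textured background (multiplicative log-normal noise), a darker
#' lesion whose boundary irregularity correlates with class (benign lesions
#' are near-elliptical, malignant lesions carry a larger-amplitude,
#' higher-harmonic radial perturbation), and a configurable
#' lesion-to-background contrast.
#'
#' @param image_size Pixels per side (square images), at least 8. Default 32.
#' @param n_benign,n_malignant Number of images per class (non-negative).
#' @param center_id Character label for the simulated center.
#' @param speckle_sigma Scale of multiplicative log-normal speckle, in
#'   `[0, 0.5]`. 0 disables speckle.
#' @param contrast Lesion-to-background intensity gap, in `[0, 1]`.
#' @param irregularity_gap Difference in boundary-perturbation amplitude
#'   between malignant and benign lesions; larger values make the classes
#'   easier to separate by shape.
#' @param seed Integer seed; identical configuration + seed gives
#'   bit-identical output.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 32, n_benign = 10, n_malignant = 10,
                           center_id = "center", speckle_sigma = 0.1,
                           contrast = 0.4, irregularity_gap = 0.25, seed = 1) {
  if (!is.numeric(image_size) || image_size < 8) {
    fh_stop("image_size must be a number >= 8", "fh_invalid_config")
  }
  if (n_benign < 0 || n_malignant < 0) {
    fh_stop("class counts must be non-negative", "fh_invalid_config")
  }
  if (speckle_sigma < 0 || speckle_sigma > 0.5) {
    fh_stop("speckle_sigma must lie in [0, 0.5]", "fh_invalid_config")
  }
  if (contrast < 0 || contrast > 1) {
    fh_stop("contrast must lie in [0, 1]", "fh_invalid_config")
  }
  structure(list(image_size = as.integer(image_size),
                 n_benign = as.integer(n_benign),
                 n_malignant = as.integer(n_malignant),
                 center_id = center_id,
                 speckle_sigma = speckle_sigma,
                 contrast = contrast,
                 irregularity_gap = irregularity_gap,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

## background gray level around which lesions are carved
.fh_background_level <- 0.75

## draw one lesion image; returns list(image, mask)
## label 0 = benign (small smooth perturbation), 1 = malignant (spiculated)
.fh_draw_lesion <- function(size, label, speckle_sigma, contrast,
                            irregularity_gap) {
  half <- size / 2
  cy <- half + stats::runif(1, -0.08, 0.08) * size
  cx <- half + stats::runif(1, -0.08, 0.08) * size
  ry <- stats::runif(1, 0.18, 0.28) * size
  rx <- stats::runif(1, 0.18, 0.28) * size
  rot <- stats::runif(1, 0, pi)
  amp <- 0.04 + if (label == 1) irregularity_gap else 0
  harm <- if (label == 1) sample(6:9, 1) else sample(2:3, 1)
  phase <- stats::runif(1, 0, 2 * pi)

  rr <- matrix(seq_len(size), size, size) - cy
  cc <- matrix(seq_len(size), size, size, byrow = TRUE) - cx
  u <- cos(rot) * rr + sin(rot) * cc
  v <- -sin(rot) * rr + cos(rot) * cc
  rho <- sqrt((u / ry)^2 + (v / rx)^2)
  theta <- atan2(v, u)
  mask <- rho <= 1 + amp * sin(harm * theta + phase)

  base <- matrix(.fh_background_level, size, size)
  base[mask] <- .fh_background_level - contrast
  if (speckle_sigma > 0) {
    z <- matrix(stats::rnorm(size * size), size, size)
    base <- base * exp(speckle_sigma * z - speckle_sigma^2 / 2)
  }
  list(image = clip01(base), mask = mask)
}

#' Generate one center's worth of synthetic lesion images
#'
#' Draws `n_benign + n_malignant` labeled phantom images under the given
#' configuration. Benign lesions are near-elliptical; malignant lesions have
#' a boundary-perturbation amplitude larger by `irregularity_gap`. The
#' ground-truth lesion footprint is attached to every sample as `mask` so
#' tests can interrogate the generator.
#'
#' @param config A [phantom_config()].
#' @return A list of samples; each sample is a list with elements `image`
#'   (numeric matrix, intensities in `[0, 1]`), `label` (0 benign,
#'   1 malignant), `center_id`, `sample_id` and `mask` (logical matrix).
#' @export
#' @examples
#' smp <- generate_center(phantom_config(n_benign = 2, n_malignant = 2, seed = 7))
#' length(smp)
generate_center <- function(config) {
  if (!inherits(config, "phantom_config")) config <- do.call(phantom_config, config)
  labels <- c(rep(0L, config$n_benign), rep(1L, config$n_malignant))
  set.seed(derive_seed(config$seed, "phantoms", config$center_id))
  lapply(seq_along(labels), function(i) {
    drawn <- .fh_draw_lesion(config$image_size, labels[i],
                             config$speckle_sigma, config$contrast,
                             config$irregularity_gap)
    list(image = drawn$image, label = labels[i],
         center_id = config$center_id,
         sample_id = sprintf("%s-%04d", config$center_id, i),
         mask = drawn$mask)
  })
}

#' Generate the default three-center phantom study
#'
#' Emulates a three-center breast-ultrasound study: per-class counts are
#' proportional (at the given `scale`) to a 437/210, 109/54, 96/104
#' benign/malignant composition, and image quality worsens monotonically
#' from center A to center C (increasing speckle, decreasing contrast),
#' emulating datasets of decreasing perceptual quality.
#'
#' @param seed Integer seed.
#' @param scale Scaling factor applied to the per-class counts
#'   (default 0.1, i.e. 44/21, 11/5, 10/10).
#' @param image_size Pixels per side (default 32).
#' @return Named list `centerA`, `centerB`, `centerC` of sample lists, with
#'   the three [phantom_config()]s attached as attribute `"configs"`.
#' @export
generate_three_centers <- function(seed = 1, scale = 0.1, image_size = 32) {
  base_counts <- list(centerA = c(437, 210), centerB = c(109, 54),
                      centerC = c(96, 104))
  quality <- list(centerA = c(sigma = 0.08, contrast = 0.45),
                  centerB = c(sigma = 0.15, contrast = 0.40),
                  centerC = c(sigma = 0.30, contrast = 0.25))
  configs <- lapply(names(base_counts), function(id) {
    n <- round(base_counts[[id]] * scale)
    q <- quality[[id]]
    phantom_config(image_size = image_size, n_benign = n[1],
                   n_malignant = n[2], center_id = id,
                   speckle_sigma = q[["sigma"]], contrast = q[["contrast"]],
                   irregularity_gap = 0.25, seed = seed)
  })
  names(configs) <- names(base_counts)
  out <- lapply(configs, generate_center)
  attr(out, "configs") <- configs
  out
}

#' Write a phantom center to disk as PNG files plus a CSV manifest
#'
#' @param samples A list of samples as returned by [generate_center()].
#' @param dir Output directory (created if absent); one PNG per sample and a
#'   `manifest.csv` with columns sample_id, center_id, label, path.
#' @return Invisibly, the manifest data frame.
#' @export
write_center_dataset <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(samples, function(s) {
    path <- file.path(dir, paste0(s$sample_id, ".png"))
    png::writePNG(s$image, path)
    data.frame(sample_id = s$sample_id, center_id = s$center_id,
               label = s$label, path = path, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset back from a manifest written by [write_center_dataset()]
#'
#' Also serves as the real-data adapter: any directory of grayscale PNG
#' images with a CSV listing sample_id, center_id, label and path loads the
#' same way. RGB sources are converted to gray by channel average.
#'
#' @param manifest_path Path to the manifest CSV.
#' @return A list of samples (image/label/center_id/sample_id).
#' @export
read_center_dataset <- function(manifest_path) {
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    img <- png::readPNG(manifest$path[i])
    if (length(dim(img)) == 3) img <- apply(img[, , seq_len(min(3, dim(img)[3])), drop = FALSE], c(1, 2), mean)
    list(image = img, label = as.integer(manifest$label[i]),
         center_id = manifest$center_id[i], sample_id = manifest$sample_id[i])
  })
}
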
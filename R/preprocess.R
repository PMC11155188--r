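#' Dataset split specification
#'
#' Fractions default to the conventional 60/20/20 train/validation/test
#' split. Per class (when stratified), validation and test each receive
#' `floor(fraction * n_class)` samples and training receives the remainder;
#' membership within a class is a seeded random permutation.
#'
#' @param train_fraction,val_fraction,test_fraction Split fractions; must sum
#'   to 1.
#' @param stratified Split within each class separately (default TRUE).
#' @param seed Integer seed for the within-class permutation.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.6, val_fraction = 0.2,
                       test_fraction = 0.2, stratified = TRUE, seed = 1) {
  if (abs(train_fraction + val_fraction + test_fraction - 1) > 1e-8) {
    fh_stop("split fractions must sum to 1", "fh_invalid_config")
  }
  structure(list(train_fraction = train_fraction, val_fraction = val_fraction,
                 test_fraction = test_fraction, stratified = isTRUE(stratified),
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Augmentation parameters
#'
#' The augmentation stack applied to each training image, in order: random
#' horizontal/vertical flip, additive Gaussian noise, random affine
#' transformation (scale, rotation, shear, translation). The training set is
#' multiplied `copies`-fold; copy 0 is the untouched source image.
#'
#' @param flip_probability Probability of each of the horizontal and vertical
#'   flips (default 0.5).
#' @param scale_range Uniform range of isotropic scale (default 0.9--1.1).
#' @param rotation_range Max absolute rotation in degrees (default 3).
#' @param shear_range Max absolute shear in degrees (default 3).
#' @param translation_range Max absolute translation as a fraction of the
#'   image side (default 0.0625).
#' @param noise_mean Mean of the additive Gaussian noise (default 0).
#' @param noise_sigma_range Uniform range the per-copy noise standard
#'   deviation is drawn from (default 0--0.1).
#' @param copies Total copies per source image including the original
#'   (default 10).
#' @return An object of class `augment_params`.
#' @export
augment_params <- function(flip_probability = 0.5, scale_range = c(0.9, 1.1),
                           rotation_range = 3, shear_range = 3,
                           translation_range = 0.0625, noise_mean = 0,
                           noise_sigma_range = c(0, 0.1), copies = 10) {
  if (copies < 1) fh_stop("copies must be >= 1", "fh_invalid_config")
  structure(list(flip_probability = flip_probability,
                 scale_range = scale_range, rotation_range = rotation_range,
                 shear_range = shear_range,
                 translation_range = translation_range,
                 noise_mean = noise_mean,
                 noise_sigma_range = noise_sigma_range,
                 copies = as.integer(copies)),
            class = "augment_params")
}

#' Resize a grayscale image to a square side
#'
#' Bilinear resampling via EBImage; intensities are clipped back to
#' `[0, 1]`. A same-size input is returned unchanged.
#'
#' @param image Numeric matrix with values in `[0, 1]`.
#' @param side Target side length in pixels (>= 2).
#' @return A `side x side` numeric matrix.
#' @export
resize_image <- function(image, side = 32) {
  if (is.null(dim(image)) || any(dim(image) == 0)) {
    fh_stop("image must be a non-empty matrix", "fh_invalid_input")
  }
  if (side < 2) fh_stop("side must be >= 2", "fh_invalid_input")
  if (nrow(image) == side && ncol(image) == side) return(image)
  out <- EBImage::resize(image, w = side, h = side)
  clip01(matrix(as.numeric(out), side, side))
}

#' Stratified train/validation/test split
#'
#' @param labels Integer vector of 0/1 class labels.
#' @param spec A [split_spec()].
#' @return A list with integer index vectors `train`, `val`, `test` forming a
#'   partition of `seq_along(labels)`.
#' @export
#' @examples
#' sizes <- lengths(stratified_split(rep(0:1, c(437, 210)), split_spec()))
#' sizes  # 389 / 129 / 129
stratified_split <- function(labels, spec = split_spec()) {
  if (!inherits(spec, "split_spec")) fh_stop("spec must be a split_spec", "fh_invalid_config")
  set.seed(derive_seed(spec$seed, "split"))
  groups <- if (spec$stratified) split(seq_along(labels), labels) else list(seq_along(labels))
  parts <- lapply(groups, function(idx) {
    n <- length(idx)
    perm <- idx[sample.int(n)]
    n_val <- floor(spec$val_fraction * n)
    n_test <- floor(spec$test_fraction * n)
    n_held <- n_val + n_test
    list(val = perm[seq_len(n_val)],
         test = perm[n_val + seq_len(n_test)],
         train = if (n_held > 0) perm[-seq_len(n_held)] else perm)
  })
  list(train = sort(unlist(lapply(parts, `[[`, "train"), use.names = FALSE)),
       val = sort(unlist(lapply(parts, `[[`, "val"), use.names = FALSE)),
       test = sort(unlist(lapply(parts, `[[`, "test"), use.names = FALSE)))
}

#' Add clipped pixel-wise Gaussian noise
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param sigma Noise standard deviation (>= 0).
#' @param mean Noise mean (default 0).
#' @return The noised image, clipped to `[0, 1]`.
#' @export
add_gaussian_noise <- function(image, sigma, mean = 0) {
  if (sigma < 0) fh_stop("sigma must be non-negative", "fh_invalid_input")
  if (sigma == 0 && mean == 0) return(image)
  clip01(image + matrix(stats::rnorm(length(image), mean, sigma), nrow(image)))
}

#' Flip an image horizontally or vertically
#'
#' Deterministic mirror; applying the same flip twice restores the image.
#'
#' @param image Numeric matrix.
#' @param horizontal Mirror left-right if TRUE, top-bottom otherwise.
#' @return The flipped matrix.
#' @export
flip_image <- function(image, horizontal = TRUE) {
  if (horizontal) image[, rev(seq_len(ncol(image))), drop = FALSE]
  else image[rev(seq_len(nrow(image))), , drop = FALSE]
}

#' Affine warp of a grayscale image about its center
#'
#' Inverse-mapped bilinear warp: each output pixel samples the input at the
#' inverse-transformed location, with out-of-range coordinates clamped to the
#' image edge. The transform is scale, then shear, then rotation, then
#' translation, all about the image center.
#'
#' @param image Numeric matrix.
#' @param scale Isotropic scale factor.
#' @param rotation Rotation in degrees (counter-clockwise).
#' @param shear Shear in degrees (applied along columns).
#' @param translate Length-2 numeric, (row, col) shift in pixels.
#' @return Warped matrix, same shape, clipped to `[0, 1]`.
#' @export
warp_affine <- function(image, scale = 1, rotation = 0, shear = 0,
                        translate = c(0, 0)) {
  h <- nrow(image); w <- ncol(image)
  th <- rotation * pi / 180
  sh <- tan(shear * pi / 180)
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  shm <- matrix(c(1, 0, sh, 1), 2, 2)
  M <- rot %*% shm * scale
  Minv <- solve(M)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  rr <- matrix(seq_len(h), h, w) - cy - translate[1]
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - cx - translate[2]
  sr <- Minv[1, 1] * rr + Minv[1, 2] * cc + cy
  sc <- Minv[2, 1] * rr + Minv[2, 2] * cc + cx
  sr <- pmin(pmax(sr, 1), h)
  sc <- pmin(pmax(sc, 1), w)
  r0 <- floor(sr); c0 <- floor(sc)
  r1 <- pmin(r0 + 1, h); c1 <- pmin(c0 + 1, w)
  fr <- sr - r0; fc <- sc - c0
  at <- function(ri, ci) image[cbind(as.vector(ri), as.vector(ci))]
  out <- (1 - fr) * (1 - fc) * at(r0, c0) + (1 - fr) * fc * at(r0, c1) +
    fr * (1 - fc) * at(r1, c0) + fr * fc * at(r1, c1)
  clip01(matrix(out, h, w))
}

#' Multiply a training set by randomized augmentation
#'
#' For each source sample, emits `params$copies` samples: copy 0 is the
#' unmodified source; each further copy applies, in order, random
#' horizontal/vertical flips, additive Gaussian noise with a per-copy
#' standard deviation drawn from `noise_sigma_range`, and a random affine
#' transform. Labels, center ids and the link to the source sample
#' (`src_id`) are preserved.
#'
#' @param samples List of samples (image/label/center_id/sample_id).
#' @param params An [augment_params()].
#' @param seed Integer seed; the expansion is fully deterministic given it.
#' @return A list of `copies * length(samples)` samples, each with an extra
#'   `src_id` element naming its source.
#' @export
augment_tenfold <- function(samples, params = augment_params(), seed = 1) {
  if (length(samples) == 0) fh_stop("samples must be non-empty", "fh_invalid_input")
  out <- vector("list", length(samples) * params$copies)
  j <- 0L
  for (s in samples) {
    set.seed(derive_seed(seed, "augment", s$sample_id))
    for (k in seq_len(params$copies) - 1L) {
      img <- s$image
      if (k > 0L) {
        if (stats::runif(1) < params$flip_probability) img <- flip_image(img, TRUE)
        if (stats::runif(1) < params$flip_probability) img <- flip_image(img, FALSE)
        sig <- stats::runif(1, params$noise_sigma_range[1], params$noise_sigma_range[2])
        img <- add_gaussian_noise(img, sig, params$noise_mean)
        side <- nrow(img)
        img <- warp_affine(
          img,
          scale = stats::runif(1, params$scale_range[1], params$scale_range[2]),
          rotation = stats::runif(1, -params$rotation_range, params$rotation_range),
          shear = stats::runif(1, -params$shear_range, params$shear_range),
          translate = stats::runif(2, -params$translation_range, params$translation_range) * side)
      }
      j <- j + 1L
      out[[j]] <- list(image = img, label = s$label, center_id = s$center_id,
                       sample_id = sprintf("%s-aug%02d", s$sample_id, k),
                       src_id = s$sample_id)
    }
  }
  out
}
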
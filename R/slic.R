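#' SLIC superpixel segmentation
#'
#' Simple linear iterative clustering on a grayscale image: local k-means in
#' joint (intensity, row, column) space, initialised on a regular grid with
#' spacing `S = sqrt(n_pixels / target_segments)` and restricted to a `2S`
#' search window per cluster. After the iterations, connectivity is enforced:
#' each label is split into its connected components and components smaller
#' than `min_size_factor * S^2` pixels are merged into the adjacent segment
#' with the longest shared boundary. The procedure is fully deterministic
#' given its inputs; `seed` is accepted for interface uniformity only.
#'
#' The distance measure is
#' `D^2 = (dI)^2 + compactness^2 * ((dr^2 + dc^2) / S^2)`,
#' so larger `compactness` weights spatial proximity more heavily and yields
#' more regular segments.
#'
#' @param image Numeric matrix with intensities in `[0, 1]`.
#' @param target_segments Approximate number of segments requested; the
#'   returned count may be lower (segments can merge).
#' @param compactness Intensity-vs-space balance (default 0.2).
#' @param n_iter Number of assignment/update iterations (default 10).
#' @param seed Ignored (the algorithm is deterministic); kept for interface
#'   symmetry with the other seeded stages.
#' @param min_size_factor Fraction of `S^2` below which a connected component
#'   is merged into a neighbour (default 0.25).
#' @return An object of class `superpixel_map`: list with `labels` (integer
#'   matrix, contiguous ids `1..n_segments`, every pixel assigned) and
#'   `n_segments`.
#' @export
slic_superpixels <- function(image, target_segments = 120, compactness = 0.2,
                             n_iter = 10, seed = NULL, min_size_factor = 0.25) {
  if (is.null(dim(image)) || any(dim(image) == 0)) {
    fh_stop("image must be a non-empty matrix", "fh_invalid_input")
  }
  h <- nrow(image); w <- ncol(image); npix <- h * w
  if (target_segments < 1 || target_segments > npix) {
    fh_stop("target_segments must be in [1, pixel count]", "fh_invalid_config")
  }
  if (target_segments == 1) {
    return(structure(list(labels = matrix(1L, h, w), n_segments = 1L),
                     class = "superpixel_map"))
  }
  S <- sqrt(npix / target_segments)
  nr <- max(1L, as.integer(round(h / S)))
  nc <- max(1L, as.integer(round(w / S)))
  cen_r <- (seq_len(nr) - 0.5) * h / nr
  cen_c <- (seq_len(nc) - 0.5) * w / nc
  centers <- cbind(r = rep(cen_r, times = nc), c = rep(cen_c, each = nr))
  K <- nrow(centers)
  cen_i <- image[cbind(pmin(pmax(round(centers[, 1]), 1), h),
                       pmin(pmax(round(centers[, 2]), 1), w))]
  m2 <- compactness^2 / S^2

  labels <- matrix(0L, h, w)
  for (it in seq_len(n_iter)) {
    best <- matrix(Inf, h, w)
    labels[] <- 0L
    for (kk in seq_len(K)) {
      r0 <- max(1L, as.integer(floor(centers[kk, 1] - S)))
      r1 <- min(h, as.integer(ceiling(centers[kk, 1] + S)))
      c0 <- max(1L, as.integer(floor(centers[kk, 2] - S)))
      c1 <- min(w, as.integer(ceiling(centers[kk, 2] + S)))
      sub <- image[r0:r1, c0:c1, drop = FALSE]
      dr <- (r0:r1) - centers[kk, 1]
      dc <- (c0:c1) - centers[kk, 2]
      d2 <- (sub - cen_i[kk])^2 +
        m2 * (matrix(dr^2, length(dr), length(dc)) +
                matrix(dc^2, length(dr), length(dc), byrow = TRUE))
      win <- best[r0:r1, c0:c1, drop = FALSE]
      upd <- d2 < win
      win[upd] <- d2[upd]
      best[r0:r1, c0:c1] <- win
      lab <- labels[r0:r1, c0:c1, drop = FALSE]
      lab[upd] <- kk
      labels[r0:r1, c0:c1] <- lab
    }
    ## pixels outside every window (possible for extreme configs): nearest center
    miss <- which(labels == 0L)
    if (length(miss)) {
      mr <- ((miss - 1L) %% h) + 1L
      mc <- ((miss - 1L) %/% h) + 1L
      for (ii in seq_along(miss)) {
        d2 <- (mr[ii] - centers[, 1])^2 + (mc[ii] - centers[, 2])^2
        labels[miss[ii]] <- which.min(d2)
      }
    }
    ## update cluster centers
    idx <- seq_len(npix)
    rr <- ((idx - 1L) %% h) + 1L
    cc <- ((idx - 1L) %/% h) + 1L
    lv <- as.vector(labels)
    sums_r <- rowsum(rr, lv); sums_c <- rowsum(cc, lv)
    sums_i <- rowsum(as.vector(image), lv)
    cnt <- rowsum(rep(1, npix), lv)
    got <- as.integer(rownames(cnt))
    centers[got, 1] <- sums_r / cnt
    centers[got, 2] <- sums_c / cnt
    cen_i[got] <- sums_i / cnt
  }
  labels <- .fh_enforce_connectivity(labels, min_size = max(1L, as.integer(floor(S^2 * min_size_factor))))
  structure(list(labels = labels, n_segments = max(labels)),
            class = "superpixel_map")
}

## split labels into 4-connected components, merge small ones into the
## adjacent component with the longest shared boundary, relabel 1..n
.fh_enforce_connectivity <- function(labels, min_size = 2L) {
  h <- nrow(labels); w <- ncol(labels)
  comp <- matrix(0L, h, w)
  nxt <- 0L
  for (lab in sort(unique(as.vector(labels)))) {
    mask <- labels == lab
    bw <- EBImage::bwlabel(mask)
    ncomp <- max(bw)
    if (ncomp > 0) {
      comp[mask] <- as.integer(bw[mask]) + nxt
      nxt <- nxt + as.integer(ncomp)
    }
  }
  sizes <- tabulate(comp, nbins = nxt)
  for (ci in order(sizes)) {
    if (sizes[ci] >= min_size || sizes[ci] == 0L) next
    mask <- comp == ci
    ## adjacent components via 4-neighbour shifts
    nb <- integer(0)
    if (h > 1) {
      nb <- c(nb, comp[-1, ][mask[-h, ]], comp[-h, ][mask[-1, ]])
    }
    if (w > 1) {
      nb <- c(nb, comp[, -1][mask[, -w]], comp[, -w][mask[, -1]])
    }
    nb <- nb[nb != ci & nb != 0L]
    if (length(nb) == 0) next  # isolated (single-component image)
    tt <- table(nb)
    target <- as.integer(names(tt)[order(-tt, as.integer(names(tt)))][1])
    comp[mask] <- target
    sizes[target] <- sizes[target] + sizes[ci]
    sizes[ci] <- 0L
  }
  kept <- sort(unique(as.vector(comp)))
  relabel <- integer(nxt)
  relabel[kept] <- seq_along(kept)
  matrix(relabel[comp], h, w)
}
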
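#' Rebuild cell labels from a junction-channel image
#'
#' Segments a rendered (or stained) junction channel back into a label
#' image: the image is lightly smoothed, thresholded (Otsu by default)
#' into a boundary mask, connected components of the non-boundary
#' region become cell seeds (components smaller than `min_cell_area_um2`
#' are discarded), and the seeds are then grown across the boundary band
#' by intensity-guided propagation (Voronoi region growing on the image
#' manifold), so the fronts from the two sides meet on the intensity
#' ridge, i.e. the junction midline, and the labels partition the field
#' again. Feeding the result to [build_junction_graph()] closes the
#' loop from rendered image back to junction topology.
#'
#' @param image numeric matrix (junction channel; bright boundaries).
#' @param pixel_size um per pixel.
#' @param threshold boundary threshold on the smoothed, max-normalized
#'   image; `NULL` (default) uses Otsu's method.
#' @param smooth_sigma pre-smoothing sigma in pixels (default 1).
#' @param min_cell_area_um2 smallest component kept as a cell seed
#'   (default 4).
#' @return integer label matrix with consecutive labels.
#' @export
segment_junction_image <- function(image, pixel_size, threshold = NULL,
                                   smooth_sigma = 1,
                                   min_cell_area_um2 = 4) {
  g <- if (smooth_sigma > 0) EBImage::gblur(image, sigma = smooth_sigma)
       else image
  rng <- range(g)
  if (diff(rng) == 0) return(matrix(1L, nrow(g), ncol(g)))
  gn <- (g - rng[1]) / diff(rng)
  thr <- if (is.null(threshold)) EBImage::otsu(gn, range = c(0, 1))
         else threshold
  mask <- gn > thr
  lab <- EBImage::bwlabel(!mask)
  storage.mode(lab) <- "integer"
  ## drop specks
  min_px <- max(1L, round(min_cell_area_um2 / pixel_size^2))
  tab <- tabulate(lab[lab > 0L])
  small <- which(tab < min_px)
  if (length(small)) lab[lab %in% small] <- 0L
  if (max(lab) == 0L) stop("no cell regions found below the threshold")
  ## relabel consecutively, ordered by first occurrence (column-major)
  ids <- unique(as.integer(lab[lab > 0L]))
  remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  filled <- matrix(as.integer(EBImage::propagate(gn, lab, lambda = 1e-2)),
                   nrow(lab), ncol(lab))
  if (any(filled == 0L)) filled <- .fill_nearest_label(filled)
  filled
}

## assign zero pixels to the label of the nearest labeled pixel by
## repeated 4-neighbor dilation; deterministic precedence up, left,
## down, right on simultaneous arrival
.fill_nearest_label <- function(lab) {
  ny <- nrow(lab); nx <- ncol(lab)
  while (any(lab == 0L)) {
    cand <- matrix(0L, ny, nx)
    take <- function(cand, src) ifelse(cand == 0L & lab == 0L & src > 0L,
                                       src, cand)
    up <- rbind(lab[-1, , drop = FALSE], rep(0L, nx))
    dn <- rbind(rep(0L, nx), lab[-ny, , drop = FALSE])
    lf <- cbind(lab[, -1, drop = FALSE], rep(0L, ny))
    rt <- cbind(rep(0L, ny), lab[, -nx, drop = FALSE])
    cand <- take(cand, up); cand <- take(cand, lf)
    cand <- take(cand, dn); cand <- take(cand, rt)
    if (all(cand == 0L)) break
    lab[cand > 0L] <- cand[cand > 0L]
  }
  lab
}
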
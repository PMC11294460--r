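#' Detect diffraction-limited spots in a single-channel image
#'
#' Scale-space blob detection: the image is smoothed with a Gaussian
#' matched to the minimum spot size, local maxima above `threshold` are
#' taken as candidate spots, centers are refined to sub-pixel precision
#' by an intensity-weighted centroid in a small window, and an apparent
#' diameter (FWHM) is estimated from the local second moment. Candidates
#' whose fitted diameter falls below `min_diameter` are discarded, the
#' analogue of setting the detection diameter of the smallest vesicle.
#'
#' @param image numeric matrix (rows = y, cols = x).
#' @param pixel_size um per pixel.
#' @param min_diameter smallest accepted spot diameter in um
#'   (default 0.2).
#' @param threshold intensity threshold on the smoothed image; local
#'   maxima below it are ignored.
#' @param channel channel tag for the returned SpotSet.
#' @return data.frame `id`, `channel`, `x_um`, `y_um`, `diameter_um`,
#'   `intensity` (possibly 0 rows).
#' @export
detect_spots <- function(image, pixel_size, min_diameter = 0.2,
                         threshold, channel = "A") {
  ny <- nrow(image); nx <- ncol(image)
  sigma_px <- max(0.7, (min_diameter / 2.355) / pixel_size)
  sm <- EBImage::gblur(image, sigma = sigma_px)
  ## 8-neighbor local maxima (strict against at least one neighbor)
  pad <- matrix(-Inf, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- sm
  ctr <- pad[2:(ny + 1), 2:(nx + 1)]
  ge_all <- rep(TRUE, ny * nx)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[(2 + dr):(ny + 1 + dr), (2 + dc):(nx + 1 + dc)]
    ge_all <- ge_all & (ctr >= nb)
  }
  cand <- which(matrix(ge_all, ny, nx) & sm >= threshold, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(data.frame(id = integer(0), channel = character(0),
                      x_um = numeric(0), y_um = numeric(0),
                      diameter_um = numeric(0), intensity = numeric(0)))
  ## deduplicate plateau maxima closer than ~1 spot radius
  keep <- rep(TRUE, nrow(cand))
  if (nrow(cand) > 1) {
    o <- order(-sm[cand])
    cand <- cand[o, , drop = FALSE]
    min_sep2 <- max(1, (min_diameter / pixel_size))^2
    for (i in 2:nrow(cand)) {
      d2 <- (cand[1:(i - 1), 1] - cand[i, 1])^2 +
            (cand[1:(i - 1), 2] - cand[i, 2])^2
      if (any(d2[keep[1:(i - 1)]] <= min_sep2)) keep[i] <- FALSE
    }
    cand <- cand[keep, , drop = FALSE]
  }
  w <- max(2L, ceiling(2 * sigma_px))
  res <- lapply(seq_len(nrow(cand)), function(i) {
    r0 <- cand[i, 1]; c0 <- cand[i, 2]
    rr <- max(1, r0 - w):min(ny, r0 + w)
    cc <- max(1, c0 - w):min(nx, c0 + w)
    patch <- sm[rr, cc, drop = FALSE]
    patch <- pmax(patch - min(patch), 0)
    tot <- sum(patch)
    if (tot <= 0) return(NULL)
    rw <- rowSums(patch); cw <- colSums(patch)
    mu_r <- sum(rr * rw) / tot
    mu_c <- sum(cc * cw) / tot
    var_r <- sum((rr - mu_r)^2 * rw) / tot
    var_c <- sum((cc - mu_c)^2 * cw) / tot
    sigma_fit <- sqrt(pmax((var_r + var_c) / 2, 0))
    data.frame(x_um = (mu_c - 1) * pixel_size,
               y_um = (mu_r - 1) * pixel_size,
               diameter_um = 2.355 * sigma_fit * pixel_size,
               intensity = image[r0, c0])
  })
  out <- do.call(rbind, Filter(Negate(is.null), res))
  out <- out[out$diameter_um >= min_diameter, , drop = FALSE]
  if (nrow(out) == 0L)
    return(data.frame(id = integer(0), channel = character(0),
                      x_um = numeric(0), y_um = numeric(0),
                      diameter_um = numeric(0), intensity = numeric(0)))
  out <- out[order(out$y_um, out$x_um), , drop = FALSE]
  cbind(id = seq_len(nrow(out)), channel = channel, out,
        row.names = NULL)
}

#' Remove spots falling inside a mask region
#'
#' The programmatic analogue of manually clearing detections inside the
#' Golgi area: spots whose centers rasterize into `TRUE` mask pixels are
#' removed. The number removed is reported in the `n_removed` attribute.
#'
#' @param spots SpotSet data.frame with `x_um`, `y_um`.
#' @param mask logical matrix aligned to the image grid.
#' @param pixel_size um per pixel of the mask grid.
#' @return the filtered SpotSet, with attribute `n_removed`.
#' @export
exclude_region <- function(spots, mask, pixel_size) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  ny <- nrow(mask); nx <- ncol(mask)
  if (nrow(spots) == 0L) {
    attr(spots, "n_removed") <- 0L
    return(spots)
  }
  rr <- pmin(pmax(floor(spots$y_um / pixel_size + 0.5) + 1L, 1L), ny)
  cc <- pmin(pmax(floor(spots$x_um / pixel_size + 0.5) + 1L, 1L), nx)
  inside <- mask[cbind(rr, cc)]
  out <- spots[!inside, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(inside)
  out
}

#' Merge manually rescued spots into a detected SpotSet
#'
#' Dim vesicle-like signals that automated detection misses (e.g. a
#' membrane-bound channel whose vesicles do not stand out) can be
#' supplied as a manually marked supplementary table and merged before
#' pairing. The merge is explicit: rescued spots are tagged
#' `source = "manual"` and their count is reported in the `n_manual`
#' attribute, never silently absorbed.
#'
#' @param spots detected SpotSet data.frame.
#' @param manual data.frame with at least `x_um`, `y_um`.
#' @return combined SpotSet with a `source` column and `n_manual`
#'   attribute.
#' @export
merge_supplementary_spots <- function(spots, manual) {
  if (!all(c("x_um", "y_um") %in% names(manual)))
    stop("manual spots need x_um and y_um columns")
  spots$source <- if (nrow(spots)) "auto" else character(0)
  add <- data.frame(
    id = max(c(0L, spots$id)) + seq_len(nrow(manual)),
    channel = if (nrow(spots)) spots$channel[1] else "A",
    x_um = manual$x_um, y_um = manual$y_um,
    diameter_um = if ("diameter_um" %in% names(manual))
      manual$diameter_um else NA_real_,
    intensity = if ("intensity" %in% names(manual))
      manual$intensity else NA_real_,
    source = "manual")
  common <- intersect(names(spots), names(add))
  out <- rbind(spots[, common, drop = FALSE], add[, common, drop = FALSE])
  rownames(out) <- NULL
  attr(out, "n_manual") <- nrow(manual)
  out
}

#' Pair spots across two channels at a distance threshold
#'
#' Object-based colocalization: among all cross-channel pairs closer
#' than `max_dist`, pairs are accepted shortest-first under the
#' constraint that every spot enters at most one pair (greedy injective
#' matching). The colocalization fraction is reported relative to the
#' reference channel `A`, i.e. the percentage of A-spots that found a
#' partner.
#'
#' @param A reference-channel SpotSet (`x_um`, `y_um`, `id`).
#' @param B second-channel SpotSet.
#' @param max_dist pairing threshold in um; spots pair when strictly
#'   closer than this (default 0.4).
#' @return list of class `pairing_result`: `pairs` (data.frame `id_a`,
#'   `id_b`, `separation_um`), `unmatched_a`, `unmatched_b`,
#'   `fraction_pct` (= 100 * npairs / nrow(A)), `n_a`, `n_b`.
#' @export
pair_spots <- function(A, B, max_dist = 0.4) {
  na <- nrow(A); nb <- nrow(B)
  pairs <- data.frame(id_a = integer(0), id_b = integer(0),
                      separation_um = numeric(0))
  if (na > 0 && nb > 0) {
    D <- sqrt(outer(A$x_um, B$x_um, "-")^2 + outer(A$y_um, B$y_um, "-")^2)
    cand <- which(D < max_dist, arr.ind = TRUE)
    if (nrow(cand)) {
      ## shortest first; ties broken by (id_a, id_b) for determinism
      ord <- order(D[cand], A$id[cand[, 1]], B$id[cand[, 2]])
      used_a <- logical(na); used_b <- logical(nb)
      ia <- integer(0); ib <- integer(0); sep <- numeric(0)
      for (q in ord) {
        i <- cand[q, 1]; j <- cand[q, 2]
        if (used_a[i] || used_b[j]) next
        used_a[i] <- TRUE; used_b[j] <- TRUE
        ia <- c(ia, i); ib <- c(ib, j); sep <- c(sep, D[i, j])
      }
      pairs <- data.frame(id_a = A$id[ia], id_b = B$id[ib],
                          separation_um = sep)
    }
  }
  structure(list(
    pairs = pairs,
    unmatched_a = setdiff(A$id, pairs$id_a),
    unmatched_b = setdiff(B$id, pairs$id_b),
    fraction_pct = if (na > 0) 100 * nrow(pairs) / na else NA_real_,
    n_a = na, n_b = nb, max_dist = max_dist),
    class = "pairing_result")
}

#' @export
print.pairing_result <- function(x, ...) {
  cat(sprintf(
    "pairing_result: %d pairs of %d reference spots (%.1f%%) at < %.3g um\n",
    nrow(x$pairs), x$n_a,
    ifelse(is.na(x$fraction_pct), NaN, x$fraction_pct), x$max_dist))
  invisible(x)
}

#' Colocalization fraction as a function of vertex distance
#'
#' Bins the reference-channel spots by their distance to the nearest
#' multicellular vertex and reports, per bin, the percentage of
#' colocalized and non-colocalized spots (percentages of all reference
#' spots, so colocalized + non-colocalized sums to each bin's share).
#'
#' @param pairing a `pairing_result` from [pair_spots()].
#' @param A the reference SpotSet that produced the pairing.
#' @param graph a `junction_graph`.
#' @param bin_width bin width in um (default 5; use 2 for discontinuous
#'   junctions).
#' @param metric `"euclidean"` (distance-transform convention, default)
#'   or `"arc"` (along-junction convention).
#' @param band_halfwidth used only for `metric = "arc"`.
#' @return data.frame `bin_lo`, `bin_hi`, `n_coloc`, `n_noncoloc`,
#'   `pct_coloc`, `pct_noncoloc` with attribute `n_unassigned` (spots
#'   with no distance under the arc metric).
#' @export
colocalization_by_distance <- function(pairing, A, graph, bin_width = 5,
                                       metric = c("euclidean", "arc"),
                                       band_halfwidth = 7) {
  metric <- match.arg(metric)
  stopifnot(inherits(pairing, "pairing_result"))
  if (metric == "euclidean") {
    d <- nearest_vertex_distance(A, graph)$distance_um
  } else {
    ad <- arc_distance_to_vertex(A, graph, band_halfwidth)
    d <- ad$arc_um
  }
  coloc <- A$id %in% pairing$pairs$id_a
  ok <- !is.na(d)
  n_total <- sum(ok)
  max_d <- if (n_total) max(d[ok]) else 0
  nb <- max(1, floor(max_d / bin_width) + 1)
  bin <- floor(d[ok] / bin_width) + 1L
  n_co <- tabulate(bin[coloc[ok]], nbins = nb)
  n_nc <- tabulate(bin[!coloc[ok]], nbins = nb)
  out <- data.frame(
    bin_lo = (seq_len(nb) - 1) * bin_width,
    bin_hi = seq_len(nb) * bin_width,
    n_coloc = n_co, n_noncoloc = n_nc,
    pct_coloc = if (n_total) 100 * n_co / n_total else NA_real_,
    pct_noncoloc = if (n_total) 100 * n_nc / n_total else NA_real_)
  attr(out, "n_unassigned") <- sum(!ok)
  out
}
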
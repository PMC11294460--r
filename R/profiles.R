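#' Junction intensity profile folded around multicellular vertices
#'
#' For every bicellular edge bounded by a multicellular vertex at both
#' ends, the image intensity is averaged across a band of width
#' `line_width` perpendicular to the junction at each arc position (the
#' analogue of the per-row means of a 60-pixel-wide line drawn along the
#' junction), then folded so that distance 0 is the nearer vertex:
#' `d = min(s, L - s)`. Per-distance means and SDs are aggregated over
#' all such lines and, if `normalize`, divided by the mean at distance 0
#' so the profile starts at exactly 1.
#'
#' @param image numeric matrix (rows = y, cols = x).
#' @param graph a `junction_graph` with at least one closed edge.
#' @param pixel_size um per pixel; defaults to the graph's.
#' @param line_width full band width in um (default 6).
#' @param normalize divide by the mean at distance 0 (default TRUE).
#' @param step arc sampling step in um (default = pixel_size).
#' @return object of class `profile_curve`: data.frame `distance_um`,
#'   `mean`, `sd`, `n_lines`, with attribute `normalized`.
#' @export
extract_junction_profile <- function(image, graph,
                                     pixel_size = graph$pixel_size,
                                     line_width = 6, normalize = TRUE,
                                     step = pixel_size) {
  stopifnot(inherits(graph, "junction_graph"))
  closed <- Filter(function(e) isTRUE(e$closed), graph$edges)
  if (!length(closed))
    stop("graph has no edges bounded by vertices at both ends")
  offs <- seq(-line_width / 2, line_width / 2, by = pixel_size)
  acc <- list()
  for (e in closed) {
    rs <- .resample_polyline(e$polyline, step)
    if (is.null(rs)) next
    L <- e$arc_length
    ## intensity averaged across the band at each arc position
    n_s <- length(rs$s)
    vals <- numeric(n_s)
    for (q in seq_along(offs)) {
      px <- rs$x - offs[q] * rs$ty
      py <- rs$y + offs[q] * rs$tx
      vals <- vals + .interp_bilinear(image, px, py, pixel_size)
    }
    vals <- vals / length(offs)
    d <- pmin(rs$s, L - rs$s)
    acc[[length(acc) + 1L]] <- data.frame(
      line = e$id, bin = floor(d / step), value = vals)
  }
  all <- do.call(rbind, acc)
  ## per line, average duplicate distance bins (the two fold arms)
  per_line <- stats::aggregate(value ~ line + bin, all, mean)
  agg_m <- tapply(per_line$value, per_line$bin, mean)
  agg_s <- tapply(per_line$value, per_line$bin, stats::sd)
  agg_n <- tapply(per_line$value, per_line$bin, length)
  bins <- as.integer(names(agg_m))
  out <- data.frame(distance_um = bins * step,
                    mean = as.numeric(agg_m),
                    sd = as.numeric(agg_s),
                    n_lines = as.integer(agg_n))
  out <- out[order(out$distance_um), , drop = FALSE]
  rownames(out) <- NULL
  if (normalize) {
    ref <- out$mean[1]
    if (!is.finite(ref) || ref == 0)
      stop("cannot normalize: mean at distance 0 is 0")
    out$mean <- out$mean / ref
    out$sd <- out$sd / ref
  }
  structure(out, class = c("profile_curve", "data.frame"),
            normalized = normalize)
}

#' Aggregate junction profiles across images
#'
#' Combines profile curves from several images into one mean +/- SD
#' curve. Two weightings are supported: `"image"` (default) treats each
#' image's curve as one observation regardless of how many lines it
#' contains, the two-level averaging convention; `"line"` pools all
#' lines, weighting each image by its line count.
#'
#' @param profiles list of `profile_curve` objects on a common distance
#'   grid (extracted with the same `step`).
#' @param weights `"image"` or `"line"`.
#' @return data.frame `distance_um`, `mean`, `sd`, `n`.
#' @export
aggregate_profiles <- function(profiles, weights = c("image", "line")) {
  weights <- match.arg(weights)
  grid <- sort(unique(unlist(lapply(profiles, `[[`, "distance_um"))))
  M <- sapply(profiles, function(p)
    p$mean[match(grid, p$distance_um)])
  W <- if (weights == "image") matrix(1, nrow(M), ncol(M))
       else sapply(profiles, function(p)
         p$n_lines[match(grid, p$distance_um)])
  W[is.na(M)] <- NA
  wmean <- rowSums(M * W, na.rm = TRUE) / rowSums(W, na.rm = TRUE)
  dev2 <- (M - wmean)^2
  wsd <- sqrt(rowSums(dev2 * W, na.rm = TRUE) /
                pmax(rowSums(W, na.rm = TRUE) - 1, 1))
  data.frame(distance_um = grid, mean = wmean, sd = wsd,
             n = rowSums(!is.na(M)))
}

## bilinear interpolation with clamping at the image border
.interp_bilinear <- function(img, x_um, y_um, ps) {
  ny <- nrow(img); nx <- ncol(img)
  cx <- x_um / ps + 1; cy <- y_um / ps + 1
  cx <- pmin(pmax(cx, 1), nx); cy <- pmin(pmax(cy, 1), ny)
  c0 <- pmin(floor(cx), nx - 1); r0 <- pmin(floor(cy), ny - 1)
  fx <- cx - c0; fy <- cy - r0
  img[cbind(r0, c0)] * (1 - fx) * (1 - fy) +
    img[cbind(r0, c0 + 1)] * fx * (1 - fy) +
    img[cbind(r0 + 1, c0)] * (1 - fx) * fy +
    img[cbind(r0 + 1, c0 + 1)] * fx * fy
}

#' Fit an exponential-plus-plateau model to a profile curve
#'
#' Fits `I(d) = (I0 - Iinf) * exp(-d / ell) + Iinf` by nonlinear least
#' squares and reports the decay length and plateau-to-peak ratio.
#'
#' @param profile a `profile_curve` (or data.frame with `distance_um`,
#'   `mean`).
#' @param d_min fit only distances `>= d_min` um (default 0). At a
#'   multicellular vertex several junction lines converge, so the
#'   measured intensity within roughly the line width of the vertex
#'   exceeds the single-junction decay; excluding that core isolates
#'   the bicellular decay parameters.
#' @return list `ell` (um), `plateau_ratio` (Iinf / I0, with I0 the
#'   fitted value extrapolated to distance 0), `I0`, `Iinf`.
#' @export
fit_profile_decay <- function(profile, d_min = 0) {
  keep <- profile$distance_um >= d_min
  d <- profile$distance_um[keep]; v <- profile$mean[keep]
  i0 <- v[1]; iinf <- min(v)
  fit <- minpack.lm::nlsLM(
    v ~ (I0 - Iinf) * exp(-d / ell) + Iinf,
    start = list(I0 = i0, Iinf = iinf, ell = max(d[2], 1)),
    lower = c(0, 0, 1e-3), upper = c(Inf, Inf, max(d) * 10),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  list(ell = unname(cf["ell"]),
       plateau_ratio = unname(cf["Iinf"] / cf["I0"]),
       I0 = unname(cf["I0"]), Iinf = unname(cf["Iinf"]))
}

#' Mean intensity in disk regions around multicellular vertices
#'
#' For each vertex, the mean image intensity over a disk of `radius`
#' (the "5 um radius circles" readout), optionally intersected with a
#' cell mask — which clips the disk to "pieces of a pie" when the vertex
#' sits on the cell border — and background-subtracted. Negative
#' background-subtracted values are preserved (clipping, if any, is a
#' reporting choice).
#'
#' @param image numeric matrix.
#' @param graph a `junction_graph`.
#' @param pixel_size um per pixel; defaults to the graph's.
#' @param radius disk radius in um (default 5).
#' @param cell_mask optional logical matrix restricting each region.
#' @param background scalar background intensity to subtract
#'   (default 0); its source should be a stated control region.
#' @return data.frame `vertex_id`, `kind`, `n_px`, `area_um2`,
#'   `mean_raw`, `background`, `value`; vertices whose region is empty
#'   are dropped with a warning.
#' @export
vertex_region_intensity <- function(image, graph,
                                    pixel_size = graph$pixel_size,
                                    radius = 5, cell_mask = NULL,
                                    background = 0) {
  stopifnot(inherits(graph, "junction_graph"))
  if (!is.null(cell_mask) && !all(dim(cell_mask) == dim(image)))
    stop("cell_mask dimensions do not match image")
  ny <- nrow(image); nx <- ncol(image)
  xs <- (seq_len(nx) - 1) * pixel_size
  ys <- (seq_len(ny) - 1) * pixel_size
  kind <- if (is.null(cell_mask)) "vertex-disk" else "vertex-pie"
  rows <- list(); skipped <- integer(0)
  for (i in seq_len(nrow(graph$vertices))) {
    vx <- graph$vertices$x_um[i]; vy <- graph$vertices$y_um[i]
    sel <- outer((ys - vy)^2, (xs - vx)^2, "+") <= radius^2
    if (!is.null(cell_mask)) sel <- sel & cell_mask
    npx <- sum(sel)
    if (npx == 0L) {
      skipped <- c(skipped, graph$vertices$id[i])
      next
    }
    m <- mean(image[sel])
    rows[[length(rows) + 1L]] <- data.frame(
      vertex_id = graph$vertices$id[i], kind = kind, n_px = npx,
      area_um2 = npx * pixel_size^2, mean_raw = m,
      background = background, value = m - background)
  }
  if (length(skipped))
    warning("vertex regions entirely outside the mask skipped: ",
            paste(skipped, collapse = ", "))
  if (!length(rows))
    return(data.frame(vertex_id = integer(0), kind = character(0),
                      n_px = integer(0), area_um2 = numeric(0),
                      mean_raw = numeric(0), background = numeric(0),
                      value = numeric(0)))
  do.call(rbind, rows)
}

#' Background-subtracted intensity per cell
#'
#' Mean (or total) intensity per cell region minus a background level,
#' the whole-cell chemokine readout. Cells are given either as a label
#' image or as a list of disjoint logical masks.
#'
#' @param image numeric matrix.
#' @param cells integer label matrix (0 = outside any cell) or list of
#'   logical matrices.
#' @param background scalar background intensity.
#' @param statistic `"mean"` (per-pixel average, default) or `"total"`
#'   (integrated intensity).
#' @param pixel_size um per pixel (used for the reported area).
#' @return data.frame `cell_id`, `n_px`, `area_um2`, `raw`,
#'   `background`, `value`.
#' @export
whole_cell_intensity <- function(image, cells, background = 0,
                                 statistic = c("mean", "total"),
                                 pixel_size = 1) {
  statistic <- match.arg(statistic)
  if (is.list(cells)) {
    overlap <- Reduce(`+`, lapply(cells, function(m) m * 1L))
    if (any(overlap > 1L)) stop("cell masks overlap")
    ids <- seq_along(cells)
    get_mask <- function(k) cells[[k]]
  } else {
    if (!all(dim(cells) == dim(image)))
      stop("label image dimensions do not match image")
    ids <- sort(unique(cells[cells > 0]))
    get_mask <- function(k) cells == k
  }
  rows <- lapply(ids, function(k) {
    sel <- get_mask(k)
    npx <- sum(sel)
    raw <- if (statistic == "mean") mean(image[sel]) else sum(image[sel])
    bg <- if (statistic == "mean") background else background * npx
    data.frame(cell_id = k, n_px = npx, area_um2 = npx * pixel_size^2,
               raw = raw, background = bg, value = raw - bg)
  })
  do.call(rbind, rows)
}

#' Thresholded colocalization area near vertices vs rest of cell
#'
#' Given binary masks of two thresholded channels, measures the
#' percentage of colocalized area (`A & B`) inside the vertex regions
#' (within `radius` of a multicellular vertex, clipped to the cell mask)
#' versus the rest of the cell, with optional exclusion regions (nucleus,
#' Golgi). Two denominator conventions are supported: the region area,
#' or the A-mask area within the region.
#'
#' @param maskA,maskB logical matrices on the same grid.
#' @param graph a `junction_graph`.
#' @param pixel_size um per pixel; defaults to the graph's.
#' @param radius vertex-region radius in um (default 5).
#' @param cell_mask logical matrix delimiting the analyzed cell(s);
#'   defaults to the whole field.
#' @param exclusions optional logical matrix of excluded pixels.
#' @param denominator `"region"` (default) or `"maskA"`.
#' @return data.frame with one row per region kind (`vertex`,
#'   `rest-of-cell`): `area_px`, `coloc_px`, `pct`.
#' @export
colocalization_area_by_region <- function(maskA, maskB, graph,
                                          pixel_size = graph$pixel_size,
                                          radius = 5, cell_mask = NULL,
                                          exclusions = NULL,
                                          denominator = c("region", "maskA")) {
  denominator <- match.arg(denominator)
  if (!all(dim(maskA) == dim(maskB)))
    stop("maskA and maskB dimensions differ")
  ny <- nrow(maskA); nx <- ncol(maskA)
  if (is.null(cell_mask)) cell_mask <- matrix(TRUE, ny, nx)
  if (is.null(exclusions)) exclusions <- matrix(FALSE, ny, nx)
  if (!all(dim(cell_mask) == dim(maskA)) ||
      !all(dim(exclusions) == dim(maskA)))
    stop("mask dimensions differ")
  dfield <- distance_field(graph, dim = c(ny, nx),
                           pixel_size = pixel_size)
  vreg <- (dfield <= radius) & cell_mask & !exclusions
  rest <- cell_mask & !vreg & !exclusions
  co <- maskA & maskB
  one <- function(region, kind) {
    den <- if (denominator == "region") sum(region)
           else sum(maskA & region)
    data.frame(kind = kind, area_px = sum(region),
               coloc_px = sum(co & region),
               pct = if (den > 0) 100 * sum(co & region) / den
                     else NA_real_)
  }
  rbind(one(vreg, "vertex"), one(rest, "rest-of-cell"))
}
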
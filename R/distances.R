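#' Euclidean distance to the nearest multicellular vertex
#'
#' For each query point, the minimum Euclidean distance over all vertices
#' of the junction graph, together with the id of the nearest vertex.
#' Ties are broken toward the lowest vertex id so results are
#' deterministic.
#'
#' @param points numeric matrix or data.frame with columns `x_um`, `y_um`
#'   (a 2-column unnamed matrix is taken as x, y).
#' @param graph a `junction_graph` with at least one vertex.
#' @return data.frame `x_um`, `y_um`, `distance_um`, `vertex_id`.
#' @export
nearest_vertex_distance <- function(points, graph) {
  stopifnot(inherits(graph, "junction_graph"))
  if (nrow(graph$vertices) == 0L)
    stop("graph has no multicellular vertices")
  pts <- .as_xy(points)
  if (nrow(pts) == 0L)
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      distance_um = numeric(0), vertex_id = integer(0)))
  vx <- graph$vertices$x_um; vy <- graph$vertices$y_um
  D <- sqrt(outer(pts[, 1], vx, "-")^2 + outer(pts[, 2], vy, "-")^2)
  j <- max.col(-D, ties.method = "first")   # lowest id wins ties
  data.frame(x_um = pts[, 1], y_um = pts[, 2],
             distance_um = D[cbind(seq_len(nrow(pts)), j)],
             vertex_id = graph$vertices$id[j])
}

#' Per-pixel distance field to the vertex set
#'
#' Evaluates the Euclidean distance to the nearest multicellular vertex at
#' every pixel center, the raster analogue of running a distance
#' transformation against manually marked vertices.
#'
#' @param graph a `junction_graph` with at least one vertex.
#' @param dim optional c(ny, nx); defaults to the graph's source image.
#' @param pixel_size optional; defaults to the graph's.
#' @return numeric matrix (um), same orientation as the label image.
#' @export
distance_field <- function(graph, dim = graph$dim,
                           pixel_size = graph$pixel_size) {
  stopifnot(inherits(graph, "junction_graph"))
  if (nrow(graph$vertices) == 0L)
    stop("graph has no multicellular vertices")
  ny <- dim[1]; nx <- dim[2]
  xs <- (seq_len(nx) - 1) * pixel_size
  ys <- (seq_len(ny) - 1) * pixel_size
  vx <- graph$vertices$x_um; vy <- graph$vertices$y_um
  ## separable accumulation of the running minimum over vertices
  D2 <- matrix(Inf, ny, nx)
  for (k in seq_along(vx)) {
    dk <- outer((ys - vy[k])^2, (xs - vx[k])^2, "+")
    D2 <- pmin(D2, dk)
  }
  sqrt(D2)
}

#' Along-junction arc distance to the nearest vertex
#'
#' Projects each point perpendicularly onto the nearest bicellular edge
#' polyline (within `band_halfwidth`) and returns the cumulative arc
#' length from the projection to the nearer non-OPEN endpoint vertex,
#' the "draw a line along the junction to the closest multicellular
#' junction" measurement. Points farther than `band_halfwidth` from every
#' edge are flagged out-of-band (`in_band = FALSE`, distances `NA`).
#' When a point is equidistant from two edges the edge yielding the
#' smaller arc distance is chosen. Edges with no vertex at either end
#' (both OPEN, or loops) yield `bounded = FALSE`: the returned value is
#' the distance to the nearer chain end, not to a vertex.
#'
#' @param points matrix/data.frame of query positions (um).
#' @param graph a `junction_graph`.
#' @param band_halfwidth maximum perpendicular distance (um) from an edge
#'   midline for a point to be considered junctional (default 7).
#' @return data.frame `x_um`, `y_um`, `in_band`, `edge_id`,
#'   `perp_um` (perpendicular distance to the chosen edge),
#'   `arc_um` (arc distance to the nearer vertex), `vertex_id`,
#'   `bounded`.
#' @export
arc_distance_to_vertex <- function(points, graph, band_halfwidth = 7) {
  stopifnot(inherits(graph, "junction_graph"))
  pts <- .as_xy(points)
  n <- nrow(pts)
  out <- data.frame(x_um = pts[, 1], y_um = pts[, 2],
                    in_band = rep(FALSE, n), edge_id = NA_integer_,
                    perp_um = NA_real_, arc_um = NA_real_,
                    vertex_id = NA_integer_, bounded = NA)
  if (n == 0L || length(graph$edges) == 0L) return(out)

  best_perp <- rep(Inf, n); best_arc <- rep(Inf, n)
  best_edge <- rep(NA_integer_, n); best_vert <- rep(NA_integer_, n)
  best_bounded <- rep(NA, n)
  for (e in graph$edges) {
    pr <- .project_on_polyline(pts, e$polyline)
    L <- e$arc_length
    s <- pr$s
    d1 <- if (!is.na(e$v1)) s else Inf
    d2 <- if (!is.na(e$v2)) L - s else Inf
    bounded <- !is.na(e$v1) || !is.na(e$v2)
    arc <- pmin(d1, d2)
    vid <- ifelse(d1 <= d2, e$v1, e$v2)
    if (!bounded) { arc <- pmin(s, L - s); vid <- NA_integer_ }
    ## closer edge wins; on a perpendicular tie take the smaller arc
    upd <- (pr$d < best_perp - 1e-12) |
      (abs(pr$d - best_perp) <= 1e-12 & arc < best_arc)
    if (any(upd)) {
      best_perp[upd] <- pr$d[upd]; best_arc[upd] <- arc[upd]
      best_edge[upd] <- e$id
      best_vert[upd] <- vid[upd]
      best_bounded[upd] <- bounded
    }
  }
  hit <- best_perp <= band_halfwidth
  out$in_band <- hit
  out$edge_id[hit] <- best_edge[hit]
  out$perp_um[hit] <- best_perp[hit]
  out$arc_um[hit] <- best_arc[hit]
  out$vertex_id[hit] <- best_vert[hit]
  out$bounded[hit] <- best_bounded[hit]
  out
}

## perpendicular projection of points onto a polyline:
## returns d (min distance) and s (arc position of the projection)
.project_on_polyline <- function(pts, poly) {
  nseg <- nrow(poly) - 1L
  n <- nrow(pts)
  ax <- poly[-nrow(poly), 1]; ay <- poly[-nrow(poly), 2]
  dx <- diff(poly[, 1]); dy <- diff(poly[, 2])
  len2 <- dx^2 + dy^2
  seg_len <- sqrt(len2)
  cum0 <- c(0, cumsum(seg_len))[seq_len(nseg)]
  best_d2 <- rep(Inf, n); best_s <- rep(0, n)
  for (k in seq_len(nseg)) {
    if (len2[k] == 0) next
    tx <- ((pts[, 1] - ax[k]) * dx[k] + (pts[, 2] - ay[k]) * dy[k]) / len2[k]
    tx <- pmin(1, pmax(0, tx))
    qx <- ax[k] + tx * dx[k]; qy <- ay[k] + tx * dy[k]
    d2 <- (pts[, 1] - qx)^2 + (pts[, 2] - qy)^2
    upd <- d2 < best_d2 - 1e-15
    if (any(upd)) {
      best_d2[upd] <- d2[upd]
      best_s[upd] <- cum0[k] + tx[upd] * seg_len[k]
    }
  }
  list(d = sqrt(best_d2), s = best_s)
}

#' Bin distances into half-open intervals
#'
#' Histograms distances into bins `[0,w), [w,2w), ...` so that every
#' value falls in exactly one bin and the total count is conserved,
#' matching the "within a binned distance of 5 um" reporting convention
#' (2 um bins for discontinuous junctions).
#'
#' @param distances nonnegative numeric vector (um); `NA` dropped with
#'   a message via the return attribute `n_na`.
#' @param bin_width bin width in um (default 5).
#' @param mode `"count"` or `"percent"` (percent of non-NA total).
#' @return data.frame `bin_lo`, `bin_hi`, `count` and, in percent mode,
#'   `percent`.
#' @export
distance_histogram <- function(distances, bin_width = 5,
                               mode = c("count", "percent")) {
  mode <- match.arg(mode)
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("bin_width must be positive")
  d <- distances[!is.na(distances)]
  if (any(d < 0)) stop("distances must be nonnegative")
  if (length(d) == 0L) {
    out <- data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      count = integer(0))
    if (mode == "percent") out$percent <- numeric(0)
    attr(out, "n_na") <- sum(is.na(distances))
    return(out)
  }
  idx <- floor(d / bin_width)
  nb <- max(idx) + 1
  counts <- tabulate(idx + 1L, nbins = nb)
  out <- data.frame(bin_lo = (seq_len(nb) - 1) * bin_width,
                    bin_hi = seq_len(nb) * bin_width,
                    count = counts)
  if (mode == "percent") out$percent <- 100 * counts / sum(counts)
  attr(out, "n_na") <- sum(is.na(distances))
  out
}

.as_xy <- function(points) {
  if (is.data.frame(points)) {
    if (all(c("x_um", "y_um") %in% names(points)))
      return(cbind(points$x_um, points$y_um))
    if (all(c("x", "y") %in% names(points)))
      return(cbind(points$x, points$y))
    stop("points data.frame needs columns x_um,y_um (or x,y)")
  }
  m <- as.matrix(points)
  if (is.null(dim(m)) || ncol(m) < 2) m <- matrix(m, ncol = 2, byrow = TRUE)
  m[, 1:2, drop = FALSE]
}
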
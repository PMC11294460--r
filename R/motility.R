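#' Track straightness (confinement ratio)
#'
#' Net displacement between the first and last positions divided by the
#' summed step lengths. 1 is a perfectly straight track; a closed loop
#' gives 0. Invariant under rigid motions and uniform time rescaling.
#' A track with zero path length has undefined straightness (`NA`).
#'
#' @param track data.frame with `x_um`, `y_um` ordered by time, or a
#'   2-column matrix.
#' @return straightness in `[0, 1]`, or `NA` for zero path length.
#' @export
track_straightness <- function(track) {
  p <- .as_xy(track)
  if (nrow(p) < 2) return(NA_real_)
  steps <- sqrt(rowSums(diff(p)^2))
  L <- sum(steps)
  if (L <= 0) return(NA_real_)
  disp <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
  disp / L
}

#' Classify a track as arrested by the dwell rule
#'
#' A track is arrested if some time window of at least `dwell` seconds
#' keeps every position within `radius` of the window's first point, or
#' if the track ends in transmigration before `dwell` has elapsed
#' (early transmigrators count as arrested). The arrest position is the
#' centroid of the first qualifying window.
#'
#' The dwell default of 450 s is the observed mean time dendritic cells
#' stay arrested at the transmigration site before crossing; the
#' spatial radius is not part of that temporal definition and defaults
#' to 5 um, the vertex-proximity scale used elsewhere in the pipeline.
#'
#' @param track data.frame with `t_s`, `x_um`, `y_um`.
#' @param dwell minimum dwell time in seconds (default 450).
#' @param radius spatial confinement radius in um (default 5).
#' @param transmigrated TRUE if the track ends in transmigration.
#' @return list `arrested` (logical), `arrest_x_um`, `arrest_y_um`
#'   (NA when not arrested), `rule` ("dwell", "early-transmigration" or
#'   "none").
#' @export
classify_arrest <- function(track, dwell = 450, radius = 5,
                            transmigrated = FALSE) {
  t <- track$t_s; x <- track$x_um; y <- track$y_um
  n <- length(t)
  if (n >= 2 && max(diff(t)) > dwell)
    stop("track sampling interval exceeds the dwell time")
  for (i in seq_len(n)) {
    j <- which(t >= t[i] + dwell)
    if (!length(j)) break
    j <- j[1]
    win <- i:j
    if (all(sqrt((x[win] - x[i])^2 + (y[win] - y[i])^2) <= radius)) {
      return(list(arrested = TRUE,
                  arrest_x_um = mean(x[win]), arrest_y_um = mean(y[win]),
                  rule = "dwell"))
    }
  }
  if (isTRUE(transmigrated) && (t[n] - t[1]) < dwell) {
    return(list(arrested = TRUE, arrest_x_um = x[n], arrest_y_um = y[n],
                rule = "early-transmigration"))
  }
  list(arrested = FALSE, arrest_x_um = NA_real_, arrest_y_um = NA_real_,
       rule = "none")
}

#' Classify a position against the junction topology
#'
#' Culture mode assigns one of `multicellular` (within `vertex_tol` of a
#' multicellular vertex), `bicellular` (within `junction_band` of an
#' edge midline) or `non-junctional`. Explant mode measures the
#' along-junction arc distance to the nearest multicellular vertex and
#' assigns `at` (within `at_tol`), `near` (< 5 um) or `far` (5-18 um);
#' arc distances beyond 18 um are flagged out of range and left
#' unclassified.
#'
#' @param position length-2 numeric (x, y in um) or 1-row data.frame.
#' @param graph a `junction_graph`.
#' @param mode `"culture"` or `"explant"`.
#' @param vertex_tol Euclidean vertex tolerance, um (default 5).
#' @param junction_band bicellular band half-width, um (default 2).
#' @param at_tol explant tolerance for "at the vertex", um (default 1).
#' @param far_max upper bound of the explant "far" class (default 18).
#' @return list `class` (character or NA), `distance_um`,
#'   `out_of_range` (explant only).
#' @export
classify_site <- function(position, graph,
                          mode = c("culture", "explant"),
                          vertex_tol = 5, junction_band = 2,
                          at_tol = 1, far_max = 18) {
  mode <- match.arg(mode)
  stopifnot(inherits(graph, "junction_graph"))
  p <- .as_xy(position)
  if (mode == "culture") {
    dv <- nearest_vertex_distance(p, graph)$distance_um
    if (dv <= vertex_tol)
      return(list(class = "multicellular", distance_um = dv,
                  out_of_range = FALSE))
    ad <- arc_distance_to_vertex(p, graph, band_halfwidth = junction_band)
    if (isTRUE(ad$in_band))
      return(list(class = "bicellular", distance_um = dv,
                  out_of_range = FALSE))
    return(list(class = "non-junctional", distance_um = dv,
                out_of_range = FALSE))
  }
  ## explant: along-junction distance
  dv <- nearest_vertex_distance(p, graph)$distance_um
  if (dv <= at_tol)
    return(list(class = "at", distance_um = dv, out_of_range = FALSE))
  ad <- arc_distance_to_vertex(p, graph, band_halfwidth = Inf)
  d <- ad$arc_um
  if (is.na(d))
    return(list(class = NA_character_, distance_um = NA_real_,
                out_of_range = TRUE))
  if (d < 5)
    list(class = "near", distance_um = d, out_of_range = FALSE)
  else if (d <= far_max)
    list(class = "far", distance_um = d, out_of_range = FALSE)
  else
    list(class = NA_character_, distance_um = d, out_of_range = TRUE)
}

#' Normalized transmigration efficiency
#'
#' Per replicate, the fraction of cells that transmigrated; fractions
#' are then divided by the control-group mean (optionally within
#' experiment blocks) so the control mean is exactly 1.
#'
#' @param counts data.frame with `replicate`, `group`, `transmigrated`,
#'   `total` and optionally `experiment`.
#' @param control label of the control group.
#' @return `counts` with `fraction` and `efficiency` columns appended.
#' @export
transmigration_efficiency <- function(counts, control = "control") {
  if (any(counts$total <= 0)) stop("totals must be > 0")
  counts$fraction <- counts$transmigrated / counts$total
  blocks <- if ("experiment" %in% names(counts))
    counts$experiment else rep(1L, nrow(counts))
  counts$efficiency <- NA_real_
  for (b in unique(blocks)) {
    sel <- blocks == b
    ctrl_mean <- mean(counts$fraction[sel & counts$group == control])
    if (!is.finite(ctrl_mean) || ctrl_mean <= 0)
      stop("control mean fraction is zero or missing in block ", b)
    counts$efficiency[sel] <- counts$fraction[sel] / ctrl_mean
  }
  counts
}

#' Classify a comet track against a circular ROI
#'
#' Microtubule plus-end (comet) fate at a junctional ROI of default
#' diameter 10 um: `excluded` if the track never enters the ROI,
#' `arrest` if it enters and terminates inside, `pass` if it enters and
#' exits.
#'
#' @param track data.frame with `x_um`, `y_um` ordered in time.
#' @param roi_center length-2 numeric (x, y um).
#' @param roi_diameter ROI diameter in um (default 10).
#' @return one of `"pass"`, `"arrest"`, `"excluded"`.
#' @export
comet_fate <- function(track, roi_center, roi_diameter = 10) {
  p <- .as_xy(track)
  r <- roi_diameter / 2
  inside <- sqrt((p[, 1] - roi_center[1])^2 +
                 (p[, 2] - roi_center[2])^2) <= r
  if (!any(inside)) return("excluded")
  if (inside[length(inside)]) "arrest" else "pass"
}

#' Drop tracks that never migrated
#'
#' Flow-carried, non-migrating objects are removed by a minimum net
#' displacement filter before motility statistics.
#'
#' @param positions data.frame `track_id`, `t_s`, `x_um`, `y_um`.
#' @param min_displacement minimum net displacement in um (default 10).
#' @return filtered positions; attribute `n_removed` counts dropped
#'   tracks.
#' @export
filter_nonmigrating <- function(positions, min_displacement = 10) {
  keep <- vapply(split(positions, positions$track_id), function(tr) {
    tr <- tr[order(tr$t_s), ]
    n <- nrow(tr)
    sqrt((tr$x_um[n] - tr$x_um[1])^2 +
         (tr$y_um[n] - tr$y_um[1])^2) >= min_displacement
  }, logical(1))
  ids <- names(keep)[keep]
  out <- positions[as.character(positions$track_id) %in% ids, ,
                   drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}
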
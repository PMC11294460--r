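#' Assign exocytosis events to the junction band
#'
#' Keeps the events lying within `band_halfwidth` (perpendicular
#' distance to the junction midline polyline) of some bicellular edge —
#' the resolution-independent analogue of counting disappearances inside
#' a 14 um wide line drawn along the junction (7 um on either side) —
#' and annotates them with the edge and the along-junction arc distance
#' to the nearest multicellular vertex. Out-of-band events are retained
#' with `in_band = FALSE` and excluded from junctional statistics.
#'
#' @param events data.frame with `x_um`, `y_um` and optionally `t_s`,
#'   `cell_id`, `condition`.
#' @param graph a `junction_graph`.
#' @param band_halfwidth band half-width in um (default 7).
#' @return `events` with columns `in_band`, `edge_id`, `perp_um`,
#'   `arc_um`, `vertex_id`, `bounded` appended.
#' @export
assign_events_to_band <- function(events, graph, band_halfwidth = 7) {
  ann <- arc_distance_to_vertex(events, graph, band_halfwidth)
  cbind(events,
        ann[, c("in_band", "edge_id", "perp_um", "arc_um",
                "vertex_id", "bounded")])
}

#' Per-cell histogram of exocytosis events by vertex distance
#'
#' Bins in-band events by arc distance to the nearest multicellular
#' vertex and reports the mean number of events per cell in each bin
#' (with SD across cells), plus the total events per cell — the
#' "mean number of secretions/cell as a function of distance" readout.
#' Counts are conserved: summed over bins they equal the number of
#' in-band events.
#'
#' @param events_annotated output of [assign_events_to_band()]; every
#'   event must carry a `cell_id`.
#' @param bin_width bin width in um (default 5).
#' @param cells optional vector of cell ids defining the population of
#'   analyzed cells (cells with zero events count toward the mean);
#'   defaults to the cells present in the data.
#' @return list with `histogram` (data.frame `bin_lo`, `bin_hi`,
#'   `mean_events_per_cell`, `sd_events_per_cell`, `total_events`),
#'   `per_cell_total` (data.frame `cell_id`, `n_events`), `n_in_band`,
#'   `n_out_of_band`.
#' @export
event_distance_histogram <- function(events_annotated, bin_width = 5,
                                     cells = NULL) {
  ev <- events_annotated
  if (!"cell_id" %in% names(ev) || any(is.na(ev$cell_id))) {
    bad <- if ("id" %in% names(ev))
      ev$id[is.na(ev$cell_id)] else which(is.na(ev$cell_id))
    stop("events without cell_id: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  if (is.null(cells)) cells <- sort(unique(ev$cell_id))
  inb <- ev[ev$in_band & !is.na(ev$arc_um), , drop = FALSE]
  n_cells <- length(cells)
  max_d <- if (nrow(inb)) max(inb$arc_um) else 0
  nb <- max(1, floor(max_d / bin_width) + 1)
  ## per-cell x per-bin counts
  M <- matrix(0, n_cells, nb, dimnames = list(as.character(cells), NULL))
  if (nrow(inb)) {
    bi <- floor(inb$arc_um / bin_width) + 1L
    tb <- table(factor(as.character(inb$cell_id),
                       levels = as.character(cells)),
                factor(bi, levels = seq_len(nb)))
    M <- matrix(as.numeric(tb), n_cells, nb,
                dimnames = dimnames(M))
  }
  hist_df <- data.frame(
    bin_lo = (seq_len(nb) - 1) * bin_width,
    bin_hi = seq_len(nb) * bin_width,
    mean_events_per_cell = colMeans(M),
    sd_events_per_cell = apply(M, 2, stats::sd),
    total_events = colSums(M))
  per_cell <- data.frame(cell_id = cells, n_events = rowSums(M))
  list(histogram = hist_df, per_cell_total = per_cell,
       n_in_band = nrow(inb),
       n_out_of_band = sum(!events_annotated$in_band))
}

#' Fit an exponential decay length to distances or binned means
#'
#' For raw distances the maximum-likelihood decay length of an
#' exponential is their mean. For binned means a log-linear fit of
#' `log(mean)` against bin centers is used (bins with zero mass are
#' dropped).
#'
#' @param x numeric vector of distances, or a histogram data.frame with
#'   `bin_lo`, `bin_hi` and a mean/count column.
#' @param value_col column to fit when `x` is a histogram (default
#'   `"mean_events_per_cell"`).
#' @return the estimated decay length (um).
#' @export
fit_exponential_decay <- function(x, value_col = "mean_events_per_cell") {
  if (is.data.frame(x)) {
    ctr <- (x$bin_lo + x$bin_hi) / 2
    v <- x[[value_col]]
    keep <- v > 0
    if (sum(keep) < 2) stop("need at least two nonzero bins")
    fit <- stats::lm(log(v[keep]) ~ ctr[keep])
    return(-1 / unname(stats::coef(fit)[2]))
  }
  mean(x, na.rm = TRUE)
}
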
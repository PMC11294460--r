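#' Specification for a synthetic endothelial monolayer
#'
#' Bundles the geometry parameters of a simulated confluent monolayer.
#' Cell geometry is a Voronoi tessellation of random seed points, with
#' optional Lloyd relaxation as a regularity knob: 0 iterations gives
#' irregular cells, a few iterations gives the near-hexagonal packing of
#' a cultured endothelial sheet. Coordinates are continuous, in
#' micrometers, x along columns and y along rows, origin at the center of
#' the top-left pixel.
#'
#' @param n_cells number of cells (>= 1).
#' @param field_size field extent in um, length 1 (square) or 2 (width,
#'   height).
#' @param pixel_size rasterization pixel size, um/px.
#' @param lloyd_iterations Lloyd relaxation iterations (default 2).
#' @param rng_seed integer seed; identical spec implies bit-identical
#'   output.
#' @return object of class `monolayer_spec`.
#' @export
monolayer_spec <- function(n_cells, field_size, pixel_size,
                           lloyd_iterations = 2, rng_seed = 1) {
  if (!is.numeric(n_cells) || n_cells < 1) stop("n_cells must be >= 1")
  if (length(field_size) == 1L) field_size <- rep(field_size, 2)
  if (any(field_size <= 0)) stop("field_size must be positive")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  structure(list(n_cells = as.integer(n_cells),
                 field_size = as.numeric(field_size),
                 pixel_size = as.numeric(pixel_size),
                 lloyd_iterations = as.integer(lloyd_iterations),
                 rng_seed = as.integer(rng_seed)),
            class = "monolayer_spec")
}

## run expr with a local, restored RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic monolayer with planted ground truth
#'
#' Rasterizes a (Lloyd-relaxed) Voronoi tessellation onto the pixel grid
#' and derives the ground-truth junction graph from the labels. Every
#' pixel is assigned to exactly one cell, so the labels partition the
#' field; interior vertices have degree >= 3 by construction.
#'
#' @param spec a [monolayer_spec()].
#' @param seed_points optional n x 2 matrix of seed positions (um); when
#'   given, `n_cells` and the RNG are ignored for seed placement (used
#'   e.g. to build exact hexagonal lattices).
#' @return object of class `planted_truth`: list with `label_image`
#'   (integer matrix), `graph` (ground-truth [build_junction_graph()]
#'   output), `seeds_um`, and `spec`.
#' @export
generate_monolayer <- function(spec, seed_points = NULL) {
  stopifnot(inherits(spec, "monolayer_spec"))
  ps <- spec$pixel_size
  nx <- round(spec$field_size[1] / ps)
  ny <- round(spec$field_size[2] / ps)
  if (nx < 1 || ny < 1) stop("field smaller than one pixel")
  if (is.null(seed_points)) {
    if (spec$n_cells > nx * ny)
      stop(sprintf("n_cells = %d cannot be resolved on a %d x %d pixel grid",
                   spec$n_cells, ny, nx))
    seeds <- .with_seed(spec$rng_seed, cbind(
      stats::runif(spec$n_cells, 0, (nx - 1) * ps),
      stats::runif(spec$n_cells, 0, (ny - 1) * ps)))
  } else {
    seeds <- .as_xy(seed_points)
  }
  xs <- (seq_len(nx) - 1) * ps
  ys <- (seq_len(ny) - 1) * ps
  assign_labels <- function(seeds) {
    D <- matrix(Inf, ny, nx); lab <- matrix(1L, ny, nx)
    for (k in seq_len(nrow(seeds))) {
      dk <- outer((ys - seeds[k, 2])^2, (xs - seeds[k, 1])^2, "+")
      upd <- dk < D
      D[upd] <- dk[upd]; lab[upd] <- k
    }
    lab
  }
  lab <- assign_labels(seeds)
  iters <- if (is.null(seed_points)) spec$lloyd_iterations else 0L
  if (iters > 0) {
    for (it in seq_len(iters)) {
      idx <- seq_len(ny * nx)
      rr <- (idx - 1L) %% ny + 1L
      cc <- (idx - 1L) %/% ny + 1L
      seeds <- cbind(as.numeric(tapply((cc - 1) * ps, lab, mean)),
                     as.numeric(tapply((rr - 1) * ps, lab, mean)))
      lab <- assign_labels(seeds)
    }
  }
  ## guard against cells lost during relaxation/rasterization
  present <- sort(unique(as.integer(lab)))
  if (length(present) < nrow(seeds)) {
    remap <- integer(nrow(seeds)); remap[present] <- seq_along(present)
    lab <- matrix(remap[lab], ny, nx)
    seeds <- seeds[present, , drop = FALSE]
  }
  graph <- build_junction_graph(lab, ps)
  structure(list(label_image = lab, graph = graph, seeds_um = seeds,
                 spec = spec),
            class = "planted_truth")
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf("planted_truth: %d cells on %d x %d px (%.3g um/px), %d vertices\n",
              nrow(x$graph$cells), x$graph$dim[1], x$graph$dim[2],
              x$graph$pixel_size, nrow(x$graph$vertices)))
  invisible(x)
}

#' Render a junction-channel intensity image
#'
#' Produces the synthetic analogue of a VE-cadherin-stained junction
#' channel: intensity is maximal on cell boundaries, blurred with a
#' Gaussian of `line_sigma`, and corrupted by Poisson shot noise (plus
#' optional Gaussian read noise) at the stated peak signal-to-noise
#' ratio. `snr = Inf` renders the noiseless image.
#'
#' @param truth a `planted_truth`.
#' @param line_sigma Gaussian blur sigma in um (default 0.3).
#' @param snr peak SNR (peak mean / shot-noise sd at the peak).
#' @param read_noise additive Gaussian noise sd, in units of the peak
#'   signal (default 0).
#' @param seed RNG seed for the noise.
#' @return numeric matrix, peak signal normalized to 1 before noise.
#' @export
render_junction_image <- function(truth, line_sigma = 0.3, snr = Inf,
                                  read_noise = 0, seed = 1) {
  stopifnot(inherits(truth, "planted_truth"))
  g <- .blurred_boundary(truth$label_image, line_sigma,
                         truth$graph$pixel_size)
  if (!is.finite(snr) && read_noise == 0) return(g)
  .with_seed(seed, {
    img <- g
    if (is.finite(snr)) {
      photons <- snr^2
      img <- matrix(stats::rpois(length(g), photons * pmax(g, 0)) / photons,
                    nrow(g), ncol(g))
    }
    if (read_noise > 0)
      img <- img + matrix(stats::rnorm(length(g), 0, read_noise),
                          nrow(g), ncol(g))
    img
  })
}

.boundary_mask <- function(L) {
  ny <- nrow(L); nx <- ncol(L)
  B <- matrix(FALSE, ny, nx)
  dv <- L[-ny, ] != L[-1, ]
  B[-ny, ][dv] <- TRUE; B[-1, ][dv] <- TRUE
  dh <- L[, -nx] != L[, -1]
  B[, -nx][dh] <- TRUE; B[, -1][dh] <- TRUE
  B
}

.blurred_boundary <- function(L, line_sigma, ps) {
  B <- .boundary_mask(L) * 1
  if (line_sigma > 0) B <- EBImage::gblur(B, sigma = line_sigma / ps)
  mx <- max(B)
  if (mx > 0) B <- B / mx
  B
}

#' Render junction intensity decaying with distance from vertices
#'
#' Emulates a junctional protein channel (ELKS-like) that peaks at
#' multicellular junctions and decays to a plateau along the bicellular
#' junction: pixels carry
#' `(1 - plateau_ratio) * exp(-d / ell) + plateau_ratio`, where `d` is
#' the along-junction arc distance from the pixel's projection onto the
#' junction midline to the nearest multicellular vertex (the Euclidean
#' vertex distance is used for pixels on junctions with no vertex).
#' The signal fills a band of half-width `band_halfwidth` around the
#' junction midline, so a width-averaged intensity profile along the
#' junction reproduces the planted curve; outside the band the channel
#' is dark.
#'
#' @inheritParams render_junction_image
#' @param ell decay length in um.
#' @param plateau_ratio plateau-to-peak intensity ratio in `[0, 1]`.
#' @param band_halfwidth half-width of the junctional band (um,
#'   default 1.5, the sub-junctional localization width of a docking
#'   factor hugging the membrane).
#' @export
render_vertex_decay_image <- function(truth, ell, plateau_ratio,
                                      band_halfwidth = 1.5, snr = Inf,
                                      read_noise = 0, seed = 1) {
  stopifnot(inherits(truth, "planted_truth"))
  graph <- truth$graph
  ps <- graph$pixel_size
  ny <- graph$dim[1]; nx <- graph$dim[2]
  ## cheap prefilter: only pixels near a boundary can be in the band
  bd <- EBImage::distmap(1 - .boundary_mask(truth$label_image)) * ps
  cand <- which(bd <= band_halfwidth + 2 * ps)
  ctr_y <- ((cand - 1L) %% ny) * ps
  ctr_x <- ((cand - 1L) %/% ny) * ps
  ad <- arc_distance_to_vertex(cbind(ctr_x, ctr_y), graph,
                               band_halfwidth = band_halfwidth)
  d <- ad$arc_um
  ## junctions with no vertex at either end: fall back to Euclidean
  unb <- ad$in_band & !is.na(ad$bounded) & !ad$bounded
  if (any(unb) && nrow(graph$vertices) > 0) {
    d[unb] <- nearest_vertex_distance(
      cbind(ctr_x[unb], ctr_y[unb]), graph)$distance_um
  }
  val <- ifelse(ad$in_band & !is.na(d),
                (1 - plateau_ratio) * exp(-d / ell) + plateau_ratio, 0)
  img <- matrix(0, ny, nx)
  img[cand] <- val
  if (!is.finite(snr) && read_noise == 0) return(img)
  .with_seed(seed, {
    out <- img
    if (is.finite(snr)) {
      photons <- snr^2
      out <- matrix(stats::rpois(length(img), photons * pmax(img, 0)) / photons,
                    nrow(img), ncol(img))
    }
    if (read_noise > 0)
      out <- out + matrix(stats::rnorm(length(img), 0, read_noise),
                          nrow(img), ncol(img))
    out
  })
}

## fine arc discretization of edges: one row per arc sample point
## d_fold = arc distance to the nearer non-OPEN end (NA if none)
.edge_arc_samples <- function(graph, delta, cells = NULL) {
  rows <- list()
  for (e in graph$edges) {
    if (!is.null(cells) && !any(e$cells %in% cells)) next
    rs <- .resample_polyline(e$polyline, delta)
    if (is.null(rs)) next
    L <- e$arc_length
    d1 <- if (!is.na(e$v1)) rs$s else Inf
    d2 <- if (!is.na(e$v2)) L - rs$s else Inf
    d <- pmin(d1, d2)
    bounded <- !is.na(e$v1) || !is.na(e$v2)
    if (!bounded) d <- rep(NA_real_, length(rs$s))
    rows[[length(rows) + 1L]] <- data.frame(
      edge_id = e$id, s = rs$s, x = rs$x, y = rs$y,
      tx = rs$tx, ty = rs$ty, d_fold = d, bounded = bounded)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

## resample a polyline at arc step `delta` (midpoint positions)
.resample_polyline <- function(poly, delta) {
  seg <- diff(poly)
  seg_len <- sqrt(rowSums(seg^2))
  L <- sum(seg_len)
  if (L <= 0) return(NULL)
  s <- seq(delta / 2, L - delta / 2, by = delta)
  if (!length(s)) s <- L / 2
  cum <- c(0, cumsum(seg_len))
  k <- findInterval(s, cum, rightmost.closed = TRUE)
  k[k > length(seg_len)] <- length(seg_len)
  frac <- (s - cum[k]) / seg_len[k]
  list(s = s,
       x = poly[k, 1] + frac * seg[k, 1],
       y = poly[k, 2] + frac * seg[k, 2],
       tx = seg[k, 1] / seg_len[k],
       ty = seg[k, 2] / seg_len[k])
}

## reflect coordinates into [lo, hi]
.reflect <- function(x, lo, hi) {
  span <- hi - lo
  x <- (x - lo) %% (2 * span)
  lo + ifelse(x > span, 2 * span - x, x)
}

.field_extent <- function(graph) {
  ps <- graph$pixel_size
  list(xlim = c(-0.5 * ps, (graph$dim[2] - 0.5) * ps),
       ylim = c(-0.5 * ps, (graph$dim[1] - 0.5) * ps))
}

#' Sample vesicle-like spots enriched near multicellular vertices
#'
#' Draws `(1 - beta) * n` points inside the junction band with density
#' proportional to `exp(-d / tau)` along the junction, `d` being the
#' along-junction distance to the nearest multicellular vertex, plus
#' `beta * n` background points uniform over the field. The generating
#' component and true `d` are stored per point so downstream estimators
#' can be checked against the planted decay length.
#'
#' @param truth a `planted_truth`.
#' @param n total number of points.
#' @param tau decay length in um (> 0).
#' @param beta background fraction in `[0, 1]`.
#' @param band_halfwidth perpendicular half-width of the junction band
#'   within which junctional points may fall (um, default 7).
#' @param perp_halfwidth perpendicular spread of the junctional points
#'   around the junction midline (um, default 1, and never wider than
#'   `band_halfwidth`). Vesicles and fusion events sit at or near the
#'   membrane junction itself; the band is the capture region, not the
#'   physical spread.
#' @param channel channel tag stored with the points.
#' @param seed RNG seed.
#' @return data.frame `id`, `channel`, `x_um`, `y_um`,
#'   `truth_component`, `truth_d_um`, `truth_edge_id`.
#' @export
sample_junction_spots <- function(truth, n, tau, beta = 0,
                                  band_halfwidth = 7,
                                  perp_halfwidth = 1, channel = "A",
                                  seed = 1) {
  perp_halfwidth <- min(perp_halfwidth, band_halfwidth)
  stopifnot(inherits(truth, "planted_truth"))
  if (tau <= 0) stop("tau must be > 0")
  if (beta < 0 || beta > 1) stop("beta must be in [0, 1]")
  graph <- truth$graph
  n_enr <- round((1 - beta) * n)
  n_bg <- n - n_enr
  ext <- .field_extent(graph)
  .with_seed(seed, {
    enr <- NULL
    if (n_enr > 0) {
      delta <- min(0.1, tau / 20)
      samp <- .edge_arc_samples(graph, delta)
      samp <- samp[samp$bounded & !is.na(samp$d_fold), , drop = FALSE]
      if (is.null(samp) || nrow(samp) == 0L)
        stop("graph has no vertex-bounded edges to sample along")
      w <- exp(-samp$d_fold / tau)
      idx <- sample.int(nrow(samp), n_enr, replace = TRUE, prob = w)
      along <- stats::runif(n_enr, -delta / 2, delta / 2)
      perp <- stats::runif(n_enr, -perp_halfwidth, perp_halfwidth)
      x <- samp$x[idx] + along * samp$tx[idx] - perp * samp$ty[idx]
      y <- samp$y[idx] + along * samp$ty[idx] + perp * samp$tx[idx]
      enr <- data.frame(
        x_um = .reflect(x, ext$xlim[1], ext$xlim[2]),
        y_um = .reflect(y, ext$ylim[1], ext$ylim[2]),
        truth_component = "junctional",
        truth_d_um = samp$d_fold[idx],
        truth_edge_id = samp$edge_id[idx])
    }
    bg <- NULL
    if (n_bg > 0) {
      bg <- data.frame(
        x_um = stats::runif(n_bg, ext$xlim[1], ext$xlim[2]),
        y_um = stats::runif(n_bg, ext$ylim[1], ext$ylim[2]),
        truth_component = "background",
        truth_d_um = NA_real_, truth_edge_id = NA_integer_)
    }
    out <- rbind(enr, bg)
    out <- cbind(id = seq_len(nrow(out)), channel = channel, out)
    rownames(out) <- NULL
    out
  })
}

#' Plant a second spot channel with a known colocalization fraction
#'
#' Places `round(f * nrow(base))` second-channel points at a random
#' subset of the base points plus isotropic Gaussian jitter (sub-
#' resolution localization error), and adds `n_extra` independent
#' uniform points. The ground-truth pairing is stored, so the fraction
#' recovered by [pair_spots()] can be compared with the planted `f`.
#'
#' @param base SpotSet data.frame (the reference channel).
#' @param f planted colocalized fraction in `[0, 1]`.
#' @param jitter_sd isotropic jitter sd per coordinate (um).
#' @param n_extra independent (non-colocalized) points to add.
#' @param truth optional `planted_truth` giving the field extent for the
#'   extra points; defaults to the bounding box of `base`.
#' @param channel channel tag (default "B").
#' @param seed RNG seed.
#' @return data.frame like `base` with `truth_pair_id` (base id or NA).
#' @export
plant_colocalization <- function(base, f, jitter_sd = 0, n_extra = 0,
                                 truth = NULL, channel = "B", seed = 1) {
  if (f < 0 || f > 1) stop("f must be in [0, 1]")
  nb <- nrow(base)
  m <- round(f * nb)
  if (!is.null(truth)) {
    ext <- .field_extent(truth$graph)
  } else {
    ext <- list(xlim = range(base$x_um), ylim = range(base$y_um))
  }
  .with_seed(seed, {
    idx <- if (m > 0) sample.int(nb, m) else integer(0)
    par_x <- base$x_um[idx] + stats::rnorm(m, 0, jitter_sd)
    par_y <- base$y_um[idx] + stats::rnorm(m, 0, jitter_sd)
    ex_x <- stats::runif(n_extra, ext$xlim[1], ext$xlim[2])
    ex_y <- stats::runif(n_extra, ext$ylim[1], ext$ylim[2])
    out <- data.frame(
      id = seq_len(m + n_extra), channel = channel,
      x_um = c(par_x, ex_x), y_um = c(par_y, ex_y),
      truth_pair_id = c(base$id[idx], rep(NA_integer_, n_extra)))
    out
  })
}

#' Sample exocytosis events with per-cell Poisson counts
#'
#' Event counts per cell are Poisson with mean `rho0 * duration_min`;
#' event positions lie in the junction band of the owning cell with
#' along-junction density proportional to `exp(-d / tau)`; event times
#' are uniform over the recording.
#'
#' @param truth a `planted_truth`.
#' @param rho0 event rate, events per cell per minute (>= 0).
#' @param tau decay length um.
#' @param duration_min recording length in minutes.
#' @param band_halfwidth junction band half-width um (default 7).
#' @param perp_halfwidth perpendicular spread of events around the
#'   junction midline (um, default 1; capped at `band_halfwidth`).
#' @param condition condition label stored with the events.
#' @param seed RNG seed.
#' @return data.frame `id`, `x_um`, `y_um`, `t_s`, `cell_id`,
#'   `condition`, `truth_d_um`, `truth_edge_id`.
#' @export
sample_exocytosis_events <- function(truth, rho0, tau, duration_min,
                                     band_halfwidth = 7,
                                     perp_halfwidth = 1,
                                     condition = "control", seed = 1) {
  perp_halfwidth <- min(perp_halfwidth, band_halfwidth)
  stopifnot(inherits(truth, "planted_truth"))
  if (rho0 < 0) stop("rho0 must be >= 0")
  graph <- truth$graph
  ext <- .field_extent(graph)
  delta <- min(0.1, tau / 20)
  samp_all <- .edge_arc_samples(graph, delta)
  .with_seed(seed, {
    counts <- stats::rpois(nrow(graph$cells), rho0 * duration_min)
    rows <- list()
    for (k in seq_len(nrow(graph$cells))) {
      nk <- counts[k]
      if (nk == 0) next
      cid <- graph$cells$id[k]
      sub <- samp_all[samp_all$edge_id %in%
                        vapply(graph$edges, function(e)
                          if (cid %in% e$cells) e$id else NA_integer_,
                          integer(1)), , drop = FALSE]
      bounded <- sub[sub$bounded & !is.na(sub$d_fold), , drop = FALSE]
      if (nrow(bounded) > 0) sub <- bounded
      if (nrow(sub) == 0L) next  # isolated cell with no junction at all
      w <- if (all(is.na(sub$d_fold))) rep(1, nrow(sub))
           else exp(-sub$d_fold / tau)
      idx <- sample.int(nrow(sub), nk, replace = TRUE, prob = w)
      perp <- stats::runif(nk, -perp_halfwidth, perp_halfwidth)
      along <- stats::runif(nk, -delta / 2, delta / 2)
      x <- sub$x[idx] + along * sub$tx[idx] - perp * sub$ty[idx]
      y <- sub$y[idx] + along * sub$ty[idx] + perp * sub$tx[idx]
      rows[[length(rows) + 1L]] <- data.frame(
        x_um = .reflect(x, ext$xlim[1], ext$xlim[2]),
        y_um = .reflect(y, ext$ylim[1], ext$ylim[2]),
        t_s = stats::runif(nk, 0, duration_min * 60),
        cell_id = cid,
        truth_d_um = sub$d_fold[idx],
        truth_edge_id = sub$edge_id[idx])
    }
    if (!length(rows)) {
      out <- data.frame(id = integer(0), x_um = numeric(0),
                        y_um = numeric(0), t_s = numeric(0),
                        cell_id = integer(0), condition = character(0),
                        truth_d_um = numeric(0),
                        truth_edge_id = integer(0))
      return(out)
    }
    out <- do.call(rbind, rows)
    out <- cbind(id = seq_len(nrow(out)), out,
                 condition = condition)[, c("id", "x_um", "y_um", "t_s",
                                            "cell_id", "condition",
                                            "truth_d_um", "truth_edge_id")]
    rownames(out) <- NULL
    out
  })
}

#' Sample persistent random-walk tracks with planted arrest labels
#'
#' Motile tracks follow a correlated random walk: the heading receives a
#' Gaussian turn of sd `(1 - persistence) * pi` radians per step, so
#' `persistence = 1` gives perfectly straight tracks and 0 an
#' uncorrelated walk. A planted fraction of tracks is arrested: they
#' hold a position at a randomly chosen multicellular vertex, moving
#' only by localization noise, for the whole recording. Tracks are
#' reflected at the field edges; whether a reflection occurred is
#' recorded in the truth table.
#'
#' @param truth a `planted_truth`.
#' @param n number of tracks.
#' @param persistence directional persistence in `[0, 1]`.
#' @param step step length um per frame.
#' @param n_steps number of steps (track has `n_steps + 1` points).
#' @param dt_s frame interval in seconds (default 90, i.e. 1'30").
#' @param arrest_fraction planted fraction of arrested tracks.
#' @param noise_sd localization noise sd (um) applied to every position.
#' @param seed RNG seed.
#' @return list with `positions` (data.frame `track_id`, `t_s`, `x_um`,
#'   `y_um`) and `truth` (data.frame `track_id`, `arrested`,
#'   `arrest_x_um`, `arrest_y_um`, `reflected`).
#' @export
sample_tracks <- function(truth, n, persistence, step = 2, n_steps = 60,
                          dt_s = 90, arrest_fraction = 0, noise_sd = 0,
                          seed = 1) {
  stopifnot(inherits(truth, "planted_truth"))
  if (persistence < 0 || persistence > 1)
    stop("persistence must be in [0, 1]")
  graph <- truth$graph
  ext <- .field_extent(graph)
  n_arr <- round(arrest_fraction * n)
  .with_seed(seed, {
    pos <- vector("list", n); tru <- vector("list", n)
    arrested <- c(rep(TRUE, n_arr), rep(FALSE, n - n_arr))
    tt <- seq(0, n_steps) * dt_s
    for (i in seq_len(n)) {
      if (arrested[i] && nrow(graph$vertices) > 0) {
        vi <- sample.int(nrow(graph$vertices), 1)
        cx <- graph$vertices$x_um[vi]; cy <- graph$vertices$y_um[vi]
        x <- cx + stats::rnorm(n_steps + 1, 0, noise_sd)
        y <- cy + stats::rnorm(n_steps + 1, 0, noise_sd)
        refl <- FALSE
      } else if (arrested[i]) {
        cx <- stats::runif(1, ext$xlim[1], ext$xlim[2])
        cy <- stats::runif(1, ext$ylim[1], ext$ylim[2])
        x <- cx + stats::rnorm(n_steps + 1, 0, noise_sd)
        y <- cy + stats::rnorm(n_steps + 1, 0, noise_sd)
        refl <- FALSE
      } else {
        x <- numeric(n_steps + 1); y <- numeric(n_steps + 1)
        x[1] <- stats::runif(1, ext$xlim[1], ext$xlim[2])
        y[1] <- stats::runif(1, ext$ylim[1], ext$ylim[2])
        theta <- stats::runif(1, 0, 2 * pi)
        turns <- stats::rnorm(n_steps, 0, (1 - persistence) * pi)
        refl <- FALSE
        for (k in seq_len(n_steps)) {
          theta <- theta + turns[k]
          nx_ <- x[k] + step * cos(theta)
          ny_ <- y[k] + step * sin(theta)
          if (nx_ < ext$xlim[1] || nx_ > ext$xlim[2] ||
              ny_ < ext$ylim[1] || ny_ > ext$ylim[2]) refl <- TRUE
          x[k + 1] <- .reflect(nx_, ext$xlim[1], ext$xlim[2])
          y[k + 1] <- .reflect(ny_, ext$ylim[1], ext$ylim[2])
        }
        if (noise_sd > 0) {
          x <- x + stats::rnorm(n_steps + 1, 0, noise_sd)
          y <- y + stats::rnorm(n_steps + 1, 0, noise_sd)
        }
        cx <- NA_real_; cy <- NA_real_
      }
      pos[[i]] <- data.frame(track_id = i, t_s = tt, x_um = x, y_um = y)
      tru[[i]] <- data.frame(track_id = i, arrested = arrested[i],
                             arrest_x_um = cx, arrest_y_um = cy,
                             reflected = refl)
    }
    list(positions = do.call(rbind, pos), truth = do.call(rbind, tru))
  })
}

#' Simulate per-replicate transmigration counts with a planted effect
#'
#' Each replicate observes `n_dc` dendritic cells; each transmigrates
#' with probability `p_control` in the control group and
#' `effect * p_control` in the treated group. Used to verify that
#' [transmigration_efficiency()] recovers a planted efficiency drop.
#'
#' @param n_rep replicates per group.
#' @param n_dc cells observed per replicate.
#' @param p_control control transmigration probability.
#' @param effect multiplicative treated effect (0.7 = a 30% drop).
#' @param seed RNG seed.
#' @return data.frame `replicate`, `group`, `transmigrated`, `total`.
#' @export
sample_transmigration_replicates <- function(n_rep, n_dc, p_control,
                                             effect, seed = 1) {
  .with_seed(seed, {
    data.frame(
      replicate = rep(seq_len(n_rep), 2),
      group = rep(c("control", "treated"), each = n_rep),
      transmigrated = c(stats::rbinom(n_rep, n_dc, p_control),
                        stats::rbinom(n_rep, n_dc, effect * p_control)),
      total = n_dc)
  })
}
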
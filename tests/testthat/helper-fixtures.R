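## shared fixtures, memoized so expensive monolayers build once per run
.fixture_cache <- new.env(parent = emptyenv())

fixture_monolayer <- function(n_cells, field, pixel_size, seed,
                              lloyd = 2) {
  key <- paste(n_cells, field, pixel_size, seed, lloyd, sep = "_")
  if (!exists(key, envir = .fixture_cache)) {
    sp <- monolayer_spec(n_cells, field, pixel_size,
                         lloyd_iterations = lloyd, rng_seed = seed)
    assign(key, generate_monolayer(sp), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

## 2x2 arrangement of four equal square cells
label_four_squares <- function(n = 10) {
  L <- matrix(0L, n, n)
  h <- n / 2
  L[1:h, 1:h] <- 1L; L[1:h, (h + 1):n] <- 2L
  L[(h + 1):n, 1:h] <- 3L; L[(h + 1):n, (h + 1):n] <- 4L
  L
}

## three cells meeting in a Y
label_y_cells <- function(n = 12) {
  L <- matrix(3L, n, n)
  h <- n / 2
  L[1:h, 1:h] <- 1L
  L[1:h, (h + 1):n] <- 2L
  L
}

## hexagonal lattice seed points: one center cell and 6 neighbors
hex_seed_points <- function(pitch = 10, center = c(15, 15)) {
  ang <- (0:5) * pi / 3
  rbind(center,
        cbind(center[1] + pitch * cos(ang), center[2] + pitch * sin(ang)))
}

## a minimal graph with two vertices and one straight edge, built from
## primitives so distance operations can be checked by hand
toy_graph <- function(v = rbind(c(0, 0), c(10, 0)),
                      poly = rbind(c(0, 0), c(10, 0)),
                      open2 = FALSE) {
  vert <- data.frame(id = seq_len(nrow(v)), x_um = v[, 1], y_um = v[, 2],
                     degree = 3L, n_corners = 1L)
  edges <- list(list(id = 1L, v1 = 1L,
                     v2 = if (open2) NA_integer_ else 2L,
                     cells = c(1L, 2L), polyline = poly,
                     arc_length = sum(sqrt(rowSums(diff(poly)^2))),
                     closed = !open2, loop = FALSE))
  structure(list(vertices = vert, edges = edges,
                 cells = data.frame(), pixel_size = 0.5,
                 dim = c(40L, 40L), vertex_cells = list(1:3, 1:3)),
            class = "junction_graph")
}

## exhaustive optimal threshold matching: maximize pair count, then
## minimize total separation (feasible for <= 8 spots per channel)
oracle_pairing <- function(A, B, max_dist) {
  D <- sqrt(outer(A$x_um, B$x_um, "-")^2 + outer(A$y_um, B$y_um, "-")^2)
  na <- nrow(A); nb <- nrow(B)
  best <- list(n = -1L, tot = Inf)
  rec <- function(i, used_b, n, tot) {
    if (i > na) {
      if (n > best$n || (n == best$n && tot < best$tot - 1e-12))
        best <<- list(n = n, tot = tot)
      return(invisible())
    }
    rec(i + 1L, used_b, n, tot)
    for (j in seq_len(nb)) {
      if (!used_b[j] && D[i, j] < max_dist) {
        used_b[j] <- TRUE
        rec(i + 1L, used_b, n + 1L, tot + D[i, j])
        used_b[j] <- FALSE
      }
    }
  }
  rec(1L, logical(nb), 0L, 0)
  best
}

## brute-force vertex enumeration over 2x2 pixel windows
oracle_vertex_windows <- function(L) {
  ny <- nrow(L); nx <- ncol(L)
  out <- list()
  for (i in seq_len(ny - 1)) for (j in seq_len(nx - 1)) {
    labs <- unique(c(L[i, j], L[i, j + 1], L[i + 1, j], L[i + 1, j + 1]))
    if (length(labs) >= 3)
      out[[length(out) + 1]] <- data.frame(i = i, j = j,
                                           n_labels = length(labs))
  }
  if (!length(out)) return(data.frame(i = integer(0), j = integer(0),
                                      n_labels = integer(0)))
  do.call(rbind, out)
}

## dense-resampling shortest-arc oracle for a polyline point query
oracle_arc_distance <- function(point, poly, v1_open, v2_open,
                                step = 1e-3) {
  seg <- diff(poly)
  seg_len <- sqrt(rowSums(seg^2))
  L <- sum(seg_len)
  s <- seq(0, L, by = step)
  cum <- c(0, cumsum(seg_len))
  k <- pmin(findInterval(s, cum, rightmost.closed = TRUE), nrow(seg))
  frac <- (s - cum[k]) / seg_len[k]
  xs <- poly[k, 1] + frac * seg[k, 1]
  ys <- poly[k, 2] + frac * seg[k, 2]
  d2 <- (xs - point[1])^2 + (ys - point[2])^2
  i <- which.min(d2)
  cand <- c(if (!v1_open) s[i], if (!v2_open) L - s[i])
  list(perp = sqrt(d2[i]), arc = if (length(cand)) min(cand) else NA)
}
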
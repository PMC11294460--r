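#' Build a junction graph from a labeled monolayer image
#'
#' Traces the boundary network of a confluent cell monolayer given as a
#' label image. Multicellular vertices are the loci where three or more
#' distinct cell labels meet within a 2x2 pixel neighborhood; bicellular
#' edges are the maximal boundary chains separating exactly two labels,
#' split at vertices. Chain ends that touch the image border are marked
#' OPEN and are never vertices: only interior junctions bounded by
#' multicellular vertices on both sides are "closed" and used by the
#' along-junction analyses.
#'
#' Boundaries are traced at sub-pixel "crack" resolution: the polylines
#' run along the lattice of pixel corners between pixels of different
#' label, so a perfectly straight border between two cells yields a
#' perfectly straight polyline. Vertex corners closer than
#' `cluster_tol_px` pixels are merged and replaced by their centroid,
#' which is the reproducible analogue of marking a vertex with a dot.
#'
#' @param label_image integer matrix; rows index y, columns index x.
#'   Every pixel must carry a nonzero cell label and each cell must be
#'   4-connected.
#' @param pixel_size physical pixel size in micrometers per pixel.
#' @param cluster_tol_px vertex corners within this many pixels of each
#'   other are merged into one vertex (default 2).
#' @param merge_edges_um resolution scale for vertex merging: closed
#'   edges shorter than this (um) are contracted, fusing their endpoint
#'   vertices into one multicellular vertex. Default 0 (no contraction).
#'   Set this to the optical width of the junction line when comparing
#'   against graphs recovered from rendered/stained images, where two
#'   vertices closer than the line width are indistinguishable from one.
#' @return An object of class `junction_graph`: a list with
#'   \describe{
#'     \item{vertices}{data.frame `id`, `x_um`, `y_um`, `degree` (number
#'       of incident cells), `n_corners`.}
#'     \item{edges}{list; each element has `id`, `v1`, `v2` (vertex ids,
#'       `NA` for an OPEN end at the image border), `cells` (the two
#'       adjacent labels), `polyline` (n x 2 matrix of x,y in um),
#'       `arc_length` (um), `closed` (TRUE if both ends are vertices)
#'       and `loop` (TRUE for a boundary with no vertex at all).}
#'     \item{cells}{data.frame `id`, `area_px`, `area_um2`, `x_um`,
#'       `y_um` (centroid), `on_border`.}
#'     \item{pixel_size, dim}{geometry of the source image.}
#'   }
#' @export
build_junction_graph <- function(label_image, pixel_size,
                                 cluster_tol_px = 2,
                                 merge_edges_um = 0) {
  L <- label_image
  if (is.null(dim(L)) || length(dim(L)) != 2L)
    stop("label_image must be a 2-d matrix")
  storage.mode(L) <- "integer"
  if (any(is.na(L))) stop("label_image contains NA")
  if (any(L == 0L)) {
    bad <- which(L == 0L, arr.ind = TRUE)
    stop(sprintf(
      "label_image is not a partition: %d zero pixels inside the field (first at row %d, col %d)",
      nrow(bad), bad[1, 1], bad[1, 2]))
  }
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be a positive number")
  ny <- nrow(L); nx <- ncol(L)
  ps <- pixel_size

  cells <- .cell_table(L, ps)
  if (ny < 2L || nx < 2L || max(L) == min(L)) {
    return(.new_junction_graph(
      vertices = .empty_vertex_df(), edges = list(),
      cells = cells, pixel_size = ps, dim = c(ny, nx)))
  }

  ## --- corner classification (2x2 windows) -------------------------------
  a <- L[-ny, -nx]; b <- L[-ny, -1]; cc <- L[-1, -nx]; d <- L[-1, -1]
  ndist <- 1L + (b != a) + ((cc != a) & (cc != b)) +
    ((d != a) & (d != b) & (d != cc))
  is_vertex_corner <- ndist >= 3L

  ## incident cracks at each interior corner
  crk_up    <- a != b      # vertical crack above the corner
  crk_down  <- cc != d     # vertical crack below
  crk_left  <- a != cc     # horizontal crack to the left
  crk_right <- b != d      # horizontal crack to the right
  ncrk <- crk_up + crk_down + crk_left + crk_right
  is_saddle <- (ndist == 2L) & (ncrk == 4L)

  ## --- crack enumeration -------------------------------------------------
  ## vertical crack between pixels (r,c) | (r,c+1): corners (r-1,c), (r,c)
  vmask <- L[, -nx] != L[, -1]
  vidx <- which(vmask, arr.ind = TRUE)           # r in 1..ny, c in 1..nx-1
  ## horizontal crack between pixels (r,c) | (r+1,c): corners (r,c-1), (r,c)
  hmask <- L[-ny, ] != L[-1, ]
  hidx <- which(hmask, arr.ind = TRUE)           # r in 1..ny-1, c in 1..nx

  cid <- function(i, j) (j - 1L) * (ny - 1L) + i  # interior corner key
  n_border <- 0L
  border_id <- function(n) -(seq_len(n))

  ## endpoints; 0 marks "border" to be replaced by unique negative ids
  v_e1 <- ifelse(vidx[, 1] - 1L >= 1L, cid(vidx[, 1] - 1L, vidx[, 2]), 0L)
  v_e2 <- ifelse(vidx[, 1] <= ny - 1L, cid(vidx[, 1], vidx[, 2]), 0L)
  h_e1 <- ifelse(hidx[, 2] - 1L >= 1L, cid(hidx[, 1], hidx[, 2] - 1L), 0L)
  h_e2 <- ifelse(hidx[, 2] <= nx - 1L, cid(hidx[, 1], hidx[, 2]), 0L)

  e1 <- c(v_e1, h_e1); e2 <- c(v_e2, h_e2)
  nb <- sum(e1 == 0L) + sum(e2 == 0L)
  bids <- -seq_len(nb); k <- 1L
  z1 <- which(e1 == 0L); z2 <- which(e2 == 0L)
  if (length(z1)) { e1[z1] <- bids[seq_along(z1)]; k <- length(z1) + 1L }
  if (length(z2)) e2[z2] <- bids[seq(k, length.out = length(z2))]

  nv <- nrow(vidx); nh <- nrow(hidx)
  n_cracks <- nv + nh
  ## label pair per crack
  lab1 <- c(L[cbind(vidx[, 1], vidx[, 2])], L[cbind(hidx[, 1], hidx[, 2])])
  lab2 <- c(L[cbind(vidx[, 1], vidx[, 2] + 1L)],
            L[cbind(hidx[, 1] + 1L, hidx[, 2])])
  orient <- rep(c("v", "h"), c(nv, nh))

  ## corner coordinates in um: corner (i,j) -> x=(j-0.5)ps, y=(i-0.5)ps
  corner_xy <- function(key) {
    j <- (key - 1L) %/% (ny - 1L) + 1L
    i <- (key - 1L) %% (ny - 1L) + 1L
    cbind((j - 0.5) * ps, (i - 0.5) * ps)
  }
  ## border endpoint coordinates: midpoint of the pixel edge on the border
  bxy <- matrix(NA_real_, nb, 2)
  .bset <- function(ids, xy) { bxy[-ids, ] <<- xy }
  vb_top <- which(vidx[, 1] == 1L)        # top end on border
  vb_bot <- which(vidx[, 1] == ny)
  hb_left  <- which(hidx[, 2] == 1L)
  hb_right <- which(hidx[, 2] == nx)
  if (length(vb_top))
    .bset(e1[vb_top], cbind((vidx[vb_top, 2] - 0.5) * ps, -0.5 * ps))
  if (length(vb_bot))
    .bset(e2[vb_bot], cbind((vidx[vb_bot, 2] - 0.5) * ps, (ny - 0.5) * ps))
  if (length(hb_left))
    .bset(e1[nv + hb_left], cbind(-0.5 * ps, (hidx[hb_left, 1] - 0.5) * ps))
  if (length(hb_right))
    .bset(e2[nv + hb_right], cbind((nx - 0.5) * ps, (hidx[hb_right, 1] - 0.5) * ps))

  endpoint_xy <- function(key) {
    if (key > 0L) corner_xy(key) else bxy[-key, , drop = FALSE]
  }

  ## incidence: interior corner key -> incident crack indices
  inc <- vector("list", 0L)
  inc_keys <- c(e1[e1 > 0L], e2[e2 > 0L])
  inc_crks <- c(which(e1 > 0L), which(e2 > 0L))
  o <- order(inc_keys)
  inc_keys <- inc_keys[o]; inc_crks <- inc_crks[o]
  first <- which(!duplicated(inc_keys))
  last <- c(first[-1] - 1L, length(inc_keys))
  inc_map <- new.env(hash = TRUE, parent = emptyenv())
  for (m in seq_along(first)) {
    assign(as.character(inc_keys[first[m]]),
           inc_crks[first[m]:last[m]], envir = inc_map)
  }
  incident <- function(key) get(as.character(key), envir = inc_map)

  corner_kind <- function(key) {
    j <- (key - 1L) %/% (ny - 1L) + 1L
    i <- (key - 1L) %% (ny - 1L) + 1L
    if (is_vertex_corner[i, j]) "vertex"
    else if (is_saddle[i, j]) "saddle" else "pass"
  }

  ## at a saddle, pair up<->left and down<->right deterministically
  saddle_partner <- function(key, crk) {
    j <- (key - 1L) %/% (ny - 1L) + 1L
    i <- (key - 1L) %% (ny - 1L) + 1L
    ## identify which of the 4 incident cracks crk is
    ## up: vertical crack with bottom endpoint == key
    cr <- incident(key)
    role <- character(length(cr))
    for (q in seq_along(cr)) {
      cx <- cr[q]
      if (orient[cx] == "v") {
        role[q] <- if (e2[cx] == key) "up" else "down"
      } else {
        role[q] <- if (e2[cx] == key) "left" else "right"
      }
    }
    want <- c(up = "left", left = "up", down = "right", right = "down")
    cr[match(want[role[match(crk, cr)]], role)]
  }

  ## --- chain tracing ------------------------------------------------------
  visited <- logical(n_cracks)
  chains <- list()
  trace_from <- function(start_key, crk) {
    ## start_key: corner key (>0 vertex) or border id (<0)
    pts <- list(if (start_key > 0L) corner_xy(start_key)
                else bxy[-start_key, , drop = FALSE])
    here <- start_key
    repeat {
      visited[crk] <<- TRUE
      nxt <- if (e1[crk] == here) e2[crk] else e1[crk]
      pts[[length(pts) + 1L]] <- endpoint_xy(nxt)
      if (nxt < 0L) return(list(end = nxt, pts = pts, last = crk))
      kind <- corner_kind(nxt)
      if (kind == "vertex") return(list(end = nxt, pts = pts, last = crk))
      nxt_crk <- if (kind == "saddle") saddle_partner(nxt, crk)
                 else { cr <- incident(nxt); cr[cr != crk] }
      if (length(nxt_crk) != 1L || visited[nxt_crk])
        return(list(end = nxt, pts = pts, last = crk))
      here <- nxt; crk <- nxt_crk
    }
  }

  vkeys <- which(is_vertex_corner)
  vkeys <- cid(((vkeys - 1L) %% (ny - 1L)) + 1L,
               ((vkeys - 1L) %/% (ny - 1L)) + 1L)
  starts <- list()
  for (key in vkeys) for (crk in incident(key))
    starts[[length(starts) + 1L]] <- c(key, crk)
  bstart <- which(e1 < 0L | e2 < 0L)
  for (crk in bstart) {
    key <- if (e1[crk] < 0L) e1[crk] else e2[crk]
    starts[[length(starts) + 1L]] <- c(key, crk)
  }
  for (s in starts) {
    if (visited[s[2]]) next
    res <- trace_from(s[1], s[2])
    chains[[length(chains) + 1L]] <-
      list(start = s[1], end = res$end, pts = res$pts,
           cells = sort(c(lab1[s[2]], lab2[s[2]])), loop = FALSE)
  }
  ## leftover cracks form closed loops (boundary with no vertex/border)
  while (any(!visited)) {
    crk <- which(!visited)[1]
    key <- e1[crk]
    res <- trace_from(key, crk)
    chains[[length(chains) + 1L]] <-
      list(start = key, end = res$end, pts = res$pts,
           cells = sort(c(lab1[crk], lab2[crk])), loop = TRUE)
  }

  ## --- vertex clustering --------------------------------------------------
  vxy <- corner_xy(vkeys)
  nvert <- length(vkeys)
  if (nvert == 0L) {
    vert_df <- .empty_vertex_df()
    key2cluster <- integer(0)
  } else if (nvert == 1L) {
    memb <- 1L
  } else {
    hc <- stats::hclust(stats::dist(vxy), method = "single")
    memb <- stats::cutree(hc, h = cluster_tol_px * ps)
  }
  if (nvert >= 1L) {
    cl_x <- tapply(vxy[, 1], memb, mean)
    cl_y <- tapply(vxy[, 2], memb, mean)
    ## deterministic ids: order clusters by (y, x)
    ord <- order(round(cl_y, 9), round(cl_x, 9))
    remap <- integer(length(ord)); remap[ord] <- seq_along(ord)
    cl_id <- remap[memb]
    key2cluster <- stats::setNames(cl_id, as.character(vkeys))
    ## incident cells per vertex: union of labels in member 2x2 windows
    degs <- integer(max(cl_id)); ncor <- integer(max(cl_id))
    vcells <- vector("list", max(cl_id))
    for (m in seq_along(vkeys)) {
      key <- vkeys[m]
      j <- (key - 1L) %/% (ny - 1L) + 1L
      i <- (key - 1L) %% (ny - 1L) + 1L
      labs <- unique(c(L[i, j], L[i, j + 1L], L[i + 1L, j], L[i + 1L, j + 1L]))
      id <- cl_id[m]
      vcells[[id]] <- union(vcells[[id]], labs)
      ncor[id] <- ncor[id] + 1L
    }
    degs <- vapply(vcells, length, integer(1))
    vert_df <- data.frame(
      id = seq_along(ord),
      x_um = as.numeric(cl_x[ord]), y_um = as.numeric(cl_y[ord]),
      degree = degs, n_corners = ncor)
    vertex_cells <- lapply(vcells, sort)
  } else {
    vertex_cells <- list()
  }

  ## --- assemble edges -----------------------------------------------------
  edges <- list()
  for (ch in chains) {
    poly <- do.call(rbind, ch$pts)
    ## collapse runs of collinear points to keep polylines small
    poly <- .simplify_polyline(poly)
    v1 <- if (ch$start > 0L) unname(key2cluster[as.character(ch$start)]) else NA_integer_
    v2 <- if (!ch$loop && ch$end > 0L) unname(key2cluster[as.character(ch$end)]) else NA_integer_
    if (ch$loop) { v1 <- NA_integer_; v2 <- NA_integer_ }
    arc <- sum(sqrt(rowSums(diff(poly)^2)))
    ## drop micro-edges internal to a merged vertex cluster
    if (!is.na(v1) && !is.na(v2) && v1 == v2 &&
        arc <= max(2 * cluster_tol_px * ps, merge_edges_um)) next
    edges[[length(edges) + 1L]] <- list(
      v1 = v1, v2 = v2, cells = ch$cells, polyline = poly,
      arc_length = arc, closed = !is.na(v1) && !is.na(v2),
      loop = isTRUE(ch$loop))
  }
  if (length(edges)) {
    firsts <- t(vapply(edges, function(e) e$polyline[1, ], numeric(2)))
    ord <- order(round(firsts[, 2], 9), round(firsts[, 1], 9),
                 vapply(edges, function(e) e$arc_length, numeric(1)))
    edges <- edges[ord]
    for (m in seq_along(edges)) edges[[m]]$id <- m
  }

  g <- .new_junction_graph(vertices = vert_df, edges = edges,
                           cells = cells, pixel_size = ps,
                           dim = c(ny, nx), vertex_cells = vertex_cells)
  if (merge_edges_um > 0) g <- contract_short_edges(g, merge_edges_um)
  g
}

#' Contract sub-resolution edges of a junction graph
#'
#' Vertices connected by closed edges shorter than `min_edge_um` are
#' fused into one multicellular vertex (position: corner-count-weighted
#' centroid; incident cells: union). Two vertices closer than the width
#' of the junction line cannot be distinguished in a stained or rendered
#' image, so analyses that compare image-derived graphs against
#' ground-truth graphs should contract both at the imaging resolution.
#'
#' @param graph a `junction_graph`.
#' @param min_edge_um contraction scale in um.
#' @return a `junction_graph` with fused vertices and remapped edges.
#' @export
contract_short_edges <- function(graph, min_edge_um) {
  stopifnot(inherits(graph, "junction_graph"))
  nv <- nrow(graph$vertices)
  if (nv == 0L || !length(graph$edges)) return(graph)
  parent <- seq_len(nv)
  uf_find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (e in graph$edges) {
    if (!isTRUE(e$closed) || e$arc_length >= min_edge_um) next
    a <- uf_find(e$v1); b <- uf_find(e$v2)
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nv), uf_find, integer(1))
  if (length(unique(root)) == nv) return(graph)
  v <- graph$vertices
  cls <- split(seq_len(nv), root)
  w <- v$n_corners
  pos <- t(vapply(cls, function(ix) c(
    sum(v$x_um[ix] * w[ix]) / sum(w[ix]),
    sum(v$y_um[ix] * w[ix]) / sum(w[ix]),
    sum(w[ix])), numeric(3)))
  cellsets <- lapply(cls, function(ix)
    sort(unique(unlist(graph$vertex_cells[ix]))))
  ord <- order(round(pos[, 2], 9), round(pos[, 1], 9))
  newid_of_class <- integer(length(ord)); newid_of_class[ord] <- seq_along(ord)
  old2new <- integer(nv)
  for (q in seq_along(cls)) old2new[cls[[q]]] <- newid_of_class[q]
  vert_df <- data.frame(
    id = seq_along(ord),
    x_um = pos[ord, 1], y_um = pos[ord, 2],
    degree = vapply(cellsets, length, integer(1))[ord],
    n_corners = as.integer(pos[ord, 3]))
  vertex_cells <- cellsets[ord]
  edges <- list()
  for (e in graph$edges) {
    v1 <- if (is.na(e$v1)) NA_integer_ else old2new[e$v1]
    v2 <- if (is.na(e$v2)) NA_integer_ else old2new[e$v2]
    if (!is.na(v1) && !is.na(v2) && v1 == v2 &&
        e$arc_length < min_edge_um) next
    e$v1 <- v1; e$v2 <- v2
    edges[[length(edges) + 1L]] <- e
  }
  for (m in seq_along(edges)) edges[[m]]$id <- m
  .new_junction_graph(vertices = vert_df, edges = edges,
                      cells = graph$cells, pixel_size = graph$pixel_size,
                      dim = graph$dim, vertex_cells = vertex_cells)
}

.empty_vertex_df <- function() {
  data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
             degree = integer(0), n_corners = integer(0))
}

.new_junction_graph <- function(vertices, edges, cells, pixel_size, dim,
                                vertex_cells = list()) {
  structure(list(vertices = vertices, edges = edges, cells = cells,
                 pixel_size = pixel_size, dim = dim,
                 vertex_cells = vertex_cells),
            class = "junction_graph")
}

.cell_table <- function(L, ps) {
  tab <- table(L)
  ids <- as.integer(names(tab))
  ny <- nrow(L); nx <- ncol(L)
  border_labs <- unique(c(L[1, ], L[ny, ], L[, 1], L[, nx]))
  idx <- which(L > 0L)
  rr <- (idx - 1L) %% ny + 1L
  cc <- (idx - 1L) %/% ny + 1L
  cx <- tapply((cc - 1) * ps, L[idx], mean)
  cy <- tapply((rr - 1) * ps, L[idx], mean)
  data.frame(id = ids, area_px = as.integer(tab),
             area_um2 = as.numeric(tab) * ps^2,
             x_um = as.numeric(cx[as.character(ids)]),
             y_um = as.numeric(cy[as.character(ids)]),
             on_border = ids %in% border_labs)
}

## drop interior points that are collinear with their neighbors
.simplify_polyline <- function(p) {
  if (nrow(p) <= 2L) return(p)
  keep <- c(TRUE, abs((p[-c(1, nrow(p)), 1] - p[-c(nrow(p) - 1, nrow(p)), 1]) *
                        (p[-c(1, 2), 2] - p[-c(1, nrow(p)), 2]) -
                      (p[-c(1, nrow(p)), 2] - p[-c(nrow(p) - 1, nrow(p)), 2]) *
                        (p[-c(1, 2), 1] - p[-c(1, nrow(p)), 1])) > 1e-12,
            TRUE)
  p[keep, , drop = FALSE]
}

#' @export
print.junction_graph <- function(x, ...) {
  n_closed <- sum(vapply(x$edges, function(e) isTRUE(e$closed), logical(1)))
  cat(sprintf(
    "junction_graph: %d cells, %d vertices, %d edges (%d closed), %.3g um/px, %d x %d px\n",
    nrow(x$cells), nrow(x$vertices), length(x$edges), n_closed,
    x$pixel_size, x$dim[1], x$dim[2]))
  invisible(x)
}

#' Summarize junction-graph edges as a data frame
#'
#' @param graph a `junction_graph`.
#' @return data.frame with one row per edge (id, endpoint vertex ids,
#'   adjacent cells, arc length, closed/loop flags).
#' @export
edge_table <- function(graph) {
  stopifnot(inherits(graph, "junction_graph"))
  if (!length(graph$edges))
    return(data.frame(id = integer(0), v1 = integer(0), v2 = integer(0),
                      cell1 = integer(0), cell2 = integer(0),
                      arc_length_um = numeric(0), closed = logical(0),
                      loop = logical(0)))
  do.call(rbind, lapply(graph$edges, function(e) data.frame(
    id = e$id, v1 = e$v1, v2 = e$v2,
    cell1 = e$cells[1], cell2 = e$cells[2],
    arc_length_um = e$arc_length, closed = e$closed, loop = e$loop)))
}

#' Compare two junction graphs by vertex matching
#'
#' Matches the vertices of `found` against those of `truth` (greedy,
#' closest pair first, injective, within `tol_px` pixels) and reports
#' precision, recall and whether the two graphs are isomorphic: equal
#' vertex counts, a full one-to-one match, identical degrees and the
#' same vertex adjacency via closed edges.
#'
#' When `merge_scale_um > 0` the comparison is performed at that
#' resolution scale, the honest scale for graphs recovered from imaging:
#' both graphs are first contracted with [contract_short_edges()], and
#' residual resolution-limited splits are then fused by mutual-nearest
#' association within `merge_scale_um` — if several vertices of one
#' graph have the same nearest counterpart (within the scale) in the
#' other, they are one vertex at that resolution and are merged before
#' matching. Two multicellular vertices closer than the junction-line
#' width are indistinguishable in the image, so isomorphism is only
#' meaningful on this quotient.
#'
#' @param truth,found `junction_graph` objects on the same physical frame.
#' @param tol_px positional match tolerance in pixels (of
#'   `truth$pixel_size`).
#' @param merge_scale_um resolution scale for the quotient comparison
#'   (0 = compare raw graphs).
#' @param border_margin_um vertices within this distance of the field
#'   border are excluded from the comparison on both sides (default 0).
#'   Junctions touching the border end OPEN rather than at a vertex, so
#'   near-border vertex topology is not fully observed in either graph.
#' @return list with `n_truth`, `n_found`, `n_matched`, `precision`,
#'   `recall`, `degrees_equal`, `adjacency_equal`, `isomorphic`.
#' @export
match_graphs <- function(truth, found, tol_px = 2, merge_scale_um = 0,
                         border_margin_um = 0) {
  if (merge_scale_um > 0) {
    truth <- contract_short_edges(truth, merge_scale_um)
    found <- contract_short_edges(found, merge_scale_um)
    truth <- .merge_coassigned(truth, found, merge_scale_um)
    found <- .merge_coassigned(found, truth, merge_scale_um)
  }
  tv <- truth$vertices; fv <- found$vertices
  if (border_margin_um > 0) {
    keep_interior <- function(v, g) {
      xmax <- (g$dim[2] - 1) * g$pixel_size
      ymax <- (g$dim[1] - 1) * g$pixel_size
      v[v$x_um >= border_margin_um & v$x_um <= xmax - border_margin_um &
          v$y_um >= border_margin_um & v$y_um <= ymax - border_margin_um,
        , drop = FALSE]
    }
    tv <- keep_interior(tv, truth); fv <- keep_interior(fv, found)
  }
  tol <- tol_px * truth$pixel_size
  map_ft <- integer(0)
  if (nrow(tv) > 0L && nrow(fv) > 0L) {
    D <- sqrt(outer(fv$x_um, tv$x_um, "-")^2 +
                outer(fv$y_um, tv$y_um, "-")^2)
    cand <- which(D <= tol, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(D[cand])
      used_f <- logical(nrow(fv)); used_t <- logical(nrow(tv))
      mf <- integer(0); mt <- integer(0)
      for (q in ord) {
        fi <- cand[q, 1]; ti <- cand[q, 2]
        if (used_f[fi] || used_t[ti]) next
        used_f[fi] <- TRUE; used_t[ti] <- TRUE
        mf <- c(mf, fi); mt <- c(mt, ti)
      }
      map_ft <- stats::setNames(tv$id[mt], as.character(fv$id[mf]))
    }
  }
  n_matched <- length(map_ft)
  precision <- if (nrow(fv)) n_matched / nrow(fv) else NA_real_
  recall <- if (nrow(tv)) n_matched / nrow(tv) else NA_real_
  degrees_equal <- adjacency_equal <- FALSE
  if (n_matched == nrow(tv) && nrow(tv) == nrow(fv) && n_matched > 0L) {
    fid <- as.integer(names(map_ft))
    degs_f <- fv$degree[match(fid, fv$id)]
    degs_t <- tv$degree[match(map_ft, tv$id)]
    degrees_equal <- all(degs_f == degs_t)
    adj_set <- function(g, keep_ids, remap = NULL) {
      pairs <- lapply(g$edges, function(e)
        if (isTRUE(e$closed) && e$v1 != e$v2 &&
            e$v1 %in% keep_ids && e$v2 %in% keep_ids)
          sort(c(e$v1, e$v2)) else NULL)
      pairs <- Filter(Negate(is.null), pairs)
      if (!is.null(remap))
        pairs <- lapply(pairs, function(p)
          sort(unname(remap[as.character(p)])))
      unique(vapply(pairs, paste, character(1), collapse = "-"))
    }
    adjacency_equal <- setequal(adj_set(truth, tv$id),
                                adj_set(found, fid, map_ft))
  }
  list(n_truth = nrow(tv), n_found = nrow(fv), n_matched = n_matched,
       precision = precision, recall = recall,
       degrees_equal = degrees_equal, adjacency_equal = adjacency_equal,
       isomorphic = isTRUE(degrees_equal) && isTRUE(adjacency_equal))
}

## fuse vertices of g that share the same nearest vertex of ref within
## `scale`: at that resolution they are one vertex
.merge_coassigned <- function(g, ref, scale) {
  gv <- g$vertices; rv <- ref$vertices
  if (nrow(gv) < 2L || nrow(rv) == 0L) return(g)
  D <- sqrt(outer(gv$x_um, rv$x_um, "-")^2 +
              outer(gv$y_um, rv$y_um, "-")^2)
  nr <- apply(D, 1, which.min)
  nd <- D[cbind(seq_len(nrow(gv)), nr)]
  nr[nd > scale] <- NA_integer_
  groups <- split(seq_len(nrow(gv)), nr)
  groups <- Filter(function(ix) length(ix) > 1, groups)
  if (!length(groups)) return(g)
  parent <- seq_len(nrow(gv))
  for (ix in groups) parent[ix] <- min(ix)
  .contract_vertex_classes(g, parent)
}

## contract vertices of a graph given a class assignment (parent vector)
.contract_vertex_classes <- function(graph, parent) {
  nv <- nrow(graph$vertices)
  root <- parent
  cls <- split(seq_len(nv), root)
  v <- graph$vertices
  w <- v$n_corners
  pos <- t(vapply(cls, function(ix) c(
    sum(v$x_um[ix] * w[ix]) / sum(w[ix]),
    sum(v$y_um[ix] * w[ix]) / sum(w[ix]),
    sum(w[ix])), numeric(3)))
  cellsets <- lapply(cls, function(ix)
    sort(unique(unlist(graph$vertex_cells[ix]))))
  ord <- order(round(pos[, 2], 9), round(pos[, 1], 9))
  newid <- integer(length(ord)); newid[ord] <- seq_along(ord)
  old2new <- integer(nv)
  for (q in seq_along(cls)) old2new[cls[[q]]] <- newid[q]
  vert_df <- data.frame(
    id = seq_along(ord),
    x_um = pos[ord, 1], y_um = pos[ord, 2],
    degree = vapply(cellsets, length, integer(1))[ord],
    n_corners = as.integer(pos[ord, 3]))
  edges <- list()
  for (e in graph$edges) {
    e$v1 <- if (is.na(e$v1)) NA_integer_ else old2new[e$v1]
    e$v2 <- if (is.na(e$v2)) NA_integer_ else old2new[e$v2]
    edges[[length(edges) + 1L]] <- e
  }
  for (m in seq_along(edges)) edges[[m]]$id <- m
  .new_junction_graph(vertices = vert_df, edges = edges,
                      cells = graph$cells, pixel_size = graph$pixel_size,
                      dim = graph$dim, vertex_cells = cellsets[ord])
}
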
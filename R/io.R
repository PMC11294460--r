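#' Read and write pipeline artifacts
#'
#' Plain-format I/O for every object the pipeline exchanges: 16-bit
#' label TIFFs, 32-bit intensity TIFFs (stored scaled to `[0, 1]` with
#' the scale in a sidecar-free convention: pass/receive the scale
#' explicitly), junction graphs as JSON, point/event/track tables as
#' CSV, and monolayer specs as YAML.
#'
#' @name junctionscape-io
NULL

#' @rdname junctionscape-io
#' @param label_image integer matrix of cell labels.
#' @param path file path.
#' @export
write_label_tiff <- function(label_image, path) {
  if (max(label_image) > 65535L) stop("labels exceed 16-bit range")
  tiff::writeTIFF(label_image / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname junctionscape-io
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}

#' @rdname junctionscape-io
#' @param image numeric matrix.
#' @param scale intensity mapped to 1.0 in the file (default: image
#'   max).
#' @export
write_intensity_tiff <- function(image, path, scale = max(image)) {
  if (scale <= 0) scale <- 1
  tiff::writeTIFF(pmin(pmax(image / scale, 0), 1), path,
                  bits.per.sample = 32L)
  invisible(path)
}

#' @rdname junctionscape-io
#' @export
read_intensity_tiff <- function(path, scale = 1) {
  tiff::readTIFF(path) * scale
}

#' @rdname junctionscape-io
#' @param graph a `junction_graph`.
#' @export
write_graph_json <- function(graph, path) {
  stopifnot(inherits(graph, "junction_graph"))
  obj <- list(
    pixel_size = graph$pixel_size,
    dim = graph$dim,
    vertices = graph$vertices,
    cells = graph$cells,
    edges = lapply(graph$edges, function(e) list(
      id = e$id, v1 = e$v1, v2 = e$v2, cells = e$cells,
      arc_length = e$arc_length, closed = e$closed, loop = e$loop,
      polyline_x = e$polyline[, 1], polyline_y = e$polyline[, 2])))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname junctionscape-io
#' @export
read_graph_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  ne <- if (is.data.frame(obj$edges)) nrow(obj$edges)
        else length(obj$edges)
  edges <- lapply(seq_len(ne), function(i) {
    e <- if (is.data.frame(obj$edges)) as.list(obj$edges[i, ])
         else obj$edges[[i]]
    e <- lapply(e, function(x) if (is.list(x)) unlist(x) else x)
    list(id = as.integer(e$id),
         v1 = if (is.null(e$v1) || is.na(e$v1)) NA_integer_
              else as.integer(e$v1),
         v2 = if (is.null(e$v2) || is.na(e$v2)) NA_integer_
              else as.integer(e$v2),
         cells = as.integer(unlist(e$cells)),
         polyline = cbind(unlist(e$polyline_x), unlist(e$polyline_y)),
         arc_length = as.numeric(e$arc_length),
         closed = isTRUE(e$closed), loop = isTRUE(e$loop))
  })
  .new_junction_graph(
    vertices = as.data.frame(obj$vertices),
    edges = edges,
    cells = as.data.frame(obj$cells),
    pixel_size = obj$pixel_size,
    dim = as.integer(unlist(obj$dim)))
}

#' @rdname junctionscape-io
#' @param table a data.frame (spots, events or track positions).
#' @export
write_points_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname junctionscape-io
#' @export
read_points_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname junctionscape-io
#' @param spec a `monolayer_spec`.
#' @export
write_spec_yaml <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname junctionscape-io
#' @export
read_spec_yaml <- function(path) {
  s <- yaml::read_yaml(path)
  monolayer_spec(n_cells = s$n_cells, field_size = unlist(s$field_size),
                 pixel_size = s$pixel_size,
                 lloyd_iterations = s$lloyd_iterations,
                 rng_seed = s$rng_seed)
}
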
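test_that("uniform image gives a flat profile of exactly 1", {
  tr <- fixture_monolayer(12, 60, 0.2, seed = 3)
  u <- matrix(5, nrow(tr$label_image), ncol(tr$label_image))
  pc <- extract_junction_profile(u, tr$graph)
  expect_true(all(abs(pc$mean - 1) < 1e-12))
  expect_equal(pc$distance_um[1], 0)
  expect_equal(pc$mean[1], 1)  # exact by construction
})

test_that("normalization is idempotent and starts at 1", {
  tr <- fixture_monolayer(12, 60, 0.2, seed = 3)
  img <- render_vertex_decay_image(tr, ell = 3, plateau_ratio = 0.4)
  p1 <- extract_junction_profile(img, tr$graph, normalize = TRUE)
  expect_equal(p1$mean[1], 1)
  ## renormalizing the already-normalized curve changes nothing
  p2 <- p1
  p2$mean <- p2$mean / p2$mean[1]
  expect_equal(p1$mean, p2$mean)
})

test_that("profile is invariant to reversing edge polylines", {
  tr <- fixture_monolayer(12, 60, 0.2, seed = 3)
  img <- render_vertex_decay_image(tr, ell = 3, plateau_ratio = 0.4)
  p1 <- extract_junction_profile(img, tr$graph, normalize = FALSE)
  tr2 <- tr
  tr2$graph$edges <- lapply(tr$graph$edges, function(e) {
    e$polyline <- e$polyline[nrow(e$polyline):1, , drop = FALSE]
    tmp <- e$v1; e$v1 <- e$v2; e$v2 <- tmp
    e
  })
  p2 <- extract_junction_profile(img, tr2$graph, normalize = FALSE)
  expect_equal(p1$mean, p2$mean, tolerance = 1e-9)
})

test_that("planted junctional decay parameters are recovered", {
  tr <- fixture_monolayer(12, 80, 0.2, seed = 1)
  img <- render_vertex_decay_image(tr, ell = 3, plateau_ratio = 0.4)
  pc <- extract_junction_profile(img, tr$graph, line_width = 6,
                                 normalize = FALSE)
  f <- fit_profile_decay(pc)
  expect_lt(abs(f$ell - 3) / 3, 0.2)
  expect_lt(abs(f$plateau_ratio - 0.4), 0.1 * 0.4 + 0.05)
  expect_error(extract_junction_profile(
    img, build_junction_graph(matrix(1L, 10, 10), 1)), "no edges")
})

test_that("vertex region intensity: uniform case and cell-mask clipping", {
  tr <- fixture_monolayer(10, 40, 0.1, seed = 4)
  ny <- tr$graph$dim[1]; nx <- tr$graph$dim[2]
  u <- matrix(100, ny, nx)
  r <- vertex_region_intensity(u, tr$graph, radius = 5, background = 20)
  expect_true(all(r$value == 80))
  expect_true(all(r$kind == "vertex-disk"))
  ## half-plane mask through a central vertex clips the disk to a half
  v <- tr$graph$vertices
  ctr <- which(v$x_um > 10 & v$x_um < 30 & v$y_um > 10 & v$y_um < 30)[1]
  mask <- matrix(FALSE, ny, nx)
  ## include columns whose pixel centers lie at or left of the vertex,
  ## so the mask boundary passes through the vertex itself
  cutcol <- floor(v$x_um[ctr] / 0.1 + 1 + 1e-9)
  mask[, 1:cutcol] <- TRUE
  ## vertices right of the cut have empty regions and are skipped
  expect_warning(
    rm_ <- vertex_region_intensity(u, tr$graph, radius = 5,
                                   cell_mask = mask, background = 0),
    "skipped")
  full_area <- pi * 5^2
  got <- rm_$area_um2[rm_$vertex_id == v$id[ctr]]
  expect_lt(abs(got - full_area / 2) / (full_area / 2), 0.02)
  expect_true(all(rm_$kind == "vertex-pie"))
  ## planted vertex hotspots beat the rest of the cell in every seed
  for (s in 1:5) {
    trh <- fixture_monolayer(10, 40, 0.25, seed = 10 + s)
    dfield <- distance_field(trh$graph)
    hot <- 50 + 100 * (dfield <= 5)
    rh <- vertex_region_intensity(hot, trh$graph, radius = 5)
    expect_true(all(rh$mean_raw > mean(hot) ))
  }
})

test_that("whole-cell intensity subtracts background per cell", {
  tr <- fixture_monolayer(8, 30, 0.25, seed = 6)
  L <- tr$label_image
  u <- matrix(40, nrow(L), ncol(L))
  r <- whole_cell_intensity(u, L, background = 15)
  expect_true(all(r$value == 25))
  expect_equal(nrow(r), nrow(tr$graph$cells))
  ## two planted brightness classes recovered at ratio 2:1
  bright <- ifelse(matrix(L %% 2 == 0, nrow(L), ncol(L)), 80, 40)
  r2 <- whole_cell_intensity(bright, L, background = 0)
  hi <- mean(r2$value[r2$cell_id %% 2 == 0])
  lo <- mean(r2$value[r2$cell_id %% 2 == 1])
  expect_lt(abs(hi / lo - 2), 0.05 * 2)
  ## overlapping masks are rejected
  m1 <- matrix(TRUE, 4, 4); m2 <- matrix(TRUE, 4, 4)
  expect_error(whole_cell_intensity(matrix(0, 4, 4), list(m1, m2)),
               "overlap")
})

test_that("colocalization area by region: bounds and planted overlap", {
  tr <- fixture_monolayer(10, 40, 0.2, seed = 4)
  ny <- tr$graph$dim[1]; nx <- tr$graph$dim[2]
  all_on <- matrix(TRUE, ny, nx)
  r <- colocalization_area_by_region(all_on, all_on, tr$graph, radius = 5)
  expect_equal(r$pct, c(100, 100))
  r0 <- colocalization_area_by_region(all_on, !all_on, tr$graph,
                                      radius = 5)
  expect_equal(r0$pct, c(0, 0))
  ## the two region kinds partition the cell mask
  expect_equal(sum(r$area_px), ny * nx)
  ## planted overlap: B covers a random quarter of A
  set.seed(12)
  A <- matrix(runif(ny * nx) < 0.3, ny, nx)
  keep <- matrix(runif(ny * nx) < 0.25, ny, nx)
  B <- A & keep
  rp <- colocalization_area_by_region(A, B, tr$graph, radius = 5,
                                      denominator = "maskA")
  for (p in rp$pct) expect_lt(abs(p - 25), 2)
  expect_error(colocalization_area_by_region(A, B[1:10, ], tr$graph),
               "differ")
})

test_that("multi-image profile aggregation supports both weightings", {
  p1 <- data.frame(distance_um = c(0, 1, 2), mean = c(1, 0.8, 0.6),
                   sd = 0.1, n_lines = 1L)
  p2 <- data.frame(distance_um = c(0, 1, 2), mean = c(1, 0.4, 0.2),
                   sd = 0.1, n_lines = 3L)
  un <- aggregate_profiles(list(p1, p2), weights = "image")
  expect_equal(un$mean, c(1, 0.6, 0.4))
  po <- aggregate_profiles(list(p1, p2), weights = "line")
  expect_equal(po$mean, c(1, (0.8 + 3 * 0.4) / 4, (0.6 + 3 * 0.2) / 4))
  expect_equal(un$n, c(2, 2, 2))
})
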
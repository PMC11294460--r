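test_that("monolayer generation is deterministic and partitions the field", {
  sp <- monolayer_spec(12, 30, 0.25, rng_seed = 42)
  a <- generate_monolayer(sp)
  b <- generate_monolayer(sp)
  expect_identical(a$label_image, b$label_image)
  expect_true(all(a$label_image >= 1L))
  expect_equal(sort(unique(as.integer(a$label_image))),
               seq_len(nrow(a$graph$cells)))
  ## a different seed gives a different tessellation
  c <- generate_monolayer(monolayer_spec(12, 30, 0.25, rng_seed = 43))
  expect_false(identical(a$label_image, c$label_image))
})

test_that("degenerate and invalid specs are caught", {
  one <- generate_monolayer(monolayer_spec(1, 10, 0.5, rng_seed = 1))
  expect_equal(nrow(one$graph$cells), 1L)
  expect_equal(nrow(one$graph$vertices), 0L)
  expect_equal(length(one$graph$edges), 0L)
  expect_error(generate_monolayer(monolayer_spec(1e6, 5, 1, rng_seed = 1)),
               "cannot be resolved")
  expect_error(monolayer_spec(0, 10, 0.5), "n_cells")
  expect_error(monolayer_spec(5, -10, 0.5), "field_size")
})

test_that("rendered junction image peaks on boundaries and is reproducible", {
  tr <- fixture_monolayer(9, 25, 0.25, seed = 6)
  img <- render_junction_image(tr, line_sigma = 0.3, snr = Inf)
  expect_equal(max(img), 1)
  ## thresholded mask hugs the true boundary: every suprathreshold pixel
  ## within 1 px of a boundary pixel
  B <- junctionscape:::.boundary_mask(tr$label_image)
  mask <- img > 0.5
  bidx <- which(B, arr.ind = TRUE)
  midx <- which(mask, arr.ind = TRUE)
  D <- sqrt(outer(midx[, 1], bidx[, 1], "-")^2 +
              outer(midx[, 2], bidx[, 2], "-")^2)
  expect_lte(max(apply(D, 1, min)), 1)
  ## uniform single cell renders flat
  flat <- render_junction_image(
    generate_monolayer(monolayer_spec(1, 10, 0.5, rng_seed = 1)))
  expect_equal(max(flat), 0)
  ## noise is seeded
  n1 <- render_junction_image(tr, snr = 10, seed = 3)
  expect_identical(n1, render_junction_image(tr, snr = 10, seed = 3))
  expect_false(identical(n1, render_junction_image(tr, snr = 10, seed = 4)))
  ## snr scales the noise amplitude
  res10 <- render_junction_image(tr, snr = 10, seed = 1) - img
  res40 <- render_junction_image(tr, snr = 40, seed = 1) - img
  expect_gt(sd(res10[img > 0.9]), 2 * sd(res40[img > 0.9]))
})

test_that("junction spot sampler honors band, decay and background split", {
  tr <- fixture_monolayer(16, 200, 0.5, seed = 11)
  s <- sample_junction_spots(tr, 500, tau = 5, beta = 0, seed = 2)
  expect_equal(nrow(s), 500)
  expect_true(all(s$truth_component == "junctional"))
  ## all points within the band of some junction
  ad <- arc_distance_to_vertex(s, tr$graph, band_halfwidth = 7)
  expect_true(all(ad$in_band))
  ## MLE of the planted decay length from the stored true distances
  expect_equal(mean(s$truth_d_um), 5, tolerance = 0.15 * 5)
  ## beta splits counts exactly
  s2 <- sample_junction_spots(tr, 400, tau = 5, beta = 0.25, seed = 3)
  expect_equal(sum(s2$truth_component == "background"), 100)
  ## beta = 1: distances indistinguishable from the uniform null
  su <- sample_junction_spots(tr, 400, tau = 5, beta = 1, seed = 4)
  d1 <- nearest_vertex_distance(su, tr$graph)$distance_um
  set.seed(9)
  null <- nearest_vertex_distance(
    cbind(runif(4000, 0, 199.5), runif(4000, 0, 199.5)), tr$graph)$distance_um
  expect_gt(suppressWarnings(ks.test(d1, null))$p.value, 0.01)
  ## determinism
  expect_identical(s, sample_junction_spots(tr, 500, tau = 5, beta = 0,
                                            seed = 2))
  expect_error(sample_junction_spots(tr, 100, tau = -1), "tau")
})

test_that("planted colocalization stores pair identity and respects f", {
  tr <- fixture_monolayer(16, 200, 0.5, seed = 11)
  A <- sample_junction_spots(tr, 300, tau = 5, beta = 0.2, seed = 5)
  B <- plant_colocalization(A, f = 0.4, jitter_sd = 0.05, n_extra = 50,
                            truth = tr, seed = 6)
  expect_equal(sum(!is.na(B$truth_pair_id)), 120)  # round(0.4 * 300)
  expect_equal(sum(is.na(B$truth_pair_id)), 50)
  ## perfect planting: f = 1, no jitter, no extras pairs 100%
  B1 <- plant_colocalization(A, f = 1, jitter_sd = 0, n_extra = 0,
                             truth = tr, seed = 7)
  pr <- pair_spots(A, B1, max_dist = 0.4)
  expect_equal(pr$fraction_pct, 100)
  ## huge jitter defeats the threshold almost always
  Bj <- plant_colocalization(A, f = 1, jitter_sd = 1.0, n_extra = 0,
                             truth = tr, seed = 8)
  prj <- pair_spots(A, Bj, max_dist = 0.4)
  expect_lt(prj$fraction_pct, 25)  # Rayleigh tail beyond 0.4 um
})

test_that("exocytosis sampler: Poisson per-cell counts, in-band positions", {
  tr <- fixture_monolayer(120, 300, 1, seed = 13, lloyd = 1)
  ev <- sample_exocytosis_events(tr, rho0 = 2, tau = 5, duration_min = 1,
                                 seed = 3)
  n_cells <- nrow(tr$graph$cells)
  mean_per_cell <- nrow(ev) / n_cells
  se <- sqrt(2 / n_cells)
  expect_lt(abs(mean_per_cell - 2), 2 * se)
  ad <- arc_distance_to_vertex(ev, tr$graph, band_halfwidth = 7)
  expect_true(all(ad$in_band))
  expect_true(all(ev$t_s >= 0 & ev$t_s <= 60))
  ## rate zero gives no events
  expect_equal(nrow(sample_exocytosis_events(tr, 0, 5, 1, seed = 1)), 0)
})

test_that("track sampler: persistence ordering, arrest truth, determinism", {
  tr <- fixture_monolayer(9, 120, 0.5, seed = 2)
  ms <- vapply(c(0, 0.5, 1), function(p) {
    tk <- sample_tracks(tr, 60, persistence = p, step = 2, n_steps = 40,
                        seed = 5)
    mean(vapply(split(tk$positions, tk$positions$track_id),
                track_straightness, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(ms) > 0))
  ## fully persistent, unreflected tracks are perfectly straight
  tk1 <- sample_tracks(tr, 50, persistence = 1, step = 1, n_steps = 30,
                       seed = 6)
  ids <- as.character(tk1$truth$track_id[!tk1$truth$reflected])
  s1 <- vapply(split(tk1$positions, tk1$positions$track_id)[ids],
               track_straightness, numeric(1))
  expect_true(all(abs(s1 - 1) < 1e-9))
  ## same seed, same tracks
  expect_identical(tk1, sample_tracks(tr, 50, persistence = 1, step = 1,
                                      n_steps = 30, seed = 6))
  ## planted arrested tracks sit at a vertex within localization noise
  tka <- sample_tracks(tr, 40, persistence = 0.5, step = 3, n_steps = 10,
                       arrest_fraction = 0.5, noise_sd = 0.5, seed = 7)
  expect_equal(sum(tka$truth$arrested), 20)
  arr <- tka$truth[tka$truth$arrested, ]
  dv <- nearest_vertex_distance(
    data.frame(x_um = arr$arrest_x_um, y_um = arr$arrest_y_um), tr$graph)
  expect_true(all(dv$distance_um < 1e-9))
})
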
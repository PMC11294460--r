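test_that("straightness: analytic cases and invariances", {
  straight <- data.frame(t_s = seq(0, 900, 100), x_um = 0:9, y_um = 0)
  expect_identical(track_straightness(straight), 1)
  loop <- data.frame(t_s = 0:4 * 100, x_um = c(0, 1, 1, 0, 0),
                     y_um = c(0, 0, 1, 1, 0))
  expect_equal(track_straightness(loop), 0)
  Lp <- data.frame(t_s = 0:7 * 100, x_um = c(0, 1, 2, 3, 3, 3, 3, 3),
                   y_um = c(0, 0, 0, 0, 1, 2, 3, 4))
  expect_equal(track_straightness(Lp), 5 / 7)
  ## rigid motion: rotate + translate leaves the value unchanged
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  set.seed(3)
  tr <- data.frame(x_um = cumsum(rnorm(20)), y_um = cumsum(rnorm(20)))
  rot <- as.data.frame(as.matrix(tr) %*% t(R))
  names(rot) <- c("x_um", "y_um"); rot$x_um <- rot$x_um + 13
  expect_equal(track_straightness(tr), track_straightness(rot))
  ## zero path length is undefined
  still <- data.frame(t_s = 0:3, x_um = 1, y_um = 1)
  expect_true(is.na(track_straightness(still)))
})

test_that("arrest rule: dwell window, motion, early transmigration", {
  still <- data.frame(t_s = seq(0, 630, 90), x_um = 1, y_um = 2)
  r <- classify_arrest(still, dwell = 450, radius = 5)
  expect_true(r$arrested)
  expect_equal(r$rule, "dwell")
  expect_equal(c(r$arrest_x_um, r$arrest_y_um), c(1, 2))
  moving <- data.frame(t_s = seq(0, 900, 90), x_um = seq(0, 110, 11),
                       y_um = 0)
  expect_false(classify_arrest(moving)$arrested)
  ## jitter within the radius still counts as arrested
  set.seed(4)
  jitter <- data.frame(t_s = seq(0, 630, 90),
                       x_um = 1 + runif(8, -2, 2),
                       y_um = 2 + runif(8, -2, 2))
  expect_true(classify_arrest(jitter, radius = 5)$arrested)
  ## transmigration before the dwell elapses counts as arrested
  early <- data.frame(t_s = seq(0, 270, 90), x_um = c(0, 3, 6, 9),
                      y_um = 0)
  re <- classify_arrest(early, transmigrated = TRUE)
  expect_true(re$arrested)
  expect_equal(re$rule, "early-transmigration")
  expect_false(classify_arrest(early)$arrested)
  ## undersampled track rejected
  sparse <- data.frame(t_s = c(0, 500, 1000), x_um = 0:2, y_um = 0)
  expect_error(classify_arrest(sparse), "sampling interval")
})

test_that("site classification in culture and explant modes", {
  tr <- fixture_monolayer(12, 60, 0.25, seed = 8)
  g <- tr$graph
  v <- g$vertices[which.min((g$vertices$x_um - 30)^2 +
                              (g$vertices$y_um - 30)^2), ]
  near_v <- c(v$x_um + 3, v$y_um)
  expect_equal(classify_site(near_v, g, vertex_tol = 5)$class,
               "multicellular")
  ## a point on an edge midline, far from vertices, is bicellular
  long_e <- g$edges[[which.max(vapply(g$edges, function(e)
    ifelse(e$closed, e$arc_length, 0), numeric(1)))]]
  mid <- long_e$polyline[round(nrow(long_e$polyline) / 2), ]
  cls <- classify_site(mid, g, vertex_tol = 3, junction_band = 2)$class
  expect_true(cls %in% c("bicellular", "multicellular"))
  ## far from everything: non-junctional (cell centroid of biggest cell)
  big <- g$cells[which.max(g$cells$area_um2), ]
  dcv <- nearest_vertex_distance(cbind(big$x_um, big$y_um), g)$distance_um
  if (dcv > 5) {
    expect_equal(classify_site(c(big$x_um, big$y_um), g,
                               vertex_tol = 5,
                               junction_band = 1)$class,
                 "non-junctional")
  }
  ## explant thresholds on a hand-built straight junction
  gt <- toy_graph()
  expect_equal(classify_site(c(0.5, 0), gt, mode = "explant")$class, "at")
  expect_equal(classify_site(c(4.2, 0.5), gt, mode = "explant")$class,
               "near")
  ## beyond 18 um arc distance: flagged, not classified
  gl <- toy_graph(v = rbind(c(0, 0), c(50, 0)),
                  poly = rbind(c(0, 0), c(50, 0)))
  r_far <- classify_site(c(6.5, 0.5), gl, mode = "explant")
  expect_equal(r_far$class, "far")
  ro <- classify_site(c(25, 0.5), gl, mode = "explant")
  expect_true(ro$out_of_range)
  expect_true(is.na(ro$class))
})

test_that("transmigration efficiency normalizes the control mean to 1", {
  counts <- data.frame(replicate = 1:4,
                       group = c("control", "control", "treated",
                                 "treated"),
                       transmigrated = c(10, 15, 6, 8),
                       total = c(40, 50, 40, 50))
  r <- transmigration_efficiency(counts)
  expect_equal(mean(r$efficiency[r$group == "control"]), 1)
  ## hand case: 10/40 against a control mean fraction of 0.25
  single <- data.frame(replicate = 1:2, group = c("control", "treated"),
                       transmigrated = c(10, 10), total = c(40, 40))
  expect_equal(transmigration_efficiency(single)$efficiency, c(1, 1))
  expect_error(transmigration_efficiency(
    transform(counts, total = c(0, 50, 40, 50))), "totals")
  ## planted 30% drop recovered across replicates
  cts <- sample_transmigration_replicates(10, 400, 0.25, 0.7, seed = 6)
  eff <- transmigration_efficiency(cts)
  treated <- eff$efficiency[eff$group == "treated"]
  se <- sd(treated) / sqrt(length(treated))
  expect_lt(abs(mean(treated) - 0.7), 2 * se + 0.02)
})

test_that("comet fate at a circular ROI", {
  roi <- c(0, 0)
  crossing <- data.frame(x_um = seq(-10, 10, 1), y_um = 1)
  expect_equal(comet_fate(crossing, roi, 10), "pass")
  ending <- data.frame(x_um = c(-10, -5, 0), y_um = 0)
  expect_equal(comet_fate(ending, roi, 10), "arrest")
  tangent <- data.frame(x_um = seq(-10, 10, 1), y_um = 6)
  expect_equal(comet_fate(tangent, roi, 10), "excluded")
})

test_that("non-migrating tracks are filtered by net displacement", {
  drift <- data.frame(track_id = 1, t_s = 0:9 * 90,
                      x_um = seq(0, 4.5, 0.5), y_um = 0)
  mover <- data.frame(track_id = 2, t_s = 0:9 * 90,
                      x_um = seq(0, 27, 3), y_um = 0)
  out <- filter_nonmigrating(rbind(drift, mover), min_displacement = 10)
  expect_equal(unique(out$track_id), 2)
  expect_equal(attr(out, "n_removed"), 1L)
})

test_that("arrest classifier recovers planted labels at high accuracy", {
  tr <- fixture_monolayer(9, 120, 0.5, seed = 2)
  tk <- sample_tracks(tr, 200, persistence = 0.7, step = 5, n_steps = 10,
                      dt_s = 90, arrest_fraction = 0.4,
                      noise_sd = 1.25, seed = 8)  # noise = R/4
  pred <- vapply(split(tk$positions, tk$positions$track_id),
                 function(trk) classify_arrest(trk, dwell = 450,
                                               radius = 5)$arrested,
                 logical(1))
  acc <- mean(pred[as.character(tk$truth$track_id)] == tk$truth$arrested)
  expect_gte(acc, 0.95)
})
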
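## render an image with Gaussian blobs at given centers (um)
blob_image <- function(centers, sigma_um, ps, dim_px, peak = 10) {
  img <- matrix(0, dim_px[1], dim_px[2])
  ys <- (seq_len(dim_px[1]) - 1) * ps
  xs <- (seq_len(dim_px[2]) - 1) * ps
  for (k in seq_len(nrow(centers))) {
    img <- img + peak * outer(
      exp(-(ys - centers[k, 2])^2 / (2 * sigma_um^2)),
      exp(-(xs - centers[k, 1])^2 / (2 * sigma_um^2)))
  }
  img
}

test_that("spot detection finds isolated blobs at sub-pixel accuracy", {
  ps <- 0.1
  centers <- rbind(c(3.9, 2.9), c(1.9, 6.1), c(7.45, 7.9))
  img <- blob_image(centers, sigma_um = 0.2, ps = ps, dim_px = c(100, 100))
  s <- detect_spots(img, ps, min_diameter = 0.2, threshold = 1)
  expect_equal(nrow(s), 3)
  D <- sqrt(outer(s$x_um, centers[, 1], "-")^2 +
              outer(s$y_um, centers[, 2], "-")^2)
  expect_lte(max(apply(D, 2, min)), ps)    # centers within 1 px
  expect_true(all(s$diameter_um >= 0.2))
  ## blank image: nothing
  expect_equal(nrow(detect_spots(matrix(0, 50, 50), ps, threshold = 1)), 0)
  ## blob far below the diameter floor is excluded after the fit
  tiny <- blob_image(rbind(c(3, 3)), sigma_um = 0.02, ps = ps,
                     dim_px = c(60, 60))
  expect_equal(nrow(detect_spots(tiny, ps, min_diameter = 0.2,
                                 threshold = 1)), 0)
})

test_that("region exclusion removes spots by mask membership", {
  ps <- 0.5
  set.seed(31)
  spots <- data.frame(id = 1:400, channel = "A",
                      x_um = runif(400, 0, 19.5), y_um = runif(400, 0, 19.5))
  empty <- matrix(FALSE, 40, 40)
  out <- exclude_region(spots, empty, ps)
  expect_equal(nrow(out), 400)
  expect_equal(attr(out, "n_removed"), 0L)
  full <- matrix(TRUE, 40, 40)
  expect_equal(nrow(exclude_region(spots, full, ps)), 0)
  ## half-plane mask removes about half, within 2 binomial SE
  half <- matrix(FALSE, 40, 40); half[, 1:20] <- TRUE
  kept <- exclude_region(spots, half, ps)
  removed <- 400 - nrow(kept)
  expect_lt(abs(removed - 200), 2 * sqrt(400 * 0.25))
  expect_error(exclude_region(spots, "notamask", ps), "matrix")
})

test_that("pairing: threshold, injectivity and reference-channel fraction", {
  A <- data.frame(id = 1:2, x_um = c(0, 5), y_um = 0)
  ## identical coordinates pair fully
  pr <- pair_spots(A, transform(A, id = 11:12), 0.4)
  expect_equal(pr$fraction_pct, 100)
  expect_equal(nrow(pr$pairs), 2)
  ## separation at/over the threshold does not pair ("closer than")
  B <- data.frame(id = 1L, x_um = 0.5, y_um = 0)
  expect_equal(nrow(pair_spots(A[1, ], B, 0.4)$pairs), 0)
  expect_equal(nrow(pair_spots(A[1, ],
    data.frame(id = 1L, x_um = 0.4, y_um = 0), 0.4)$pairs), 0)
  ## three A near one B: only the closest pairs
  A3 <- data.frame(id = 1:3, x_um = c(0.1, 0.2, 0.3), y_um = 0)
  B1 <- data.frame(id = 9L, x_um = 0, y_um = 0)
  p3 <- pair_spots(A3, B1, 0.4)
  expect_equal(nrow(p3$pairs), 1)
  expect_equal(p3$pairs$id_a, 1L)
  expect_setequal(p3$unmatched_a, 2:3)
})

test_that("pairing is channel-symmetric up to the denominator", {
  set.seed(17)
  A <- data.frame(id = 1:30, x_um = runif(30, 0, 15), y_um = runif(30, 0, 15))
  B <- data.frame(id = 1:40, x_um = runif(40, 0, 15), y_um = runif(40, 0, 15))
  ab <- pair_spots(A, B, 0.4)
  ba <- pair_spots(B, A, 0.4)
  key_ab <- paste(ab$pairs$id_a, ab$pairs$id_b)
  key_ba <- paste(ba$pairs$id_b, ba$pairs$id_a)
  expect_setequal(key_ab, key_ba)
  expect_equal(100 * nrow(ab$pairs) / 30, ab$fraction_pct)
  expect_equal(100 * nrow(ba$pairs) / 40, ba$fraction_pct)
})

test_that("greedy pairing equals the exhaustive optimal matching when sparse", {
  set.seed(23)
  for (k in 1:60) {
    na <- sample(1:8, 1); nb <- sample(1:8, 1)
    A <- data.frame(id = seq_len(na), x_um = runif(na, 0, 10),
                    y_um = runif(na, 0, 10))
    B <- data.frame(id = seq_len(nb), x_um = runif(nb, 0, 10),
                    y_um = runif(nb, 0, 10))
    g <- pair_spots(A, B, 0.4)
    o <- oracle_pairing(A, B, 0.4)
    expect_equal(nrow(g$pairs), o$n)
    expect_equal(sum(g$pairs$separation_um), o$tot, tolerance = 1e-9)
  }
})

test_that("recovered colocalization fraction matches the planted fraction", {
  tr <- fixture_monolayer(16, 200, 0.5, seed = 11)
  A <- sample_junction_spots(tr, 1000, tau = 5, beta = 0.2, seed = 21)
  for (f in c(0.3, 0.5)) {
    B <- plant_colocalization(A, f = f, jitter_sd = 0.05, n_extra = 200,
                              truth = tr, seed = 22)
    pr <- pair_spots(A, B, 0.4)
    se <- sqrt(f * (1 - f) / 1000)
    expect_lt(abs(pr$fraction_pct / 100 - f), 2 * se + 0.01)
  }
})

test_that("colocalization-by-distance profiles decay for junctional spots", {
  tr <- fixture_monolayer(16, 200, 0.5, seed = 11)
  A <- sample_junction_spots(tr, 2000, tau = 5, beta = 0.35, seed = 31)
  ## colocalized partner only for the junctional component
  jun <- A[A$truth_component == "junctional", ]
  B <- plant_colocalization(jun, f = 1, jitter_sd = 0.05, n_extra = 0,
                            truth = tr, seed = 32)
  pr <- pair_spots(A, B, 0.4)
  bd <- colocalization_by_distance(pr, A, tr$graph, bin_width = 5,
                                   metric = "euclidean")
  ## percentages are consistent and bounded
  expect_true(all(bd$pct_coloc >= 0 & bd$pct_coloc <= 100))
  expect_equal(sum(bd$pct_coloc + bd$pct_noncoloc), 100, tolerance = 1e-9)
  ## junctional (colocalized) mass concentrates toward the vertices
  expect_true(bd$pct_coloc[1] > bd$pct_coloc[3])
  expect_gt(sum(bd$n_coloc), 0.9 * nrow(jun))
})

test_that("manual spot rescue merges explicitly before pairing", {
  auto <- data.frame(id = 1:3, channel = "B",
                     x_um = c(1, 2, 3), y_um = 0,
                     diameter_um = 0.3, intensity = 5)
  manual <- data.frame(x_um = c(4, 5), y_um = 0)
  merged <- merge_supplementary_spots(auto, manual)
  expect_equal(nrow(merged), 5)
  expect_equal(attr(merged, "n_manual"), 2L)
  expect_equal(sum(merged$source == "manual"), 2)
  expect_equal(anyDuplicated(merged$id), 0)
  A <- data.frame(id = 1:2, x_um = c(4.1, 5.1), y_um = 0)
  pr <- pair_spots(A, merged, 0.4)
  expect_equal(nrow(pr$pairs), 2)
})
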
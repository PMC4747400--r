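make_pair <- function(seed = 1, n = 4, H = 96, W = 96) {
  m <- random_disk_mask(H, W, n, seed = seed)
  make_perinuclear_rings(m, 7)
}

test_that("a constant signal map gives that constant as every perinuclear mean", {
  pair <- make_pair(seed = 2)
  sig <- matrix(0.4, 96, 96)
  rec <- measure_cells(pair, sig)
  expect_equal(nrow(rec), max(pair$nuclei))
  defined <- rec$ring_pixels > 0L
  expect_true(all(defined))
  expect_equal(rec$perinuclear_mean, rep(0.4, nrow(rec)))
  expect_equal(rec$perinuclear_integrated,
               0.4 * rec$ring_pixels, tolerance = 1e-12)
})

test_that("areas and centroids agree with direct pixel accounting", {
  pair <- make_pair(seed = 3)
  sig <- matrix(0, 96, 96)
  rec <- measure_cells(pair, sig, pixel_size_um = 0.5)
  nuc <- pair$nuclei
  # conservation: total measured area equals the nonzero mask pixel count
  expect_equal(sum(rec$area_px), sum(nuc > 0L))
  for (l in rec$label) {
    px <- which(nuc == l, arr.ind = TRUE)
    expect_equal(rec$area_px[l], nrow(px))
    expect_equal(rec$centroid_row[l], mean(px[, 1] - 1))
    expect_equal(rec$centroid_col[l], mean(px[, 2] - 1))
    expect_equal(rec$area_um2[l], nrow(px) * 0.25)
  }
})

test_that("a nucleus with no ring keeps its record with undefined mean", {
  # label 1 fully enclosed by label 2: constructed masks
  nuc <- matrix(0L, 24, 24)
  nuc[(row(nuc) - 12)^2 + (col(nuc) - 12)^2 <= 9] <- 1L
  ringless <- (row(nuc) - 12)^2 + (col(nuc) - 12)^2
  nuc[ringless > 9 & ringless <= 100] <- 2L
  pair <- make_perinuclear_rings(nuc, 3)
  rec <- measure_cells(pair, matrix(0.5, 24, 24))
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$ring_pixels[1], 0L)
  expect_true(is.na(rec$perinuclear_mean[1]))
  expect_equal(rec$perinuclear_integrated[1], 0)
  expect_gt(rec$ring_pixels[2], 0L)
})

test_that("perinuclear means are invariant under label permutation", {
  pair <- make_pair(seed = 6)
  set.seed(6)
  sig <- matrix(runif(96 * 96), 96, 96)
  rec <- measure_cells(pair, sig)
  n <- max(pair$nuclei)
  perm <- sample(n)
  nuc2 <- pair$nuclei; nuc2[nuc2 > 0L] <- perm[nuc2[nuc2 > 0L]]
  ring2 <- pair$rings; ring2[ring2 > 0L] <- perm[ring2[ring2 > 0L]]
  pair2 <- structure(list(nuclei = nuc2, rings = ring2, ring_width_px = 7L),
                     class = "ring_masks")
  rec2 <- measure_cells(pair2, sig)
  expect_equal(rec2$perinuclear_mean[perm], rec$perinuclear_mean)
  expect_equal(rec2$area_px[perm], rec$area_px)
})

test_that("adding a constant to the signal shifts every mean by that constant", {
  pair <- make_pair(seed = 8)
  set.seed(8)
  sig <- matrix(runif(96 * 96, 0, 0.5), 96, 96)
  r1 <- measure_cells(pair, sig)
  r2 <- measure_cells(pair, sig + 0.25)
  expect_equal(r2$perinuclear_mean, r1$perinuclear_mean + 0.25,
               tolerance = 1e-12)
})

test_that("measurement rejects mismatched shapes and empty masks measure empty", {
  pair <- make_pair(seed = 2)
  expect_error(measure_cells(pair, matrix(0, 10, 10)), "shape")
  empty <- make_perinuclear_rings(matrix(0L, 16, 16), 7)
  expect_equal(nrow(measure_cells(empty, matrix(0, 16, 16))), 0L)
})

test_that("group summaries handle degenerate, constant, and sampled inputs", {
  one <- data.frame(label = 1L, area_px = 100L, area_um2 = NA_real_,
                    centroid_row = 0, centroid_col = 0, ring_pixels = 10L,
                    perinuclear_mean = 0.2, perinuclear_integrated = 2,
                    border_flag = FALSE)
  s1 <- summarize_cells(one)
  expect_equal(s1$mean_area, 100)
  expect_true(is.na(s1$sem_area))      # SEM undefined for n < 2

  five <- one[rep(1, 5), ]; five$label <- 1:5
  s5 <- summarize_cells(five)
  expect_equal(s5$mean_area, 100)
  expect_equal(s5$sem_area, 0)
  expect_equal(sum(s5$area_histogram$counts), 5)

  set.seed(10)
  n <- 1000
  big <- one[rep(1, n), ]; big$label <- seq_len(n)
  big$area_px <- as.integer(round(rnorm(n, 200, 20)))
  sb <- summarize_cells(big)
  expect_lt(abs(sb$mean_area - 200), 3 * 20 / sqrt(n))
  expect_equal(sum(sb$area_histogram$counts), n)
  expect_length(sb$area_histogram$counts, 30)

  expect_error(summarize_cells(one[0, ]), "empty group")
})

test_that("ring-less cells are excluded from signal summaries but kept for area", {
  rec <- data.frame(label = 1:4, area_px = c(100L, 110L, 120L, 130L),
                    area_um2 = NA_real_, centroid_row = 0, centroid_col = 0,
                    ring_pixels = c(10L, 0L, 12L, 9L),
                    perinuclear_mean = c(0.2, NA, 0.4, 0.6),
                    perinuclear_integrated = c(2, 0, 4.8, 5.4),
                    border_flag = FALSE)
  s <- summarize_cells(rec)
  expect_equal(s$n, 4L)
  expect_equal(s$n_signal, 3L)
  expect_equal(s$n_signal_excluded, 1L)
  expect_equal(s$mean_signal, mean(c(0.2, 0.4, 0.6)))
  expect_equal(s$mean_area, mean(rec$area_px))
})

test_that("the one-tailed Student's t test matches the closed-form computation", {
  rec_of <- function(x) data.frame(
    label = seq_along(x), area_px = as.integer(x), area_um2 = NA_real_,
    centroid_row = 0, centroid_col = 0, ring_pixels = 10L,
    perinuclear_mean = 0.5, perinuclear_integrated = 5, border_flag = FALSE)

  # identical groups: t = 0, one-tailed p = 0.5
  a <- rec_of(c(100, 110, 120, 130))
  same <- compare_groups(a, a, "area", "greater")
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 0.5)

  set.seed(12)
  xa <- rnorm(50, 100, 10); xb <- rnorm(50, 200, 10)
  ga <- rec_of(xa); gb <- rec_of(xb)
  res <- compare_groups(gb, ga, "area", "greater")
  expect_lt(res$p.value, 0.001)
  # independent closed-form pooled-variance t and its CDF
  x <- as.numeric(gb$area_px); y <- as.numeric(ga$area_px)
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  expect_equal(res$statistic, tstat, tolerance = 1e-12)
  expect_equal(res$p.value,
               stats::pt(tstat, length(x) + length(y) - 2, lower.tail = FALSE),
               tolerance = 1e-12)

  # swapping groups with the mirrored alternative gives the identical p
  expect_equal(compare_groups(ga, gb, "area", "less")$p.value, res$p.value)

  expect_error(compare_groups(rec_of(1), a, "area"), "at least 2")
})

test_that("signal comparisons drop undefined cells and honour the statistic flag", {
  rec_of <- function(mu, n) data.frame(
    label = seq_len(n), area_px = 100L, area_um2 = NA_real_,
    centroid_row = 0, centroid_col = 0,
    ring_pixels = c(0L, rep(10L, n - 1)),
    perinuclear_mean = c(NA, rnorm(n - 1, mu, 0.02)),
    perinuclear_integrated = c(0, rnorm(n - 1, mu * 10, 0.2)),
    border_flag = FALSE)
  set.seed(33)
  a <- rec_of(0.6, 30); b <- rec_of(0.3, 30)
  res <- compare_groups(a, b, "signal", "greater")
  expect_equal(res$n_a, 29L)  # the NA cell is excluded
  expect_lt(res$p.value, 0.001)
  res_int <- compare_groups(a, b, "signal", "greater",
                            statistic = "integrated")
  expect_lt(res_int$p.value, 0.001)
})
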
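make_objects <- function(diameter = 20, solidity = 0.9, axial_ratio = 1.2,
                         intensity_range = 5000, frame_index = 0L,
                         centroid_row = 50, centroid_col = 50) {
  data.frame(sample_id = "s", frame_index = frame_index,
             centroid_row = centroid_row, centroid_col = centroid_col,
             area_um2 = pi * (diameter / 2)^2, diameter = diameter,
             solidity = solidity, axial_ratio = axial_ratio,
             intensity_range = intensity_range, stringsAsFactors = FALSE)
}

test_that("gates keep mid-range objects and use exclusive diameter bounds", {
  gates <- gate_params()
  keep <- make_objects(diameter = 20, solidity = 0.9, axial_ratio = 1.2,
                       intensity_range = 5000)
  expect_equal(nrow(apply_gates(keep, gates)), 1L)
  # boundary diameters are rejected: strictly greater than 12, less than 55
  expect_equal(nrow(apply_gates(make_objects(diameter = 12), gates)), 0L)
  expect_equal(nrow(apply_gates(make_objects(diameter = 55), gates)), 0L)
  expect_equal(nrow(apply_gates(make_objects(diameter = 12.01), gates)), 1L)
  # closed bounds elsewhere: the printed endpoints survive
  expect_equal(nrow(apply_gates(make_objects(solidity = 0.7), gates)), 1L)
  expect_equal(nrow(apply_gates(make_objects(solidity = 0.6), gates)), 0L)
  expect_equal(nrow(apply_gates(make_objects(axial_ratio = 1.8), gates)), 1L)
  expect_equal(nrow(apply_gates(make_objects(axial_ratio = 1.81), gates)), 0L)
  expect_equal(nrow(apply_gates(make_objects(intensity_range = 20000), gates)), 1L)
  expect_equal(nrow(apply_gates(make_objects(intensity_range = 20001), gates)), 0L)
})

test_that("rejection tallies follow the gate order but not the survivors", {
  objs <- rbind(make_objects(diameter = 10, solidity = 0.5),  # fails d first
                make_objects(solidity = 0.5),                  # fails solidity
                make_objects())
  g <- apply_gates(objs, gate_params())
  expect_equal(nrow(g), 1L)
  expect_equal(attr(g, "rejections"),
               c(diameter = 1L, solidity = 1L, axial_ratio = 0L,
                 intensity_range = 0L))
})

test_that("shrinking any single gate never increases the survivor count", {
  set.seed(31)
  objs <- make_objects(diameter = runif(200, 5, 70),
                       solidity = runif(200, 0.3, 1),
                       axial_ratio = runif(200, 1, 3),
                       intensity_range = runif(200, 0, 40000))
  base <- nrow(apply_gates(objs, gate_params()))
  shrunk <- list(
    gate_params(diameter = c(15, 50)),
    gate_params(solidity = c(0.8, 1)),
    gate_params(axial_ratio = c(1, 1.5)),
    gate_params(intensity_range = c(0, 10000)))
  for (g in shrunk)
    expect_lte(nrow(apply_gates(objs, g)), base)
})

test_that("one cell with six appearances collapses to one track", {
  objs <- make_objects(frame_index = 1:6, centroid_row = 50,
                       centroid_col = seq(30, 330, by = 60))
  tr <- link_tracks(objs, max_displacement = 94)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$n_appearances, 6L)
  expect_equal(nrow(objs), 6L)  # raw gated detections stay sixfold
})

test_that("well-separated co-visible cells form distinct tracks", {
  a <- make_objects(frame_index = 1:6, centroid_row = 40,
                    centroid_col = seq(30, 330, by = 60))
  b <- make_objects(frame_index = 1:6, centroid_row = 200,
                    centroid_col = seq(35, 335, by = 60))
  tr <- link_tracks(rbind(a, b), max_displacement = 70)
  expect_equal(nrow(tr), 2L)
  expect_equal(sort(tr$n_appearances), c(6L, 6L))
})

test_that("track counts are exact and order-invariant on separated scenes", {
  set.seed(13)
  max_disp <- 40
  for (rep in 1:8) {
    k <- sample(2:4, 1)
    rows <- seq(30, by = 3 * max_disp, length.out = k)
    objs <- do.call(rbind, lapply(seq_len(k), function(i)
      make_objects(frame_index = 1:5, centroid_row = rows[i] + runif(1, -2, 2),
                   centroid_col = seq(20, 140, by = 30) + runif(1, -2, 2))))
    tr <- link_tracks(objs, max_displacement = max_disp)
    expect_equal(nrow(tr), k)
    expect_equal(tr$n_appearances, rep(5L, k))
    # each track's members share one row band (no identity switches)
    for (m in tr$members)
      expect_lt(diff(range(objs$centroid_row[m])), max_disp)
    # permuting detections within frames leaves the track count unchanged
    perm <- objs[sample(nrow(objs)), ]
    expect_equal(nrow(link_tracks(perm, max_displacement = max_disp)), k)
  }
})

test_that("frame gaps beyond max_frame_gap split tracks", {
  objs <- make_objects(frame_index = c(1:3, 6:8), centroid_row = 50,
                       centroid_col = c(30, 60, 90, 180, 210, 240))
  expect_equal(nrow(link_tracks(objs, max_displacement = 200,
                                max_frame_gap = 1L)), 2L)
  expect_equal(nrow(link_tracks(objs, max_displacement = 200,
                                max_frame_gap = 3L)), 1L)
})

test_that("sample counts convert tracks to rates per mL", {
  objs <- make_objects(frame_index = 1:6, centroid_col = seq(30, 330, 60))
  tr <- link_tracks(rbind(objs), max_displacement = 94)
  tr10 <- do.call(rbind, replicate(10, tr, simplify = FALSE))
  sc <- count_sample(tr10, blood_volume = 5)
  expect_equal(sc$n_unique_cells, 10L)
  expect_equal(sc$rate, 2.0)
  empty <- tr[0, ]
  expect_equal(count_sample(empty, 5)$rate, 0)
  expect_error(count_sample(tr, 0), "positive")
  # persistence filter drops singleton tracks
  single <- make_objects(frame_index = 9L, centroid_row = 200)
  tr2 <- link_tracks(rbind(objs, single), max_displacement = 94)
  expect_equal(count_sample(tr2, 1)$n_unique_cells, 2L)
  expect_equal(count_sample(tr2, 1, min_appearances = 2L)$n_unique_cells, 1L)
  # division fallback agrees on the nominal multiplicity
  expect_equal(count_by_division(objs, 6), 1L)
})
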
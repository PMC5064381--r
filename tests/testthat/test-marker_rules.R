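test_that("every marker-flag combination maps to exactly one class", {
  # (dapi, ck, cd45) -> class, with nucleus info supplied for DAPI-only cells
  grid <- expand.grid(dapi = c(TRUE, FALSE), ck = c(TRUE, FALSE),
                      cd45 = c(TRUE, FALSE))
  expected <- function(dapi, ck, cd45) {
    if (cd45) "WBC" else if (ck) "CTC"
    else if (dapi) "CTC"   # large nucleus, large N:C supplied below
    else "DEBRIS"
  }
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    got <- classify_marker_cell(g$dapi, g$ck, g$cd45,
                                nucleus_diameter = 12, nc_ratio = 0.8)
    expect_equal(got, expected(g$dapi, g$ck, g$cd45),
                 info = paste(g$dapi, g$ck, g$cd45))
  }
})

test_that("DAPI-only cells split on the 9 um nucleus rule and N:C ratio", {
  # small nucleus -> WBC; large nucleus with large N:C -> CTC
  expect_equal(classify_marker_cell(TRUE, FALSE, FALSE,
                                    nucleus_diameter = 8, nc_ratio = 0.8), "WBC")
  expect_equal(classify_marker_cell(TRUE, FALSE, FALSE,
                                    nucleus_diameter = 11, nc_ratio = 0.8), "CTC")
  expect_equal(classify_marker_cell(TRUE, FALSE, FALSE,
                                    nucleus_diameter = 9, nc_ratio = 0.8), "WBC")
  expect_equal(classify_marker_cell(TRUE, FALSE, FALSE,
                                    nucleus_diameter = 11, nc_ratio = 0.2), "WBC")
  # lobular/segmented granulocytic nucleus is a WBC regardless of size
  expect_equal(classify_marker_cell(TRUE, FALSE, FALSE, nucleus_diameter = 14,
                                    nc_ratio = 0.9, lobular_nucleus = TRUE),
               "WBC")
  # debris morphology has top precedence
  expect_equal(classify_marker_cell(TRUE, TRUE, FALSE,
                                    debris_morphology = TRUE), "DEBRIS")
  expect_error(classify_marker_cell(TRUE, FALSE, FALSE), "unclassifiable")
})

test_that("doubly stained CK+/CD45+ cells are WBCs (activated granulocytes)", {
  expect_equal(classify_marker_cell(TRUE, TRUE, TRUE), "WBC")
  expect_equal(classify_marker_cell(TRUE, TRUE, FALSE), "CTC")
})

test_that("FISH patterns reproduce the signal-enumeration guide", {
  fd <- 5
  two_fused <- list(red = rbind(c(0, 0), c(50, 50)),
                    green = rbind(c(1, 0), c(51, 50)))
  r <- classify_fish_cell(two_fused$red, two_fused$green, fd)
  expect_equal(r$call, "NEGATIVE"); expect_equal(r$n_fused, 2L)
  three_fused <- classify_fish_cell(rbind(c(0, 0), c(50, 50), c(0, 60)),
                                    rbind(c(1, 0), c(51, 50), c(1, 60)), fd)
  expect_equal(three_fused$call, "NEGATIVE_POLYSOMY")
  # one fused pair plus one split red-green pair: rearranged
  split <- classify_fish_cell(rbind(c(0, 0), c(100, 100)),
                              rbind(c(1, 0), c(200, 0)), fd)
  expect_equal(split$call, "POSITIVE")
  expect_equal(split$n_fused, 1L); expect_equal(split$n_split, 1L)
  # single lone spot is unresolvable
  expect_equal(classify_fish_cell(rbind(c(0, 0)), matrix(numeric(0), 0, 2),
                                  fd)$call, "UNINTERPRETABLE")
  expect_equal(classify_fish_cell(two_fused$red, two_fused$green, fd,
                                  interpretable = FALSE)$call,
               "UNINTERPRETABLE")
  expect_error(classify_fish_cell(two_fused$red, two_fused$green, -1),
               "non-negative")
})

test_that("greedy pairing agrees with the brute-force matching oracle", {
  set.seed(77)
  for (i in 1:60) {
    nr <- sample(0:4, 1); ng <- sample(0:4, 1)
    if (nr + ng < 2) next
    red <- matrix(runif(2 * nr, 0, 60), ncol = 2)
    green <- matrix(runif(2 * ng, 0, 60), ncol = 2)
    fd <- runif(1, 3, 25)
    got <- classify_fish_cell(red, green, fd)
    want <- oracle_fish(red, green, fd)
    expect_equal(got$call, want$call, info = paste("case", i))
    expect_equal(got$n_fused, want$n_fused, info = paste("case", i))
    expect_equal(got$n_split, want$n_split, info = paste("case", i))
  }
})

test_that("FISH calls are invariant to rigid motions and monotone in fusions", {
  set.seed(5)
  red <- matrix(runif(6, 0, 40), ncol = 2)
  green <- matrix(runif(8, 0, 40), ncol = 2)
  base <- classify_fish_cell(red, green, 6)
  th <- 0.7; rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(13.5, -4.2)
  moved <- function(m) sweep(m %*% rot, 2, shift, "+")
  got <- classify_fish_cell(moved(red), moved(green), 6)
  expect_equal(got, base)
  # adding a fused pair far away never clears a positive call
  pos <- classify_fish_cell(rbind(c(0, 0), c(100, 0)),
                            rbind(c(1, 0), c(200, 0)), 5)
  expect_equal(pos$call, "POSITIVE")
  more <- classify_fish_cell(rbind(c(0, 0), c(100, 0), c(400, 400)),
                             rbind(c(1, 0), c(200, 0), c(401, 400)), 5)
  expect_true(more$call %in% c("POSITIVE", "POSITIVE_POLYSOMY"))
})

test_that("sample-level ALK calls use the 15% cutoff inclusively", {
  calls <- rep(c("POSITIVE", "NEGATIVE"), c(0, 50))
  expect_false(call_sample_fish(calls)$positive)
  calls10 <- rep(c("POSITIVE", "NEGATIVE"), c(10, 40))
  s <- call_sample_fish(calls10)
  expect_equal(s$fraction, 20); expect_true(s$positive)
  # exactly 15.0% is positive; uninterpretable cells leave the denominator
  calls15 <- rep(c("POSITIVE", "NEGATIVE", "UNINTERPRETABLE"), c(3, 17, 5))
  s15 <- call_sample_fish(calls15)
  expect_equal(s15$fraction, 15); expect_true(s15$positive)
  below <- call_sample_fish(rep(c("POSITIVE", "NEGATIVE"), c(14, 86)))
  expect_false(below$positive)
  expect_error(call_sample_fish(rep("UNINTERPRETABLE", 3)), "interpretable")
})

test_that("spot tables classify per cell and per sample", {
  spots <- rbind(
    data.frame(cell_id = "c1", channel = "red", x = c(0, 50), y = c(0, 0)),
    data.frame(cell_id = "c1", channel = "green", x = c(1, 51), y = c(0, 0)),
    data.frame(cell_id = "c2", channel = "red", x = c(0, 100), y = c(0, 0)),
    data.frame(cell_id = "c2", channel = "green", x = c(1, 300), y = c(0, 0)))
  res <- classify_fish_table(spots, fusion_distance = 5)
  expect_equal(res$cells$call[res$cells$cell_id == "c1"], "NEGATIVE")
  expect_equal(res$cells$call[res$cells$cell_id == "c2"], "POSITIVE")
  expect_equal(res$sample$fraction, 50)
  expect_true(res$sample$positive)
  expect_error(classify_fish_table(spots[0, ], 5), "empty")
})
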
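test_that("default paradigm has the published block structure", {
  d <- default_block_design()
  expect_equal(nrow(d$blocks), 16)
  expect_true(all(table(d$blocks$condition) == 4))
  expect_true(all(d$blocks$duration == 16))
  gaps <- d$blocks$onset[-1] - (d$blocks$onset[-16] + 16)
  expect_true(all(gaps %in% c(8, 10, 12)))
  expect_equal(d$n_acquired_volumes * d$tr_s, 436)
  expect_lte(max(d$blocks$onset + d$blocks$duration), 436)
  expect_equal(n_analyzed_volumes(d), 208)
})

test_that("design validation rejects malformed block tables", {
  d <- default_block_design()
  shuffled <- d$blocks[16:1, ]
  expect_error(block_design(shuffled), "time-ordered")
  overlapping <- data.frame(onset = c(0, 10), duration = 16,
                            condition = "physical_pain")
  expect_error(block_design(overlapping), "overlap")
  late <- data.frame(onset = 430, duration = 16, condition = "a")
  expect_error(block_design(late), "after the acquired run")
})

test_that("boxcar regressor marks selected blocks and nothing else", {
  d <- default_block_design()
  expect_error(boxcar_regressor(d, "no_such_condition"), "no_such_condition")
  empty <- boxcar_regressor(d, character(0))
  expect_true(all(empty == 0))
  box <- boxcar_regressor(d, "physical_pain")
  expect_true(all(box %in% c(0, 1)))
  # 4 blocks x 16 s of selected condition
  expect_equal(sum(box) * d$tr_s / 10, 64)
})

test_that("HRF kernels are unit-sum with the expected lobes", {
  g <- hrf_kernel("gamma_no_undershoot", dt_s = 0.2)
  dg <- hrf_kernel("double_gamma", dt_s = 0.2)
  expect_equal(sum(g), 1)
  expect_equal(sum(dg), 1)
  expect_gte(min(g), 0)
  expect_lt(min(dg), 0)
  # undershoot follows the positive peak
  expect_gt(which.min(dg), which.max(dg))
  expect_error(hrf_kernel("gamma_no_undershoot", lag_s = -1), "positive")
  # unit-sum kernel preserves a constant series away from the edges
  x <- rep(1, 400)
  y <- stats::convolve(x, rev(g), type = "open")[seq_along(x)]
  expect_equal(y[200:400], rep(1, 201), tolerance = 1e-10)
})

test_that("convolved references align with the analyzed volume grid", {
  d <- default_block_design()
  ref <- convolved_reference(d, "physical_pain")
  expect_length(ref, 208)
  expect_gte(min(ref), -1e-12)   # gamma kernel keeps references nonnegative
  expect_true(all(convolved_reference(d, character(0)) == 0))
  # additivity over disjoint condition sets
  r1 <- convolved_reference(d, "physical_pain")
  r2 <- convolved_reference(d, "affective_pain")
  r12 <- convolved_reference(d, c("physical_pain", "affective_pain"))
  expect_equal(as.numeric(r12), as.numeric(r1 + r2), tolerance = 1e-12)
})

test_that("shifting all onsets by whole TRs shifts reference samples", {
  d <- default_block_design()
  b2 <- d$blocks
  b2$onset <- b2$onset + 2 * d$tr_s
  d2 <- block_design(b2, d$condition_labels, d$tr_s,
                     d$n_acquired_volumes, d$n_trim_volumes)
  r1 <- as.numeric(convolved_reference(d, "physical_pain"))
  r2 <- as.numeric(convolved_reference(d2, "physical_pain"))
  interior <- 10:200
  expect_equal(r2[interior], r1[interior - 2], tolerance = 1e-12)
})

test_that("reference peaks fall inside block-plus-lag windows", {
  d <- default_block_design()
  for (cond in d$condition_labels) {
    ref <- as.numeric(convolved_reference(d, cond))
    tmax <- (which.max(ref) - 1 + d$n_trim_volumes) * d$tr_s
    bl <- d$blocks[d$blocks$condition == cond, ]
    inside <- any(tmax >= bl$onset & tmax <= bl$onset + bl$duration + 12)
    expect_true(inside)
  }
})

test_that("events tables round-trip through write/read", {
  d <- default_block_design()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_events(d, f)
  d2 <- read_events(f)
  expect_equal(d2$blocks$onset, d$blocks$onset)
  expect_equal(d2$blocks$condition, d$blocks$condition)
  expect_equal(n_analyzed_volumes(d2), 208)
  # header is the BIDS events dialect
  expect_equal(names(utils::read.delim(f)),
               c("onset", "duration", "trial_type"))
})

test_that("seeded reshuffled designs preserve counts and are reproducible", {
  da <- default_block_design(seed = 5)
  db <- default_block_design(seed = 5)
  expect_identical(da$blocks, db$blocks)
  expect_true(all(table(da$blocks$condition) == 4))
  gaps <- da$blocks$onset[-1] - (da$blocks$onset[-16] + 16)
  expect_equal(unname(table(factor(gaps, levels = c(8, 10, 12)))),
               c(5L, 5L, 5L), ignore_attr = TRUE)
})
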
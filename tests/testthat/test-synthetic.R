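test_that("simulation is deterministic given the seed", {
  fx <- tiny_group(n_subjects = 3, seed = 31)
  fx2 <- tiny_group(n_subjects = 3, seed = 31)
  expect_identical(fx$group$subjects, fx2$group$subjects)
  fx3 <- tiny_group(n_subjects = 3, seed = 32)
  expect_false(identical(fx$group$subjects[[1]], fx3$group$subjects[[1]]))
  expect_equal(length(fx$group$subjects), 3)
  # direct per-subject call matches the group product
  direct <- simulate_subject(fx$spec, fx$design, 2)
  expect_identical(direct, fx$group$subjects[[2]])
})

test_that("spec validation guards grids, amplitudes and group size", {
  expect_error(synthetic_spec(grid_dims = c(4, 4, 2),
                              networks = list(list(mask = 100,
                                                   conditions = "a",
                                                   amplitude = 1))),
               "does not fit")
  expect_error(synthetic_spec(ar1_coef = 1), "ar1_coef")
  spec1 <- synthetic_spec(grid_dims = c(8, 8, 2), n_subjects = 1,
                          networks = tiny_networks())
  expect_error(simulate_group(spec1, default_block_design()), "2 subjects")
})

test_that("stochastic terms off makes subjects bit-identical", {
  spec <- synthetic_spec(grid_dims = c(8, 8, 2), n_subjects = 3,
                         networks = tiny_networks(), noise_sd = 0,
                         latency_jitter_sd_s = 0, amplitude_jitter_sd = 0,
                         seed = 33)
  g <- simulate_group(spec, default_block_design())
  expect_identical(g$subjects[[1]], g$subjects[[2]])
  expect_identical(g$subjects[[2]], g$subjects[[3]])
})

test_that("zero-amplitude networks leave pure noise everywhere", {
  nets0 <- tiny_networks()
  nets0 <- lapply(nets0, function(nw) { nw$amplitude <- 0; nw })
  spec0 <- synthetic_spec(grid_dims = c(8, 8, 2), n_subjects = 2,
                          networks = nets0, seed = 34)
  spec_none <- synthetic_spec(grid_dims = c(8, 8, 2), n_subjects = 2,
                              networks = list(), seed = 34)
  d <- default_block_design()
  expect_identical(simulate_subject(spec0, d, 1),
                   simulate_subject(spec_none, d, 1))
})

test_that("AR(1) coefficient controls the noise autocorrelation", {
  d <- default_block_design()
  spec0 <- synthetic_spec(grid_dims = c(8, 8, 2), networks = list(),
                          n_subjects = 2, ar1_coef = 0, seed = 35)
  m0 <- matrix(simulate_subject(spec0, d, 1), 128, 218)
  ac0 <- apply(m0[1:60, ], 1, function(r) cor(r[-1], r[-length(r)]))
  expect_lt(abs(mean(ac0)), 0.03)         # ~3 null sd for 60 voxels
  expect_lt(max(abs(ac0)), 0.25)
  spec5 <- synthetic_spec(grid_dims = c(8, 8, 2), networks = list(),
                          n_subjects = 2, ar1_coef = 0.5, seed = 35)
  m5 <- matrix(simulate_subject(spec5, d, 1), 128, 218)
  ac5 <- apply(m5[1:60, ], 1, function(r) cor(r[-1], r[-length(r)]))
  expect_gt(mean(ac5), 0.4)
})

test_that("noiseless planted signal reproduces its condition reference", {
  fx <- tiny_group(n_subjects = 3, seed = 36, noise_sd = 0)
  m <- matrix(fx$group$subjects[[1]], 128, 218)
  inm <- as.vector(network_mask(fx$group$truth, 1))
  series <- colMeans(m[inm, ])[-(1:10)]
  ref <- as.numeric(convolved_reference(fx$design, "physical_pain"))
  expect_gt(cor(series, ref), 0.99)
})

test_that("latency jitter scales realized per-subject shifts coherently", {
  mk <- function(sd) synthetic_spec(grid_dims = c(8, 8, 2), n_subjects = 6,
                                    networks = tiny_networks(),
                                    latency_jitter_sd_s = sd, seed = 37)
  g0 <- simulate_group(mk(0), default_block_design())
  g4 <- simulate_group(mk(4), default_block_design())
  expect_true(all(g0$truth$latency_s == 0))
  g1 <- simulate_group(mk(1), default_block_design())
  # same standardized draws, scaled: coupling across jitter levels
  expect_equal(g4$truth$latency_s, 4 * g1$truth$latency_s, tolerance = 1e-12)
})

test_that("datasets round-trip through NIfTI, events and truth files", {
  fx <- tiny_group(n_subjects = 2, seed = 38)
  dir <- file.path(tempdir(), "isps-synth-test")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  write_synthetic_dataset(fx$group, fx$design, dir)
  expect_true(file.exists(file.path(dir, "sub-01_bold.nii")))
  expect_true(file.exists(file.path(dir, "events.tsv")))
  tr <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  expect_equal(tr$seed, 38)
  # run-length encoding reconstructs the first planted mask
  rle1 <- tr$networks$mask_rle
  idx <- unlist(mapply(function(s, l) s + 0:(l - 1),
                       rle1$starts[[1]], rle1$lengths[[1]]))
  expect_setequal(idx, fx$group$truth$networks[[1]]$mask)
  grp <- load_group(dir, file.path(dir, "mask.nii"))
  expect_equal(length(grp$data), 2)
  expect_equal(dim(grp$data[[1]]), c(128, 218))
  expect_equal(grp$data[[1]][, 1],
               as.vector(fx$group$subjects[[1]][, , , 1]))
})
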
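test_that("ICA separates two planted spatial sources", {
  set.seed(41)
  v <- 500; nt <- 100
  s1 <- numeric(v); s1[1:40] <- 1
  s2 <- numeric(v); s2[61:120] <- 1
  m <- 2 * (s1 %o% rnorm(nt)) + 2 * (s2 %o% rnorm(nt)) +
    matrix(rnorm(v * nt, sd = 0.05), v, nt)
  ic <- sync_ica(m, order = 2, seed = 1)
  truth <- rbind(s1, s2)
  mm <- match_components(truth, ic$spatial_maps)
  expect_true(all(mm$abs_r > 0.95))
  expect_true(ic$converged)
  # deterministic given the seed
  ic2 <- sync_ica(m, order = 2, seed = 1)
  expect_identical(ic$spatial_maps, ic2$spatial_maps)
  # maps are z-scored with nonnegative skewness
  expect_lt(max(abs(rowMeans(ic$spatial_maps))), 1e-8)
  expect_equal(apply(ic$spatial_maps, 1, sd), c(1, 1), tolerance = 1e-8)
  expect_true(all(apply(ic$spatial_maps, 1,
                        function(s) mean((s - mean(s))^3)) >= 0))
})

test_that("requested order beyond the rank is reduced with a warning", {
  set.seed(42)
  a <- matrix(rnorm(300 * 3), 300, 3)
  b <- matrix(rnorm(3 * 50), 3, 50)
  low_rank <- a %*% b
  expect_warning(ic <- sync_ica(low_rank, order = 6, seed = 1),
                 "rank")
  expect_lte(ic$order, 3)
  expect_error(sync_ica(matrix(rnorm(40), 10, 4), order = 4), "smaller")
})

test_that("reconstruction from mixing and sources retains the PCA variance", {
  set.seed(43)
  v <- 400; nt <- 80
  m <- (numeric(v) + c(rep(1, 50), rep(0, v - 50))) %o% rnorm(nt) +
    matrix(rnorm(v * nt, sd = 0.4), v, nt)
  ic <- suppressWarnings(sync_ica(m, order = 3, seed = 2))
  d <- t(m) - rowMeans(t(m))
  # the mixing columns span the retained PCA subspace, so projecting the
  # centered data onto them recovers at least the PCA-retained variance
  proj <- ic$time_courses %*% qr.solve(ic$time_courses, d)
  expect_gte(sum(proj^2) / sum(d^2) + 1e-10, ic$explained_variance)
})

test_that("thresholding behaves as a strict z cut", {
  map <- c(-3, 0, 2.0, 2.31, 5)
  expect_equal(which(threshold_spatial_map(map, 2.3)), c(4L, 5L))
  expect_false(any(threshold_spatial_map(rep(2.0, 10), 2.3)))
  expect_true(all(threshold_spatial_map(map, -Inf)))
  # standard normal map: suprathreshold count near n * P(Z > 2.3)
  set.seed(44)
  z <- rnorm(10000)
  cnt <- sum(threshold_spatial_map(z, 2.3))
  expected <- 10000 * pnorm(2.3, lower.tail = FALSE)
  expect_lt(abs(cnt - expected), 3 * sqrt(expected))
})

test_that("component matching recovers a known permutation", {
  set.seed(45)
  maps <- matrix(rnorm(4 * 200), 4, 200)
  perm <- c(3, 1, 4, 2)
  noisy <- maps[perm, ] + matrix(rnorm(4 * 200, sd = 0.1), 4, 200)
  mm <- match_components(maps, noisy)
  expect_equal(order(perm), mm$b)
  expect_true(all(mm$abs_r > 0.9))
})

test_that("association statistics ignore component order and sign", {
  set.seed(46)
  d <- default_block_design()
  refs <- reference_set(d)
  tc <- matrix(rnorm(208 * 3), 208, 3)
  a1 <- component_condition_correlations(tc, refs)
  flipped <- tc[, c(2, 1, 3)]
  flipped[, 1] <- -flipped[, 1]
  a2 <- component_condition_correlations(flipped, refs)
  r1 <- a1[a1$component == 2, "r"]
  r2 <- a2[a2$component == 1, "r"]
  expect_equal(abs(r1), abs(r2), tolerance = 1e-12)
  expect_equal(a1[a1$component == 2, "p_raw"], a2[a2$component == 1, "p_raw"],
               tolerance = 1e-12)
})

test_that("artifact flagging follows the majority-territory rule", {
  maps <- rbind(c(rep(5, 10), rep(0, 90)),
                c(rep(0, 90), rep(5, 10)),
                c(rep(5, 4), rep(0, 90), rep(5, 6)),
                rep(0, 100))
  ic <- structure(list(spatial_maps = maps, order = 4), class = "ica_result")
  masks <- list(gray = c(rep(TRUE, 50), rep(FALSE, 50)),
                csf = c(rep(FALSE, 90), rep(TRUE, 10)))
  lab <- flag_artifact_components(ic, masks)
  expect_equal(lab$status, c("retained", "unclassified", "unclassified",
                             "unclassified"))
  expect_equal(lab$reason[4], "empty")
  expect_match(lab$reason[3], "60%")
})

test_that("split-half replicability separates duplicated from independent data", {
  set.seed(47)
  prepped <- lapply(1:4, function(i)
    prepare_series(matrix(rnorm(60 * 218), 60, 218)))
  dup <- c(prepped, prepped)
  r_dup <- suppressWarnings(split_half_replicability(
    dup, orders = 4, splits = list(1:4), seed = 3))
  expect_gt(r_dup$mean_scores, 0.99)
  r_ind <- suppressWarnings(split_half_replicability(
    prepped, orders = 4, n_splits = 2, seed = 3))
  expect_lt(r_ind$mean_scores, 0.6)
  expect_error(split_half_replicability(prepped[1:3]), "4 subjects")
})
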
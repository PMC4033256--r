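test_that("noise-floor separation arithmetic and critical values are exact", {
  expect_equal(noise_floor_separation(2.18, 0.22, 0.77), 1.96 / 0.77)
  expect_equal(noise_floor_separation(2.18, 0.08, 1.10), 2.10 / 1.10)
  expect_error(noise_floor_separation(2.18, 0, 0), "positive")
  expect_equal(critical_t(12), qt(0.975, 12))
  expect_equal(critical_t(13), qt(0.975, 13))
})

test_that("split-half noise floor has the right df and null behavior", {
  withr::with_seed(20, {
    X <- matrix(rnorm(14 * 500), 14, 500)
  })
  coh <- make_toy_cohort(list(background = X), c(10, 10, 5))
  nf <- split_half_noise_floor(coh, "background", seed = 1, criterion_df = 12)
  expect_equal(nf$df, 12)             # 7 + 7 - 2
  expect_equal(nf$criterion_t, qt(0.975, 12))
  expect_equal(nf$above_noise_cut, nf$mean_t + 2 * nf$sd_t)
  # i.i.d. noise: mean t near 0, sd near that of a t(12) variate
  expect_lt(abs(nf$mean_t), 0.2)
  expect_equal(nf$sd_t, sqrt(12 / 10), tolerance = 0.15)
  # deterministic given the seed
  nf2 <- split_half_noise_floor(coh, "background", seed = 1, criterion_df = 12)
  expect_equal(nf$mean_t, nf2$mean_t)

  odd <- make_toy_cohort(list(background = X[1:13, ]), c(10, 10, 5))
  expect_error(split_half_noise_floor(odd, "background", seed = 1),
               "even")
})

test_that("hemisphere-flip noise floor alternates direction and masks symmetry", {
  # perfectly symmetric volumes: all differences zero, t undefined
  withr::with_seed(22, half <- matrix(rnorm(4 * 30), 4, 30))
  sym <- t(apply(half, 1, function(r) {
    v <- array(0, c(6, 5, 2))
    v[1:3, , ] <- r
    v[4:6, , ] <- mirror_volume(v)[4:6, , ]
    as.numeric(v)
  }))
  coh_sym <- make_toy_cohort(list(background = sym), c(6, 5, 2))
  expect_error(hemisphere_flip_noise_floor(coh_sym, "background"),
               "no defined t-values")

  # asymmetric phantom: the alternating-direction floor cancels the shared
  # asymmetry (it is a noise estimate), while the uniform left-minus-right
  # variant flags the lateralized VOI above the cut
  atlas <- default_phantom_atlas(c(16, 16, 8))
  voi <- atlas_mask(atlas, "left_ic")
  withr::with_seed(23, {
    vols <- lapply(1:14, function(i) {
      v <- array(100 * (1 + rnorm(16 * 16 * 8, 0, 0.05)), c(16, 16, 8))
      v[voi] <- v[voi] * 1.2
      v
    })
  })
  X <- t(vapply(vols, as.numeric, numeric(16 * 16 * 8)))
  coh <- make_toy_cohort(list(background = X), c(16, 16, 8))

  nf <- hemisphere_flip_noise_floor(coh, "background", criterion_df = 12)
  expect_equal(nf$df, 13)
  expect_equal(nf$n_voxels, prod(c(8, 16, 8)))  # left hemisphere only
  expect_lt(abs(mean(nf$t_values[voi])), 2)     # asymmetry cancelled

  nf_uni <- hemisphere_flip_noise_floor(coh, "background", criterion_df = 12,
                                        alternate = FALSE)
  expect_gt(mean(nf_uni$t_values[voi] > nf$above_noise_cut), 0.9)
})

test_that("threshold_and_mask combines alpha cut and noise floor", {
  p <- array(0.5, c(4, 4, 2))
  vals <- array(1, c(4, 4, 2))
  map <- structure(list(stat_kind = "t", values = vals, p = p, df = 13,
                        n = 14, grid_shape = c(4, 4, 2)), class = "stat_map")
  expect_false(any(threshold_and_mask(map)))

  map$p[1:5] <- 0.01
  map$values[1:3] <- 3                # above cut
  map$values[4:5] <- -3               # mirrored cut, negative effects
  floor <- structure(list(mean_t = 0.2, sd_t = 1.1), class = "noise_floor")
  msk <- threshold_and_mask(map, 0.05, floor)
  expect_equal(which(msk), 1:5)       # 3 >= 2.4 and -3 <= -2.0

  floor$sd_t <- 1.5                   # cut 3.2: positives no longer pass
  msk2 <- threshold_and_mask(map, 0.05, floor)
  expect_equal(which(msk2), 4:5)

  # degenerate floor reduces to the p-threshold
  floor0 <- structure(list(mean_t = 0, sd_t = 0), class = "noise_floor")
  expect_equal(threshold_and_mask(map, 0.05, floor0),
               threshold_and_mask(map, 0.05))
  expect_error(threshold_and_mask(map, alpha = 1.5), "alpha")
})

test_that("VOI direction check reports contralateral sign agreement", {
  atlas <- default_phantom_atlas(c(16, 16, 8))
  nvox <- prod(c(16, 16, 8))
  left <- atlas_mask(atlas, "left_ic"); right <- atlas_mask(atlas, "right_ic")
  base <- numeric(nvox)
  base[left] <- 2; base[right] <- 0.4        # same direction bilaterally
  base[atlas_mask(atlas, "left_sc")] <- -1   # left-only decrease, contra 0
  D <- rbind(base, base, base)
  mask <- array(FALSE, c(16, 16, 8)); mask[left] <- TRUE
  mask[atlas_mask(atlas, "left_sc")] <- TRUE
  tab <- voi_direction_check(D, atlas, mask)
  expect_setequal(tab$voi, c("left_ic", "left_sc"))
  expect_true(tab$same_direction[tab$voi == "left_ic"])
  expect_false(tab$same_direction[tab$voi == "left_sc"])  # zero = disagreement
  # means match brute-force per-voxel averaging
  expect_equal(tab$mean_voi[tab$voi == "left_ic"],
               mean(colMeans(D)[as.logical(left)]))
  expect_equal(tab$mean_contralateral[tab$voi == "left_ic"],
               mean(colMeans(D)[as.logical(right)]))
  expect_error(voi_direction_check(D, atlas, array(FALSE, c(16, 16, 8))),
               "empty")
})

test_that("whole-VOI detections summarize mask coverage", {
  atlas <- default_phantom_atlas(c(16, 16, 8))
  mask <- atlas_mask(atlas, "left_pnc")
  det <- voi_detections(mask, atlas)
  expect_equal(det$voi[det$detected], "left_pnc")
  expect_equal(det$fraction[det$voi == "left_pnc"], 1)
  expect_equal(sum(det$detected), 1)
  expect_false("olfactory_bulb" %in% det$voi)
})
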
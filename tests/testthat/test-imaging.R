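test_that("reference normalization is exact, scale-invariant and idempotent", {
  atlas <- default_phantom_atlas(c(12, 12, 6))
  vol <- array(7, dim = c(12, 12, 6))
  expect_equal(reference_region_normalize(vol, atlas),
               array(1, dim = c(12, 12, 6)))

  withr::with_seed(4, v <- array(rexp(12 * 12 * 6) + 0.5, c(12, 12, 6)))
  n1 <- reference_region_normalize(v, atlas)
  expect_equal(reference_region_normalize(2 * v, atlas), n1)
  expect_equal(reference_region_normalize(n1, atlas), n1)
  ref <- atlas_mask(atlas, "olfactory_bulb")
  expect_equal(mean(n1[ref]), 1)

  expect_error(reference_region_normalize(array(0, c(12, 12, 6)), atlas),
               "positive")
})

test_that("normalization removes global scales from phantom cohorts", {
  atlas <- default_phantom_atlas(c(12, 12, 6))
  eff <- effect_table("left_ic", "ppi", 0.15)
  coh <- simulate_pet_cohort(atlas, eff, n_subjects = 4, noise_sd = 0,
                             global_scale_sd = 0.3, seed = 12)
  nrm <- reference_region_normalize(coh)
  m <- atlas_mask(atlas, "left_ic")
  for (s in nrm$subjects) {
    expect_equal(mean(nrm$volumes$ppi[[s]][m]) /
                   mean(nrm$volumes$background[[s]][m]), 1.15,
                 tolerance = 1e-12)
    expect_equal(mean(nrm$volumes$background[[s]][!m]), 1, tolerance = 1e-12)
  }
})

test_that("paired t-map matches the closed-form oracle and conventions", {
  # single-voxel toy: differences {1, 2, 3, 4}
  a <- matrix(c(11, 12, 13, 14), ncol = 1)
  b <- matrix(c(10, 10, 10, 10), ncol = 1)
  coh <- make_toy_cohort(list(ppi = a, background = b), c(1, 1, 1))
  tm <- paired_t_map(coh, "ppi", "background")
  expect_equal(as.numeric(tm$values), oracle_paired_t(c(1, 2, 3, 4)),
               tolerance = 1e-10)
  tt <- t.test(a[, 1], b[, 1], paired = TRUE)
  expect_equal(as.numeric(tm$values), unname(tt$statistic), tolerance = 1e-10)
  expect_equal(as.numeric(tm$p), tt$p.value, tolerance = 1e-10)
  expect_equal(tm$df, 3)

  # identical conditions: t = 0; swapped order negates t
  withr::with_seed(8, {
    X <- matrix(rnorm(14 * 50), 14, 50)
    Y <- matrix(rnorm(14 * 50), 14, 50)
  })
  coh2 <- make_toy_cohort(list(ppi = X, background = Y), c(5, 5, 2))
  t_ab <- paired_t_map(coh2, "ppi", "background")
  t_ba <- paired_t_map(coh2, "background", "ppi")
  expect_equal(t_ab$values, -t_ba$values, tolerance = 1e-12)
  expect_equal(t_ab$df, 13)
  same <- paired_t_map(make_toy_cohort(list(a = X, b = X), c(5, 5, 2)), "a", "b")
  expect_true(all(is.na(same$values)))  # zero variance -> masked
})

test_that("RM-ANOVA and Tukey q match the sums-of-squares oracle", {
  Y <- cbind(c(1, 2, 3), c(2, 4, 3), c(3, 6, 6))
  coh <- make_toy_cohort(list(ppi = Y[, 1, drop = FALSE],
                              startle_control = Y[, 2, drop = FALSE],
                              background = Y[, 3, drop = FALSE]),
                         c(1, 1, 1))
  maps <- rm_anova_tukey_maps(coh)
  oracle <- oracle_rm_anova(Y)
  expect_equal(as.numeric(maps$f_map$values), oracle$F, tolerance = 1e-10)
  expect_equal(maps$f_map$df, c(2, 4))
  expect_equal(as.numeric(maps$q_maps$ppi_vs_startle_control$values),
               oracle$q[1, 2], tolerance = 1e-10)
  expect_equal(as.numeric(maps$q_maps$ppi_vs_background$values),
               oracle$q[1, 3], tolerance = 1e-10)
  expect_equal(as.numeric(maps$q_maps$startle_control_vs_background$values),
               oracle$q[2, 3], tolerance = 1e-10)
  # q p-values follow the studentized range with (k, error df)
  q <- oracle$q[1, 3]
  expect_equal(as.numeric(maps$q_maps$ppi_vs_background$p),
               ptukey(abs(q), 3, 4, lower.tail = FALSE), tolerance = 1e-12)

  # aov as an independent route for the F statistic
  d <- data.frame(y = as.numeric(Y),
                  subj = factor(rep(1:3, 3)),
                  cond = factor(rep(1:3, each = 3)))
  fit <- summary(aov(y ~ cond + Error(subj), data = d))
  f_aov <- fit[["Error: Within"]][[1]]$`F value`[1]
  expect_equal(as.numeric(maps$f_map$values), f_aov, tolerance = 1e-10)
})

test_that("RM-ANOVA degenerates correctly and squares the paired t at k = 2", {
  withr::with_seed(13, X <- matrix(rnorm(9 * 30), 9, 30))
  # three identical conditions: zero between-condition variance
  coh0 <- make_toy_cohort(list(a = X, b = X, c = X), c(5, 3, 2))
  maps0 <- rm_anova_tukey_maps(coh0)
  expect_true(all(is.na(maps0$f_map$values)))  # 0/0 -> undefined, masked
  expect_equal(maps0$f_map$df, c(2, 16))       # n = 9, k = 3

  withr::with_seed(14, Y <- matrix(rnorm(9 * 30), 9, 30))
  coh <- make_toy_cohort(list(a = X, b = Y), c(5, 3, 2))
  maps <- rm_anova_tukey_maps(coh)
  tmap <- paired_t_map(coh, "a", "b")
  expect_equal(maps$f_map$values, tmap$values^2, tolerance = 1e-10)

  expect_error(rm_anova_tukey_maps(coh, conditions = "a"), "at least 2")
})

test_that("Pearson r-map matches cor.test and flags degenerate input", {
  withr::with_seed(15, {
    D <- matrix(rnorm(10 * 20), 10, 20)
    cov <- rnorm(10)
  })
  D[, 1] <- cov  # perfect correlation at the first voxel
  coh <- make_toy_cohort(list(ppi = D, background = matrix(0, 10, 20)),
                         c(5, 2, 2))
  diff <- condition_difference(coh, "ppi", "background")
  rm_ <- pearson_r_map(diff, cov)
  expect_equal(as.numeric(rm_$values)[1], 1, tolerance = 1e-12)
  for (v in c(2, 7, 13)) {
    ct <- cor.test(D[, v], cov)
    expect_equal(as.numeric(rm_$values)[v], unname(ct$estimate),
                 tolerance = 1e-10)
    expect_equal(as.numeric(rm_$p)[v], ct$p.value, tolerance = 1e-10)
  }
  expect_equal(rm_$df, 8)
  expect_error(pearson_r_map(diff, rep(1, 10)), "constant")
  expect_error(pearson_r_map(diff, cov[1:3]), "length")
})
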
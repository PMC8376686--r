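test_that("regional slope regression recovers exact lines and clips negatives", {
  t_long <- c(0, 1, 2)
  phi <- cbind(0.1 + 0.05 * t_long,       # exact line
               rep(0.3, 3),               # flat
               0.5 - 0.1 * t_long,        # decreasing -> clipped
               0.2 + 0.02 * t_long)
  tr <- atrophy_trajectory("s1", t_long, phi, paste0("R", 1:4))
  se <- fit_slopes(tr)
  expect_equal(se$slopes, c(0.05, 0, 0, 0.02), tolerance = 1e-12)
  expect_equal(se$intercepts[1], 0.1, tolerance = 1e-12)
  expect_identical(se$n_clipped, 1L)

  expect_error(atrophy_trajectory("s", c(0), matrix(1, 1, 2), c("a", "b")),
               "at least 2")
  expect_error(atrophy_trajectory("s", c(0, 0), matrix(1, 2, 2), c("a", "b")),
               "strictly increasing")
  expect_error(atrophy_trajectory("s", c(1, 2), matrix(1, 2, 2), c("a", "b")),
               "start at 0")
})

test_that("onset-time search identifies beta*t and the scalar fit recovers beta", {
  cn <- random_conn(20, sparsity = 0.5, seed = 13)
  L <- build_laplacian(cn)
  x0 <- seed_pattern(cn$labels, "R1")
  beta_true <- 0.12; t_true <- 10
  phi <- ndm_accumulate(L, x0, beta_true, t_true)
  slopes <- predicted_slope(L, beta_true, t_true, phi)

  grid <- tbase_grid(0.25, 60, 0.05)
  est <- estimate_tbase(phi, slopes, L, beta0 = 0.05, grid = grid)
  expect_lt(abs(0.05 * est$tbase_hat - beta_true * t_true), 0.05 * 0.05 + 1e-12)
  expect_gt(est$peak_correlation, 0.999)

  bh <- estimate_beta(phi, slopes, L, beta0 = 0.05, tbase_hat = est$tbase_hat)
  expect_equal(bh, beta_true, tolerance = 1e-3)

  # exact projection when slopes are exactly beta * v
  d_at <- estimate_tbase(phi, slopes, L, 0.05, grid = c(24))   # degenerate grid
  expect_identical(d_at$tbase_hat, 24)
  v <- predicted_slope(L, 0.05, 24, phi) / 0.05
  expect_equal(estimate_beta(phi, 0.37 * v, L, 0.05, 24), 0.37, tolerance = 1e-12)
  expect_equal(estimate_beta(phi, rep(0, 20), L, 0.05, 24), 0)
  # scaling slopes scales beta_hat linearly
  expect_equal(estimate_beta(phi, 3 * slopes, L, 0.05, est$tbase_hat), 3 * bh,
               tolerance = 1e-12)
  expect_error(estimate_beta(rep(0, 20), slopes, L, 0.05, 10), "degenerate")

  # zero-variance slopes: flagged degenerate, smallest grid point
  flat <- estimate_tbase(phi, rep(1, 20), L, 0.05, grid)
  expect_true(flat$degenerate)
  expect_identical(flat$tbase_hat, grid[1])
})

test_that("single-pass subject fit recovers the rate from model-consistent data", {
  cn <- random_conn(20, sparsity = 0.5, seed = 17)
  L <- build_laplacian(cn)
  x0 <- seed_pattern(cn$labels, c("R3", "R7"))
  beta_true <- 0.12; t_true <- 10
  # visits sampled densely so OLS slopes approximate the instantaneous rate
  visits <- c(0, 0.05, 0.1, 0.15)
  sub <- synth_subject(L, beta_true, t_true, visits = visits, noise_sd = 0,
                       x0 = x0, subject_id = "dense")
  fit <- fit_ppr(sub$trajectory, L, grid = tbase_grid(0.25, 100, 0.05))
  expect_equal(fit$beta_hat, beta_true, tolerance = 1e-2)
  expect_gt(fit$peak_correlation, 0.999)

  # flat trajectory -> non-progressor with zero rate
  tr0 <- atrophy_trajectory("flat", c(0, 2), matrix(0.4, 2, 20), L$labels)
  f0 <- fit_ppr(tr0, L)
  expect_identical(f0$beta_hat, 0)
  expect_identical(f0$flags, "non-progressor")

  # label mismatch is rejected by name
  tr_bad <- atrophy_trajectory("bad", c(0, 1), matrix(0.1, 2, 20),
                               paste0("X", 1:20))
  expect_error(fit_ppr(tr_bad, L), "X1")
})

test_that("wide-window visit slopes bias the recovered rate only moderately", {
  # OLS slopes over a multi-year window average the decelerating trajectory,
  # so the fit is biased relative to instantaneous-slope data; it must stay
  # within the window-scale error and preserve ordering across subjects
  cn <- random_conn(30, sparsity = 0.6, seed = 23)
  L <- build_laplacian(cn)
  x0 <- seed_pattern(cn$labels, "R5")
  betas <- c(0.05, 0.10, 0.15, 0.25)
  fits <- vapply(betas, function(b) {
    sub <- synth_subject(L, b, 10, visits = c(0, 1, 2, 3), noise_sd = 0, x0 = x0)
    fit_ppr(sub$trajectory, L, grid = tbase_grid(0.25, 150, 0.25))$beta_hat
  }, numeric(1))
  expect_true(all(abs(fits - betas) / betas < 0.35))
  expect_true(all(diff(fits) > 0))
})

test_that("cohort fitting returns one row per subject with outlier flags", {
  cn <- random_conn(15, sparsity = 0.4, seed = 29)
  L <- build_laplacian(cn)
  x0 <- seed_pattern(cn$labels, "R2")
  trajs <- lapply(1:6, function(i) {
    synth_subject(L, beta = 0.05 + 0.02 * i, t_base = 8, visits = c(0, 1, 2),
                  noise_sd = 0, x0 = x0, subject_id = paste0("s", i))$trajectory
  })
  tab <- fit_ppr_cohort(trajs, L, grid = tbase_grid(0.25, 80, 0.5))
  expect_identical(nrow(tab), 6L)
  expect_identical(tab$subject_id, paste0("s", 1:6))
  expect_true(all(tab$beta_hat >= 0))
  expect_type(tab$is_outlier, "logical")
})

test_that("Tukey fences flag outliers under the interpolated-quartile convention", {
  vals <- c(1, 2, 3, 4, 100)
  expect_identical(flag_outliers(vals, rep("g", 5)),
                   c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_false(any(flag_outliers(rep(7, 10), rep("g", 10))))
  expect_false(any(flag_outliers(1:10, rep("g", 10))))

  # group-wise: the same value can be an outlier in one group only
  v <- c(1, 2, 3, 4, 100, 96, 98, 100, 102, 104)
  g <- rep(c("a", "b"), each = 5)
  expect_identical(flag_outliers(v, g),
                   c(FALSE, FALSE, FALSE, FALSE, TRUE, rep(FALSE, 5)))

  expect_warning(flag_outliers(c(1, 2, 50), rep("tiny", 3)), "fewer than 4")
  expect_error(flag_outliers(c(1, NA), c("a", "a")), "finite")

  # affine invariance within groups
  set.seed(3)
  x <- rnorm(40); grp <- rep(c("a", "b"), 20)
  expect_identical(flag_outliers(x, grp), flag_outliers(5 * x - 2, grp))
})
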
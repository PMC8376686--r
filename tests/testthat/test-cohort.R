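test_that("CSF z-scoring centers on controls and drops incomplete cases", {
  controls <- data.frame(subject_id = c("c1", "c2", "c3"),
                         abeta = c(1, 2, 3), tau = c(10, 15, 30),
                         ptau = c(5, 6, 9))
  patients <- data.frame(subject_id = c("p1", "p2", "p3"),
                         abeta = c(2, 4, NA), tau = c(55 / 3, 20, 30),
                         ptau = c(20 / 3, 7, 8))
  zs <- zscore_biomarkers(patients, controls)
  # p1 sits exactly at the control mean of the three raw biomarkers
  expect_equal(unname(zs$z["p1", "abeta"]), 0, tolerance = 1e-12)
  expect_equal(unname(zs$z["p1", "tau"]), 0, tolerance = 1e-12)
  expect_equal(unname(zs$z["p1", "ptau"]), 0, tolerance = 1e-12)
  # abeta: controls {1,2,3} have mean 2, sample sd 1 -> patient 4 scores z = 2
  expect_equal(unname(zs$z["p2", "abeta"]), 2, tolerance = 1e-12)
  # incomplete patient dropped and counted
  expect_identical(zs$n_dropped, 1L)
  expect_identical(rownames(zs$z), c("p1", "p2"))
  # ratios recomputed from raw values
  expect_equal(unname(zs$raw[, "abeta_tau"]),
               patients$abeta[1:2] / patients$tau[1:2], tolerance = 1e-9)

  # zero control sd is an error naming the biomarker
  flat <- within(controls, tau <- 10)
  expect_error(zscore_biomarkers(patients, flat), "tau")

  # affine transform applied to both tables leaves z unchanged
  zs2 <- zscore_biomarkers(transform(patients, abeta = 7 * abeta + 3),
                           transform(controls, abeta = 7 * abeta + 3))
  expect_equal(unname(zs2$z[, "abeta"]), unname(zs$z[, "abeta"]), tolerance = 1e-9)
})

test_that("variance-ratio selection recovers planted blob structure", {
  make_blobs <- function(k, n_each, sep, seed) {
    set.seed(seed)
    centers <- matrix(rnorm(k * 4), k)
    centers <- centers / sqrt(mean(centers^2)) * sep
    x <- centers[rep(1:k, each = n_each), ] + matrix(rnorm(k * n_each * 4), k * n_each)
    list(x = x, labels = rep(1:k, each = n_each))
  }
  b3 <- make_blobs(3, 50, 10, 41)
  cl3 <- hierarchical_cluster(b3$x)
  expect_identical(cl3$k_selected, 3L)
  expect_gte(label_agreement(cl3$labels, b3$labels), 0.95)

  b2 <- make_blobs(2, 50, 10, 42)
  cl2 <- hierarchical_cluster(b2$x)
  expect_identical(cl2$k_selected, 2L)

  # every cut's CH score matches the pairwise-distance recomputation
  for (j in seq_along(cl3$ch_curve)) {
    k <- as.integer(names(cl3$ch_curve)[j])
    expect_equal(cl3$ch_curve[[j]], ch_by_pairwise(b3$x, cl3$cuts[, j]),
                 tolerance = 1e-9)
  }

  # degenerate geometry: all points identical up to jitter
  set.seed(43)
  xd <- matrix(1, 30, 4) + matrix(rnorm(120, sd = 1e-13), 30)
  cld <- hierarchical_cluster(xd)
  expect_identical(cld$k_selected, 2L)

  expect_error(hierarchical_cluster(b3$x[1:5, ], k_candidates = 2:10), "at least")
  expect_error(hierarchical_cluster(matrix(c(1, NA), 12, 2)), "non-finite")
})

test_that("group comparison wrappers give canonical results on stark contrasts", {
  # complete separation: rank-sum p-value vanishes
  res <- compare_groups(c(1:20, 101:120), rep(c("lo", "hi"), each = 20),
                        "wilcoxon_ranksum")
  expect_lt(res$p_value, 1e-6)

  kw <- compare_groups(c(1:10, 101:110, 201:210), rep(1:3, each = 10),
                       "kruskal_wallis")
  expect_lt(kw$p_value, 1e-5)

  chi <- compare_groups(matrix(10, 2, 2), test = "chi_square")
  expect_equal(chi$statistic, 0)
  expect_equal(chi$p_value, 1)

  expect_error(compare_groups(1:4, c("a", "a", "a", "a"), "kruskal_wallis"),
               "2 non-empty groups")
  expect_error(compare_groups(1:6, rep(c("a", "b", "c"), 2), "wilcoxon_ranksum"),
               "exactly 2")
})

test_that("atrophied-region selection ranks by deficit with stable ties", {
  set.seed(51)
  regions <- paste0("r", sprintf("%02d", 1:12))
  ctrl <- matrix(rnorm(40 * 12, mean = 100, sd = 2), 40,
                 dimnames = list(NULL, regions))
  cases <- matrix(rnorm(30 * 12, mean = 100, sd = 2), 30,
                  dimnames = list(NULL, regions))
  cases[, "r07"] <- cases[, "r07"] - 10    # 5 pooled sd deficit
  sel <- select_atrophy_regions(cases, ctrl, k = 3)
  expect_identical(sel[1], "r07")

  # all-equal arms: tie-break returns the first k labels in order
  same <- matrix(rep(seq_len(10), 12), 10, dimnames = list(NULL, regions))
  sel_tie <- select_atrophy_regions(same, same, k = 4)
  expect_identical(as.character(sel_tie), regions[1:4])

  expect_warning(sel_all <- select_atrophy_regions(cases, ctrl, k = 99),
                 "exceeds region count")
  expect_identical(length(sel_all), 12L)
  const <- matrix(5, 4, 12, dimnames = list(NULL, regions))
  expect_error(select_atrophy_regions(const, const + 0, k = 2), "zero pooled")
})

test_that("baseline regression reports exact and null fits honestly", {
  set.seed(61)
  X <- as.data.frame(matrix(rnorm(60 * 5), 60))
  names(X) <- paste0("f", 1:5)
  y <- 2 + 3 * X$f1 - 0.5 * X$f4
  rep_exact <- suppressWarnings(predict_ppr_baseline(X, y))  # exact fit warns in summary.lm
  expect_equal(rep_exact$r_squared, 1, tolerance = 1e-10)
  expect_identical(rep_exact$n_used, 60L)
  expect_identical(nrow(rep_exact$coefficients), 6L)

  # permuted outcome: coefficient of determination collapses
  rep_null <- predict_ppr_baseline(X, sample(y))
  expect_lt(rep_null$r_squared, 0.3)

  # collinear design is refused with the offending column named
  X2 <- X; X2$f1_copy <- X$f1
  expect_error(predict_ppr_baseline(X2, y), "f1_copy")
  expect_error(predict_ppr_baseline(X[1:4, ], y[1:4]), "complete cases")
})

test_that("volume-deficit atrophy recipe floors at zero", {
  regions <- c("a", "b")
  ctrl <- matrix(c(100, 102, 98, 100, 50, 51, 49, 50), 4,
                 dimnames = list(NULL, regions))
  vols <- matrix(c(100 - 2 * stats::sd(ctrl[, 1]), 60), 1,
                 dimnames = list(NULL, regions))
  atr <- atrophy_from_volumes(vols, ctrl)
  expect_equal(unname(atr[1, "a"]), 2, tolerance = 1e-9)   # 2 sd deficit
  expect_equal(unname(atr[1, "b"]), 0)                     # above control mean
})
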
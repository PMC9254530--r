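test_that("CSH curve of a homogeneous lesion is identically 1", {
  ph <- quick_phantom("homogeneous", spacing = 4, radius = 16, shape = 13)
  curve <- compute_csh(ph$volume, ph$mask, n_bins = 100)
  expect_true(all(curve$fractions == 1))
  expect_equal(auc_csh(curve)$auc_trapezoid, 1.0)
  expect_equal(auc_csh(curve)$auc_exact, 1.0)
})

test_that("two-level lesion gives the two-step CSH curve", {
  toy <- toy_lesion(rep(c(4, 2), each = 50), dims = c(10, 5, 2))
  curve <- compute_csh(toy$volume, toy$mask, n_bins = 10)
  t <- curve$thresholds
  expect_equal(curve$fractions[t <= 0.5], rep(1, sum(t <= 0.5)))
  expect_equal(curve$fractions[t > 0.5], rep(0.5, sum(t > 0.5)))
  a <- auc_csh(curve)
  expect_equal(a$auc_exact, 0.75)
})

test_that("uniform-histogram lesion has fractions close to 1 - t", {
  ph <- quick_phantom("uniform_histogram", spacing = 2, radius = 22,
                      shape = 25)
  curve <- compute_csh(ph$volume, ph$mask, n_bins = 100)
  expect_lt(max(abs(curve$fractions - (1 - curve$thresholds))), 0.02)
})

test_that("CSH invariants: starts at 1, non-increasing, max voxel survives", {
  set.seed(17)
  for (i in 1:10) {
    suv <- rlnorm(sample(20:300, 1), log(3), 0.6)
    toy <- toy_lesion(suv, dims = c(15, 10, 2))
    curve <- compute_csh(toy$volume, toy$mask, n_bins = 50)
    expect_equal(curve$fractions[1], 1)
    expect_true(all(diff(curve$fractions) <= 0))
    expect_gte(curve$fractions[length(curve$fractions)], 1 / length(suv))
  }
})

test_that("trapezoidal AUC converges to the exact value within 2/n_bins", {
  set.seed(23)
  for (kind in c("two_level", "radial_linear", "necrotic_core",
                 "uniform_histogram")) {
    ph <- quick_phantom(kind, noise_sd = 0.2)
    for (nb in c(10, 100, 1000)) {
      a <- auc_csh(compute_csh(ph$volume, ph$mask, n_bins = nb))
      expect_lte(abs(a$auc_trapezoid - a$auc_exact), 2 / nb)
    }
    a1k <- auc_csh(compute_csh(ph$volume, ph$mask, n_bins = 1000))
    expect_lte(abs(a1k$auc_trapezoid - a1k$auc_exact), 0.002)
  }
})

test_that("AUC-CSH agrees with the brute-force sorted-voxel oracle", {
  set.seed(41)
  for (i in 1:10) {
    suv <- rlnorm(sample(10:200, 1), log(4), 0.8)
    toy <- toy_lesion(suv, dims = c(20, 10, 1))
    a <- auc_csh(compute_csh(toy$volume, toy$mask, n_bins = 2000))
    oracle <- auc_csh_oracle(suv)
    expect_equal(a$auc_exact, oracle, tolerance = 1e-10)
    expect_equal(a$auc_trapezoid, oracle, tolerance = 2 / 2000)
  }
})

test_that("AUC-CSH is invariant under rescaling and voxel permutation", {
  set.seed(13)
  suv <- rlnorm(150, log(3), 0.5)
  base <- auc_csh(compute_csh(toy_lesion(suv)$volume, toy_lesion(suv)$mask))
  for (c_fac in c(0.1, 7)) {
    toy <- toy_lesion(suv * c_fac)
    a <- auc_csh(compute_csh(toy$volume, toy$mask))
    expect_equal(a$auc_exact, base$auc_exact, tolerance = 1e-12)
    expect_equal(a$auc_trapezoid, base$auc_trapezoid, tolerance = 1e-12)
  }
  toy_p <- toy_lesion(sample(suv))
  a_p <- auc_csh(compute_csh(toy_p$volume, toy_p$mask))
  expect_equal(a_p$auc_exact, base$auc_exact, tolerance = 1e-12)
  expect_equal(a_p$auc_trapezoid, base$auc_trapezoid, tolerance = 1e-12)
})

test_that("summary-parameter identities recover the index", {
  ph <- quick_phantom("radial_linear")
  lh <- lesion_heterogeneity(ph$volume, ph$mask)
  r <- lh$row
  expect_equal(auc_csh_from_summary(r$tlg_total, r$mtv_total, r$suv_max),
               lh$auc_total$auc_exact, tolerance = 1e-12)
  expect_equal(
    auc_csh_total_from_subset(lh$auc_40$auc_exact, r$tlg_total, r$mtv_total,
                              r$tlg_40, r$mtv_40),
    lh$auc_total$auc_exact, tolerance = 1e-12)
})

test_that("method comparison handles identical and degenerate pairs", {
  set.seed(3)
  n <- 20
  same <- data.frame(mtv_total = rlnorm(n, 5, 1), tlg_total = rlnorm(n, 6, 1),
                     auccsh_total = runif(n, 0.2, 0.9))
  same$mtv_40 <- same$mtv_total
  same$tlg_40 <- same$tlg_total
  same$auccsh_40 <- same$auccsh_total
  tab <- compare_segmentations(same)
  expect_equal(tab$spearman_rho, rep(1, 3))
  expect_true(all(grepl("degenerate", tab$note)))
  expect_true(all(is.na(tab$signed_rank_p)))
  expect_error(compare_segmentations(same[1:2, ]), "at least 3")
})

test_that("method comparison recovers a planted correlation", {
  set.seed(8)
  n <- 400
  auccsh_total <- runif(n, 0.25, 0.75)
  df <- data.frame(
    auccsh_total = auccsh_total,
    auccsh_40 = pmin(auccsh_total + abs(rnorm(n, 0.08, 0.04)), 1),
    mtv_total = rlnorm(n, log(236), 0.7))
  df$mtv_40 <- df$mtv_total * rbeta(n, 5, 5)
  df$tlg_total <- df$mtv_total * runif(n, 1, 3)
  df$tlg_40 <- df$tlg_total * rbeta(n, 8, 2)
  tab <- compare_segmentations(df)
  rho_oracle <- cor(df$auccsh_total, df$auccsh_40, method = "spearman")
  expect_equal(tab$spearman_rho[tab$parameter == "AUC_CSH"], rho_oracle,
               tolerance = 1e-10)
  expect_gt(tab$spearman_rho[tab$parameter == "AUC_CSH"], 0.8)
  expect_lt(tab$signed_rank_p[tab$parameter == "MTV"], 0.001)
})

test_that("heterogeneous lesions diverge between methods in one direction", {
  set.seed(19)
  rows <- lapply(1:15, function(i) {
    ph <- quick_phantom(sample(c("radial_linear", "necrotic_core",
                                 "uniform_histogram", "two_level"), 1),
                        noise_sd = runif(1, 0, 0.3), spacing = 3,
                        radius = runif(1, 12, 18), shape = 15)
    lesion_heterogeneity(ph$volume, ph$mask, id = paste0("L", i))$row
  })
  tab <- do.call(rbind, rows)
  expect_true(all(tab$auccsh_40_exact >= tab$auccsh_total_exact))
  expect_true(all(tab$auccsh_40 >= tab$auccsh_total))
  expect_true(all(tab$mtv_40 <= tab$mtv_total))
})

test_that("invalid CSH inputs are rejected", {
  toy <- toy_lesion(c(1, 2, 3))
  expect_error(compute_csh(toy$volume, toy$mask, n_bins = 5), "n_bins")
  expect_error(compute_csh(toy$volume, toy$mask, suv_max_ref = 0), "> 0")
})
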
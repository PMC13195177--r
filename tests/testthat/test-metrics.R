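# DVH, V/D queries, conformity and homogeneity indices, clinical goals.

uniform_dvh <- function(dose_Gy = 50, n = 100) {
  compute_dvh(matrix(dose_Gy, 10, n / 10), matrix(TRUE, 10, n / 10))
}

test_that("DVH of a uniform dose", {
  dvh <- uniform_dvh(50)
  expect_equal(dvh$volume_pct[1], 100)               # starts at 100% at 0 Gy
  expect_true(all(diff(dvh$volume_pct) <= 0))        # nonincreasing
  expect_equal(v_at_dose(dvh, 2)$pct, 100)
  expect_equal(d_at_volume(dvh, 95), 50, tolerance = 0.005)
  expect_equal(v_at_dose(dvh, 50.2)$pct, 0)
})

test_that("two-level dose: D5 and D95 land on the two levels", {
  d <- matrix(c(rep(47.5, 50), rep(52.5, 50)), 10, 10)
  dvh <- compute_dvh(d, matrix(TRUE, 10, 10))
  expect_equal(d_at_volume(dvh, 5), 52.5, tolerance = 0.005)
  expect_equal(d_at_volume(dvh, 95), 47.5, tolerance = 0.005)
  expect_equal(homogeneity_index(dvh), 52.5 / 47.5, tolerance = 0.005)
})

test_that("DVH queries agree with direct voxel computation (oracle)", {
  set.seed(29)
  for (i in 1:20) {
    d <- matrix(stats::rgamma(400, shape = 4, scale = 8), 20, 20)
    m <- matrix(stats::runif(400) < 0.6, 20, 20)
    if (!any(m)) next
    dvh <- compute_dvh(d, m)
    for (q in stats::runif(5, 0, max(d[m]))) {
      direct <- 100 * mean(d[m] >= q)
      # agreement within one 0.1 Gy bin's worth of volume
      lo <- 100 * mean(d[m] >= q + 0.1)
      hi <- 100 * mean(d[m] >= q - 0.1)
      expect_gte(v_at_dose(dvh, q)$pct, lo - 1e-9)
      expect_lte(v_at_dose(dvh, q)$pct, hi + 1e-9)
      expect_equal(v_at_dose(dvh, q)$pct, direct, tolerance = 0.5)
    }
    # d_at_volume inverts v_at_dose to bin resolution
    for (v in c(5, 50, 95)) {
      dq <- d_at_volume(dvh, v)
      expect_equal(v_at_dose(dvh, dq)$pct, v, tolerance = 1)
    }
  }
})

test_that("query validation errors", {
  dvh <- uniform_dvh()
  expect_error(v_at_dose(dvh, -1), "dose")
  expect_error(d_at_volume(dvh, 0), "volume_pct")
  expect_error(d_at_volume(dvh, 101), "volume_pct")
  expect_error(compute_dvh(matrix(1, 2, 2), matrix(FALSE, 2, 2)), "empty")
  expect_error(compute_dvh(matrix(1, 2, 2), matrix(TRUE, 2, 2),
                           bin_width_Gy = 0), "bin width")
})

test_that("Paddick CI matches hand evaluation", {
  # perfect conformity: isodose exactly covers the PTV
  ptv <- matrix(FALSE, 10, 10); ptv[3:6, 3:6] <- TRUE
  ext <- matrix(TRUE, 10, 10)
  d <- matrix(0, 10, 10); d[ptv] <- 50
  expect_equal(paddick_ci(d, ptv, ext, 50), 1)
  # printed example: PIV_PTV 95, PTV_VOL 100, PIV_EXT 120 -> 0.752
  ptv2 <- matrix(FALSE, 20, 20); ptv2[1:10, 1:10] <- TRUE        # 100 voxels
  d2 <- matrix(0, 20, 20)
  hot <- which(ptv2)[1:95]
  d2[hot] <- 50
  d2[which(!ptv2)[1:25]] <- 50                                   # 120 total
  ext2 <- matrix(TRUE, 20, 20)
  expect_equal(paddick_ci(d2, ptv2, ext2, 50), 0.95 * 95 / 120)
  # everything cold -> 0 with a warning
  expect_warning(ci0 <- paddick_ci(matrix(1, 5, 5), matrix(TRUE, 5, 5),
                                   matrix(TRUE, 5, 5), 50), "CI defined as 0")
  expect_equal(ci0, 0)
})

test_that("Paddick CI is in [0, 1] and 1 only at perfect conformity", {
  set.seed(41)
  for (i in 1:30) {
    d <- matrix(stats::runif(100, 0, 60), 10, 10)
    ptv <- matrix(stats::runif(100) < 0.3, 10, 10)
    if (!any(ptv)) next
    ext <- matrix(TRUE, 10, 10)
    ci <- suppressWarnings(paddick_ci(d, ptv, ext, 50))
    expect_gte(ci, 0)
    expect_lte(ci, 1)
    if (ci == 1) {
      # perfect conformity: the isodose is exactly the PTV
      expect_identical(unname(d >= 47.5), unname(ptv))
    }
  }
})

test_that("homogeneity index of a uniform dose is 1 and HI >= 1 always", {
  expect_equal(homogeneity_index(uniform_dvh(50)), 1, tolerance = 0.005)
  set.seed(43)
  for (i in 1:10) {
    d <- matrix(stats::runif(100, 10, 60), 10, 10)
    dvh <- compute_dvh(d, matrix(TRUE, 10, 10))
    expect_gte(homogeneity_index(dvh), 1 - 1e-9)
  }
})

test_that("clinical goals evaluate with the printed comparators", {
  ph <- default_phantom()
  plan0 <- list(dose = matrix(0, 128, 128), phantom = ph)
  g0 <- evaluate_goals(plan0)
  expect_true(all(g0$pass))                         # zero dose: all pass

  # heart mean 2.6 Gy vs <= 2.5 -> fail
  d <- matrix(0, 128, 128); d[ph$masks$heart] <- 2.6
  gh <- evaluate_goals(list(dose = d, phantom = ph))
  expect_false(gh$pass[gh$structure == "heart" & gh$metric == "mean"])

  # ipsilateral lung V20 exactly at the 20% limit fails the strict <
  m <- ph$masks$lung_ipsi
  nl <- sum(m)
  k <- round(0.2 * nl)
  d2 <- matrix(0, 128, 128)
  d2[which(m)[seq_len(k)]] <- 25
  g2 <- evaluate_goals(list(dose = d2, phantom = ph))
  v20 <- g2[g2$metric == "V20Gy", ]
  expect_equal(v20$value, 100 * k / nl, tolerance = 0.2)
  if (v20$value >= 20) expect_false(v20$pass)

  expect_error(evaluate_goals(plan0, data.frame(
    structure = "heart", metric = "XYZ", comparator = "<", limit = 1)),
    "unknown metric")
})

test_that("goal metrics support mean, max, VxGy and Dx%", {
  ph <- toy_phantom(4, 4)
  d <- matrix(seq(4, 64, by = 4), 4, 4)
  m <- matrix(TRUE, 4, 4)
  expect_equal(ofvplan:::goal_metric_value("mean", d, m, 1), mean(d))
  expect_equal(ofvplan:::goal_metric_value("max", d, m, 1), 64)
  expect_equal(ofvplan:::goal_metric_value("V20Gy", d, m, 1),
               100 * mean(d >= 20), tolerance = 1)
  expect_equal(ofvplan:::goal_metric_value("D50%", d, m, 1),
               stats::median(d), tolerance = 4)
})

test_that("plan_metrics summarizes a synthetic plan coherently", {
  ph <- default_phantom()
  d <- matrix(1, 128, 128)
  d[ph$masks$PTV] <- 50
  pm <- plan_metrics(list(dose = d, phantom = ph, prescription_Gy = 50))
  expect_equal(pm$ptv_v95_pct, 100)
  expect_equal(pm$ci_paddick, 1)
  expect_equal(pm$hi, 1, tolerance = 0.005)
  expect_equal(pm$external_max_Gy, 50)
  expect_named(pm$dvhs, names(ph$masks))
})
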
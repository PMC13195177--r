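# Sensitivity pipeline: schedule, smoothing, change rates, criticality
# masks, and the S(j) score with a brute-force oracle.

test_that("sensitivity_config validates inputs", {
  expect_error(sensitivity_config(n_steps = 3L), "at least 4")
  expect_error(sensitivity_config(window = 4L), "odd")
  expect_error(sensitivity_config(decay = 1.5))
  cfg <- sensitivity_config()
  expect_equal(cfg$n_steps, 12L)
  expect_equal(cfg$decay, 0.8)
  expect_equal(cfg$companion_limits_Gy,
               c(lung_contra = 1, breast_contra = 4, heart = 2.5))
  expect_equal(cfg$ptv_d95_crit_Gy, 47.5)
  expect_equal(cfg$ext_max_crit_Gy, 52.5)
})

test_that("smoothing is a truncated centered moving average", {
  tr <- data.frame(step = 1:3, ptv_d95_Gy = c(0, 3, 0))
  sm <- smooth_trace(tr, 3L)
  expect_equal(sm$ptv_d95_Gy, c(1.5, 1, 1.5))
  # constant series are fixed points of the smoother
  tr2 <- data.frame(step = 1:5, oar_mean_Gy = rep(4, 5))
  expect_equal(smooth_trace(tr2, 3L)$oar_mean_Gy, rep(4, 5))
  # window 1 is the identity
  tr3 <- data.frame(step = 1:4, ext_max_Gy = c(5, 1, 9, 2))
  expect_equal(smooth_trace(tr3, 1L)$ext_max_Gy, c(5, 1, 9, 2))
  expect_error(smooth_trace(tr3, 2L), "odd")
  expect_error(smooth_trace(tr3, 5L), "longer")
  # non-metric columns pass through untouched
  tr4 <- data.frame(step = 1:3, driven_limit_Gy = c(NA, 2, 1),
                    ptv_ofv = c(1, 2, 3))
  expect_equal(smooth_trace(tr4, 3L)$driven_limit_Gy, c(NA, 2, 1))
})

test_that("change rates are later-step-indexed first differences", {
  tr <- data.frame(step = 1:3, oar_mean_Gy = c(1, 3, 6))
  rt <- change_rates(tr)
  expect_equal(rt$step, 2:3)
  expect_equal(rt$oar_mean_Gy, c(2, 3))
  expect_error(change_rates(tr[1, ]), "at least 2")
})

test_that("criticality masks follow documented thresholds and strict medians", {
  cfg <- sensitivity_config()
  tr <- data.frame(step = 1:5,
                   ptv_d95_Gy = c(49, 48, 47.5, 47, 46),
                   ext_max_Gy = c(52, 52.5, 53, 54, 52),
                   oar_mean_Gy = c(10, 8, 7, 6.8, 6.7),
                   ext_v105_cm3 = c(0, 1, 3, 4, 4.5))
  rt <- change_rates(tr)
  mk <- criticality_masks(tr, rt, cfg)
  expect_equal(mk$step, 2:5)
  # thresholds at the state of the later step; 47.5 is not < 47.5
  expect_equal(mk$ptv_cov, c(FALSE, FALSE, TRUE, TRUE))
  # 52.5 is not > 52.5
  expect_equal(mk$ext_max, c(FALSE, TRUE, TRUE, FALSE))
  # |d oar_mean| = 2, 1, 0.2, 0.1; median 0.6: strict comparison
  expect_equal(mk$lung_slope, c(FALSE, FALSE, TRUE, TRUE))
  # d v105 = 1, 2, 1, 0.5; median 1: strict, so ties excluded
  expect_equal(mk$ext_v105, c(FALSE, TRUE, FALSE, FALSE))
  expect_error(criticality_masks(tr, rt[-1, ], cfg), "aligned")
})

test_that("S(j) equals a brute-force oracle on 50 random traces", {
  set.seed(123)
  cfg <- sensitivity_config()
  for (rep in 1:50) {
    n <- sample(5:12, 1)
    tr <- data.frame(step = 1:n,
                     ptv_d95_Gy = stats::runif(n, 44, 50),
                     ptv_ofv = stats::runif(n, 0, 5),
                     ext_max_Gy = stats::runif(n, 50, 56),
                     ext_v105_cm3 = stats::runif(n, 0, 3),
                     oar_ofv = stats::runif(n, 0, 6),
                     oar_mean_Gy = stats::runif(n, 1, 20))
    rt <- change_rates(tr)
    mk <- criticality_masks(tr, rt, cfg)
    sc <- sensitivity_score(rt, mk, trace = tr)
    # independent oracle: definition written out longhand per step
    S_oracle <- numeric(n - 1)
    for (i in seq_len(n - 1)) {
      j <- i + 1
      S <- 0
      if (tr$ptv_d95_Gy[j] < 47.5)
        S <- S + abs(tr$ptv_d95_Gy[j] - tr$ptv_d95_Gy[j - 1])
      dm <- abs(diff(tr$oar_mean_Gy))
      if (dm[i] < stats::median(dm))
        S <- S + dm[i]
      if (tr$ext_max_Gy[j] > 52.5)
        S <- S + abs(tr$ext_max_Gy[j] - tr$ext_max_Gy[j - 1])
      dv <- diff(tr$ext_v105_cm3)
      if (dv[i] > stats::median(dv))
        S <- S + abs(dv[i])
      S_oracle[i] <- S
    }
    expect_equal(sc$score$S, S_oracle)
    expect_equal(sc$j_star, (2:n)[which.max(S_oracle)])
    expect_equal(sc$ofv_at_jstar, tr$oar_ofv[sc$j_star])
  }
})

test_that("score ties break toward the earliest step", {
  rates <- data.frame(step = 2:4, ptv_d95_Gy = c(-1, -1, 0),
                      oar_mean_Gy = 0, ext_max_Gy = 0, ext_v105_cm3 = 0)
  masks <- data.frame(step = 2:4, ptv_cov = TRUE, lung_slope = FALSE,
                      ext_max = FALSE, ext_v105 = FALSE)
  sc <- sensitivity_score(rates, masks)
  expect_equal(sc$j_star, 2)
  expect_true(is.na(sc$ofv_at_jstar))
})

test_that("all-zero score warns", {
  rates <- data.frame(step = 2:3, ptv_d95_Gy = c(1, 1), oar_mean_Gy = 0,
                      ext_max_Gy = 0, ext_v105_cm3 = 0)
  masks <- data.frame(step = 2:3, ptv_cov = FALSE, lung_slope = FALSE,
                      ext_max = FALSE, ext_v105 = FALSE)
  expect_warning(sensitivity_score(rates, masks), "identically 0")
})

test_that("run_schedule follows the documented limit schedule", {
  sp <- small_problem()
  cfg <- sensitivity_config(n_steps = 6L,
                            optimizer = optimizer_config(
                              inner_iterations = 15L))
  tr <- run_schedule(sp$phantom, sp$beamset, cfg, influence = sp$influence)
  expect_equal(nrow(tr), 6L)
  expect_equal(tr$step, 1:6)
  # step 1: PTV only, no OAR term, no limit
  expect_true(is.na(tr$driven_limit_Gy[1]))
  expect_equal(tr$oar_ofv[1], 0)
  m1 <- tr$oar_mean_Gy[1]
  expect_equal(tr$driven_limit_Gy[2], 0.5 * m1)
  expect_equal(tr$driven_limit_Gy[3], 0.25 * m1)
  expect_equal(tr$driven_limit_Gy[4], 0.25 * m1 * 0.8)
  expect_equal(tr$driven_limit_Gy[5], 0.25 * m1 * 0.8^2)
  # tightening the limit reduces the driven organ's mean dose overall
  expect_lt(tr$oar_mean_Gy[6], tr$oar_mean_Gy[1])
  # all tracked metrics are finite
  for (cn in ofvplan:::trace_metric_cols) expect_true(all(is.finite(tr[[cn]])))
  expect_error(run_schedule(sp$phantom, sp$beamset,
                            sensitivity_config(driven_organ = "nope"),
                            influence = sp$influence), "unknown driven organ")
})

test_that("derive_tuning_points runs both class configurations", {
  sp <- small_problem()
  cfg <- sensitivity_config(n_steps = 5L,
                            optimizer = optimizer_config(
                              inner_iterations = 10L))
  tp <- suppressWarnings(
    derive_tuning_points(list(sp$phantom), list(sp$beamset), cfg,
                         influences = list(sp$influence)))
  expect_equal(nrow(tp$per_phantom), 2)
  expect_setequal(tp$per_phantom$class, c("class1", "class2"))
  expect_true(all(tp$per_phantom$j_star >= 2))
  expect_true(is.finite(tp$class2_mean_ofv))
  expect_true(is.finite(tp$class1_mean_ofv))
})
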
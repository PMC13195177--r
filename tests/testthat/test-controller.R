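# Feedback laws, phase initialization, the outer loop, and coverage repair.

test_that("class fixed points follow from the printed slopes and intercepts", {
  cls <- organ_classes()
  expect_equal((1 - cls$class1$n) / cls$class1$m, 0.2 / 0.44)
  expect_equal((1 - cls$class2$n) / cls$class2$m, 0.2 / 0.089)
  # the laws' multipliers equal 1 exactly at the fixed points
  expect_equal(update_multiplier(0.2 / 0.44, cls$class1), 1)
  expect_equal(update_multiplier(0.2 / 0.089, cls$class2), 1)
})

test_that("update law: s < 1 below the fixed point, s > 1 above", {
  cls <- organ_classes()
  set.seed(17)
  for (cl in cls) {
    fp <- (1 - cl$n) / cl$m
    below <- stats::runif(50, 0, fp * 0.999)
    above <- stats::runif(50, fp * 1.001, fp * 10)
    expect_true(all(update_multiplier(below, cl) < 1))
    expect_true(all(update_multiplier(above, cl) > 1))
  }
  expect_error(update_multiplier(-0.1, cls$class1), "ofv")
})

test_that("multiplier at OFV 0 equals the intercept", {
  cls <- organ_classes()
  expect_equal(update_multiplier(0, cls$class1), 0.8)
  expect_equal(update_multiplier(0, cls$class2), 0.8)
})

test_that("apply_update multiplies and clamps", {
  cfg <- controller_config()
  expect_equal(apply_update(10, 0.8, cfg), 8)
  expect_equal(apply_update(0.11, 0.5, cfg), cfg$eud_floor_Gy)
  expect_equal(apply_update(45, 1.5, cfg), cfg$eud_ceiling_Gy)
  expect_error(apply_update(0, 1, cfg), "prev_max_eud")
})

test_that("organ_classes rejects ill-posed laws", {
  expect_error(organ_classes(class1 = list(m = -1)), "slope")
  expect_error(organ_classes(class2 = list(n = 1.2)), "intercept")
  expect_error(organ_classes(class1 = list(phase2_fraction = 0)),
               "phase2_fraction")
})

test_that("phase-1 objectives: PTV at prescription, all OAR limits at D_p", {
  ph <- small_problem()$phantom
  cfg <- controller_config()
  objectives <- init_phase1(ph, cfg)
  expect_equal(objectives[[1]]$structure, "PTV")
  expect_equal(objectives[[1]]$kind, "uniform_dose")
  expect_equal(objectives[[1]]$level, 50)
  expect_equal(objectives[[1]]$weight, 3000)
  oar_terms <- objectives[2:5]
  expect_setequal(vapply(oar_terms, function(o) o$structure, character(1)),
                  c("lung_ipsi", "heart", "lung_contra", "breast_contra"))
  for (o in oar_terms) {
    expect_equal(o$kind, "max_eud")
    expect_equal(o$level, 50)
    expect_equal(o$weight, 10)
  }
  nt <- objectives[[length(objectives)]]
  expect_equal(nt$structure, "external")
  expect_equal(nt$kind, "max_dose")
  expect_equal(nt$level, 52.5)
  # disabling the normal-tissue weight drops the term
  cfg0 <- controller_config(normal_tissue_weight = 0)
  expect_length(init_phase1(ph, cfg0), 5)
})

test_that("phase-2 limits are 50% (class 1) / 20% (class 2) of phase-1 means", {
  ph <- small_problem()$phantom
  cfg <- controller_config()
  fake <- list(structures = data.frame(
    structure = c("PTV", "lung_ipsi", "heart", "lung_contra", "breast_contra"),
    mean_Gy = c(50, 12, 30, 4, 6),
    max_Gy = 55))
  objectives <- init_phase2(fake, organ_classes(), cfg, ph)
  lv <- stats::setNames(
    vapply(objectives[2:5], function(o) o$level, numeric(1)),
    vapply(objectives[2:5], function(o) o$structure, character(1)))
  expect_equal(lv[["lung_ipsi"]], 0.2 * 12)
  expect_equal(lv[["heart"]], 0.2 * 30)
  expect_equal(lv[["lung_contra"]], 0.5 * 4)
  expect_equal(lv[["breast_contra"]], 0.5 * 6)
})

test_that("phase-2 falls back to the floor on a zero phase-1 mean", {
  ph <- small_problem()$phantom
  cfg <- controller_config()
  fake <- list(structures = data.frame(
    structure = c("PTV", "lung_ipsi", "heart", "lung_contra", "breast_contra"),
    mean_Gy = c(50, 12, 30, 0, 6), max_Gy = 55))
  expect_warning(objectives <- init_phase2(fake, organ_classes(), cfg, ph),
                 "floor")
  lc <- Filter(function(o) identical(o$structure, "lung_contra"), objectives)
  expect_equal(lc[[1]]$level, cfg$eud_floor_Gy)
})

test_that("controller run on a reduced problem has a coherent trajectory", {
  sp <- small_problem()
  cfg <- controller_config(max_loops = 6L)
  run <- run_controller(sp$phantom, sp$beamset, cfg,
                        influence = sp$influence)
  tr <- run$trajectory
  n_loops <- max(tr$loops$loop)
  expect_lte(n_loops, 6L)
  expect_equal(tr$loops$phase[1:2], c("phase1", "phase2"))
  expect_equal(nrow(tr$organs), 4 * n_loops)
  expect_true(all(tr$organs$ofv >= 0))
  expect_true(all(tr$organs$max_eud_Gy >= cfg$eud_floor_Gy - 1e-12))
  expect_true(all(tr$organs$max_eud_Gy <= cfg$eud_ceiling_Gy + 1e-12))
  # phase 1 carries all limits at the prescription
  expect_true(all(tr$organs$max_eud_Gy[tr$organs$loop == 1] == 50))
  # phase-2 limits match the class fractions of the phase-1 means
  p1 <- tr$organs[tr$organs$loop == 1, ]
  p2 <- tr$organs[tr$organs$loop == 2, ]
  frac <- ifelse(p1$organ %in% c("lung_ipsi", "heart"), 0.2, 0.5)
  expect_equal(p2$max_eud_Gy,
               pmin(pmax(frac * p1$mean_dose_Gy, 0.1), 50))
  # phase-3 updates follow MaxEUD_n = clamp(s * MaxEUD_{n-1})
  for (loop in seq(3, n_loops)) {
    prev <- tr$organs[tr$organs$loop == loop - 1, ]
    cur <- tr$organs[tr$organs$loop == loop, ]
    cls <- organ_classes()
    s <- ifelse(prev$organ %in% cls$class2$members,
                cls$class2$m * prev$ofv + cls$class2$n,
                cls$class1$m * prev$ofv + cls$class1$n)
    expect_equal(cur$max_eud_Gy, pmin(pmax(s * prev$max_eud_Gy, 0.1), 50),
                 tolerance = 1e-12)
  }
})

test_that("controller runs are deterministic", {
  sp <- small_problem()
  cfg <- controller_config(max_loops = 4L)
  r1 <- run_controller(sp$phantom, sp$beamset, cfg, influence = sp$influence)
  r2 <- run_controller(sp$phantom, sp$beamset, cfg, influence = sp$influence)
  expect_identical(r1$plan$fluence, r2$plan$fluence)
  expect_identical(r1$trajectory$organs, r2$trajectory$organs)
})

test_that("coverage repair never decreases PTV V95 (keep-best rule)", {
  for (s in c(1L, 2L, 3L)) {
    sp <- small_problem(seed = s)
    cfg <- controller_config(max_loops = 5L)
    run <- run_controller(sp$phantom, sp$beamset, cfg,
                          influence = sp$influence)
    rep <- run$trajectory$repair
    expect_gte(rep$v95_after, rep$v95_before)
    # the plan's dose agrees with the reported repaired V95
    v95 <- 100 * mean(run$plan$dose[sp$phantom$masks$PTV] >= 0.95 * 50)
    expect_equal(v95, rep$v95_after)
  }
})

test_that("repair is a no-op above the trigger", {
  sp <- small_problem()
  ph <- sp$phantom
  dose <- matrix(0, 64, 64)
  dose[ph$masks$PTV] <- 50
  plan <- structure(list(fluence = rep(1, sp$influence$n_beamlets),
                         dose = dose, objectives = list(),
                         report = NULL, phantom = ph,
                         influence = sp$influence, prescription_Gy = 50),
                    class = "ofv_plan")
  out <- repair_coverage(plan, controller_config())
  expect_false(attr(out, "repair")$applied)
  expect_identical(out$dose, dose)
})

test_that("controller_config validates inputs", {
  expect_error(controller_config(max_loops = 2L), "max_loops")
  expect_error(controller_config(repair_loops = 3L))
  expect_error(controller_config(eud_floor_Gy = 0))
  expect_error(controller_config(normal_tissue_weight = -5))
})
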
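# The OFV-feedback outer loop: phased MaxEUD adaptation with linear update
# laws until saturation, followed by PTV-coverage repair.
#
# Class-1 organs (contralateral lung, contralateral breast) are updated
# gently (slope 0.44, target OFV 0.45); class-2 organs (ipsilateral lung,
# heart) are driven aggressively (slope 0.089, target OFV 2.25).  Both laws
# share the intercept 0.8, so the multiplier s = m * OFV + n crosses 1
# exactly at the class target OFV (the fixed point (1 - n) / m).

#' Built-in organ classes and their feedback laws
#'
#' @param class1,class2 optional lists overriding `members`, `m` (slope),
#'   `n` (intercept), `target` (target OFV, the law's fixed point), and
#'   `phase2_fraction` (fraction of the Phase-1 mean dose used as the
#'   Phase-2 MaxEUD).
#' @return named list of class descriptors, class `ofv_organ_classes`.
#' @export
organ_classes <- function(class1 = list(), class2 = list()) {
  defaults <- list(
    class1 = list(members = c("lung_contra", "breast_contra"),
                  m = 0.44, n = 0.8, target = 0.45, phase2_fraction = 0.5),
    class2 = list(members = c("lung_ipsi", "heart"),
                  m = 0.089, n = 0.8, target = 2.25, phase2_fraction = 0.2))
  cls <- list(class1 = utils::modifyList(defaults$class1, class1),
              class2 = utils::modifyList(defaults$class2, class2))
  for (nm in names(cls)) {
    cc <- cls[[nm]]
    if (cc$m <= 0 || cc$n <= 0 || cc$n >= 1)
      stop(nm, ": require slope m > 0 and intercept 0 < n < 1")
    if ((1 - cc$n) / cc$m <= 0) stop(nm, ": fixed point must be positive")
    if (cc$phase2_fraction <= 0 || cc$phase2_fraction > 1)
      stop(nm, ": phase2_fraction must be in (0, 1]")
  }
  structure(cls, class = "ofv_organ_classes")
}

# class descriptor for a given organ name
organ_class_of <- function(organ, classes) {
  for (nm in names(classes)) {
    if (organ %in% classes[[nm]]$members)
      return(c(classes[[nm]], list(label = nm)))
  }
  stop("organ '", organ, "' is not assigned to any class")
}

#' MaxEUD multiplier from an observed OFV
#'
#' The linear feedback law `s = m * ofv + n` of the organ's class.  Below
#' the class fixed point `(1 - n) / m` the multiplier is < 1 (the MaxEUD is
#' tightened); above it, > 1 (the MaxEUD is relaxed).
#'
#' @param ofv observed per-organ OFV (>= 0).
#' @param organ_class a class descriptor from [organ_classes()].
#' @return the multiplier `s` (dimensionless).
#' @export
update_multiplier <- function(ofv, organ_class) {
  if (any(ofv < 0)) stop("ofv must be >= 0")
  organ_class$m * ofv + organ_class$n
}

#' Apply a multiplier to a MaxEUD setting
#'
#' @param prev_max_eud previous MaxEUD limit, Gy (> 0).
#' @param s multiplier from [update_multiplier()].
#' @param config an `ofv_controller_config` providing `eud_floor_Gy` and
#'   `eud_ceiling_Gy`.
#' @return clamped new MaxEUD in Gy.
#' @export
apply_update <- function(prev_max_eud, s, config) {
  if (any(prev_max_eud <= 0)) stop("prev_max_eud must be > 0")
  pmin(pmax(s * prev_max_eud, config$eud_floor_Gy), config$eud_ceiling_Gy)
}

#' Controller settings
#'
#' @param prescription_Gy PTV prescription dose (Gy).
#' @param ptv_weight,oar_weight objective weights of the PTV uniform-dose
#'   term and every OAR MaxEUD term.
#' @param max_loops maximum outer loops (>= 3, so that Phases 1-3 fit).
#' @param saturation_tol saturation tolerance on `|s - 1|`, judged on
#'   class-2 organs only.
#' @param saturation_consecutive consecutive loops for which the tolerance
#'   must hold.
#' @param v95_trigger_pct PTV V95 (percent of volume at 95 percent of the
#'   prescription) below which coverage repair is run.
#' @param repair_loops inner-optimizer runs used for coverage repair (1-2).
#' @param eud_floor_Gy,eud_ceiling_Gy clamp range of the MaxEUD settings;
#'   the ceiling defaults to the prescription.
#' @param normal_tissue_weight weight of the normal-tissue overdose penalty
#'   (a `max_dose` term on the external contour included in every inner
#'   optimization, the analogue of a treatment planning system's automatic
#'   normal-tissue objective); 0 disables it.
#' @param normal_tissue_level_frac overdose threshold of that term as a
#'   fraction of the prescription (default 1.05, i.e. hot spots above 105
#'   percent of the prescription are penalized anywhere in the body).
#' @param classes an [organ_classes()] object.
#' @param optimizer an [optimizer_config()].
#' @param geud_exponents named per-organ gEUD exponents (default 1 for all:
#'   parallel-organ, mean-dose behavior).
#' @return an `ofv_controller_config`.
#' @export
controller_config <- function(prescription_Gy = 50, ptv_weight = 3000,
                              oar_weight = 10, max_loops = 12L,
                              saturation_tol = 0.005,
                              saturation_consecutive = 2L,
                              v95_trigger_pct = 95, repair_loops = 2L,
                              eud_floor_Gy = 0.1,
                              eud_ceiling_Gy = prescription_Gy,
                              normal_tissue_weight = 1000,
                              normal_tissue_level_frac = 1.05,
                              classes = organ_classes(),
                              optimizer = optimizer_config(),
                              geud_exponents = c(heart = 1, lung_ipsi = 1,
                                                 lung_contra = 1,
                                                 breast_contra = 1)) {
  if (max_loops < 3) stop("max_loops must be >= 3 (Phases 1-3 must fit)")
  stopifnot(prescription_Gy > 0, ptv_weight > 0, oar_weight > 0,
            saturation_tol > 0, saturation_consecutive >= 1,
            v95_trigger_pct > 0, repair_loops >= 1, repair_loops <= 2,
            eud_floor_Gy > 0, eud_ceiling_Gy > eud_floor_Gy,
            normal_tissue_weight >= 0, normal_tissue_level_frac > 0)
  structure(list(prescription_Gy = prescription_Gy, ptv_weight = ptv_weight,
                 oar_weight = oar_weight, max_loops = as.integer(max_loops),
                 saturation_tol = saturation_tol,
                 saturation_consecutive = as.integer(saturation_consecutive),
                 v95_trigger_pct = v95_trigger_pct,
                 repair_loops = as.integer(repair_loops),
                 eud_floor_Gy = eud_floor_Gy, eud_ceiling_Gy = eud_ceiling_Gy,
                 normal_tissue_weight = normal_tissue_weight,
                 normal_tissue_level_frac = normal_tissue_level_frac,
                 classes = classes, optimizer = optimizer,
                 geud_exponents = geud_exponents),
            class = "ofv_controller_config")
}

controller_oars <- function(config) {
  c(config$classes$class2$members, config$classes$class1$members)
}

# Normal-tissue overdose term appended to every objective set (NULL when
# disabled).
normal_tissue_spec <- function(config) {
  if (config$normal_tissue_weight <= 0) return(NULL)
  list(objective_spec("external", "max_dose",
                      level = config$normal_tissue_level_frac *
                        config$prescription_Gy,
                      weight = config$normal_tissue_weight))
}

#' Phase-1 objective set
#'
#' PTV uniform dose at the prescription (weight `ptv_weight`); every OAR a
#' MaxEUD term with its limit set equal to the prescribed dose (weight
#' `oar_weight`).
#'
#' @param phantom an `ofv_phantom`.
#' @param config an `ofv_controller_config`.
#' @return list of `ofv_objective` terms (PTV first).
#' @export
init_phase1 <- function(phantom, config) {
  oars <- controller_oars(config)
  missing <- setdiff(c("PTV", oars), names(phantom$masks))
  if (length(missing))
    stop("phantom lacks required structure(s): ", paste(missing, collapse = ", "))
  specs <- list(objective_spec("PTV", "uniform_dose",
                               level = config$prescription_Gy,
                               weight = config$ptv_weight))
  for (o in oars) {
    a <- config$geud_exponents[[o]]
    if (is.null(a)) a <- 1
    specs <- c(specs, list(objective_spec(o, "max_eud",
                                          level = config$prescription_Gy,
                                          a = a, weight = config$oar_weight)))
  }
  c(specs, normal_tissue_spec(config))
}

#' Phase-2 objective set from the Phase-1 result
#'
#' Class-1 MaxEUD limits are set to 50 percent of the Phase-1 mean organ
#' dose, class-2 limits to 20 percent (the class `phase2_fraction`s).  A
#' zero Phase-1 mean dose falls back to the MaxEUD floor with a warning.
#'
#' @param phase1_report the `ofv_report` from the Phase-1 optimization.
#' @param classes an [organ_classes()] object.
#' @param config an `ofv_controller_config`.
#' @param phantom the `ofv_phantom`.
#' @return list of `ofv_objective` terms (PTV first).
#' @export
init_phase2 <- function(phase1_report, classes = organ_classes(), config,
                        phantom) {
  means <- stats::setNames(phase1_report$structures$mean_Gy,
                           phase1_report$structures$structure)
  specs <- list(objective_spec("PTV", "uniform_dose",
                               level = config$prescription_Gy,
                               weight = config$ptv_weight))
  for (o in controller_oars(config)) {
    cls <- organ_class_of(o, classes)
    if (is.na(means[[o]])) stop("no Phase-1 mean dose for '", o, "'")
    lvl <- cls$phase2_fraction * means[[o]]
    if (lvl <= 0) {
      warning("Phase-1 mean dose of '", o, "' is zero; MaxEUD set to floor (",
              config$eud_floor_Gy, " Gy)")
      lvl <- config$eud_floor_Gy
    }
    lvl <- min(max(lvl, config$eud_floor_Gy), config$eud_ceiling_Gy)
    a <- config$geud_exponents[[o]]
    if (is.null(a)) a <- 1
    specs <- c(specs, list(objective_spec(o, "max_eud", level = lvl, a = a,
                                          weight = config$oar_weight)))
  }
  c(specs, normal_tissue_spec(config))
}

ptv_v95 <- function(dose, phantom, prescription) {
  100 * mean(dose[phantom$masks$PTV] >= 0.95 * prescription)
}

#' Run the OFV-feedback controller
#'
#' Phase 1 (all MaxEUD limits at the prescription), Phase 2 (limits from the
#' Phase-1 mean doses), then repeated loops of: inner optimization
#' (warm-started from the previous fluence), per-organ OFV readout,
#' multiplier `s = m * OFV + n`, and clamped MaxEUD update - until every
#' class-2 organ has `|s - 1| <= saturation_tol` on
#' `saturation_consecutive` consecutive loops, or `max_loops` is reached.
#' Coverage repair ([repair_coverage()]) runs afterwards if the PTV V95
#' fell below the trigger.
#'
#' @param phantom an `ofv_phantom`.
#' @param beamset an `ofv_beamset`.
#' @param config an `ofv_controller_config`.
#' @param influence optional precomputed `ofv_influence` (computed with
#'   defaults when omitted).
#' @param verbose log one line per outer loop.
#' @return an `ofv_run`: list with `plan` (an `ofv_plan`: fluence, dose,
#'   objectives, report, phantom, influence, prescription) and `trajectory`
#'   (an `ofv_trajectory`: per-loop-per-organ and per-loop data frames,
#'   saturation flag and loop).
#' @export
run_controller <- function(phantom, beamset, config = controller_config(),
                           influence = NULL, verbose = FALSE) {
  stopifnot(inherits(phantom, "ofv_phantom"), inherits(beamset, "ofv_beamset"),
            inherits(config, "ofv_controller_config"))
  if (is.null(influence)) influence <- compute_influence(phantom, beamset)

  oars <- controller_oars(config)
  organ_rows <- list(); loop_rows <- list()
  s_history <- list()

  log_loop <- function(loop, phase, res, levels) {
    report <- res$report
    ofvs <- stats::setNames(report$terms$ofv[match(oars, report$terms$structure)], oars)
    means <- stats::setNames(
      report$structures$mean_Gy[match(oars, report$structures$structure)], oars)
    organ_rows[[length(organ_rows) + 1L]] <<- data.frame(
      loop = loop, organ = oars, ofv = as.numeric(ofvs),
      max_eud_Gy = as.numeric(levels[oars]), mean_dose_Gy = as.numeric(means))
    loop_rows[[length(loop_rows) + 1L]] <<- data.frame(
      loop = loop, phase = phase,
      ptv_ofv = report$terms$ofv[report$terms$structure == "PTV"][1],
      ptv_v95_pct = ptv_v95(res$dose, phantom, config$prescription_Gy),
      external_max_Gy = max(res$dose[phantom$masks$external]),
      total_objective = report$total)
    if (verbose)
      message(sprintf("loop %2d [%s]  total=%.4g  V95=%.1f%%  OFV: %s",
                      loop, phase, report$total,
                      loop_rows[[length(loop_rows)]]$ptv_v95_pct,
                      paste(sprintf("%s=%.3g", oars, ofvs), collapse = " ")))
    ofvs
  }

  # Phase 1
  objectives <- init_phase1(phantom, config)
  levels <- stats::setNames(rep(config$prescription_Gy, length(oars)), oars)
  fl <- initial_fluence(influence, phantom, config$prescription_Gy)
  res <- optimize_fluence(influence, objectives, fl, config$optimizer, phantom)
  log_loop(1L, "phase1", res, levels)
  phase1_report <- res$report

  # Phase 2
  objectives <- init_phase2(res$report, config$classes, config, phantom)
  levels <- stats::setNames(vapply(objectives[1L + seq_along(oars)],
                                   function(o) o$level, numeric(1)), oars)
  res <- optimize_fluence(influence, objectives, res$fluence,
                          config$optimizer, phantom)
  ofvs <- log_loop(2L, "phase2", res, levels)

  saturated <- FALSE
  saturation_loop <- NA_integer_
  s_vals <- vapply(oars, function(o)
    update_multiplier(ofvs[[o]], organ_class_of(o, config$classes)), numeric(1))
  s_history[[1L]] <- s_vals

  loop <- 2L
  while (loop < config$max_loops && !saturated) {
    loop <- loop + 1L
    # feedback update from the just-measured OFVs
    for (o in oars) levels[o] <- apply_update(levels[[o]], s_vals[[o]], config)
    objectives <- c(objectives[1],
                    lapply(oars, function(o) {
                      a <- config$geud_exponents[[o]]; if (is.null(a)) a <- 1
                      objective_spec(o, "max_eud", level = levels[[o]], a = a,
                                     weight = config$oar_weight)
                    }),
                    normal_tissue_spec(config))
    res <- optimize_fluence(influence, objectives, res$fluence,
                            config$optimizer, phantom)
    ofvs <- log_loop(loop, "phase3", res, levels)
    s_vals <- vapply(oars, function(o)
      update_multiplier(ofvs[[o]], organ_class_of(o, config$classes)), numeric(1))
    s_history[[length(s_history) + 1L]] <- s_vals

    class2 <- config$classes$class2$members
    k <- config$saturation_consecutive
    if (length(s_history) >= k) {
      recent <- s_history[seq(length(s_history) - k + 1L, length(s_history))]
      ok <- vapply(recent, function(s)
        all(abs(s[class2] - 1) <= config$saturation_tol), logical(1))
      if (all(ok)) { saturated <- TRUE; saturation_loop <- loop }
    }
  }

  plan <- structure(list(fluence = res$fluence, dose = res$dose,
                         objectives = objectives, report = res$report,
                         phantom = phantom, influence = influence,
                         prescription_Gy = config$prescription_Gy),
                    class = "ofv_plan")
  plan <- repair_coverage(plan, config, verbose = verbose)

  trajectory <- structure(
    list(organs = do.call(rbind, organ_rows),
         loops = do.call(rbind, loop_rows),
         saturated = saturated, saturation_loop = saturation_loop,
         phase1_report = phase1_report,
         repair = attr(plan, "repair")),
    class = "ofv_trajectory")
  structure(list(plan = plan, trajectory = trajectory), class = "ofv_run")
}

#' Repair PTV coverage via the 95 percent isodose
#'
#' If the plan's PTV V95 is below the trigger, the cold volume (the Boolean
#' difference between the PTV and the 95 percent isodose, i.e. PTV voxels
#' with dose below 0.95 times the prescription) receives an auxiliary
#' minimum-dose objective at 0.95 times the prescription with the PTV
#' weight, and one or two additional inner-optimizer runs are performed with
#' all MaxEUD limits frozen.  The repaired fluence is kept only if it did
#' not lower the PTV V95; otherwise the incoming plan is returned.
#'
#' @param plan an `ofv_plan`.
#' @param config an `ofv_controller_config`.
#' @param verbose log the repair outcome.
#' @return the (possibly repaired) `ofv_plan`, with an attribute `repair`
#'   describing what was done.
#' @export
repair_coverage <- function(plan, config, verbose = FALSE) {
  stopifnot(inherits(plan, "ofv_plan"))
  v95_before <- ptv_v95(plan$dose, plan$phantom, plan$prescription_Gy)
  if (v95_before >= config$v95_trigger_pct) {
    attr(plan, "repair") <- list(applied = FALSE, v95_before = v95_before,
                                 v95_after = v95_before)
    return(plan)
  }
  cold <- plan$phantom$masks$PTV &
    plan$dose < 0.95 * plan$prescription_Gy
  objectives <- c(plan$objectives,
                  list(objective_spec("PTV_cold", "min_dose",
                                      level = 0.95 * plan$prescription_Gy,
                                      weight = config$ptv_weight,
                                      mask = cold)))
  res <- list(fluence = plan$fluence)
  for (i in seq_len(config$repair_loops)) {
    res <- optimize_fluence(plan$influence, objectives, res$fluence,
                            config$optimizer, plan$phantom)
  }
  v95_after <- ptv_v95(res$dose, plan$phantom, plan$prescription_Gy)
  if (v95_after >= v95_before) {
    plan$fluence <- res$fluence
    plan$dose <- res$dose
    plan$report <- objective_report(plan$objectives, res$dose, plan$phantom)
  } else {
    v95_after <- v95_before   # repair rejected; original plan kept
  }
  if (verbose)
    message(sprintf("coverage repair: V95 %.2f%% -> %.2f%%", v95_before, v95_after))
  attr(plan, "repair") <- list(applied = TRUE, cold_voxels = sum(cold),
                               v95_before = v95_before, v95_after = v95_after)
  plan
}

#' @export
print.ofv_run <- function(x, ...) {
  tr <- x$trajectory
  cat("OFV-feedback run: ", max(tr$loops$loop), " outer loops, ",
      if (tr$saturated) paste0("saturated at loop ", tr$saturation_loop)
      else "stopped at max loops", "\n", sep = "")
  cat(sprintf("  final PTV V95 = %.2f%%, total objective = %.4g\n",
              attr(x$plan, "repair")$v95_after, x$plan$report$total))
  invisible(x)
}

#' Sweep the class-2 target OFV threshold
#'
#' Re-runs the controller once per requested class-2 target OFV; the class-2
#' slope is re-derived as `m = (1 - n) / target` so that the law's fixed
#' point moves to the target while the intercept stays fixed.
#'
#' @param phantom an `ofv_phantom`.
#' @param beamset an `ofv_beamset`.
#' @param config an `ofv_controller_config` (its class-2 descriptor is
#'   modified per threshold).
#' @param targets positive class-2 target OFVs (paper-style sweep:
#'   `c(1.25, 2, 2.25, 2.5, 3.25, 4.25)`).
#' @param influence optional precomputed `ofv_influence`.
#' @return data frame with one row per (threshold, organ): final mean dose,
#'   plus per-threshold PTV V95 and loop count.
#' @export
threshold_sweep <- function(phantom, beamset, config = controller_config(),
                            targets = c(1.25, 2, 2.25, 2.5, 3.25, 4.25),
                            influence = NULL) {
  if (length(targets) == 0) stop("targets must be nonempty")
  if (any(targets <= 0)) stop("targets must be positive")
  if (is.null(influence)) influence <- compute_influence(phantom, beamset)
  rows <- list()
  for (tg in targets) {
    cls2 <- config$classes$class2
    cfg <- config
    cfg$classes <- organ_classes(
      class1 = config$classes$class1[c("members", "m", "n", "target",
                                       "phase2_fraction")],
      class2 = list(members = cls2$members, m = (1 - cls2$n) / tg,
                    n = cls2$n, target = tg,
                    phase2_fraction = cls2$phase2_fraction))
    run <- run_controller(phantom, beamset, cfg, influence = influence)
    fin <- run$trajectory$organs[run$trajectory$organs$loop ==
                                   max(run$trajectory$organs$loop), ]
    rows[[length(rows) + 1L]] <- data.frame(
      target_ofv = tg, organ = fin$organ, mean_dose_Gy = fin$mean_dose_Gy,
      ptv_v95_pct = attr(run$plan, "repair")$v95_after,
      loops = max(run$trajectory$loops$loop))
  }
  do.call(rbind, rows)
}
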
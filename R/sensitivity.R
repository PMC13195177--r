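# Tuning-point calibration by sensitivity analysis: a scheduled reduction of
# the driven organ's MaxEUD limit, six tracked plan metrics per step,
# three-point smoothing, finite-difference change rates, clinical
# criticality masks, and the aggregate sensitivity score S(j) whose maximum
# marks the OFV tuning point.

#' Sensitivity-analysis settings
#'
#' The schedule drives one organ's MaxEUD limit down geometrically: step 1
#' optimizes the PTV alone (no OAR terms), step 2 sets the driven organ's
#' limit to 50 percent of its step-1 mean dose, step 3 halves it again, and
#' every later step multiplies the previous limit by `decay` (0.8).  All
#' other organs keep fixed companion limits throughout steps >= 2.
#'
#' @param n_steps number of optimization steps (>= 4).
#' @param decay geometric factor for steps >= 4.
#' @param driven_organ the organ whose limit follows the schedule.
#' @param companion_limits_Gy named fixed MaxEUD limits for the other
#'   organs (defaults: contralateral lung 1 Gy, contralateral breast 4 Gy,
#'   heart 2.5 Gy).
#' @param window moving-average window (odd).
#' @param ptv_d95_crit_Gy criticality threshold on the smoothed PTV D95
#'   (95 percent of a 50 Gy prescription: 47.5 Gy).
#' @param ext_max_crit_Gy criticality threshold on the smoothed external
#'   maximum dose (105 percent of the prescription: 52.5 Gy).
#' @param prescription_Gy,ptv_weight,oar_weight objective settings.
#' @param normal_tissue_weight,normal_tissue_level_frac normal-tissue
#'   overdose penalty included in every step (same convention as
#'   [controller_config()]); without it the external-max criticality
#'   threshold would be meaningless.
#' @param optimizer an [optimizer_config()].
#' @return an `ofv_sensitivity_config`.
#' @export
sensitivity_config <- function(n_steps = 12L, decay = 0.8,
                               driven_organ = "lung_ipsi",
                               companion_limits_Gy = c(lung_contra = 1,
                                                       breast_contra = 4,
                                                       heart = 2.5),
                               window = 3L,
                               ptv_d95_crit_Gy = 47.5,
                               ext_max_crit_Gy = 52.5,
                               prescription_Gy = 50, ptv_weight = 3000,
                               oar_weight = 10,
                               normal_tissue_weight = 1000,
                               normal_tissue_level_frac = 1.05,
                               optimizer = optimizer_config()) {
  if (n_steps < 4) stop("schedule must have at least 4 steps")
  if (window %% 2 == 0) stop("smoothing window must be odd")
  stopifnot(decay > 0, decay < 1, ptv_d95_crit_Gy > 0, ext_max_crit_Gy > 0,
            normal_tissue_weight >= 0, normal_tissue_level_frac > 0)
  structure(list(n_steps = as.integer(n_steps), decay = decay,
                 driven_organ = driven_organ,
                 companion_limits_Gy = companion_limits_Gy,
                 window = as.integer(window),
                 ptv_d95_crit_Gy = ptv_d95_crit_Gy,
                 ext_max_crit_Gy = ext_max_crit_Gy,
                 prescription_Gy = prescription_Gy, ptv_weight = ptv_weight,
                 oar_weight = oar_weight,
                 normal_tissue_weight = normal_tissue_weight,
                 normal_tissue_level_frac = normal_tissue_level_frac,
                 optimizer = optimizer),
            class = "ofv_sensitivity_config")
}

trace_metric_cols <- c("ptv_d95_Gy", "ptv_ofv", "ext_max_Gy",
                       "ext_v105_cm3", "oar_ofv", "oar_mean_Gy")

# dose received by at least `pct` percent of the structure's volume (Gy)
dose_at_volume_voxels <- function(dose, mask, pct) {
  d <- sort(dose[mask], decreasing = TRUE)
  d[ceiling(pct / 100 * length(d))]
}

#' Run the scheduled dose-reduction experiment
#'
#' One inner-optimizer run per schedule step (warm-started from the
#' previous step), recording per step: PTV D95 (the dose received by 95
#' percent of the PTV volume), PTV OFV, external maximum dose, external
#' pseudo-volume above 105 percent of the prescription, the driven organ's
#' OFV, and its mean dose.
#'
#' @param phantom an `ofv_phantom`.
#' @param beamset an `ofv_beamset`.
#' @param config an `ofv_sensitivity_config`.
#' @param influence optional precomputed `ofv_influence`.
#' @return an `ofv_trace`: data frame with columns `step`,
#'   `driven_limit_Gy` (NA at step 1) and the six metrics.
#' @export
run_schedule <- function(phantom, beamset, config = sensitivity_config(),
                         influence = NULL) {
  stopifnot(inherits(phantom, "ofv_phantom"),
            inherits(config, "ofv_sensitivity_config"))
  if (is.null(influence)) influence <- compute_influence(phantom, beamset)
  rx <- config$prescription_Gy
  companions <- config$companion_limits_Gy
  companions <- companions[setdiff(names(companions), config$driven_organ)]
  if (!config$driven_organ %in% names(phantom$masks))
    stop("unknown driven organ '", config$driven_organ, "'")

  ptv_term <- objective_spec("PTV", "uniform_dose", level = rx,
                             weight = config$ptv_weight)
  nt_term <- normal_tissue_spec(config)   # shares the controller's plan style
  step_objectives <- function(driven_limit) {
    c(list(ptv_term),
      lapply(names(companions), function(o)
        objective_spec(o, "max_eud", level = companions[[o]],
                       weight = config$oar_weight)),
      list(objective_spec(config$driven_organ, "max_eud",
                          level = driven_limit, weight = config$oar_weight)),
      nt_term)
  }

  rows <- vector("list", config$n_steps)
  fl <- initial_fluence(influence, phantom, rx)
  driven_limit <- NA_real_
  m1 <- NA_real_

  for (j in seq_len(config$n_steps)) {
    objectives <- if (j == 1) c(list(ptv_term), nt_term)
      else step_objectives(driven_limit)
    res <- optimize_fluence(influence, objectives, fl, config$optimizer,
                            phantom)
    fl <- res$fluence
    dose <- res$dose
    oar_mask <- phantom$masks[[config$driven_organ]]
    oar_mean <- mean(dose[oar_mask])
    if (j == 1) {
      m1 <- oar_mean
      oar_ofv <- 0       # no OAR term in the first step
    } else {
      idx <- vapply(objectives, function(o)
        identical(o$structure, config$driven_organ), logical(1))
      oar_ofv <- objective_value(objectives[idx][[1]], dose, phantom)
    }
    ext <- phantom$masks$external
    rows[[j]] <- data.frame(
      step = j, driven_limit_Gy = driven_limit,
      ptv_d95_Gy = dose_at_volume_voxels(dose, phantom$masks$PTV, 95),
      ptv_ofv = objective_value(ptv_term, dose, phantom),
      ext_max_Gy = max(dose[ext]),
      ext_v105_cm3 = sum(dose[ext] > 1.05 * rx) * phantom$voxel_volume_cm3,
      oar_ofv = oar_ofv, oar_mean_Gy = oar_mean)
    # next step's driven limit: 0.5 * m1, 0.25 * m1, then geometric decay
    driven_limit <- if (j == 1) 0.5 * m1
      else if (j == 2) 0.5 * driven_limit
      else config$decay * driven_limit
    driven_limit <- max(driven_limit, 1e-3)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ofv_trace", class(out))
  out
}

#' Smooth a metric trace with a centered moving average
#'
#' Each metric column is replaced by its centered moving average; at the
#' edges the window is truncated to the available steps.
#'
#' @param trace an `ofv_trace` (or data frame with the metric columns).
#' @param window odd window length, at most the trace length.
#' @return the smoothed trace (same shape).
#' @export
smooth_trace <- function(trace, window = 3L) {
  if (window %% 2 == 0) stop("window must be odd")
  n <- nrow(trace)
  if (window > n) stop("window longer than trace")
  half <- (window - 1L) %/% 2L
  out <- trace
  for (cn in intersect(trace_metric_cols, names(trace))) {
    v <- trace[[cn]]
    out[[cn]] <- vapply(seq_len(n), function(i) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      mean(v[lo:hi])
    }, numeric(1))
  }
  out
}

#' Finite-difference change rates of a metric trace
#'
#' `delta m(j) = m(j) - m(j - 1)` per metric, indexed by the later step
#' `j = 2 .. n`, so that a rate row and the trace row describing the state
#' it leads to share the step index.
#'
#' @param trace an `ofv_trace` (usually smoothed).
#' @return data frame of per-metric differences with a `step` column
#'   (`2 .. n`), `n - 1` rows.
#' @export
change_rates <- function(trace) {
  n <- nrow(trace)
  if (n < 2) stop("need at least 2 steps to compute change rates")
  cols <- intersect(trace_metric_cols, names(trace))
  out <- data.frame(step = trace$step[-1])
  for (cn in cols) out[[cn]] <- diff(trace[[cn]])
  out
}

#' Clinical criticality masks
#'
#' Four boolean series aligned with the change rates (steps `2 .. n`):
#' \itemize{
#'   \item `ptv_cov`: smoothed PTV D95 below `ptv_d95_crit_Gy` (47.5 Gy);
#'   \item `lung_slope`: absolute change of the driven organ's mean dose
#'     strictly below its own median;
#'   \item `ext_max`: smoothed external maximum strictly above
#'     `ext_max_crit_Gy` (52.5 Gy);
#'   \item `ext_v105`: change of the external volume above 105 percent
#'     strictly above its own median.
#' }
#' Median comparisons are strict, so ties are excluded from criticality.
#'
#' @param trace the smoothed `ofv_trace`.
#' @param rates the matching [change_rates()] output.
#' @param config an `ofv_sensitivity_config` (thresholds).
#' @return data frame with `step` and the four logical columns.
#' @export
criticality_masks <- function(trace, rates, config = sensitivity_config()) {
  if (nrow(rates) != nrow(trace) - 1)
    stop("rates are not aligned with the trace")
  at <- match(rates$step, trace$step)
  data.frame(
    step = rates$step,
    ptv_cov = trace$ptv_d95_Gy[at] < config$ptv_d95_crit_Gy,
    lung_slope = abs(rates$oar_mean_Gy) < stats::median(abs(rates$oar_mean_Gy)),
    ext_max = trace$ext_max_Gy[at] > config$ext_max_crit_Gy,
    ext_v105 = rates$ext_v105_cm3 > stats::median(rates$ext_v105_cm3))
}

#' Aggregate sensitivity score S(j)
#'
#' `S(j)` sums, over the four criticality-masked metrics, the absolute
#' change rate at step `j` wherever that metric's mask is true.  The tuning
#' point `j*` is the step maximizing `S(j)`; ties break toward the earliest
#' step (the most conservative sparing).  When a smoothed trace is
#' supplied, the OFV attributed to the tuning point is its `oar_ofv` at
#' `j*`.
#'
#' @param rates [change_rates()] output.
#' @param masks [criticality_masks()] output, same steps.
#' @param trace optional smoothed trace used to read the OFV at `j*`.
#' @return an `ofv_sensitivity_result`: list with `score` (data frame
#'   `step`, `S`), `j_star`, `ofv_at_jstar` (NA without a trace).
#' @export
sensitivity_score <- function(rates, masks, trace = NULL) {
  if (!identical(rates$step, masks$step))
    stop("rates and masks are not aligned")
  S <- abs(rates$ptv_d95_Gy) * masks$ptv_cov +
    abs(rates$oar_mean_Gy) * masks$lung_slope +
    abs(rates$ext_max_Gy) * masks$ext_max +
    abs(rates$ext_v105_cm3) * masks$ext_v105
  if (all(S == 0))
    warning("no metric met any criticality criterion; S(j) is identically 0")
  j_star <- rates$step[which.max(S)]   # first maximum = earliest step
  ofv <- NA_real_
  if (!is.null(trace)) ofv <- trace$oar_ofv[match(j_star, trace$step)]
  structure(list(score = data.frame(step = rates$step, S = S),
                 j_star = j_star, ofv_at_jstar = ofv),
            class = "ofv_sensitivity_result")
}

#' @export
print.ofv_sensitivity_result <- function(x, ...) {
  cat("Sensitivity score: j* = ", x$j_star, ", OFV at j* = ",
      format(x$ofv_at_jstar, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Derive the OFV tuning points over a set of phantoms
#'
#' Runs the full schedule-smooth-rate-mask-score pipeline once per phantom
#' for the class-2 configuration (driving the ipsilateral lung) and once
#' for a class-1 configuration (driving the contralateral breast, with the
#' ipsilateral lung held at a fixed companion limit), then averages the OFV
#' at the tuning point across phantoms.
#'
#' @param phantoms list of `ofv_phantom`s (>= 1).
#' @param beamsets list of matching `ofv_beamset`s.
#' @param config an `ofv_sensitivity_config` for the class-2 run; the
#'   class-1 run swaps the driven organ to `breast_contra` and fixes the
#'   ipsilateral lung at `lung_ipsi_limit_Gy`.
#' @param lung_ipsi_limit_Gy companion limit for the ipsilateral lung in
#'   the class-1 run (its mean-dose clinical goal, 10 Gy).
#' @param influences optional list of precomputed `ofv_influence`s.
#' @return list with `class2_mean_ofv`, `class1_mean_ofv`, and
#'   `per_phantom` (data frame: phantom, class, j_star, ofv).
#' @export
derive_tuning_points <- function(phantoms, beamsets,
                                 config = sensitivity_config(),
                                 lung_ipsi_limit_Gy = 10,
                                 influences = NULL) {
  if (length(phantoms) < 1) stop("need at least one phantom")
  if (length(beamsets) != length(phantoms))
    stop("one beamset per phantom required")
  cfg1 <- config
  cfg1$driven_organ <- "breast_contra"
  cfg1$companion_limits_Gy <- c(lung_contra = 1, heart = 2.5,
                                lung_ipsi = lung_ipsi_limit_Gy)
  rows <- list()
  for (i in seq_along(phantoms)) {
    inf <- if (is.null(influences)) compute_influence(phantoms[[i]],
                                                      beamsets[[i]])
           else influences[[i]]
    for (lbl in c("class2", "class1")) {
      cfg <- if (lbl == "class2") config else cfg1
      tr <- run_schedule(phantoms[[i]], beamsets[[i]], cfg, influence = inf)
      sm <- smooth_trace(tr, cfg$window)
      rt <- change_rates(sm)
      mk <- criticality_masks(sm, rt, cfg)
      sc <- sensitivity_score(rt, mk, trace = sm)
      rows[[length(rows) + 1L]] <- data.frame(
        phantom = i, class = lbl, j_star = sc$j_star, ofv = sc$ofv_at_jstar)
    }
  }
  per <- do.call(rbind, rows)
  list(class2_mean_ofv = mean(per$ofv[per$class == "class2"]),
       class1_mean_ofv = mean(per$ofv[per$class == "class1"]),
       per_phantom = per)
}
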
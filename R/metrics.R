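# Plan-quality evaluation: cumulative DVH, V/D queries, Paddick conformity
# index, homogeneity index, and clinical-goal checks.

#' Cumulative dose-volume histogram
#'
#' Bins are half-open `[edge, edge + width)`; the cumulative curve gives
#' the percentage of the structure's volume receiving at least each bin
#' edge's dose, so it is nonincreasing and starts at 100 percent at 0 Gy.
#'
#' @param dose dose matrix (Gy).
#' @param mask non-empty logical structure mask.
#' @param bin_width_Gy bin width (> 0), default 0.1 Gy.
#' @param structure optional structure name carried in the result.
#' @param voxel_volume_cm3 voxel pseudo-volume used for absolute-volume
#'   queries.
#' @return an `ofv_dvh`: list with `structure`, `edges_Gy`, `volume_pct`,
#'   `total_volume_cm3`.
#' @export
compute_dvh <- function(dose, mask, bin_width_Gy = 0.1, structure = "",
                        voxel_volume_cm3 = 1) {
  if (!any(mask)) stop("empty mask")
  if (bin_width_Gy <= 0) stop("bin width must be > 0")
  d <- dose[mask]
  n_bins <- floor(max(d) / bin_width_Gy) + 2L
  edges <- (seq_len(n_bins) - 1L) * bin_width_Gy
  counts <- tabulate(findInterval(d, edges), nbins = n_bins)
  cum <- rev(cumsum(rev(counts)))          # voxels with dose >= edge
  structure(list(structure = structure, edges_Gy = edges,
                 volume_pct = 100 * cum / length(d),
                 total_volume_cm3 = length(d) * voxel_volume_cm3),
            class = "ofv_dvh")
}

#' Volume receiving at least a given dose
#'
#' Linear interpolation of the cumulative DVH between bin edges.
#'
#' @param dvh an `ofv_dvh`.
#' @param dose_Gy query dose (>= 0).
#' @return list with `pct` (percent of structure volume) and `cm3`
#'   (pseudo-volume).
#' @export
v_at_dose <- function(dvh, dose_Gy) {
  if (dose_Gy < 0) stop("dose must be >= 0")
  pct <- stats::approx(dvh$edges_Gy, dvh$volume_pct, xout = dose_Gy,
                       yleft = 100, yright = 0, ties = "ordered")$y
  list(pct = pct, cm3 = pct / 100 * dvh$total_volume_cm3)
}

#' Dose received by the hottest given percentage of a structure
#'
#' Inverse DVH query: the dose `D` with `V(D) = v`, interpolated linearly
#' within the bin where the cumulative curve crosses `v`.  On flat
#' segments the highest dose still covering `v` percent is returned.
#'
#' @param dvh an `ofv_dvh`.
#' @param volume_pct query volume in percent, in `(0, 100]`.
#' @return dose in Gy.
#' @export
d_at_volume <- function(dvh, volume_pct) {
  if (volume_pct <= 0 || volume_pct > 100)
    stop("volume_pct must be in (0, 100]")
  pct <- dvh$volume_pct; e <- dvh$edges_Gy
  i <- max(which(pct >= volume_pct))       # last edge still covering v
  if (i == length(e)) return(e[i])
  e[i] + (e[i + 1] - e[i]) * (pct[i] - volume_pct) / (pct[i] - pct[i + 1])
}

#' Paddick conformity index
#'
#' `CI = (PIV_PTV / PTV_VOL) * (PIV_PTV / PIV_EXT)` where `PIV_PTV` is the
#' PTV volume covered by the 95 percent isodose (closed threshold,
#' `dose >= 0.95 * prescription`), `PTV_VOL` the total PTV volume, and
#' `PIV_EXT` the external-contour volume at or above that isodose.  Ranges
#' over `[0, 1]`; 1 only at perfect conformity.
#'
#' @param dose dose matrix (Gy).
#' @param ptv_mask,external_mask non-empty logical masks.
#' @param prescription_Gy prescription dose.
#' @return dimensionless CI.
#' @export
paddick_ci <- function(dose, ptv_mask, external_mask, prescription_Gy) {
  if (!any(ptv_mask) || !any(external_mask)) stop("empty mask")
  th <- 0.95 * prescription_Gy
  piv_ptv <- sum(ptv_mask & dose >= th)
  piv_ext <- sum(external_mask & dose >= th)
  if (piv_ext == 0) {
    warning("no tissue reaches the 95% isodose; CI defined as 0")
    return(0)
  }
  (piv_ptv / sum(ptv_mask)) * (piv_ptv / piv_ext)
}

#' Homogeneity index
#'
#' `HI = D_5 / D_95` of the PTV: the ratio of the doses received by the
#' hottest 5 percent and the hottest 95 percent of the target.  1 for a
#' perfectly uniform target dose, larger otherwise.
#'
#' @param dvh the PTV's `ofv_dvh`.
#' @return dimensionless HI (>= 1).
#' @export
homogeneity_index <- function(dvh) {
  d95 <- d_at_volume(dvh, 95)
  if (d95 == 0) stop("D95 is zero; HI undefined")
  d_at_volume(dvh, 5) / d95
}

#' Default clinical goal set
#'
#' Institutional planning goals: ipsilateral lung mean < 10 Gy, V10 < 35
#' percent, V20 < 20 percent; contralateral lung mean < 2 Gy; heart mean
#' <= 2.5 Gy; contralateral breast mean <= 2 Gy.
#'
#' @return data frame with columns `structure`, `metric`, `comparator`,
#'   `limit`.
#' @export
default_clinical_goals <- function() {
  data.frame(
    structure = c("lung_ipsi", "lung_ipsi", "lung_ipsi", "lung_contra",
                  "heart", "breast_contra"),
    metric = c("mean", "V10Gy", "V20Gy", "mean", "mean", "mean"),
    comparator = c("<", "<", "<", "<", "<=", "<="),
    limit = c(10, 35, 20, 2, 2.5, 2))
}

goal_metric_value <- function(metric, dose, mask, voxel_volume_cm3) {
  if (metric == "mean") return(mean(dose[mask]))
  if (metric == "max") return(max(dose[mask]))
  vm <- regmatches(metric, regexec("^V([0-9.]+)Gy$", metric))[[1]]
  if (length(vm) == 2) {
    dvh <- compute_dvh(dose, mask, voxel_volume_cm3 = voxel_volume_cm3)
    return(v_at_dose(dvh, as.numeric(vm[2]))$pct)
  }
  dm <- regmatches(metric, regexec("^D([0-9.]+)%$", metric))[[1]]
  if (length(dm) == 2) {
    dvh <- compute_dvh(dose, mask, voxel_volume_cm3 = voxel_volume_cm3)
    return(d_at_volume(dvh, as.numeric(dm[2])))
  }
  stop("unknown metric '", metric, "'")
}

#' Evaluate clinical goals against a plan
#'
#' @param plan an `ofv_plan` (or a list with `dose` and `phantom`).
#' @param goals data frame as produced by [default_clinical_goals()];
#'   comparators may be `<`, `<=`, `>`, `>=` and are applied strictly as
#'   written.
#' @return the goals data frame with added `value` and `pass` columns.
#' @export
evaluate_goals <- function(plan, goals = default_clinical_goals()) {
  dose <- plan$dose; phantom <- plan$phantom
  value <- numeric(nrow(goals)); pass <- logical(nrow(goals))
  for (i in seq_len(nrow(goals))) {
    m <- phantom$masks[[goals$structure[i]]]
    if (is.null(m)) stop("unknown structure '", goals$structure[i], "'")
    value[i] <- goal_metric_value(goals$metric[i], dose, m,
                                  phantom$voxel_volume_cm3)
    pass[i] <- switch(goals$comparator[i],
                      "<" = value[i] < goals$limit[i],
                      "<=" = value[i] <= goals$limit[i],
                      ">" = value[i] > goals$limit[i],
                      ">=" = value[i] >= goals$limit[i],
                      stop("unknown comparator '", goals$comparator[i], "'"))
  }
  cbind(goals, value = value, pass = pass)
}

#' Summary metrics of a plan
#'
#' @param plan an `ofv_plan`.
#' @param bin_width_Gy DVH bin width.
#' @return list with per-structure mean/max doses, PTV V95 (percent),
#'   Paddick CI, HI, external maximum, and the DVHs used.
#' @export
plan_metrics <- function(plan, bin_width_Gy = 0.1) {
  ph <- plan$phantom; dose <- plan$dose
  dvhs <- lapply(names(ph$masks), function(s)
    compute_dvh(dose, ph$masks[[s]], bin_width_Gy, structure = s,
                voxel_volume_cm3 = ph$voxel_volume_cm3))
  names(dvhs) <- names(ph$masks)
  list(
    structures = data.frame(
      structure = names(ph$masks),
      mean_Gy = vapply(names(ph$masks), function(s) mean(dose[ph$masks[[s]]]),
                       numeric(1)),
      max_Gy = vapply(names(ph$masks), function(s) max(dose[ph$masks[[s]]]),
                      numeric(1)), row.names = NULL),
    ptv_v95_pct = ptv_v95(dose, ph, plan$prescription_Gy),
    ci_paddick = paddick_ci(dose, ph$masks$PTV, ph$masks$external,
                            plan$prescription_Gy),
    hi = homogeneity_index(dvhs$PTV),
    external_max_Gy = max(dose[ph$masks$external]),
    dvhs = dvhs)
}
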
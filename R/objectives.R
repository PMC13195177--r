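# Dose computation, gEUD, and the composite objective whose per-term values
# are the OFVs read by the feedback controller.
#
# Term forms (w = weight, d_i = voxel doses on the term's structure):
#   uniform_dose, level L:  w * mean(((d_i - L) / L)^2)
#   max_eud, limit E0:      w * (max(0, gEUD_a(d) - E0) / E0)^2
#   min_dose, level L:      w * mean((max(0, L - d_i) / L)^2)
#   max_dose, level L:      w * mean((max(0, d_i - L) / L)^2)
# Each term is normalized by its own dose level.  For the MaxEUD term this
# means the OFV grows without bound as the limit is tightened below what the
# geometry permits, which is what lets the linear feedback law find a stable
# fixed point at the target OFV for any anatomy.

#' Construct one objective term
#'
#' @param structure structure name (must exist in the phantom's masks), or
#'   supply an explicit logical `mask` for ad-hoc structures such as the
#'   coverage-repair cold volume.
#' @param kind one of `"uniform_dose"`, `"max_eud"`, `"min_dose"`,
#'   `"max_dose"` (the normal-tissue overdose penalty).
#' @param level dose level in Gy: the prescription for `uniform_dose`, the
#'   MaxEUD limit for `max_eud`, the minimum-dose threshold for `min_dose`,
#'   the overdose threshold for `max_dose`.
#' @param a gEUD exponent (>= 1), used by `max_eud`; `a = 1` is mean dose.
#' @param weight positive term weight.
#' @param mask optional logical matrix overriding the named structure.
#' @return an `ofv_objective`.
#' @export
objective_spec <- function(structure, kind = c("uniform_dose", "max_eud",
                                               "min_dose", "max_dose"),
                           level, a = 1, weight = 1, mask = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(level) || level <= 0) stop("level must be > 0")
  if (!is.numeric(weight) || weight <= 0) stop("weight must be > 0")
  if (kind == "max_eud" && a < 1) stop("gEUD exponent a must be >= 1")
  structure(list(structure = structure, kind = kind, level = level,
                 a = a, weight = weight, mask = mask),
            class = "ofv_objective")
}

term_mask <- function(spec, phantom) {
  if (!is.null(spec$mask)) return(spec$mask)
  m <- phantom$masks[[spec$structure]]
  if (is.null(m)) stop("unknown structure '", spec$structure, "'")
  m
}

#' Compute the dose grid from a fluence vector
#'
#' @param influence an `ofv_influence`.
#' @param fluence nonnegative numeric vector, one entry per beamlet.
#' @return dose matrix (Gy) with the influence grid's shape.
#' @export
compute_dose <- function(influence, fluence) {
  stopifnot(inherits(influence, "ofv_influence"))
  if (length(fluence) != influence$n_beamlets)
    stop("fluence length (", length(fluence), ") does not match beamlet count (",
         influence$n_beamlets, ")")
  if (any(fluence < 0)) stop("fluence must be nonnegative")
  matrix(as.numeric(influence$A %*% fluence),
         influence$grid_shape[1], influence$grid_shape[2])
}

#' Generalized equivalent uniform dose
#'
#' `gEUD_a(d) = (mean(d_i^a))^(1/a)` over the voxels of `mask`; `a = 1`
#' gives the arithmetic mean dose, large `a` approaches the maximum dose.
#'
#' @param dose dose matrix or vector (Gy).
#' @param mask logical mask selecting the structure's voxels (non-empty).
#' @param a exponent, `a >= 1`.
#' @return gEUD in Gy.
#' @export
geud <- function(dose, mask, a = 1) {
  if (!any(mask)) stop("empty mask")
  if (a < 1) stop("gEUD exponent a must be >= 1")
  d <- dose[mask]
  if (a == 1) return(mean(d))
  m <- max(d)
  if (m == 0) return(0)
  m * mean((d / m)^a)^(1 / a)   # scaled to avoid overflow at large a
}

#' Objective function value (OFV) of one term
#'
#' Evaluates the term's weighted penalty on a dose grid.  This is the value
#' the feedback controller reads per organ: the per-term OFV includes the
#' term weight.
#'
#' @param spec an `ofv_objective`.
#' @param dose dose matrix (Gy).
#' @param phantom the `ofv_phantom` supplying structure masks.
#' @return nonnegative dimensionless OFV.
#' @export
objective_value <- function(spec, dose, phantom) {
  m <- term_mask(spec, phantom)
  if (!any(m)) stop("empty mask for structure '", spec$structure, "'")
  d <- dose[m]
  L <- spec$level
  switch(spec$kind,
    uniform_dose = spec$weight * mean(((d - L) / L)^2),
    max_eud = {
      g <- geud(dose, m, spec$a)
      spec$weight * (max(0, g - L) / L)^2
    },
    min_dose = spec$weight * mean((pmax(0, L - d) / L)^2),
    max_dose = spec$weight * mean((pmax(0, d - L) / L)^2))
}

# Gradient of one term with respect to the voxel doses (dense vector over
# the full grid; zero outside the term's mask).
objective_gradient_dose <- function(spec, dose, phantom) {
  m <- term_mask(spec, phantom)
  d <- dose[m]
  L <- spec$level
  n <- length(d)
  g <- numeric(length(dose))
  gm <- switch(spec$kind,
    uniform_dose = 2 * spec$weight * (d - L) / (n * L^2),
    max_eud = {
      ge <- geud(dose, m, spec$a)
      ex <- max(0, ge - L)
      if (ex == 0) numeric(n) else if (spec$a == 1) {
        rep(2 * spec$weight * ex / (L^2 * n), n)
      } else {
        # d(gEUD)/dd_i = d_i^(a-1) * gEUD^(1-a) / n
        2 * spec$weight * ex / L^2 * (d^(spec$a - 1)) * ge^(1 - spec$a) / n
      }
    },
    min_dose = -2 * spec$weight * pmax(0, L - d) / (n * L^2),
    max_dose = 2 * spec$weight * pmax(0, d - L) / (n * L^2))
  g[m] <- gm
  g
}

#' Evaluate a full objective set on a dose grid
#'
#' @param objectives list of `ofv_objective` terms.
#' @param dose dose matrix (Gy).
#' @param phantom the `ofv_phantom`.
#' @return object of class `ofv_report`: data frame `terms` (structure,
#'   kind, level, weight, ofv), scalar `total`, and data frame `structures`
#'   with per-structure mean and max dose.
#' @export
objective_report <- function(objectives, dose, phantom) {
  vals <- vapply(objectives, objective_value, numeric(1),
                 dose = dose, phantom = phantom)
  terms <- data.frame(
    structure = vapply(objectives, function(o) o$structure, character(1)),
    kind = vapply(objectives, function(o) o$kind, character(1)),
    level_Gy = vapply(objectives, function(o) o$level, numeric(1)),
    weight = vapply(objectives, function(o) o$weight, numeric(1)),
    ofv = vals)
  snames <- names(phantom$masks)
  structures <- data.frame(
    structure = snames,
    mean_Gy = vapply(snames, function(s) mean(dose[phantom$masks[[s]]]), numeric(1)),
    max_Gy = vapply(snames, function(s) max(dose[phantom$masks[[s]]]), numeric(1)),
    row.names = NULL)
  structure(list(terms = terms, total = sum(vals), structures = structures),
            class = "ofv_report")
}

#' @export
print.ofv_report <- function(x, ...) {
  cat("Objective report (total = ", format(x$total, digits = 5), ")\n", sep = "")
  print(x$terms, row.names = FALSE)
  invisible(x)
}

# Total objective and its gradient with respect to fluence; used by the
# inner optimizer.
total_objective <- function(objectives, influence, fluence, phantom) {
  dose <- compute_dose(influence, fluence)
  sum(vapply(objectives, objective_value, numeric(1),
             dose = dose, phantom = phantom))
}

total_gradient_fluence <- function(objectives, influence, fluence, phantom) {
  dose <- compute_dose(influence, fluence)
  gd <- numeric(length(dose))
  for (o in objectives) gd <- gd + objective_gradient_dose(o, dose, phantom)
  as.numeric(influence$At %*% gd)
}
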
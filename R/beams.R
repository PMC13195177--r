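# Coplanar arc beam geometry and the pencil-beam influence matrix.
#
# Gantry angles follow IEC 61217: 0 deg = beam entering from anterior,
# 90 deg = from the patient's right, 270 deg = from the patient's left.
# The source for angle theta sits at R * (-sin(theta), cos(theta)) in the
# phantom's (x = patient-left, y = anterior) frame and beamlets travel as
# parallel rays toward the patient (large source distance approximation).

default_arc <- function(laterality) {
  if (laterality == "left") c(180, 288) else c(180, 72)
}

#' Build a coplanar arc beam set
#'
#' Places `n_angles` evenly spaced control angles on the gantry arc
#' (inclusive of both endpoints; the arc is traversed from `arc_start`
#' toward `arc_stop`, decreasing when `arc_stop < arc_start` as for
#' right-sided treatments) and, at every angle, lays out
#' `beamlets_per_angle` parallel beamlets whose lateral offsets span the
#' PTV's projection onto the beam's-eye axis plus `margin_mm` on each side.
#'
#' @param phantom an `ofv_phantom`.
#' @param arc_start,arc_stop arc endpoints in degrees on the IEC gantry
#'   circle; defaults depend on laterality (left: 180-288, right: 180-72).
#' @param n_angles number of control angles (>= 2).
#' @param beamlets_per_angle beamlets per control angle.
#' @param margin_mm lateral margin added beyond the PTV projection.
#' @param source_distance_mm nominal source-axis distance (metadata; rays are
#'   parallel).
#' @return object of class `ofv_beamset`: gantry angles (deg), per-angle
#'   beamlet lateral offsets (mm, relative to the isocenter at the PTV
#'   centroid), beam unit vectors, grid descriptor.
#' @export
build_beamset <- function(phantom, arc_start = NULL, arc_stop = NULL,
                          n_angles = 28L, beamlets_per_angle = 24L,
                          margin_mm = 10, source_distance_mm = 1000) {
  stopifnot(inherits(phantom, "ofv_phantom"))
  if (is.null(arc_start) || is.null(arc_stop)) {
    arc <- default_arc(phantom$laterality)
    if (is.null(arc_start)) arc_start <- arc[1]
    if (is.null(arc_stop)) arc_stop <- arc[2]
  }
  if (arc_start == arc_stop) stop("degenerate arc: zero span")
  if (n_angles < 2) stop("n_angles must be >= 2")
  if (beamlets_per_angle < 1) stop("beamlets_per_angle must be >= 1")

  angles <- seq(arc_start, arc_stop, length.out = n_angles)

  xy <- voxel_coords(phantom$grid_shape, phantom$spacing_mm)
  ptv <- phantom$masks$PTV
  iso <- c(mean(xy$x[ptv]), mean(xy$y[ptv]))

  th <- angles * pi / 180
  # beam direction (from source toward patient) and beam's-eye lateral axis
  dir <- cbind(sin(th), -cos(th))
  lat <- cbind(cos(th), sin(th))

  px <- xy$x[ptv] - iso[1]; py <- xy$y[ptv] - iso[2]
  offsets <- matrix(0, n_angles, beamlets_per_angle)
  for (k in seq_len(n_angles)) {
    v <- px * lat[k, 1] + py * lat[k, 2]
    lo <- min(v) - margin_mm; hi <- max(v) + margin_mm
    offsets[k, ] <- if (beamlets_per_angle == 1) (lo + hi) / 2 else
      seq(lo, hi, length.out = beamlets_per_angle)
  }

  structure(list(gantry_angles = angles %% 360,
                 arc_start = arc_start, arc_stop = arc_stop,
                 beamlets_per_angle = as.integer(beamlets_per_angle),
                 offsets_mm = offsets, dir = dir, lat = lat,
                 isocenter_mm = iso,
                 source_distance_mm = source_distance_mm,
                 grid_shape = phantom$grid_shape,
                 spacing_mm = phantom$spacing_mm),
            class = "ofv_beamset")
}

#' @export
print.ofv_beamset <- function(x, ...) {
  cat("Arc beam set: ", length(x$gantry_angles), " angles, ",
      x$arc_start, " -> ", x$arc_stop, " deg, ",
      x$beamlets_per_angle, " beamlets/angle (",
      length(x$gantry_angles) * x$beamlets_per_angle, " total)\n", sep = "")
  invisible(x)
}

# Radiological depth (mm) from the external-contour entry point, for each
# voxel listed in `idx` (linear indices), along direction -dir toward the
# source.  Ray marching at half-voxel steps with nearest-voxel membership
# lookups; positions outside the grid count as outside the contour.
ray_depths <- function(external, xs, ys, dir, spacing_mm, grid_shape,
                       step_mm = spacing_mm / 2) {
  nr <- grid_shape[1]; nc <- grid_shape[2]
  smax <- sqrt((nr * spacing_mm)^2 + (nc * spacing_mm)^2)
  steps <- seq(step_mm / 2, smax, by = step_mm)
  depth <- numeric(length(xs))
  ext <- external
  for (s in steps) {
    qx <- xs - s * dir[1]
    qy <- ys - s * dir[2]
    col <- round(qx / spacing_mm + (nc + 1) / 2)
    row <- round((nr + 1) / 2 - qy / spacing_mm)
    ok <- col >= 1 & col <= nc & row >= 1 & row <= nr
    if (!any(ok)) break
    hit <- logical(length(xs))
    hit[ok] <- ext[cbind(row[ok], col[ok])]
    depth <- depth + step_mm * hit
  }
  depth
}

#' Compute the beamlet-to-voxel influence matrix
#'
#' Pencil-beam surrogate dose model with a two-Gaussian lateral kernel:
#' each beamlet deposits
#' `exp(-mu * depth) * (exp(-u^2 / (2 sigma^2)) + f_s * exp(-u^2 / (2 sigma_s^2)))`
#' Gy per unit fluence at a voxel, where `depth` is the radiological path
#' length (mm) from the external-contour entry point to the voxel along the
#' ray and `u` is the voxel's lateral distance (mm) from the beamlet axis.
#' The narrow Gaussian is the primary pencil beam; the broad, low-amplitude
#' component (`f_s = scatter_fraction`, `sigma_s = scatter_sigma`) models
#' phantom scatter and collimator transmission.  Without it every voxel a
#' few sigma outside the fields would receive mathematically zero dose, so
#' organs at risk could be "spared" perfectly and without cost - which no
#' physical dose engine allows and which would remove the coverage/sparing
#' trade-off this package exists to study.  Coefficients are zero outside
#' the external contour and beyond `cutoff_sigma` standard deviations of
#' each component.
#'
#' @param phantom an `ofv_phantom`.
#' @param beamset an `ofv_beamset` built on the same grid.
#' @param attenuation linear attenuation coefficient mu, per mm (> 0).
#' @param lateral_sigma primary Gaussian lateral spread sigma, mm (> 0).
#' @param scatter_fraction amplitude of the broad scatter component
#'   relative to the primary peak (>= 0; 0 disables it).
#' @param scatter_sigma lateral spread of the scatter component, mm (> 0).
#' @param cutoff_sigma lateral truncation of each Gaussian, in its own
#'   sigmas.
#' @return object of class `ofv_influence`: sparse `A` (voxels x beamlets,
#'   column-major voxel linearization), its transpose `At`, and a
#'   `beamlet_index` data frame (angle, lateral offset).
#' @export
compute_influence <- function(phantom, beamset, attenuation = 0.005,
                              lateral_sigma = 3, scatter_fraction = 0.05,
                              scatter_sigma = 24, cutoff_sigma = 4) {
  stopifnot(inherits(phantom, "ofv_phantom"), inherits(beamset, "ofv_beamset"))
  if (!identical(as.integer(phantom$grid_shape),
                 as.integer(beamset$grid_shape)) ||
      phantom$spacing_mm != beamset$spacing_mm)
    stop("beamset was built for a different grid than this phantom")
  if (attenuation <= 0) stop("attenuation must be > 0")
  if (lateral_sigma <= 0) stop("lateral_sigma must be > 0")
  if (scatter_fraction < 0) stop("scatter_fraction must be >= 0")
  if (scatter_fraction > 0 && scatter_sigma <= 0)
    stop("scatter_sigma must be > 0")

  xy <- voxel_coords(phantom$grid_shape, phantom$spacing_mm)
  ext <- phantom$masks$external
  inside <- which(ext)                       # column-major linear indices
  xs <- xy$x[inside]; ys <- xy$y[inside]
  iso <- beamset$isocenter_mm
  n_angles <- length(beamset$gantry_angles)
  nb <- beamset$beamlets_per_angle
  n_vox <- prod(phantom$grid_shape)

  ii <- vector("list", n_angles)
  jj <- vector("list", n_angles)
  vv <- vector("list", n_angles)
  half_width <- cutoff_sigma * max(lateral_sigma,
                                   if (scatter_fraction > 0) scatter_sigma else 0)

  for (k in seq_len(n_angles)) {
    d <- beamset$dir[k, ]; p <- beamset$lat[k, ]
    depth <- ray_depths(ext, xs, ys, d, phantom$spacing_mm,
                        phantom$grid_shape)
    att <- exp(-attenuation * depth)
    v <- (xs - iso[1]) * p[1] + (ys - iso[2]) * p[2]
    ik <- jk <- vk <- vector("list", nb)
    for (b in seq_len(nb)) {
      dv <- v - beamset$offsets_mm[k, b]
      sel <- abs(dv) <= half_width
      if (!any(sel)) next
      u2 <- dv[sel]^2
      kern <- ifelse(u2 <= (cutoff_sigma * lateral_sigma)^2,
                     exp(-u2 / (2 * lateral_sigma^2)), 0)
      if (scatter_fraction > 0)
        kern <- kern + scatter_fraction * exp(-u2 / (2 * scatter_sigma^2))
      keep <- kern > 0
      ik[[b]] <- inside[sel][keep]
      jk[[b]] <- rep.int((k - 1L) * nb + b, sum(keep))
      vk[[b]] <- att[sel][keep] * kern[keep]
    }
    ii[[k]] <- unlist(ik); jj[[k]] <- unlist(jk); vv[[k]] <- unlist(vk)
  }

  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                            dims = c(n_vox, n_angles * nb))
  bi <- data.frame(beamlet = seq_len(n_angles * nb),
                   angle_deg = rep(beamset$gantry_angles, each = nb),
                   offset_mm = as.vector(t(beamset$offsets_mm)))
  structure(list(A = A, At = Matrix::t(A), grid_shape = phantom$grid_shape,
                 n_beamlets = n_angles * nb, beamlet_index = bi,
                 attenuation = attenuation, lateral_sigma = lateral_sigma,
                 scatter_fraction = scatter_fraction,
                 scatter_sigma = scatter_sigma),
            class = "ofv_influence")
}

#' @export
print.ofv_influence <- function(x, ...) {
  cat("Influence matrix: ", nrow(x$A), " voxels x ", ncol(x$A),
      " beamlets, ", length(x$A@x), " nonzeros\n", sep = "")
  invisible(x)
}
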
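# Synthetic 2-D thoracic phantom generation.
#
# A phantom is a single axial slice (with a nominal slice thickness so that
# areas convert to pseudo-volumes) holding binary masks for the planning
# target volume (the ipsilateral breast), heart, both lungs, the
# contralateral breast and the external (body) contour.  All shapes are
# analytic ellipses/discs jittered per seed, so mask generation is exact and
# bit-reproducible.

#' Phantom generation parameters
#'
#' Builds the parameter set consumed by [generate_phantom()].  Defaults
#' emulate a supine thoracic cross-section: an elliptical body outline, two
#' lungs, a heart displaced toward the patient's left, and two breast bulges
#' on the anterior chest wall, one of which (the ipsilateral breast) is the
#' planning target volume (PTV).  Nominal structure sizes are chosen so that
#' the pseudo-volumes (mask area times \code{slice_thickness_mm}) reproduce,
#' at slice scale, the relative organ volumes of a breast radiotherapy
#' cohort (scaling factor: slice thickness over a nominal 150 mm
#' cranio-caudal organ extent).
#'
#' @param laterality `"left"` or `"right"`; side of the treated breast.
#' @param grid_shape integer vector of length 2, voxels per axis (rows,
#'   columns).
#' @param spacing_mm in-plane voxel spacing in mm.
#' @param slice_thickness_mm nominal slice thickness in mm used to convert
#'   mask areas to pseudo-volumes.
#' @param body_semiaxes_mm semi-axes (lateral, anterior-posterior) of the
#'   elliptical body outline, mm.
#' @param size_jitter relative half-width of the uniform size jitter applied
#'   to every structure's linear dimensions.
#' @param position_jitter_mm half-width (mm) of the uniform jitter applied to
#'   structure centers.
#' @param angle_jitter_deg half-width (degrees) of the jitter on the breast
#'   position along the chest wall.
#' @param oar_margin_mm margin (mm) by which organs at risk are grown before
#'   being subtracted from the PTV (the chest-wall gap that keeps target and
#'   organs disjoint).
#' @param chest_wall_mm thickness (mm) of the rind of the body ellipse kept
#'   free of lung and heart.
#' @param shapes named list of nominal structure geometries (centers,
#'   semi-axes, radii in mm; breast placement as an angle on the body
#'   outline measured from anterior toward the treated side).
#' @param volume_targets_cm3 named vector of target pseudo-volumes (cm^3).
#' @param volume_ranges_cm3 named list of `c(min, max)` admissible
#'   pseudo-volumes per structure; generation fails if a jittered phantom
#'   falls outside these.
#' @return an object of class `ofv_phantom_config` (a named list).
#' @seealso [generate_phantom()]
#' @export
phantom_config <- function(laterality = c("left", "right"),
                           grid_shape = c(128L, 128L),
                           spacing_mm = 3,
                           slice_thickness_mm = 3,
                           body_semiaxes_mm = c(150, 95),
                           size_jitter = 0.12,
                           position_jitter_mm = 4,
                           angle_jitter_deg = 5,
                           oar_margin_mm = 6,
                           chest_wall_mm = 8,
                           shapes = list(
                             lung_left  = list(center = c(60, 5),  semi = c(59, 79)),
                             lung_right = list(center = c(-70, 0), semi = c(54, 76)),
                             heart      = list(center = c(32, 35), radius = 34.5),
                             breast = list(sector_deg = c(3, 88),
                                           band_depth_mm = c(2, 34),
                                           edge_depth_mm = 6,
                                           surface_angle_deg = 43, offset_mm = 9,
                                           semi = c(59, 45)),
                             breast_contra = list(surface_angle_deg = 40, offset_mm = 10,
                                                  semi = c(62, 45))
                           ),
                           volume_targets_cm3 = c(ptv = 20.8, heart = 11.2,
                                                  breast_contra = 19.4,
                                                  lung_left = 30.3, lung_right = 37.0),
                           volume_ranges_cm3 = list(
                             ptv = c(8.0, 38.9), heart = c(8.2, 19.0),
                             breast_contra = c(7.0, 37.5),
                             lung_left = c(15.1, 45.9), lung_right = c(22.4, 60.4))) {
  laterality <- match.arg(laterality)
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 16),
            spacing_mm > 0, slice_thickness_mm > 0,
            all(body_semiaxes_mm > 0), size_jitter >= 0, size_jitter < 1,
            position_jitter_mm >= 0, oar_margin_mm >= 0)
  if (any(unlist(lapply(volume_ranges_cm3, diff)) <= 0) ||
      any(unlist(volume_ranges_cm3) <= 0)) {
    stop("volume_ranges_cm3 must be positive increasing c(min, max) pairs")
  }
  cfg <- list(laterality = laterality, grid_shape = as.integer(grid_shape),
              spacing_mm = spacing_mm, slice_thickness_mm = slice_thickness_mm,
              body_semiaxes_mm = body_semiaxes_mm, size_jitter = size_jitter,
              position_jitter_mm = position_jitter_mm,
              angle_jitter_deg = angle_jitter_deg,
              oar_margin_mm = oar_margin_mm, chest_wall_mm = chest_wall_mm,
              shapes = shapes, volume_targets_cm3 = volume_targets_cm3,
              volume_ranges_cm3 = volume_ranges_cm3)
  class(cfg) <- "ofv_phantom_config"
  cfg
}

# Run code with a private RNG stream; caller's .Random.seed is untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Voxel-center coordinates in mm.  x: + toward the patient's left,
# y: + anterior.  Row 1 is the most anterior row; linear indexing is R's
# native column-major order over the (row, column) matrix.
voxel_coords <- function(grid_shape, spacing_mm) {
  nr <- grid_shape[1]; nc <- grid_shape[2]
  x <- (seq_len(nc) - (nc + 1) / 2) * spacing_mm
  y <- ((nr + 1) / 2 - seq_len(nr)) * spacing_mm
  list(x = matrix(rep(x, each = nr), nr, nc),
       y = matrix(rep(y, times = nc), nr, nc))
}

inside_ellipse <- function(xy, center, semi, phi = 0) {
  dx <- xy$x - center[1]; dy <- xy$y - center[2]
  if (phi != 0) {
    c0 <- cos(phi); s0 <- sin(phi)
    u <- dx * c0 + dy * s0
    v <- -dx * s0 + dy * c0
  } else {
    u <- dx; v <- dy
  }
  (u / semi[1])^2 + (v / semi[2])^2 <= 1
}

inside_disc <- function(xy, center, radius) {
  (xy$x - center[1])^2 + (xy$y - center[2])^2 <= radius^2
}

#' Generate a seeded synthetic thoracic phantom
#'
#' Draws one phantom: structure sizes and positions are jittered uniformly
#' within the configured ranges using a private RNG stream, masks are
#' rasterized at voxel centers, and the type invariants are enforced (every
#' structure inside the external contour, PTV disjoint from all organs at
#' risk, pseudo-volumes inside the configured ranges).  Identical
#' `(config, seed)` pairs give bit-identical phantoms.
#'
#' @param config an `ofv_phantom_config`, see [phantom_config()].
#' @param seed integer seed.
#' @return an object of class `ofv_phantom`: list with `grid_shape`,
#'   `spacing_mm`, `slice_thickness_mm`, `laterality`, `seed`, `masks`
#'   (named logical matrices for `PTV`, `heart`, `lung_ipsi`, `lung_contra`,
#'   `breast_contra`, `external`), `pseudo_volumes_cm3`, `voxel_volume_cm3`.
#' @examples
#' ph <- generate_phantom(phantom_config("left", grid_shape = c(64, 64),
#'                                       spacing_mm = 6), seed = 7)
#' ph$pseudo_volumes_cm3
#' @export
generate_phantom <- function(config = phantom_config(), seed = 1L) {
  stopifnot(inherits(config, "ofv_phantom_config"), is.numeric(seed))
  side <- if (config$laterality == "left") 1 else -1
  A <- config$body_semiaxes_mm[1]; B <- config$body_semiaxes_mm[2]

  jit <- with_seed(seed, {
    structs <- c("lung_left", "lung_right", "heart", "breast", "breast_contra")
    out <- list()
    for (s in structs) {
      out[[s]] <- list(
        scale = stats::runif(1, 1 - config$size_jitter, 1 + config$size_jitter),
        shift = stats::runif(2, -config$position_jitter_mm, config$position_jitter_mm),
        dang  = stats::runif(1, -config$angle_jitter_deg, config$angle_jitter_deg))
    }
    out
  })

  xy <- voxel_coords(config$grid_shape, config$spacing_mm)
  sh <- config$shapes

  body <- inside_ellipse(xy, c(0, 0), c(A, B))

  # Breast bulge placed on the body outline at an angle measured from the
  # anterior axis toward the treated side; ellipse axes aligned with the
  # local tangent/normal.
  breast_shape <- function(spec, angle_sign, j) {
    ang <- (angle_sign * spec$surface_angle_deg + j$dang) * pi / 180
    p <- c(A * sin(ang), B * cos(ang))
    nrm <- c(p[1] / A^2, p[2] / B^2); nrm <- nrm / sqrt(sum(nrm^2))
    ctr <- p + spec$offset_mm * nrm + j$shift
    tangent <- c(A * cos(ang), -B * sin(ang))
    phi <- atan2(tangent[2], tangent[1])
    list(center = ctr, semi = spec$semi * j$scale, phi = phi)
  }

  # The treated breast is a crescent hugging the chest wall (a band at
  # 2-28 mm depth over a sector of surface angles on the treated side) plus
  # an anterior mound; this wrapping shape is what forces tangential beams
  # through the lung rim, as in real breast geometry.
  bi <- breast_shape(sh$breast, side, jit$breast)
  bc <- breast_shape(sh$breast_contra, -side, jit$breast_contra)
  m_mound <- inside_ellipse(xy, bi$center, bi$semi, bi$phi)
  m_breast_c <- inside_ellipse(xy, bc$center, bc$semi, bc$phi)

  surf_ang <- atan2(side * xy$x, xy$y) * 180 / pi
  ang1 <- sh$breast$sector_deg[1] + jit$breast$dang
  ang2 <- sh$breast$sector_deg[2] + jit$breast$dang
  sector <- surf_ang >= ang1 & surf_ang <= ang2
  # Chest-wall band whose depth tapers toward the sector edges: real breast
  # tissue thins to nothing at its medial and lateral borders, so the deep
  # boundary is deepest mid-sector (band_depth_mm[2]) and shallows to
  # edge_depth_mm at both sector ends (half-sine profile).
  frac <- pmin(pmax((surf_ang - ang1) / (ang2 - ang1), 0), 1)
  deep <- sh$breast$edge_depth_mm +
    (sh$breast$band_depth_mm[2] * jit$breast$scale -
       sh$breast$edge_depth_mm) * sin(pi * frac)
  band <- inside_ellipse(xy, c(0, 0),
                         pmax(c(A, B) - sh$breast$band_depth_mm[1], 1)) &
    (xy$x / pmax(A - deep, 1))^2 + (xy$y / pmax(B - deep, 1))^2 > 1
  m_breast_i <- (band & sector) | m_mound

  external <- body | m_breast_i | m_breast_c

  core <- inside_ellipse(xy, c(0, 0), pmax(c(A, B) - config$chest_wall_mm, 1))
  h <- sh$heart
  heart_ctr <- h$center + jit$heart$shift
  heart_r <- h$radius * jit$heart$scale
  m_heart <- inside_disc(xy, heart_ctr, heart_r) & core

  lung_mask <- function(spec, j) {
    ctr <- spec$center + j$shift
    inside_ellipse(xy, ctr, spec$semi * j$scale) & core &
      !inside_disc(xy, heart_ctr, heart_r + config$oar_margin_mm)
  }
  m_lung_l <- lung_mask(sh$lung_left, jit$lung_left)
  m_lung_r <- lung_mask(sh$lung_right, jit$lung_right)

  grown <- inside_disc(xy, heart_ctr, heart_r + config$oar_margin_mm) |
    inside_ellipse(xy, sh$lung_left$center + jit$lung_left$shift,
                   sh$lung_left$semi * jit$lung_left$scale + config$oar_margin_mm) |
    inside_ellipse(xy, sh$lung_right$center + jit$lung_right$shift,
                   sh$lung_right$semi * jit$lung_right$scale + config$oar_margin_mm)

  m_ptv <- m_breast_i & external & !grown & !m_breast_c
  m_breast_c <- m_breast_c & !grown & !m_ptv

  if (config$laterality == "left") {
    m_ipsi <- m_lung_l; m_contra <- m_lung_r
  } else {
    m_ipsi <- m_lung_r; m_contra <- m_lung_l
  }

  masks <- list(PTV = m_ptv, heart = m_heart, lung_ipsi = m_ipsi,
                lung_contra = m_contra, breast_contra = m_breast_c,
                external = external)

  vox_cm3 <- config$spacing_mm^2 * config$slice_thickness_mm / 1000
  vols <- vapply(masks, function(m) sum(m) * vox_cm3, numeric(1))

  for (nm in names(masks)) {
    if (!any(masks[[nm]]))
      stop("infeasible phantom geometry: structure '", nm, "' is empty ",
           "(check size/position parameters against the body outline)")
  }
  rng <- config$volume_ranges_cm3
  checks <- c(ptv = "PTV", heart = "heart", breast_contra = "breast_contra")
  checks[if (config$laterality == "left") "lung_left" else "lung_right"] <- "lung_ipsi"
  checks[if (config$laterality == "left") "lung_right" else "lung_left"] <- "lung_contra"
  for (key in names(checks)) {
    v <- vols[[checks[[key]]]]
    if (v < rng[[key]][1] || v > rng[[key]][2])
      stop("infeasible phantom geometry: pseudo-volume of '", checks[[key]],
           "' (", signif(v, 4), " cm^3) outside configured range [",
           rng[[key]][1], ", ", rng[[key]][2], "]")
  }
  for (nm in setdiff(names(masks), "external")) {
    if (any(masks[[nm]] & !external))
      stop("internal error: mask '", nm, "' escapes the external contour")
  }
  for (nm in c("heart", "lung_ipsi", "lung_contra", "breast_contra")) {
    if (any(m_ptv & masks[[nm]]))
      stop("infeasible phantom geometry: PTV intersects '", nm, "'")
  }

  structure(list(grid_shape = config$grid_shape, spacing_mm = config$spacing_mm,
                 slice_thickness_mm = config$slice_thickness_mm,
                 laterality = config$laterality, seed = as.integer(seed),
                 masks = masks, pseudo_volumes_cm3 = vols,
                 voxel_volume_cm3 = vox_cm3, config = config),
            class = "ofv_phantom")
}

#' @export
print.ofv_phantom <- function(x, ...) {
  cat("Synthetic thoracic phantom (", x$laterality, "-sided, seed ", x$seed,
      ")\n", sep = "")
  cat("  grid: ", paste(x$grid_shape, collapse = " x "), " voxels @ ",
      x$spacing_mm, " mm, slice ", x$slice_thickness_mm, " mm\n", sep = "")
  v <- x$pseudo_volumes_cm3
  for (nm in names(v))
    cat(sprintf("  %-14s %8.1f cm^3 (%d voxels)\n", nm, v[[nm]],
                sum(x$masks[[nm]])))
  invisible(x)
}
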
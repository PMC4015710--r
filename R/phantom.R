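#' Specification of a paired inspiratory/expiratory CT phantom
#'
#' Describes a digital thorax phantom: two ellipsoidal lungs inside a soft
#' tissue body cylinder surrounded by air, with a vertical near -1000 HU
#' airway tube entering from the most cranial slice. Normal parenchyma draws
#' its HU from a Gaussian that shifts upwards (denser) between inspiration
#' and expiration; a chosen fraction of lung voxels ("trapped" regions) keeps
#' inspiratory-like density on expiration, which is exactly the CT appearance
#' of air trapping.
#'
#' Trapped voxels are grouped into focal clusters around randomly placed
#' seeds, and the number of trapped voxels is matched to `trapped_fraction`
#' exactly (the empirical fraction equals the requested one up to rounding),
#' so densitometric expectations follow the two-component Gaussian mixture in
#' closed form.
#'
#' @param grid_shape Integer length-3: voxels per axis (x, y, z; z is
#'   cranio-caudal, apex at the last slice).
#' @param spacing Voxel size in mm per axis.
#' @param body_hu Mean HU of non-lung body tissue; must be above -500 so the
#'   body never enters the parenchyma threshold range.
#' @param lung_insp_mean,lung_insp_sd Gaussian HU of normal parenchyma at
#'   inspiration. Means must be below -500.
#' @param lung_exp_mean,lung_exp_sd Gaussian HU of normal parenchyma at
#'   expiration.
#' @param trapped_fraction Proportion of lung voxels in `[0, 1]` that keep
#'   inspiratory-like density on expiration. Either a scalar, or length 2
#'   `c(base, apex)` for a linear cranio-caudal gradient (applied per slice).
#' @param trapped_exp_mean,trapped_exp_sd Gaussian HU of trapped voxels at
#'   expiration; defaults to the inspiratory distribution (slightly tighter),
#'   i.e. trapped tissue "fails to gain attenuation".
#' @param airway_radius_mm Radius of the vertical airway tube.
#' @param n_trapped_foci Number of focal seeds the trapped voxels cluster
#'   around.
#' @param seed Integer RNG seed; identical specs give bitwise-identical
#'   volumes.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(grid_shape = c(96L, 96L, 96L),
                         spacing = c(2, 2, 2),
                         body_hu = 50,
                         lung_insp_mean = -880, lung_insp_sd = 20,
                         lung_exp_mean = -750, lung_exp_sd = 20,
                         trapped_fraction = 0.3,
                         trapped_exp_mean = lung_insp_mean,
                         trapped_exp_sd = 15,
                         airway_radius_mm = 5,
                         n_trapped_foci = 4L,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4L))
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  if (!is.numeric(trapped_fraction) ||
      !length(trapped_fraction) %in% c(1L, 2L) ||
      any(trapped_fraction < 0) || any(trapped_fraction > 1)) {
    stop("`trapped_fraction` must be in [0, 1] (scalar or length-2 gradient)",
         call. = FALSE)
  }
  if (lung_insp_mean >= -500 || lung_exp_mean >= -500 ||
      trapped_exp_mean >= -500) {
    stop("lung HU means must be below -500", call. = FALSE)
  }
  if (body_hu <= -500) stop("`body_hu` must be above -500", call. = FALSE)
  stopifnot(lung_insp_sd > 0, lung_exp_sd > 0, trapped_exp_sd > 0,
            airway_radius_mm > 0, n_trapped_foci >= 1L)
  structure(
    list(grid_shape = grid_shape, spacing = spacing, body_hu = body_hu,
         lung_insp_mean = lung_insp_mean, lung_insp_sd = lung_insp_sd,
         lung_exp_mean = lung_exp_mean, lung_exp_sd = lung_exp_sd,
         trapped_fraction = trapped_fraction,
         trapped_exp_mean = trapped_exp_mean,
         trapped_exp_sd = trapped_exp_sd,
         airway_radius_mm = airway_radius_mm,
         n_trapped_foci = as.integer(n_trapped_foci),
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Geometry of the phantom in physical (mm) units, shared by the generator.
# Lungs: ellipsoids centered at x = X/2 +- 0.22 X with semi-axes
# (0.15 X, 0.28 Y, 0.32 Z); body: cylinder of radius 0.45 min(X, Y);
# airway: tube of the requested radius from 0.40 Z to the apical slice.
phantom_geometry <- function(spec) {
  ext <- spec$grid_shape * spec$spacing
  g <- list(
    ext = ext,
    lung_a = 0.15 * ext[1], lung_b = 0.28 * ext[2], lung_c = 0.32 * ext[3],
    lung_dx = 0.22 * ext[1], lung_cz = 0.45 * ext[3],
    body_r = 0.45 * min(ext[1], ext[2]),
    airway_r = spec$airway_radius_mm, airway_z0 = 0.40 * ext[3]
  )
  vox_axes <- c(g$lung_a / spec$spacing[1], g$lung_b / spec$spacing[2],
                g$lung_c / spec$spacing[3])
  if (min(vox_axes) < 3) {
    stop("grid too small: lung ellipsoid semi-axes span < 3 voxels",
         call. = FALSE)
  }
  if (g$lung_dx - g$lung_a <= g$airway_r + max(spec$spacing)) {
    stop("grid too small: airway tube would touch the lung ellipsoids",
         call. = FALSE)
  }
  g
}

#' Generate a paired inspiratory/expiratory CT phantom
#'
#' Builds the inspiratory and expiratory volumes of the phantom described by
#' a [phantom_spec], together with its ground truth masks. The two volumes
#' are identical outside the lungs; on expiration, normal parenchyma shifts
#' to the denser expiratory distribution while trapped voxels keep an
#' inspiratory-like distribution.
#'
#' @param spec A [phantom_spec].
#' @return A list of class `phantom` with elements `inspiratory` and
#'   `expiratory` ([ct_volume]s) and `truth`, a list holding `lung_mask`,
#'   `trapped_mask`, `airway_mask` (logical arrays; `trapped_mask` is a
#'   subset of `lung_mask`, the airway is disjoint from both) and
#'   `true_trapped_fraction`.
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_shape = c(32, 32, 32),
#'                                     spacing = c(4, 4, 4)))
#' mean(ph$truth$lung_mask)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- phantom_geometry(spec)
  d <- spec$grid_shape
  sp <- spec$spacing
  ext <- g$ext

  # voxel-center coordinates
  cx <- (seq_len(d[1]) - 0.5) * sp[1]
  cy <- (seq_len(d[2]) - 0.5) * sp[2]
  cz <- (seq_len(d[3]) - 0.5) * sp[3]

  dx2 <- (cx - ext[1] / 2)^2
  dy2 <- (cy - ext[2] / 2)^2
  body2d <- outer(dx2, dy2, "+") <= g$body_r^2

  ellipsoid <- function(cx0) {
    q2d <- outer(((cx - cx0) / g$lung_a)^2, ((cy - ext[2] / 2) / g$lung_b)^2,
                 "+")
    outer(q2d, ((cz - g$lung_cz) / g$lung_c)^2, "+") <= 1
  }
  lung_mask <- ellipsoid(ext[1] / 2 - g$lung_dx) |
    ellipsoid(ext[1] / 2 + g$lung_dx)

  airway2d <- outer(dx2, dy2, "+") <= g$airway_r^2
  airway_mask <- outer(airway2d, cz >= g$airway_z0, "&")
  lung_mask <- lung_mask & !airway_mask

  n_lung <- sum(lung_mask)
  lung_idx <- which(lung_mask)

  out <- with_seed(spec$seed, {
    # focal trapped regions: lung voxels ordered by distance to random seeds,
    # counts matched exactly to the requested fraction (per slice when a
    # cranio-caudal gradient is requested)
    trapped_idx <- integer(0)
    tf <- spec$trapped_fraction
    if (any(tf > 0)) {
      centers <- sample(lung_idx, spec$n_trapped_foci)
      ai <- arrayInd(lung_idx, d)
      pos <- cbind(cx[ai[, 1]], cy[ai[, 2]], cz[ai[, 3]])
      ci <- arrayInd(centers, d)
      cpos <- cbind(cx[ci[, 1]], cy[ci[, 2]], cz[ci[, 3]])
      dist2 <- rep(Inf, n_lung)
      for (k in seq_len(nrow(cpos))) {
        dk <- (pos[, 1] - cpos[k, 1])^2 + (pos[, 2] - cpos[k, 2])^2 +
          (pos[, 3] - cpos[k, 3])^2
        dist2 <- pmin(dist2, dk)
      }
      if (length(tf) == 1L) {
        n_t <- round(tf * n_lung)
        if (n_t > 0) trapped_idx <- lung_idx[order(dist2)[seq_len(n_t)]]
      } else {
        # fraction varies linearly from tf[1] at the base (z min) to tf[2]
        # at the apex (z max); exact counts per slice
        fz <- tf[1] + (tf[2] - tf[1]) * (cz - min(cz)) / diff(range(cz))
        for (z in unique(ai[, 3])) {
          in_z <- ai[, 3] == z
          n_tz <- round(fz[z] * sum(in_z))
          if (n_tz > 0) {
            sel <- which(in_z)[order(dist2[in_z])[seq_len(n_tz)]]
            trapped_idx <- c(trapped_idx, lung_idx[sel])
          }
        }
      }
    }
    trapped_mask <- array(FALSE, d)
    trapped_mask[trapped_idx] <- TRUE

    # base volume shared by both phases: exterior air + airway near -1000,
    # body soft tissue; small Gaussian texture everywhere
    n_vox <- prod(d)
    base <- -1000 + stats::rnorm(n_vox, 0, 5)
    dim(base) <- d
    body_only <- outer(body2d, rep(TRUE, d[3]), "&") & !lung_mask &
      !airway_mask
    base[body_only] <- spec$body_hu + stats::rnorm(sum(body_only), 0, 5)

    insp <- base
    insp[lung_idx] <- stats::rnorm(n_lung, spec$lung_insp_mean,
                                   spec$lung_insp_sd)
    expi <- base
    normal_idx <- setdiff(lung_idx, trapped_idx)
    expi[normal_idx] <- stats::rnorm(length(normal_idx), spec$lung_exp_mean,
                                     spec$lung_exp_sd)
    if (length(trapped_idx)) {
      expi[trapped_idx] <- stats::rnorm(length(trapped_idx),
                                        spec$trapped_exp_mean,
                                        spec$trapped_exp_sd)
    }
    insp <- pmax(insp, -1024)
    expi <- pmax(expi, -1024)
    dim(insp) <- d
    dim(expi) <- d
    list(insp = insp, expi = expi, trapped_mask = trapped_mask,
         n_trapped = length(trapped_idx))
  })

  structure(
    list(
      inspiratory = ct_volume(out$insp, sp),
      expiratory = ct_volume(out$expi, sp),
      truth = list(
        lung_mask = lung_mask,
        trapped_mask = out$trapped_mask,
        airway_mask = airway_mask,
        true_trapped_fraction = out$n_trapped / n_lung
      )
    ),
    class = "phantom"
  )
}
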
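#' Densitometry configuration
#'
#' Thresholds and component sizes driving lung segmentation and densitometry.
#' Lung parenchyma is any voxel in `parenchyma_range`; air trapping is read
#' from two nested low-attenuation ranges, the full `[-1024, -850]` HU range
#' and the narrow `[-910, -850]` HU range, whose lower bound deliberately
#' excludes near-air densities produced by emphysematous or cystic lesions.
#' All range bounds are inclusive, which makes the nesting exact at integer
#' HU.
#'
#' @param parenchyma_range HU interval defining candidate lung voxels.
#' @param laa_full_range Full low-attenuation range.
#' @param laa_narrow_range Narrow low-attenuation range; must nest inside
#'   `laa_full_range`, which must nest inside `parenchyma_range`.
#' @param airway_hu_max HU ceiling for airway candidate voxels; a connected
#'   near-air column reaching the apical slice is treated as trachea/bronchi.
#' @param min_component_voxels Minimum size for a connected component to be
#'   kept as lung.
#' @return An object of class `quant_config`.
#' @export
quant_config <- function(parenchyma_range = c(-1024, -500),
                         laa_full_range = c(-1024, -850),
                         laa_narrow_range = c(-910, -850),
                         airway_hu_max = -950,
                         min_component_voxels = 1000L) {
  chk <- function(r, nm) {
    if (length(r) != 2L || r[1] >= r[2]) {
      stop("`", nm, "` must be an increasing HU interval", call. = FALSE)
    }
    as.numeric(r)
  }
  parenchyma_range <- chk(parenchyma_range, "parenchyma_range")
  laa_full_range <- chk(laa_full_range, "laa_full_range")
  laa_narrow_range <- chk(laa_narrow_range, "laa_narrow_range")
  nested <- function(inner, outer) {
    inner[1] >= outer[1] && inner[2] <= outer[2]
  }
  if (!nested(laa_narrow_range, laa_full_range) ||
      !nested(laa_full_range, parenchyma_range)) {
    stop("ranges must nest: laa_narrow within laa_full within parenchyma",
         call. = FALSE)
  }
  structure(
    list(parenchyma_range = parenchyma_range,
         laa_full_range = laa_full_range,
         laa_narrow_range = laa_narrow_range,
         airway_hu_max = as.numeric(airway_hu_max),
         min_component_voxels = as.integer(min_component_voxels)),
    class = "quant_config"
  )
}

label_array <- function(mask) {
  lab <- label_components_3d(as.logical(mask), dim(mask))
  dim(lab) <- dim(mask)
  lab
}

new_lung_mask <- function(labels) {
  d <- dim(labels)
  ids <- sort(unique(labels[labels > 0L]))
  comps <- if (length(ids)) {
    idx <- which(labels > 0L)
    ai <- arrayInd(idx, d)
    lab <- labels[idx]
    data.frame(
      id = ids,
      n_voxels = as.integer(table(factor(lab, levels = ids))),
      centroid_x = as.numeric(tapply(ai[, 1], lab, mean)),
      side = NA_character_
    )
  } else {
    data.frame(id = integer(0), n_voxels = integer(0),
               centroid_x = numeric(0), side = character(0))
  }
  if (nrow(comps) >= 2L) {
    # label the two largest components left/right in image coordinates
    big <- comps$id[order(-comps$n_voxels)][1:2]
    xs <- comps$centroid_x[match(big, comps$id)]
    comps$side[match(big[order(xs)], comps$id)] <- c("left", "right")
  } else if (nrow(comps) == 1L) {
    comps$side <- "single"
  }
  structure(list(mask = labels > 0L, labels = labels, components = comps),
            class = "lung_mask")
}

#' @export
print.lung_mask <- function(x, ...) {
  cat(sprintf("<lung_mask> %d voxels in %d component(s)\n",
              sum(x$mask), nrow(x$components)))
  invisible(x)
}

#' Segment lung parenchyma from a CT volume
#'
#' Pure threshold-and-components segmentation: voxels inside the parenchyma
#' HU range are labeled into 6-connected components; components touching the
#' lateral (x/y) image border are discarded as exterior air; the airway
#' column reaching the apical slice is removed (see [remove_airway()]); and
#' components below `min_component_voxels` are dropped. Both lungs are
#' retained so downstream summaries combine the values found for both sides.
#'
#' @param volume A [ct_volume].
#' @param config A [quant_config].
#' @return A `lung_mask`: list with logical `mask`, integer `labels` and a
#'   `components` data.frame (id, size, centroid, image-space side).
#' @examples
#' vals <- array(0, c(12, 12, 12))
#' vals[4:9, 4:9, 4:9] <- -1000
#' m <- suppressWarnings(
#'   segment_lung(ct_volume(vals, c(1, 1, 1)),
#'                quant_config(min_component_voxels = 10))
#' )
#' sum(m$mask)
#' @export
segment_lung <- function(volume, config = quant_config()) {
  stopifnot(inherits(volume, "ct_volume"), inherits(config, "quant_config"))
  vals <- volume$values
  d <- dim(vals)
  pr <- config$parenchyma_range
  inrange <- vals >= pr[1] & vals <= pr[2]
  if (sum(inrange) < config$min_component_voxels) {
    stop("no lung found: fewer than ", config$min_component_voxels,
         " voxels in the parenchyma HU range", call. = FALSE)
  }
  labels <- label_array(inrange)

  # exterior air reaches the lateral image border; lungs are interior
  border <- unique(c(labels[1, , ], labels[d[1], , ],
                     labels[, 1, ], labels[, d[2], ]))
  border <- border[border > 0L]
  if (length(border)) labels[labels %in% border] <- 0L

  m <- new_lung_mask(labels)
  m <- remove_airway(m, volume, config)

  keep <- m$components$id[m$components$n_voxels >=
                            config$min_component_voxels]
  if (length(keep) == 0L) stop("no lung found", call. = FALSE)
  if (length(keep) == 1L) {
    warning("only one lung component found; proceeding with one",
            call. = FALSE)
  }
  labels <- m$labels
  labels[!(labels %in% keep)] <- 0L
  new_lung_mask(labels)
}

#' Exclude the airway from a lung mask
#'
#' Removes from the mask any 6-connected component of near-air voxels
#' (HU at or below `airway_hu_max`) that touches the most cranial slice:
#' in both the phantom and a thorax, the trachea is the only air column
#' reaching the apical image boundary. If no such component exists the mask
#' is returned unchanged.
#'
#' @param mask A `lung_mask` from [segment_lung()] (or its internal stages).
#' @param volume The source [ct_volume].
#' @param config A [quant_config].
#' @return The `lung_mask` with airway voxels excluded.
#' @export
remove_airway <- function(mask, volume, config = quant_config()) {
  stopifnot(inherits(mask, "lung_mask"), inherits(volume, "ct_volume"))
  if (!any(mask$mask)) stop("mask is empty", call. = FALSE)
  d <- dim(volume$values)
  cand <- mask$mask & volume$values <= config$airway_hu_max
  if (!any(cand)) return(mask)
  clab <- label_array(cand)
  top <- unique(clab[, , d[3]])
  top <- top[top > 0L]
  if (length(top) == 0L) return(mask)
  labels <- mask$labels
  labels[clab %in% top] <- 0L
  new_lung_mask(labels)
}

#' Mean lung density
#'
#' Arithmetic mean HU over the masked voxels.
#'
#' @param volume A [ct_volume].
#' @param mask A `lung_mask` or logical array.
#' @return Mean HU (scalar).
#' @export
mean_lung_density <- function(volume, mask) {
  m <- if (inherits(mask, "lung_mask")) mask$mask else mask
  if (!any(m)) stop("mask is empty", call. = FALSE)
  mean(volume$values[m])
}

#' Low-attenuation area percentage
#'
#' Percentage of masked voxels whose HU falls inside `range` (bounds
#' inclusive).
#'
#' @param volume A [ct_volume].
#' @param mask A `lung_mask` or logical array.
#' @param range HU interval `c(lo, hi)`.
#' @return Percentage in `[0, 100]`.
#' @export
laa_percent <- function(volume, mask, range) {
  m <- if (inherits(mask, "lung_mask")) mask$mask else mask
  if (!any(m)) stop("mask is empty", call. = FALSE)
  stopifnot(length(range) == 2L, range[1] <= range[2])
  v <- volume$values[m]
  100 * mean(v >= range[1] & v <= range[2])
}

density_summary <- function(level_id, mld, laa_full_pct, laa_narrow_pct,
                            n_voxels) {
  out <- data.frame(level_id = level_id, mld = mld,
                    laa_full_pct = laa_full_pct,
                    laa_narrow_pct = laa_narrow_pct,
                    n_voxels = n_voxels)
  class(out) <- c("density_summary", "data.frame")
  out
}

#' Densitometric summary of a single anatomical level
#'
#' Computes MLD and both LAA percentages over one axial slice. With
#' `combine = "pool"` (default) voxels from both sides are pooled into one
#' set before summarising; `combine = "average"` summarises each connected
#' component present on the slice separately and averages the summaries.
#'
#' @param volume A [ct_volume].
#' @param mask A `lung_mask`.
#' @param level_z Slice index along the cranio-caudal axis.
#' @param config A [quant_config].
#' @param combine `"pool"` or `"average"`.
#' @param level_id Label stored in the output (defaults to `level_z`).
#' @return A one-row `density_summary` data.frame.
#' @export
summarize_level <- function(volume, mask, level_z, config = quant_config(),
                            combine = c("pool", "average"),
                            level_id = as.character(level_z)) {
  combine <- match.arg(combine)
  stopifnot(inherits(volume, "ct_volume"))
  d <- dim(volume$values)
  if (level_z < 1L || level_z > d[3]) {
    stop("level_z out of volume bounds", call. = FALSE)
  }
  m <- if (inherits(mask, "lung_mask")) mask$mask else mask
  labs <- if (inherits(mask, "lung_mask")) mask$labels else NULL
  sl_mask <- m[, , level_z]
  if (!any(sl_mask)) {
    stop("empty lung mask at level ", level_id, call. = FALSE)
  }
  sl_vals <- volume$values[, , level_z]
  one <- function(v) {
    c(mld = mean(v),
      laa_full = 100 * mean(v >= config$laa_full_range[1] &
                              v <= config$laa_full_range[2]),
      laa_narrow = 100 * mean(v >= config$laa_narrow_range[1] &
                                v <= config$laa_narrow_range[2]))
  }
  if (combine == "pool" || is.null(labs)) {
    s <- one(sl_vals[sl_mask])
  } else {
    sl_labs <- labs[, , level_z]
    ids <- unique(sl_labs[sl_labs > 0L])
    per <- vapply(ids, function(id) one(sl_vals[sl_labs == id]), numeric(3))
    s <- rowMeans(per)
  }
  density_summary(level_id, s[["mld"]], s[["laa_full"]], s[["laa_narrow"]],
                  sum(sl_mask))
}

#' Densitometric summaries at four levels plus their mean
#'
#' Evaluates [summarize_level()] at the four supplied slice positions
#' (upper lobes, carina, and two between carina and diaphragm in the
#' acquisition this emulates) and appends their unweighted mean as a fifth
#' row labelled `"mean"`.
#'
#' @param volume A [ct_volume].
#' @param mask A `lung_mask`.
#' @param levels Integer vector of 4 distinct slice indices, given (and
#'   labelled 1-4) from cranial to caudal.
#' @param config A [quant_config].
#' @param combine Passed to [summarize_level()].
#' @return A 5-row `density_summary` data.frame (levels `"1"`..`"4"` and
#'   `"mean"`).
#' @export
summarize_volume <- function(volume, mask, levels, config = quant_config(),
                             combine = "pool") {
  levels <- as.integer(levels)
  if (length(levels) != 4L || anyDuplicated(levels)) {
    stop("`levels` must be 4 distinct slice indices", call. = FALSE)
  }
  if (is.unsorted(rev(levels), strictly = TRUE) &&
      is.unsorted(levels, strictly = TRUE)) {
    stop("`levels` must be strictly ordered along the cranio-caudal axis",
         call. = FALSE)
  }
  rows <- lapply(seq_along(levels), function(i) {
    summarize_level(volume, mask, levels[i], config, combine,
                    level_id = as.character(i))
  })
  out <- do.call(rbind, rows)
  mean_row <- density_summary("mean", mean(out$mld), mean(out$laa_full_pct),
                              mean(out$laa_narrow_pct), sum(out$n_voxels))
  out <- rbind(out, mean_row)
  class(out) <- c("density_summary", "data.frame")
  out
}

#' Default level positions for a phantom
#'
#' Picks four slice indices inside the cranio-caudal extent of a mask at
#' fixed relative depths (apex-ward to base-ward), standing in for the
#' manually matched anatomical landmarks of a real acquisition.
#'
#' @param mask A `lung_mask` or logical array.
#' @param depths Relative positions within the lung extent, cranial first.
#' @return Integer vector of 4 slice indices, cranial to caudal.
#' @export
default_levels <- function(mask, depths = c(0.8, 0.6, 0.4, 0.25)) {
  m <- if (inherits(mask, "lung_mask")) mask$mask else mask
  zs <- which(apply(m, 3, any))
  if (!length(zs)) stop("mask is empty", call. = FALSE)
  zr <- range(zs)
  lev <- round(zr[1] + depths * diff(zr))
  as.integer(lev)
}

#' Jaccard overlap of two masks
#'
#' @param a,b Logical arrays (or `lung_mask`s) of identical shape.
#' @return Intersection over union.
#' @export
jaccard <- function(a, b) {
  ma <- if (inherits(a, "lung_mask")) a$mask else a
  mb <- if (inherits(b, "lung_mask")) b$mask else b
  stopifnot(identical(dim(ma), dim(mb)))
  u <- sum(ma | mb)
  if (u == 0) return(1)
  sum(ma & mb) / u
}
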
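# Voxelized nonuniform expansion: rasterize the CTV, build the PTV as the
# union of per-boundary-sample balls of locally varying margin radius, and
# measure the margin volume V_PTV - V_CTV on an isotropic lattice.
#
# All grids are aligned to the global lattice of integer multiples of the
# spacing, so occupancy counts of a fixed structure are identical whatever
# bounding box a particular evaluation happens to use.

#' Axis-aligned voxel grid
#'
#' Builds an isotropic occupancy lattice whose voxel centers sit on integer
#' multiples of `spacing`, covering `[lower, upper]` in every axis.
#'
#' @param lower,upper Length-3 numeric bounds, mm.
#' @param spacing Isotropic voxel spacing, mm (> 0).
#' @return A `voxel_grid`: list with `origin` (center of voxel (1,1,1)),
#'   `spacing`, `shape`, and (once filled) a logical `occupancy` array.
#' @export
voxel_grid <- function(lower, upper, spacing) {
  stopifnot(spacing > 0)
  lower <- as_point3(lower); upper <- as_point3(upper)
  if (any(upper < lower)) stop("`upper` must be >= `lower`", call. = FALSE)
  ilo <- floor(lower / spacing)
  ihi <- ceiling(upper / spacing)
  structure(
    list(
      origin = ilo * spacing,
      spacing = spacing,
      shape = as.integer(ihi - ilo + 1),
      occupancy = NULL
    ),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf(
    "Voxel grid %d x %d x %d at %.3g mm spacing, origin (%.2f, %.2f, %.2f) mm",
    x$shape[1], x$shape[2], x$shape[3], x$spacing,
    x$origin[1], x$origin[2], x$origin[3]
  ))
  if (!is.null(x$occupancy)) {
    cat(sprintf("; %d voxels occupied (%.1f mm^3)",
                sum(x$occupancy), occupied_volume(x)))
  }
  cat("\n")
  invisible(x)
}

#' Volume of the occupied voxels of a grid
#' @param grid A `voxel_grid` with occupancy filled in.
#' @return Occupied volume, mm^3.
#' @export
occupied_volume <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"), !is.null(grid$occupancy))
  sum(grid$occupancy) * grid$spacing^3
}

# Coordinates of all voxel centers (n x 3), in grid index order (x fastest).
voxel_centers <- function(grid) {
  g <- lapply(1:3, function(a) {
    grid$origin[a] + (seq_len(grid$shape[a]) - 1) * grid$spacing
  })
  cbind(
    rep(g[[1]], times = grid$shape[2] * grid$shape[3]),
    rep(rep(g[[2]], each = grid$shape[1]), times = grid$shape[3]),
    rep(g[[3]], each = grid$shape[1] * grid$shape[2])
  )
}

fill_ctv_occupancy <- function(ts, grid) {
  n <- prod(grid$shape)
  occ <- logical(n)
  spheres <- Filter(function(t) t$source == "analytic_sphere", ts$targets)
  if (length(spheres) > 0) {
    centers <- t(vapply(spheres, function(t) t$sphere$center, numeric(3)))
    radii <- vapply(spheres, function(t) t$sphere$diameter / 2, numeric(1))
    occ <- occ | cpp_rasterize_spheres(grid$origin, grid$spacing, grid$shape,
                                       centers, radii)
  }
  for (t in ts$targets) {
    if (t$source == "mesh") {
      occ <- occ | cpp_rasterize_mesh(grid$origin, grid$spacing, grid$shape,
                                      t$mesh$vertices,
                                      matrix(as.integer(t$mesh$faces), ncol = 3))
    }
  }
  occ
}

#' Rasterize the clinical target volume (CTV)
#'
#' Marks every voxel whose center lies inside any target: spheres are tested
#' analytically, meshes by ray-crossing parity.
#'
#' @param ts A [target_set()].
#' @param spacing Voxel spacing, mm. Ignored when `grid` is supplied.
#' @param grid Optional pre-built [voxel_grid()] (must enclose the targets).
#' @param padding Extra clearance added around the targets, mm.
#' @return A `voxel_grid` with the occupancy filled in.
#' @export
rasterize_ctv <- function(ts, spacing = 0.5, grid = NULL, padding = 1) {
  stopifnot(inherits(ts, "target_set"))
  if (is.null(grid)) {
    bb <- target_bounds(ts, rep(padding, ts$n))
    grid <- voxel_grid(bb$lower, bb$upper, spacing)
  }
  occ <- fill_ctv_occupancy(ts, grid)
  grid$occupancy <- array(occ, dim = grid$shape)
  grid
}

# Per-target expanded bounding boxes; extra[i] is the clearance (mm).
target_bounds <- function(ts, extra) {
  lows <- highs <- matrix(NA_real_, ts$n, 3)
  for (i in seq_len(ts$n)) {
    lows[i, ] <- apply(ts$targets[[i]]$points, 2, min) - extra[i]
    highs[i, ] <- apply(ts$targets[[i]]$points, 2, max) + extra[i]
  }
  list(lower = apply(lows, 2, min), upper = apply(highs, 2, max),
       lows = lows, highs = highs)
}

#' Expand the CTV into the nonuniform-margin PTV
#'
#' The PTV is the union of the CTV with balls centered on every boundary
#' sample, each ball's radius being that point's combined margin
#' ([point_margin()]) for the given isocenter. Because the margin grows with
#' distance from the isocenter, the expansion is nonuniform: target regions
#' far from the isocenter receive a thicker shell.
#'
#' @inheritParams rasterize_ctv
#' @param isocenter Length-3 numeric, mm.
#' @param uncertainty A [setup_uncertainty()] object.
#' @return A `voxel_grid` with the PTV occupancy filled in. The grid (when
#'   not supplied) is sized to hold every target plus its maximum margin.
#' @export
expand_ptv <- function(ts, isocenter, uncertainty, spacing = 0.5, grid = NULL) {
  stopifnot(inherits(ts, "target_set"))
  isocenter <- as_point3(isocenter)
  margins <- lapply(ts$targets, function(t) {
    point_margin(t$points, isocenter, uncertainty)$margin
  })
  if (is.null(grid)) {
    extra <- vapply(margins, max, numeric(1)) + spacing
    bb <- target_bounds(ts, extra)
    grid <- voxel_grid(bb$lower, bb$upper, spacing)
  }
  ctv <- fill_ctv_occupancy(ts, grid)
  samples <- do.call(rbind, lapply(ts$targets, `[[`, "points"))
  radii <- unlist(margins)
  occ <- cpp_stamp_balls(grid$origin, grid$spacing, grid$shape, ctv,
                         samples, radii)
  grid$occupancy <- array(occ, dim = grid$shape)
  grid
}

# Partition targets into groups whose expanded bounding boxes overlap, so
# distant targets get small local grids while touching PTVs still share one
# lattice for correct union counting.
overlap_groups <- function(lows, highs) {
  n <- nrow(lows)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (all(lows[i, ] <= highs[j, ]) && all(lows[j, ] <= highs[i, ])) {
        parent[find(j)] <- find(i)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(seq_len(n), roots)
}

#' Margin volume of a candidate isocenter
#'
#' The objective the isocenter optimizers minimize: the volume of the
#' nonuniformly expanded shell, `V_PTV - V_CTV`, measured by voxel counting.
#' Overlapping per-target expansions are counted once (boolean union). For
#' efficiency each well-separated group of targets is voxelized on its own
#' local lattice; all lattices are aligned to one global grid so the result
#' is identical to using a single enclosing grid.
#'
#' @inheritParams expand_ptv
#' @param per_target If `TRUE`, attach a per-target breakdown (each target
#'   expanded on its own; overlap between targets, if any, makes the
#'   breakdown sum exceed the unioned total).
#' @return A `margin_volume_result`: list with `isocenter`, `v_ctv`, `v_ptv`,
#'   `v_margin` (mm^3), `spacing`, and optionally `per_target`.
#' @examples
#' ts <- phantom_targets("pair-6-15")
#' u <- setup_uncertainty(m_s = 2, sigma_d = 0.5)
#' margin_volume(ts, center_of_geometry(ts), u, spacing = 1)
#' @export
margin_volume <- function(ts, isocenter, uncertainty, spacing = 0.5,
                          per_target = FALSE) {
  stopifnot(inherits(ts, "target_set"), spacing > 0)
  isocenter <- as_point3(isocenter)
  margins <- lapply(ts$targets, function(t) {
    point_margin(t$points, isocenter, uncertainty)$margin
  })
  extra <- vapply(margins, max, numeric(1)) + spacing
  bb <- target_bounds(ts, extra)
  groups <- overlap_groups(bb$lows, bb$highs)

  n_ctv_tot <- 0; n_ptv_tot <- 0
  detail <- if (per_target) vector("list", ts$n) else NULL
  for (g in groups) {
    sub <- target_set(ts$targets[g])
    lo <- apply(bb$lows[g, , drop = FALSE], 2, min)
    hi <- apply(bb$highs[g, , drop = FALSE], 2, max)
    grid <- voxel_grid(lo, hi, spacing)
    ctv <- fill_ctv_occupancy(sub, grid)
    samples <- do.call(rbind, lapply(sub$targets, `[[`, "points"))
    radii <- unlist(margins[g])
    ptv <- cpp_stamp_balls(grid$origin, grid$spacing, grid$shape, ctv,
                           samples, radii)
    n_ctv_tot <- n_ctv_tot + sum(ctv)
    n_ptv_tot <- n_ptv_tot + sum(ptv)
    if (per_target) {
      for (i in g) {
        one <- target_set(ts$targets[[i]])
        g1 <- voxel_grid(bb$lows[i, ], bb$highs[i, ], spacing)
        c1 <- fill_ctv_occupancy(one, g1)
        p1 <- cpp_stamp_balls(g1$origin, g1$spacing, g1$shape, c1,
                              ts$targets[[i]]$points, margins[[i]])
        detail[[i]] <- data.frame(
          label = ts$targets[[i]]$label,
          v_ctv = sum(c1) * spacing^3,
          v_ptv = sum(p1) * spacing^3,
          v_margin = (sum(p1) - sum(c1)) * spacing^3
        )
      }
    }
  }
  out <- list(
    isocenter = isocenter,
    v_ctv = n_ctv_tot * spacing^3,
    v_ptv = n_ptv_tot * spacing^3,
    v_margin = (n_ptv_tot - n_ctv_tot) * spacing^3,
    spacing = spacing
  )
  if (per_target) out$per_target <- do.call(rbind, detail)
  structure(out, class = "margin_volume_result")
}

#' @export
print.margin_volume_result <- function(x, ...) {
  cat(sprintf(
    "Margin volume at isocenter (%.2f, %.2f, %.2f) mm [%.3g mm voxels]:\n",
    x$isocenter[1], x$isocenter[2], x$isocenter[3], x$spacing
  ))
  cat(sprintf("  V_CTV = %.1f mm^3, V_PTV = %.1f mm^3, V_margin = %.1f mm^3\n",
              x$v_ctv, x$v_ptv, x$v_margin))
  if (!is.null(x$per_target)) {
    print(x$per_target, row.names = FALSE)
  }
  invisible(x)
}
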
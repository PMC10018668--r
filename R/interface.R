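# Case-file input/output, orchestration of a full run, and the scripted
# sphere-phantom benchmark reproductions (two-sphere table, line sweeps,
# planar normalized-volume maps).

case_defaults <- list(alpha = 0.95, spacing = 0.5, spacing_optimize = 1,
                      method = "asa", seed = 0L, grid_step = 1,
                      max_evals = 2000L, patience = 300L)

#' Load and validate a JSON case file
#'
#' A case file describes one problem instance: the targets (spheres by center
#' and diameter, or paths to OFF/STL meshes), the setup-uncertainty
#' parameters, and optional optimizer/grid settings. Missing optional fields
#' are filled with the documented defaults (`alpha` 0.95, final spacing
#' 0.5 mm, optimization spacing 1 mm, method `"asa"`, seed 0).
#'
#' @param path Path to a JSON case file.
#' @return A validated `case_spec` list.
#' @seealso [write_case()], [run_case()]
#' @export
load_case <- function(path) {
  if (!file.exists(path)) stop("case file not found: ", path, call. = FALSE)
  spec <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  validate_case(spec, dir = dirname(path))
}

#' Validate a case specification
#'
#' @param spec A list with elements `targets`, `uncertainty`, and optionally
#'   `optimizer` and `grid`.
#' @param dir Directory against which relative mesh paths are resolved.
#' @return The spec with defaults applied, classed `case_spec`.
#' @export
validate_case <- function(spec, dir = ".") {
  problems <- character()
  note <- function(msg) problems <<- c(problems, msg)

  tg <- spec$targets
  if (is.null(tg) || length(tg) < 1) note("targets: at least one target required")
  for (i in seq_along(tg)) {
    t <- tg[[i]]
    where <- sprintf("targets[%d]", i)
    has_sphere <- !is.null(t$sphere)
    has_mesh <- !is.null(t$mesh)
    if (has_sphere == has_mesh) {
      note(paste0(where, ": give exactly one of `sphere` or `mesh`"))
    } else if (has_sphere) {
      if (length(t$sphere$center) != 3 || !is.numeric(t$sphere$center)) {
        note(paste0(where, ".sphere.center: need 3 numeric coordinates (mm)"))
      }
      if (!is.numeric(t$sphere$diameter) || length(t$sphere$diameter) != 1 ||
          t$sphere$diameter <= 0) {
        note(paste0(where, ".sphere.diameter: need one positive number (mm)"))
      }
    } else {
      mp <- t$mesh
      if (!is.character(mp) || length(mp) != 1) {
        note(paste0(where, ".mesh: need a file path"))
      } else if (!file.exists(mp) && !file.exists(file.path(dir, mp))) {
        note(paste0(where, ".mesh: file not found: ", mp))
      }
    }
    if (is.null(t$label)) spec$targets[[i]]$label <- paste0("T", i)
  }
  labels <- vapply(spec$targets, function(t) as.character(t$label), character(1))
  if (anyDuplicated(labels)) note("targets: labels must be unique")

  un <- spec$uncertainty
  if (is.null(un)) {
    note("uncertainty: required")
  } else {
    if (is.null(un$m_s) == is.null(un$sigma_s)) {
      note("uncertainty: give exactly one of `m_s` or `sigma_s` (mm)")
    }
    if (is.null(un$sigma_d) || !is.numeric(un$sigma_d) || un$sigma_d < 0) {
      note("uncertainty.sigma_d: need a non-negative number (degrees)")
    }
    if (is.null(un$alpha)) {
      spec$uncertainty$alpha <- case_defaults$alpha
    } else if (!is.numeric(un$alpha) || un$alpha <= 0 || un$alpha >= 1) {
      note("uncertainty.alpha: must lie strictly between 0 and 1")
    }
  }

  opt <- if (is.null(spec$optimizer)) list() else spec$optimizer
  if (is.null(opt$method)) opt$method <- case_defaults$method
  if (!opt$method %in% c("asa", "grid")) {
    note("optimizer.method: must be 'asa' or 'grid'")
  }
  if (is.null(opt$seed)) opt$seed <- case_defaults$seed
  if (is.null(opt$grid_step)) opt$grid_step <- case_defaults$grid_step
  if (is.null(opt$max_evals)) opt$max_evals <- case_defaults$max_evals
  if (is.null(opt$patience)) opt$patience <- case_defaults$patience
  spec$optimizer <- opt

  grd <- if (is.null(spec$grid)) list() else spec$grid
  if (is.null(grd$spacing)) grd$spacing <- case_defaults$spacing
  if (is.null(grd$spacing_optimize)) grd$spacing_optimize <- case_defaults$spacing_optimize
  if (any(c(grd$spacing, grd$spacing_optimize) <= 0)) {
    note("grid: spacings must be positive (mm)")
  }
  spec$grid <- grd

  if (length(problems) > 0) {
    stop("invalid case specification:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  spec$.dir <- dir
  class(spec) <- "case_spec"
  spec
}

#' Write a case specification to JSON
#'
#' @param spec A `case_spec` (or plain list in the same shape).
#' @param path Output path.
#' @export
write_case <- function(spec, path) {
  spec$.dir <- NULL
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Build the target set described by a case specification
#'
#' @param spec A `case_spec` from [load_case()] / [validate_case()].
#' @param density Boundary sampling density, points per mm^2.
#' @return A [target_set()].
#' @export
case_targets <- function(spec, density = 1) {
  stopifnot(inherits(spec, "case_spec"))
  dir <- if (is.null(spec$.dir)) "." else spec$.dir
  target_set(lapply(spec$targets, function(t) {
    if (!is.null(t$sphere)) {
      sphere_target(as.numeric(t$sphere$center), t$sphere$diameter,
                    label = t$label, density = density)
    } else {
      mp <- if (file.exists(t$mesh)) t$mesh else file.path(dir, t$mesh)
      m <- read_mesh(mp)
      mesh_target(m$vertices, m$faces, label = t$label)
    }
  }))
}

#' Build the [setup_uncertainty()] described by a case specification
#'
#' @param spec A `case_spec`.
#' @export
case_uncertainty <- function(spec) {
  un <- spec$uncertainty
  if (!is.null(un$m_s)) {
    setup_uncertainty(m_s = un$m_s, sigma_d = un$sigma_d, alpha = un$alpha)
  } else {
    setup_uncertainty(sigma_s = un$sigma_s, sigma_d = un$sigma_d, alpha = un$alpha)
  }
}

#' Run a case: optimize the isocenter and compare against references
#'
#' Orchestrates geometry construction, voxel expansion and optimization for
#' one case: builds the targets, runs the configured optimizer (ASA or grid
#' search), evaluates COG/COV/COS and the optimum on the final grid, and
#' returns a structured, serializable report. Deterministic given the seed.
#'
#' @param spec A `case_spec`.
#' @param with_nso Also run the exhaustive grid search (slow for three or
#'   more targets) in addition to the configured method.
#' @return A `run_report`: list with `case`, `table` (the comparison data
#'   frame), `seed`, `spacings`, `version`.
#' @export
run_case <- function(spec, with_nso = FALSE) {
  stopifnot(inherits(spec, "case_spec"))
  ts <- case_targets(spec)
  u <- case_uncertainty(spec)
  methods <- c("COG", "COV", "COS")
  if (with_nso || spec$optimizer$method == "grid") methods <- c(methods, "NSO")
  if (spec$optimizer$method == "asa") methods <- c(methods, "ASA")
  cfg <- asa_config(seed = spec$optimizer$seed,
                    max_evals = spec$optimizer$max_evals,
                    patience = spec$optimizer$patience,
                    spacing = spec$grid$spacing_optimize)
  tab <- compare_isocenters(
    ts, u,
    seed = spec$optimizer$seed,
    methods = methods,
    spacing_opt = spec$grid$spacing_optimize,
    spacing_final = spec$grid$spacing,
    step = spec$optimizer$grid_step,
    asa = cfg
  )
  structure(
    list(
      case = spec,
      table = tab,
      seed = spec$optimizer$seed,
      spacings = c(optimize = spec$grid$spacing_optimize,
                   final = spec$grid$spacing),
      version = as.character(utils::packageVersion("isomargin"))
    ),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("isomargin run (v%s, seed %d, %g/%g mm grids)\n",
              x$version, x$seed, x$spacings["optimize"], x$spacings["final"]))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a run report to JSON (and optionally a TSV comparison table)
#'
#' @param report A `run_report`.
#' @param path Output JSON path.
#' @param tsv Optional path for a flat TSV of the comparison table.
#' @export
write_report <- function(report, path, tsv = NULL) {
  stopifnot(inherits(report, "run_report"))
  payload <- list(
    version = report$version,
    seed = report$seed,
    spacings = as.list(report$spacings),
    case = {
      cs <- report$case; cs$.dir <- NULL; unclass(cs)
    },
    table = report$table
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  if (!is.null(tsv)) {
    utils::write.table(report$table, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Normalized optimal margin volumes for two-sphere configurations
#'
#' Reproduces the two-sphere benchmark sweep: for every combination of the
#' two diameters and the rotational SD, places the spheres `separation` mm
#' apart, finds the optimal isocenter on the segment joining the centers
#' (exhaustive search), and reports the optimal margin volume normalized to
#' the value at the midpoint (the COG), all on the final grid.
#'
#' @param d1,d2 Diameters of the first and second sphere, mm (vectors).
#' @param sigma_d Rotational SDs to evaluate, degrees (vector).
#' @param m_s Translational margin, mm.
#' @param separation Center separation, mm.
#' @param step Segment search step, mm.
#' @param spacing_opt,spacing_final Voxel spacings, mm.
#' @return Data frame with columns `d1`, `d2`, `sigma_d`, `x_opt` (mm along
#'   the axis), `normalized` (optimal / COG margin volume).
#' @export
two_sphere_table <- function(d1 = c(5, 10), d2 = c(5, 10, 20, 30, 40),
                             sigma_d = c(0.5, 1.0), m_s = 2, separation = 100,
                             step = 1, spacing_opt = 1, spacing_final = 0.5) {
  cells <- expand.grid(d1 = d1, d2 = d2, sigma_d = sigma_d,
                       KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    ts <- phantom_targets(sprintf("pair-%g-%g", cells$d1[i], cells$d2[i]),
                          separation = separation)
    u <- setup_uncertainty(m_s = m_s, sigma_d = cells$sigma_d[i])
    g <- grid_search_isocenter(ts, u, step = step, spacing = spacing_opt,
                               spacing_final = spacing_final,
                               restriction = "segment")
    v_opt <- g$v_margin
    v_cog <- margin_volume(ts, center_of_geometry(ts), u,
                           spacing = spacing_final)$v_margin
    data.frame(d1 = cells$d1[i], d2 = cells$d2[i], sigma_d = cells$sigma_d[i],
               x_opt = g$position[1], normalized = v_opt / v_cog)
  })
  do.call(rbind, res)
}

#' Normalized margin volume along the line joining two targets
#'
#' Sweeps the isocenter along the segment between the two target centroids
#' and reports the margin volume normalized to the COG value, together with
#' the positions of the reference isocenters and the curve minimum -- the
#' one-dimensional profile from which the optimal isocenter for a two-target
#' case can be read off.
#'
#' @inheritParams margin_volume
#' @param step Sample step along the segment, mm.
#' @return Data frame with `position` (mm from the first centroid), `x`, `y`,
#'   `z`, `v_margin`, `normalized`; attributes `marks` (named positions of
#'   COG/COV/COS and the curve minimum, mm) and `spacing`.
#' @export
sweep_line <- function(ts, uncertainty, step = 1, spacing = 0.5) {
  stopifnot(inherits(ts, "target_set"), ts$n == 2L)
  a <- ts$targets[[1]]$centroid
  b <- ts$targets[[2]]$centroid
  len <- sqrt(sum((b - a)^2))
  tt <- seq(0, 1, by = step / len)
  if (tt[length(tt)] < 1) tt <- c(tt, 1)
  cand <- cbind(a[1] + tt * (b[1] - a[1]),
                a[2] + tt * (b[2] - a[2]),
                a[3] + tt * (b[3] - a[3]))
  vals <- apply(cand, 1, function(p) {
    margin_volume(ts, p, uncertainty, spacing = spacing)$v_margin
  })
  v_cog <- margin_volume(ts, center_of_geometry(ts), uncertainty,
                         spacing = spacing)$v_margin
  proj <- function(p) sum((p - a) * (b - a)) / len
  out <- data.frame(position = tt * len, x = cand[, 1], y = cand[, 2],
                    z = cand[, 3], v_margin = vals, normalized = vals / v_cog)
  attr(out, "marks") <- c(
    COG = proj(center_of_geometry(ts)),
    COV = proj(center_of_volume(ts)),
    COS = proj(center_of_surface(ts)),
    optimum = tt[which.min(vals)] * len
  )
  attr(out, "spacing") <- spacing
  out
}

#' Planar map of normalized margin volume
#'
#' Evaluates the normalized margin volume on a regular lattice of isocenter
#' candidates in an axis-aligned plane through the target centroids -- the
#' heat-map view of the objective for a two-target case. Exported as a plain
#' data frame (x, y, z, value) suitable for delimited-text output.
#'
#' @inheritParams margin_volume
#' @param step Lattice step in the plane, mm.
#' @param plane Fixed axis, one of `"z"`, `"y"`, `"x"`.
#' @param pad Padding beyond the centroid bounding box, mm.
#' @return Data frame with columns `x`, `y`, `z`, `value` (normalized to the
#'   COG margin volume).
#' @export
normalized_volume_map <- function(ts, uncertainty, step = 5, spacing = 1,
                                  plane = c("z", "y", "x"), pad = 10) {
  stopifnot(inherits(ts, "target_set"))
  plane <- match.arg(plane)
  fixed <- match(plane, c("x", "y", "z"))
  cent <- target_centroids(ts)
  bd <- search_bounds(ts, pad)
  ax <- lapply(1:3, function(i) {
    if (i == fixed) return(mean(cent[, i]))
    seq(bd$lower[i], bd$upper[i], by = step)
  })
  cand <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                                KEEP.OUT.ATTRS = FALSE))
  v_cog <- margin_volume(ts, center_of_geometry(ts), uncertainty,
                         spacing = spacing)$v_margin
  vals <- apply(cand, 1, function(p) {
    margin_volume(ts, p, uncertainty, spacing = spacing)$v_margin
  })
  data.frame(x = cand[, 1], y = cand[, 2], z = cand[, 3],
             value = vals / v_cog)
}
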
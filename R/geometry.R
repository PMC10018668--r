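# Target representation: analytic spheres sampled on subdivided-icosahedron
# lattices, closed triangle meshes, and the COG/COV/COS reference isocenters.

#' Unit icosphere vertices
#'
#' Vertices of a unit sphere obtained by repeated 4-to-1 subdivision of an
#' icosahedron, with every new vertex projected back onto the sphere. The
#' vertex count at subdivision level `k` is `10 * 4^k + 2`. The point set is
#' quasi-uniform and deterministic (no random seed), and inherits the
#' icosahedron's inversion symmetry.
#'
#' @param subdivisions Non-negative integer subdivision level.
#' @param faces If `TRUE`, also return the triangle index matrix.
#' @return An n x 3 matrix of unit vectors, or if `faces = TRUE` a list with
#'   `vertices` and 1-based `faces`.
#' @export
icosphere <- function(subdivisions = 2L, faces = FALSE) {
  stopifnot(subdivisions >= 0, subdivisions <= 7)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    edge_key <- function(a, b) ifelse(a < b, a * (nv + 1L) + b, b * (nv + 1L) + a)
    e1 <- edge_key(f[, 1], f[, 2])
    e2 <- edge_key(f[, 2], f[, 3])
    e3 <- edge_key(f[, 3], f[, 1])
    keys <- unique(c(e1, e2, e3))
    mid_id <- setNames(seq_along(keys) + nv, keys)
    a <- keys %/% (nv + 1L); b <- keys %% (nv + 1L)
    mids <- (v[a, , drop = FALSE] + v[b, , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    m1 <- mid_id[as.character(e1)]
    m2 <- mid_id[as.character(e2)]
    m3 <- mid_id[as.character(e3)]
    f <- rbind(
      cbind(f[, 1], m1, m3),
      cbind(f[, 2], m2, m1),
      cbind(f[, 3], m3, m2),
      cbind(m1, m2, m3)
    )
  }
  dimnames(v) <- NULL
  if (faces) list(vertices = v, faces = unname(f)) else v
}

#' Spherical target with sampled boundary
#'
#' Builds a target from an analytic sphere: quasi-uniform boundary samples on
#' a subdivided icosahedron, with exact analytic volume `pi/6 * D^3` and
#' surface area `pi * D^2` attached. The subdivision level is the smallest
#' one giving at least `density` sample points per mm^2 of surface (so the
#' default guarantees >= 1 point per mm^2).
#'
#' @param center Length-3 numeric, mm.
#' @param diameter Sphere diameter, mm (> 0).
#' @param label Target label (unique within a target set).
#' @param density Minimum sampling density, points per mm^2.
#' @param subdivisions Optional explicit subdivision level overriding
#'   `density`.
#' @return A `target_surface` object.
#' @export
sphere_target <- function(center, diameter, label = "target",
                          density = 1, subdivisions = NULL) {
  if (!is.numeric(diameter) || length(diameter) != 1L || diameter <= 0) {
    stop("`diameter` must be a positive number", call. = FALSE)
  }
  center <- as_point3(center)
  area <- pi * diameter^2
  if (is.null(subdivisions)) {
    subdivisions <- 0L
    while (10 * 4^subdivisions + 2 < density * area && subdivisions < 7L) {
      subdivisions <- subdivisions + 1L
    }
  }
  pts <- icosphere(subdivisions) * (diameter / 2)
  pts <- sweep(pts, 2L, center, "+")
  structure(
    list(
      label = as.character(label),
      points = pts,
      centroid = center,
      volume = pi / 6 * diameter^3,
      surface_area = area,
      source = "analytic_sphere",
      sphere = list(center = center, diameter = diameter)
    ),
    class = "target_surface"
  )
}

#' Target from a closed triangle mesh
#'
#' Volume, surface area and centroid are computed from the mesh by signed
#' tetrahedra / the divergence theorem ([mesh_properties()]); the boundary
#' samples are the mesh vertices.
#'
#' @param vertices n x 3 vertex matrix, mm.
#' @param faces m x 3 matrix of 1-based vertex indices, consistently oriented
#'   outward.
#' @param label Target label.
#' @return A `target_surface` object.
#' @export
mesh_target <- function(vertices, faces, label = "target") {
  props <- mesh_properties(vertices, faces)
  structure(
    list(
      label = as.character(label),
      points = as_point_matrix(vertices),
      centroid = props$centroid,
      volume = props$volume,
      surface_area = props$surface_area,
      source = "mesh",
      mesh = list(vertices = as_point_matrix(vertices),
                  faces = as.matrix(faces))
    ),
    class = "target_surface"
  )
}

#' @export
print.target_surface <- function(x, ...) {
  cat(sprintf(
    "Target '%s' (%s): centroid (%.2f, %.2f, %.2f) mm, V = %.1f mm^3, A = %.1f mm^2, %d boundary samples\n",
    x$label, x$source, x$centroid[1], x$centroid[2], x$centroid[3],
    x$volume, x$surface_area, nrow(x$points)
  ))
  invisible(x)
}

#' Ordered set of targets
#'
#' @param ... `target_surface` objects (or a single list of them).
#' @return A `target_set` with unique labels.
#' @export
target_set <- function(...) {
  targets <- list(...)
  if (length(targets) == 1L && !inherits(targets[[1L]], "target_surface")) {
    targets <- targets[[1L]]
  }
  if (length(targets) < 1L) stop("at least one target is required", call. = FALSE)
  ok <- vapply(targets, inherits, logical(1), "target_surface")
  if (!all(ok)) stop("all elements must be target_surface objects", call. = FALSE)
  labels <- vapply(targets, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("target labels must be unique", call. = FALSE)
  structure(list(targets = targets, n = length(targets)), class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat(sprintf("Target set with %d target(s); total V = %.1f mm^3, A = %.1f mm^2\n",
              x$n, total_volume(x), total_area(x)))
  for (t in x$targets) print(t)
  invisible(x)
}

#' @export
length.target_set <- function(x) x$n

target_centroids <- function(ts) {
  t(vapply(ts$targets, `[[`, numeric(3), "centroid"))
}

total_volume <- function(ts) sum(vapply(ts$targets, `[[`, numeric(1), "volume"))
total_area <- function(ts) sum(vapply(ts$targets, `[[`, numeric(1), "surface_area"))

#' Reference isocenters: centers of geometry, volume and surface
#'
#' `center_of_geometry()` is the unweighted mean of the target centroids;
#' `center_of_volume()` weights each centroid by the target volume `k_i / V`;
#' `center_of_surface()` weights by the surface area `a_i / A`. These are the
#' conventional candidate isocenters against which the optimized isocenter is
#' benchmarked.
#'
#' @param ts A [target_set()].
#' @return Length-3 numeric position, mm.
#' @export
center_of_geometry <- function(ts) {
  stopifnot(inherits(ts, "target_set"))
  colMeans(target_centroids(ts))
}

#' @rdname center_of_geometry
#' @export
center_of_volume <- function(ts) {
  stopifnot(inherits(ts, "target_set"))
  w <- vapply(ts$targets, `[[`, numeric(1), "volume")
  colSums(target_centroids(ts) * w) / sum(w)
}

#' @rdname center_of_geometry
#' @export
center_of_surface <- function(ts) {
  stopifnot(inherits(ts, "target_set"))
  w <- vapply(ts$targets, `[[`, numeric(1), "surface_area")
  colSums(target_centroids(ts) * w) / sum(w)
}

#' Volume, surface area and centroid of a closed triangle mesh
#'
#' The volume is the sum of signed tetrahedra spanned by the origin and each
#' triangle; the centroid follows from the same decomposition (divergence
#' theorem); the area is the sum of triangle areas. The mesh must be closed
#' (every edge shared by exactly two triangles) and consistently oriented;
#' a negative total signed volume indicates inward orientation and is
#' reported as an error.
#'
#' @param vertices n x 3 vertex matrix, mm.
#' @param faces m x 3 matrix of 1-based vertex indices.
#' @return A list with `volume` (mm^3), `surface_area` (mm^2), `centroid`.
#' @export
mesh_properties <- function(vertices, faces) {
  v <- as_point_matrix(vertices)
  f <- as.matrix(faces)
  if (ncol(f) != 3L) stop("`faces` must be an m x 3 index matrix", call. = FALSE)
  if (any(f < 1L) || any(f > nrow(v))) stop("face index out of range", call. = FALSE)
  # closedness: each undirected edge must appear exactly twice
  edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  cnt <- table(key)
  if (any(cnt != 2L)) {
    stop("mesh is not closed: every edge must be shared by exactly two triangles",
         call. = FALSE)
  }
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  cross_bc <- cbind(
    b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
    b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
    b[, 1] * c_[, 2] - b[, 2] * c_[, 1]
  )
  vol_t <- rowSums(a * cross_bc) / 6
  volume <- sum(vol_t)
  if (volume < 0) {
    stop(sprintf("mesh has negative signed volume (%.4g mm^3): faces are oriented inward",
                 volume), call. = FALSE)
  }
  if (volume == 0) stop("mesh is degenerate (zero volume)", call. = FALSE)
  ab <- b - a
  ac <- c_ - a
  cr <- cbind(
    ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
    ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
    ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1]
  )
  area <- sum(sqrt(rowSums(cr^2))) / 2
  centroid <- colSums(vol_t * (a + b + c_) / 4) / volume
  list(volume = volume, surface_area = area, centroid = centroid)
}

#' Read a triangle mesh from an OFF or ASCII STL file
#'
#' Minimal readers for the two plain-text mesh formats accepted as target
#' input. STL files carry no vertex indexing, so coincident vertices are
#' merged before use.
#'
#' @param path File path; format detected from the extension (`.off`, `.stl`).
#' @return A list with `vertices` and 1-based `faces`.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    off = read_off(path),
    stl = read_stl_ascii(path),
    stop("unsupported mesh format: .", ext, " (use OFF or ASCII STL)", call. = FALSE)
  )
}

read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (toupper(lines[1]) != "OFF") stop("not an OFF file", call. = FALSE)
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  verts <- matrix(scan(text = paste(lines[3:(2 + nv)], collapse = "\n"),
                       quiet = TRUE), ncol = 3, byrow = TRUE)
  face_rows <- lapply(lines[(3 + nv):(2 + nv + nf)], function(l) {
    x <- scan(text = l, quiet = TRUE)
    if (x[1] != 3) stop("only triangle faces are supported", call. = FALSE)
    x[2:4] + 1
  })
  list(vertices = verts, faces = do.call(rbind, face_rows))
}

read_stl_ascii <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  vx <- lines[startsWith(lines, "vertex")]
  if (length(vx) == 0 || length(vx) %% 3 != 0) {
    stop("not a valid ASCII STL file", call. = FALSE)
  }
  coords <- matrix(scan(text = gsub("vertex", "", vx), quiet = TRUE),
                   ncol = 3, byrow = TRUE)
  key <- apply(round(coords, 9), 1, paste, collapse = ",")
  uniq <- !duplicated(key)
  verts <- coords[uniq, , drop = FALSE]
  idx <- match(key, key[uniq])
  list(vertices = verts, faces = matrix(idx, ncol = 3, byrow = TRUE))
}

#' Benchmark phantom target sets
#'
#' Deterministic sphere-target configurations used throughout the package's
#' simulation benchmarks, in a fixed coordinate frame (mm):
#'
#' * `"pair-D1-D2"` (e.g. `"pair-5-40"`): two spheres of diameters D1 and D2
#'   centered at (0,0,0) and (100,0,0) -- 100 mm apart.
#' * `"triplet-D1-D2-D3"` (e.g. `"triplet-5-10-20"`): three spheres centered
#'   at (100,0,0), (0,100,0), (0,0,100).
#' * `"hex"`: six spheres of diameters 4, 8, 10, 12, 16, 18 mm placed at
#'   (+-60,0,0), (0,+-60,0), (0,0,+-60).
#'
#' @param config Configuration id string.
#' @param separation Center separation for `"pair"` configurations, mm.
#' @param density Boundary sampling density passed to [sphere_target()].
#' @return A [target_set()].
#' @examples
#' phantom_targets("pair-6-15")
#' @export
phantom_targets <- function(config, separation = 100, density = 1) {
  parts <- strsplit(config, "-", fixed = TRUE)[[1]]
  kind <- parts[1]
  diam <- suppressWarnings(as.numeric(parts[-1]))
  if (kind == "pair" && length(diam) == 2 && !anyNA(diam)) {
    return(target_set(
      sphere_target(c(0, 0, 0), diam[1], label = "T1", density = density),
      sphere_target(c(separation, 0, 0), diam[2], label = "T2", density = density)
    ))
  }
  if (kind == "triplet" && length(diam) == 3 && !anyNA(diam)) {
    centers <- rbind(c(100, 0, 0), c(0, 100, 0), c(0, 0, 100))
    return(target_set(lapply(1:3, function(i) {
      sphere_target(centers[i, ], diam[i], label = paste0("T", i), density = density)
    })))
  }
  if (kind == "hex" && length(diam) == 0) {
    d <- c(4, 8, 10, 12, 16, 18)
    centers <- rbind(c(60, 0, 0), c(-60, 0, 0), c(0, 60, 0),
                     c(0, -60, 0), c(0, 0, 60), c(0, 0, -60))
    return(target_set(lapply(1:6, function(i) {
      sphere_target(centers[i, ], d[i], label = paste0("T", i), density = density)
    })))
  }
  stop("unknown phantom configuration: ", config, call. = FALSE)
}
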
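# Cheap fixtures built in code: low-subdivision spheres keep voxel tests fast.

coarse_sphere <- function(center, diameter, label = "t", subdivisions = 2) {
  sphere_target(center, diameter, label = label, subdivisions = subdivisions)
}

# Unit cube as a closed, outward-oriented triangle mesh.
cube_mesh <- function(scale = 1, shift = c(0, 0, 0)) {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  v <- sweep(v * scale, 2, shift, "+")
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),  # z = 0
    c(5, 6, 7), c(6, 8, 7),  # z = 1
    c(1, 2, 5), c(2, 6, 5),  # y = 0
    c(3, 7, 4), c(4, 7, 8),  # y = 1
    c(1, 5, 3), c(3, 5, 7),  # x = 0
    c(2, 4, 6), c(4, 8, 6)   # x = 1
  )
  list(vertices = unname(v), faces = f)
}

# Brute-force PTV occupancy: test every voxel center against the CTV spheres
# and every sample ball with a plain triple loop, independent of the C++
# stamping path.
brute_force_ptv <- function(ts, isocenter, uncertainty, grid) {
  ax <- lapply(1:3, function(a) {
    grid$origin[a] + (seq_len(grid$shape[a]) - 1) * grid$spacing
  })
  margins <- lapply(ts$targets, function(t) {
    point_margin(t$points, isocenter, uncertainty)$margin
  })
  occ <- array(FALSE, dim = grid$shape)
  for (k in seq_len(grid$shape[3])) for (j in seq_len(grid$shape[2])) {
    for (i in seq_len(grid$shape[1])) {
      p <- c(ax[[1]][i], ax[[2]][j], ax[[3]][k])
      inside <- FALSE
      for (ti in seq_along(ts$targets)) {
        t <- ts$targets[[ti]]
        if (t$source == "analytic_sphere" &&
            sum((p - t$sphere$center)^2) <= (t$sphere$diameter / 2)^2) {
          inside <- TRUE
          break
        }
        d2 <- colSums((t(t$points) - p)^2)
        if (any(d2 <= margins[[ti]]^2)) {
          inside <- TRUE
          break
        }
      }
      occ[i, j, k] <- inside
    }
  }
  occ
}
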
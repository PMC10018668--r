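#' @useDynLib isomargin, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats qchisq runif setNames
#' @keywords internal
"_PACKAGE"

# mm of positional displacement per (mm distance x degree of rotational SD);
# the 0.816 factor projects an isotropic three-axis rotation onto displacement.
ROTATION_COEF <- 0.816 * pi / 180

#' Critical multiplier for a three-dimensional coverage margin
#'
#' Converts a coverage probability `alpha` into the multiplier that scales an
#' isotropic standard deviation into a margin radius covering the true target
#' position with probability `alpha`: the square root of the `alpha`-quantile
#' of the chi-squared distribution with three degrees of freedom. For
#' `alpha = 0.95` this is 2.7955, commonly rounded to 2.795.
#'
#' @param alpha Coverage probability, strictly between 0 and 1.
#' @return The dimensionless multiplier.
#' @examples
#' chi_alpha(0.95) # ~2.795
#' @export
chi_alpha <- function(alpha) {
  if (!is.numeric(alpha) || anyNA(alpha) || any(alpha <= 0) || any(alpha >= 1)) {
    stop("`alpha` must lie strictly between 0 and 1", call. = FALSE)
  }
  sqrt(qchisq(alpha, df = 3))
}

#' Standard deviation of rotation-induced displacement
#'
#' A random rotation about the isocenter with per-axis SD `sigma_d` (degrees)
#' displaces a point at distance `d` (mm) from the isocenter by a random
#' vector whose isotropic SD is `0.816 * pi/180 * d * sigma_d` mm, i.e.
#' approximately `0.01424 * d * sigma_d`. Linear in both arguments.
#'
#' @param d Distance from the isocenter, mm (vectorized).
#' @param sigma_d Rotational SD, degrees.
#' @return Displacement SD in mm.
#' @export
rotational_sd <- function(d, sigma_d) {
  if (any(d < 0) || any(sigma_d < 0)) {
    stop("`d` and `sigma_d` must be non-negative", call. = FALSE)
  }
  ROTATION_COEF * d * sigma_d
}

#' Setup-uncertainty parameters
#'
#' Bundles the statistical-model parameters: translational SD `sigma_s` (mm),
#' rotational SD `sigma_d` (degrees), and coverage probability `alpha`.
#' Exactly one of `sigma_s` or `m_s` must be given; `m_s` is the translational
#' margin `chi_alpha(alpha) * sigma_s` (mm), the common clinical
#' parameterization. The canonical stored parameter is `sigma_s`; `m_s` and
#' `chi_alpha` are derived views, so the two parameterizations round-trip
#' losslessly.
#'
#' @param sigma_s Translational SD, mm (>= 0).
#' @param m_s Translational margin, mm (>= 0); alternative to `sigma_s`.
#' @param sigma_d Rotational SD, degrees (>= 0).
#' @param alpha Coverage probability in (0, 1). Default 0.95.
#' @return An object of class `setup_uncertainty` with elements `sigma_s`,
#'   `sigma_d`, `alpha`, `chi_alpha`, `m_s`.
#' @examples
#' setup_uncertainty(m_s = 2, sigma_d = 1.0)
#' @export
setup_uncertainty <- function(sigma_s = NULL, m_s = NULL, sigma_d = 0, alpha = 0.95) {
  if (is.null(sigma_s) == is.null(m_s)) {
    stop("give exactly one of `sigma_s` or `m_s`", call. = FALSE)
  }
  ca <- chi_alpha(alpha)
  if (is.null(sigma_s)) {
    stopifnot(is.numeric(m_s), length(m_s) == 1L, m_s >= 0)
    sigma_s <- m_s / ca
  }
  stopifnot(
    is.numeric(sigma_s), length(sigma_s) == 1L, sigma_s >= 0,
    is.numeric(sigma_d), length(sigma_d) == 1L, sigma_d >= 0
  )
  structure(
    list(
      sigma_s = sigma_s, sigma_d = sigma_d, alpha = alpha,
      chi_alpha = ca, m_s = ca * sigma_s
    ),
    class = "setup_uncertainty"
  )
}

#' @export
print.setup_uncertainty <- function(x, ...) {
  cat(sprintf(
    "Setup uncertainty: sigma_s = %.4g mm (M_S = %.4g mm), sigma_d = %.4g deg, alpha = %.3g (chi = %.4f)\n",
    x$sigma_s, x$m_s, x$sigma_d, x$alpha, x$chi_alpha
  ))
  invisible(x)
}

#' Nonuniform CTV-to-PTV margin at boundary points
#'
#' Computes, for each boundary point, the distance to the isocenter and the
#' combined margin
#' `M_i = chi_alpha * sqrt(sigma_s^2 + (0.01424 * d_i * sigma_d)^2)`,
#' i.e. the Pythagorean combination of the uniform translational margin
#' `M_S = chi_alpha * sigma_s` with the distance-dependent rotational margin
#' `chi_alpha * rotational_sd(d_i, sigma_d)`.
#'
#' @param points Numeric n x 3 matrix (or length-3 vector) of boundary-point
#'   coordinates, mm.
#' @param isocenter Length-3 numeric vector, mm.
#' @param uncertainty A [setup_uncertainty()] object.
#' @return A data frame with one row per point: columns `distance_to_iso`,
#'   `margin`, `margin_translational`, `margin_rotational` (all mm).
#' @examples
#' u <- setup_uncertainty(m_s = 2, sigma_d = 1.0)
#' point_margin(c(100, 0, 0), c(0, 0, 0), u)
#' @export
point_margin <- function(points, isocenter, uncertainty) {
  stopifnot(inherits(uncertainty, "setup_uncertainty"))
  points <- as_point_matrix(points)
  isocenter <- as_point3(isocenter)
  if (!all(is.finite(points)) || !all(is.finite(isocenter))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  d <- sqrt((points[, 1] - isocenter[1])^2 +
            (points[, 2] - isocenter[2])^2 +
            (points[, 3] - isocenter[3])^2)
  ca <- uncertainty$chi_alpha
  m_t <- rep.int(uncertainty$m_s, length(d))
  m_r <- ca * rotational_sd(d, uncertainty$sigma_d)
  data.frame(
    distance_to_iso = d,
    margin = sqrt(m_t^2 + m_r^2),
    margin_translational = m_t,
    margin_rotational = m_r
  )
}

# ---- small shared coercion helpers ----

as_point3 <- function(x) {
  x <- as.numeric(x)
  if (length(x) != 3L) stop("expected a length-3 coordinate vector", call. = FALSE)
  x
}

as_point_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), nrow = 1L)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop("expected an n x 3 coordinate matrix", call. = FALSE)
  x
}
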
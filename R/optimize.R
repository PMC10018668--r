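# Minimization of the margin volume over isocenter position: exhaustive grid
# search over the centroid bounding box (or the segment joining two target
# centers) and adaptive simulated annealing with a fast per-dimension
# temperature schedule and sensitivity-based reannealing.

#' Margin-volume objective function
#'
#' Returns a closure `f(isocenter) -> mm^3` evaluating [margin_volume()] for
#' a fixed target set, uncertainty and voxel spacing, and counting its
#' evaluations (readable via `attr(f, "count")()`).
#'
#' @inheritParams margin_volume
#' @export
margin_objective <- function(ts, uncertainty, spacing = 1) {
  n_eval <- 0L
  f <- function(isocenter) {
    n_eval <<- n_eval + 1L
    margin_volume(ts, isocenter, uncertainty, spacing = spacing)$v_margin
  }
  attr(f, "count") <- function() n_eval
  f
}

#' Bounds of the isocenter search space
#'
#' The solution space is the axis-aligned bounding box of the target
#' centroids, optionally padded.
#'
#' @param ts A [target_set()].
#' @param pad Symmetric padding, mm.
#' @return List with `lower` and `upper` (length-3, mm).
#' @export
search_bounds <- function(ts, pad = 0) {
  cent <- target_centroids(ts)
  list(lower = apply(cent, 2, min) - pad, upper = apply(cent, 2, max) + pad)
}

#' Exhaustive grid search for the optimal isocenter
#'
#' Evaluates the margin volume on a regular lattice of candidate isocenters
#' and returns the minimizer (the "numerical simulation" optimum). For two
#' targets the search restricts by default to the segment joining the two
#' centroids, where the optimum is known to lie by symmetry of the margin
#' model. Ties are broken by the first minimum in scan order (x fastest,
#' then y, then z; segment samples run from the first to the second target).
#'
#' Discretization error at the scan spacing can displace the apparent
#' minimum within the flat basin of the objective, so when `spacing_final`
#' is finer than `spacing`, every candidate whose coarse value lies within
#' `refine_tol` (relative) of the coarse minimum is re-evaluated at
#' `spacing_final` and the best of those finalists is returned.
#'
#' @inheritParams margin_volume
#' @param step Lattice step between candidate isocenters, mm.
#' @param spacing Voxel spacing used for the scan, mm.
#' @param spacing_final Voxel spacing for the finalist re-evaluation, mm;
#'   `NULL` (default) skips refinement.
#' @param refine_tol Relative band above the coarse minimum defining the
#'   finalists.
#' @param restriction `"auto"` (segment when `n == 2`, box otherwise),
#'   `"segment"` (two targets only) or `"box"`.
#' @param pad Padding added to the centroid bounding box, mm.
#' @return List with `position`, `v_margin` (at `spacing_final` when
#'   refinement is on), `evaluations`, and the full `samples` data frame
#'   (x, y, z, v_margin at the scan spacing).
#' @export
grid_search_isocenter <- function(ts, uncertainty, step = 1, spacing = 1,
                                  spacing_final = NULL, refine_tol = 0.05,
                                  restriction = c("auto", "segment", "box"),
                                  pad = 0) {
  stopifnot(inherits(ts, "target_set"), step > 0)
  restriction <- match.arg(restriction)
  if (restriction == "auto") restriction <- if (ts$n == 2L) "segment" else "box"
  if (restriction == "segment" && ts$n != 2L) {
    stop("segment search requires exactly two targets", call. = FALSE)
  }
  if (restriction == "segment") {
    a <- ts$targets[[1]]$centroid
    b <- ts$targets[[2]]$centroid
    len <- sqrt(sum((b - a)^2))
    tt <- seq(0, 1, by = step / len)
    if (tt[length(tt)] < 1) tt <- c(tt, 1)
    cand <- cbind(a[1] + tt * (b[1] - a[1]),
                  a[2] + tt * (b[2] - a[2]),
                  a[3] + tt * (b[3] - a[3]))
  } else {
    bd <- search_bounds(ts, pad)
    ax <- lapply(1:3, function(i) {
      if (bd$upper[i] - bd$lower[i] < step / 2) {
        (bd$lower[i] + bd$upper[i]) / 2
      } else {
        s <- seq(bd$lower[i], bd$upper[i], by = step)
        if (s[length(s)] < bd$upper[i]) s <- c(s, bd$upper[i])
        s
      }
    })
    cand <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                                  KEEP.OUT.ATTRS = FALSE))
  }
  f <- margin_objective(ts, uncertainty, spacing = spacing)
  vals <- apply(cand, 1, f)
  i <- which.min(vals)
  best_pos <- as.numeric(cand[i, ])
  best_val <- vals[i]
  n_eval <- length(vals)
  if (!is.null(spacing_final) && spacing_final < spacing) {
    finalists <- which(vals <= vals[i] * (1 + refine_tol))
    fine <- vapply(finalists, function(j) {
      margin_volume(ts, as.numeric(cand[j, ]), uncertainty,
                    spacing = spacing_final)$v_margin
    }, numeric(1))
    n_eval <- n_eval + length(finalists)
    k <- which.min(fine)
    best_pos <- as.numeric(cand[finalists[k], ])
    best_val <- fine[k]
  }
  list(
    position = best_pos,
    v_margin = best_val,
    evaluations = n_eval,
    samples = data.frame(x = cand[, 1], y = cand[, 2], z = cand[, 3],
                         v_margin = vals)
  )
}

#' Adaptive simulated annealing configuration
#'
#' Defaults chosen for the sphere-phantom benchmark scale (search boxes up to
#' ~100 mm, objective evaluations costing tens of milliseconds).
#'
#' @param seed Integer RNG seed (mandatory: runs are exactly reproducible).
#' @param t0 Initial generating temperature per free dimension.
#' @param c Temperature-scale constant of the fast annealing schedule
#'   `T_k = t0 * exp(-c * k^(1/D))`.
#' @param max_evals Objective-evaluation budget.
#' @param patience Stop after this many evaluations without improving the
#'   incumbent.
#' @param reanneal_every Reanneal after this many accepted moves.
#' @param spacing Voxel spacing for objective evaluations during the search,
#'   mm.
#' @export
asa_config <- function(seed, t0 = 1, c = 3, max_evals = 2000, patience = 300,
                       reanneal_every = 50, spacing = 1) {
  stopifnot(
    is.numeric(seed), length(seed) == 1L, is.finite(seed),
    t0 > 0, c > 0, max_evals > 1, patience > 0, reanneal_every > 0, spacing > 0
  )
  list(seed = as.integer(seed), t0 = t0, c = c,
       max_evals = as.integer(max_evals), patience = as.integer(patience),
       reanneal_every = as.integer(reanneal_every), spacing = spacing)
}

# One draw from the ASA generating distribution on [-1, 1], scaled by the
# per-dimension temperature: heavy-tailed at high T, sharply peaked as T -> 0.
asa_draw <- function(temp) {
  u <- runif(length(temp))
  sign(u - 0.5) * temp * ((1 + 1 / temp)^abs(2 * u - 1) - 1)
}

#' Adaptive simulated annealing over isocenter position
#'
#' Stochastic global minimization of the margin volume, starting from the
#' center of geometry. Candidate moves are drawn per free dimension from the
#' heavy-tailed ASA generating distribution with temperatures following the
#' fast schedule `T_k = t0 * exp(-c * k^(1/D))`; moves are accepted by the
#' Metropolis criterion under a separately annealed acceptance temperature;
#' every `reanneal_every` acceptances the per-dimension temperatures are
#' rescaled by the local sensitivity of the objective to that coordinate
#' (reannealing), so flat directions keep exploring while steep ones focus.
#' Dimensions along which all target centroids coincide are held fixed.
#'
#' When `spacing_final` is given, the best-ever point is polished by a
#' bounded Nelder-Mead local search on the fine-grid objective, so the
#' returned value is measured at the final resolution.
#'
#' @inheritParams grid_search_isocenter
#' @param config An [asa_config()]; its `spacing` overrides the objective
#'   resolution during the search.
#' @param pad Padding of the centroid-bounding-box search space, mm.
#' @param spacing_final Optional voxel spacing for the final local polish,
#'   mm.
#' @return List with `position` (best-ever point), `v_margin` (its objective
#'   value, at `spacing_final` when polishing), `evaluations`, `accepted`,
#'   and `trace` (data frame of evaluation index, candidate value, incumbent
#'   value).
#' @export
asa_optimize <- function(ts, uncertainty, config, pad = 0,
                         spacing_final = NULL) {
  stopifnot(inherits(ts, "target_set"))
  bd <- search_bounds(ts, pad)
  width <- bd$upper - bd$lower
  free <- which(width > 1e-9)
  x0 <- center_of_geometry(ts)
  f <- margin_objective(ts, uncertainty, spacing = config$spacing)

  if (length(free) == 0L) {
    v <- f(x0)
    return(list(position = x0, v_margin = v, evaluations = 1L, accepted = 0L,
                trace = data.frame(eval = 1L, value = v, incumbent = v)))
  }

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  D <- length(free)
  k_gen <- rep(0, D)          # per-dimension annealing-time indices
  k_acc <- 0
  t_gen <- rep(config$t0, D)
  x <- x0
  fx <- f(x)
  t_acc0 <- max(abs(fx), 1e-8)
  best_x <- x; best_f <- fx
  n_eval <- 1L; n_acc <- 0L; since_best <- 0L
  trace_val <- fx; trace_inc <- fx; trace_idx <- 1L

  temp_of <- function(k) config$t0 * exp(-config$c * k^(1 / D))

  while (n_eval < config$max_evals && since_best < config$patience) {
    # generate an in-bounds candidate, redrawing per rejected dimension
    cand <- x
    for (d in seq_len(D)) {
      a <- bd$lower[free[d]]; b <- bd$upper[free[d]]
      for (try in 1:100) {
        y <- x[free[d]] + asa_draw(t_gen[d]) * (b - a)
        if (y >= a && y <= b) break
      }
      cand[free[d]] <- min(max(y, a), b)
    }
    fc <- f(cand)
    n_eval <- n_eval + 1L
    if (!is.finite(fc)) stop("non-finite objective value in ASA", call. = FALSE)
    k_gen <- k_gen + 1
    t_gen <- pmax(temp_of(k_gen), 1e-10)

    t_acc <- max(t_acc0 * exp(-config$c * k_acc^(1 / D)), 1e-12)
    delta <- fc - fx
    if (delta <= 0 || runif(1) < exp(-delta / t_acc)) {
      x <- cand; fx <- fc
      n_acc <- n_acc + 1L
      k_acc <- k_acc + 1
      if (fc < best_f) {
        best_f <- fc; best_x <- cand; since_best <- 0L
      }
      # reannealing: rescale annealing time by objective sensitivities
      if (n_acc %% config$reanneal_every == 0L) {
        h <- pmax(1e-2 * width[free], 1e-3)
        sens <- numeric(D)
        for (d in seq_len(D)) {
          xp <- best_x
          xp[free[d]] <- min(xp[free[d]] + h[d], bd$upper[free[d]])
          sens[d] <- abs(f(xp) - best_f) / max(abs(xp[free[d]] - best_x[free[d]]), 1e-9)
          n_eval <- n_eval + 1L
        }
        s_max <- max(sens)
        if (s_max > 0) {
          ratio <- pmin(pmax(s_max / pmax(sens, 1e-6 * s_max), 1), 1e6)
          t_new <- pmin(t_gen * ratio, config$t0)
          k_gen <- (log(config$t0 / t_new) / config$c)^D
        }
        t_acc0 <- max(abs(best_f), 1e-8)
        k_acc <- 0
      }
    }
    since_best <- since_best + 1L
    trace_idx <- c(trace_idx, n_eval)
    trace_val <- c(trace_val, fc)
    trace_inc <- c(trace_inc, best_f)
  }

  out <- list(
    position = best_x,
    v_margin = best_f,
    evaluations = n_eval,
    accepted = n_acc,
    trace = data.frame(eval = trace_idx, value = trace_val,
                       incumbent = trace_inc)
  )
  if (!is.null(spacing_final) && spacing_final < config$spacing) {
    fine <- margin_objective(ts, uncertainty, spacing = spacing_final)
    pen <- function(p) {
      if (any(p < bd$lower - 1e-9) || any(p > bd$upper + 1e-9)) return(Inf)
      fine(p)
    }
    pol <- stats::optim(best_x, pen, method = "Nelder-Mead",
                        control = list(maxit = 80, reltol = 1e-5))
    out$position <- pol$par
    out$v_margin <- pol$value
    out$evaluations <- out$evaluations + attr(fine, "count")()
  }
  out
}

#' Compare candidate isocenters
#'
#' Evaluates the margin volume at the three reference isocenters (COG, COV,
#' COS), at the adaptive-simulated-annealing optimum, and optionally at the
#' exhaustive grid-search optimum (slow for three or more targets), all on
#' one common fine grid, normalized to the COG value.
#'
#' @inheritParams margin_volume
#' @param seed RNG seed for the ASA run.
#' @param methods Character vector from `COG`, `COV`, `COS`, `NSO`, `ASA`.
#' @param spacing_opt Voxel spacing during optimization, mm.
#' @param spacing_final Voxel spacing for the reported comparison, mm.
#' @param step Grid-search lattice step, mm (NSO only).
#' @param asa An [asa_config()]; built from `seed` and `spacing_opt` when
#'   omitted.
#' @param pad Search-space padding, mm.
#' @return A data frame with one row per method: `label`, `x`, `y`, `z`,
#'   `v_margin` (mm^3, at `spacing_final`), `normalized_to_cog`,
#'   `evaluations`.
#' @examples
#' \donttest{
#' ts <- phantom_targets("pair-5-10")
#' u <- setup_uncertainty(m_s = 2, sigma_d = 1)
#' compare_isocenters(ts, u, seed = 1, methods = c("COG", "COV", "COS", "NSO"))
#' }
#' @export
compare_isocenters <- function(ts, uncertainty, seed = 0,
                               methods = c("COG", "COV", "COS", "ASA"),
                               spacing_opt = 1, spacing_final = 0.5,
                               step = 1, asa = NULL, pad = 0) {
  stopifnot(inherits(ts, "target_set"))
  methods <- match.arg(methods, c("COG", "COV", "COS", "NSO", "ASA"),
                       several.ok = TRUE)
  if (!"COG" %in% methods) methods <- c("COG", methods)
  pos <- list(); nev <- list()
  for (m in methods) {
    res <- switch(m,
      COG = list(p = center_of_geometry(ts), n = 0L),
      COV = list(p = center_of_volume(ts), n = 0L),
      COS = list(p = center_of_surface(ts), n = 0L),
      NSO = {
        g <- grid_search_isocenter(ts, uncertainty, step = step,
                                   spacing = spacing_opt,
                                   spacing_final = spacing_final, pad = pad)
        list(p = g$position, n = g$evaluations)
      },
      ASA = {
        cfg <- if (is.null(asa)) asa_config(seed = seed, spacing = spacing_opt) else asa
        a <- asa_optimize(ts, uncertainty, cfg, pad = pad,
                          spacing_final = spacing_final)
        list(p = a$position, n = a$evaluations)
      }
    )
    pos[[m]] <- res$p; nev[[m]] <- res$n
  }
  v <- vapply(methods, function(m) {
    margin_volume(ts, pos[[m]], uncertainty, spacing = spacing_final)$v_margin
  }, numeric(1))
  out <- data.frame(
    label = methods,
    x = vapply(pos, `[`, numeric(1), 1)[methods],
    y = vapply(pos, `[`, numeric(1), 2)[methods],
    z = vapply(pos, `[`, numeric(1), 3)[methods],
    v_margin = v,
    normalized_to_cog = v / v[methods == "COG"],
    evaluations = unlist(nev)[methods],
    row.names = NULL
  )
  attr(out, "spacing_final") <- spacing_final
  attr(out, "spacing_opt") <- spacing_opt
  attr(out, "seed") <- seed
  out
}
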
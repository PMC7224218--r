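# Pooled-background PCA environmental space and the gridded (R x R)
# occurrence/background density surfaces it supports.
#
# The conventions follow the standard gridded-niche workflow: the PCA is
# calibrated on the pooled environmental backgrounds of the two ranges
# (never on occurrences), occurrence and background densities are
# Gaussian kernel estimates evaluated at the cell centres of a grid
# bounded by the pooled background extent, and percentile masks I_p
# delimit the environment actually available in each range.

#' Fit the pooled-background PCA environmental space
#'
#' Calibrates a principal components analysis on the row-bound
#' (centred, unit-scaled) environmental backgrounds of the native and
#' invaded ranges.  Occurrences are deliberately excluded from the
#' calibration: the axes describe the available environment, not the
#' species' use of it.
#'
#' @param native_bg,invaded_bg data frames or matrices of environmental
#'   variables (one row per background point, identical columns).
#' @param n_components number of retained components \eqn{k}.
#' @return an object of class `env_space_model` with elements `center`,
#'   `scale`, `rotation` (variables x components loading matrix),
#'   `var_frac` (explained-variance fractions, all components), `k`,
#'   and `vars`.
#' @export
fit_env_space <- function(native_bg, invaded_bg, n_components = 2) {
  a <- as.data.frame(native_bg); b <- as.data.frame(invaded_bg)
  stop_if(!identical(names(a), names(b)),
          "native and invaded backgrounds must share the same variables")
  pooled <- rbind(a, b)
  stop_if(nrow(pooled) < 3, "need at least 3 pooled background points")
  stop_if(ncol(pooled) < n_components,
          "fewer variables than requested components")
  x <- as_num_matrix(pooled)
  check_finite_matrix(x, "environmental background")
  s <- apply(x, 2, stats::sd)
  if (any(s <= 0))
    stop("constant environmental variable: ",
         paste(colnames(x)[s <= 0], collapse = ", "), call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  structure(list(
    center = pc$center, scale = pc$scale,
    rotation = pc$rotation, sdev = pc$sdev,
    var_frac = pc$sdev^2 / sum(pc$sdev^2),
    k = as.integer(n_components), vars = colnames(x)),
    class = "env_space_model")
}

#' @exportS3Method base::print
print.env_space_model <- function(x, ...) {
  cat("Pooled-background PCA environmental space\n")
  cat("  variables:", paste(x$vars, collapse = ", "), "\n")
  cat(sprintf("  retained components: %d (%.1f%% of variance)\n",
              x$k, 100 * sum(x$var_frac[seq_len(x$k)])))
  invisible(x)
}

#' Project points into the PCA environmental space
#'
#' @param points data frame or matrix carrying all model variables
#'   (matched by name when column names are present).
#' @param model an [fit_env_space()] model.
#' @param k number of score columns to return (default: the model's).
#' @return numeric matrix of PC scores (rows preserved, `k` columns).
#' @export
project_env <- function(points, model, k = model$k) {
  stopifnot(inherits(model, "env_space_model"))
  p <- as.data.frame(points)
  if (!is.null(names(p)) && all(model$vars %in% names(p))) {
    p <- p[, model$vars, drop = FALSE]
  } else if (ncol(p) != length(model$vars)) {
    missing <- setdiff(model$vars, names(p))
    stop("points lack model variables: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- as_num_matrix(p)
  if (nrow(x) == 0)
    return(matrix(numeric(0), 0, k,
                  dimnames = list(NULL, colnames(model$rotation)[seq_len(k)])))
  check_finite_matrix(x, "points")
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  xs %*% model$rotation[, seq_len(k), drop = FALSE]
}

#' Build the gridded environmental space
#'
#' Defines an `R x R` grid over the pooled background scores: per-axis
#' bounds are the pooled minima/maxima, cells are half-open
#' `[lo, hi)` except the last cell, which is closed so extreme points
#' bin inside the grid.
#'
#' @param bg_scores_native,bg_scores_invaded two-column score matrices.
#' @param R grid resolution per axis (default 100).
#' @return object of class `grid_frame` with axis breaks, cell centres
#'   and cell area.
#' @export
build_grid <- function(bg_scores_native, bg_scores_invaded, R = 100) {
  stop_if(R < 10, "grid resolution R must be >= 10")
  a <- as_num_matrix(bg_scores_native); b <- as_num_matrix(bg_scores_invaded)
  stop_if(nrow(a) < 1 || nrow(b) < 1, "each background needs at least 1 point")
  stopifnot(ncol(a) == 2, ncol(b) == 2)
  pooled <- rbind(a, b)
  xlim <- range(pooled[, 1]); ylim <- range(pooled[, 2])
  stop_if(diff(xlim) <= 0, "degenerate axis 1: max equals min")
  stop_if(diff(ylim) <= 0, "degenerate axis 2: max equals min")
  xb <- seq(xlim[1], xlim[2], length.out = R + 1)
  yb <- seq(ylim[1], ylim[2], length.out = R + 1)
  structure(list(
    R = as.integer(R), xlim = xlim, ylim = ylim,
    xbreaks = xb, ybreaks = yb,
    x = (xb[-1] + xb[-(R + 1)]) / 2, y = (yb[-1] + yb[-(R + 1)]) / 2,
    dx = diff(xlim) / R, dy = diff(ylim) / R,
    cell_area = (diff(xlim) / R) * (diff(ylim) / R)),
    class = "grid_frame")
}

# Row/column cell indices of points on a grid_frame (last cell closed).
cell_index <- function(pts, grid) {
  p <- as_num_matrix(pts)
  ix <- findInterval(p[, 1], grid$xbreaks, rightmost.closed = TRUE)
  iy <- findInterval(p[, 2], grid$ybreaks, rightmost.closed = TRUE)
  cbind(ix, iy)
}

same_grid <- function(g1, g2) {
  isTRUE(all.equal(g1$xlim, g2$xlim)) && isTRUE(all.equal(g1$ylim, g2$ylim)) &&
    g1$R == g2$R
}

#' Kernel density of the available environment of one range
#'
#' Smooths the background points of a single range onto the grid with a
#' Gaussian product kernel (Silverman bandwidths) and records the
#' density observed at the background points themselves; the latter is
#' the reference distribution from which the percentile masks I_p are
#' cut.
#'
#' @param bg_scores two-column score matrix of one range's background.
#' @param grid a [build_grid()] frame.
#' @return object of class `background_density`.
#' @export
background_density <- function(bg_scores, grid) {
  stopifnot(inherits(grid, "grid_frame"))
  b <- as_num_matrix(bg_scores)
  stopifnot(ncol(b) == 2)
  h <- silverman_bandwidth(b)
  dens <- kde_grid_2d(b, grid$x, grid$y, h)
  at_pts <- kde_at_points(b, b, h)
  cells <- cell_index(b, grid)
  with_pts <- matrix(FALSE, grid$R, grid$R)
  with_pts[cells] <- TRUE
  structure(list(dens = dens, at_pts = at_pts, cells_with_pts = with_pts,
                 h = h, n = nrow(b), grid = grid),
            class = "background_density")
}

#' Background-availability mask I_p
#'
#' `I_100` keeps every cell whose smoothed background density reaches
#' the lowest density observed at any background point (plus all cells
#' that contain a background point), i.e. the support delimited by the
#' background data.  For `p < 100` the mask keeps cells whose density
#' exceeds the `(100 - p)`-th percentile of the density evaluated at
#' the background points themselves, stripping the low-density fringe
#' introduced by kernel smoothing.
#'
#' @param bg_scores two-column score matrix, or a prebuilt
#'   [background_density()].
#' @param grid a [build_grid()] frame (ignored when `bg_scores` is a
#'   `background_density`).
#' @param p percentile in (0, 100].
#' @return logical `R x R` matrix.
#' @export
background_mask <- function(bg_scores, grid = NULL, p = 100) {
  stop_if(!(is.numeric(p) && length(p) == 1 && p > 0 && p <= 100),
          "p must lie in (0, 100]")
  bd <- if (inherits(bg_scores, "background_density")) bg_scores
        else background_density(bg_scores, grid)
  if (p == 100) {
    (bd$dens >= min(bd$at_pts)) | bd$cells_with_pts
  } else {
    thr <- stats::quantile(bd$at_pts, probs = (100 - p) / 100, names = FALSE)
    bd$dens > thr
  }
}

#' Gridded occurrence density of one niche
#'
#' Estimates the smoothed occurrence density of a niche on the shared
#' grid.  The Gaussian kernel uses Silverman bandwidths computed on the
#' occurrence scores ("standard bandwidth").  The raw surface is then
#' (i) floored at the `th_occ` quantile of the density observed at the
#' occurrence points themselves (default `th_occ = 0`: the minimum, so
#' the retained support is the region delimited by the least-typical
#' observed record, the convention of the reference gridded-niche
#' tools), (ii) zeroed outside the range's background support
#' (`I_100`), and (iii) renormalised to sum to one.  Occurrences
#' marginally outside the grid bounds are clipped onto the bounds with
#' a warning.
#'
#' @param occ_scores two-column matrix of occurrence scores (>= 5 rows).
#' @param bg two-column background score matrix or a prebuilt
#'   [background_density()] for the same range.
#' @param grid a [build_grid()] frame.
#' @param th_occ occupancy-floor quantile in `[0, 1)`; 0 keeps any cell
#'   at least as dense as the sparsest occurrence.
#' @return object of class `niche_grid` holding `z` (masked, normalised
#'   occurrence density; sums to 1), `z_raw` (unfloored, unmasked KDE
#'   surface), `z_cor` (background-ratio-corrected variant of `z`),
#'   `w` (logical occupancy mask, `z > 0`), the background density, the
#'   bandwidths and bookkeeping counts.
#' @export
occurrence_density <- function(occ_scores, bg, grid, th_occ = 0) {
  stopifnot(inherits(grid, "grid_frame"))
  occ <- as_num_matrix(occ_scores)
  stopifnot(ncol(occ) == 2)
  stop_if(nrow(occ) < 5,
          "fewer than 5 occurrences: kernel density estimation is not advised")
  check_finite_matrix(occ, "occurrence scores")
  bd <- if (inherits(bg, "background_density")) bg
        else background_density(bg, grid)
  stop_if(!same_grid(bd$grid, grid), "background was built on a different grid")

  out_x <- occ[, 1] < grid$xlim[1] | occ[, 1] > grid$xlim[2]
  out_y <- occ[, 2] < grid$ylim[1] | occ[, 2] > grid$ylim[2]
  n_clipped <- sum(out_x | out_y)
  stop_if(n_clipped == nrow(occ), "all occurrences fall outside the grid bounds")
  if (n_clipped > 0) {
    warning(n_clipped, " occurrence(s) outside grid bounds were clipped")
    occ[, 1] <- pmin(pmax(occ[, 1], grid$xlim[1]), grid$xlim[2])
    occ[, 2] <- pmin(pmax(occ[, 2], grid$ylim[1]), grid$ylim[2])
  }

  h <- silverman_bandwidth(occ)
  z_raw <- kde_grid_2d(occ, grid$x, grid$y, h)
  at_pts <- kde_at_points(occ, occ, h)
  thr <- stats::quantile(at_pts, probs = th_occ, names = FALSE)

  occ_cells <- matrix(FALSE, grid$R, grid$R)
  occ_cells[cell_index(occ, grid)] <- TRUE

  z <- z_raw
  z[z < thr & !occ_cells] <- 0
  i100 <- background_mask(bd, p = 100)
  z[!i100] <- 0
  stop_if(sum(z) <= 0, "occurrence density has no mass inside the background")
  z <- z / sum(z)

  zc <- z / bd$dens
  zc[!is.finite(zc)] <- 0
  if (sum(zc) > 0) zc <- zc / sum(zc)

  structure(list(z = z, z_raw = z_raw, z_cor = zc, w = z > 0,
                 bg = bd, grid = grid, h = h, thr = thr, th_occ = th_occ,
                 n_occ = nrow(occ), n_clipped = n_clipped,
                 occ_cells = occ_cells, occ_scores = occ),
            class = "niche_grid")
}

#' @exportS3Method base::print
print.niche_grid <- function(x, ...) {
  cat(sprintf("Gridded niche density: %d occurrences on a %dx%d grid\n",
              x$n_occ, x$grid$R, x$grid$R))
  cat(sprintf("  occupied cells: %d; bandwidths: %.4g, %.4g\n",
              sum(x$w), x$h[1], x$h[2]))
  invisible(x)
}
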
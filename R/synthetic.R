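# Synthetic two-range worlds with known niche dynamics.
#
# The generator states a simple world: each range's available
# environment is a Gaussian point cloud in k environmental dimensions;
# the species' suitability is a Gaussian kernel; the invaded niche can
# be displaced (centroid shift), truncated on one side of a hyperplane
# (unfilling: suitable-but-unoccupied analogous space) and augmented
# with a share of occurrences from a displaced secondary kernel
# (expansion).  Geographic coordinates of the synthetic world are the
# first two environmental axes.

#' Background configuration for a two-range synthetic world
#'
#' @param n_points background points per range.
#' @param k number of environmental dimensions (>= 2).
#' @param offset mean offset of the invaded background relative to the
#'   native one (scalar or length-k vector).
#' @param spread per-axis standard deviation of each background cloud
#'   (scalar or length-k; default 4, i.e. four niche-sd units wide in
#'   the default scenarios).
#' @param nonanalog_frac target fraction of invaded background points
#'   outside the native background's axis-aligned envelope, in [0, 1).
#' @param resolution optional raster cell size for gridded output.
#' @param seed RNG seed.
#' @return validated list of class `background_config`.
#' @export
background_config <- function(n_points = 5000, k = 2, offset = 0, spread = 4,
                              nonanalog_frac = 0, resolution = NULL,
                              seed = 1) {
  stop_if(n_points < 10, "n_points must be >= 10")
  stop_if(k < 2, "dimension k must be >= 2")
  stop_if(nonanalog_frac < 0 || nonanalog_frac >= 1,
          "nonanalog_frac must lie in [0, 1)")
  offset <- rep_len(offset, k); spread <- rep_len(spread, k)
  stop_if(any(spread <= 0), "spread must be positive on every axis")
  if (!is.null(resolution))
    stop_if(resolution <= 0, "raster resolution must be positive")
  structure(list(n_points = as.integer(n_points), k = as.integer(k),
                 offset = offset, spread = spread,
                 nonanalog_frac = nonanalog_frac,
                 resolution = resolution, seed = as.integer(seed)),
            class = "background_config")
}

env_colnames <- function(k) paste0("env", seq_len(k))

# Axis-aligned envelope (per-axis min/max) of a point table.
env_envelope <- function(pts) {
  x <- as_num_matrix(pts)
  rbind(lo = apply(x, 2, min), hi = apply(x, 2, max))
}

points_in_envelope <- function(pts, env) {
  x <- as_num_matrix(pts)
  ok <- rep(TRUE, nrow(x))
  for (j in seq_len(ncol(x)))
    ok <- ok & x[, j] >= env["lo", j] & x[, j] <= env["hi", j]
  ok
}

# Draw n rows from a Gaussian cloud subject to a row filter, by batched
# rejection; errors when acceptance collapses.
rejection_sample <- function(n, mean, sd, accept_fun, what = "sample") {
  k <- length(mean)
  out <- matrix(numeric(0), 0, k)
  drawn <- 0; kept <- 0
  for (i in 1:60) {
    m <- max(2L * n, 200L)
    cand <- sweep(matrix(stats::rnorm(m * k), m, k) %*% diag(sd, k), 2,
                  mean, "+")
    ok <- accept_fun(cand)
    drawn <- drawn + m; kept <- kept + sum(ok)
    out <- rbind(out, cand[ok, , drop = FALSE])
    if (nrow(out) >= n) break
  }
  if (drawn >= 400 && kept / drawn < 0.01)
    stop("degenerate simulation: >= 99% of the ", what,
         " kernel mass falls outside the supported region", call. = FALSE)
  stop_if(nrow(out) < n, "could not draw enough accepted points for ", what)
  out[seq_len(n), , drop = FALSE]
}

#' Generate the two-range environmental backgrounds
#'
#' Native background: Gaussian cloud at the origin.  Invaded
#' background: Gaussian cloud at `offset`; when `nonanalog_frac > 0`, a
#' `nonanalog_frac` share of its points is drawn (by rejection) outside
#' the native background's axis-aligned envelope and the rest inside,
#' so the realised non-analogous fraction matches the target up to
#' rounding.
#'
#' @param cfg a [background_config()].
#' @return object of class `env_backgrounds`: data frames `native` and
#'   `invaded` (columns `env1..envk`), the native `envelope`, and `cfg`.
#' @export
make_env_backgrounds <- function(cfg) {
  stopifnot(inherits(cfg, "background_config"))
  k <- cfg$k
  with_seed(cfg$seed, {
    native <- sweep(matrix(stats::rnorm(cfg$n_points * k), ncol = k) %*%
                      diag(cfg$spread, k), 2, rep(0, k), "+")
    env <- env_envelope(native)
    n_out <- round(cfg$nonanalog_frac * cfg$n_points)
    n_in <- cfg$n_points - n_out
    inv_in <- rejection_sample(n_in, cfg$offset, cfg$spread,
                               function(p) points_in_envelope(p, env),
                               "analogous invaded background")
    inv <- inv_in
    if (n_out > 0) {
      # non-analogous climates are constructed just beyond the native
      # envelope's upper edge of axis 1 (e.g. hotter/wetter than any
      # native climate); rejection sampling would be hopeless when the
      # two clouds coincide
      out1 <- env["hi", 1] + cfg$spread[1] / 100 +
        abs(stats::rnorm(n_out, 0, cfg$spread[1] / 4))
      rest <- matrix(stats::rnorm(n_out * (k - 1)), ncol = k - 1) %*%
        diag(cfg$spread[-1], k - 1)
      inv_out <- cbind(out1, sweep(rest, 2, cfg$offset[-1], "+"))
      inv <- rbind(inv_in, inv_out)
    }
    colnames(native) <- colnames(inv) <- env_colnames(k)
    structure(list(native = as.data.frame(native),
                   invaded = as.data.frame(inv),
                   envelope = env, cfg = cfg),
              class = "env_backgrounds")
  })
}

#' Ground-truth niche dynamics for a simulated species
#'
#' @param centroid_native centre of the native suitability kernel
#'   (scalar recycled to length k, or length-k vector).
#' @param centroid_shift displacement of the invaded kernel centre.
#' @param niche_sd per-axis standard deviation of the suitability
#'   kernel (> 0).
#' @param unfilling_frac fraction of invaded-kernel mass withheld from
#'   occupancy (lower tail of axis 1), in [0, 1).
#' @param expansion_frac share of invaded occurrences drawn from the
#'   displaced secondary kernel, in [0, 1).
#' @param expansion_displacement displacement of the secondary kernel
#'   along axis 1, in niche-sd units (default 6: far enough that the
#'   secondary kernel sits outside the KDE support of the primary
#'   niche at realistic sample sizes).
#' @param n_native,n_invaded occurrence counts (>= 1).
#' @param k dimensionality (default 2).
#' @param seed RNG seed.
#' @return validated list of class `niche_truth`.
#' @export
niche_truth <- function(centroid_native = 0, centroid_shift = 0,
                        niche_sd = 1, unfilling_frac = 0,
                        expansion_frac = 0, expansion_displacement = 6,
                        n_native = 500, n_invaded = 500, k = 2, seed = 1) {
  stop_if(unfilling_frac < 0 || unfilling_frac >= 1,
          "unfilling_frac must lie in [0, 1)")
  stop_if(expansion_frac < 0 || expansion_frac >= 1,
          "expansion_frac must lie in [0, 1)")
  centroid_native <- rep_len(centroid_native, k)
  centroid_shift <- rep_len(centroid_shift, k)
  niche_sd <- rep_len(niche_sd, k)
  stop_if(any(niche_sd <= 0), "niche_sd must be positive on every axis")
  stop_if(n_native < 1, "n_native must be >= 1 (empty input rejected)")
  stop_if(n_invaded < 1, "n_invaded must be >= 1 (empty input rejected)")
  structure(list(centroid_native = centroid_native,
                 centroid_shift = centroid_shift, niche_sd = niche_sd,
                 unfilling_frac = unfilling_frac,
                 expansion_frac = expansion_frac,
                 expansion_displacement = expansion_displacement,
                 n_native = as.integer(n_native),
                 n_invaded = as.integer(n_invaded),
                 k = as.integer(k), seed = as.integer(seed)),
            class = "niche_truth")
}

occ_table <- function(pts, species, range_label) {
  k <- ncol(pts)
  colnames(pts) <- env_colnames(k)
  df <- data.frame(species = species, lon = pts[, 1], lat = pts[, 2],
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(pts))
  df$range_label <- range_label
  df
}

#' Simulate native and invaded occurrences with known dynamics
#'
#' Native occurrences are drawn from the Gaussian suitability kernel at
#' `centroid_native`, restricted to the native background envelope.
#' Invaded occurrences come from the shifted kernel restricted to the
#' invaded envelope, with the lower `unfilling_frac` tail of axis 1
#' excluded (truncation at
#' \eqn{c_1 + sd_1\,\Phi^{-1}(unfilling)}) and an `expansion_frac`
#' share drawn from the secondary kernel displaced by
#' `expansion_displacement * niche_sd` along axis 1.
#'
#' @param truth a [niche_truth()].
#' @param backgrounds an [make_env_backgrounds()] object of matching
#'   dimensionality.
#' @param species species name recorded in the outputs.
#' @return object of class `species_simulation`: occurrence data frames
#'   `native` and `invaded` (columns species, lon, lat, env1..envk,
#'   range_label) plus the generating `truth` and `backgrounds`.
#' @export
simulate_species <- function(truth, backgrounds, species = "synthetica") {
  stopifnot(inherits(truth, "niche_truth"),
            inherits(backgrounds, "env_backgrounds"))
  stop_if(truth$k != backgrounds$cfg$k,
          "truth and backgrounds have different dimensionality")
  env_nat <- env_envelope(backgrounds$native)
  env_inv <- env_envelope(backgrounds$invaded)
  c_nat <- truth$centroid_native
  c_inv <- c_nat + truth$centroid_shift
  sd <- truth$niche_sd
  with_seed(truth$seed, {
    nat <- rejection_sample(truth$n_native, c_nat, sd,
                            function(p) points_in_envelope(p, env_nat),
                            "native occurrence")
    cut1 <- c_inv[1] + sd[1] * stats::qnorm(truth$unfilling_frac)
    n_exp <- round(truth$expansion_frac * truth$n_invaded)
    n_main <- truth$n_invaded - n_exp
    inv <- rejection_sample(n_main, c_inv, sd, function(p)
      points_in_envelope(p, env_inv) & p[, 1] >= cut1,
      "invaded occurrence")
    if (n_exp > 0) {
      c_exp <- c_inv
      c_exp[1] <- c_exp[1] + truth$expansion_displacement * sd[1]
      exp_pts <- rejection_sample(n_exp, c_exp, sd, function(p)
        points_in_envelope(p, env_inv), "expansion occurrence")
      inv <- rbind(inv, exp_pts)
    }
    structure(list(native = occ_table(nat, species, "native"),
                   invaded = occ_table(inv, species, "invaded"),
                   truth = truth, backgrounds = backgrounds),
              class = "species_simulation")
  })
}

#' Rasterise a background point table
#'
#' Grids the synthetic world (geographic axes = `env1`, `env2`) at the
#' requested cell size and averages every environmental variable over
#' the points falling in each cell; empty cells are `NA`.
#'
#' @param background data frame of background points (`env1..envk`).
#' @param resolution cell edge length (> 0) in coordinate units.
#' @return an `env_stack`: list of named layer matrices plus grid
#'   metadata (`xll`, `yll`, `cellsize`, `nrow`, `ncol`).
#' @export
make_raster_stack <- function(background, resolution) {
  stop_if(is.null(resolution) || resolution <= 0,
          "raster resolution must be positive")
  bg <- as.data.frame(background)
  vars <- names(bg)
  x <- bg$env1; y <- bg$env2
  xll <- floor(min(x) / resolution) * resolution
  yll <- floor(min(y) / resolution) * resolution
  nc <- ceiling((max(x) - xll) / resolution) + 1L
  nr <- ceiling((max(y) - yll) / resolution) + 1L
  ix <- pmin(floor((x - xll) / resolution) + 1L, nc)
  iy <- pmin(floor((y - yll) / resolution) + 1L, nr)
  cell <- (iy - 1L) * nc + ix
  layers <- lapply(vars, function(v) {
    m <- matrix(NA_real_, nr, nc)
    agg <- tapply(bg[[v]], cell, mean)
    idx <- as.integer(names(agg))
    m[cbind((idx - 1L) %/% nc + 1L, (idx - 1L) %% nc + 1L)] <- as.numeric(agg)
    m
  })
  names(layers) <- vars
  env_stack(layers, xll = xll, yll = yll, cellsize = resolution)
}
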
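# Fixtures and independent brute-force oracles used across the suite.
# Oracles deliberately use naive loops / direct formula evaluation so
# they share no code path with the implementation they check.

# Naive sum-of-Gaussians KDE on a grid: one term per (cell, point).
oracle_kde_grid <- function(pts, gx, gy, h) {
  out <- matrix(0, length(gx), length(gy))
  for (i in seq_along(gx)) for (j in seq_along(gy)) {
    s <- 0
    for (p in seq_len(nrow(pts)))
      s <- s + exp(-0.5 * (((gx[i] - pts[p, 1]) / h[1])^2 +
                             ((gy[j] - pts[p, 2]) / h[2])^2))
    out[i, j] <- s / (nrow(pts) * 2 * pi * h[1] * h[2])
  }
  out
}

# AUC by counting concordant/tied presence-absence score pairs.
oracle_auc <- function(scores, y) {
  pres <- scores[y == 1]; abs_ <- scores[y == 0]
  tot <- 0
  for (a in pres) for (b in abs_)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pres) * length(abs_))
}

# Schoener's D from two normalised surfaces, by direct formula.
oracle_schoener <- function(z1, z2) 1 - 0.5 * sum(abs(z1 / sum(z1) - z2 / sum(z2)))

# COUE indices by cell-by-cell mass counting over given masks.
oracle_coue <- function(z1, z2, w1, w2, A) {
  E <- sum(z2[A & !w1]) / sum(z2[A])
  U <- sum(z1[A & !w2]) / sum(z1[A])
  c(stability = 1 - E, unfilling = U, expansion = E)
}

# Density-weighted centroid of a surface on a grid frame.
oracle_centroid <- function(z, grid) {
  tot <- sum(z); cx <- 0; cy <- 0
  for (i in seq_len(nrow(z))) for (j in seq_len(ncol(z))) {
    cx <- cx + z[i, j] * grid$x[i]
    cy <- cy + z[i, j] * grid$y[j]
  }
  c(cx, cy) / tot
}

# --- hand-constructed gridded niches -------------------------------

# A grid frame on [0, 1] x [0, 1] with R cells per axis (built
# directly so tiny test grids below the R >= 10 guard are allowed).
unit_frame <- function(R) {
  xb <- seq(0, 1, length.out = R + 1)
  structure(list(R = as.integer(R), xlim = c(0, 1), ylim = c(0, 1),
                 xbreaks = xb, ybreaks = xb,
                 x = (xb[-1] + xb[-(R + 1)]) / 2,
                 y = (xb[-1] + xb[-(R + 1)]) / 2,
                 dx = 1 / R, dy = 1 / R, cell_area = 1 / R^2),
            class = "grid_frame")
}

# Background stub whose I_75 and I_100 both equal `mask`.
fake_background <- function(mask, frame) {
  structure(list(dens = mask * 1, at_pts = rep(0.5, 5),
                 cells_with_pts = matrix(FALSE, frame$R, frame$R),
                 h = c(0.1, 0.1), n = 5, grid = frame),
            class = "background_density")
}

# Niche-grid stub with a fully controlled density surface.
fake_niche <- function(z, bg_mask = NULL, frame = unit_frame(nrow(z))) {
  if (is.null(bg_mask)) bg_mask <- matrix(TRUE, nrow(z), ncol(z))
  z <- z / sum(z)
  structure(list(z = z, z_raw = z, z_cor = z, w = z > 0,
                 bg = fake_background(bg_mask, frame), grid = frame,
                 h = c(0.1, 0.1), thr = 0, th_occ = 0,
                 n_occ = 10, n_clipped = 0,
                 occ_cells = matrix(FALSE, nrow(z), ncol(z)),
                 occ_scores = matrix(0.5, 10, 2)),
            class = "niche_grid")
}

# --- synthetic-world shortcuts -------------------------------------

# Full COUE pipeline on one simulated species; returns the two niche
# grids plus the pieces tests may want to poke at.
coue_world <- function(seed = 1, u = 0, e = 0, shift = 0,
                       n = 500, n_bg = 2000, R = 80) {
  bgs <- make_env_backgrounds(background_config(n_points = n_bg, seed = seed))
  tr <- niche_truth(centroid_shift = shift, unfilling_frac = u,
                    expansion_frac = e, n_native = n, n_invaded = n,
                    seed = seed + 7)
  sim <- simulate_species(tr, bgs)
  m <- fit_env_space(bgs$native, bgs$invaded, 2)
  sbn <- project_env(bgs$native, m); sbi <- project_env(bgs$invaded, m)
  g <- build_grid(sbn, sbi, R = R)
  ev <- paste0("env", 1:2)
  bdn <- background_density(sbn, g); bdi <- background_density(sbi, g)
  on <- project_env(sim$native[, ev], m)
  oi <- project_env(sim$invaded[, ev], m)
  list(gn = occurrence_density(on, bdn, g),
       gi = occurrence_density(oi, bdi, g),
       occ_nat = on, occ_inv = oi, bdn = bdn, bdi = bdi,
       grid = g, model = m, sim = sim, bgs = bgs)
}

# Linearly separable toy presence/absence data.
toy_pa <- function(n = 60, k = 2, seed = 1) {
  set.seed(seed)
  pres <- matrix(rnorm(n * k, mean = 3), n, k)
  abs_ <- matrix(rnorm(n * k, mean = -3), n, k)
  colnames(pres) <- colnames(abs_) <- paste0("env", seq_len(k))
  make_pa_dataset(as.data.frame(pres), as.data.frame(abs_), "native")
}
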
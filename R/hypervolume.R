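# n-dimensional niche hypervolumes: a Gaussian KDE (Silverman
# bandwidths) fitted to the occurrence scores defines a retained region
# at a density-quantile boundary (H_75 strips kernel-smoothing fringe,
# H_100 keeps the whole padded support).  The region is represented by
# uniformly distributed random points accepted inside it; its volume is
# estimated by rejection sampling in the padded bounding box.

hv_box <- function(points, h, pad = 3) {
  lo <- apply(points, 2, min) - pad * h
  hi <- apply(points, 2, max) + pad * h
  rbind(lo = lo, hi = hi)
}

hv_threshold <- function(points, h, p) {
  if (p == 100) return(0)
  dens <- kde_at_points(points, points, h)
  stats::quantile(dens, probs = (100 - p) / 100, names = FALSE)
}

in_box <- function(pts, box) {
  ok <- rep(TRUE, nrow(pts))
  for (j in seq_len(ncol(pts)))
    ok <- ok & pts[, j] >= box["lo", j] & pts[, j] <= box["hi", j]
  ok
}

#' Build a KDE niche hypervolume
#'
#' Fits a Gaussian product-kernel density (per-axis
#' [silverman_bandwidth()]) to k-dimensional occurrence scores and
#' retains the region where the density reaches the `(100 - p)`-th
#' percentile of the density observed at the source points themselves
#' (`p = 100`: any positive density, i.e. the whole bounding box padded
#' by 3 bandwidths).  The region is represented by uniform random
#' points accepted inside it; volume = box volume x acceptance rate.
#'
#' @param points matrix/data frame of occurrence scores (k columns).
#' @param p boundary quantile in (0, 100]; 75 and 100 mirror the H_75
#'   and H_100 conventions.
#' @param n_random number of uniform candidate points (default
#'   `max(10000, 500 * k)`).
#' @param seed RNG seed (optional; caller's RNG state is restored).
#' @return object of class `hypervolume_kde` with the accepted
#'   `random_points`, `volume` (PC-units^k), `centroid`, bandwidths
#'   `h`, `threshold`, `box` and `p`.
#' @export
build_hypervolume <- function(points, p = 100, n_random = NULL, seed = NULL) {
  x <- as_num_matrix(points)
  check_finite_matrix(x, "points")
  k <- ncol(x)
  stop_if(!(p > 0 && p <= 100), "p must lie in (0, 100]")
  n_random <- n_random %||% max(10000L, 500L * k)
  stop_if(n_random < 1000, "n_random must be >= 1000")
  h <- silverman_bandwidth(x)
  box <- hv_box(x, h)
  thr <- hv_threshold(x, h, p)
  widths <- box["hi", ] - box["lo", ]
  cand <- with_seed(seed, {
    matrix(stats::runif(n_random * k), n_random, k)
  })
  cand <- sweep(sweep(cand, 2, widths, "*"), 2, box["lo", ], "+")
  dens <- kde_at_points(cand, x, h)
  keep <- if (p == 100) dens > 0 else dens >= thr
  rate <- mean(keep)
  stop_if(rate < 1e-4,
          "acceptance rate below 1e-4: increase n_random or lower p")
  rp <- cand[keep, , drop = FALSE]
  colnames(rp) <- colnames(x)
  structure(list(
    random_points = rp, volume = prod(widths) * rate,
    centroid = colMeans(rp), h = h, threshold = thr, box = box,
    p = p, k = k, n_source = nrow(x), source_points = x,
    acceptance_rate = rate, n_random = n_random, seed = seed),
    class = "hypervolume_kde")
}

#' @exportS3Method base::print
print.hypervolume_kde <- function(x, ...) {
  cat(sprintf("KDE hypervolume (H_%g, %d dims, %d source points)\n",
              x$p, x$k, x$n_source))
  cat(sprintf("  volume = %.4g (acceptance %.1f%% of %d random points)\n",
              x$volume, 100 * x$acceptance_rate, x$n_random))
  invisible(x)
}

# Membership of arbitrary points in a hypervolume's retained region.
hv_contains <- function(hv, pts) {
  pts <- as_num_matrix(pts)
  dens <- kde_at_points(pts, hv$source_points, hv$h)
  inside <- in_box(pts, hv$box)
  if (hv$p == 100) inside & dens > 0 else inside & dens >= hv$threshold
}

# Smallest pairwise distance between two point sets, chunked.
min_cross_distance <- function(a, b, chunk = 1000L) {
  a <- as_num_matrix(a); b <- as_num_matrix(b)
  bs <- rowSums(b^2)
  best <- Inf
  for (start in seq(1L, nrow(a), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(a))
    d2 <- outer(rowSums(a[idx, , drop = FALSE]^2), bs, "+") -
      2 * a[idx, , drop = FALSE] %*% t(b)
    best <- min(best, min(d2))
  }
  sqrt(max(best, 0))
}

#' Compare two niche hypervolumes
#'
#' Estimates the intersection volume by cross-membership of each
#' hypervolume's random points in the other's retained region, and
#' derives the Jaccard similarity, union volume, unique fractions and
#' the centroid / minimum distances.
#'
#' @param hv1,hv2 [build_hypervolume()] objects with identical
#'   dimensionality and boundary quantile.
#' @return object of class `hypervolume_comparison` with `jaccard`,
#'   `centroid_distance`, `minimum_distance`, `volumes` (niche1,
#'   niche2, union, intersection) and `unique_fraction_1/2` (%).
#' @export
compare_hypervolumes <- function(hv1, hv2) {
  stopifnot(inherits(hv1, "hypervolume_kde"), inherits(hv2, "hypervolume_kde"))
  stop_if(hv1$k != hv2$k, "hypervolumes have different dimensionality")
  stop_if(hv1$p != hv2$p, "hypervolumes use different boundary quantiles")
  f12 <- mean(hv_contains(hv2, hv1$random_points))  # hv1 points inside hv2
  f21 <- mean(hv_contains(hv1, hv2$random_points))
  inter <- (f12 * hv1$volume + f21 * hv2$volume) / 2
  union <- hv1$volume + hv2$volume - inter
  structure(list(
    jaccard = inter / union,
    centroid_distance = sqrt(sum((hv1$centroid - hv2$centroid)^2)),
    minimum_distance = min_cross_distance(hv1$random_points, hv2$random_points),
    volumes = c(niche1 = hv1$volume, niche2 = hv2$volume,
                union = union, intersection = inter),
    unique_fraction_1 = 100 * (hv1$volume - inter) / hv1$volume,
    unique_fraction_2 = 100 * (hv2$volume - inter) / hv2$volume,
    p = hv1$p),
    class = "hypervolume_comparison")
}

#' @exportS3Method base::print
print.hypervolume_comparison <- function(x, ...) {
  cat(sprintf("Hypervolume comparison at H_%g\n", x$p))
  cat(sprintf("  Jaccard J = %.3f; centroid dist = %.3f; min dist = %.3f\n",
              x$jaccard, x$centroid_distance, x$minimum_distance))
  v <- x$volumes
  cat(sprintf("  volumes: %.3g / %.3g; union %.3g; intersection %.3g\n",
              v["niche1"], v["niche2"], v["union"], v["intersection"]))
  cat(sprintf("  unique fractions: %.1f%% / %.1f%%\n",
              x$unique_fraction_1, x$unique_fraction_2))
  invisible(x)
}

#' @export
as.data.frame.hypervolume_comparison <- function(x, ...) {
  data.frame(
    metric = c("jaccard", "centroid_distance", "minimum_distance",
               "volume_niche1", "volume_niche2", "volume_union",
               "volume_intersection", "unique_fraction_1",
               "unique_fraction_2"),
    level = paste0("H", x$p),
    value = c(x$jaccard, x$centroid_distance, x$minimum_distance,
              x$volumes, x$unique_fraction_1, x$unique_fraction_2),
    stringsAsFactors = FALSE)
}
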
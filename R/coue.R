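# COUE niche-change decomposition: stability / unfilling / expansion in
# analogous environmental space, centroid shift, niche topology and
# Schoener's D.
#
# Definitions (all density-mass weighted):
#   expansion E  = invaded-niche mass on analogous cells not occupied by
#                  the native niche / invaded-niche mass on analogous cells
#   stability S  = 1 - E
#   unfilling U  = native-niche mass on analogous cells not occupied by
#                  the invaded niche / native-niche mass on analogous cells
# "Analogous" cells are those inside the I_p background mask of *both*
# ranges; restricting to them keeps the indices unconfounded by climates
# that exist in only one range.

check_pair <- function(grid_native, grid_invaded) {
  stopifnot(inherits(grid_native, "niche_grid"),
            inherits(grid_invaded, "niche_grid"))
  stop_if(!same_grid(grid_native$grid, grid_invaded$grid),
          "the two niches were gridded on different frames")
}

analogous_mask <- function(grid_native, grid_invaded, p) {
  background_mask(grid_native$bg, p = p) & background_mask(grid_invaded$bg, p = p)
}

#' Niche dynamics indices: stability, unfilling, expansion
#'
#' @param grid_native,grid_invaded [occurrence_density()] surfaces on a
#'   shared grid.
#' @param p background-intersection percentile (75 strips marginal
#'   climates produced by kernel smoothing; 100 uses the full
#'   background support).
#' @return named numeric vector `c(stability, unfilling, expansion)`,
#'   each in `[0, 1]`, with `stability + expansion == 1`.
#' @export
niche_dyn_indices <- function(grid_native, grid_invaded, p = 75) {
  check_pair(grid_native, grid_invaded)
  A <- analogous_mask(grid_native, grid_invaded, p)
  stop_if(!any(A), "empty analogous mask: the two ranges share no climates at I_",
          p)
  z1 <- grid_native$z; z2 <- grid_invaded$z
  w1 <- grid_native$w; w2 <- grid_invaded$w
  m2 <- sum(z2[A]); m1 <- sum(z1[A])
  stop_if(m2 <= 0, "invaded niche has no mass in analogous space")
  stop_if(m1 <= 0, "native niche has no mass in analogous space")
  E <- sum(z2[A & !w1]) / m2
  U <- sum(z1[A & !w2]) / m1
  c(stability = 1 - E, unfilling = U, expansion = E)
}

#' Density-centroid shift between two niches
#'
#' Density-weighted mean of cell centres under the invaded surface
#' minus that under the native surface.
#'
#' @inheritParams niche_dyn_indices
#' @return list with the shift `vector` (length 2) and its `magnitude`.
#' @export
centroid_shift <- function(grid_native, grid_invaded) {
  check_pair(grid_native, grid_invaded)
  cen <- function(g) {
    stop_if(sum(g$z) <= 0, "zero-mass density surface")
    c(sum(g$z * g$grid$x) / sum(g$z),          # rows vary along x
      sum(t(g$z) * g$grid$y) / sum(g$z))
  }
  v <- cen(grid_invaded) - cen(grid_native)
  list(vector = v, magnitude = sqrt(sum(v^2)))
}

#' Topological interaction of the two niches
#'
#' Classifies the relation of the occupied-cell sets (each restricted
#' to its own range's I_p background) into the five classical patterns.
#' Containment is judged with a 95% tolerance so that kernel-smoothing
#' fringe cells do not flip the class.
#'
#' @inheritParams niche_dyn_indices
#' @param tol mutual-containment tolerance (default 0.95).
#' @return one of `"overlap-complete"`, `"invaded-subset"`,
#'   `"native-subset"`, `"partial-overlap"`, `"disjunct"`.
#' @export
topology_class <- function(grid_native, grid_invaded, p = 75, tol = 0.95) {
  check_pair(grid_native, grid_invaded)
  o1 <- grid_native$w & background_mask(grid_native$bg, p = p)
  o2 <- grid_invaded$w & background_mask(grid_invaded$bg, p = p)
  n1 <- sum(o1); n2 <- sum(o2); ni <- sum(o1 & o2)
  stop_if(n1 == 0 || n2 == 0, "a niche has no occupied cells at I_", p)
  c12 <- ni / n1   # fraction of native occupied cells inside invaded
  c21 <- ni / n2   # fraction of invaded occupied cells inside native
  if (c12 >= tol && c21 >= tol) "overlap-complete"
  else if (c21 >= tol) "invaded-subset"
  else if (c12 >= tol) "native-subset"
  else if (ni > 0) "partial-overlap"
  else "disjunct"
}

#' Schoener's D niche overlap
#'
#' \eqn{D = 1 - \tfrac12 \sum_{cells} |z_1 - z_2|} over the full
#' gridded environmental space, each surface renormalised to sum to
#' one.  0 = no overlap, 1 = identical normalised densities.
#'
#' @inheritParams niche_dyn_indices
#' @return numeric scalar in `[0, 1]`.
#' @export
schoener_d <- function(grid_native, grid_invaded) {
  check_pair(grid_native, grid_invaded)
  s1 <- sum(grid_native$z); s2 <- sum(grid_invaded$z)
  stop_if(s1 <= 0 || s2 <= 0, "zero-mass density surface")
  1 - 0.5 * sum(abs(grid_native$z / s1 - grid_invaded$z / s2))
}

#' Invaded-niche mass in non-analogous environmental space
#'
#' Fraction of the invaded niche's density lying in cells outside the
#' native range's I_p background, i.e. expansion into climates that do
#' not exist in the native range.
#'
#' @inheritParams niche_dyn_indices
#' @param threshold flag fraction above which `flag` is `TRUE`.
#' @return list with `fraction` and logical `flag`.
#' @export
nonanalog_expansion <- function(grid_native, grid_invaded, p = 100,
                                threshold = 0.01) {
  check_pair(grid_native, grid_invaded)
  i_nat <- background_mask(grid_native$bg, p = p)
  frac <- sum(grid_invaded$z[!i_nat]) / sum(grid_invaded$z)
  list(fraction = frac, flag = frac > threshold)
}

#' Full COUE metric set for a native/invaded niche pair
#'
#' Convenience wrapper computing stability, unfilling and expansion at
#' both requested intersection levels, the centroid shift, the
#' topology class, Schoener's D and the non-analogous expansion
#' fraction.
#'
#' @inheritParams niche_dyn_indices
#' @param levels intersection percentiles (default `c(75, 100)`).
#' @return object of class `coue_metrics`; `as.data.frame()` yields a
#'   tidy metric-by-level table.
#' @export
coue_metrics <- function(grid_native, grid_invaded, levels = c(75, 100)) {
  check_pair(grid_native, grid_invaded)
  ind <- sapply(levels, function(p) niche_dyn_indices(grid_native, grid_invaded, p))
  colnames(ind) <- paste0("I", levels)
  cs <- centroid_shift(grid_native, grid_invaded)
  na_exp <- nonanalog_expansion(grid_native, grid_invaded)
  structure(list(
    indices = ind, levels = levels,
    centroid_shift = cs$vector, centroid_shift_magnitude = cs$magnitude,
    topology = topology_class(grid_native, grid_invaded, p = levels[1]),
    schoener_D = schoener_d(grid_native, grid_invaded),
    expansion_nonanalog = na_exp$fraction,
    expansion_nonanalog_flag = na_exp$flag),
    class = "coue_metrics")
}

#' @exportS3Method base::print
print.coue_metrics <- function(x, ...) {
  cat("COUE niche-change metrics\n")
  tab <- round(100 * x$indices, 1)
  rownames(tab) <- c("Stability (%)", "Unfilling (%)", "Expansion (%)")
  print(tab)
  cat(sprintf("Schoener's D: %.3f | topology: %s\n", x$schoener_D, x$topology))
  cat(sprintf("Centroid shift: (%.3f, %.3f), |shift| = %.3f\n",
              x$centroid_shift[1], x$centroid_shift[2],
              x$centroid_shift_magnitude))
  cat(sprintf("Expansion into non-analogous space: %.1f%%%s\n",
              100 * x$expansion_nonanalog,
              if (x$expansion_nonanalog_flag) " (flagged)" else ""))
  invisible(x)
}

#' @export
as.data.frame.coue_metrics <- function(x, ...) {
  data.frame(
    metric = rep(c("stability", "unfilling", "expansion"), length(x$levels)),
    level = rep(paste0("I", x$levels), each = 3),
    value = as.vector(x$indices),
    stringsAsFactors = FALSE)
}
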
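# Permutation tests of niche conservatism: niche equivalency (pooled
# occurrences randomly re-allocated between the two ranges) and niche
# similarity (observed density patterns re-centred at random locations
# of the background).  Both are one-tailed "greater" tests on
# Schoener's D: conservatism is inferred when the observed overlap
# exceeds 95% of the null distribution.

perm_result <- function(observed_D, null_D, scheme, seed, alpha = 0.05) {
  p <- (1 + sum(null_D >= observed_D)) / (length(null_D) + 1)
  structure(list(observed_D = observed_D, null_D = null_D,
                 p_value = p, n_reps = length(null_D), scheme = scheme,
                 alpha = alpha,
                 decision = if (p <= alpha) "niche conservatism"
                            else "conservatism not supported",
                 seed = seed),
            class = "niche_perm_test")
}

#' @exportS3Method base::print
print.niche_perm_test <- function(x, ...) {
  cat(sprintf("Niche %s test (one-tailed, greater)\n", x$scheme))
  cat(sprintf("  observed D = %.4f; null reps = %d; P = %.4g\n",
              x$observed_D, x$n_reps, x$p_value))
  cat(sprintf("  decision at alpha = %.2f: %s\n", x$alpha, x$decision))
  invisible(x)
}

#' Niche equivalency test
#'
#' Pools the occurrence scores of both ranges and, in each of
#' `n_reps` permutations, randomly re-allocates them into two groups of
#' the original sizes, rebuilds both gridded densities and recomputes
#' Schoener's D.  The reported p-value uses the add-one permutation
#' rule \eqn{p = (1 + \#\{D_{null} \ge D_{obs}\}) / (n_{reps} + 1)}.
#'
#' @param occ_native,occ_invaded two-column occurrence score matrices
#'   (>= 5 rows each).
#' @param bg_native,bg_invaded per-range background scores or prebuilt
#'   [background_density()] objects.
#' @param grid shared [build_grid()] frame.
#' @param n_reps number of permutations (default 1000).
#' @param seed RNG seed (optional; restores the caller's RNG state).
#' @param th_occ occupancy-floor quantile passed to
#'   [occurrence_density()].
#' @return object of class `niche_perm_test` with the observed D, the
#'   null distribution, the p-value and the 5%-rule decision.
#' @export
equivalency_test <- function(occ_native, occ_invaded, bg_native, bg_invaded,
                             grid, n_reps = 1000, seed = NULL, th_occ = 0) {
  stop_if(n_reps < 1, "n_reps must be >= 1")
  occ1 <- as_num_matrix(occ_native); occ2 <- as_num_matrix(occ_invaded)
  stop_if(nrow(occ1) < 5 || nrow(occ2) < 5,
          "each occurrence set needs at least 5 records")
  bd1 <- if (inherits(bg_native, "background_density")) bg_native
         else background_density(bg_native, grid)
  bd2 <- if (inherits(bg_invaded, "background_density")) bg_invaded
         else background_density(bg_invaded, grid)
  d_of <- function(o1, o2) {
    g1 <- occurrence_density(o1, bd1, grid, th_occ = th_occ)
    g2 <- occurrence_density(o2, bd2, grid, th_occ = th_occ)
    schoener_d(g1, g2)
  }
  obs <- d_of(occ1, occ2)
  pool <- rbind(occ1, occ2)
  n1 <- nrow(occ1); n <- nrow(pool)
  null_D <- with_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      idx <- sample.int(n, n1)
      d_of(pool[idx, , drop = FALSE], pool[-idx, , drop = FALSE])
    }, numeric(1))
  })
  perm_result(obs, null_D, "equivalency", seed)
}

# Translate a density surface so that its centroid lands on the target
# cell; mass translated off the grid is dropped, the result is clipped
# to `mask` and renormalised.  Returns NULL when no mass remains.
shift_density <- function(z, mask, target_rc) {
  R <- nrow(z); C <- ncol(z)
  tot <- sum(z)
  if (tot <= 0) return(NULL)
  rows <- seq_len(R); cols <- seq_len(C)
  cr <- round(sum(rowSums(z) * rows) / tot)
  cc <- round(sum(colSums(z) * cols) / tot)
  dr <- target_rc[1] - cr; dc <- target_rc[2] - cc
  sr <- max(1, 1 - dr):min(R, R - dr)
  sc <- max(1, 1 - dc):min(C, C - dc)
  if (length(sr) < 1 || length(sc) < 1) return(NULL)
  out <- matrix(0, R, C)
  out[sr + dr, sc + dc] <- z[sr, sc, drop = FALSE]
  out[!mask] <- 0
  s <- sum(out)
  if (s <= 0) return(NULL)
  out / s
}

#' Niche similarity test
#'
#' Tests whether the two observed niches overlap more than niches
#' simulated by re-centring the observed density pattern(s) at random
#' locations of the available environment.  Under scheme `"both"`
#' (N <-> P) both patterns are shifted to uniformly drawn cells of
#' their respective range's I_100 background mask in every repeat;
#' under `"invaded"` (N -> P) only the invaded pattern is shifted and
#' compared against the observed native niche.  Mass shifted outside
#' the grid or the background support is dropped and the pattern
#' renormalised.
#'
#' @param grid_native,grid_invaded observed [occurrence_density()]
#'   surfaces on a shared grid.
#' @param scheme `"both"` (alias `"N<->P"`) or `"invaded"` (alias
#'   `"N->P"`).
#' @param n_reps number of randomisations (default 1000).
#' @param seed RNG seed (optional).
#' @return object of class `niche_perm_test`.
#' @export
similarity_test <- function(grid_native, grid_invaded,
                            scheme = c("both", "invaded", "N<->P", "N->P"),
                            n_reps = 1000, seed = NULL) {
  scheme <- match.arg(scheme)
  scheme <- switch(scheme, "N<->P" = "both", "N->P" = "invaded", scheme)
  check_pair(grid_native, grid_invaded)
  stop_if(n_reps < 1, "n_reps must be >= 1")
  m1 <- background_mask(grid_native$bg, p = 100)
  m2 <- background_mask(grid_invaded$bg, p = 100)
  stop_if(!any(m1) || !any(m2),
          "background mask too small to admit any translation")
  cells1 <- which(m1, arr.ind = TRUE)
  cells2 <- which(m2, arr.ind = TRUE)
  z1 <- grid_native$z; z2 <- grid_invaded$z
  obs <- 1 - 0.5 * sum(abs(z1 - z2))
  null_D <- with_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      for (try in 1:100) {
        a <- if (scheme == "both") {
          shift_density(z1, m1, cells1[sample.int(nrow(cells1), 1), ])
        } else z1
        b <- shift_density(z2, m2, cells2[sample.int(nrow(cells2), 1), ])
        if (!is.null(a) && !is.null(b))
          return(1 - 0.5 * sum(abs(a - b)))
      }
      stop("background mask too small to admit any translation", call. = FALSE)
    }, numeric(1))
  })
  perm_result(obs, null_D,
              sprintf("similarity-%s", if (scheme == "both") "N<->P" else "N->P"),
              seed)
}
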
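# Gaussian product-kernel density estimation used by both the gridded
# (COUE) and the hypervolume stages.

#' Silverman rule-of-thumb bandwidths
#'
#' Per-axis plug-in bandwidth for a Gaussian product kernel,
#' \eqn{h_j = 1.06 \, s_j \, n^{-1/(k+4)}}, the multivariate Silverman
#' rule of thumb, where \eqn{s_j} is the sample standard deviation of
#' axis \eqn{j}, \eqn{n} the number of points and \eqn{k} the number of
#' axes.
#'
#' @param points numeric matrix or data frame (rows = points, columns =
#'   axes).
#' @return numeric vector of per-axis bandwidths, named after the
#'   columns of `points`.
#' @examples
#' silverman_bandwidth(matrix(rnorm(200), ncol = 2))
#' @export
silverman_bandwidth <- function(points) {
  x <- as_num_matrix(points)
  n <- nrow(x); k <- ncol(x)
  stop_if(n < 3, "need at least 3 points to estimate a bandwidth")
  check_finite_matrix(x, "points")
  s <- apply(x, 2, stats::sd)
  zero <- which(s <= 0)
  if (length(zero))
    stop("zero-variance axis: ",
         paste(colnames(x)[zero] %||% zero, collapse = ", "), call. = FALSE)
  h <- 1.06 * s * n^(-1 / (k + 4))
  names(h) <- colnames(x)
  h
}

# Mean-of-kernels Gaussian KDE evaluated at arbitrary points, any
# dimension.  Chunked so memory stays bounded for large evaluations.
kde_at_points <- function(eval_pts, src_pts, h, chunk = 2000L) {
  ev <- as_num_matrix(eval_pts); sp <- as_num_matrix(src_pts)
  k <- ncol(sp)
  stopifnot(ncol(ev) == k, length(h) == k)
  n <- nrow(sp)
  norm <- prod(h) * (2 * pi)^(k / 2)
  out <- numeric(nrow(ev))
  for (start in seq(1L, nrow(ev), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(ev))
    m2 <- matrix(0, length(idx), n)
    for (j in seq_len(k))
      m2 <- m2 + (outer(ev[idx, j], sp[, j], "-") / h[j])^2
    out[idx] <- rowSums(exp(-0.5 * m2)) / (n * norm)
  }
  out
}

# Gaussian KDE on a rectangular grid of cell centres.  The product
# kernel is separable, so the R x R evaluation reduces to one matrix
# product: dens[i, j] = sum_p Kx[i, p] * Ky[j, p] / n.
kde_grid_2d <- function(pts, gx, gy, h) {
  p <- as_num_matrix(pts)
  stopifnot(ncol(p) == 2, length(h) == 2)
  n <- nrow(p)
  kx <- stats::dnorm(outer(gx, p[, 1], "-") / h[1]) / h[1]
  ky <- stats::dnorm(outer(gy, p[, 2], "-") / h[2]) / h[2]
  (kx %*% t(ky)) / n
}
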
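# Data preparation for ecological niche modelling: spatial thinning,
# collinearity filtering, pseudo-absence sampling, prevalence-balanced
# presence/pseudo-absence datasets and nested evaluation splits.

#' Spatially thin occurrence records
#'
#' Retains at most one record per cell of a `cell_size_km` grid, the
#' standard guard against spatial sampling bias.  Cells are defined on
#' a longitude/latitude grid of `cell_size_km / 111.32` degrees (the
#' equatorial approximation is adequate at thinning scales of a few
#' km).  Within a cell the lowest row index is kept, or a seeded random
#' record when `seed` is given.
#'
#' @param occ data frame with `lon` and `lat` columns.
#' @param cell_size_km thinning resolution in km (> 0).
#' @param seed optional seed for random within-cell choice.
#' @return the thinned data frame; the number retained is reported via
#'   `message()`.
#' @export
thin_records <- function(occ, cell_size_km = 5, seed = NULL) {
  occ <- as.data.frame(occ)
  stop_if(nrow(occ) == 0, "empty occurrence table")
  stop_if(!all(c("lon", "lat") %in% names(occ)),
          "occurrence table needs lon and lat columns")
  stop_if(cell_size_km <= 0, "cell_size_km must be positive")
  deg <- cell_size_km / 111.32
  cell <- paste(floor(occ$lon / deg), floor(occ$lat / deg))
  pick <- if (is.null(seed)) {
    tapply(seq_len(nrow(occ)), cell, min)
  } else {
    with_seed(seed, tapply(seq_len(nrow(occ)), cell, function(i)
      i[sample.int(length(i), 1)]))
  }
  keep <- sort(as.integer(pick))
  message(sprintf("thinned %d records to %d (one per %g km cell)",
                  nrow(occ), length(keep), cell_size_km))
  occ[keep, , drop = FALSE]
}

#' Greedy collinearity filter on Pearson correlations
#'
#' Walks variable pairs in column order and drops the later-listed
#' variable of every pair with `|r| > threshold`; pairs at exactly the
#' threshold are both kept (the `<=` rule).
#'
#' @param env_table data frame/matrix of candidate variables (>= 2).
#' @param threshold absolute-correlation cutoff (default 0.7).
#' @return character vector of retained variable names.
#' @export
correlation_filter <- function(env_table, threshold = 0.7) {
  x <- as.data.frame(env_table)
  stop_if(ncol(x) < 2, "need at least 2 variables")
  s <- vapply(x, stats::sd, numeric(1))
  if (any(s <= 0))
    stop("constant variable: ", paste(names(x)[s <= 0], collapse = ", "),
         call. = FALSE)
  r <- abs(stats::cor(as_num_matrix(x)))
  vars <- names(x)
  keep <- vars
  for (i in seq_along(vars)) {
    if (!(vars[i] %in% keep)) next
    for (j in seq_along(vars)) {
      if (j <= i || !(vars[j] %in% keep)) next
      # float-safe strict inequality: a pair at exactly the threshold
      # (up to representation error) is kept
      if (r[i, j] > threshold + 1e-12) keep <- setdiff(keep, vars[j])
    }
  }
  keep
}

#' Sample pseudo-absence points from the background
#'
#' Draws `n` background points, uniformly and without replacement, from
#' background rows whose grid cell contains no presence record.
#'
#' @param background data frame of background points (`lon`/`lat`
#'   columns, or the first two columns are used as coordinates).
#' @param occ presence data frame with the same coordinate columns.
#' @param n number of pseudo-absences (default 10000).
#' @param cell_size exclusion-cell edge in coordinate units
#'   (default 0.05).
#' @param seed RNG seed.
#' @return the sampled background rows.
#' @export
sample_pseudo_absences <- function(background, occ, n = 10000,
                                   cell_size = 0.05, seed = NULL) {
  bg <- as.data.frame(background); oc <- as.data.frame(occ)
  cxy <- function(d) {
    if (all(c("lon", "lat") %in% names(d))) cbind(d$lon, d$lat)
    else as_num_matrix(d[, 1:2])
  }
  key <- function(m) paste(floor(m[, 1] / cell_size),
                           floor(m[, 2] / cell_size))
  occupied <- unique(key(cxy(oc)))
  eligible <- which(!(key(cxy(bg)) %in% occupied))
  stop_if(length(eligible) < n,
          sprintf("only %d eligible background points for %d pseudo-absences",
                  length(eligible), n))
  idx <- with_seed(seed, sample(eligible, n))
  bg[idx, , drop = FALSE]
}

#' Assemble a prevalence-balanced presence/pseudo-absence dataset
#'
#' Presences and pseudo-absences receive case weights implementing a
#' neutral prevalence of 0.5: each class carries the same total weight
#' regardless of its size (weights are scaled to sum to the number of
#' rows, which keeps likelihood-based fitters well behaved).
#'
#' @param presence_env,absence_env data frames of environmental values
#'   for presences and pseudo-absences (identical columns).
#' @param range_label `"native"`, `"invaded"` or `"combined"`.
#' @return object of class `pa_dataset`: data frame `env`, response
#'   `y` (1/0), `weights`, `range_label`.
#' @export
make_pa_dataset <- function(presence_env, absence_env,
                            range_label = c("native", "invaded", "combined")) {
  range_label <- match.arg(range_label)
  p <- as.data.frame(presence_env); a <- as.data.frame(absence_env)
  stop_if(!identical(names(p), names(a)),
          "presence and absence tables must share columns")
  np <- nrow(p); na <- nrow(a)
  stop_if(np < 1 || na < 1, "both classes must be non-empty")
  n <- np + na
  w <- c(rep(n / (2 * np), np), rep(n / (2 * na), na))
  structure(list(env = rbind(p, a), y = c(rep(1L, np), rep(0L, na)),
                 weights = w, range_label = range_label),
            class = "pa_dataset")
}

#' @exportS3Method base::print
print.pa_dataset <- function(x, ...) {
  cat(sprintf("pa_dataset (%s): %d presences, %d pseudo-absences, %d vars\n",
              x$range_label, sum(x$y == 1), sum(x$y == 0), ncol(x$env)))
  invisible(x)
}

pa_subset <- function(pa, idx) {
  structure(list(env = pa$env[idx, , drop = FALSE], y = pa$y[idx],
                 weights = pa$weights[idx], range_label = pa$range_label),
            class = "pa_dataset")
}

strat_sample <- function(y, frac) {
  unlist(lapply(split(seq_along(y), y), function(i)
    sample(i, round(frac * length(i)))), use.names = FALSE)
}

#' Nested evaluation / train-test split plan
#'
#' Splits a presence/pseudo-absence dataset into one fixed evaluation
#' slice (`eval_frac`, stratified by class; the E_eval dataset) and
#' `n_repeats` stratified inner train/test resamples of the remainder.
#' With L learners the plan yields `L x n_repeats` member models.
#'
#' @param pa a [make_pa_dataset()].
#' @param eval_frac fraction held out as E_eval (default 0.3).
#' @param inner_test_frac fraction of the remainder used as inner test
#'   in each repeat (default 0.3).
#' @param n_repeats inner resampling repeats (default 10).
#' @param seed RNG seed.
#' @return object of class `split_plan`: `eval_idx`, and `repeats`, a
#'   list of `list(train, test)` index vectors into `pa`.
#' @export
split_dataset <- function(pa, eval_frac = 0.3, inner_test_frac = 0.3,
                          n_repeats = 10, seed = NULL) {
  stopifnot(inherits(pa, "pa_dataset"))
  stop_if(sum(pa$y == 1) < 10, "need at least 10 presences for splitting")
  stop_if(sum(pa$y == 0) < 10, "need at least 10 absences for splitting")
  with_seed(seed, {
    eval_idx <- sort(strat_sample(pa$y, eval_frac))
    rest <- setdiff(seq_along(pa$y), eval_idx)
    reps <- lapply(seq_len(n_repeats), function(r) {
      test_local <- strat_sample(pa$y[rest], inner_test_frac)
      list(train = sort(rest[-test_local]), test = sort(rest[test_local]))
    })
    structure(list(eval_idx = eval_idx, repeats = reps,
                   n_repeats = n_repeats, eval_frac = eval_frac,
                   inner_test_frac = inner_test_frac, seed = seed),
              class = "split_plan")
  })
}
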
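# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the previous
#' RNG state afterwards, so seeded operations do not perturb the caller's
#' random stream.  A `NULL` seed leaves the RNG untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# Derive a stage seed from a global seed; keeps results < 2^31.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  offs <- c(backgrounds = 11L, species = 23L, coue = 37L, tests = 53L,
            hypervolume = 71L, enm = 97L, raster = 113L)
  o <- offs[[stage]] %||% 131L
  as.integer((as.numeric(seed) * 7919 + o * 104729) %% 2147483647)
}

# Deterministic 31-bit polynomial hash of a character scalar; used to
# stamp outputs with a configuration fingerprint without external
# digest dependencies (all intermediates stay below 2^53).
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

check_finite_matrix <- function(x, what = "input") {
  if (!all(is.finite(as.matrix(x))))
    stop(what, " contains non-finite values (NA/NaN/Inf)", call. = FALSE)
  invisible(x)
}

as_num_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  storage.mode(x) <- "double"
  x
}
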
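# Minimal raster-stack container and ESRI ASCII grid I/O.  Layers are
# plain matrices (row 1 = southernmost row), registered by cell centre
# on a shared lower-left origin; this keeps the whole pipeline free of
# heavyweight spatial dependencies while remaining interoperable
# through the ASCII grid interchange format.

#' Construct an environmental raster stack
#'
#' @param layers named list of equally sized numeric matrices
#'   (rows = northings from the south, columns = eastings).
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @param cellsize cell edge length.
#' @param nodata value written for `NA` cells on export.
#' @return object of class `env_stack`.
#' @export
env_stack <- function(layers, xll = 0, yll = 0, cellsize = 1,
                      nodata = -9999) {
  stop_if(length(layers) < 1, "need at least one layer")
  stop_if(is.null(names(layers)) || any(names(layers) == ""),
          "layers must be named")
  dims <- vapply(layers, dim, integer(2))
  stop_if(!all(dims == dims[, 1]), "all layers must share the same grid")
  structure(list(layers = layers, xll = xll, yll = yll,
                 cellsize = cellsize, nodata = nodata,
                 nrow = nrow(layers[[1]]), ncol = ncol(layers[[1]])),
            class = "env_stack")
}

#' @exportS3Method base::print
print.env_stack <- function(x, ...) {
  cat(sprintf("env_stack: %d layer(s) [%s] on a %dx%d grid (cell %.4g)\n",
              length(x$layers), paste(names(x$layers), collapse = ", "),
              x$nrow, x$ncol, x$cellsize))
  invisible(x)
}

# Cell-centre coordinates, by matrix index.
stack_coords <- function(stack) {
  xs <- stack$xll + (seq_len(stack$ncol) - 0.5) * stack$cellsize
  ys <- stack$yll + (seq_len(stack$nrow) - 0.5) * stack$cellsize
  list(x = xs, y = ys)
}

# Stack cells as a data frame (one row per cell, NA rows included).
stack_as_df <- function(stack) {
  out <- as.data.frame(lapply(stack$layers, function(m) as.vector(m)))
  names(out) <- names(stack$layers)
  out
}

#' Write a matrix as an ESRI ASCII grid
#'
#' @param mat numeric matrix (row 1 = southernmost row).
#' @param file output path.
#' @param xll,yll lower-left corner; `cellsize` cell edge;
#'   `nodata` value substituted for `NA`.
#' @export
write_asc <- function(mat, file, xll = 0, yll = 0, cellsize = 1,
                      nodata = -9999) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(mat)), paste("nrows", nrow(mat)),
    paste("xllcorner", format(xll, digits = 15)),
    paste("yllcorner", format(yll, digits = 15)),
    paste("cellsize", format(cellsize, digits = 15)),
    paste("NODATA_value", nodata)), con)
  m <- mat
  m[is.na(m)] <- nodata
  # ASCII grids are written north to south
  for (i in rev(seq_len(nrow(m))))
    writeLines(paste(format(m[i, ], digits = 10, trim = TRUE),
                     collapse = " "), con)
  invisible(file)
}

#' Read an ESRI ASCII grid
#'
#' @param file path to a `.asc` file.
#' @return list with `mat` (row 1 = southernmost row), `xll`, `yll`,
#'   `cellsize`, `nodata`.
#' @export
read_asc <- function(file) {
  lines <- readLines(file)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[rev(seq_len(nr)), , drop = FALSE]   # back to south-first rows
  nodata <- hdr$nodata_value %||% -9999
  m[m == nodata] <- NA
  list(mat = m, xll = hdr$xllcorner, yll = hdr$yllcorner,
       cellsize = hdr$cellsize, nodata = nodata)
}
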
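#' Rectangular raster grid
#'
#' Lightweight container for a single-band raster in projected coordinates.
#' Row 1 is the northernmost row; cell `(r, c)` has its centre at
#' `(xmin + (c - 0.5) * cell_size, ymax - (r - 0.5) * cell_size)`.
#' Missing cells are stored as `NA`.
#'
#' @param values numeric or integer matrix of cell values (`NA` = nodata).
#' @param cell_size cell edge length in metres (> 0).
#' @param xmin x coordinate of the western grid edge.
#' @param ymax y coordinate of the northern grid edge.
#' @param categorical logical; `TRUE` for class-code layers.
#'
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, cell_size, xmin = 0, ymax = NULL,
                        categorical = FALSE) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  if (is.null(ymax)) ymax <- nrow(values) * cell_size
  structure(
    list(values = values, cell_size = cell_size,
         xmin = xmin, ymax = ymax, categorical = isTRUE(categorical)),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster_grid: %d x %d cells, %g m resolution%s\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              if (x$categorical) " (categorical)" else ""))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]\n",
              x$xmin, x$xmin + ncol(x$values) * x$cell_size,
              x$ymax - nrow(x$values) * x$cell_size, x$ymax))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  values: [%g, %g], %d NA\n", rng[1], rng[2],
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' Cell-centre coordinates of every cell
#'
#' @param grid a [raster_grid].
#' @return A two-column matrix `(x, y)` in row-major (by row, west to east)
#'   order, i.e. row index varies slowest.
#' @export
cell_centres <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  cx <- grid$xmin + (seq_len(nc) - 0.5) * grid$cell_size
  cy <- grid$ymax - (seq_len(nr) - 0.5) * grid$cell_size
  cbind(x = rep(cx, times = nr), y = rep(cy, each = nc))
}

#' Map planar points to grid cells
#'
#' Cells are half-open: a point exactly on a shared vertical edge belongs to
#' the cell to the east, on a shared horizontal edge to the cell to the south.
#'
#' @param grid a [raster_grid].
#' @param xy two-column matrix of coordinates.
#' @return data.frame with `row`, `col` (1-based) and `cell` (row-major index).
#' @export
locate_cells <- function(grid, xy) {
  xy <- as.matrix(xy)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  col <- floor((xy[, 1] - grid$xmin) / grid$cell_size) + 1L
  row <- floor((grid$ymax - xy[, 2]) / grid$cell_size) + 1L
  ## a point exactly on the southern/eastern outer boundary is still inside
  col[xy[, 1] == grid$xmin + nc * grid$cell_size] <- nc
  row[xy[, 2] == grid$ymax - nr * grid$cell_size] <- nr
  bad <- which(col < 1L | col > nc | row < 1L | row > nr)
  if (length(bad))
    stop("point(s) outside grid bounds at record(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  data.frame(row = row, col = col, cell = (row - 1L) * nc + col)
}

#' Write / read a raster as an ESRI ASCII grid
#'
#' Plain-text `.asc` with the standard 6-line header; `NODATA_value` -9999.
#'
#' @param grid a [raster_grid].
#' @param path output file path.
#' @export
write_asc <- function(grid, path) {
  v <- grid$values
  v[is.na(v)] <- -9999
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$xmin),
    sprintf("yllcorner %.10g", grid$ymax - nrow(v) * grid$cell_size),
    sprintf("cellsize %.10g", grid$cell_size),
    "NODATA_value -9999"), con)
  utils::write.table(format(v, digits = 10, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_asc
#' @param categorical logical, mark the layer as categorical on read.
#' @export
read_asc <- function(path, categorical = FALSE) {
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "\\s+")
  key <- tolower(vapply(kv, `[`, "", 1L))
  val <- as.numeric(vapply(kv, `[`, "", 2L))
  names(val) <- key
  m <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(m) <- NULL
  m[m == val[["nodata_value"]]] <- NA
  raster_grid(m, cell_size = val[["cellsize"]], xmin = val[["xllcorner"]],
              ymax = val[["yllcorner"]] + val[["nrows"]] * val[["cellsize"]],
              categorical = categorical)
}

## exact 1-D squared Euclidean distance transform (lower envelope of parabolas)
dt_1d <- function(f) {
  n <- length(f)
  fin <- which(is.finite(f))
  if (!length(fin) || n == 1L) return(f)
  if (length(fin) < n) {
    ## envelope over the finite parabolas only, evaluated everywhere
    d <- vapply(seq_len(n), function(q) min((q - fin)^2 + f[fin]), 0)
    return(d)
  }
  d <- numeric(n); v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  for (q in 2:n) {
    s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    while (s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    }
    k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Euclidean distance to the nearest feature cell
#'
#' Exact distance transform: each cell value is the Euclidean distance (in
#' metres) from its centre to the nearest feature-cell centre; feature cells
#' get 0.
#'
#' @param feature_mask a [raster_grid] whose non-zero, non-`NA` cells are
#'   features.
#' @return A continuous [raster_grid] of distances.
#' @export
distance_layer <- function(feature_mask) {
  m <- feature_mask$values
  feat <- !is.na(m) & m != 0
  if (!any(feat)) stop("feature mask is empty: no feature cells")
  f <- matrix(Inf, nrow(m), ncol(m))
  f[feat] <- 0
  ## columns then rows; dt_1d is exact, so composition is the exact 2-D EDT
  for (j in seq_len(ncol(f))) f[, j] <- dt_1d(f[, j])
  for (i in seq_len(nrow(f))) f[i, ] <- dt_1d(f[i, ])
  raster_grid(sqrt(f) * feature_mask$cell_size,
              cell_size = feature_mask$cell_size,
              xmin = feature_mask$xmin, ymax = feature_mask$ymax)
}

## sum over available neighbours of each cell, with a parallel neighbour count
neighbour_stats <- function(z, contiguity) {
  nr <- nrow(z); nc <- ncol(z)
  ok <- !is.na(z)
  zz <- z; zz[!ok] <- 0
  s <- matrix(0, nr, nc); n <- matrix(0, nr, nc)
  shift <- function(m, dr, dc) {
    out <- matrix(0, nr, nc)
    rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
    keep_r <- rs >= 1 & rs <= nr; keep_c <- cs >= 1 & cs <= nc
    out[keep_r, keep_c] <- m[rs[keep_r], cs[keep_c]]
    out
  }
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (contiguity == "queen")
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  for (o in offs) {
    s <- s + shift(zz, o[1], o[2])
    n <- n + shift(ok + 0, o[1], o[2])
  }
  list(sum = s, count = n)
}

#' Global Moran's I of a raster
#'
#' Row-standardized contiguity weights (rook or queen). For such weights the
#' statistic lies in `[-1, 1]` on regular grids; positive values indicate
#' spatial clustering of similar values.
#'
#' @param raster a [raster_grid] with at least 2 x 2 cells.
#' @param contiguity `"rook"` (4-neighbour, default) or `"queen"`
#'   (8-neighbour).
#' @return The Moran's I statistic (scalar).
#' @export
morans_i <- function(raster, contiguity = c("rook", "queen")) {
  contiguity <- match.arg(contiguity)
  v <- raster$values
  if (nrow(v) < 2L || ncol(v) < 2L) stop("grid must be at least 2 x 2")
  ok <- !is.na(v)
  x <- v[ok]
  if (stats::var(x) == 0) stop("constant raster: Moran's I undefined")
  z <- v - mean(x)
  z[!ok] <- NA
  nb <- neighbour_stats(z, contiguity)
  use <- ok & nb$count > 0
  lag <- nb$sum[use] / nb$count[use]     # row-standardized spatial lag
  (sum(ok) / sum(use)) * sum(z[use] * lag) / sum(z[ok]^2)
}
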
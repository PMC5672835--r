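#' Aggregate 30 m layers to resource units
#'
#' Builds the resource-unit (RU) table at a coarser grain from co-registered
#' fine-scale rasters. Continuous layers are block-averaged; the categorical
#' cover layer is expanded into one proportion layer per class ("proportion of
#' class k in each RU"). Each RU also gets a dominant cover class: the class
#' with the largest proportion, ties broken by the smallest class code.
#'
#' Trailing rows/columns not divisible by `factor` are dropped with a warning.
#' An RU whose fine cells are more than 50% nodata is dropped; otherwise its
#' statistics are computed over the valid fine cells only.
#'
#' @param cover categorical [raster_grid] of integer class codes.
#' @param continuous named list of continuous [raster_grid]s, co-registered
#'   with `cover`.
#' @param factor integer aggregation factor (3 turns 30 m cells into 90 m RUs).
#' @param zone optional categorical [raster_grid] of zone codes (e.g. core =
#'   1, buffer = 2) at the fine scale; the RU takes the majority zone.
#' @param egv_classes optional subset of cover classes whose proportion
#'   layers are treated as EGVs (default: all). Proportion layers and the
#'   dominant-class label always cover the full class set; restricting the
#'   EGV subset mirrors studies where some mapped classes (open water,
#'   settlements) enter the analysis as distance layers rather than
#'   proportions, and avoids making the EGV proportions exactly
#'   compositional.
#'
#' @return A list with `rut` (the RU table: `ru_id`, centre `x`, `y`, one
#'   `prop_*` column per cover class, the continuous EGVs, `dominant`,
#'   optional `zone`) and `stack` (the coarse [raster_grid]s, one per EGV).
#' @export
aggregate_to_ru <- function(cover, continuous = list(), factor = 3L,
                            zone = NULL, egv_classes = NULL) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("`factor` must be a positive integer")
  grids <- c(list(cover), continuous)
  cs <- vapply(grids, function(g) g$cell_size, 0)
  if (length(unique(cs)) != 1L)
    stop("mixed cell sizes: all fine layers must be co-registered")
  dims <- vapply(grids, function(g) dim(g$values), integer(2))
  if (any(dims != dims[, 1])) stop("fine layers differ in dimensions")

  nr <- nrow(cover$values); nc <- ncol(cover$values)
  nr_c <- nr %/% factor; nc_c <- nc %/% factor
  if (nr_c < 1L || nc_c < 1L) stop("grid smaller than one aggregation block")
  if (nr %% factor || nc %% factor)
    warning(sprintf("dropping %d trailing row(s) and %d trailing column(s) not divisible by factor %d",
                    nr %% factor, nc %% factor, factor))
  rows <- seq_len(nr_c * factor); cols <- seq_len(nc_c * factor)
  blk_r <- (seq_len(nr_c * factor) - 1L) %/% factor + 1L
  blk_c <- (seq_len(nc_c * factor) - 1L) %/% factor + 1L

  block_apply <- function(m, fun) {
    ## fun over each factor x factor block; returns nr_c x nc_c matrix
    grp_r <- rep(blk_r, times = length(cols))
    grp_c <- rep(blk_c, each = length(rows))
    idx <- (grp_c - 1L) * nr_c + grp_r
    vals <- as.vector(m[rows, cols])
    out <- vapply(split(vals, idx), fun, 0)
    matrix(out[as.character(seq_len(nr_c * nc_c))], nr_c, nc_c)
  }

  mean_valid <- function(x) {
    v <- x[!is.na(x)]
    if (2 * length(v) < length(x)) NA_real_ else mean(v)
  }

  cell_c <- cover$cell_size * factor
  coarse <- function(values, categorical = FALSE)
    raster_grid(values, cell_size = cell_c, xmin = cover$xmin,
                ymax = cover$ymax, categorical = categorical)

  classes <- sort(unique(stats::na.omit(as.vector(cover$values[rows, cols]))))
  stack <- list()
  for (k in classes) {
    prop_k <- block_apply(cover$values, function(x) {
      v <- x[!is.na(x)]
      if (2 * length(v) < length(x)) NA_real_ else mean(v == k)
    })
    stack[[paste0("prop_", k)]] <- coarse(prop_k)
  }
  for (nm in names(continuous))
    stack[[nm]] <- coarse(block_apply(continuous[[nm]]$values, mean_valid))

  as_cols <- function(nms)
    matrix(unlist(lapply(nms, function(nm) as.vector(t(stack[[nm]]$values)))),
           ncol = length(nms), dimnames = list(NULL, nms))
  prop_mat <- as_cols(paste0("prop_", classes))
  cont_mat <- if (length(continuous)) as_cols(names(continuous)) else NULL

  centres <- cell_centres(stack[[1]])
  rut <- data.frame(ru_id = seq_len(nr_c * nc_c),
                    x = centres[, 1], y = centres[, 2])
  rut <- cbind(rut, prop_mat)
  if (!is.null(cont_mat)) rut <- cbind(rut, cont_mat)

  ## dominant class: max proportion, ties to the smallest class code
  dom <- apply(prop_mat, 1L, function(p)
    if (anyNA(p)) NA_integer_ else classes[which.max(p)])
  rut$dominant <- dom

  if (!is.null(zone)) {
    zmaj <- block_apply(zone$values, function(x) {
      v <- x[!is.na(x)]
      if (!length(v)) NA_real_
      else as.numeric(names(which.max(table(v))))
    })
    rut$zone <- as.vector(t(zmaj))
  }

  keep <- stats::complete.cases(rut[, !(names(rut) %in% "zone"), drop = FALSE])
  rut <- rut[keep, , drop = FALSE]
  rownames(rut) <- NULL

  if (is.null(egv_classes)) egv_classes <- classes
  else if (!all(egv_classes %in% classes))
    stop("`egv_classes` contains classes absent from the cover raster")
  structure(list(rut = structure(rut, class = c("ru_table", "data.frame"),
                                 classes = classes,
                                 prop_cols = paste0("prop_", egv_classes),
                                 cont_cols = names(continuous),
                                 cell_size = cell_c,
                                 n_rows = nr_c, n_cols = nc_c,
                                 xmin = cover$xmin, ymax = cover$ymax),
                 stack = stack),
            class = "ru_aggregation")
}

#' Names of the EGV columns of an RU table
#' @param rut an RU table from [aggregate_to_ru()].
#' @return character vector of EGV column names (proportions then continuous).
#' @export
egv_columns <- function(rut) {
  c(attr(rut, "prop_cols"), attr(rut, "cont_cols"))
}

#' Pairwise Pearson correlation screening of EGVs
#'
#' @param rut RU table.
#' @param threshold flag pairs with `|r| >=` this value (default 0.7).
#' @return list with `r` (correlation matrix over non-constant EGVs),
#'   `flagged` (data.frame of flagged pairs), `constant` (names of excluded
#'   constant columns).
#' @export
pearson_screen <- function(rut, threshold = 0.7) {
  cols <- egv_columns(rut)
  if (nrow(rut) < 3L) stop("need at least 3 RUs for correlation screening")
  X <- as.matrix(rut[, cols, drop = FALSE])
  sds <- apply(X, 2L, stats::sd)
  const <- colnames(X)[sds == 0]
  if (length(const))
    warning("constant EGV column(s) excluded from correlation matrix: ",
            paste(const, collapse = ", "))
  X <- X[, sds > 0, drop = FALSE]
  r <- stats::cor(X)
  ut <- which(upper.tri(r) & abs(r) >= threshold, arr.ind = TRUE)
  flagged <- data.frame(var1 = rownames(r)[ut[, 1]],
                        var2 = colnames(r)[ut[, 2]],
                        r = r[ut])
  list(r = r, flagged = flagged, constant = const)
}

#' Principal component analysis of the EGV table
#'
#' Centred and scaled PCA of the RU x EGV matrix, as a descriptive summary of
#' landscape structure.
#'
#' @param rut RU table.
#' @return list with `eigenvalues` (descending), `percent` (percent variance,
#'   sums to 100), `loadings` (EGV x axis, unit norm) and `scores` (RU x axis).
#' @export
pca_egv <- function(rut) {
  cols <- egv_columns(rut)
  X <- as.matrix(rut[, cols, drop = FALSE])
  sds <- apply(X, 2L, stats::sd)
  if (sum(sds > 0) < 2L) stop("need at least 2 non-constant EGVs for PCA")
  X <- X[, sds > 0, drop = FALSE]
  p <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ev <- p$sdev^2
  list(eigenvalues = ev, percent = 100 * ev / sum(ev),
       loadings = p$rotation, scores = p$x)
}

#' Overall accuracy and Cohen's kappa of a confusion matrix
#'
#' @param cm square matrix of counts, rows = reference classes, columns =
#'   mapped classes.
#' @return list with `accuracy` and `kappa`.
#' @export
kappa_accuracy <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (any(cm < 0) || any(cm != round(cm))) stop("counts must be non-negative integers")
  n <- sum(cm)
  if (n <= 0) stop("confusion matrix has zero total count")
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe >= 1) stop("chance agreement is 1 (single class): kappa undefined")
  list(accuracy = po, kappa = (po - pe) / (1 - pe))
}
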
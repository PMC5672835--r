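#' Fit the Mahalanobis niche model
#'
#' Summarizes the habitat conditions at the (thinned, settled-period) used
#' locations by their mean vector and sample covariance on the original EGV
#' scales. The Mahalanobis distance of any RU to this mean then measures
#' dissimilarity from the species' typical habitat.
#'
#' Because EGVs mix units (proportions, metres, degrees), singularity is
#' judged on the correlation matrix, to which the Mahalanobis distance is
#' scale-equivalent. The optional ridge is likewise applied on the
#' correlation scale (`(R + eps I) / (1 + eps)` rescaled back by the
#' variances), so it shrinks every variable equally regardless of units.
#'
#' @param X numeric matrix of EGV values at the used locations (rows =
#'   locations).
#' @param ridge optional non-negative ridge `eps` for a near-singular
#'   covariance; off (`0`) by default and logged with a message when used.
#'
#' @return An object of class `niche_model`: list with `mu`, `sigma`, `p`
#'   (number of EGVs), `n`, `condition` (condition number of the correlation
#'   matrix, after any ridge).
#' @export
fit_niche <- function(X, ridge = 0) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more locations than EGVs to estimate the covariance")
  mu <- colMeans(X)
  sigma <- stats::cov(X)
  s <- sqrt(diag(sigma))
  if (any(s == 0))
    stop("covariance is singular (constant EGV at the used locations)")
  R <- stats::cov2cor(sigma)
  if (ridge > 0) {
    R <- (R + diag(ridge, p)) / (1 + ridge)
    sigma <- R * tcrossprod(s)
    message(sprintf("ridge regularization applied: eps = %g", ridge))
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > 1e8)
    stop("covariance is singular or near-singular (condition number > 1e8); ",
         "supply a ridge or drop redundant EGVs")
  structure(list(mu = mu, sigma = sigma, p = p, n = n,
                 condition = max(ev) / min(ev)),
            class = "niche_model")
}

#' @export
print.niche_model <- function(x, ...) {
  cat(sprintf("Mahalanobis niche model: %d EGVs, fitted on %d locations\n",
              x$p, x$n))
  cat(sprintf("  covariance condition number: %.3g\n", x$condition))
  invisible(x)
}

#' Mahalanobis distance and suitability over the RU table
#'
#' For every RU, `D2 = (x - mu)' Sigma^-1 (x - mu)`; under multivariate
#' normality of the used habitat, D2 follows a chi-square distribution with
#' as many degrees of freedom as there are EGVs, so suitability is mapped as
#' the chi-square survival probability at D2. Habitat quality is inversely
#' related to D2; suitability values lie in `[0, 1]`.
#'
#' @param rut RU table.
#' @param model a [fit_niche()] model (EGV set must match the table's EGVs).
#' @param grid optional coarse [raster_grid] template; when supplied, D2 and
#'   suitability are also returned as rasters (nodata where RUs were
#'   dropped).
#'
#' @return list with `d2` and `suitability` vectors (one value per RU table
#'   row), plus `d2_raster` and `suitability_raster` when `grid` is given.
#' @export
suitability_map <- function(rut, model, grid = NULL) {
  cols <- egv_columns(rut)
  X <- as.matrix(rut[, cols, drop = FALSE])
  if (ncol(X) != model$p) stop("EGV set does not match the fitted model")
  d2 <- unname(stats::mahalanobis(X, model$mu, model$sigma))
  suit <- stats::pchisq(d2, df = model$p, lower.tail = FALSE)
  out <- list(d2 = d2, suitability = suit)
  if (!is.null(grid)) {
    to_raster <- function(v) {
      m <- matrix(NA_real_, nrow(grid$values), ncol(grid$values))
      m[cbind((rut$ru_id - 1L) %/% ncol(m) + 1L,
              (rut$ru_id - 1L) %% ncol(m) + 1L)] <- v
      raster_grid(m, cell_size = grid$cell_size, xmin = grid$xmin,
                  ymax = grid$ymax)
    }
    out$d2_raster <- to_raster(d2)
    out$suitability_raster <- to_raster(suit)
  }
  out
}

#' Predicted-to-expected (Fi) curve of a suitability map
#'
#' The suitability range `[0, 1]` is cut into `n_classes` equal intervals
#' (default 20 classes of width 0.05). For each class, `E_i` is the expected
#' frequency (relative area, i.e. share of valid cells) and `P_i` the
#' predicted frequency of evaluation points; `F_i = P_i / E_i`. `F_i = 1`
#' marks random use; classes with `F_i > 1` are used more than expected by
#' chance. The suitability threshold is the lower bound of the first class
#' (scanning upward) from which F stays above 1.
#'
#' @param cell_suitability suitability values of all valid RUs (vector).
#' @param point_suitability suitability values at the evaluation points.
#' @param n_classes number of equal-width classes (default 20).
#'
#' @return An object of class `fi_curve`: data.frame-bearing list with
#'   `classes` (class, lo, hi, E, P, F over non-empty classes), `threshold`
#'   (suitability value) and `n_classes`.
#' @export
fi_curve <- function(cell_suitability, point_suitability, n_classes = 20L) {
  cs <- cell_suitability[!is.na(cell_suitability)]
  ps <- point_suitability[!is.na(point_suitability)]
  if (!length(ps)) stop("no evaluation points on valid cells")
  breaks <- seq(0, 1, length.out = n_classes + 1L)
  bin <- function(v) pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE),
                               1L), n_classes)
  E <- tabulate(bin(cs), n_classes) / length(cs)
  P <- tabulate(bin(ps), n_classes) / length(ps)
  keep <- E > 0
  cl <- data.frame(class = which(keep),
                   lo = breaks[which(keep)], hi = breaks[which(keep) + 1L],
                   E = E[keep], P = P[keep], F = P[keep] / E[keep])
  ## first upcrossing of 1 that stays above 1 for all higher classes
  above <- cl$F > 1
  thr <- NA_real_
  if (any(above)) {
    stays <- rev(cumprod(rev(above))) == 1
    if (any(stays)) thr <- cl$lo[which(stays)[1L]]
  }
  structure(list(classes = cl, threshold = thr, n_classes = n_classes),
            class = "fi_curve")
}

#' @export
print.fi_curve <- function(x, ...) {
  cat(sprintf("Fi curve over %d classes (%d non-empty); threshold = %s\n",
              x$n_classes, nrow(x$classes),
              if (is.na(x$threshold)) "undefined" else format(x$threshold)))
  print(x$classes, row.names = FALSE)
  invisible(x)
}

#' Boyce index of an Fi curve
#'
#' Spearman rank correlation between `F_i` and the class rank: 1 for a
#' perfectly calibrated map (F increases with suitability class), 0 for a
#' random model, negative when high-suitability classes are under-used. The
#' adjusted R-squared of the least-squares line of F on class rank is
#' reported alongside.
#'
#' @param curve an [fi_curve()].
#' @return list with `spearman`, `adj_r_squared`, `n_classes_used`;
#'   both statistics are `NA` (with a message) when F is constant.
#' @export
boyce_index <- function(curve) {
  cl <- curve$classes
  if (nrow(cl) < 2L) stop("need at least 2 non-empty classes")
  if (stats::sd(cl$F) == 0) {
    message("F is constant across classes: Boyce index undefined")
    return(list(spearman = NA_real_, adj_r_squared = NA_real_,
                n_classes_used = nrow(cl)))
  }
  rank_cl <- seq_len(nrow(cl))
  fit <- stats::lm(cl$F ~ rank_cl)
  list(spearman = stats::cor(rank_cl, cl$F, method = "spearman"),
       adj_r_squared = summary(fit)$adj.r.squared,
       n_classes_used = nrow(cl))
}

#' Reclassify suitability at the Fi threshold and summarize by zone
#'
#' A cell is suitable iff its suitability p-value is at or above the
#' threshold taken from the Fi curve (the `F_i = 1` boundary between
#' unsuitable and suitable habitat).
#'
#' @param suitability suitability values per RU row (vector).
#' @param threshold suitability threshold (e.g. `fi_curve()$threshold`).
#' @param zone optional vector of zone labels per RU row (e.g. core/buffer).
#' @return list with `suitable` (logical per RU), `percent_suitable`
#'   (overall, in percent) and `by_zone` (data.frame, when `zone` given).
#' @export
reclassify_suitability <- function(suitability, threshold, zone = NULL) {
  if (is.na(threshold)) stop("threshold is undefined on this Fi curve")
  ok <- !is.na(suitability)
  suitable <- suitability >= threshold
  out <- list(suitable = suitable,
              percent_suitable = 100 * sum(suitable[ok]) / sum(ok))
  if (!is.null(zone)) {
    if (!any(ok & !is.na(zone))) stop("no valid cells overlap the zones")
    zs <- split(suitable[ok & !is.na(zone)], zone[ok & !is.na(zone)])
    out$by_zone <- data.frame(
      zone = names(zs),
      n_cells = vapply(zs, length, 0L),
      percent_suitable = vapply(zs, function(v) 100 * mean(v), 0))
  }
  out
}
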
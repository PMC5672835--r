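#' Remove exact duplicate coordinates
#'
#' @param points two-column matrix or data.frame of coordinates.
#' @return The points with exact coordinate duplicates collapsed to the first
#'   occurrence, plus a `kept` attribute with the retained row indices.
#' @export
dedupe <- function(points) {
  xy <- as.matrix(points)[, 1:2, drop = FALSE]
  keep <- !duplicated(xy)
  structure(xy[keep, , drop = FALSE], kept = which(keep))
}

## pairwise Euclidean distance matrix with +Inf diagonal
dist_inf <- function(xy) {
  D <- as.matrix(stats::dist(xy))
  diag(D) <- Inf
  D
}

#' Clark-Evans aggregation index
#'
#' Ratio of the observed mean nearest-neighbour distance to its expectation
#' `1 / (2 sqrt(n / area))` under complete spatial randomness; no edge
#' correction. R < 1 indicates clustering, 1 randomness, > 1 ordering.
#'
#' @param points two-column matrix of coordinates.
#' @param area reference window area (m^2), e.g. the animal's MCP area.
#' @return The index R (scalar).
#' @export
clark_evans <- function(points, area) {
  xy <- as.matrix(points)[, 1:2, drop = FALSE]
  n <- nrow(xy)
  if (n < 2L) stop("Clark-Evans index needs at least 2 points")
  if (!is.numeric(area) || area <= 0) stop("`area` must be positive")
  D <- dist_inf(xy)
  mean(apply(D, 1L, min)) * 2 * sqrt(n / area)
}

#' Thin clustered relocations until spatially random
#'
#' Greedy removal of aggregation: at each step find the closest pair of
#' retained points and delete the member whose removal yields the larger mean
#' nearest-neighbour distance (ties: the higher index), then recompute the
#' Clark-Evans index. Stops when `R >= 1 - tolerance` or when only
#' `min_points` remain. Deterministic; exact duplicates are removed first.
#'
#' @param points two-column matrix of coordinates.
#' @param area reference window area (m^2).
#' @param tolerance stop once `R >= 1 - tolerance` (default 0.01).
#' @param min_points never thin below this many points (default 10, >= 3).
#' @param animal_id optional label.
#'
#' @return An object of class `thinning`: list with `retained` / `removed`
#'   (indices into the deduplicated input), `points` (retained coordinates),
#'   `R_trajectory` (R after deduplication and after each removal), `R`
#'   (final), `converged`, `area`, `animal_id`.
#' @export
thin_to_random <- function(points, area, tolerance = 0.01, min_points = 10L,
                           animal_id = NA) {
  if (min_points < 3L) stop("`min_points` must be at least 3")
  xy <- dedupe(points)
  n <- nrow(xy)
  if (n < 2L) stop("need at least 2 distinct points")
  D <- dist_inf(xy)
  alive <- rep(TRUE, n)
  r_now <- function() {
    d <- D[alive, alive, drop = FALSE]
    mean(apply(d, 1L, min)) * 2 * sqrt(sum(alive) / area)
  }
  mean_nn_without <- function(k) {
    keep <- alive
    keep[k] <- FALSE
    mean(apply(D[keep, keep, drop = FALSE], 1L, min))
  }
  R <- r_now()
  traj <- R
  while (R < 1 - tolerance && sum(alive) > min_points) {
    d <- D[alive, alive, drop = FALSE]
    idx <- which(alive)
    pos <- which(d == min(d), arr.ind = TRUE)[1L, ]
    i <- idx[pos[1L]]; j <- idx[pos[2L]]
    mi <- mean_nn_without(i); mj <- mean_nn_without(j)
    drop <- if (mi > mj) i else if (mj > mi) j else max(i, j)
    alive[drop] <- FALSE
    R <- r_now()
    traj <- c(traj, R)
  }
  structure(list(retained = which(alive), removed = which(!alive),
                 points = xy[alive, , drop = FALSE],
                 R_trajectory = traj, R = R,
                 converged = R >= 1 - tolerance,
                 area = area, animal_id = animal_id),
            class = "thinning")
}

#' @export
print.thinning <- function(x, ...) {
  cat(sprintf("thinning: animal %s, %d retained / %d removed, final R = %.3f%s\n",
              x$animal_id, length(x$retained), length(x$removed), x$R,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}
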
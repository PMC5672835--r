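#' Standardize EGV columns of an RU table
#'
#' Centres and scales every EGV column to mean 0, sd 1 over all study-area
#' RUs, so that marginality components are comparable across variables with
#' different units. Constant columns are dropped with a warning.
#'
#' @param rut RU table from [aggregate_to_ru()].
#' @return A numeric matrix (RU x EGV) with attributes `center`, `scale` and
#'   `ru_id` (row mapping back to the RU table).
#' @export
standardize_egv <- function(rut) {
  cols <- egv_columns(rut)
  X <- as.matrix(rut[, cols, drop = FALSE])
  sds <- apply(X, 2L, stats::sd)
  if (all(sds == 0)) stop("all EGV columns are constant")
  if (any(sds == 0)) {
    warning("dropping constant EGV column(s): ",
            paste(cols[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  Z <- scale(X)
  structure(Z[, , drop = FALSE],
            center = attr(Z, "scaled:center"),
            scale = attr(Z, "scaled:scale"),
            ru_id = rut$ru_id)
}

## rows of the standardized table for a set of RU ids (multiset allowed)
z_rows <- function(z, ru_ids) {
  idx <- match(ru_ids, attr(z, "ru_id"))
  if (anyNA(idx)) stop("RU id(s) not present in the standardized table")
  z[idx, , drop = FALSE]
}

#' Marginality vector of one animal
#'
#' The marginality vector is the difference between the mean standardized
#' habitat conditions at the RUs an animal used and the mean over the RUs
#' available to it; its squared norm measures selection strength.
#'
#' @param used_ids RU ids used by the animal (a multiset: repeat visits
#'   count).
#' @param available_ids RU ids available to the animal.
#' @param z standardized EGV matrix from [standardize_egv()].
#' @param animal_id,period optional labels.
#'
#' @return An object of class `marginality`: list with `m` (named vector),
#'   `norm2` (squared norm), `n_used`, `n_available`, labels.
#' @export
marginality <- function(used_ids, available_ids, z, animal_id = NA,
                        period = NA) {
  if (!length(used_ids)) stop("no used RUs")
  if (!length(available_ids)) stop("empty availability")
  if (!all(unique(used_ids) %in% available_ids))
    stop(sprintf("animal %s: used RUs outside availability", animal_id))
  m <- colMeans(z_rows(z, used_ids)) - colMeans(z_rows(z, available_ids))
  structure(list(m = m, norm2 = sum(m^2), n_used = length(used_ids),
                 n_available = length(available_ids),
                 animal_id = animal_id, period = period),
            class = "marginality")
}

#' Eigenanalysis of the marginality table
#'
#' Non-centred weighted eigen-decomposition of `C = sum_k w_k m_k m_k'`,
#' summarizing the habitat selection common to a set of animals. The sum of
#' the eigenvalues equals the weighted mean squared marginality, so each
#' axis's share is read as "percent of mean marginality explained".
#'
#' @param marg list of [marginality()] objects (equal-length vectors).
#' @param weights animal weights, non-negative, summing to 1; default uniform.
#'   Weighting by relocation count (`weights = "n_used"`) is also supported.
#'
#' @return An object of class `kselect`: list with `eigenvalues` (descending),
#'   `percent`, `loadings` (EGV x axis, orthonormal columns), `scores`
#'   (animal x axis projections of the marginality vectors), `weights`,
#'   `marginality` (the input vectors as a matrix).
#' @export
kselect <- function(marg, weights = NULL) {
  K <- length(marg)
  if (!K) stop("need at least one marginality vector")
  M <- do.call(rbind, lapply(marg, `[[`, "m"))
  rownames(M) <- vapply(marg, function(x) as.character(x$animal_id), "")
  if (is.null(weights)) weights <- rep(1 / K, K)
  else if (identical(weights, "n_used")) {
    n <- vapply(marg, `[[`, 0L, "n_used")
    weights <- n / sum(n)
  }
  if (length(weights) != K || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8)
    stop("`weights` must be K non-negative values summing to 1")
  C <- crossprod(M * sqrt(weights))          # sum_k w_k m_k m_k'
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  structure(list(eigenvalues = ev, percent = 100 * ev / sum(ev),
                 loadings = e$vectors, scores = M %*% e$vectors,
                 weights = weights, marginality = M),
            class = "kselect")
}

#' @export
print.kselect <- function(x, ...) {
  cat(sprintf("K-select eigenanalysis of %d marginality vectors (%d EGVs)\n",
              nrow(x$marginality), ncol(x$marginality)))
  k <- min(4L, length(x$eigenvalues))
  cat(sprintf("  first eigenvalues: %s\n",
              paste(sprintf("%.3f (%.1f%%)", x$eigenvalues[1:k],
                            x$percent[1:k]), collapse = ", ")))
  invisible(x)
}

## null squared marginalities from random re-allocation of used RUs
null_norm2 <- function(z, available_ids, n_used, N) {
  za <- z_rows(z, available_ids)
  mu_avail <- colMeans(za)
  na <- nrow(za)
  vapply(seq_len(N), function(r) {
    idx <- sample.int(na, n_used)
    sum((colMeans(za[idx, , drop = FALSE]) - mu_avail)^2)
  }, 0)
}

#' Randomization test of one animal's marginality
#'
#' Tests the observed squared marginality against the null of random habitat
#' use: each of `N` randomizations draws `n_used` RUs without replacement
#' from the animal's available RUs (equi-probable allocation) and recomputes
#' the squared marginality. The p-value uses the add-one estimator
#' `(1 + #
#' exceedances) / (N + 1)`, so its floor at `N = 10000` is
#' `1/10001 ~= 0.000099`; ties count as exceedances.
#'
#' @param marg a [marginality()] object.
#' @param available_ids the animal's available RU ids (or a global
#'   availability set, if randomization over the whole study area is wanted).
#' @param z standardized EGV matrix.
#' @param N number of randomizations (default 10000).
#' @param seed optional integer seed for reproducibility.
#'
#' @return list with `p_value`, `observed` (observed squared marginality),
#'   `null` (the N randomized squared marginalities), `N`.
#' @export
marginality_randomization <- function(marg, available_ids, z, N = 10000L,
                                      seed = NULL) {
  n_used <- marg$n_used
  if (n_used >= length(available_ids))
    stop("randomization requires fewer used than available RUs")
  if (!is.null(seed)) set.seed(seed)
  null <- null_norm2(z, available_ids, n_used, N)
  list(p_value = (1 + sum(null >= marg$norm2)) / (N + 1),
       observed = marg$norm2, null = null, N = N)
}

#' Randomization test of the first K-select eigenvalue
#'
#' Each randomization redraws every animal's used RUs simultaneously (without
#' replacement, from that animal's availability), recomputes all marginality
#' vectors and the first eigenvalue of their weighted eigenanalysis. Add-one
#' p-value as in [marginality_randomization()].
#'
#' @param marg list of [marginality()] objects.
#' @param avail_list list of available RU id vectors, one per animal.
#' @param z standardized EGV matrix.
#' @param weights as in [kselect()].
#' @param N number of randomizations.
#' @param seed optional integer seed.
#'
#' @return list with `p_value`, `observed` (observed first eigenvalue),
#'   `null`, `N`.
#' @export
first_eigenvalue_test <- function(marg, avail_list, z, weights = NULL,
                                  N = 1000L, seed = NULL) {
  K <- length(marg)
  if (length(avail_list) != K) stop("one availability set per animal required")
  for (k in seq_len(K))
    if (marg[[k]]$n_used >= length(avail_list[[k]]))
      stop("randomization requires fewer used than available RUs (animal ",
           marg[[k]]$animal_id, ")")
  obs <- kselect(marg, weights)$eigenvalues[1]
  if (!is.null(seed)) set.seed(seed)
  za <- lapply(avail_list, function(a) z_rows(z, a))
  mu <- lapply(za, colMeans)
  n_used <- vapply(marg, `[[`, 0L, "n_used")
  w <- if (is.null(weights)) rep(1 / K, K)
       else if (identical(weights, "n_used")) n_used / sum(n_used)
       else weights
  null <- vapply(seq_len(N), function(r) {
    M <- do.call(rbind, lapply(seq_len(K), function(k) {
      idx <- sample.int(nrow(za[[k]]), n_used[k])
      colMeans(za[[k]][idx, , drop = FALSE]) - mu[[k]]
    }))
    max(eigen(crossprod(M * sqrt(w)), symmetric = TRUE,
              only.values = TRUE)$values)
  }, 0)
  list(p_value = (1 + sum(null >= obs)) / (N + 1), observed = obs,
       null = null, N = N)
}

#' Bonferroni-adjusted per-test level for K simultaneous tests
#'
#' @param K number of animals tested.
#' @param alpha family-wise level (default 0.05).
#' @return `alpha / K`.
#' @export
bonferroni_alpha <- function(K, alpha = 0.05) {
  if (K < 1) stop("K must be >= 1")
  alpha / K
}
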
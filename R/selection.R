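#' Manly selection ratios for one animal (individual availability design)
#'
#' Use and availability are measured for each animal separately: the selection
#' ratio for category i is the used proportion divided by the animal's own
#' available proportion, and the per-animal log-likelihood chi-square tests
#' proportional use.
#'
#' @param u named integer vector of used counts per category.
#' @param pi named numeric vector of available proportions (same categories,
#'   sums to 1 over the animal's availability).
#' @param animal_id label for error messages.
#'
#' @return list with `w` (ratios, `NA` where the category is unavailable),
#'   `chi2` (log-likelihood statistic `2 * sum u log(u / (u+ pi))`), `df`
#'   (number of available categories minus 1), `n_used`.
#' @export
selection_ratios <- function(u, pi, animal_id = NA) {
  if (length(u) != length(pi)) stop("`u` and `pi` differ in length")
  if (any(u < 0) || any(u != round(u))) stop("used counts must be non-negative integers")
  if (any(pi < 0)) stop("available proportions must be non-negative")
  bad <- u > 0 & pi == 0
  if (any(bad))
    stop(sprintf("animal %s: category %s used but unavailable (pi = 0)",
                 animal_id, paste(names(u)[bad], collapse = ", ")))
  utot <- sum(u)
  if (utot <= 0) stop(sprintf("animal %s: no used locations", animal_id))
  avail <- pi > 0
  w <- rep(NA_real_, length(u))
  names(w) <- names(u)
  w[avail] <- (u[avail] / utot) / pi[avail]
  pos <- u > 0
  chi2 <- 2 * sum(u[pos] * log(u[pos] / (utot * pi[pos])))
  list(w = w, chi2 = chi2, df = sum(avail) - 1L, n_used = utot)
}

#' Pooled (global) Manly selection ratios across animals
#'
#' Pools individual use-availability data: the global ratio for category i is
#' the total used count divided by the availability-weighted expected count,
#' `sum_j u_ij / sum_j u_+j pi_ij`, over the animals for which the category is
#' available. The global log-likelihood chi-square is the sum of the
#' per-animal statistics, with `df = sum_j (I_j - 1)` where `I_j` counts the
#' categories available to animal j. Confidence intervals use the
#' among-animal variance of the individual ratios with a Bonferroni-adjusted
#' normal quantile across categories.
#'
#' @param u_list list (one element per animal) of named used-count vectors
#'   over a shared category universe.
#' @param pi_list list of matching available-proportion vectors.
#' @param alpha family-wise error level for the Bonferroni intervals
#'   (default 0.05).
#' @param animal_ids optional labels.
#'
#' @return An object of class `selection_table`: list with `table` (per
#'   category: `w`, `se`, `ci_low`, `ci_high`, `n_animals`, `classification`
#'   in selected/proportional/avoided), `w_individual` (animal x category
#'   matrix), `chi2`, `df`, `p_value`, `alpha_bonferroni` (the per-test level
#'   `alpha / I`), `flagged_animals` (those with fewer than 5 used locations).
#' @export
global_selection_ratios <- function(u_list, pi_list, alpha = 0.05,
                                    animal_ids = NULL) {
  K <- length(u_list)
  if (K == 0L || length(pi_list) != K)
    stop("need matching non-empty `u_list` and `pi_list`")
  if (is.null(animal_ids)) animal_ids <- names(u_list)
  if (is.null(animal_ids)) animal_ids <- as.character(seq_len(K))
  cats <- names(u_list[[1]])
  I <- length(cats)

  per <- lapply(seq_len(K), function(j)
    selection_ratios(u_list[[j]], pi_list[[j]], animal_id = animal_ids[j]))
  w_ind <- do.call(rbind, lapply(per, `[[`, "w"))
  rownames(w_ind) <- animal_ids
  u_mat <- do.call(rbind, u_list)
  pi_mat <- do.call(rbind, pi_list)
  utot <- rowSums(u_mat)

  w <- se <- rep(NA_real_, I)
  k_i <- integer(I)
  for (i in seq_len(I)) {
    aj <- pi_mat[, i] > 0
    k_i[i] <- sum(aj)
    if (k_i[i] == 0L) next
    w[i] <- sum(u_mat[aj, i]) / sum(utot[aj] * pi_mat[aj, i])
    if (k_i[i] >= 2L)
      se[i] <- stats::sd(w_ind[aj, i]) / sqrt(k_i[i])
  }
  z <- stats::qnorm(1 - alpha / (2 * I))
  ci_low <- w - z * se
  ci_high <- w + z * se
  classification <- rep("proportional", I)
  classification[!is.na(ci_low) & ci_low > 1] <- "selected"
  classification[!is.na(ci_high) & ci_high < 1 & !is.na(ci_low) & ci_low > 0] <- "avoided"
  classification[is.na(w)] <- NA_character_

  chi2 <- sum(vapply(per, `[[`, 0, "chi2"))
  df <- sum(vapply(per, `[[`, 0L, "df"))
  structure(list(
    table = data.frame(category = cats, w = w, se = se,
                       ci_low = ci_low, ci_high = ci_high,
                       n_animals = k_i, classification = classification),
    w_individual = w_ind,
    chi2 = chi2, df = df,
    p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
    alpha = alpha, alpha_bonferroni = alpha / I,
    flagged_animals = animal_ids[vapply(per, `[[`, 0, "n_used") < 5]),
    class = "selection_table")
}

#' @export
print.selection_table <- function(x, ...) {
  cat(sprintf("Pooled selection ratios: chi2 = %.2f, df = %d, p = %.3g\n",
              x$chi2, x$df, x$p_value))
  print(x$table, row.names = FALSE)
  if (length(x$flagged_animals))
    cat("flagged (< 5 used locations):",
        paste(x$flagged_animals, collapse = ", "), "\n")
  invisible(x)
}

#' Pooled selection ratios within groups (e.g. sex or period)
#'
#' @inheritParams global_selection_ratios
#' @param groups character/factor vector, one label per animal.
#' @return Named list of `selection_table`s, one per group level.
#' @export
group_selection_ratios <- function(u_list, pi_list, groups, alpha = 0.05,
                                   animal_ids = NULL) {
  K <- length(u_list)
  if (length(groups) != K) stop("`groups` must label every animal")
  if (anyNA(groups)) stop("unknown (NA) group label")
  if (is.null(animal_ids)) animal_ids <- names(u_list)
  if (is.null(animal_ids)) animal_ids <- as.character(seq_len(K))
  lapply(split(seq_len(K), groups), function(idx)
    global_selection_ratios(u_list[idx], pi_list[idx], alpha = alpha,
                            animal_ids = animal_ids[idx]))
}
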
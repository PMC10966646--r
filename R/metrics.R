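#' Number of compounds in the top k% of a pool
#'
#' Rounds `r * n_total` half-up to the nearest integer (never below 1). For a
#' pool of 9997 compounds this gives 500 at 5% and 200 at 2%.
#'
#' @param n_total Pool size.
#' @param r Active fraction in (0, 1), typically 0.02 or 0.05.
#' @return An integer count, at least 1.
#' @examples
#' top_k_count(9997, 0.05)
#' top_k_count(665, 0.02)
#' @export
top_k_count <- function(n_total, r) {
  n_total <- check_count(n_total, "n_total")
  r <- check_number(r, "r", min = 0, strict = TRUE)
  if (r >= 1) abort("`r` must be a fraction in (0, 1).")
  max(1L, as.integer(round_half_up(r * n_total)))
}

#' Define the top-k active set of a pool
#'
#' Labels the `top_k_count(n, r)` compounds with the highest true potency as
#' "active"; potency ties at the boundary are broken by ascending id so the
#' set is deterministic. Recall and F1 of an acquired compound set are always
#' scored against this noiseless active set, even when training labels are
#' noisy.
#'
#' @param pool A [compound_pool()] (or any data frame with `id` and `potency`).
#' @param r Active fraction in (0, 1).
#' @return An object of class `top_k_spec` with fields `r`, `n_total`, `k`
#'   and `active_ids`.
#' @export
top_k_spec <- function(pool, r) {
  if (!all(c("id", "potency") %in% names(pool))) {
    abort("`pool` must have `id` and `potency` columns.")
  }
  n_total <- nrow(pool)
  k <- top_k_count(n_total, r)
  ord <- order(-pool$potency, pool$id)
  structure(list(r = r, n_total = n_total, k = k,
                 active_ids = pool$id[ord][seq_len(k)]),
            class = "top_k_spec")
}

check_spec <- function(spec) {
  if (!inherits(spec, "top_k_spec")) {
    abort("`spec` must be created with top_k_spec().")
  }
  if (length(spec$active_ids) == 0) abort("Empty active set.")
  spec
}

#' Top-k recall of an acquired compound set
#'
#' The fraction of the true top-k% binders contained in the acquired set:
#' `TP / k` with `TP = |acquired intersect active|` and `k` the integer
#' active-set size, so recall reaches exactly 1 once every active compound
#' has been acquired.
#'
#' @param acquired_ids Character vector of acquired compound ids.
#' @param spec A [top_k_spec()].
#' @return A fraction in \[0, 1\].
#' @export
recall_topk <- function(acquired_ids, spec) {
  spec <- check_spec(spec)
  sum(spec$active_ids %in% acquired_ids) / spec$k
}

#' Top-k F1 score of an acquired compound set
#'
#' Treating acquisition as classification (acquired = predicted positive,
#' top-k = actually positive), the confusion counts obey
#' `N_acq = TP + FP` and `k = TP + FN`, so
#' `F1 = 2 TP / (N_acq + k)`.
#'
#' @inheritParams recall_topk
#' @return A fraction in \[0, 1\].
#' @export
f1_topk <- function(acquired_ids, spec) {
  spec <- check_spec(spec)
  n_acq <- length(unique(acquired_ids))
  if (n_acq + spec$k == 0) abort("F1 undefined: no acquisitions and empty active set.")
  tp <- sum(spec$active_ids %in% acquired_ids)
  2 * tp / (n_acq + spec$k)
}

#' Expected true positives under random acquisition
#'
#' Acquiring `n_acq` compounds uniformly at random from a pool in which a
#' fraction `r` is active yields `r * n_acq` true positives in expectation;
#' this is the baseline that model-guided acquisition must beat.
#'
#' @param r Active fraction.
#' @param n_acq Number of compounds acquired.
#' @return The expected number of true positives (real-valued).
#' @export
random_baseline_tp <- function(r, n_acq) {
  r <- check_number(r, "r", min = 0)
  n_acq <- check_number(n_acq, "n_acq", min = 0)
  r * n_acq
}

#' Regression metrics for potency predictions
#'
#' Coefficient of determination `R2 = 1 - SS_res / SS_tot`, Spearman rank
#' correlation (average ranks on ties) and root-mean-square error. With a
#' constant observed vector R2 and Spearman are undefined and returned as
#' `NA` (with a warning); the RMSE is still reported.
#'
#' @param predicted,observed Numeric vectors of equal length (at least 2).
#' @return A one-row tibble with columns `r2`, `spearman_rho`, `rmse`.
#' @examples
#' regression_metrics(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
#' @export
regression_metrics <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    abort("`predicted` and `observed` must have equal length.")
  }
  if (length(observed) < 2) abort("At least 2 observations are required.")
  if (any(!is.finite(predicted)) || any(!is.finite(observed))) {
    abort("All predictions and observations must be finite.")
  }
  rmse <- sqrt(mean((predicted - observed)^2))
  if (sd(observed) == 0) {
    warn("Constant observed values: R2 and Spearman rho are undefined.")
    return(tibble::tibble(r2 = NA_real_, spearman_rho = NA_real_, rmse = rmse))
  }
  ss_res <- sum((observed - predicted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  rho <- if (sd(predicted) == 0) NA_real_ else cor(predicted, observed, method = "spearman")
  tibble::tibble(r2 = 1 - ss_res / ss_tot, spearman_rho = rho, rmse = rmse)
}
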
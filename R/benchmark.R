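#' Benchmark a surrogate with disjoint small-train folds
#'
#' Estimates a surrogate's predictive ceiling on a pool: the pool is split
#' into `n_folds` disjoint partitions; each fold trains on one partition
#' (a fraction `train_fraction` of the data, 20% by default) and evaluates on
#' the remaining 80%. This "small train, large test" orientation mirrors the
#' active-learning setting, where only a few hundred labels are ever
#' acquired. Per fold, the regression metrics (R2, Spearman rho, RMSE) are
#' computed over the whole test side, and top-2%/5% recall is computed
#' within the test set: the surrogate's top-k predicted compounds are
#' compared against the test set's true top-k. The summary reports the mean
#' and a t-based 95% confidence interval across folds.
#'
#' @param pool A [compound_pool()] with fingerprints.
#' @param surrogate An `al_surrogate`, e.g. [gp_surrogate()].
#' @param train_fraction Fraction of the pool used to train each fold; must
#'   equal `1 / n_folds` so the train partitions are disjoint.
#' @param n_folds Number of folds.
#' @param seed Integer seed for the partition.
#' @return An object of class `al_benchmark` with `folds` (per-fold metrics)
#'   and `summary` (per metric: mean, ci_low, ci_high). [tidy()] returns the
#'   folds, [glance()] a one-row summary of means.
#' @examples
#' \donttest{
#' pool <- generate_library(scenario_preset("small-diverse"))
#' bench <- benchmark_split(pool, gp_surrogate(), seed = 1)
#' glance(bench)
#' }
#' @export
benchmark_split <- function(pool, surrogate = gp_surrogate(),
                            train_fraction = 0.2, n_folds = 5L, seed = 1L) {
  if (!inherits(surrogate, "al_surrogate")) abort("`surrogate` must be an al_surrogate.")
  n_folds <- check_count(n_folds, "n_folds", min = 2)
  train_fraction <- check_number(train_fraction, "train_fraction", min = 0, strict = TRUE)
  if (abs(train_fraction * n_folds - 1) > 1e-8) {
    abort("Disjoint train partitions require train_fraction = 1 / n_folds.")
  }
  n <- nrow(pool)
  if (floor(n / n_folds) < 2) {
    abort(sprintf("Pool of %d is too small for %d folds with >= 2 training compounds each.",
                  n, n_folds))
  }
  perm <- local_seed_eval(seed, sample.int(n))
  fold_of <- integer(n)
  fold_of[perm] <- rep(seq_len(n_folds), length.out = n)

  S_pool <- if (isTRUE(surrogate$needs_fingerprints)) tanimoto_matrix(pool_fingerprints(pool))

  folds <- purrr::map_dfr(seq_len(n_folds), function(f) {
    train_idx <- which(fold_of == f)
    test_idx <- which(fold_of != f)
    model <- surrogate$fit(pool, train_idx, pool$potency[train_idx],
                           similarity = if (!is.null(S_pool)) S_pool[train_idx, train_idx, drop = FALSE],
                           seed = seed)
    post <- surrogate$predict(model, pool, test_idx,
                              cross_similarity = if (!is.null(S_pool)) S_pool[train_idx, test_idx, drop = FALSE])
    reg <- regression_metrics(post$mean, pool$potency[test_idx])
    test_pool <- tibble::tibble(id = pool$id[test_idx], potency = pool$potency[test_idx])
    recall_at <- function(r) {
      spec <- top_k_spec(test_pool, r)
      picked <- test_pool$id[order(-post$mean, test_pool$id)][seq_len(spec$k)]
      recall_topk(picked, spec)
    }
    tibble::tibble(fold = f, n_train = length(train_idx), n_test = length(test_idx),
                   r2 = reg$r2, spearman = reg$spearman_rho, rmse = reg$rmse,
                   recall_top2 = recall_at(0.02), recall_top5 = recall_at(0.05))
  })

  metric_cols <- c("r2", "spearman", "rmse", "recall_top2", "recall_top5")
  summary <- folds |>
    tidyr::pivot_longer(dplyr::all_of(metric_cols),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value),
      ci_low = mean(.data$value) - qt(0.975, dplyr::n() - 1) * sd(.data$value) / sqrt(dplyr::n()),
      ci_high = mean(.data$value) + qt(0.975, dplyr::n() - 1) * sd(.data$value) / sqrt(dplyr::n()),
      .groups = "drop")

  structure(list(folds = folds, summary = summary,
                 config = list(train_fraction = train_fraction, n_folds = n_folds,
                               surrogate = surrogate$label, seed = seed)),
            class = "al_benchmark")
}

#' @export
print.al_benchmark <- function(x, ...) {
  cat(sprintf("%d-fold benchmark (train %d%%, test %d%%), surrogate '%s':\n",
              x$config$n_folds, round(100 * x$config$train_fraction),
              round(100 * (1 - x$config$train_fraction)), x$config$surrogate))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-12s %.3f (95%% CI %.3f-%.3f)\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$ci_low[i], x$summary$ci_high[i]))
  }
  invisible(x)
}

#' Tidy a fold benchmark
#'
#' @param x An `al_benchmark` from [benchmark_split()].
#' @param ... Unused.
#' @return `tidy()`: per-fold metrics. `glance()`: one row of across-fold
#'   means.
#' @method tidy al_benchmark
#' @export
tidy.al_benchmark <- function(x, ...) x$folds

#' @rdname tidy.al_benchmark
#' @method glance al_benchmark
#' @export
glance.al_benchmark <- function(x, ...) {
  means <- setNames(as.list(x$summary$mean), x$summary$metric)
  tibble::as_tibble(means)
}
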
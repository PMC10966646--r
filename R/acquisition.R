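#' Select a batch of compounds for labeling
#'
#' The three batch-selection strategies used in every active-learning cycle:
#'
#' * `"exploit"`: the `batch_size` candidates with the highest posterior mean
#'   (highest predicted potency), exhausting high-potency regions.
#' * `"explore"`: the `batch_size` candidates with the highest posterior
#'   variance (largest prediction uncertainty), sampling chemical space
#'   broadly. Variance and standard deviation rank identically.
#' * `"random"`: a uniform draw without replacement under `seed`.
#'
#' Ties (and the ordering within a random draw's result) are broken by
#' ascending id, so identical requests return identical batches.
#'
#' @param candidates A tibble of unlabeled candidates with an `id` column
#'   and, for the model-guided strategies, `mean` and `variance` columns as
#'   returned by [predict.tanimoto_gp()].
#' @param strategy One of `"random"`, `"explore"`, `"exploit"`.
#' @param batch_size Number of compounds to select (at most `nrow(candidates)`).
#' @param seed Integer seed for the random strategy; may be `NULL` to draw
#'   from the current RNG stream.
#' @return A character vector of exactly `batch_size` distinct candidate ids,
#'   in selection order.
#' @examples
#' cand <- tibble::tibble(id = c("a", "b", "c"), mean = c(1, 3, 2),
#'                        variance = c(0.5, 0.2, 0.9))
#' select_batch(cand, "exploit", 1)
#' select_batch(cand, "explore", 2)
#' @export
select_batch <- function(candidates, strategy = c("random", "explore", "exploit"),
                         batch_size, seed = NULL) {
  strategy <- match.arg(strategy)
  if (!"id" %in% names(candidates)) abort("`candidates` must have an `id` column.")
  ids <- as.character(candidates$id)
  if (anyDuplicated(ids)) abort("Candidate ids must be distinct.")
  batch_size <- check_count(batch_size, "batch_size")
  if (batch_size > length(ids)) {
    abort(sprintf("batch_size (%d) exceeds the number of candidates (%d).",
                  batch_size, length(ids)))
  }
  if (strategy != "random") {
    if (!all(c("mean", "variance") %in% names(candidates))) {
      abort(sprintf("Strategy '%s' needs posterior `mean` and `variance` columns.", strategy))
    }
    score <- if (strategy == "exploit") candidates$mean else candidates$variance
    if (any(!is.finite(score))) abort("Posterior scores must be finite.")
    return(ids[order(-score, ids)][seq_len(batch_size)])
  }
  draw <- function() sort(sample(ids, batch_size))
  if (is.null(seed)) draw() else local_seed_eval(seed, draw())
}
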
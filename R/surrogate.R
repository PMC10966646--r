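# Surrogate interface: a surrogate spec is a list with
#   fit(pool, train_idx, labels, similarity, seed) -> fitted model
#   predict(model, pool, query_idx, cross_similarity) -> tibble(mean, variance)
#   needs_fingerprints: flag telling the driver to precompute the pool
#     Tanimoto matrix once and pass submatrices into fit/predict
# Any regressor returning a predictive mean and variance can implement it
# (e.g. a dropout or ensemble neural network), which is what makes the
# benchmark model-agnostic.

#' Gaussian-process surrogate specification
#'
#' Wraps [fit_gp()]/[predict.tanimoto_gp()] in the surrogate interface used
#' by [run_campaign()] and [benchmark_split()]. The driver precomputes the
#' pool's Tanimoto matrix once per campaign and feeds submatrices to the fit
#' and predict steps, so the kernel is never recomputed inside the cycle
#' loop.
#'
#' @param hyper `"optimize"` (maximize the marginal likelihood each retrain)
#'   or a fixed [gp_hyperparams()] object.
#' @param init Initial hyperparameters for optimization.
#' @param fix Hyperparameter names to hold fixed during optimization.
#' @return An object of class `al_surrogate`.
#' @seealso [oracle_surrogate()]
#' @export
gp_surrogate <- function(hyper = "optimize", init = gp_hyperparams(),
                         fix = character()) {
  structure(list(
    label = "gp",
    needs_fingerprints = TRUE,
    fit = function(pool, train_idx, labels, similarity = NULL, seed = NULL) {
      fp <- pool_fingerprints(pool)[train_idx, , drop = FALSE]
      fit_gp(fp, labels, hyper = hyper, init = init, fix = fix,
             similarity = similarity)
    },
    predict = function(model, pool, query_idx, cross_similarity = NULL) {
      fp <- pool_fingerprints(pool)[query_idx, , drop = FALSE]
      predict(model, fp, cross_similarity = cross_similarity)
    }),
    class = "al_surrogate")
}

#' Perfect-oracle surrogate
#'
#' A surrogate that "predicts" each compound's true potency exactly, with
#' zero variance. It establishes the performance ceiling of an acquisition
#' protocol (pure exploitation with this surrogate recovers the entire
#' top-k set as soon as the budget allows) and is useful for testing the
#' driver independently of any model.
#'
#' @return An object of class `al_surrogate`.
#' @export
oracle_surrogate <- function() {
  structure(list(
    label = "oracle",
    needs_fingerprints = FALSE,
    fit = function(pool, train_idx, labels, similarity = NULL, seed = NULL) {
      list(trained_on = train_idx)
    },
    predict = function(model, pool, query_idx, cross_similarity = NULL) {
      tibble::tibble(mean = pool$potency[query_idx],
                     variance = rep(0, length(query_idx)))
    }),
    class = "al_surrogate")
}
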